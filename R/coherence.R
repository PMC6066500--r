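# Epoch-averaged magnitude-squared coherence between ROI lead sets.
#
# Estimator: per-epoch Hann-windowed periodograms, averaged across kept
# epochs (Welch across epochs); 1-s epochs fix a 1 Hz bin spacing. Band
# values are arithmetic means of per-bin msc over all bins with
# f_lo <= f <= f_hi (endpoints inclusive).

#' Standard frequency bands
#'
#' Conventional EEG band edges in Hz: delta 1-4, theta 4-8, alpha 8-13,
#' low beta 13-20, high beta 20-30 (the primary band of the analysis).
#'
#' @return named list of `c(f_lo, f_hi)` pairs
#' @export
default_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       low_beta = c(13, 20), high_beta = c(20, 30))
}

pair_key <- function(i, j) paste(i, j, sep = "|")

#' Estimate auto- and cross-spectra from kept epochs
#'
#' Computes, for every lead involved in `lead_pairs`, the per-epoch
#' Hann-windowed FFT, and averages the per-epoch auto- and cross-
#' periodograms across kept epochs. Cross-spectra are computed lazily for
#' the requested pairs only; results are identical to a full cross-spectral
#' matrix restricted to those pairs.
#'
#' @param ep `fpcoh_epochs` with at least 2 kept epochs
#' @param lead_pairs list of length-2 character vectors of lead ids
#' @param max_freq highest frequency bin retained, Hz (default 50, the
#'   analysis ceiling)
#' @return object of class `fpcoh_spectra`: `freqs` (Hz bin centers),
#'   `auto` (bin x lead real matrix), `cross` (named list of complex
#'   per-bin vectors keyed `"i|j"`), `n_epochs`
#' @export
estimate_spectra <- function(ep, lead_pairs, max_freq = 50) {
  M <- sum(ep$kept_mask)
  if (M < 2) stop("coherence needs at least 2 kept epochs (undefined at M=1)")
  leads <- unique(unlist(lead_pairs))
  lead_ids <- dimnames(ep$epochs)[[1]]
  bad <- setdiff(leads, lead_ids)
  if (length(bad)) stop("unknown leads: ", paste(bad, collapse = ", "))
  L <- dim(ep$epochs)[2]
  keep <- which(ep$kept_mask)
  nbin <- floor(L / 2) - 1L           # DC and Nyquist excluded
  nbin <- min(nbin, as.integer(floor(max_freq * ep$epoch_len_s)))
  freqs <- seq_len(nbin) / ep$epoch_len_s
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(L) / L)  # Hann
  Fhat <- vector("list", length(leads)); names(Fhat) <- leads
  auto <- matrix(0, nbin, length(leads), dimnames = list(NULL, leads))
  for (ld in leads) {
    seg <- matrix(ep$epochs[ld, , keep], nrow = L) * w
    Fl <- stats::mvfft(seg)[2L:(nbin + 1L), , drop = FALSE]
    Fhat[[ld]] <- Fl
    auto[, ld] <- rowMeans(Re(Fl * Conj(Fl)))
  }
  cross <- list()
  for (pr in lead_pairs) {
    key <- pair_key(pr[1], pr[2])
    if (is.null(cross[[key]]))
      cross[[key]] <- rowMeans(Fhat[[pr[1]]] * Conj(Fhat[[pr[2]]]))
  }
  structure(list(freqs = freqs, auto = auto, cross = cross, n_epochs = M),
            class = "fpcoh_spectra")
}

get_cross <- function(spec, i, j) {
  key <- pair_key(i, j)
  if (!is.null(spec$cross[[key]])) return(spec$cross[[key]])
  rkey <- pair_key(j, i)
  if (!is.null(spec$cross[[rkey]])) return(Conj(spec$cross[[rkey]]))
  stop("cross-spectrum for pair (", i, ",", j, ") was not estimated")
}

#' Band-averaged magnitude-squared coherence between two leads
#'
#' Per-bin msc is `|S_ij|^2 / (S_ii * S_jj)`; the band value is the mean
#' over all bins whose center frequency lies in `[f_lo, f_hi]` (endpoints
#' inclusive; at 1 Hz spacing the 20-30 Hz band spans 11 bins).
#'
#' @param spec `fpcoh_spectra`
#' @param i,j lead ids
#' @param band numeric `c(f_lo, f_hi)` in Hz
#' @return msc in `[0, 1]`
#' @export
msc <- function(spec, i, j, band) {
  bins <- which(spec$freqs >= band[1] & spec$freqs <= band[2])
  if (length(bins) == 0) stop("band [", band[1], ",", band[2],
                              "] contains no frequency bins")
  sii <- spec$auto[bins, i]
  sjj <- spec$auto[bins, j]
  if (any(sii <= 0) || any(sjj <= 0)) {
    bad <- spec$freqs[bins][which(sii <= 0 | sjj <= 0)[1]]
    stop("zero auto-power at ", bad, " Hz: coherence undefined")
  }
  if (identical(i, j)) return(1)
  sij <- get_cross(spec, i, j)[bins]
  mean(Mod(sij)^2 / (sii * sjj))
}

roi_lead_pairs <- function(rois, pair) {
  a <- rois$rois[[pair[1]]]; b <- rois$rois[[pair[2]]]
  if (is.null(a) || is.null(b))
    stop("undefined ROI in pair: ", paste(pair, collapse = "-"))
  prs <- expand.grid(i = a, j = b, stringsAsFactors = FALSE)
  prs <- prs[prs$i != prs$j, , drop = FALSE]      # shared leads excluded
  if (nrow(prs) == 0) stop("ROI pair ", paste(pair, collapse = "-"),
                           " has no usable lead pairs")
  lapply(seq_len(nrow(prs)), function(k) c(prs$i[k], prs$j[k]))
}

#' Band coherence between two ROIs
#'
#' Mean msc over all cross-ROI lead pairs (one lead from each ROI;
#' identical leads excluded, so disjoint 7- and 21-lead ROIs give 147
#' pairs).
#'
#' @param spec `fpcoh_spectra` covering the needed lead pairs
#' @param rois `fpcoh_roiset`
#' @param pair length-2 character vector of ROI names
#' @param band numeric `c(f_lo, f_hi)` Hz
#' @return list with `coherence` and `n_lead_pairs`
#' @export
roi_pair_coherence <- function(spec, rois, pair, band) {
  prs <- roi_lead_pairs(rois, pair)
  vals <- vapply(prs, function(p) msc(spec, p[1], p[2], band), numeric(1))
  list(coherence = mean(vals), n_lead_pairs = length(prs))
}

#' Coherence table over all circuits and bands
#'
#' Estimates spectra once (for the union of needed lead pairs) and returns
#' band coherence for the primary ROI pair and every control pair, in every
#' configured band. With `aggregate = "roi_mean"` the msc is instead
#' computed between the ROI-averaged signals (a sensitivity-analysis
#' alternative to pair averaging).
#'
#' @param ep `fpcoh_epochs`
#' @param rois `fpcoh_roiset`
#' @param bands named list of band edges (default [default_bands()])
#' @param aggregate `"pairs"` (default) or `"roi_mean"`
#' @return data frame: roi_pair, band, coherence, n_epochs, n_lead_pairs
#' @export
coherence_table <- function(ep, rois, bands = default_bands(),
                            aggregate = c("pairs", "roi_mean")) {
  aggregate <- match.arg(aggregate)
  for (b in bands)
    if (b[1] < 1 || b[2] > 50 || b[1] >= b[2])
      stop("band edges must satisfy 1 <= f_lo < f_hi <= 50")
  circuits <- c(list(rois$primary_pair), rois$control_pairs)
  if (aggregate == "roi_mean") return(
    coherence_table_roi_mean(ep, rois, bands, circuits))
  all_pairs <- unique(do.call(c, lapply(circuits, roi_lead_pairs, rois = rois)))
  spec <- estimate_spectra(ep, all_pairs)
  rows <- list()
  for (circ in circuits) {
    for (bn in names(bands)) {
      rc <- roi_pair_coherence(spec, rois, circ, bands[[bn]])
      rows[[length(rows) + 1L]] <- data.frame(
        roi_pair = paste(circ, collapse = "-"), band = bn,
        coherence = rc$coherence, n_epochs = spec$n_epochs,
        n_lead_pairs = rc$n_lead_pairs)
    }
  }
  do.call(rbind, rows)
}

coherence_table_roi_mean <- function(ep, rois, bands, circuits) {
  # virtual leads: per-ROI mean signal, then lead-level msc between them
  roi_names <- unique(unlist(circuits))
  n_ep <- dim(ep$epochs)[3]
  L <- dim(ep$epochs)[2]
  virt <- array(0, dim = c(length(roi_names), L, n_ep),
                dimnames = list(roi_names, NULL, NULL))
  for (rn in roi_names) {
    leads <- rois$rois[[rn]]
    virt[rn, , ] <- apply(ep$epochs[leads, , , drop = FALSE], c(2, 3), mean)
  }
  vep <- structure(list(epochs = virt, fs = ep$fs,
                        epoch_len_s = ep$epoch_len_s,
                        kept_mask = ep$kept_mask, montage = NULL,
                        provenance = ep$provenance),
                   class = "fpcoh_epochs")
  spec <- estimate_spectra(vep, circuits)
  rows <- list()
  for (circ in circuits) {
    for (bn in names(bands)) {
      rows[[length(rows) + 1L]] <- data.frame(
        roi_pair = paste(circ, collapse = "-"), band = bn,
        coherence = msc(spec, circ[1], circ[2], bands[[bn]]),
        n_epochs = spec$n_epochs, n_lead_pairs = 1L)
    }
  }
  do.call(rbind, rows)
}

#' Write a per-subject coherence table as CSV
#' @param tab data frame from [coherence_table()]
#' @param subject_id subject identifier column value
#' @param path output CSV
#' @export
write_coherence_csv <- function(tab, subject_id, path) {
  out <- cbind(subject_id = subject_id, tab)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
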