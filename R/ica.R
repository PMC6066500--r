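# Infomax independent component analysis (extended variant) and the
# artifact-component rejection rules.

#' Infomax ICA decomposition of kept epochs
#'
#' Runs extended Infomax ICA (natural-gradient learning with a per-component
#' sub/super-Gaussian switch, so both spiky artifacts and near-sinusoidal
#' rhythms are separable) on the concatenation of kept epochs. The data are
#' first reduced to `n_components` principal components and whitened; the
#' square unmixing matrix is then learned on the whitened data. The result
#' is deterministic for a given seed (the seed drives the block order of the
#' stochastic gradient passes).
#'
#' Components are ordered by explained variance; sources are scaled to unit
#' variance, with sign fixed so each mixing column's largest-magnitude
#' weight is positive. With `n_components` equal to the data rank,
#' `mixing %*% sources` reconstructs the (centered) input to numerical
#' tolerance; with fewer components the reconstruction is the PCA-truncated
#' one.
#'
#' @param ep `fpcoh_epochs`
#' @param n_components number of components (default `min(n_leads, 64)`)
#' @param rng_seed integer seed (mandatory: the fit is stochastic-gradient)
#' @param max_iter maximum training passes (default 150)
#' @param tol stop when the squared weight change per pass falls below this
#'   (default 1e-8)
#' @param lrate initial learning rate (default 0.05; annealed each pass and
#'   halved on divergence)
#' @return object of class `fpcoh_ica`: `mixing` (lead x component),
#'   `sources` (component x sample, kept epochs concatenated), `rejected`
#'   logical, `reject_reason` character, plus fit metadata
#' @export
decompose_ica <- function(ep, n_components = NULL, rng_seed,
                          max_iter = 150, tol = 1e-8, lrate = NULL) {
  if (missing(rng_seed)) stop("rng_seed is mandatory for decompose_ica")
  X <- kept_epoch_matrix(ep)
  n_lead <- nrow(X); n_samp <- ncol(X)
  if (is.null(n_components)) n_components <- min(n_lead, 64L)
  n_components <- as.integer(n_components)
  if (n_samp < 3L * n_components * n_components)
    stop("too few kept samples (", n_samp, ") for ", n_components,
         " components; reduce n_components")
  row_means <- rowMeans(X)
  Xc <- X - row_means
  cv <- tcrossprod(Xc) / n_samp
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[n_components] < 1e-12 * eg$values[1])
    stop("data rank below ", n_components,
         " components; try fewer components")
  E <- eg$vectors[, seq_len(n_components), drop = FALSE]
  d <- eg$values[seq_len(n_components)]
  wh <- (t(E) / sqrt(d))            # whitening: comp x lead
  dewh <- E * rep(sqrt(d), each = n_lead)  # de-whitening: lead x comp
  Z <- wh %*% Xc                    # whitened data, comp x sample
  k <- n_components
  if (is.null(lrate)) lrate <- 0.05
  block <- as.integer(min(max(n_samp %/% 32L, 64L), 2048L))
  set.seed(as.integer(rng_seed %% .Machine$integer.max))
  W <- diag(k)
  I_k <- diag(k)
  signs <- rep(1, k)                # +1 super-Gaussian, -1 sub-Gaussian
  oldW <- W
  old_change <- Inf
  n_blocks <- floor(n_samp / block)
  for (it in seq_len(max_iter)) {
    perm <- sample.int(n_samp)
    for (b in seq_len(n_blocks)) {
      idx <- perm[((b - 1) * block + 1):(b * block)]
      u <- W %*% Z[, idx, drop = FALSE]
      tu <- tanh(u)
      grad <- I_k - (signs * tu) %*% t(u) / block - tcrossprod(u) / block
      W <- W + lrate * grad %*% W
      if (!all(is.finite(W)) || max(abs(W)) > 1e8) {
        W <- diag(k); oldW <- W; lrate <- lrate * 0.5
        break
      }
    }
    # re-estimate sub/super-Gaussian switch from full-data statistics
    U <- W %*% Z
    signs <- sign(rowMeans(1 - tanh(U)^2) * rowMeans(U^2) -
                    rowMeans(tanh(U) * U))
    signs[signs == 0] <- 1
    change <- sum((W - oldW)^2)
    if (is.finite(change) && change > old_change) lrate <- lrate * 0.9
    lrate <- lrate * 0.97                  # annealing schedule
    if (change < tol || lrate < 1e-6) break
    oldW <- W
    old_change <- change
  }
  S <- W %*% Z                              # comp x sample
  A <- dewh %*% solve(W)                    # lead x comp mixing
  # unit-variance sources, sign and order conventions
  sdS <- sqrt(rowMeans(S^2))
  sdS[sdS == 0] <- 1
  S <- S / sdS
  A <- A * rep(sdS, each = n_lead)
  sgn <- apply(A, 2, function(a) sign(a[which.max(abs(a))]))
  sgn[sgn == 0] <- 1
  A <- A * rep(sgn, each = n_lead)
  S <- S * sgn
  ord <- order(colSums(A^2), decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  S <- S[ord, , drop = FALSE]
  rownames(A) <- rownames(X)
  structure(list(mixing = A, sources = S, row_means = row_means,
                 n_components = k, fs = ep$fs, seed = rng_seed,
                 iterations = it,
                 rejected = rep(FALSE, k),
                 reject_reason = rep(NA_character_, k)),
            class = "fpcoh_ica")
}

component_band_power <- function(dec, f_lo, f_hi) {
  # per-component power in [f_lo, f_hi], Welch over 1-s segments
  fs <- dec$fs
  L <- as.integer(fs)
  n_seg <- floor(ncol(dec$sources) / L)
  vapply(seq_len(nrow(dec$sources)), function(i) {
    x <- dec$sources[i, seq_len(n_seg * L)]
    seg <- matrix(x, nrow = L)
    P <- abs(stats::mvfft(seg))^2
    freqs <- seq_len(floor(L / 2)) # 1 Hz bins, DC excluded
    psd <- rowMeans(P[freqs + 1L, , drop = FALSE])
    sum(psd[freqs >= f_lo & freqs <= f_hi])
  }, numeric(1))
}

#' Automatic artifact-component flagging
#'
#' Applies the two automatic rejection rules: (1) *single-channel*
#' components, whose scalp topography is dominated by one lead
#' (`max |weight| / sum |weights| > tau_single`); (2) *muscle-band*
#' components, whose source power is concentrated in the 35-50 Hz band
#' typical of muscle artifact (`power(35-50) / power(1-50) > tau_muscle`).
#' Both rules are applied independently; already-flagged components keep
#' their first reason.
#'
#' @param dec `fpcoh_ica`
#' @param tau_single topography-dominance threshold (default 0.8)
#' @param tau_muscle high-band power-fraction threshold (default 0.5)
#' @return `fpcoh_ica` with updated `rejected` / `reject_reason`
#' @export
auto_flag_components <- function(dec, tau_single = 0.8, tau_muscle = 0.5) {
  dom <- apply(abs(dec$mixing), 2, function(a) max(a) / sum(a))
  hi <- component_band_power(dec, 35, 50)
  tot <- component_band_power(dec, 1, 50)
  frac <- ifelse(tot > 0, hi / tot, 0)
  for (i in seq_len(dec$n_components)) {
    if (!dec$rejected[i] && dom[i] > tau_single) {
      dec$rejected[i] <- TRUE; dec$reject_reason[i] <- "single_channel"
    }
    if (!dec$rejected[i] && frac[i] > tau_muscle) {
      dec$rejected[i] <- TRUE; dec$reject_reason[i] <- "muscle_band"
    }
  }
  dec
}

spectral_centroid_hz <- function(dec, i) {
  fs <- dec$fs
  L <- as.integer(fs)
  n_seg <- floor(ncol(dec$sources) / L)
  x <- dec$sources[i, seq_len(n_seg * L)]
  P <- abs(stats::mvfft(matrix(x, nrow = L)))^2
  freqs <- seq_len(floor(L / 2))
  psd <- rowMeans(P[freqs + 1L, , drop = FALSE])
  use <- freqs <= 50
  sum(freqs[use] * psd[use]) / sum(psd[use])
}

autocorr_period_match <- function(dec, i, period_s, rel_tol = 0.2) {
  fs <- dec$fs
  x <- dec$sources[i, ]
  max_lag <- as.integer(min(1.5 * period_s * fs, length(x) - 1))
  ac <- stats::acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  lo <- as.integer(max(2, (1 - rel_tol) * period_s * fs))
  hi <- as.integer(min(max_lag, (1 + rel_tol) * period_s * fs))
  if (lo >= hi) return(FALSE)
  peak <- lo - 1L + which.max(ac[lo:hi])
  # a genuine periodicity shows a positive autocorrelation peak at the
  # period that stands clear of the mid-lag background (short lags are
  # ignored: low-pass smoothness makes them high for every component)
  mid <- ac[as.integer(max(2, 0.3 * period_s * fs)):(lo - 1L)]
  ac[peak] > 0.2 && ac[peak] > max(mid) + 0.05
}

#' Flag stereotyped artifact components by template matching
#'
#' Automated stand-in for visual identification of blink, eye-movement and
#' cardiac components: a component is flagged with a template's reason when
#' its scalp topography correlates with the template topography above
#' `cor_min` and its source matches the template's spectral class — a
#' low-frequency spectral centroid for blink/eye templates
#' (`max_centroid_hz`), or a periodic source at the template period for
#' cardiac templates (`period_s`, detected by an autocorrelation peak).
#'
#' @param dec `fpcoh_ica`
#' @param templates list of templates; each a list with `reason` (one of
#'   `"blink"`, `"eye_movement"`, `"cardiac"`), `topography` (numeric, one
#'   weight per lead), and either `max_centroid_hz` or `period_s`
#' @param cor_min topography correlation threshold (default 0.9)
#' @return `fpcoh_ica` with updated flags
#' @export
flag_stereotyped_artifacts <- function(dec, templates, cor_min = 0.9) {
  for (tpl in templates) {
    topo_cor <- apply(dec$mixing, 2, function(a)
      abs(stats::cor(a, tpl$topography)))
    for (i in which(topo_cor > cor_min & !dec$rejected)) {
      ok <- TRUE
      if (!is.null(tpl$max_centroid_hz))
        ok <- spectral_centroid_hz(dec, i) <= tpl$max_centroid_hz
      if (ok && !is.null(tpl$period_s))
        ok <- autocorr_period_match(dec, i, tpl$period_s)
      if (ok) {
        dec$rejected[i] <- TRUE
        dec$reject_reason[i] <- tpl$reason
      }
    }
  }
  dec
}

#' Reconstruct cleaned epochs with flagged components removed
#'
#' Rebuilds the kept epochs with the flagged components' contributions
#' zeroed: each flagged component's back-projection (mixing column times
#' source) is subtracted from the original data, so unflagged activity --
#' including any variance outside the decomposition's principal subspace --
#' is preserved exactly, and with nothing flagged the input is recovered
#' unchanged. Epochs that were rejected earlier keep their original data
#' but stay masked out.
#'
#' Two removal methods are available. `"project"` (the default) projects
#' the data off the flagged components' scalp patterns (signal-space
#' projection): everything in the span of the flagged mixing columns is
#' removed, which is robust when the decomposition is reduced-rank and the
#' source time courses carry leaked background noise. `"subtract"` removes
#' `mixing[, flagged] %*% sources[flagged, ]` literally.
#'
#' @param dec `fpcoh_ica` fitted on `ep`'s kept epochs
#' @param ep the `fpcoh_epochs` the decomposition was fitted on
#' @param method `"project"` (signal-space projection) or `"subtract"`
#' @return `fpcoh_epochs` with cleaned kept epochs
#' @export
reconstruct_clean <- function(dec, ep, method = c("project", "subtract")) {
  method <- match.arg(method)
  if (all(dec$rejected)) stop("all components flagged: no neural components remain")
  bad <- which(dec$rejected)
  Xorig <- kept_epoch_matrix(ep)
  Xhat <- Xorig
  if (length(bad)) {
    Af <- dec$mixing[, bad, drop = FALSE]
    if (method == "project") {
      qa <- qr.Q(qr(Af))
      Xhat <- Xhat - qa %*% crossprod(qa, Xhat)
    } else {
      Xhat <- Xhat - Af %*% dec$sources[bad, , drop = FALSE]
    }
  }
  keep_ep <- which(ep$kept_mask)
  L <- dim(ep$epochs)[2]
  n_lead <- dim(ep$epochs)[1]
  if (ncol(Xhat) != length(keep_ep) * L)
    stop("decomposition does not match the epoch set's kept epochs")
  for (j in seq_along(keep_ep))
    ep$epochs[, , keep_ep[j]] <- Xhat[, ((j - 1) * L + 1):(j * L)]
  ep$provenance <- c(ep$provenance,
                     list(list(step = "ica_clean",
                               n_components = dec$n_components,
                               n_rejected = sum(dec$rejected),
                               reasons = dec$reject_reason[dec$rejected],
                               seed = dec$seed)))
  ep
}

#' @export
print.fpcoh_ica <- function(x, ...) {
  cat(sprintf("fpcoh ICA: %d components (%d flagged) over %d samples\n",
              x$n_components, sum(x$rejected), ncol(x$sources)))
  if (any(x$rejected))
    cat("  reasons:", paste(x$reject_reason[x$rejected], collapse = ", "), "\n")
  invisible(x)
}
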