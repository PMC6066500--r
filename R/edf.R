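# Minimal EDF (European Data Format, 16-bit continuous) writer/reader for
# EEG interchange. Supports the plain-EDF subset used here: equal sampling
# rate on all signals, 1-s data records, per-signal physical scaling.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with one 1-s data record per second and per-lead physical
#' scaling chosen from the data range. The trailing partial second is
#' dropped (EDF stores whole records).
#'
#' @param rec `fpcoh_recording`
#' @param path output file
#' @return the path, invisibly
#' @export
write_edf <- function(rec, path) {
  X <- rec$data
  fs <- as.integer(round(rec$fs))
  n_rec <- floor(ncol(X) / fs)
  if (n_rec < 1) stop("recording shorter than one EDF record (1 s)")
  ns <- nrow(X)
  pmax_ <- apply(abs(X), 1, max)
  pmax_[pmax_ == 0] <- 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(pad_field("0", 8),
                pad_field("synthetic subject", 80),
                pad_field("fpcoh synthetic recording", 80),
                pad_field("01.01.00", 8), pad_field("00.00.00", 8),
                pad_field(256 + 256 * ns, 8),
                pad_field("", 44),
                pad_field(n_rec, 8), pad_field("1", 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- c(vapply(rownames(X), pad_field, "", width = 16),
              rep(pad_field("", 80), ns),
              rep(pad_field("uV", 8), ns),
              vapply(-pmax_, function(v) pad_field(sprintf("%.6g", v), 8), ""),
              vapply(pmax_, function(v) pad_field(sprintf("%.6g", v), 8), ""),
              rep(pad_field("-32767", 8), ns),
              rep(pad_field("32767", 8), ns),
              rep(pad_field("", 80), ns),
              rep(pad_field(fs, 8), ns),
              rep(pad_field("", 32), ns))
  writeChar(paste(fields, collapse = ""), con, eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    dig <- round(t(X[, idx, drop = FALSE]) *
                   rep(32767 / pmax_, each = fs))
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file
#' @return list with `data` (lead x sample matrix, physical units),
#'   `fs`, `labels`, `n_records`
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    out <- readChar(con, w, useBytes = TRUE)
    if (length(out) == 0 || nchar(out, type = "bytes") < w)
      stop("corrupted EDF file: ", path)
    trimws(out)
  }
  rd(8)                                   # version
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(n_rec) || is.na(ns) || ns < 1) stop("corrupted EDF file: ", path)
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16)
  rdv(80); rdv(8)
  pmin_ <- as.numeric(rdv(8)); pmax_ <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))
  rdv(32)
  if (length(unique(spr)) != 1)
    stop("EDF with mixed sampling rates is not supported")
  fs <- spr[1] / rec_dur
  X <- matrix(0, ns, n_rec * spr[1], dimnames = list(labels, NULL))
  scale <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = ns * spr[1], size = 2,
                   endian = "little")
    if (length(raw) < ns * spr[1]) stop("corrupted EDF file: ", path)
    blk <- matrix(raw, nrow = spr[1])
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    X[, idx] <- t(blk * rep(scale, each = spr[1]) +
                    rep(pmin_ - dmin * scale, each = spr[1]))
  }
  list(data = X, fs = fs, labels = labels, n_records = n_rec)
}
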