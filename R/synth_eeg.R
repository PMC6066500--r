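# Synthetic resting EEG with controllable band-limited inter-regional
# coupling and stereotyped artifacts.
#
# Coupling model: a single band-limited source s(t) (flat spectral density
# across the analysis band, slightly widened so estimator bins at the band
# edges see full source power) is projected with weight 1 onto the motor
# ROI leads and weight gamma onto the parietal ROI leads; every lead also
# carries an independent 1/f background. Because mixing weights and
# spectral densities are known, band coherence has a closed form that is
# stored as ground truth next to every generated recording.

#' Simulation configuration for the synthetic cohort
#'
#' Defaults mirror the emulated acquisition: 1000 samples/s, 180 s of
#' resting EEG, a dense hexagonal montage (10 rings = 271 leads, standing in
#' for a ~256-lead net), 12 subjects. The coupling-to-gain link is linear,
#' `gain_i = a + b * gamma_i + e_i`, with defaults calibrated so the
#' cohort-level mean and spread of the relative success-rate gain and the
#' strength of the coupling-gain association are of the magnitude reported
#' for the emulated study (gain ~ 24 +- 22 %, rank correlation ~ 0.6).
#'
#' @param n_subjects number of subjects (>= 3; default 12)
#' @param fs_eeg EEG sampling rate, Hz (default 1000)
#' @param duration recording length, s (default 180)
#' @param montage_rings rings of the synthetic hexagonal montage
#'   (default 10, i.e. 271 leads)
#' @param coupling_range range of per-subject coupling gamma, within `[0,1]`
#'   (default `c(0.05, 0.6)`)
#' @param link_intercept,link_slope,link_noise_sd parameters a, b, sd(e) of
#'   the coupling-to-gain link (defaults -3.2, 84, 17.4, in percent SR gain)
#' @param band analysis band of the shared source, Hz (default `c(20, 30)`)
#' @param band_snr ratio of per-bin shared-source band power (at weight 1)
#'   to mean per-bin background band power (default 16)
#' @param noise_band_power_uv2 background band power within the analysis
#'   band, microvolt^2 per lead (default 4)
#' @param artifact_amplitudes named amplitudes (microvolts) for
#'   `blink`, `muscle`, `cardiac`, `spike`; zero disables a class
#'   (default all zero: artifact-free)
#' @param rng_seed integer master seed (mandatory)
#' @return object of class `fpcoh_simconfig`
#' @export
sim_config <- function(n_subjects = 12, fs_eeg = 1000, duration = 180,
                       montage_rings = 10,
                       coupling_range = c(0.05, 0.6),
                       link_intercept = -3.2, link_slope = 84,
                       link_noise_sd = 17.4,
                       band = c(20, 30), band_snr = 16,
                       noise_band_power_uv2 = 4,
                       artifact_amplitudes = c(blink = 0, muscle = 0,
                                               cardiac = 0, spike = 0),
                       rng_seed) {
  if (missing(rng_seed)) stop("rng_seed is mandatory")
  if (n_subjects < 3) stop("n_subjects must be >= 3")
  if (coupling_range[1] < 0 || coupling_range[2] > 1 ||
      coupling_range[1] > coupling_range[2])
    stop("coupling_range must be an interval within [0, 1]")
  if (link_noise_sd < 0 || noise_band_power_uv2 <= 0 || band_snr <= 0)
    stop("scales must be positive")
  if (any(artifact_amplitudes < 0)) stop("artifact amplitudes must be >= 0")
  amp <- c(blink = 0, muscle = 0, cardiac = 0, spike = 0)
  amp[names(artifact_amplitudes)] <- artifact_amplitudes
  structure(list(n_subjects = as.integer(n_subjects), fs_eeg = fs_eeg,
                 duration = duration, montage_rings = montage_rings,
                 coupling_range = coupling_range,
                 link_intercept = link_intercept, link_slope = link_slope,
                 link_noise_sd = link_noise_sd, band = band,
                 band_snr = band_snr,
                 noise_band_power_uv2 = noise_band_power_uv2,
                 artifact_amplitudes = amp,
                 rng_seed = as.integer(rng_seed)),
            class = "fpcoh_simconfig")
}

subject_seed <- function(config, i, stream = 0L) {
  as.integer((as.numeric(config$rng_seed) + 7919 * i + 104729 * stream) %%
               2147483647)
}

# spectral synthesis: x with power sigma2_bins[k] in 1-Hz-wide bin centered
# on integer frequency... general: band synthesis from a per-frequency PSD
freq_synth <- function(n, fs, psd_fun) {
  K <- floor((n - 1) / 2)
  f <- seq_len(K) * fs / n
  S <- psd_fun(f)
  use <- which(S > 0)
  X <- complex(length.out = n)
  df <- fs / n
  sig <- n * sqrt(S[use] * df / 2)
  X[use + 1L] <- sig * complex(real = stats::rnorm(length(use)),
                               imaginary = stats::rnorm(length(use))) / sqrt(2)
  X[n + 1L - use] <- Conj(X[use + 1L])
  Re(stats::fft(X, inverse = TRUE)) / n
}

# per-bin background power (1-Hz bins centered on integer f) implied by the
# pink 1/f background scaled to noise_band_power over the widened band
pink_bin_power <- function(f, config) {
  lo <- config$band[1] - 0.5; hi <- config$band[2] + 0.5
  c0 <- config$noise_band_power_uv2 / log(hi / lo)
  c0 * log((f + 0.5) / (f - 0.5))
}

source_bin_power <- function(config) {
  nb <- config$band[2] - config$band[1] + 1
  config$band_snr * config$noise_band_power_uv2 / nb
}

#' Scalp projection of the shared source
#'
#' Weight 1 on the motor-ROI leads and `gamma` on the parietal-ROI leads,
#' plus a weak negative return field spread uniformly over leads belonging
#' to no configured ROI, sized so the weights sum to zero across the
#' montage. Real cortical source fields integrate to approximately zero
#' over a dense array; the zero-sum construction reproduces that property,
#' so common-average re-referencing is near-neutral for the coupled source
#' and control circuits stay uncoupled. When every lead belongs to some ROI
#' the return field is dropped (weights then do not sum to zero).
#'
#' @param montage `fpcoh_montage`
#' @param rois `fpcoh_roiset`
#' @param gamma coupling weight
#' @return list with `w` (named weight vector) and `zero_mean` (logical)
#' @export
source_topography <- function(montage, rois, gamma) {
  leads <- montage$lead_ids
  w <- stats::setNames(numeric(length(leads)), leads)
  a <- rois$rois[[rois$primary_pair[1]]]
  b <- rois$rois[[rois$primary_pair[2]]]
  w[a] <- 1
  w[b] <- gamma
  ret <- setdiff(leads, unique(unlist(rois$rois)))
  zero_mean <- length(ret) > 0
  if (zero_mean) w[ret] <- -(length(a) + length(b) * gamma) / length(ret)
  list(w = w, zero_mean = zero_mean)
}

#' Analytic band coherence implied by a coupling weight
#'
#' Closed form for the epoch-averaged magnitude-squared coherence between a
#' motor-ROI lead (shared-source weight 1) and a parietal-ROI lead (weight
#' `gamma`) under the generator's mixing model: per integer-frequency bin f,
#' `C_f = (gamma * k_f)^2 / ((k_f + 1) * (gamma^2 * k_f + 1))` with
#' `k_f` the bin's source-to-background power ratio; the band value is the
#' mean over the band's bins. With `avg_reference = TRUE` the formula
#' accounts for common-average re-referencing: the across-lead mean source
#' weight (zero under the zero-sum topography of [source_topography()]) is
#' subtracted from the ROI weights, and the small noise covariance induced
#' by subtracting the noise mean enters the spectra.
#'
#' @param gamma coupling weight in `[0, 1]`
#' @param config `fpcoh_simconfig`
#' @param montage,rois montage and ROI set (needed only for
#'   `avg_reference = TRUE`, to know the lead counts)
#' @param avg_reference account for common-average re-referencing
#' @return coherence in `[0, 1]`
#' @export
analytic_band_coherence <- function(gamma, config, montage = NULL,
                                    rois = NULL, avg_reference = FALSE) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  f <- seq(config$band[1], config$band[2])
  Nf <- pink_bin_power(f, config)
  ps <- source_bin_power(config)
  if (!avg_reference) {
    kf <- ps / Nf
    return(mean((gamma * kf)^2 / ((kf + 1) * (gamma^2 * kf + 1))))
  }
  n <- length(montage$lead_ids)
  topo <- source_topography(montage, rois, gamma)
  m <- mean(topo$w)                       # 0 under the zero-sum topography
  w1 <- 1 - m; w2 <- gamma - m
  num <- (w1 * w2 * ps - Nf / n)^2
  den <- (w1^2 * ps + Nf * (1 - 1 / n)) * (w2^2 * ps + Nf * (1 - 1 / n))
  mean(num / den)
}

#' Coupling weight that yields a target analytic coherence
#' @param target coherence in `[0, max attainable)`
#' @param config `fpcoh_simconfig`
#' @return gamma in `[0, 1]`
#' @export
gamma_for_coherence <- function(target, config) {
  if (target == 0) return(0)
  cmax <- analytic_band_coherence(1, config)
  if (target >= cmax)
    stop(sprintf("target %.3f exceeds the maximum attainable %.3f %s",
                 target, cmax, "(raise band_snr)"))
  stats::uniroot(function(g) analytic_band_coherence(g, config) - target,
                 c(0, 1), tol = 1e-10)$root
}

frontal_topography <- function(montage) {
  p <- montage$positions
  ctr <- c(0, max(p[, 2]) + 0.5)
  w <- exp(-((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2) / (2 * 1.5^2))
  w / max(w)
}

edge_topography <- function(montage) {
  p <- montage$positions
  rad <- sqrt(rowSums(p[, 1:2]^2))
  # a posterior-lateral edge sector (neck/temporal muscle), on the same
  # side as the parietal ROI so that muscle activity contaminates it
  ang <- 240 * pi / 180
  ctr <- max(rad) * c(cos(ang), sin(ang))
  w <- exp(-((p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2) / (2 * 2.0^2))
  w / max(w)
}

cardiac_topography <- function(montage) {
  p <- montage$positions
  # smooth fixed gradient across the array (far-field source)
  w <- 0.35 + 0.65 * (p[, 1] - min(p[, 1])) / diff(range(p[, 1]))
  w / max(w)
}

gaussian_pulse_train <- function(n, fs, times_s, width_s, biphasic = FALSE) {
  t <- seq_len(n) / fs
  x <- numeric(n)
  for (tc in times_s) {
    idx <- which(abs(t - tc) < 5 * width_s)
    g <- exp(-(t[idx] - tc)^2 / (2 * width_s^2))
    if (biphasic) g <- g * (t[idx] - tc) / width_s
    x[idx] <- x[idx] + g
  }
  x
}

#' Generate one subject's resting EEG with known coupling
#'
#' Builds a lead x sample matrix from the linear source-mixing model (see
#' the module header) plus optional stereotyped artifacts: frontal
#' low-frequency blink bursts, a 35-50 Hz-dominant broadband muscle source
#' on an edge-lead patch, an exactly periodic ~1.2 Hz cardiac component with
#' a fixed whole-array topography, and a single-channel spike train. The
#' returned ground truth records the coupling, the analytic band coherence
#' (raw-mixing and after average re-referencing), and each artifact's mixing
#' vector, period and class.
#'
#' @param config `fpcoh_simconfig`
#' @param gamma coupling weight in `[0, 1]`
#' @param montage `fpcoh_montage`
#' @param rois `fpcoh_roiset` naming the primary pair
#' @param rng_seed integer seed; same seed reproduces the matrices exactly
#' @param keep_parts store the neural-only and artifact-only lead-space
#'   signals in the ground truth (memory-heavy; default FALSE)
#' @return list with `recording` (`fpcoh_recording`) and `truth` (list)
#' @export
generate_subject_eeg <- function(config, gamma, montage, rois, rng_seed,
                                 keep_parts = FALSE) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  set.seed(as.integer(rng_seed))
  fs <- config$fs_eeg
  n <- as.integer(round(fs * config$duration))
  leads <- montage$lead_ids
  nl <- length(leads)
  lo <- config$band[1] - 0.5; hi <- config$band[2] + 0.5
  ps <- source_bin_power(config)           # per-1-Hz-bin source power
  c0 <- config$noise_band_power_uv2 / log(hi / lo)
  s <- freq_synth(n, fs, function(f) ifelse(f >= lo & f <= hi, ps, 0))
  X <- matrix(0, nl, n, dimnames = list(leads, NULL))
  for (i in seq_len(nl))
    X[i, ] <- freq_synth(n, fs, function(f) ifelse(f >= 1 & f <= 50,
                                                   c0 / f, 0))
  topo <- source_topography(montage, rois, gamma)
  neural <- X + outer(topo$w, s)
  X <- neural
  amp <- config$artifact_amplitudes
  topo_art <- list(); periods <- list()
  artifact <- if (keep_parts) matrix(0, nl, n) else NULL
  add_artifact <- function(X, name, wvec, src) {
    comp <- outer(amp[[name]] * wvec, src)
    topo_art[[name]] <<- wvec
    if (keep_parts) artifact <<- artifact + comp
    X + comp
  }
  if (amp[["blink"]] > 0) {
    nb <- max(1, stats::rpois(1, 0.25 * config$duration))
    times <- sort(stats::runif(nb, 1, config$duration - 1))
    src <- gaussian_pulse_train(n, fs, times, width_s = 0.08)
    X <- add_artifact(X, "blink", frontal_topography(montage), src)
  }
  if (amp[["muscle"]] > 0) {
    # broadband, dominant in 35-50 Hz (85 % of power), shelf down to 15 Hz
    p35 <- 0.85 / 15; p15 <- 0.15 / 20
    src <- freq_synth(n, fs, function(f)
      ifelse(f >= 35 & f <= 50, p35, ifelse(f >= 15 & f < 35, p15, 0)))
    src <- src / stats::sd(src)
    X <- add_artifact(X, "muscle", edge_topography(montage), src)
  }
  if (amp[["cardiac"]] > 0) {
    period <- 1 / 1.2
    phase <- stats::runif(1, 0, period)
    times <- seq(phase, config$duration, by = period)
    src <- gaussian_pulse_train(n, fs, times, width_s = 0.012,
                                biphasic = TRUE)
    src <- src / max(abs(src))
    X <- add_artifact(X, "cardiac", cardiac_topography(montage), src)
    periods$cardiac <- period
  }
  if (amp[["spike"]] > 0) {
    lead <- sample(setdiff(leads, c(rois$rois[[rois$primary_pair[1]]],
                                    rois$rois[[rois$primary_pair[2]]])), 1)
    nsp <- max(1, stats::rpois(1, 0.5 * config$duration))
    times <- sort(stats::runif(nsp, 0.5, config$duration - 0.5))
    src <- gaussian_pulse_train(n, fs, times, width_s = 0.005) *
      sample(c(-1, 1), 1)
    wvec <- stats::setNames(as.numeric(leads == lead), leads)
    X <- add_artifact(X, "spike", wvec, src)
  }
  truth <- list(
    gamma = gamma,
    analytic_coherence = analytic_band_coherence(gamma, config),
    analytic_coherence_avgref = analytic_band_coherence(
      gamma, config, montage, rois, avg_reference = TRUE),
    band = config$band,
    source_topography = topo$w,
    artifact_topographies = topo_art,
    artifact_periods = periods,
    artifact_amplitudes = amp,
    seed = rng_seed)
  if (keep_parts) {
    truth$neural <- neural
    truth$artifact <- artifact
  }
  list(recording = eeg_recording(X, fs, montage, reference = "Cz"),
       truth = truth)
}
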