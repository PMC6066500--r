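# Shared fixtures, built in code.

hex5 <- build_synthetic_montage(5)          # 61 leads
hex5_rois <- default_roi_set(hex5)

# a small, fast simulation configuration used across tests
fast_config <- function(seed, duration = 30, fs = 125, rings = 5, ...) {
  sim_config(n_subjects = 4, fs_eeg = fs, duration = duration,
             montage_rings = rings, rng_seed = seed, ...)
}

# constant-offset trace: cursor = target + (dx, dy)
offset_trace <- function(n = 100, dx = 0, dy = 0) {
  tg <- cbind(seq_len(n), rep(5, n))
  tracking_trace(t = (seq_len(n) - 1) / 30, target_xy = tg,
                 cursor_xy = tg + matrix(c(dx, dy), n, 2, byrow = TRUE))
}

# trace with prescribed per-sample distances (cursor offset along x)
distance_trace <- function(d) {
  n <- length(d)
  tg <- cbind(rep(0, n), rep(0, n))
  tracking_trace(t = (seq_len(n) - 1) / 30, target_xy = tg,
                 cursor_xy = cbind(d, rep(0, n)))
}

# two-lead recording with a shared band-limited source:
# x = s + n1, y = g*s + n2, with per-bin powers controlled exactly
shared_source_recording <- function(g, n_sec, fs = 250, seed = 1,
                                    band = c(19.5, 30.5)) {
  set.seed(seed)
  n <- n_sec * fs
  synth <- function() {
    K <- floor((n - 1) / 2)
    f <- seq_len(K) * fs / n
    X <- complex(length.out = n)
    use <- which(f >= band[1] & f <= band[2])
    X[use + 1L] <- complex(real = stats::rnorm(length(use)),
                           imaginary = stats::rnorm(length(use))) / sqrt(2)
    X[n + 1L - use] <- Conj(X[use + 1L])
    Re(stats::fft(X, inverse = TRUE)) / n
  }
  s <- synth(); n1 <- synth(); n2 <- synth()
  mm <- montage_from_positions(data.frame(lead_id = c("A", "B"),
                                          x = c(0, 1), y = c(0, 0)))
  eeg_recording(rbind(A = s + n1, B = g * s + n2) * 1e3, fs, mm)
}
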