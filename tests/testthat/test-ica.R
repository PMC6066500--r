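mixed_sources_fixture <- function(seed = 5, n_sec = 32, fs = 250) {
  set.seed(seed)
  n <- n_sec * fs
  t <- seq_len(n) / fs
  S <- rbind(sin(2 * pi * 7 * t),                      # sub-Gaussian rhythm
             sign(sin(2 * pi * 3.1 * t + 1)),          # square wave
             rexp(n) - 1)                              # super-Gaussian
  A <- matrix(rnorm(18), 6, 3)
  X <- A %*% S + 0.01 * matrix(rnorm(6 * n), 6)
  mm <- montage_from_positions(data.frame(lead_id = paste0("L", 1:6),
                                          x = runif(6) + 1:6, y = runif(6)))
  list(ep = epoch_and_detrend(eeg_recording(X, fs, mm)), S = S, A = A)
}

test_that("infomax recovers independently mixed sources", {
  fx <- mixed_sources_fixture()
  dec <- decompose_ica(fx$ep, n_components = 3, rng_seed = 1)
  cors <- abs(cor(t(dec$sources), t(fx$S[, seq_len(ncol(dec$sources))])))
  # match by maximal absolute correlation (sign/permutation free)
  expect_true(all(apply(cors, 2, max) >= 0.95))
})

test_that("ica is deterministic given a seed, up to nothing", {
  fx <- mixed_sources_fixture(seed = 8, n_sec = 16)
  d1 <- decompose_ica(fx$ep, n_components = 3, rng_seed = 42)
  d2 <- decompose_ica(fx$ep, n_components = 3, rng_seed = 42)
  expect_identical(d1$mixing, d2$mixing)
  expect_error(decompose_ica(fx$ep, n_components = 3), "rng_seed")
})

test_that("reconstruction with nothing flagged recovers the input", {
  fx <- mixed_sources_fixture(seed = 9, n_sec = 16)
  dec <- decompose_ica(fx$ep, n_components = 3, rng_seed = 2)
  out <- reconstruct_clean(dec, fx$ep)
  expect_equal(out$epochs, fx$ep$epochs, tolerance = 1e-12)
  dec$rejected[] <- TRUE
  expect_error(reconstruct_clean(dec, fx$ep), "no neural components")
})

test_that("rank-deficient data are refused with guidance", {
  set.seed(3)
  base <- matrix(rnorm(2 * 4000), 2)
  X <- rbind(base, base[1, ] + base[2, ], base[1, ] - 2 * base[2, ])
  mm <- montage_from_positions(data.frame(lead_id = paste0("L", 1:4),
                                          x = 1:4, y = rep(0, 4)))
  ep <- epoch_and_detrend(eeg_recording(X, 250, mm))
  expect_error(decompose_ica(ep, n_components = 4, rng_seed = 1),
               "fewer components")
})

test_that("automatic rules flag single-channel and muscle-band components", {
  # direct rule checks on a constructed decomposition
  fs <- 250
  n <- 10 * fs
  t <- seq_len(n) / fs
  mixing <- cbind(c(1, 0, 0, 0, 0, 0),              # one-channel topography
                  c(0.8, 1, 0.9, 1.1, 0.7, 1),      # distributed
                  c(1.2, 0.6, 1, 0.8, 1.1, 0.9))    # distributed
  sources <- rbind(rnorm(n),
                   sin(2 * pi * 40 * t),             # all power in 35-50 Hz
                   sin(2 * pi * 10 * t))
  dec <- structure(list(mixing = mixing, sources = sources, fs = fs,
                        n_components = 3L, rejected = rep(FALSE, 3),
                        reject_reason = rep(NA_character_, 3)),
                   class = "fpcoh_ica")
  out <- auto_flag_components(dec)
  expect_identical(out$reject_reason, c("single_channel", "muscle_band", NA))
  # both rules are threshold-controlled
  lax <- auto_flag_components(dec, tau_single = 1.01, tau_muscle = 1.01)
  expect_false(any(lax$rejected))
})

test_that("a spiky single-lead source is isolated and auto-flagged", {
  fs <- 250
  set.seed(14)
  n <- 24 * fs
  iso <- rnorm(n, 0, 16) * rbinom(n, 1, 0.08)   # spiky electrode artifact
  X <- matrix(rnorm(6 * n, 0, 0.5), 6)
  X[1, ] <- X[1, ] + iso
  X <- X + outer(c(1.2, 0.6, 1, 0.8, 1.1, 0.9),
                 rexp(n) - 1)                    # distributed neural source
  mm <- montage_from_positions(data.frame(lead_id = paste0("L", 1:6),
                                          x = 1:6, y = rep(0, 6)))
  ep <- epoch_and_detrend(eeg_recording(X, fs, mm))
  dec <- auto_flag_components(decompose_ica(ep, n_components = 2,
                                            rng_seed = 4))
  expect_true("single_channel" %in% dec$reject_reason)
  surviving <- which(!dec$rejected)
  expect_true(length(surviving) >= 1)
})

test_that("template matching flags blink and cardiac components", {
  cfg <- fast_config(77, duration = 40, fs = 250, rings = 5,
                     artifact_amplitudes = c(blink = 80, cardiac = 20))
  ge <- generate_subject_eeg(cfg, 0.3, hex5, hex5_rois, rng_seed = 6,
                             keep_parts = TRUE)
  ep <- reject_epochs_amplitude(epoch_and_detrend(
    lowpass_50(rereference_average(ge$recording))), 100)
  dec <- decompose_ica(ep, n_components = 16, rng_seed = 7)
  dec <- flag_stereotyped_artifacts(dec, default_artifact_templates(hex5))
  expect_true("blink" %in% dec$reject_reason)
  expect_true("cardiac" %in% dec$reject_reason)
  # with no matching template nothing is flagged
  dec2 <- decompose_ica(ep, n_components = 16, rng_seed = 7)
  lateral <- as.numeric(hex5$positions[, 1] > 0)
  dec2 <- flag_stereotyped_artifacts(
    dec2, list(list(reason = "blink", topography = lateral * 0 +
                      seq_along(lateral) %% 2, max_centroid_hz = 2)))
  expect_false(any(dec2$rejected))
})

test_that("removing the flagged artifact strips most of its energy", {
  cfg <- fast_config(88, duration = 40, fs = 250, rings = 5,
                     artifact_amplitudes = c(blink = 80))
  ge <- generate_subject_eeg(cfg, 0.3, hex5, hex5_rois, rng_seed = 16,
                             keep_parts = TRUE)
  rec <- lowpass_50(rereference_average(ge$recording))
  ep <- reject_epochs_amplitude(epoch_and_detrend(rec), 100)
  dec <- decompose_ica(ep, n_components = 16, rng_seed = 3)
  dec <- flag_stereotyped_artifacts(dec, default_artifact_templates(hex5))
  expect_true("blink" %in% dec$reject_reason)
  # the projection cleaning is a linear operator on the data; its effect on
  # the artifact alone is found by pushing the known injected artifact
  # through the same preprocessing chain and the same projection
  art_rec <- ge$recording; art_rec$data <- ge$truth$artifact
  art_ep <- epoch_and_detrend(lowpass_50(rereference_average(art_rec)))
  art_ep$kept_mask <- ep$kept_mask
  art_clean <- reconstruct_clean(dec, art_ep, method = "project")
  keep <- which(ep$kept_mask)
  E_before <- sum(art_ep$epochs[, , keep]^2)
  E_after <- sum(art_clean$epochs[, , keep]^2)
  expect_lt(E_after / E_before, 0.10)        # >= 90% energy removed
})
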