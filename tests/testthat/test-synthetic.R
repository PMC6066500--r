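test_that("simulation config validates its ranges", {
  expect_error(sim_config(n_subjects = 2, rng_seed = 1), "n_subjects")
  expect_error(sim_config(coupling_range = c(-0.1, 0.5), rng_seed = 1),
               "coupling_range")
  expect_error(sim_config(rng_seed = 1,
                          artifact_amplitudes = c(blink = -1)), ">= 0")
  expect_error(sim_config(), "rng_seed")
})

test_that("analytic coherence: zero at gamma 0, strictly increasing", {
  cfg <- fast_config(1)
  expect_equal(analytic_band_coherence(0, cfg), 0)
  g <- seq(0, 1, by = 0.05)
  cc <- vapply(g, analytic_band_coherence, numeric(1), config = cfg)
  expect_true(all(diff(cc) > 0))
  expect_true(all(cc >= 0 & cc <= 1))
  # gamma_for_coherence inverts the map
  for (target in c(0.1, 0.25, 0.5, 0.8))
    expect_equal(analytic_band_coherence(gamma_for_coherence(target, cfg),
                                         cfg), target, tolerance = 1e-8)
  expect_error(gamma_for_coherence(0.99, cfg), "attainable")
  expect_error(analytic_band_coherence(1.2, cfg), "gamma")
})

test_that("subject EEG generation is seeded and artifact-aware", {
  cfg <- fast_config(2, duration = 10)
  a <- generate_subject_eeg(cfg, 0.4, hex5, hex5_rois, rng_seed = 5)
  b <- generate_subject_eeg(cfg, 0.4, hex5, hex5_rois, rng_seed = 5)
  expect_identical(a$recording$data, b$recording$data)
  expect_error(generate_subject_eeg(cfg, 1.4, hex5, hex5_rois, rng_seed = 1),
               "gamma")
  # gamma = 0, artifact-free: no shared source anywhere
  z <- generate_subject_eeg(cfg, 0, hex5, hex5_rois, rng_seed = 5)
  expect_equal(z$truth$analytic_coherence, 0)
  cfg_art <- fast_config(2, duration = 10,
                         artifact_amplitudes = c(blink = 80, muscle = 30,
                                                 cardiac = 15, spike = 60))
  w <- generate_subject_eeg(cfg_art, 0.4, hex5, hex5_rois, rng_seed = 5,
                            keep_parts = TRUE)
  expect_setequal(names(w$truth$artifact_topographies),
                  c("blink", "muscle", "cardiac", "spike"))
  expect_equal(w$truth$artifact_periods$cardiac, 1 / 1.2)
  # spike topography touches exactly one lead
  expect_equal(sum(w$truth$artifact_topographies$spike != 0), 1)
})

test_that("estimated coherence converges to the analytic ground truth", {
  cfg <- fast_config(3, duration = 60, fs = 250)
  for (target in c(0, 0.5)) {
    g <- if (target == 0) 0 else gamma_for_coherence(target, cfg)
    est <- vapply(1:3, function(s) {
      ge <- generate_subject_eeg(cfg, g, hex5, hex5_rois, rng_seed = 200 + s)
      ep <- epoch_and_detrend(ge$recording)
      spec <- estimate_spectra(ep, fpcoh:::roi_lead_pairs(hex5_rois,
                                                          c("iM1", "iPAR")))
      roi_pair_coherence(spec, hex5_rois, c("iM1", "iPAR"),
                         c(20, 30))$coherence
    }, numeric(1))
    expect_lt(abs(median(est) - target), 0.05)
  }
})

test_that("coupled circuit out-coheres the visual control circuit", {
  cfg <- fast_config(4, duration = 30, fs = 125)
  g <- gamma_for_coherence(0.5, cfg)
  wins <- vapply(1:5, function(s) {
    ge <- generate_subject_eeg(cfg, g, hex5, hex5_rois, rng_seed = 300 + s)
    tab <- coherence_table(epoch_and_detrend(ge$recording), hex5_rois,
                           bands = list(high_beta = c(20, 30)))
    tab$coherence[tab$roi_pair == "iM1-iPAR"] >
      tab$coherence[tab$roi_pair == "iM1-iV1"]
  }, logical(1))
  expect_true(all(wins))
})

test_that("cohorts are reproducible and link gains to coupling", {
  cfg <- fast_config(5, duration = 10)
  co <- generate_cohort(cfg, eeg = FALSE)
  co2 <- generate_cohort(cfg, eeg = FALSE)
  expect_identical(co$truth, co2$truth)
  expect_equal(nrow(co$truth), 4)
  # adding subjects leaves existing subjects untouched
  cfg6 <- fast_config(5, duration = 10); cfg6$n_subjects <- 6L
  co6 <- generate_cohort(cfg6, eeg = FALSE)
  expect_equal(co6$truth[1:4, ], co$truth, ignore_attr = TRUE)
  # noiseless positive link: gain rank order equals coupling rank order
  cfg_mono <- sim_config(n_subjects = 6, fs_eeg = 125, duration = 10,
                         montage_rings = 5, link_noise_sd = 0,
                         link_intercept = 5, link_slope = 40, rng_seed = 9)
  mono <- generate_cohort(cfg_mono, eeg = FALSE)
  expect_equal(cor(mono$truth$gamma, mono$truth$delta_true,
                   method = "spearman"), 1)
  expect_equal(cor(mono$truth$gamma, mono$truth$delta_achieved,
                   method = "spearman"), 1)
  # b = 0: gains carry no information about coupling (null cohort)
  cfg_null <- sim_config(n_subjects = 8, fs_eeg = 125, duration = 10,
                         montage_rings = 5, link_slope = 0, rng_seed = 10)
  nul <- generate_cohort(cfg_null, eeg = FALSE)
  expect_lt(abs(cor(nul$truth$gamma, nul$truth$delta_true,
                    method = "spearman")), 1)
})

test_that("infeasible gains are clipped and flagged", {
  cfg <- sim_config(n_subjects = 3, fs_eeg = 125, duration = 10,
                    montage_rings = 5, link_intercept = 400, link_slope = 0,
                    link_noise_sd = 0, rng_seed = 11)
  co <- generate_cohort(cfg, eeg = FALSE)
  expect_true(all(co$truth$clipped))
  expect_true(all(co$truth$delta_achieved < co$truth$delta_true))
})

test_that("achieved gains track the drawn gains when feasible", {
  co <- generate_cohort(fast_config(12, duration = 10), eeg = FALSE)
  ok <- !co$truth$clipped
  expect_true(any(ok))
  expect_lt(max(abs(co$truth$delta_true[ok] - co$truth$delta_achieved[ok])),
            2)
})
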