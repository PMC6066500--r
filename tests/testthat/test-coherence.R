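two_lead_epochs <- function(X, fs = 250) {
  mm <- montage_from_positions(data.frame(lead_id = c("A", "B"),
                                          x = c(0, 1), y = c(0, 0)))
  epoch_and_detrend(eeg_recording(X, fs, mm))
}

test_that("self-coherence is exactly 1 and M=1 is rejected", {
  set.seed(1)
  ep <- two_lead_epochs(matrix(rnorm(2 * 2500), 2))
  spec <- estimate_spectra(ep, list(c("A", "A"), c("A", "B")))
  expect_equal(msc(spec, "A", "A", c(20, 30)), 1, tolerance = 1e-10)
  one <- two_lead_epochs(matrix(rnorm(2 * 250), 2))
  expect_error(estimate_spectra(one, list(c("A", "B"))), "at least 2")
})

test_that("auto-spectrum of a sinusoid peaks at its frequency bin", {
  fs <- 250
  t <- seq_len(10 * fs) / fs
  X <- rbind(sin(2 * pi * 10 * t), rnorm(10 * fs))
  spec <- estimate_spectra(two_lead_epochs(X, fs), list(c("A", "B")))
  expect_equal(spec$freqs[which.max(spec$auto[, "A"])], 10)
})

test_that("independent noise gives near-zero band coherence at M=180", {
  set.seed(7)
  vals <- replicate(5, {
    ep <- two_lead_epochs(matrix(rnorm(2 * 180 * 250), 2))
    spec <- estimate_spectra(ep, list(c("A", "B")))
    msc(spec, "A", "B", c(20, 30))
  })
  expect_true(all(vals <= 0.03))       # estimator bias ~ 1/M = 0.0056
})

test_that("equal shared and independent band power gives msc 0.25", {
  vals <- vapply(1:5, function(s) {
    rec <- shared_source_recording(1, 180, seed = s)
    spec <- estimate_spectra(epoch_and_detrend(rec), list(c("A", "B")))
    msc(spec, "A", "B", c(20, 30))
  }, numeric(1))
  # closed form (1/(1+1))^2 = 0.25; single-seed sd ~ 0.02, so the center
  # of the Monte-Carlo draw is what the closed form pins down
  expect_lt(abs(median(vals) - 0.25), 0.03)
})

test_that("msc is scale invariant and bounded", {
  set.seed(12)
  X <- matrix(rnorm(2 * 20 * 250), 2)
  s1 <- estimate_spectra(two_lead_epochs(X), list(c("A", "B")))
  X2 <- X; X2[1, ] <- X2[1, ] * 1e4
  s2 <- estimate_spectra(two_lead_epochs(X2), list(c("A", "B")))
  for (band in default_bands()) {
    a <- msc(s1, "A", "B", band); b <- msc(s2, "A", "B", band)
    expect_equal(a, b, tolerance = 1e-12)
    expect_gte(a, 0); expect_lte(a, 1)
  }
})

test_that("half-period time shifts do not change magnitude coherence", {
  fs <- 250
  rec <- shared_source_recording(0.9, 20, fs = fs, seed = 3,
                                 band = c(24.5, 25.5))   # ~25 Hz narrowband
  shift <- round(fs / 25 / 2)                            # half period
  X2 <- rec$data
  X2[2, ] <- c(X2[2, -seq_len(shift)], X2[2, seq_len(shift)])
  rec2 <- rec; rec2$data <- X2
  c1 <- msc(estimate_spectra(epoch_and_detrend(rec), list(c("A", "B"))),
            "A", "B", c(24, 26))
  c2 <- msc(estimate_spectra(epoch_and_detrend(rec2), list(c("A", "B"))),
            "A", "B", c(24, 26))
  expect_equal(c1, c2, tolerance = 0.02)
})

test_that("ROI pairing excludes shared leads and reports counts", {
  ep <- epoch_and_detrend(eeg_recording(
    matrix(rnorm(61 * 3 * 125), 61), 125, hex5))
  spec <- estimate_spectra(ep, fpcoh:::roi_lead_pairs(hex5_rois,
                                                      c("iM1", "iPAR")))
  rc <- roi_pair_coherence(spec, hex5_rois, c("iM1", "iPAR"), c(20, 30))
  expect_equal(rc$n_lead_pairs, 147)                    # 7 x 21, disjoint
  shared <- hex5_rois
  shared$rois$iPAR[1] <- shared$rois$iM1[1]             # one overlap lead
  spec2 <- estimate_spectra(ep, fpcoh:::roi_lead_pairs(shared,
                                                       c("iM1", "iPAR")))
  rc2 <- roi_pair_coherence(spec2, shared, c("iM1", "iPAR"), c(20, 30))
  expect_equal(rc2$n_lead_pairs, 146)
})

test_that("the coherence table covers all circuits and bands", {
  set.seed(20)
  ep <- epoch_and_detrend(eeg_recording(
    matrix(rnorm(61 * 4 * 125), 61), 125, hex5))
  tab <- coherence_table(ep, hex5_rois)
  expect_equal(nrow(tab), 35)                           # 7 circuits x 5 bands
  expect_true(all(tab$coherence >= 0 & tab$coherence <= 1))
  zero <- epoch_and_detrend(eeg_recording(matrix(0, 61, 4 * 125), 125, hex5))
  expect_error(coherence_table(zero, hex5_rois), "zero auto-power")
  # the roi-mean aggregation alternative returns the same shape
  tab2 <- coherence_table(ep, hex5_rois, aggregate = "roi_mean")
  expect_equal(nrow(tab2), 35)
  expect_true(all(tab2$n_lead_pairs == 1))
})

test_that("estimation error shrinks as epochs accumulate", {
  err_at <- function(M) {
    median(vapply(1:10, function(s) {
      rec <- shared_source_recording(1, M, seed = 100 + s)
      spec <- estimate_spectra(epoch_and_detrend(rec), list(c("A", "B")))
      abs(msc(spec, "A", "B", c(20, 30)) - 0.25)
    }, numeric(1)))
  }
  errs <- vapply(c(20, 60, 180), err_at, numeric(1))
  expect_true(errs[3] < errs[1])
  expect_lt(errs[3], 0.02)
})
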