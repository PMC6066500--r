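test_that("spearman handles monotone and degenerate inputs", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.9)
  expect_equal(spearman(x, x)$r, 1)
  expect_equal(spearman(x, -x)$r, -1)
  expect_error(spearman(rep(1, 6), 1:6), "constant")
  expect_error(spearman(1:3, 3:1), "at least 4")
})

test_that("exact spearman p matches the full permutation oracle at n=8", {
  set.seed(21)
  for (rep in 1:3) {
    x <- rnorm(8); y <- rnorm(8)
    got <- spearman(x, y)
    expect_identical(got$method, "exact_permutation")
    # independent oracle: loop over all 8! permutations with cor()
    rx <- rank(x); ry <- rank(y)
    r_obs <- cor(rx, ry)
    perms <- fpcoh:::all_permutations(8)
    cnt <- 0L
    for (i in seq_len(nrow(perms)))
      if (abs(cor(rx, ry[perms[i, ]])) >= abs(r_obs) - 1e-12) cnt <- cnt + 1L
    expect_equal(got$p, cnt / factorial(8))
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(5)
  x <- rnorm(9); y <- rnorm(9)
  base <- spearman(x, y)
  expect_equal(spearman(exp(x), y)$r, base$r)
  expect_equal(spearman(x, y^3)$p, base$p)
})

test_that("exact and approximate spearman p agree near the crossover", {
  set.seed(9)
  d <- replicate(60, {
    x <- rnorm(9); y <- x + rnorm(9, 0, 2)
    abs(spearman(x, y, exact_max = 9)$p - spearman(x, y, exact_max = 0)$p)
  })
  expect_lt(median(d), 0.02)
})

test_that("wilcoxon signed-rank: extreme, symmetric and degenerate cases", {
  pre <- rnorm(12)
  wt <- wilcoxon_signed_rank(pre, pre + 5)
  expect_identical(wt$method, "exact_enumeration")
  expect_equal(wt$p, 2 / 2^12)            # one-sided extreme, doubled
  # perfectly symmetric differences sit at the null center
  pre2 <- 1:10
  post2 <- pre2 + c(rep(2, 5), rep(-2, 5))
  expect_equal(wilcoxon_signed_rank(pre2, post2)$p, 1)
  expect_error(wilcoxon_signed_rank(1:6, 1:6), "zero")
})

test_that("exact wilcoxon p matches the 2^n sign-enumeration oracle", {
  set.seed(13)
  for (rep in 1:3) {
    pre <- rnorm(10); post <- pre + rnorm(10, 0.4)
    got <- wilcoxon_signed_rank(pre, post)
    d <- post - pre
    d <- d[d != 0]
    n <- length(d)
    rk <- rank(abs(d))
    V <- sum(rk[d > 0])
    # enumerate all sign assignments
    W <- colSums(rk * (t(expand.grid(rep(list(c(0, 1)), n)))))
    p_le <- mean(W <= V + 1e-12); p_ge <- mean(W >= V - 1e-12)
    expect_equal(got$p, min(1, 2 * min(p_le, p_ge)))
    expect_equal(got$statistic, V)
  }
})

test_that("cohort prediction finds the coupled circuit and sorts it first", {
  set.seed(31)
  bands <- names(default_bands())
  mk_rec <- function(i, coh_primary, gain) {
    tab <- expand.grid(roi_pair = c("iM1-iPAR", "iM1-iV1"), band = bands,
                       stringsAsFactors = FALSE)
    tab$coherence <- runif(nrow(tab), 0, 0.1)
    tab$coherence[tab$roi_pair == "iM1-iPAR" & tab$band == "high_beta"] <-
      coh_primary
    subject_record(sprintf("S%02d", i), tab,
                   sr_pre = 60, sr_post = 60 * (1 + gain / 100),
                   er_pre = 30, er_post = 28,
                   excluded_lesion = i <= 2)
  }
  coh <- runif(10, 0.1, 0.8)
  gain <- 5 + 50 * coh + rnorm(10, 0, 2)
  recs <- lapply(1:10, function(i) mk_rec(i, coh[i], gain[i]))
  rois <- list(primary_pair = c("iM1", "iPAR"),
               control_pairs = list(c("iM1", "iV1")))
  out <- run_prediction(recs, rois, bands, "sr")
  expect_identical(out$circuit[1], "iM1-iPAR")
  expect_identical(out$band[1], "high_beta")
  expect_identical(out$cohort[1], "all")
  expect_gt(out$r[1], 0.8)
  expect_lt(out$p[1], 0.05)
  expect_equal(out$n[out$cohort == "lesion_excluded"][1], 8)
  expect_true(all(out$p_holm >= out$p))
  expect_error(run_prediction(recs[1:3], rois, bands, "sr"), "at least 4")
})

test_that("change tests report signed percent change with wilcoxon p", {
  set.seed(41)
  bands <- names(default_bands())
  tab <- expand.grid(roi_pair = "iM1-iPAR", band = bands,
                     stringsAsFactors = FALSE)
  recs <- lapply(1:12, function(i) {
    tab$coherence <- runif(nrow(tab), 0.1, 0.6)
    subject_record(i, tab, sr_pre = 60 + rnorm(1), sr_post = 74 + rnorm(1),
                   er_pre = 32 + rnorm(1), er_post = 26 + rnorm(1))
  })
  ct <- change_tests(recs)
  expect_identical(ct$measure, c("sr", "er"))
  expect_true(all(ct$mean_change > 0))    # ER falls but change is positive
  expect_true(all(ct$p < 0.05))
  br <- baseline_relation(recs)
  expect_equal(nrow(br), 3)
})
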