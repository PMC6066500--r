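# Nonparametric statistics: exact Spearman rank correlation, exact Wilcoxon
# signed-rank test, and the cohort-level brain-behavior prediction analyses.

all_permutations <- function(n) {
  # n! x n integer matrix of all permutations of 1..n
  if (n == 1L) return(matrix(1L, 1, 1))
  sp <- all_permutations(n - 1L)
  p <- nrow(sp)
  out <- matrix(0L, n * p, n)
  for (i in seq_len(n)) {
    rest <- sp
    rest[rest >= i] <- rest[rest >= i] + 1L
    out[(i - 1L) * p + seq_len(p), ] <- cbind(rep.int(i, p), rest)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes the Spearman coefficient as the Pearson correlation of mid-ranks
#' (average ranks for ties). The two-sided p-value is obtained by full
#' enumeration of all `n!` permutations of one margin when `n <= exact_max`
#' (conditioning on the observed rank multisets), and by the t approximation
#' with `n - 2` degrees of freedom otherwise. The method used is recorded in
#' the result.
#'
#' @param x,y equal-length numeric vectors, `n >= 4`, finite values
#' @param exact_max largest n for which the permutation enumeration is used
#'   (default 9)
#' @return list with `r`, `p`, `n`, `method`
#' @export
spearman <- function(x, y, exact_max = 9L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 4) stop("at least 4 paired observations are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: constant input")
  r <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perm <- all_permutations(n)
    # r is linear in sum(rx * ry_perm); enumerate that sum
    ryp <- matrix(ry[perm], nrow(perm), n)
    s <- as.vector(ryp %*% rx)
    mu <- n * mean(rx) * mean(ry)
    sc <- (n - 1) * stats::sd(rx) * stats::sd(ry)
    rperm <- (s - mu) / sc
    p <- mean(abs(rperm) >= abs(r) - 1e-12)
    method <- "exact_permutation"
  } else {
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t_approximation"
  }
  list(r = r, p = min(p, 1), n = n, method = method)
}

signed_rank_distribution <- function(ranks2) {
  # exact null distribution of 2*W (W = sum of positive ranks) by
  # convolution over sign assignments; ranks2 = 2*midranks (integers)
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r2 in ranks2) {
    g <- f
    idx <- seq_len(total + 1L - r2)
    g[idx + r2] <- g[idx + r2] + f[idx]
    f <- g
  }
  f / sum(f)
}

#' Wilcoxon signed-rank test with exact enumeration
#'
#' Paired test of within-subject change. Zero differences are dropped (the
#' classic reduction); tied absolute differences receive average ranks. The
#' two-sided p-value is exact — from the full distribution over the `2^n`
#' sign assignments — for `n <= exact_max` non-zero differences, and uses
#' the normal approximation with tie correction otherwise. The method used
#' is recorded.
#'
#' @param pre,post equal-length paired numeric vectors
#' @param exact_max largest n for which exact enumeration is used (default 20)
#' @return list with `statistic` (V, sum of positive ranks), `p`, `n`
#'   (non-zero pairs), `n_zero_dropped`, `method`
#' @export
wilcoxon_signed_rank <- function(pre, post, exact_max = 20L) {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  d <- post - pre
  nz <- d != 0
  n_zero <- sum(!nz)
  d <- d[nz]
  n <- length(d)
  if (n == 0L) stop("all differences are zero: test undefined")
  if (n < 5) stop("fewer than 5 non-zero differences: test unreliable")
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  center <- n * (n + 1) / 4
  if (n <= exact_max) {
    ranks2 <- as.integer(round(2 * rk))
    f <- signed_rank_distribution(ranks2)
    w2 <- as.integer(round(2 * V))
    p_le <- sum(f[seq_len(w2 + 1L)])
    p_ge <- sum(f[(w2 + 1L):length(f)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact_enumeration"
  } else {
    ties <- table(rk)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - center) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal_approximation"
  }
  list(statistic = V, p = p, n = n, n_zero_dropped = n_zero, method = method)
}

#' Construct a per-subject analysis record
#'
#' Bundles one subject's baseline coherence table, pre/post tracking scores
#' and lesion-exclusion flag for the cohort analyses. Percent changes are
#' derived with [percent_change()] (SR higher-better, ER lower-better).
#'
#' @param subject_id identifier
#' @param coherence_table data frame with columns `roi_pair`, `band`,
#'   `coherence` (baseline coherence per circuit and band)
#' @param sr_pre,sr_post,er_pre,er_post session scores in percent
#' @param excluded_lesion logical: lesion touches a critical ROI
#' @return object of class `fpcoh_subject`
#' @export
subject_record <- function(subject_id, coherence_table, sr_pre, sr_post,
                           er_pre, er_post, excluded_lesion = FALSE) {
  if (any(coherence_table$coherence < 0 | coherence_table$coherence > 1))
    stop("coherence values must lie in [0, 1]")
  structure(list(
    subject_id = subject_id, coherence_table = coherence_table,
    sr_pre = sr_pre, sr_post = sr_post, er_pre = er_pre, er_post = er_post,
    pct_change_sr = percent_change(sr_pre, sr_post, "higher_better"),
    pct_change_er = percent_change(er_pre, er_post, "lower_better"),
    excluded_lesion = isTRUE(excluded_lesion)),
    class = "fpcoh_subject")
}

get_subject_coherence <- function(rec, circuit, band) {
  ct <- rec$coherence_table
  hit <- ct$roi_pair == circuit & ct$band == band
  if (!any(hit)) stop("subject ", rec$subject_id, " has no coherence entry ",
                      circuit, " / ", band)
  ct$coherence[which(hit)[1]]
}

#' Brain-behavior prediction analysis across circuits and bands
#'
#' For every circuit (the primary ROI pair plus all control pairs) and every
#' configured frequency band, correlates baseline coherence with the percent
#' change in the chosen tracking endpoint (Spearman), for the full cohort
#' and for the lesion-excluded cohort. Per-test alpha is the convention; a
#' Holm-corrected column is emitted additionally (within cohort) but the
#' headline decision uses the uncorrected p.
#'
#' @param records list of `fpcoh_subject`
#' @param rois `fpcoh_roiset` naming the primary and control pairs
#' @param bands character vector of band names present in the subjects'
#'   coherence tables (default the five standard bands)
#' @param endpoint `"sr"` or `"er"`
#' @return data frame: circuit, band, cohort, n, r, p, p_holm, method;
#'   primary circuit and band first
#' @export
run_prediction <- function(records, rois, bands = names(default_bands()),
                           endpoint = c("sr", "er")) {
  endpoint <- match.arg(endpoint)
  if (length(records) < 4) stop("at least 4 subject records are required")
  circuits <- c(list(rois$primary_pair), rois$control_pairs)
  circuit_ids <- vapply(circuits, paste, character(1), collapse = "-")
  gain <- vapply(records, function(r)
    if (endpoint == "sr") r$pct_change_sr else r$pct_change_er, numeric(1))
  excl <- vapply(records, function(r) r$excluded_lesion, logical(1))
  rows <- list()
  for (cohort in c("all", "lesion_excluded")) {
    keep <- if (cohort == "all") rep(TRUE, length(records)) else !excl
    for (ci in seq_along(circuit_ids)) {
      for (band in bands) {
        coh <- vapply(records, get_subject_coherence, numeric(1),
                      circuit = circuit_ids[ci], band = band)
        if (sum(keep) >= 4) {
          sp <- spearman(coh[keep], gain[keep])
          rows[[length(rows) + 1L]] <- data.frame(
            circuit = circuit_ids[ci], band = band, cohort = cohort,
            n = sp$n, r = sp$r, p = sp$p, method = sp$method)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_holm <- NA_real_
  for (cohort in unique(out$cohort)) {
    i <- out$cohort == cohort
    out$p_holm[i] <- stats::p.adjust(out$p[i], method = "holm")
  }
  prim <- out$circuit == circuit_ids[1]
  primband <- prim & out$band == bands[length(bands)]
  # primary circuit/band first, then primary circuit, then the rest
  out[order(out$cohort != "all", !primband, !prim), ]
}

#' Within-subject change tests for the tracking endpoints
#'
#' Wilcoxon signed-rank tests of pre vs post SR and ER, with the mean and sd
#' of the per-subject percent change reported alongside.
#'
#' @param records list of `fpcoh_subject` (>= 5)
#' @return data frame: measure, mean_change, sd_change, statistic, p, method
#' @export
change_tests <- function(records) {
  if (length(records) < 5) stop("at least 5 subjects are required")
  grab <- function(f) vapply(records, function(r) r[[f]], numeric(1))
  out <- lapply(list(c("sr_pre", "sr_post", "pct_change_sr"),
                     c("er_pre", "er_post", "pct_change_er")), function(ff) {
    wt <- wilcoxon_signed_rank(grab(ff[1]), grab(ff[2]))
    pc <- grab(ff[3])
    data.frame(measure = sub("_pre$", "", ff[1]),
               mean_change = mean(pc), sd_change = stats::sd(pc),
               statistic = wt$statistic, p = wt$p, method = wt$method)
  })
  do.call(rbind, out)
}

#' Baseline relationships (secondary descriptives)
#'
#' Spearman correlations of baseline primary-circuit coherence with baseline
#' SR and ER, and of baseline SR with baseline ER.
#'
#' @param records list of `fpcoh_subject` (>= 4)
#' @param circuit primary circuit id (default `"iM1-iPAR"`)
#' @param band band name (default `"high_beta"`)
#' @return data frame: relation, r, p, n, method
#' @export
baseline_relation <- function(records, circuit = "iM1-iPAR",
                              band = "high_beta") {
  if (length(records) < 4) stop("at least 4 subject records are required")
  coh <- vapply(records, get_subject_coherence, numeric(1),
                circuit = circuit, band = band)
  sr0 <- vapply(records, function(r) r$sr_pre, numeric(1))
  er0 <- vapply(records, function(r) r$er_pre, numeric(1))
  rel <- list(coherence_vs_sr_pre = list(coh, sr0),
              coherence_vs_er_pre = list(coh, er0),
              sr_pre_vs_er_pre = list(sr0, er0))
  do.call(rbind, lapply(names(rel), function(nm) {
    sp <- spearman(rel[[nm]][[1]], rel[[nm]][[2]])
    data.frame(relation = nm, r = sp$r, p = sp$p, n = sp$n,
               method = sp$method)
  }))
}
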