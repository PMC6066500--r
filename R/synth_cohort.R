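# End-to-end synthetic study: per-subject resting EEG with known coupling,
# speed calibration, and pre/post tracking sessions whose learning gain
# follows a linear link to the coupling.

# fast battery scorer: same arithmetic as scoring the generated traces,
# with the path interpolations batched across the three runs
battery_sr <- function(skill, speed, jitters, duration = 90, fs = 30,
                       lag0 = 0.12, sig0 = 50, v_ref = 150, q = 1.8,
                       amplitude = 300, center = c(640, 400),
                       threshold_px = 32) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  n <- length(t)
  lag <- skill_lag_s(skill, lag0)
  sig <- skill_jitter_px(skill, speed, sig0, v_ref, q)
  target <- rose_point_at_arclength(speed * t, amplitude, center)
  lagged <- rose_point_at_arclength(speed * pmax(t - lag, 0), amplitude,
                                    center)
  off <- lagged - target
  mean(vapply(jitters, function(J) {
    dx <- off[, 1] + sig * J[seq_len(n), 1]
    dy <- off[, 2] + sig * J[seq_len(n), 2]
    100 * sum(sqrt(dx^2 + dy^2) < threshold_px) / n
  }, numeric(1)))
}

# invert the skill -> battery-SR map (monotone up to sampling noise):
# bracket on a coarse skill grid, then root-find inside the bracket
invert_battery_skill <- function(target_sr, speed, jitters,
                                 grid = c(0.02, 0.2, 0.5, 1, 2, 4, 8, 16, 50)) {
  sr <- vapply(grid, battery_sr, numeric(1), speed = speed, jitters = jitters)
  if (target_sr >= max(sr))
    return(list(skill = grid[which.max(sr)], clipped = target_sr > max(sr)))
  if (target_sr <= sr[1])
    return(list(skill = grid[1], clipped = target_sr < sr[1]))
  hi <- which(sr >= target_sr)[1]
  root <- stats::uniroot(function(sk)
    battery_sr(sk, speed, jitters) - target_sr,
    c(grid[hi - 1], grid[hi]), tol = 5e-3)$root
  list(skill = root, clipped = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' For each subject: a coupling weight `gamma_i` is drawn uniformly on the
#' configured range; a true learning gain
#' `delta_i = a + b * gamma_i + e_i` (percent relative SR change) is drawn;
#' the speed-calibration procedure is run at the common baseline skill to
#' set the subject's training speed; three 90-s baseline runs are scored;
#' and the post-training skill is found by numerically inverting the
#' skill-to-SR map (common random numbers across skill levels) so that the
#' realized relative SR gain equals `delta_i`. Gains that would require
#' SR > 100 (or below the floor) are clipped and flagged. Optionally each
#' subject's resting EEG is generated with coupling `gamma_i`.
#'
#' Per-subject seeds are derived from the master seed as independent
#' substreams, so adding subjects does not perturb existing ones.
#'
#' @param config `fpcoh_simconfig`
#' @param montage optional `fpcoh_montage` (default: hexagonal grid with
#'   `config$montage_rings` rings)
#' @param rois optional `fpcoh_roiset` (default: [default_roi_set()])
#' @param eeg generate EEG recordings (default TRUE; FALSE keeps only the
#'   behavioral arm and analytic ground truth, for fast statistical
#'   simulations)
#' @param skill_pre common baseline skill (default 0.5, which puts the
#'   baseline SR near 60% at the calibrated training speed)
#' @param keep_parts pass-through to [generate_subject_eeg()]
#' @return object of class `fpcoh_cohort`: list with `config`, `montage`,
#'   `rois`, `subjects` (per-subject recordings, traces, calibration,
#'   scores, truth) and `truth` (cohort-level data frame)
#' @export
generate_cohort <- function(config, montage = NULL, rois = NULL, eeg = TRUE,
                            skill_pre = 0.5, keep_parts = FALSE) {
  if (is.null(montage)) montage <- build_synthetic_montage(config$montage_rings)
  if (is.null(rois)) rois <- default_roi_set(montage)
  subjects <- vector("list", config$n_subjects)
  rows <- list()
  for (i in seq_len(config$n_subjects)) {
    set.seed(subject_seed(config, i, 2L))
    gamma <- stats::runif(1, config$coupling_range[1], config$coupling_range[2])
    delta_true <- config$link_intercept + config$link_slope * gamma +
      stats::rnorm(1, 0, config$link_noise_sd)
    cal <- calibrate_speed(skill_pre, subject_seed(config, i, 3L))
    v_train <- cal$calibration$v_train
    # common random numbers: one jitter matrix per assessment run
    set.seed(subject_seed(config, i, 4L))
    jitters <- lapply(1:3, function(k) matrix(stats::rnorm(2 * 2700), 2700, 2))
    pre_traces <- lapply(jitters, function(J)
      generate_tracking_session(v_train, skill_pre, duration = 90, jitter = J))
    pre <- score_battery(pre_traces)
    target_sr <- pre$sr * (1 + delta_true / 100)
    inv <- invert_battery_skill(target_sr, v_train, jitters)
    skill_post <- inv$skill
    clipped <- inv$clipped
    post_traces <- lapply(jitters, function(J)
      generate_tracking_session(v_train, skill_post, duration = 90,
                                jitter = J))
    post <- score_battery(post_traces)
    subj <- list(id = sprintf("S%02d", i), gamma = gamma,
                 calibration = cal$calibration, v_train = v_train,
                 pre_traces = pre_traces, post_traces = post_traces,
                 pre = pre, post = post,
                 skill_pre = skill_pre, skill_post = skill_post)
    if (eeg) {
      ge <- generate_subject_eeg(config, gamma, montage, rois,
                                 rng_seed = subject_seed(config, i, 5L),
                                 keep_parts = keep_parts)
      subj$recording <- ge$recording
      subj$truth <- ge$truth
    } else {
      subj$truth <- list(
        gamma = gamma,
        analytic_coherence = analytic_band_coherence(gamma, config),
        analytic_coherence_avgref = analytic_band_coherence(
          gamma, config, montage, rois, avg_reference = TRUE))
    }
    subjects[[i]] <- subj
    rows[[i]] <- data.frame(
      subject = subj$id, gamma = gamma,
      analytic_coherence = subj$truth$analytic_coherence,
      analytic_coherence_avgref = subj$truth$analytic_coherence_avgref,
      delta_true = delta_true,
      delta_achieved = percent_change(pre$sr, post$sr, "higher_better"),
      clipped = clipped, v_train = v_train,
      sr_pre = pre$sr, sr_post = post$sr,
      er_pre = pre$er, er_post = post$er)
  }
  structure(list(config = config, montage = montage, rois = rois,
                 subjects = subjects, truth = do.call(rbind, rows)),
            class = "fpcoh_cohort")
}

#' @export
print.fpcoh_cohort <- function(x, ...) {
  cat(sprintf("fpcoh cohort: %d subjects, %s EEG\n", length(x$subjects),
              if (!is.null(x$subjects[[1]]$recording)) "with" else "without"))
  print(utils::head(x$truth[, c("subject", "gamma", "analytic_coherence",
                                "delta_true", "delta_achieved")]))
  invisible(x)
}
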