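# Pursuit-tracking performance scoring: success rate, error rate,
# speed calibration, pre/post percent change.

#' Construct a tracking trace
#'
#' A pursuit-tracking trace holds per-sample target and cursor pixel
#' coordinates sampled at a fixed rate (30 samples/s in the standard
#' assessment).
#'
#' @param t time in seconds
#' @param target_xy n x 2 matrix of target pixel coordinates
#' @param cursor_xy n x 2 matrix of cursor pixel coordinates
#' @param fs sampling rate in samples/s (default 30)
#' @param speed target path speed setting in pixels/s (metadata)
#' @return object of class `fpcoh_trace`
#' @export
tracking_trace <- function(t, target_xy, cursor_xy, fs = 30, speed = NA_real_) {
  target_xy <- as.matrix(target_xy); cursor_xy <- as.matrix(cursor_xy)
  n <- length(t)
  if (nrow(target_xy) != n || nrow(cursor_xy) != n)
    stop("t, target_xy and cursor_xy must have equal lengths")
  if (!all(is.finite(target_xy)) || !all(is.finite(cursor_xy)))
    stop("coordinates must be finite")
  structure(list(t = as.numeric(t), target_xy = target_xy,
                 cursor_xy = cursor_xy, fs = fs, speed = speed),
            class = "fpcoh_trace")
}

#' Read/write a tracking trace as CSV (t,target_x,target_y,cursor_x,cursor_y)
#' @param path CSV path
#' @param fs sampling rate (samples/s)
#' @param speed optional speed metadata
#' @return `fpcoh_trace`
#' @export
read_trace_csv <- function(path, fs = 30, speed = NA_real_) {
  df <- utils::read.csv(path)
  need <- c("t", "target_x", "target_y", "cursor_x", "cursor_y")
  if (!all(need %in% names(df)))
    stop("trace CSV needs columns ", paste(need, collapse = ","))
  tracking_trace(df$t, cbind(df$target_x, df$target_y),
                 cbind(df$cursor_x, df$cursor_y), fs = fs, speed = speed)
}

#' @rdname read_trace_csv
#' @param trace `fpcoh_trace`
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(t = trace$t,
                   target_x = trace$target_xy[, 1],
                   target_y = trace$target_xy[, 2],
                   cursor_x = trace$cursor_xy[, 1],
                   cursor_y = trace$cursor_xy[, 2])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-sample cursor-target Euclidean distance
#'
#' `d_k = sqrt((x_cursor - x_target)^2 + (y_cursor - y_target)^2)` in pixels.
#'
#' @param trace `fpcoh_trace`
#' @return numeric vector of distances, one per sample
#' @export
distance_series <- function(trace) {
  dxy <- trace$cursor_xy - trace$target_xy
  sqrt(dxy[, 1]^2 + dxy[, 2]^2)
}

#' Success Rate (SR) score
#'
#' A sample is a success when the cursor-target distance is strictly below
#' the success radius (32 pixels by default); the SR score is
#' `100 * successes / samples`. A distance of exactly the threshold is a
#' failure.
#'
#' @param trace `fpcoh_trace`
#' @param threshold_px success radius in pixels (default 32)
#' @return SR in percent, in `[0, 100]`
#' @export
success_rate <- function(trace, threshold_px = 32) {
  d <- distance_series(trace)
  if (length(d) == 0L) stop("empty trace: success rate undefined")
  100 * sum(d < threshold_px) / length(d)
}

#' Error Rate (ER) score
#'
#' A distance-magnitude-weighted tracking error: each sample's distance is
#' clipped at a reference distance `d_ref` and the mean clipped distance is
#' expressed as a percent of `d_ref`:
#' `ER = 100 * mean(min(d_k, d_ref)) / d_ref`. Perfect pursuit gives 0;
#' distances at or beyond `d_ref` everywhere give 100. The default reference
#' is 128 px (four success radii); it is exposed for sensitivity analysis.
#'
#' @param trace `fpcoh_trace`
#' @param d_ref reference distance in pixels (default 128)
#' @return ER in percent, in `[0, 100]`
#' @export
error_rate <- function(trace, d_ref = 128) {
  if (d_ref <= 0) stop("d_ref must be positive")
  d <- distance_series(trace)
  if (length(d) == 0L) stop("empty trace: error rate undefined")
  100 * mean(pmin(d, d_ref)) / d_ref
}

#' Score a battery of repeated runs
#'
#' The standard assessment is repeated (three 90-s runs); per-run SR and ER
#' are computed then averaged with equal weights.
#'
#' @param traces list of `fpcoh_trace`
#' @param threshold_px success radius (default 32)
#' @param d_ref ER reference distance (default 128)
#' @return list with `sr`, `er`, `n_runs`, `n_samples`, `threshold_px` and
#'   the per-run scores
#' @export
score_battery <- function(traces, threshold_px = 32, d_ref = 128) {
  if (inherits(traces, "fpcoh_trace")) traces <- list(traces)
  if (length(traces) == 0L) stop("at least one run is required")
  sr <- vapply(traces, success_rate, numeric(1), threshold_px = threshold_px)
  er <- vapply(traces, error_rate, numeric(1), d_ref = d_ref)
  list(sr = mean(sr), er = mean(er), n_runs = length(traces),
       n_samples = sum(vapply(traces, function(x) length(x$t), integer(1))),
       threshold_px = threshold_px, per_run = data.frame(run = seq_along(sr),
                                                         sr = sr, er = er))
}

#' Pre-to-post percent change
#'
#' Signed so that improvement is positive: for `higher_better` measures
#' (SR) the change is `100 * (post - pre) / pre`; for `lower_better`
#' measures (ER) it is `100 * (pre - post) / pre`, so a falling error rate
#' reports a positive gain.
#'
#' @param pre baseline value (nonzero)
#' @param post post-training value
#' @param improvement_direction `"higher_better"` or `"lower_better"`
#' @return percent change
#' @export
percent_change <- function(pre, post,
                           improvement_direction = c("higher_better",
                                                     "lower_better")) {
  improvement_direction <- match.arg(improvement_direction)
  if (any(pre == 0)) stop("percent change undefined for pre = 0")
  if (improvement_direction == "higher_better") 100 * (post - pre) / pre
  else 100 * (pre - post) / pre
}

#' Fit the speed-calibration curve and derive the training speed
#'
#' Across calibration rounds the target speed rises and the success rate
#' falls along a sigmoid: the left asymptote is the too-easy/no-error
#' regime, the right asymptote the too-hard/maximum-error regime. A
#' decreasing four-parameter logistic
#' `sr(v) = L + (U - L) / (1 + exp((v - v50)/s))`
#' is least-squares fitted; the maximum-error speed `v_maxerr` is the
#' smallest speed at which the fitted curve has descended to within 5% of
#' the span above the lower asymptote, i.e. `sr(v) <= L + 0.05*(U - L)`
#' (closed form `v50 + s*log(19)`), and the training speed is 60% of
#' `v_maxerr`.
#'
#' @param rounds data frame with columns `speed` (pixels/s) and `sr`
#'   (percent), at least 5 rounds spanning high- and low-SR regimes
#' @return object of class `fpcoh_calibration`: list with `rounds`, `fit`
#'   (U, L, v50, slope), `v_maxerr`, `v_train`
#' @export
fit_calibration <- function(rounds) {
  rounds <- as.data.frame(rounds)
  if (!all(c("speed", "sr") %in% names(rounds)))
    stop("rounds needs columns speed, sr")
  if (nrow(rounds) < 5) stop("at least 5 calibration rounds are required")
  if (diff(range(rounds$sr)) < 1e-9)
    stop("degenerate calibration: all success rates equal, no sigmoid span")
  if (max(rounds$sr) - min(rounds$sr) < 20)
    stop("calibration rounds do not span both high- and low-SR regimes")
  U0 <- max(rounds$sr); L0 <- min(rounds$sr)
  mid <- (U0 + L0) / 2
  v50_0 <- rounds$speed[which.min(abs(rounds$sr - mid))]
  s0 <- diff(range(rounds$speed)) / 8
  fit <- tryCatch(
    minpack.lm::nlsLM(sr ~ L + (U - L) / (1 + exp((speed - v50) / s)),
                      data = rounds,
                      start = list(U = U0, L = L0, v50 = v50_0, s = s0),
                      lower = c(U = 0, L = 0, v50 = 0, s = 1e-6),
                      upper = c(U = 110, L = 110, v50 = Inf, s = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("calibration fit did not converge: ",
                             conditionMessage(e)))
  p <- stats::coef(fit)
  if (p[["U"]] <= p[["L"]])
    stop("calibration fit degenerate: upper asymptote <= lower asymptote")
  v_maxerr <- p[["v50"]] + p[["s"]] * log(19)
  structure(list(rounds = rounds,
                 fit = list(U = p[["U"]], L = p[["L"]], v50 = p[["v50"]],
                            slope = p[["s"]]),
                 v_maxerr = v_maxerr, v_train = 0.6 * v_maxerr),
            class = "fpcoh_calibration")
}

#' @export
print.fpcoh_calibration <- function(x, ...) {
  cat(sprintf("fpcoh calibration: U=%.1f L=%.1f v50=%.1f slope=%.2f\n",
              x$fit$U, x$fit$L, x$fit$v50, x$fit$slope))
  cat(sprintf("  v_maxerr=%.1f px/s  v_train=%.1f px/s (60%%)\n",
              x$v_maxerr, x$v_train))
  invisible(x)
}
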