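# Synthetic pursuit-tracking sessions: a cloverleaf (four-lobed rose) target
# traversed at constant path speed, pursued by a lagged, jittered cursor.

.path_cache <- new.env(parent = emptyenv())

rose_path_table <- function(amplitude) {
  key <- sprintf("%.9g", amplitude)
  tab <- .path_cache[[key]]
  if (is.null(tab)) {
    n_grid <- 8192L
    th <- seq(0, 2 * pi, length.out = n_grid + 1L)
    r <- amplitude * sin(2 * th)
    x <- r * cos(th); y <- r * sin(th)
    cum <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
    tab <- list(th = th, cum = cum, total = cum[n_grid + 1L])
    .path_cache[[key]] <- tab
  }
  tab
}

rose_point_at_arclength <- function(s, amplitude, center) {
  tab <- rose_path_table(amplitude)
  thi <- stats::approx(tab$cum, tab$th, xout = s %% tab$total,
                       ties = "ordered")$y
  ri <- amplitude * sin(2 * thi)
  cbind(ri * cos(thi) + center[1], ri * sin(thi) + center[2])
}

#' Target path: four-lobed rose curve at constant path speed
#'
#' The cloverleaf is parameterized as the rose `r(theta) = A * sin(2*theta)`
#' and traversed at constant speed along the path, so "speed" is the
#' pixels/s actually travelled. Arc length is tabulated numerically and
#' inverted to sample the position at the trace's frame times.
#'
#' @param speed path speed, pixels/s
#' @param duration seconds
#' @param fs samples/s (default 30)
#' @param amplitude lobe length A in pixels (default 300)
#' @param center 2-vector, pattern center in pixels (default c(640, 400))
#' @return n x 2 matrix of target positions
#' @export
rose_target_path <- function(speed, duration, fs = 30, amplitude = 300,
                             center = c(640, 400)) {
  if (speed <= 0 || duration <= 0) stop("speed and duration must be positive")
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  rose_point_at_arclength(speed * t, amplitude, center)
}

skill_lag_s <- function(skill, lag0 = 0.12) lag0 / (1 + skill)

# Pursuit jitter grows superlinearly with target speed (capacity-limited
# pursuit) and shrinks with skill; this shape produces the observed
# 100 -> 0 sigmoidal SR-vs-speed calibration curve with a mid-range
# operating point at the 60%-of-maximum-error training speed.
skill_jitter_px <- function(skill, speed, sig0 = 50, v_ref = 150, q = 1.8)
  sig0 * (speed / v_ref)^q / (1 + skill)

#' Generate one pursuit-tracking session
#'
#' The cursor is a lagged pursuit of the target with isotropic Gaussian
#' jitter: `cursor(t) = target(t - lag) + noise`. Both the lag and the
#' jitter standard deviation decrease with `skill` (`lag0 / (1 + skill)`
#' and `sig0 * (speed/v_ref)^q / (1 + skill)`); the jitter additionally
#' grows superlinearly with target speed, emulating capacity-limited
#' pursuit, which is what bends the SR-vs-speed calibration curve into a
#' sigmoid running from ~100 down to ~0. Infinite skill gives a perfect
#' pursuit. With `jitter` supplied, the same standard-normal draws are
#' reused across skill levels (common random numbers), which makes the
#' skill-to-score map smooth enough to invert numerically.
#'
#' @param speed target path speed, pixels/s
#' @param skill non-negative skill parameter
#' @param duration seconds (default 90)
#' @param rng_seed integer seed (ignored when `jitter` is given)
#' @param fs samples/s (default 30)
#' @param lag0 lag at skill 0, seconds (default 0.12)
#' @param sig0 jitter sd at skill 0 and the reference speed, pixels
#'   (default 50)
#' @param v_ref,q reference speed (pixels/s) and exponent of the
#'   speed-dependence of the jitter (defaults 150, 1.8)
#' @param amplitude,center rose-curve geometry
#' @param jitter optional n x 2 matrix of standard-normal draws
#' @return `fpcoh_trace`
#' @export
generate_tracking_session <- function(speed, skill, duration = 90, rng_seed,
                                      fs = 30, lag0 = 0.12, sig0 = 50,
                                      v_ref = 150, q = 1.8,
                                      amplitude = 300, center = c(640, 400),
                                      jitter = NULL) {
  if (skill < 0) stop("skill must be non-negative")
  if (speed <= 0 || duration <= 0) stop("speed and duration must be positive")
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  n <- length(t)
  target <- rose_point_at_arclength(speed * t, amplitude, center)
  lag <- skill_lag_s(skill, lag0)
  sig <- skill_jitter_px(skill, speed, sig0, v_ref, q)
  lagged <- rose_point_at_arclength(speed * pmax(t - lag, 0), amplitude,
                                    center)
  if (is.null(jitter)) {
    if (missing(rng_seed)) stop("rng_seed is required when jitter is not given")
    set.seed(as.integer(rng_seed))
    jitter <- matrix(stats::rnorm(2 * n), n, 2)
  }
  cursor <- lagged + sig * jitter[seq_len(n), , drop = FALSE]
  tracking_trace(t, target, cursor, fs = fs, speed = speed)
}

#' Run the speed-calibration procedure on the simulator
#'
#' Plays calibration rounds of increasing target speed at a fixed skill,
#' scores each round's success rate, and fits the sigmoidal calibration
#' curve to obtain the training speed (60% of the maximum-error speed).
#'
#' @param skill subject skill
#' @param rng_seed integer seed
#' @param speeds round speeds, pixels/s (default 8 rounds, 40-400)
#' @param round_duration seconds per round (default 30)
#' @param ... passed to [generate_tracking_session()]
#' @return list with `rounds` (speed, sr data frame) and `calibration`
#'   (`fpcoh_calibration`)
#' @export
calibrate_speed <- function(skill, rng_seed,
                            speeds = seq(40, 400, length.out = 8),
                            round_duration = 30, ...) {
  sr <- vapply(seq_along(speeds), function(i) {
    tr <- generate_tracking_session(speeds[i], skill,
                                    duration = round_duration,
                                    rng_seed = rng_seed + i, ...)
    success_rate(tr)
  }, numeric(1))
  rounds <- data.frame(speed = speeds, sr = sr)
  list(rounds = rounds, calibration = fit_calibration(rounds))
}
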