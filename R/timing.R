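#' Construct an arm trajectory
#'
#' An arm trajectory is the uniformly sampled lever angle time series of
#' one throw with a marked release sample. Angular velocity, if not
#' recorded, is estimated at every sample with the same trailing
#' 20-sample linear fit used for the release velocity, so the error
#' trajectory and the scored release use one estimator (the first 20
#' samples inherit the first defined estimate).
#'
#' @param angle Numeric vector of lever angles, degrees.
#' @param release_index 1-based index of the release sample.
#' @param sample_rate Sampling rate, Hz.
#' @param velocity Optional numeric vector of angular velocities,
#'   degrees/s; estimated when omitted.
#' @param time Optional time vector, s; defaults to `0, 1/fs, ...`.
#' @return A tibble of class `skittler_trajectory` with columns `time`,
#'   `angle`, `velocity`, and attributes `release_index`, `sample_rate`.
#' @export
arm_trajectory <- function(angle, release_index, sample_rate = 1000,
                           velocity = NULL, time = NULL) {
  n <- length(angle)
  if (n < 21)
    stop("arm trajectory needs at least 21 samples", call. = FALSE)
  release_index <- as.integer(release_index)
  if (release_index < 1 || release_index > n)
    stop("release_index out of range", call. = FALSE)
  if (is.null(time)) time <- (seq_len(n) - 1) / sample_rate
  if (length(time) != n)
    stop("time and angle lengths differ", call. = FALSE)
  dt <- diff(time)
  if (any(abs(dt - 1 / sample_rate) > 1e-9))
    stop("trajectory is not uniformly sampled at sample_rate",
         call. = FALSE)
  if (is.null(velocity)) velocity <- trailing_slope(angle, sample_rate)
  if (length(velocity) != n)
    stop("velocity and angle lengths differ", call. = FALSE)
  structure(
    tibble::tibble(time = time, angle = angle, velocity = velocity),
    release_index = release_index,
    sample_rate = sample_rate,
    class = c("skittler_trajectory", class(tibble::tibble())))
}

#' @export
print.skittler_trajectory <- function(x, ...) {
  ri <- attr(x, "release_index")
  cat(sprintf(
    "<arm trajectory: %d samples at %g Hz, release at sample %d (t = %.3f s)>\n",
    nrow(x), attr(x, "sample_rate"), ri, x$time[ri]))
  NextMethod()
}

#' Convert an arm trajectory into an error trajectory
#'
#' Scores every sample of the trajectory as a hypothetical ball release,
#' yielding the error time series on which both timing measures are
#' defined. The error at the release sample equals the throw's actual
#' performance error by construction.
#'
#' @param traj A [arm_trajectory()] (or a data frame with `time`, `angle`,
#'   `velocity` plus a `release_index` attribute).
#' @param config A [task_config()].
#' @return A tibble of class `skittler_error_trajectory` with columns
#'   `time`, `error` (cm), `post_hit`; attributes `release_index`,
#'   `sample_rate`, `success_threshold`, `subthreshold_intervals` (maximal
#'   runs of sub-threshold samples, as a two-column matrix of start/end
#'   indices) and `ideal_index` (global error minimum).
#' @export
error_trajectory <- function(traj, config) {
  validate_task_config(config)
  stopifnot(all(c("angle", "velocity") %in% names(traj)))
  if (nrow(traj) < 21)
    stop("arm trajectory needs at least 21 samples", call. = FALSE)
  ri <- attr(traj, "release_index")
  if (is.null(ri)) stop("trajectory has no release_index", call. = FALSE)
  fs <- attr(traj, "sample_rate") %||% config$sample_rate
  scored <- score_states_quick(traj$angle, traj$velocity, config)
  new_error_trajectory(traj$time, scored$error, scored$post_hit,
                       release_index = ri, sample_rate = fs,
                       success_threshold = config$success_threshold)
}

#' Assemble an error trajectory from a precomputed error series
#'
#' Mainly useful for constructed error series (analyses of hypothetical
#' trajectories, unit checks); [error_trajectory()] is the standard route.
#'
#' @param time Time vector, s (uniform).
#' @param error Error series, cm (>= 0).
#' @param release_index 1-based release sample.
#' @param sample_rate Hz.
#' @param success_threshold cm.
#' @param post_hit Optional logical vector.
#' @return A `skittler_error_trajectory`.
#' @export
as_error_trajectory <- function(time, error, release_index,
                                sample_rate = 1000,
                                success_threshold = 1.1,
                                post_hit = NULL) {
  if (any(error < 0)) stop("errors must be >= 0", call. = FALSE)
  new_error_trajectory(time, error,
                       post_hit %||% rep(FALSE, length(error)),
                       release_index, sample_rate, success_threshold)
}

new_error_trajectory <- function(time, error, post_hit, release_index,
                                 sample_rate, success_threshold) {
  sub <- error < success_threshold
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- cbind(lo = starts[r$values], hi = ends[r$values])
  structure(
    tibble::tibble(time = time, error = error, post_hit = post_hit),
    release_index = as.integer(release_index),
    sample_rate = sample_rate,
    success_threshold = success_threshold,
    subthreshold_intervals = runs,
    ideal_index = which.min(error),
    class = c("skittler_error_trajectory", class(tibble::tibble())))
}

# Reference sample of the ideal release under a given rule.
# nearest_crossing: among the local minima of the sub-threshold runs, the
# one closest in time to the release; falls back to the global minimum
# when no sample is sub-threshold. window_midpoint: midpoint of the run
# selected by nearest_crossing. global_min: global error minimum.
ideal_reference <- function(et, rule) {
  ri <- attr(et, "release_index")
  runs <- attr(et, "subthreshold_intervals")
  if (rule == "global_min" || nrow(runs) == 0)
    return(list(index = attr(et, "ideal_index"), run = NA_integer_))
  run_min <- vapply(seq_len(nrow(runs)), function(k) {
    idx <- runs[k, "lo"]:runs[k, "hi"]
    idx[which.min(et$error[idx])]
  }, integer(1))
  k <- which.min(abs(run_min - ri))
  idx <- if (rule == "window_midpoint")
    as.integer(round((runs[k, "lo"] + runs[k, "hi"]) / 2))
  else run_min[k]
  list(index = idx, run = k)
}

timing_rules <- c("nearest_crossing", "global_min", "window_midpoint")

#' Timing error of a throw
#'
#' Absolute time difference, in ms, between the actual release and the
#' ideal release of the error trajectory. Under the default
#' `nearest_crossing` rule the ideal release is the error minimum of the
#' sub-threshold run nearest in time to the release (if the trajectory
#' crosses the solution manifold more than once, the closest crossing
#' counts); with no sub-threshold sample it falls back to the global
#' minimum. `global_min` always uses the global minimum;
#' `window_midpoint` uses the midpoint of the selected run.
#'
#' @param et A `skittler_error_trajectory`.
#' @param rule Reference-selection rule.
#' @return Timing error in ms (>= 0).
#' @export
timing_error <- function(et, rule = timing_rules) {
  rule <- match.arg(rule)
  ref <- ideal_reference(et, rule)
  fs <- attr(et, "sample_rate")
  abs(attr(et, "release_index") - ref$index) / fs * 1000
}

#' Timing window of a throw
#'
#' Duration, in ms, of the contiguous sub-threshold segment of the error
#' trajectory containing the ideal release selected by the
#' `nearest_crossing` rule: the number of samples with error below the
#' success threshold in that run times the sampling interval. When the
#' trajectory crosses the manifold more than once only the segment near
#' the ideal release counts; 0 when no sample is sub-threshold.
#'
#' @param et A `skittler_error_trajectory`.
#' @return Timing window in ms (>= 0).
#' @export
timing_window <- function(et) {
  runs <- attr(et, "subthreshold_intervals")
  if (nrow(runs) == 0) return(0)
  ref <- ideal_reference(et, "nearest_crossing")
  if (is.na(ref$run)) return(0)
  unname((runs[ref$run, "hi"] - runs[ref$run, "lo"] + 1) /
           attr(et, "sample_rate") * 1000)
}

#' Both timing measures of one throw
#'
#' @param et A `skittler_error_trajectory`.
#' @param rule Reference rule for the timing error (see [timing_error()]).
#' @return A one-row tibble: `timing_error` (ms), `timing_window` (ms),
#'   `ideal_release_time` (s), `rule`.
#' @export
timing_measures <- function(et, rule = timing_rules) {
  rule <- match.arg(rule)
  ref <- ideal_reference(et, rule)
  tibble::tibble(
    timing_error = timing_error(et, rule),
    timing_window = timing_window(et),
    ideal_release_time = et$time[ref$index],
    rule = rule)
}

#' Timing measures in polar and Cartesian execution frames
#'
#' Computes timing error and timing window twice for the same trajectory:
#' once from the recorded polar execution variables (angle, angular
#' velocity) and once after mapping every sample through the Cartesian
#' velocity parameterization and back. The two frames describe the same
#' physical launches at the same times, so both measures are invariant
#' under the change of coordinates; this function makes that check
#' executable on any trajectory.
#'
#' @param traj An [arm_trajectory()].
#' @param config A [task_config()].
#' @param rule Reference rule, as in [timing_error()].
#' @return A two-row tibble with a `frame` column (`"polar"`,
#'   `"cartesian"`) and the [timing_measures()] columns.
#' @export
timing_measures_by_frame <- function(traj, config,
                                     rule = timing_rules) {
  rule <- match.arg(rule)
  et_polar <- error_trajectory(traj, config)
  cart <- exec_to_cartesian(
    tibble::tibble(angle = traj$angle, velocity = traj$velocity), config)
  # the Cartesian frame is undefined at zero velocity (no tangent
  # direction); those samples keep their polar representation
  moving <- cart$vx != 0 | cart$vy != 0
  back <- tibble::tibble(angle = traj$angle, velocity = traj$velocity)
  if (any(moving)) {
    bk <- exec_from_cartesian(
      tibble::tibble(vx = cart$vx[moving], vy = cart$vy[moving]), config,
      sense = sign(traj$velocity[moving]))
    back$angle[moving] <- bk$angle
    back$velocity[moving] <- bk$velocity
  }
  traj_cart <- arm_trajectory(back$angle,
                              release_index = attr(traj, "release_index"),
                              sample_rate = attr(traj, "sample_rate"),
                              velocity = back$velocity,
                              time = traj$time)
  et_cart <- error_trajectory(traj_cart, config)
  dplyr::bind_rows(
    dplyr::mutate(timing_measures(et_polar, rule), frame = "polar"),
    dplyr::mutate(timing_measures(et_cart, rule), frame = "cartesian")) |>
    dplyr::relocate("frame")
}

#' Plot an error trajectory
#'
#' Error against time with the success threshold, the release marker and
#' the ideal-release reference: the standard picture for reading off the
#' timing error (horizontal offset of the two markers) and the timing
#' window (sub-threshold segment).
#'
#' @param object A `skittler_error_trajectory`.
#' @param rule Reference rule, as in [timing_error()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skittler_error_trajectory <- function(object,
                                               rule = timing_rules, ...) {
  rule <- match.arg(rule)
  ri <- attr(object, "release_index")
  ref <- ideal_reference(object, rule)
  thr <- attr(object, "success_threshold")
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thr, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$time[ri], colour = "red") +
    ggplot2::geom_vline(xintercept = object$time[ref$index],
                        colour = "blue", linetype = 3) +
    ggplot2::labs(x = "time (s)", y = "error (cm)",
                  subtitle = sprintf(
                    "timing error %.1f ms, timing window %.1f ms",
                    timing_error(object, rule), timing_window(object))) +
    ggplot2::theme_minimal()
}
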