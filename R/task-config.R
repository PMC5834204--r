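#' Define a skittles task configuration
#'
#' A task configuration bundles the workspace geometry, the ball-flight
#' physics and the scoring thresholds of one variant of the virtual
#' skittles (tetherball) throwing task. The workspace is a top-down 2-D
#' plane in centimetres with the spring rest position at the origin; the
#' player rotates a lever about a fixed pivot and the ball, once released,
#' follows the closed-form damped two-spring orbit around the origin.
#'
#' @param post_center Centre of the post, cm (2-vector).
#' @param post_radius Post radius, cm. `0` removes the post entirely.
#' @param target_center Centre of the target, cm (2-vector).
#' @param target_radius Target radius, cm (display/feedback only; scoring
#'   uses the thresholds below on the centre-to-centre distance).
#' @param ball_radius Ball radius, cm (enters post-contact detection).
#' @param lever_pivot Lever pivot, cm (2-vector).
#' @param lever_length Lever length, cm.
#' @param omega Natural frequency of the two restoring springs, rad/s.
#' @param tau Damping time constant, s; `Inf` gives an undamped orbit.
#' @param success_threshold Error below which a throw is a hit, cm.
#' @param miss_threshold Error below which a throw still strikes the
#'   target ("near"), cm.
#' @param max_display_error Errors above this (or post hits) are
#'   invalid/off-screen, cm.
#' @param throw_direction `"clockwise"` or `"counterclockwise"`; the sense
#'   of lever rotation used when a velocity magnitude must be signed.
#' @param sample_rate Encoder sampling rate for arm trajectories, Hz.
#' @param name Optional label for the configuration.
#'
#' @return An object of class `skittler_config` (a named list).
#' @examples
#' cfg <- task_config(target_center = c(0, 110), tau = Inf)
#' cfg
#' @export
task_config <- function(post_center = c(0, 0),
                        post_radius = 25,
                        target_center = c(0, 60),
                        target_radius = 2.5,
                        ball_radius = 2.5,
                        lever_pivot = c(0, -150),
                        lever_length = 40,
                        omega = 2 * pi,
                        tau = 10,
                        success_threshold = 1.1,
                        miss_threshold = 2.5,
                        max_display_error = 40,
                        throw_direction = c("counterclockwise", "clockwise"),
                        sample_rate = 1000,
                        name = NULL) {
  throw_direction <- match.arg(throw_direction)
  cfg <- structure(list(
    post_center = as.numeric(post_center),
    post_radius = as.numeric(post_radius),
    target_center = as.numeric(target_center),
    target_radius = as.numeric(target_radius),
    ball_radius = as.numeric(ball_radius),
    lever_pivot = as.numeric(lever_pivot),
    lever_length = as.numeric(lever_length),
    omega = as.numeric(omega),
    tau = as.numeric(tau),
    success_threshold = as.numeric(success_threshold),
    miss_threshold = as.numeric(miss_threshold),
    max_display_error = as.numeric(max_display_error),
    throw_direction = throw_direction,
    sample_rate = as.numeric(sample_rate),
    name = name
  ), class = "skittler_config")
  validate_task_config(cfg)
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "skittler_config"))
  with(cfg, {
    if (length(post_center) != 2 || length(target_center) != 2 ||
        length(lever_pivot) != 2)
      stop("post_center, target_center and lever_pivot must be 2-vectors",
           call. = FALSE)
    if (!all(is.finite(c(post_center, target_center, lever_pivot))))
      stop("geometry coordinates must be finite", call. = FALSE)
    if (post_radius < 0) stop("post_radius must be >= 0", call. = FALSE)
    if (target_radius <= 0 || ball_radius <= 0 || lever_length <= 0)
      stop("radii and lever_length must be positive", call. = FALSE)
    if (!(omega > 0)) stop("omega must be positive", call. = FALSE)
    if (!(tau > 0)) stop("tau must be positive (Inf = undamped)",
                         call. = FALSE)
    if (!(success_threshold < miss_threshold &&
          miss_threshold <= max_display_error))
      stop("need success_threshold < miss_threshold <= max_display_error",
           call. = FALSE)
    if (!(sample_rate > 0)) stop("sample_rate must be positive",
                                 call. = FALSE)
  })
  cfg
}

#' @export
print.skittler_config <- function(x, ...) {
  cat("<skittler task config", if (!is.null(x$name)) paste0(": ", x$name),
      ">\n", sep = "")
  cat(sprintf("  post    centre (%g, %g) cm, radius %g cm%s\n",
              x$post_center[1], x$post_center[2], x$post_radius,
              if (x$post_radius == 0) " (no post)" else ""))
  cat(sprintf("  target  centre (%g, %g) cm, radius %g cm\n",
              x$target_center[1], x$target_center[2], x$target_radius))
  cat(sprintf("  lever   pivot (%g, %g) cm, length %g cm, %s throws\n",
              x$lever_pivot[1], x$lever_pivot[2], x$lever_length,
              x$throw_direction))
  cat(sprintf("  flight  omega %g rad/s, tau %g s\n", x$omega, x$tau))
  cat(sprintf("  scoring hit < %g cm, near < %g cm, invalid > %g cm\n",
              x$success_threshold, x$miss_threshold, x$max_display_error))
  invisible(x)
}

config_fields <- c("post_center", "post_radius", "target_center",
                   "target_radius", "ball_radius", "lever_pivot",
                   "lever_length", "omega", "tau", "success_threshold",
                   "miss_threshold", "max_display_error",
                   "throw_direction", "sample_rate", "name")

#' Read and write task configurations
#'
#' Task configurations are stored as flat YAML key/value files whose keys
#' are exactly the `task_config()` argument names (lengths in cm, times in
#' s, omega in rad/s, sample_rate in Hz). `tau: .inf` denotes an undamped
#' task.
#'
#' @param path File path.
#' @return `read_task_config()` returns a `skittler_config`;
#'   `write_task_config()` returns `path` invisibly.
#' @export
read_task_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown <- setdiff(names(raw), config_fields)
  if (length(unknown))
    stop("unknown config keys in ", path, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  raw <- lapply(raw, function(v) {
    if (identical(v, ".inf") || identical(v, "Inf")) Inf else v
  })
  do.call(task_config, raw)
}

#' @param config A `skittler_config`.
#' @rdname read_task_config
#' @export
write_task_config <- function(config, path) {
  validate_task_config(config)
  x <- unclass(config)
  x <- x[!vapply(x, is.null, logical(1))]
  header <- paste(
    "# skittler task configuration",
    "# units: lengths cm, times s, omega rad/s, sample_rate Hz",
    "# tau: .inf means an undamped (tau = infinity) flight", sep = "\n")
  txt <- yaml::as.yaml(x, precision = 15)
  writeLines(c(header, txt), path)
  invisible(path)
}

#' Bundled task variants
#'
#' Loads one of the four bundled task geometries. The four variants are
#' named after the qualitative shape of their solution manifold in
#' execution space (release angle x release velocity):
#'
#' * `"u_shape"`: a symmetric valley; tolerance widens at lower velocities.
#' * `"j_shape"`: the manifold runs into the post-hit region and ends in a
#'   discontinuity.
#' * `"box_shape"`: post displaced from the origin; shallow error gradient
#'   and a manifold reaching down to low velocities.
#' * `"i_shape"`: undamped flight with the target at the antipode of a
#'   release position, so error does not depend on release velocity and
#'   the manifold is a band parallel to the velocity axis.
#'
#' These are representative geometries chosen by a coarse search over
#' target placements (see the package vignette); the original experiment's
#' exact coordinates are not public, so any study-specific geometry should
#' be supplied via [task_config()] or [read_task_config()].
#'
#' @param name One of `"u_shape"`, `"j_shape"`, `"box_shape"`, `"i_shape"`.
#' @return A `skittler_config`.
#' @examples
#' skittler_task("box_shape")
#' @export
skittler_task <- function(name = c("u_shape", "j_shape", "box_shape",
                                   "i_shape")) {
  name <- match.arg(name)
  path <- system.file("extdata", "configs", paste0(name, ".yaml"),
                      package = "skittler", mustWork = TRUE)
  read_task_config(path)
}
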