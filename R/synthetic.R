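#' Throwing strategy parameters
#'
#' A strategy is the deterministic skeleton of a simulated single-joint
#' throw: a minimum-jerk lever rotation from `start_angle` to `end_angle`
#' over `movement_time`, followed by a hold ("follow-through") segment,
#' with the ball released at a planned fraction of the movement. The
#' minimum-jerk profile is the canonical smooth single-joint movement:
#' \eqn{\theta(s) = \theta_s + \Delta\theta\,(10 s^3 - 15 s^4 + 6 s^5)}
#' with \eqn{s = t/T}, whose peak angular speed is
#' \eqn{1.875\,|\Delta\theta|/T} at \eqn{s = 1/2}.
#'
#' @param start_angle,end_angle Degrees; must differ.
#' @param movement_time Movement duration `T`, s.
#' @param planned_release_fraction Planned release time as a fraction of
#'   the realized movement duration, in (0, 1).
#' @param follow_through_fraction Extra simulated duration after the
#'   movement, as a fraction of `movement_time` (>= 0).
#' @return An object of class `skittler_strategy`.
#' @export
strategy_params <- function(start_angle, end_angle, movement_time,
                            planned_release_fraction = 0.5,
                            follow_through_fraction = 0.25) {
  if (end_angle == start_angle)
    stop("degenerate strategy: start and end angle coincide", call. = FALSE)
  if (!(movement_time > 0)) stop("movement_time must be > 0", call. = FALSE)
  if (!(planned_release_fraction > 0 && planned_release_fraction < 1))
    stop("planned_release_fraction must lie in (0, 1)", call. = FALSE)
  if (follow_through_fraction < 0)
    stop("follow_through_fraction must be >= 0", call. = FALSE)
  structure(list(start_angle = start_angle, end_angle = end_angle,
                 movement_time = movement_time,
                 planned_release_fraction = planned_release_fraction,
                 follow_through_fraction = follow_through_fraction),
            class = "skittler_strategy")
}

#' Trial-to-trial noise model
#'
#' Gaussian trial-to-trial variability applied to a strategy: jitter of
#' the release time (the intrinsic timing noise the timing measures are
#' designed to quantify), variability of the movement amplitude, and
#' variability of the movement duration. All draws are reproducible from
#' `seed`.
#'
#' @param release_jitter_sd SD of release-time jitter, ms.
#' @param amplitude_sd SD of the end-angle perturbation, degrees.
#' @param duration_sd SD of the movement-duration perturbation, ms.
#' @param seed Integer seed.
#' @return An object of class `skittler_noise`.
#' @export
noise_model <- function(release_jitter_sd = 20, amplitude_sd = 2,
                        duration_sd = 30, seed = 1L) {
  if (any(c(release_jitter_sd, amplitude_sd, duration_sd) < 0))
    stop("noise SDs must be >= 0", call. = FALSE)
  structure(list(release_jitter_sd = release_jitter_sd,
                 amplitude_sd = amplitude_sd,
                 duration_sd = duration_sd,
                 seed = as.integer(seed)),
            class = "skittler_noise")
}

#' Generate one synthetic arm trajectory
#'
#' Draws the trial's duration and amplitude perturbations, samples the
#' minimum-jerk rotation at the task's sampling rate, appends the
#' follow-through hold, and marks the release sample at the planned
#' fraction of the realized movement plus Gaussian release jitter
#' (truncated so the release stays strictly inside the simulated span and
#' keeps the 20-sample velocity-estimation history).
#'
#' @param strategy A [strategy_params()].
#' @param noise A [noise_model()]; its `seed` makes the trial
#'   reproducible.
#' @param config A [task_config()] (supplies `sample_rate`).
#' @param estimate_velocity If `TRUE` (default) the trajectory carries
#'   velocities from the trailing 20-sample fit, as for recorded data;
#'   otherwise the analytic minimum-jerk velocity is stored.
#' @return An [arm_trajectory()].
#' @examples
#' cfg <- skittler_task("box_shape")
#' sp <- strategy_params(150, 60, 0.45)
#' traj <- generate_arm_trajectory(sp, noise_model(seed = 7), cfg)
#' traj
#' @export
generate_arm_trajectory <- function(strategy, noise, config,
                                    estimate_velocity = TRUE) {
  stopifnot(inherits(strategy, "skittler_strategy"),
            inherits(noise, "skittler_noise"))
  validate_task_config(config)
  fs <- config$sample_rate
  draws <- with_seed(noise$seed, {
    stats::rnorm(3)
  })
  dur <- strategy$movement_time + draws[1] * noise$duration_sd / 1000
  dur <- max(dur, 30 / fs)
  amp_end <- strategy$end_angle + draws[2] * noise$amplitude_sd
  if (amp_end == strategy$start_angle)
    stop("degenerate trial: zero amplitude", call. = FALSE)
  jitter <- draws[3] * noise$release_jitter_sd / 1000

  n_move <- round(dur * fs)
  n_follow <- round(strategy$follow_through_fraction * dur * fs)
  s <- seq(0, 1, length.out = n_move + 1)
  dtheta <- amp_end - strategy$start_angle
  theta <- strategy$start_angle + dtheta * (10 * s^3 - 15 * s^4 + 6 * s^5)
  theta <- c(theta, rep(theta[length(theta)], n_follow))
  n <- length(theta)

  t_release <- strategy$planned_release_fraction * dur + jitter
  ri <- round(t_release * fs) + 1L
  ri <- min(max(ri, 21L), n - 1L)

  vel <- if (estimate_velocity) NULL else {
    v <- 30 * dtheta / dur * s^2 * (1 - s)^2
    c(v, rep(0, n_follow))
  }
  arm_trajectory(theta, release_index = ri, sample_rate = fs,
                 velocity = vel)
}

#' Multi-day practice schedule
#'
#' A learner schedule pairs one [strategy_params()] and one
#' [noise_model()] per practice day, with the session size of the
#' standard protocol: 240 throws per day in 4 blocks of 60.
#'
#' @param strategies List of per-day strategies (length = days).
#' @param noises List of per-day noise models (same length).
#' @param throws_per_day Throws per daily session.
#' @param blocks Blocks per session; must divide `throws_per_day`.
#' @return An object of class `skittler_schedule`.
#' @export
learner_schedule <- function(strategies, noises, throws_per_day = 240,
                             blocks = 4) {
  if (length(strategies) < 1 || length(strategies) != length(noises))
    stop("need one strategy and one noise model per day", call. = FALSE)
  if (throws_per_day %% blocks != 0)
    stop("throws_per_day must be divisible by blocks", call. = FALSE)
  structure(list(strategies = strategies, noises = noises,
                 throws_per_day = as.integer(throws_per_day),
                 blocks = as.integer(blocks),
                 days = length(strategies)),
            class = "skittler_schedule")
}

#' Simulate one practice session
#'
#' Generates the day's trajectories. Each throw gets its own sub-seed
#' derived from the day's noise seed and the (day, throw) counters via
#' [derive_seed()], so sessions are reproducible and throws independent.
#'
#' @param schedule A [learner_schedule()].
#' @param day Day number (1-based).
#' @param config A [task_config()].
#' @return A list of [arm_trajectory()] objects with attributes `day`,
#'   `block` recorded per element.
#' @export
simulate_session <- function(schedule, day, config) {
  stopifnot(inherits(schedule, "skittler_schedule"))
  if (day < 1 || day > schedule$days)
    stop("day out of schedule range", call. = FALSE)
  sp <- schedule$strategies[[day]]
  nm <- schedule$noises[[day]]
  per_block <- schedule$throws_per_day / schedule$blocks
  purrr::map(seq_len(schedule$throws_per_day), function(throw) {
    nm_throw <- nm
    nm_throw$seed <- derive_seed(nm$seed, day, throw)
    tr <- generate_arm_trajectory(sp, nm_throw, config)
    attr(tr, "day") <- day
    attr(tr, "throw") <- throw
    attr(tr, "block") <- ((throw - 1) %/% per_block) + 1L
    tr
  })
}

#' Calibrate a strategy to a task's solution manifold
#'
#' Searches for strategy parameters whose noiseless trajectory overlaps
#' the solution manifold long enough to reach a requested timing window.
#' Candidate strategies are seeded from manifold points (the minimum-jerk
#' peak velocity is placed on the manifold: mid-movement angle at the
#' manifold angle, peak speed at the manifold velocity) over a range of
#' movement amplitudes, then the best candidate is refined by a local
#' coordinate search; the planned release fraction is always reset to the
#' trajectory's own ideal release sample. On a geometry whose manifold
#' runs parallel to the velocity axis the achievable window has a floor
#' (crossing the angle band more slowly eventually drives the ball into
#' the post), so the target may be unattainable; the best strategy found
#' is returned with `achieved = FALSE`.
#'
#' @param config A [task_config()].
#' @param target_window_ms Requested timing window, ms.
#' @param amplitudes Candidate movement amplitudes, degrees.
#' @param angle_range Release-angle range mapped when searching for the
#'   manifold; the default extends the frontal arc by 90 degrees in the
#'   task's throw direction.
#' @param resolution Grid resolution for the manifold map.
#' @param follow_through_fraction Passed to the candidate strategies.
#' @param n_seeds Number of manifold points used as candidate seeds.
#' @return A [strategy_params()] with attributes `achieved_window` (ms)
#'   and `achieved` (logical).
#' @export
calibrate_strategy <- function(config, target_window_ms,
                               amplitudes = c(20, 30, 45, 60, 80, 100),
                               angle_range = NULL,
                               resolution = c(150, 100),
                               follow_through_fraction = 0.25,
                               n_seeds = 9) {
  validate_task_config(config)
  if (is.null(angle_range))
    angle_range <- if (config$throw_direction == "counterclockwise")
      c(0, 270) else c(-90, 180)
  space <- solution_space(config, angle_range = angle_range,
                          resolution = resolution)
  mf <- solution_manifold(space)
  if (nrow(mf) == 0)
    stop("task has an empty solution manifold; nothing to calibrate to",
         call. = FALSE)
  sgn <- if (config$throw_direction == "counterclockwise") 1 else -1
  pick <- mf[round(seq(1, nrow(mf), length.out = min(n_seeds, nrow(mf)))), ]

  best <- NULL
  eval_candidate <- function(theta_star, v_star, amp) {
    if (v_star < 20) return(NULL)
    Tm <- 1.875 * amp / v_star
    # keep movements in the range of fast human single-joint throws
    if (Tm < 0.12 || Tm > 0.45) return(NULL)
    sp <- strategy_params(theta_star - sgn * amp / 2,
                          theta_star + sgn * amp / 2,
                          Tm, 0.5, follow_through_fraction)
    sp <- set_release_at_ideal(sp, config)
    w <- noiseless_window(sp, config)
    list(sp = sp, window = w)
  }
  consider <- function(cand) {
    if (!is.null(cand) && (is.null(best) || cand$window > best$window))
      best <<- cand
    invisible(NULL)
  }
  for (i in seq_len(nrow(pick))) for (amp in amplitudes)
    consider(eval_candidate(pick$angle[i],
                            (pick$v_lo[i] + pick$v_hi[i]) / 2, amp))
  if (is.null(best))
    stop("no feasible candidate strategy found", call. = FALSE)

  # local coordinate refinement around the best seed
  sp0 <- best$sp
  theta0 <- (sp0$start_angle + sp0$end_angle) / 2
  amp0 <- abs(sp0$end_angle - sp0$start_angle)
  v0 <- 1.875 * amp0 / sp0$movement_time
  for (step in c(1, 0.5, 0.25)) {
    for (dth in c(-2, 0, 2) * step) for (dv in c(-0.12, 0, 0.12) * step)
      for (da in c(-10, 0, 10) * step)
        consider(eval_candidate(theta0 + dth, v0 * (1 + dv), amp0 + da))
    theta0 <- (best$sp$start_angle + best$sp$end_angle) / 2
    amp0 <- abs(best$sp$end_angle - best$sp$start_angle)
    v0 <- 1.875 * amp0 / best$sp$movement_time
  }

  out <- best$sp
  attr(out, "achieved_window") <- best$window
  attr(out, "achieved") <- best$window >= target_window_ms
  out
}

# Timing window of the noiseless trajectory of a strategy.
noiseless_window <- function(strategy, config) {
  nm <- noise_model(0, 0, 0, seed = 1L)
  tr <- generate_arm_trajectory(strategy, nm, config)
  timing_window(error_trajectory(tr, config))
}

# Reset the planned release fraction so the noiseless release falls on
# the trajectory's own ideal release sample: the midpoint of its timing
# window when one exists (the release that maximizes tolerance to timing
# jitter, which is what practice converges to), else the global error
# minimum.
set_release_at_ideal <- function(strategy, config) {
  nm <- noise_model(0, 0, 0, seed = 1L)
  tr <- generate_arm_trajectory(strategy, nm, config)
  et <- error_trajectory(tr, config)
  ref <- ideal_reference(et, "window_midpoint")
  fs <- config$sample_rate
  dur <- strategy$movement_time
  f <- (ref$index - 1L) / fs / dur
  f <- min(max(f, 1e-3), 1 - 1e-3)
  strategy$planned_release_fraction <- f
  strategy
}
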