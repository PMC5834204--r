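#' Build a practice schedule for one simulated learner
#'
#' Emulates the two-phase learning pattern of multi-day throwing
#' practice: release-timing jitter drops geometrically over the first
#' days and then plateaus (fast early reduction of timing error), while
#' the strategy's angular placement converges linearly from a displaced
#' ("naive") version of the calibrated strategy toward the
#' manifold-aligned one (steady, continuing growth of the timing window
#' throughout practice). Movement tempo is held at the calibrated value,
#' so on geometries where the window cannot be lengthened by alignment
#' (manifold parallel to the velocity axis) the window stays near its
#' floor.
#'
#' @param config A [task_config()].
#' @param calibrated A manifold-aligned [strategy_params()], e.g. from
#'   [calibrate_strategy()].
#' @param days Number of practice days.
#' @param jitter_start,jitter_floor,jitter_decay Release-jitter SD
#'   schedule, ms: day d uses
#'   `floor + (start - floor) * decay^(d-1)`.
#' @param shift_start,shift_floor Angular misalignment schedule, degrees:
#'   the displacement of the calibrated start/end angles interpolates
#'   linearly from `shift_start` on day 1 to `shift_floor` on the last
#'   day. A non-zero floor models a learner who never aligns perfectly.
#' @param amplitude_sd,duration_sd Trial-to-trial execution noise
#'   (degrees, ms), constant across days.
#' @param seed Seed for the schedule's noise models.
#' @param throws_per_day,blocks Session size.
#' @return A [learner_schedule()].
#' @export
practice_schedule <- function(config, calibrated, days = 6,
                              jitter_start = 50, jitter_floor = 18,
                              jitter_decay = 0.45,
                              shift_start = 12, shift_floor = 0,
                              amplitude_sd = 1.2, duration_sd = 20,
                              seed = 1L, throws_per_day = 240,
                              blocks = 4) {
  stopifnot(inherits(calibrated, "skittler_strategy"))
  shift_start <- max(shift_start, shift_floor)
  strategies <- purrr::map(seq_len(days), function(d) {
    frac <- if (days > 1) (d - 1) / (days - 1) else 1
    shift <- shift_start + (shift_floor - shift_start) * frac
    sp <- calibrated
    sp$start_angle <- sp$start_angle + shift
    sp$end_angle <- sp$end_angle + shift
    set_release_at_ideal(sp, config)
  })
  noises <- purrr::map(seq_len(days), function(d) {
    sigma <- jitter_floor + (jitter_start - jitter_floor) *
      jitter_decay^(d - 1)
    noise_model(release_jitter_sd = sigma, amplitude_sd = amplitude_sd,
                duration_sd = duration_sd, seed = derive_seed(seed, d))
  })
  learner_schedule(strategies, noises, throws_per_day, blocks)
}

#' Simulate a multi-day practice cohort
#'
#' Generates and analyzes a full synthetic experiment on one task:
#' `n_subjects` learners, each practicing `days` daily sessions of
#' `throws_per_day` throws. Subjects share the task's calibrated strategy
#' but differ in independent random factors: the scale of their release
#' jitter (initial and asymptotic), the initial size of their angular
#' misalignment, and the asymptotic misalignment they converge to (some
#' learners never align fully). Jitter and alignment factors are drawn
#' independently so that between-subject variance in the two timing
#' measures is not collinear.
#'
#' @param config A [task_config()].
#' @param n_subjects Number of simulated subjects.
#' @param days Practice days per subject.
#' @param seed Top-level seed; everything (subject factors, trial noise)
#'   derives from it.
#' @param throws_per_day Throws per daily session.
#' @param rule Timing-error reference rule. The default matches the
#'   generator's release placement (mid-window), so with a stable window
#'   the timing error reduces to the injected release jitter; the
#'   `nearest_crossing` rule gives equivalent results on short windows
#'   but its run-minimum reference wanders on long flat error valleys.
#' @param calibrated Optional pre-computed calibrated strategy (computed
#'   via [calibrate_strategy()] when omitted).
#' @param keep_trajectories Retain the generated trajectories (as a
#'   `trajectories` element keyed by `subject_day_throw`); off by default
#'   as full cohorts are large.
#' @param ... Further arguments passed to [practice_schedule()].
#' @return A list of class `skittler_cohort`: `throws` (per-throw tibble
#'   with `subject`, `day`, measures), `summaries` (per subject-day
#'   [summarize_session()] rows), `config`, `seed`.
#' @examples
#' \donttest{
#' cfg <- skittler_task("box_shape")
#' coh <- simulate_cohort(cfg, n_subjects = 4, days = 2, seed = 1,
#'                        throws_per_day = 20)
#' coh$summaries
#' }
#' @export
simulate_cohort <- function(config, n_subjects = 10, days = 6, seed = 1L,
                            throws_per_day = 240,
                            rule = c("window_midpoint",
                                     "nearest_crossing", "global_min"),
                            calibrated = NULL,
                            keep_trajectories = FALSE, ...) {
  rule <- match.arg(rule)
  validate_task_config(config)
  if (is.null(calibrated))
    calibrated <- calibrate_strategy(config, target_window_ms = 0)

  per_subject <- purrr::map(seq_len(n_subjects), function(s) {
    fac <- with_seed(derive_seed(seed, s, 999L), stats::runif(3))
    jit_scale <- 0.8 + 0.5 * fac[1]
    shift_scale <- 0.7 + 0.6 * fac[2]
    # timing ability converges to a narrow band across learners, while
    # the alignment each learner settles at varies widely
    shift_floor <- 0.4 + 9.6 * fac[3]
    sched <- practice_schedule(
      config, calibrated, days = days,
      jitter_start = 50 * jit_scale,
      jitter_floor = 17.5 + 2 * fac[1],
      shift_start = 12 * shift_scale, shift_floor = shift_floor,
      seed = derive_seed(seed, s),
      throws_per_day = throws_per_day, ...)
    day_res <- purrr::map(seq_len(days), function(d) {
      session <- simulate_session(sched, d, config)
      throws <- analyze_trajectories(session, config, rule)
      trajs <- if (keep_trajectories) {
        names(session) <- sprintf("s%d_d%d_t%03d", s, d,
                                  seq_along(session))
        session
      }
      list(throws = dplyr::mutate(throws, subject = s, day = d),
           summary = summarize_session(throws, subject = s, day = d),
           trajs = trajs)
    })
    list(throws = purrr::list_rbind(purrr::map(day_res, "throws")),
         summaries = purrr::list_rbind(purrr::map(day_res, "summary")),
         trajs = purrr::flatten(purrr::map(day_res, "trajs")))
  })

  structure(list(
    throws = purrr::list_rbind(purrr::map(per_subject, "throws")),
    summaries = purrr::list_rbind(purrr::map(per_subject, "summaries")),
    trajectories = if (keep_trajectories)
      purrr::flatten(purrr::map(per_subject, "trajs")),
    config = config, seed = seed,
    calibrated = calibrated), class = "skittler_cohort")
}

#' @export
print.skittler_cohort <- function(x, ...) {
  cat(sprintf(
    "<simulated cohort: %d subjects x %d days, %d throws analyzed>\n",
    length(unique(x$summaries$subject)),
    length(unique(x$summaries$day)), nrow(x$throws)))
  print(x$summaries)
  invisible(x)
}
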