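# Dense-sampling brute-force scorer: evaluates the closed-form flight on
# a fine fixed time grid, truncates at the first sample inside post
# contact, and takes the minimum distance to the target. Kept deliberately
# independent of the package's coarse-scan + refinement search path.
brute_force_error <- function(angle, velocity, config, dt = 1e-5) {
  la <- launch_states(tibble::tibble(angle = angle, velocity = velocity),
                      config)
  fp <- flight_params(la, config)
  t <- seq(0, 2 * pi / config$omega, by = dt)
  pb <- ball_path(fp, t)
  if (config$post_radius > 0) {
    dpost <- sqrt((pb$x - config$post_center[1])^2 +
                    (pb$y - config$post_center[2])^2)
    inside <- which(dpost < config$post_radius + config$ball_radius)
    if (length(inside)) pb <- pb[seq_len(max(inside[1] - 1, 1)), ]
  }
  min(sqrt((pb$x - config$target_center[1])^2 +
             (pb$y - config$target_center[2])^2))
}

# A post-free undamped task with the target at the antipode of the
# theta = 90 degree release position: the singular geometry where release
# velocity cannot matter.
antipodal_config <- function() {
  task_config(target_center = c(0, 110), post_radius = 0, tau = Inf,
              throw_direction = "counterclockwise", name = "antipodal")
}

# Construct a solution-space object from an arbitrary error surface, for
# oracle tests of manifold extraction on known functions.
synthetic_space <- function(angle_axis, velocity_axis, error_fun,
                            config = task_config()) {
  grid <- tidyr::expand_grid(angle = angle_axis, velocity = velocity_axis)
  grid$error <- error_fun(grid$angle, grid$velocity)
  grid$post_hit <- FALSE
  grid$category <- factor(
    ifelse(grid$error < config$success_threshold, "hit",
           ifelse(grid$error < config$miss_threshold, "near",
                  ifelse(grid$error > config$max_display_error,
                         "invalid", "miss"))),
    levels = c("hit", "near", "miss", "invalid"))
  structure(grid, angle_axis = angle_axis, velocity_axis = velocity_axis,
            config = config,
            class = c("skittler_space", class(grid)))
}

# Small min-jerk trajectory through a chosen execution state: peak
# velocity v_star is reached at mid-movement angle theta_star.
trajectory_through <- function(theta_star, v_star, config, amp = 50,
                               seed = 1L, noise = noise_model(0, 0, 0,
                                                              seed = seed)) {
  sgn_v <- sign(v_star)
  Tm <- 1.875 * amp / abs(v_star)
  sp <- strategy_params(theta_star - sgn_v * amp / 2,
                        theta_star + sgn_v * amp / 2, Tm, 0.5)
  generate_arm_trajectory(sp, noise, config)
}
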