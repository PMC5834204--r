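#' Map lever release states to ball launch states
#'
#' The ball is attached to the tip of a lever of length \eqn{L} rotating
#' about a fixed pivot. A release state is the pair (angle, angular
#' velocity); the launch state is the Cartesian position and tangential
#' velocity of the lever tip at that instant. Angles are measured from the
#' workspace +x axis, positive counterclockwise, so the tip sits at
#' `pivot + L (cos theta, sin theta)` and moves along
#' `L thetadot (-sin theta, cos theta)`.
#'
#' @param states A data frame with columns `angle` (degrees) and
#'   `velocity` (angular velocity, degrees/s, signed: positive =
#'   counterclockwise).
#' @param config A [task_config()].
#' @return `states` as a tibble with launch columns `x0`, `y0` (cm) and
#'   `vx0`, `vy0` (cm/s) appended.
#' @examples
#' cfg <- task_config()
#' launch_states(tibble::tibble(angle = 90, velocity = 0), cfg)
#' @export
launch_states <- function(states, config) {
  validate_task_config(config)
  stopifnot(all(c("angle", "velocity") %in% names(states)))
  th <- states$angle * pi / 180
  w <- states$velocity * pi / 180
  if (!all(is.finite(th)) || !all(is.finite(w)))
    stop("release states must be finite", call. = FALSE)
  L <- config$lever_length
  tibble::as_tibble(states) |>
    dplyr::mutate(
      x0 = config$lever_pivot[1] + L * cos(th),
      y0 = config$lever_pivot[2] + L * sin(th),
      vx0 = -L * w * sin(th),
      vy0 = L * w * cos(th))
}

#' Closed-form flight coefficients from a launch state
#'
#' The released ball moves on two orthogonal damped springs with rest
#' position at the origin: per axis \eqn{x(t) = A_x \sin(\omega t +
#' \varphi_x) e^{-t/\tau}}. The amplitude and phase of each axis are
#' recovered from the launch position and velocity by matching
#' \eqn{x(0)} and \eqn{\dot x(0)}:
#' \eqn{A\sin\varphi = x_0} and \eqn{A\omega\cos\varphi = v_0 + x_0/\tau}.
#' A motionless axis (both conditions zero) gets \eqn{A = 0,
#' \varphi = 0} by convention.
#'
#' @param launches A data frame with columns `x0`, `y0`, `vx0`, `vy0`
#'   (e.g. from [launch_states()]).
#' @param config A [task_config()] supplying `omega` and `tau`.
#' @return `launches` with columns `Ax`, `Ay` (cm) and `phix`, `phiy`
#'   (rad, in (-pi, pi]) appended.
#' @export
flight_params <- function(launches, config) {
  validate_task_config(config)
  invtau <- if (is.infinite(config$tau)) 0 else 1 / config$tau
  ap <- function(p0, v0) {
    P <- p0
    Q <- (v0 + p0 * invtau) / config$omega
    A <- sqrt(P^2 + Q^2)
    phi <- ifelse(A == 0, 0, atan2(P, Q))
    phi <- ifelse(phi <= -pi, pi, phi)
    list(A = A, phi = phi)
  }
  x <- ap(launches$x0, launches$vx0)
  y <- ap(launches$y0, launches$vy0)
  tibble::as_tibble(launches) |>
    dplyr::mutate(Ax = x$A, phix = x$phi, Ay = y$A, phiy = y$phi,
                  omega = config$omega, tau = config$tau)
}

#' Evaluate the ball flight path
#'
#' Evaluates the closed-form orbit of one flight at the requested times.
#'
#' @param flight A one-row data frame with columns `Ax`, `phix`, `Ay`,
#'   `phiy`, `omega`, `tau` (from [flight_params()]).
#' @param times Numeric vector of times, s (each >= 0).
#' @return A tibble with columns `time`, `x`, `y` (cm).
#' @export
ball_path <- function(flight, times) {
  stopifnot(nrow(flight) == 1, all(times >= 0))
  damp <- if (is.infinite(flight$tau)) rep(1, length(times))
          else exp(-times / flight$tau)
  tibble::tibble(
    time = times,
    x = flight$Ax * sin(flight$omega * times + flight$phix) * damp,
    y = flight$Ay * sin(flight$omega * times + flight$phiy) * damp)
}

# Analytic velocity of the flight path; used by round-trip checks.
ball_path_velocity <- function(flight, times) {
  invtau <- if (is.infinite(flight$tau)) 0 else 1 / flight$tau
  damp <- exp(-times * invtau)
  vx <- flight$Ax * damp * (flight$omega * cos(flight$omega * times +
          flight$phix) - invtau * sin(flight$omega * times + flight$phix))
  vy <- flight$Ay * damp * (flight$omega * cos(flight$omega * times +
          flight$phiy) - invtau * sin(flight$omega * times + flight$phiy))
  tibble::tibble(time = times, vx = vx, vy = vy)
}

throw_categories <- c("hit", "near", "miss", "invalid")

# Lean scoring path used in inner loops (error trajectories, grids):
# plain vectors in, list(error, post_hit, t_min) out, no data-frame
# overhead.
score_states_quick <- function(angle, velocity, config,
                               refine_tol = 1e-6) {
  th <- angle * pi / 180
  w <- velocity * pi / 180
  L <- config$lever_length
  score_states_cpp(
    config$lever_pivot[1] + L * cos(th),
    config$lever_pivot[2] + L * sin(th),
    -L * w * sin(th), L * w * cos(th),
    config$omega, config$tau,
    config$target_center[1], config$target_center[2],
    config$post_center[1], config$post_center[2],
    config$post_radius + config$ball_radius,
    config$post_radius > 0,
    2 * pi / config$omega, 1e-3, refine_tol)
}

categorize_error <- function(error, post_hit, config) {
  dplyr::case_when(
    post_hit | error > config$max_display_error ~ "invalid",
    error < config$success_threshold ~ "hit",
    error < config$miss_threshold ~ "near",
    .default = "miss")
}

#' Score throws against the target and post
#'
#' Simulates each release over one full oscillation period `2 pi / omega`,
#' truncating the flight at the first post contact (centre-to-centre
#' distance below `post_radius + ball_radius`; a zero `post_radius` removes
#' the post). The performance error of a throw is the minimum distance
#' between the (untruncated) ball path and the target centre, located by a
#' 1 ms coarse scan with golden-section refinement. Categories follow the
#' feedback shown to players: `hit` (error below the success threshold,
#' no post contact), `near` (below the miss threshold), `invalid` (post
#' contact or error beyond the display range), else `miss`.
#'
#' @param states A data frame with columns `angle` (degrees) and `velocity`
#'   (degrees/s, signed). Extra columns are carried through.
#' @param config A [task_config()].
#' @param refine_tol Time resolution of the minimum search, s.
#' @return `states` as a tibble with columns `error` (cm), `post_hit`,
#'   `time_closest` (s) and `category` appended.
#' @examples
#' cfg <- skittler_task("box_shape")
#' score_throws(tibble::tibble(angle = 120, velocity = 400), cfg)
#' @export
score_throws <- function(states, config, refine_tol = 1e-6) {
  validate_task_config(config)
  stopifnot(all(c("angle", "velocity") %in% names(states)))
  if (!all(is.finite(states$angle)) || !all(is.finite(states$velocity)))
    stop("release states must be finite", call. = FALSE)
  res <- score_states_quick(states$angle, states$velocity, config,
                            refine_tol)
  tibble::as_tibble(states) |>
    dplyr::mutate(
      error = res$error,
      post_hit = res$post_hit,
      time_closest = res$t_min,
      category = factor(categorize_error(res$error, res$post_hit, config),
                        levels = throw_categories))
}

#' Score a single release state
#'
#' Convenience scalar wrapper around [score_throws()].
#'
#' @param angle Release angle, degrees.
#' @param velocity Release angular velocity, degrees/s (signed).
#' @inheritParams score_throws
#' @return A one-row tibble (see [score_throws()]).
#' @export
score_throw <- function(angle, velocity, config, refine_tol = 1e-6) {
  score_throws(tibble::tibble(angle = angle, velocity = velocity),
               config, refine_tol = refine_tol)
}

#' Convert execution variables between polar and Cartesian frames
#'
#' The same physical launch can be parameterized either by the lever's
#' release angle and angular velocity (polar execution variables) or by
#' the Cartesian components of the tangential release velocity, `vx` and
#' `vy`. Because the hand stays on the lever circle and its velocity is
#' tangential, the velocity vector determines the release angle up to the
#' rotation sense, which the task's `throw_direction` resolves; the two
#' frames therefore map to the same ball flight and the same error.
#' The inverse is undefined for a zero velocity vector.
#'
#' @param states A data frame with columns `angle`, `velocity` (for
#'   `exec_to_cartesian()`).
#' @param config A [task_config()]; `throw_direction` resolves the sign
#'   ambiguity in the inverse map.
#' @return `exec_to_cartesian()`: input with columns `vx`, `vy` (cm/s)
#'   appended. `exec_from_cartesian()`: input with columns `angle`
#'   (degrees) and `velocity` (degrees/s) appended.
#' @examples
#' cfg <- task_config(throw_direction = "counterclockwise")
#' s <- tibble::tibble(angle = 120, velocity = 300)
#' exec_to_cartesian(s, cfg) |> exec_from_cartesian(cfg)
#' @export
exec_to_cartesian <- function(states, config) {
  la <- launch_states(states, config)
  tibble::as_tibble(states) |>
    dplyr::mutate(vx = la$vx0, vy = la$vy0)
}

#' @param cart A data frame with columns `vx`, `vy` (cm/s), for
#'   `exec_from_cartesian()`.
#' @param sense Optional rotation sense per row, `+1` (counterclockwise)
#'   or `-1` (clockwise), overriding the task's `throw_direction` where a
#'   sample is known to rotate against it.
#' @rdname exec_to_cartesian
#' @export
exec_from_cartesian <- function(cart, config, sense = NULL) {
  validate_task_config(config)
  stopifnot(all(c("vx", "vy") %in% names(cart)))
  speed <- sqrt(cart$vx^2 + cart$vy^2)
  if (any(speed == 0))
    stop("the zero velocity vector has no release angle", call. = FALSE)
  sgn <- sense %||%
    (if (config$throw_direction == "counterclockwise") 1 else -1)
  # unit tangent u = (-sin theta, cos theta) = sgn * v / |v|
  ux <- sgn * cart$vx / speed
  uy <- sgn * cart$vy / speed
  theta <- atan2(-ux, uy) * 180 / pi
  thetadot <- sgn * speed / config$lever_length * 180 / pi
  tibble::as_tibble(cart) |>
    dplyr::mutate(angle = theta, velocity = thetadot)
}
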