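test_that("lever kinematics follow the angle convention", {
  cfg <- task_config()
  la <- launch_states(
    tibble::tibble(angle = c(90, 0), velocity = c(0, 0)), cfg)
  expect_equal(la$x0, c(0, 40), tolerance = 1e-12)
  expect_equal(la$y0, c(-110, -150))
  expect_equal(la$vx0, c(0, 0))
  expect_equal(la$vy0, c(0, 0))

  # speed = L * |thetadot| in rad/s, for any angle
  onerad <- 180 / pi
  la2 <- launch_states(
    tibble::tibble(angle = runif(20, -180, 180), velocity = onerad), cfg)
  expect_equal(sqrt(la2$vx0^2 + la2$vy0^2), rep(40, 20),
               tolerance = 1e-12)

  # velocity direction: tangential, consistent with finite differences
  th <- 37; dth <- 1e-6
  p1 <- launch_states(tibble::tibble(angle = th, velocity = 0), cfg)
  p2 <- launch_states(tibble::tibble(angle = th + dth, velocity = 0), cfg)
  v <- launch_states(tibble::tibble(angle = th, velocity = 1), cfg)
  fd <- c(p2$x0 - p1$x0, p2$y0 - p1$y0) / (dth * pi / 180)
  expect_equal(c(v$vx0, v$vy0) / (pi / 180), fd, tolerance = 1e-5)
})

test_that("launch states are rejected when non-finite", {
  cfg <- task_config()
  expect_error(launch_states(tibble::tibble(angle = NA_real_,
                                            velocity = 0), cfg), "finite")
  expect_error(score_throw(Inf, 0, cfg), "finite")
})

test_that("flight coefficients reproduce position and velocity at release", {
  cfg <- task_config()
  set.seed(101)
  states <- tibble::tibble(angle = runif(200, -180, 360),
                           velocity = runif(200, -1000, 1000))
  la <- launch_states(states, cfg)
  fp <- flight_params(la, cfg)
  for (i in sample.int(200, 25)) {
    p0 <- ball_path(fp[i, ], 0)
    v0 <- skittler:::ball_path_velocity(fp[i, ], 0)
    expect_equal(c(p0$x, p0$y), c(la$x0[i], la$y0[i]), tolerance = 1e-9)
    expect_equal(c(v0$vx, v0$vy), c(la$vx0[i], la$vy0[i]),
                 tolerance = 1e-9)
  }
  expect_true(all(fp$Ax >= 0 & fp$Ay >= 0))
  expect_true(all(fp$phix > -pi & fp$phix <= pi))
})

test_that("degenerate flight axes get amplitude 0 and phase 0", {
  cfg <- task_config(tau = Inf)
  fp <- flight_params(
    tibble::tibble(x0 = 0, y0 = 10, vx0 = 0, vy0 = 0), cfg)
  expect_equal(fp$Ax, 0)
  expect_equal(fp$phix, 0)
  # release at a turning point: phase pi/2, amplitude = displacement
  expect_equal(fp$Ay, 10)
  expect_equal(fp$phiy, pi / 2)
})

test_that("undamped flights are antipodal and periodic", {
  cfg <- task_config(tau = Inf)
  la <- launch_states(tibble::tibble(angle = 132, velocity = 411), cfg)
  fp <- flight_params(la, cfg)
  w <- cfg$omega
  for (t0 in c(0, 0.13, 0.48)) {
    a <- ball_path(fp, t0)
    b <- ball_path(fp, t0 + pi / w)
    expect_equal(c(b$x, b$y), -c(a$x, a$y), tolerance = 1e-9)
  }
  p0 <- ball_path(fp, 0)
  p1 <- ball_path(fp, 2 * pi / w)
  expect_equal(c(p1$x, p1$y), c(p0$x, p0$y), tolerance = 1e-9)
  # zero-amplitude flight never moves
  still <- flight_params(tibble::tibble(x0 = 0, y0 = 0, vx0 = 0,
                                        vy0 = 0), cfg)
  pb <- ball_path(still, seq(0, 1, 0.1))
  expect_true(all(pb$x == 0 & pb$y == 0))
})

test_that("damping shrinks the orbit envelope monotonically", {
  cfg <- task_config(tau = 3)
  la <- launch_states(tibble::tibble(angle = 80, velocity = 300), cfg)
  fp <- flight_params(la, cfg)
  w <- cfg$omega
  # sample the same phase once per cycle: amplitude decays by e^(-T/tau)
  t <- (0:4) * 2 * pi / w + 0.1
  pb <- ball_path(fp, t)
  r <- sqrt(pb$x^2 + pb$y^2)
  expect_equal(r[-1] / r[-5], rep(exp(-2 * pi / w / 3), 4),
               tolerance = 1e-9)
})

test_that("score_throw finds constructed zero-error releases", {
  cfg0 <- task_config(post_radius = 0, name = "free")
  la <- launch_states(tibble::tibble(angle = 120, velocity = 500), cfg0)
  fp <- flight_params(la, cfg0)
  tstar <- 0.31
  pt <- ball_path(fp, tstar)
  cfg1 <- task_config(post_radius = 0,
                      target_center = c(pt$x, pt$y))
  res <- score_throw(120, 500, cfg1)
  expect_lt(res$error, 1e-6)
  expect_equal(as.character(res$category), "hit")
  expect_equal(res$time_closest, tstar, tolerance = 1e-3)
})

test_that("undamped antipodal targets are hit at any release velocity", {
  cfg <- antipodal_config()
  vels <- seq(10, 1000, length.out = 25)
  res <- score_throws(tibble::tibble(angle = 90, velocity = vels), cfg)
  expect_true(all(res$error < 1e-6))
})

test_that("scored error matches the dense brute-force oracle", {
  cfg <- task_config()
  set.seed(7)
  n <- 100
  states <- tibble::tibble(angle = runif(n, 0, 180),
                           velocity = runif(n, -1000, 1000))
  scored <- score_throws(states, cfg)
  oracle <- mapply(brute_force_error, states$angle, states$velocity,
                   MoreArgs = list(config = cfg))
  expect_lt(max(abs(scored$error - oracle)), 0.01)
})

test_that("throw categories follow the feedback thresholds", {
  cfg <- task_config()
  cats <- skittler:::categorize_error(
    error = c(0.5, 1.09, 1.1, 1.5, 2.49, 2.5, 39, 41, 0.5),
    post_hit = c(rep(FALSE, 8), TRUE), cfg)
  expect_equal(cats, c("hit", "hit", "near", "near", "near", "miss",
                       "miss", "invalid", "invalid"))
})

test_that("release velocity estimation is the trailing-20-sample OLS slope", {
  # constant angle: zero velocity
  expect_equal(estimate_angular_velocity(rep(5, 40), 30), 0)
  # exact linear ramp at 1 kHz: slope recovered exactly
  t <- (0:499) / 1000
  expect_equal(estimate_angular_velocity(100 * t, 400), 100,
               tolerance = 1e-9)
  # quadratic profile: matches an independent least-squares fit
  th <- 50 * t^2
  idx <- 501 - 1 # release at t = 0.5 s
  got <- estimate_angular_velocity(th, 500)
  win <- 480:499
  fit <- lm(th[win] ~ t[win])
  expect_equal(got, unname(coef(fit)[2]), tolerance = 1e-9)
  # insufficient history is an error
  expect_error(estimate_angular_velocity(th, 20), "insufficient history")
})

test_that("polar and Cartesian execution variables are interchangeable", {
  for (dir in c("clockwise", "counterclockwise")) {
    cfg <- task_config(throw_direction = dir)
    sgn <- if (dir == "counterclockwise") 1 else -1
    set.seed(11)
    states <- tibble::tibble(angle = runif(50, 0, 180),
                             velocity = sgn * runif(50, 10, 1000))
    back <- exec_to_cartesian(states, cfg) |>
      dplyr::select("vx", "vy") |>
      exec_from_cartesian(cfg)
    expect_equal(back$angle, states$angle, tolerance = 1e-9)
    expect_equal(back$velocity, states$velocity, tolerance = 1e-9)

    # the same physical launch: identical scores in both frames
    s1 <- score_throws(states, cfg)
    s2 <- score_throws(back[c("angle", "velocity")], cfg)
    expect_equal(s2$error, s1$error, tolerance = 1e-9)
    expect_identical(s2$post_hit, s1$post_hit)
  }
  # theta = 0, positive spin: velocity along +y; inverse recovers it
  cfg <- task_config(throw_direction = "counterclockwise")
  v <- exec_to_cartesian(tibble::tibble(angle = 0, velocity = 100), cfg)
  expect_equal(c(v$vx, v$vy), c(0, 40 * 100 * pi / 180), tolerance = 1e-12)
  expect_error(
    exec_from_cartesian(tibble::tibble(vx = 0, vy = 0), cfg), "zero")
})
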