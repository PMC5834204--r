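vshape_series <- function(min_ms, n_ms = 600, slope = 0.02, floor = 0) {
  # |t - min| ramp in cm at 1 kHz, minimum value `floor`
  t <- 0:(n_ms - 1)
  floor + slope * abs(t - min_ms)
}

test_that("timing error measures the offset to the ideal release", {
  et <- as_error_trajectory(time = (0:599) / 1000,
                            error = vshape_series(300),
                            release_index = 251)
  # release 50 ms before a sub-threshold minimum at 300 ms
  expect_equal(timing_error(et, "nearest_crossing"), 50)
  expect_equal(timing_error(et, "global_min"), 50)
  # release exactly at the minimum: zero under every rule
  et0 <- as_error_trajectory((0:599) / 1000, vshape_series(300), 301)
  expect_equal(timing_error(et0, "global_min"), 0)
  expect_equal(timing_error(et0, "nearest_crossing"), 0)
})

test_that("with two manifold crossings the closest one is the reference", {
  # two sub-threshold minima, the *global* one at 200 ms, a local one at
  # 400 ms; release at 360 ms sits nearer the 400 ms crossing
  err <- pmin(vshape_series(200), vshape_series(400, floor = 0.2))
  et <- as_error_trajectory((0:599) / 1000, err, 361)
  expect_equal(timing_error(et, "nearest_crossing"), 40)
  expect_equal(timing_error(et, "global_min"), 160)
})

test_that("above-threshold trajectories fall back to the global minimum", {
  err <- vshape_series(300, floor = 2) # never below 1.1 cm
  et <- as_error_trajectory((0:599) / 1000, err, 251)
  expect_equal(timing_error(et, "nearest_crossing"), 50)
  expect_equal(timing_window(et), 0)
})

test_that("timing window counts the sub-threshold run at the reference", {
  # samples 100..149 (1-based 101..150) below threshold: 50 ms window
  err <- rep(5, 600)
  err[101:150] <- 0.5
  et <- as_error_trajectory((0:599) / 1000, err, 120)
  expect_equal(timing_window(et), 50)

  # two runs of 30 ms and 80 ms; release nearest the 30 ms run
  err2 <- rep(5, 600)
  err2[101:130] <- 0.5   # 30 ms run
  err2[401:480] <- 0.4   # 80 ms run
  et2 <- as_error_trajectory((0:599) / 1000, err2, 140)
  expect_equal(timing_window(et2), 30)
  et3 <- as_error_trajectory((0:599) / 1000, err2, 390)
  expect_equal(timing_window(et3), 80)
})

test_that("window midpoint rule references the centre of the chosen run", {
  err <- rep(5, 600)
  err[101:150] <- 0.5
  err[120] <- 0.3
  et <- as_error_trajectory((0:599) / 1000, err, 140)
  # run spans samples 101..150, midpoint sample 126 (= 125 ms); the run
  # minimum sits at sample 120
  expect_equal(timing_error(et, "window_midpoint"), 14)
  expect_equal(timing_error(et, "nearest_crossing"), 20)
})

test_that("timing window grows with the success threshold", {
  # single-basin error series: the reference stays in the same basin, so
  # raising the threshold can only extend its sub-threshold run
  set.seed(3)
  for (rep in 1:5) {
    min_at <- sample(100:500, 1)
    left <- runif(1, 0.005, 0.05)
    right <- runif(1, 0.005, 0.05)
    t <- 0:599
    err <- ifelse(t < min_at, left * (min_at - t), right * (t - min_at))
    release <- sample(50:550, 1)
    w <- vapply(c(0.3, 1.1, 2, 5), function(thr) {
      timing_window(as_error_trajectory(t / 1000, err, release,
                                        success_threshold = thr))
    }, numeric(1))
    expect_true(all(diff(w) >= 0))
  }
})

test_that("shifting the release marker shifts timing error linearly", {
  err <- vshape_series(300)
  for (k in c(-20, -5, 5, 20)) {
    et0 <- as_error_trajectory((0:599) / 1000, err, 250)
    etk <- as_error_trajectory((0:599) / 1000, err, 250 + k)
    expect_equal(timing_error(etk, "global_min") -
                   timing_error(et0, "global_min"), -k)
  }
})

test_that("error trajectories reproduce the scored release exactly", {
  cfg <- skittler_task("u_shape")
  tr <- trajectory_through(90, -420, cfg, seed = 5,
                           noise = noise_model(10, 1, 10, seed = 5))
  et <- error_trajectory(tr, cfg)
  ri <- attr(tr, "release_index")
  direct <- score_throws(
    tibble::tibble(angle = tr$angle[ri], velocity = tr$velocity[ri]), cfg)
  expect_identical(et$error[ri], direct$error)
  expect_identical(et$post_hit[ri], direct$post_hit)
  expect_equal(attr(et, "sample_rate"), 1000)
})

test_that("a frozen arm state yields a constant error trajectory", {
  cfg <- skittler_task("j_shape")
  tr <- arm_trajectory(rep(45, 100), release_index = 50,
                       velocity = rep(-300, 100))
  et <- error_trajectory(tr, cfg)
  expect_equal(length(unique(et$error)), 1)
  expect_true(timing_window(et) %in% c(0, 100))
})

test_that("trajectories through a manifold point dip below threshold", {
  cfg <- skittler_task("box_shape")
  mf <- solution_manifold(
    solution_space(cfg, angle_range = c(-90, 180),
                   resolution = c(100, 80)))
  k <- which.max(mf$v_hi - mf$v_lo)
  tr <- trajectory_through(mf$angle[k],
                           -(mf$v_lo[k] + mf$v_hi[k]) / 2, cfg)
  et <- error_trajectory(tr, cfg)
  expect_lt(min(et$error), cfg$success_threshold)
  expect_gt(timing_window(et), 0)
})

test_that("too-short trajectories are rejected", {
  expect_error(arm_trajectory(rep(1, 10), 5), "21 samples")
  cfg <- task_config()
  expect_error(error_trajectory(tibble::tibble(
    time = 0, angle = 1, velocity = 0), cfg), "21 samples")
})

test_that("timing measures are invariant to the execution frame", {
  cfgs <- list(skittler_task("u_shape"), skittler_task("i_shape"))
  set.seed(21)
  for (cfg in cfgs) {
    sgn <- if (cfg$throw_direction == "counterclockwise") 1 else -1
    for (rep in 1:10) {
      tr <- trajectory_through(runif(1, 60, 120),
                               sgn * runif(1, 250, 700), cfg,
                               amp = runif(1, 35, 70), seed = rep,
                               noise = noise_model(15, 1, 15, seed = rep))
      both <- timing_measures_by_frame(tr, cfg)
      expect_equal(both$timing_error[1], both$timing_error[2])
      expect_equal(both$timing_window[1], both$timing_window[2])
      expect_equal(both$ideal_release_time[1], both$ideal_release_time[2])
    }
  }
})

test_that("frozen-state trajectories agree across frames", {
  cfg <- skittler_task("i_shape")
  tr <- arm_trajectory(rep(90, 80), release_index = 40,
                       velocity = rep(500, 80))
  both <- timing_measures_by_frame(tr, cfg)
  expect_equal(both$timing_window[1], both$timing_window[2])
  expect_true(both$timing_window[1] %in% c(0, 80))
})
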