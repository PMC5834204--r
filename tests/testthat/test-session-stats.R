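fake_throws <- function(errors, hits, te, tw) {
  tibble::tibble(
    error = errors,
    category = factor(ifelse(hits, "hit", "miss"),
                      levels = c("hit", "near", "miss", "invalid")),
    timing_error = te, timing_window = tw)
}

test_that("session summaries use the documented conventions", {
  th <- fake_throws(errors = c(1, 2, 3, 4, 5, 1, 1, 1, 2, 2),
                    hits = c(rep(TRUE, 4), rep(FALSE, 6)),
                    te = rep(c(5, 7, 100, 7, 7), 2),
                    tw = rep(c(0, 10, 20, 10, 10), 2))
  s <- summarize_session(th, subject = 3, day = 2)
  expect_equal(s$success_rate, 40)
  expect_equal(s$median_error, 2)
  expect_equal(s$n_throws, 10)
  # median for timing error, mean for timing window
  th2 <- fake_throws(1:3, rep(TRUE, 3), te = c(5, 7, 100),
                     tw = c(0, 10, 20))
  s2 <- summarize_session(th2)
  expect_equal(s2$median_timing_error, 7)
  expect_equal(s2$mean_timing_window, 10)
  expect_error(summarize_session(th[0, ]), "empty")
})

test_that("standardized regression recovers constructed coefficients", {
  set.seed(5)
  n <- 50
  x1 <- rnorm(n, 20, 4)
  x2 <- rnorm(n, 30, 8)
  noise <- rnorm(n, 0, 0.05 * 4)
  s <- tibble::tibble(median_timing_error = x1, mean_timing_window = x2,
                      median_error = x1 + noise)
  r <- regress_error_on_timing(s)
  expect_lt(abs(r$beta1 - 1), 0.05)
  expect_lt(abs(r$beta2), 0.1)
  expect_gt(r$r_squared, 0.99)
  expect_lt(r$vif, 1.5)
  # y = -x2 exactly: beta2 = +1 under the minus-sign convention
  s2 <- dplyr::mutate(s, median_error = -mean_timing_window)
  r2 <- suppressWarnings(regress_error_on_timing(s2))
  expect_equal(r2$beta2, 1, tolerance = 1e-9)
  expect_equal(r2$beta1, 0, tolerance = 1e-9)
  expect_equal(r2$r_squared, 1, tolerance = 1e-9)
  # exact linear combination: perfect fit
  s3 <- dplyr::mutate(s, median_error = 2 * median_timing_error -
                        0.5 * mean_timing_window + 7)
  expect_equal(suppressWarnings(regress_error_on_timing(s3))$r_squared, 1,
               tolerance = 1e-9)
})

test_that("z-scoring makes the fit invariant to affine rescaling", {
  set.seed(8)
  s <- tibble::tibble(median_timing_error = rnorm(20, 20, 5),
                      mean_timing_window = rnorm(20, 30, 6),
                      median_error = rnorm(20, 3, 1))
  r <- regress_error_on_timing(s)
  s_scaled <- dplyr::mutate(s,
    median_timing_error = 1000 * median_timing_error - 4,
    mean_timing_window = 0.001 * mean_timing_window + 2,
    median_error = 12 * median_error + 100)
  r_scaled <- regress_error_on_timing(s_scaled)
  expect_equal(r_scaled$beta1, r$beta1, tolerance = 1e-9)
  expect_equal(r_scaled$beta2, r$beta2, tolerance = 1e-9)
  expect_equal(r_scaled$ci1, r$ci1, tolerance = 1e-9)
  expect_equal(r_scaled$r_squared, r$r_squared, tolerance = 1e-9)
  # z-scored variables have mean 0 and sd 1
  z <- skittler:::zscore(s$median_error)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
})

test_that("degenerate regressions are refused", {
  s <- tibble::tibble(median_timing_error = 1:3,
                      mean_timing_window = 1:3, median_error = 1:3)
  expect_error(regress_error_on_timing(s), "at least 4")
  s4 <- tibble::tibble(median_timing_error = rep(2, 5),
                       mean_timing_window = 1:5, median_error = 1:5)
  expect_error(regress_error_on_timing(s4), "zero variance")
})

test_that("confidence intervals contain their estimates and match car", {
  set.seed(9)
  s <- tibble::tibble(median_timing_error = rnorm(12, 20, 5),
                      mean_timing_window = rnorm(12, 30, 6),
                      median_error = rnorm(12, 3, 1))
  r <- regress_error_on_timing(s)
  expect_true(r$ci1[1] <= r$beta1 && r$beta1 <= r$ci1[2])
  expect_true(r$ci2[1] <= r$beta2 && r$beta2 <= r$ci2[2])
  td <- tidy(r)
  expect_equal(td$estimate, c(r$beta1, r$beta2))
  expect_true(all(td$conf.low <= td$estimate &
                    td$estimate <= td$conf.high))
  gl <- glance(r)
  expect_equal(gl$n_subjects, 12)
  # VIF cross-check against the field-standard implementation
  if (requireNamespace("car", quietly = TRUE)) {
    z <- tibble::tibble(
      y = skittler:::zscore(s$median_error),
      x1 = skittler:::zscore(s$median_timing_error),
      x2 = skittler:::zscore(s$mean_timing_window))
    v <- car::vif(lm(y ~ x1 + x2, data = z))
    expect_equal(unname(v["x1"]), r$vif, tolerance = 1e-9)
  }
})

test_that("per-day regression tables carry one row per predictor", {
  set.seed(10)
  s <- tidyr::expand_grid(day = 1:3, subject = 1:8) |>
    dplyr::mutate(median_timing_error = rnorm(24, 20, 5),
                  mean_timing_window = rnorm(24, 30, 6),
                  median_error = 0.2 * median_timing_error -
                    0.1 * mean_timing_window + rnorm(24, 0, 0.5))
  tab <- regress_by_day(s)
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$term), c("timing_error", "timing_window"))
  expect_true(all(tab$r.squared >= 0 & tab$r.squared <= 1))
  p <- autoplot(tab)
  expect_s3_class(p, "ggplot")
})

test_that("plots build from cohort-shaped summaries", {
  s <- tidyr::expand_grid(day = 1:2, subject = 1:4) |>
    dplyr::mutate(success_rate = runif(8, 0, 100),
                  median_error = runif(8, 1, 5),
                  median_timing_error = runif(8, 10, 40),
                  mean_timing_window = runif(8, 5, 50))
  expect_s3_class(plot_learning_curves(s), "ggplot")
})
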