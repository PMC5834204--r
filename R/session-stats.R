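#' Analyze a set of arm trajectories
#'
#' The per-throw analysis stage: converts each trajectory to an error
#' trajectory, scores the actual release, and computes both timing
#' measures.
#'
#' @param trajectories A list of [arm_trajectory()] objects.
#' @param config A [task_config()].
#' @param rule Reference rule for the timing error (see [timing_error()]).
#' @return A tibble with one row per throw: `throw`, `day` and `block`
#'   (when recorded on the trajectory), `error` (cm), `post_hit`,
#'   `category`, `timing_error` (ms), `timing_window` (ms),
#'   `ideal_release_time` (s), `release_time` (s).
#' @export
analyze_trajectories <- function(trajectories, config,
                                 rule = timing_rules) {
  rule <- match.arg(rule)
  validate_task_config(config)
  n <- length(trajectories)
  cols <- list(throw = integer(n), day = integer(n), block = integer(n),
               error = numeric(n), post_hit = logical(n),
               timing_error = numeric(n), timing_window = numeric(n),
               ideal_release_time = numeric(n), release_time = numeric(n))
  for (i in seq_len(n)) {
    tr <- trajectories[[i]]
    et <- error_trajectory(tr, config)
    ri <- attr(tr, "release_index")
    ref <- ideal_reference(et, rule)
    fs <- attr(et, "sample_rate")
    cols$throw[i] <- attr(tr, "throw") %||% i
    cols$day[i] <- attr(tr, "day") %||% NA_integer_
    cols$block[i] <- attr(tr, "block") %||% NA_integer_
    cols$error[i] <- et$error[ri]
    cols$post_hit[i] <- et$post_hit[ri]
    cols$timing_error[i] <- abs(ri - ref$index) / fs * 1000
    cols$timing_window[i] <- timing_window(et)
    cols$ideal_release_time[i] <- et$time[ref$index]
    cols$release_time[i] <- tr$time[ri]
  }
  tibble::as_tibble(cols) |>
    dplyr::mutate(category = factor(
      categorize_error(.data$error, .data$post_hit, config),
      levels = throw_categories), .after = "post_hit")
}

#' Summarize one daily session
#'
#' The standard per-day descriptive measures: success rate (percentage of
#' hits), median performance error (errors are non-negative and skewed,
#' so the median characterizes the day), median timing error (same
#' argument) and mean timing window.
#'
#' @param throws A tibble of per-throw results from
#'   [analyze_trajectories()] (columns `category`, `error`,
#'   `timing_error`, `timing_window`).
#' @param subject,day Identifiers attached to the summary row.
#' @return A one-row tibble: `subject`, `day`, `success_rate` (percent),
#'   `median_error` (cm), `median_timing_error` (ms),
#'   `mean_timing_window` (ms), `n_throws`.
#' @export
summarize_session <- function(throws, subject = NA, day = NA) {
  if (nrow(throws) == 0)
    stop("cannot summarize an empty session", call. = FALSE)
  tibble::tibble(
    subject = subject,
    day = day,
    success_rate = 100 * mean(throws$category == "hit"),
    median_error = stats::median(throws$error),
    median_timing_error = stats::median(throws$timing_error),
    mean_timing_window = mean(throws$timing_window),
    n_throws = nrow(throws))
}

#' Regress performance error on the two timing measures
#'
#' Fits the standardized multiple regression `error ~ timing error +
#' timing window` across the subjects of one day (one summary row per
#' subject). All three variables are z-scored before the fit so the
#' coefficients are standardized. Coefficients are reported in the
#' convention `y = b1 x1 - b2 x2`: `beta1` is the fitted coefficient of
#' timing error and `beta2` enters with the minus sign, i.e. `beta2 =
#' -coef(timing window)`, so a window that lowers error yields a positive
#' `beta2`. 95% confidence intervals use the t distribution on the OLS
#' standard errors; the variance-inflation factor of the two predictors
#' (`1 / (1 - r^2)` for a two-predictor fit) diagnoses collinearity.
#'
#' @param summaries A data frame with columns `median_error`,
#'   `median_timing_error`, `mean_timing_window`; one row per subject.
#' @param conf_level Confidence level for the intervals.
#' @return An object of class `skittler_regression`; see
#'   [tidy.skittler_regression()] and [glance.skittler_regression()].
#' @export
regress_error_on_timing <- function(summaries, conf_level = 0.95) {
  need <- c("median_error", "median_timing_error", "mean_timing_window")
  stopifnot(all(need %in% names(summaries)))
  n <- nrow(summaries)
  if (n < 4)
    stop("need at least 4 subjects for the two-predictor regression",
         call. = FALSE)
  z <- tibble::tibble(
    y = zscore(summaries$median_error),
    x1 = zscore(summaries$median_timing_error),
    x2 = zscore(summaries$mean_timing_window))
  fit <- stats::lm(y ~ x1 + x2, data = z)
  ci <- stats::confint(fit, level = conf_level)
  co <- stats::coef(summary(fit))
  structure(list(
    beta1 = unname(co["x1", "Estimate"]),
    beta2 = -unname(co["x2", "Estimate"]),
    ci1 = unname(ci["x1", ]),
    ci2 = rev(-unname(ci["x2", ])),
    se = unname(co[c("x1", "x2"), "Std. Error"]),
    p_values = unname(co[c("x1", "x2"), "Pr(>|t|)"]),
    r_squared = summary(fit)$r.squared,
    vif = 1 / (1 - stats::cor(z$x1, z$x2)^2),
    n_subjects = n,
    conf_level = conf_level,
    fit = fit), class = "skittler_regression")
}

#' @export
print.skittler_regression <- function(x, ...) {
  cat("<standardized regression: error ~ timing error - timing window>\n")
  cat(sprintf("  beta1 (timing error)  %6.3f  [%.3f, %.3f]\n",
              x$beta1, x$ci1[1], x$ci1[2]))
  cat(sprintf("  beta2 (timing window) %6.3f  [%.3f, %.3f]\n",
              x$beta2, x$ci2[1], x$ci2[2]))
  cat(sprintf("  R^2 %.3f, VIF %.2f, n = %d subjects\n",
              x$r_squared, x$vif, x$n_subjects))
  invisible(x)
}

#' Tidy a standardized timing regression
#'
#' @param x A `skittler_regression`.
#' @param ... Unused.
#' @return A tibble with one row per predictor (`timing_error`,
#'   `timing_window`), the standardized estimate in the reporting
#'   convention of [regress_error_on_timing()], its standard error,
#'   confidence bounds and p value.
#' @export
tidy.skittler_regression <- function(x, ...) {
  tibble::tibble(
    term = c("timing_error", "timing_window"),
    estimate = c(x$beta1, x$beta2),
    std.error = x$se,
    conf.low = c(x$ci1[1], x$ci2[1]),
    conf.high = c(x$ci1[2], x$ci2[2]),
    p.value = x$p_values)
}

#' @rdname tidy.skittler_regression
#' @return `glance()`: a one-row tibble with `r.squared`, `vif`,
#'   `n_subjects`.
#' @export
glance.skittler_regression <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, vif = x$vif,
                 n_subjects = x$n_subjects)
}

#' Per-day standardized regressions across subjects
#'
#' Convenience wrapper running [regress_error_on_timing()] within each
#' day (z-scoring within day) of a cohort summary table.
#'
#' @param summaries A data frame of per-subject-per-day rows (columns as
#'   in [summarize_session()] plus `day`).
#' @return A tibble of class `skittler_betas`: one row per day and
#'   predictor with estimate, confidence bounds, `r.squared` and `vif`.
#' @export
regress_by_day <- function(summaries) {
  out <- summaries |>
    dplyr::group_by(.data$day) |>
    dplyr::group_modify(function(d, key) {
      r <- regress_error_on_timing(d)
      dplyr::cross_join(tidy(r), glance(r))
    }) |>
    dplyr::ungroup()
  class(out) <- c("skittler_betas", class(out))
  out
}

#' Pooled standardized regression over late practice days
#'
#' Stabilized variant of the per-day regression for small cohorts:
#' variables are z-scored within each requested day (as in
#' [regress_by_day()]) and a single OLS fit is run on the pooled rows,
#' doubling the effective sample behind the late-practice coefficient
#' comparison.
#'
#' @param summaries Per-subject-per-day summary rows (with a `day`
#'   column).
#' @param days Days to pool (default the last two of the table).
#' @return A `skittler_regression` (see [regress_error_on_timing()]).
#' @export
late_practice_regression <- function(summaries, days = NULL) {
  if (is.null(days)) days <- sort(unique(summaries$day), decreasing = TRUE)[1:2]
  pooled <- summaries |>
    dplyr::filter(.data$day %in% days) |>
    dplyr::group_by(.data$day) |>
    dplyr::mutate(
      median_error = zscore(.data$median_error),
      median_timing_error = zscore(.data$median_timing_error),
      mean_timing_window = zscore(.data$mean_timing_window)) |>
    dplyr::ungroup()
  regress_error_on_timing(pooled)
}

#' Bar chart of standardized regression coefficients by day
#'
#' @param object A `skittler_betas` table from [regress_by_day()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skittler_betas <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(factor(.data$day), .data$estimate,
                               fill = .data$term)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      position = ggplot2::position_dodge(0.9), width = 0.25,
      colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(timing_error = "#4472c4",
                                          timing_window = "#c0504d")) +
    ggplot2::labs(x = "practice day", y = "standardized coefficient") +
    ggplot2::theme_minimal()
}

#' Learning curves of a cohort summary
#'
#' Day-by-day mean (with standard-error ribbon across subjects) of the
#' four dependent measures.
#'
#' @param summaries Per-subject-per-day summary rows.
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(summaries) {
  long <- summaries |>
    tidyr::pivot_longer(c("success_rate", "median_error",
                          "median_timing_error", "mean_timing_window"),
                        names_to = "measure") |>
    dplyr::group_by(.data$day, .data$measure) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = stats::sd(.data$value) /
                       sqrt(dplyr::n()), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "practice day", y = NULL) +
    ggplot2::theme_minimal()
}
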