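#' Map the execution space onto the error surface
#'
#' Evaluates [score_throws()] on a regular grid over release angle and
#' release velocity magnitude, producing the task's solution space: the
#' error surface whose sub-threshold set is the solution manifold. The
#' velocity axis is the magnitude of the angular velocity; each grid cell
#' is scored with the sign implied by the task's `throw_direction`.
#'
#' @param config A [task_config()].
#' @param angle_range Length-2 numeric, degrees. Default spans the lever
#'   arc `0..180` degrees, the plausible throwing range for a lever
#'   pivoted below the workspace.
#' @param velocity_range Length-2 numeric, degrees/s (magnitudes).
#' @param resolution Cells per axis (length 1 or 2: angle, velocity).
#' @return A tibble of class `skittler_space` with one row per grid cell:
#'   `angle`, `velocity` (cell centres), `error` (cm), `post_hit`,
#'   `category`. Attributes `angle_axis`, `velocity_axis` and `config`
#'   record the grid.
#' @examples
#' sp <- solution_space(skittler_task("i_shape"), resolution = 40)
#' dplyr::count(sp, category)
#' @export
solution_space <- function(config,
                           angle_range = c(0, 180),
                           velocity_range = c(0, 1000),
                           resolution = 300) {
  validate_task_config(config)
  if (length(resolution) == 1) resolution <- rep(resolution, 2)
  stopifnot(length(angle_range) == 2, length(velocity_range) == 2,
            all(resolution >= 2), diff(angle_range) > 0,
            diff(velocity_range) >= 0)
  angle_axis <- seq(angle_range[1], angle_range[2],
                    length.out = resolution[1])
  velocity_axis <- seq(velocity_range[1], velocity_range[2],
                       length.out = resolution[2])
  sgn <- if (config$throw_direction == "counterclockwise") 1 else -1
  grid <- tidyr::expand_grid(angle = angle_axis, velocity = velocity_axis)
  scored <- score_throws(
    dplyr::mutate(grid, velocity = sgn * .data$velocity), config) |>
    dplyr::mutate(velocity = abs(.data$velocity))
  structure(scored,
            angle_axis = angle_axis,
            velocity_axis = velocity_axis,
            config = config,
            class = c("skittler_space", class(scored)))
}

space_axes <- function(space) {
  list(angle = attr(space, "angle_axis"),
       velocity = attr(space, "velocity_axis"),
       config = attr(space, "config"))
}

#' Extract the solution manifold from a mapped space
#'
#' The solution manifold is the set of execution states whose error lies
#' below the success threshold. It is returned per angle column as maximal
#' runs of sub-threshold cells, converted to velocity intervals spanning
#' the outer cell edges of each run (so a single sub-threshold cell yields
#' an interval one cell wide). Several disjoint intervals per angle are
#' possible (and real: some geometries have two solution branches).
#'
#' @param space A `skittler_space` from [solution_space()].
#' @return A tibble with columns `angle`, `v_lo`, `v_hi` (degrees/s), one
#'   row per interval; zero rows if the manifold is empty.
#' @export
solution_manifold <- function(space) {
  ax <- space_axes(space)
  thr <- ax$config$success_threshold
  dv <- if (length(ax$velocity) > 1) diff(ax$velocity[1:2]) else 0
  space |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$angle) |>
    dplyr::arrange(.data$velocity, .by_group = TRUE) |>
    dplyr::summarise(runs = list(subthreshold_runs(
      .data$error < thr & !.data$post_hit)), .groups = "drop") |>
    tidyr::unnest_longer("runs") |>
    tidyr::unnest_wider("runs") |>
    dplyr::filter(!is.na(.data$lo)) |>
    dplyr::mutate(v_lo = ax$velocity[.data$lo] - dv / 2,
                  v_hi = ax$velocity[.data$hi] + dv / 2) |>
    dplyr::select("angle", "v_lo", "v_hi")
}

# Maximal runs of TRUE in a logical vector -> list of lists(lo, hi) of
# 1-based indices; list(list(lo = NA, hi = NA)) if none.
subthreshold_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(list(list(lo = NA_integer_, hi = NA_integer_)))
  purrr::map(keep, function(k) list(lo = starts[k], hi = ends[k]))
}

#' Sensitivity of the error surface to release velocity
#'
#' For each angle column of a mapped space, the coefficient of variation
#' of the error across the velocity axis (post-hit cells excluded), with
#' the mean floored at 1e-6 cm so the measure stays defined where the
#' error vanishes identically. A near-zero value flags a geometry whose
#' outcome does not depend on release velocity: the singular case where
#' the manifold runs parallel to the velocity axis and releasing at the
#' right angle is all that matters.
#'
#' @param space A `skittler_space`.
#' @return A tibble with columns `angle`, `cv` (NA where every cell of the
#'   column is a post hit) and `n_cells` (cells entering the statistic).
#' @export
velocity_sensitivity <- function(space) {
  tibble::as_tibble(space) |>
    dplyr::group_by(.data$angle) |>
    dplyr::summarise(
      n_cells = sum(!.data$post_hit),
      cv = if (sum(!.data$post_hit) < 2) NA_real_ else {
        e <- .data$error[!.data$post_hit]
        stats::sd(e) / max(mean(e), 1e-6)
      },
      .groups = "drop")
}

#' Geometric summary of a mapped solution space
#'
#' One-row description of the manifold's extent and shape, used to compare
#' task variants: angle span of the manifold, velocity range it reaches,
#' maximal number of disjoint branches per angle, mean interval width,
#' fraction of manifold-adjacent cells that are post hits (a manifold
#' ending against the post), and the median error gradient magnitude just
#' outside the manifold (surface steepness).
#'
#' @param space A `skittler_space`.
#' @return A one-row tibble.
#' @export
space_summary <- function(space) {
  ax <- space_axes(space)
  mf <- solution_manifold(space)
  counts <- tibble::as_tibble(space) |>
    dplyr::count(.data$category, .drop = FALSE)
  n_hit <- counts$n[counts$category == "hit"]
  if (nrow(mf) == 0) {
    return(tibble::tibble(
      n_manifold_cells = n_hit, angle_span = 0, v_min = NA_real_,
      v_max = NA_real_, max_branches = 0L, mean_width = NA_real_,
      post_adjacent_frac = NA_real_, median_gradient = NA_real_))
  }
  branches <- mf |> dplyr::count(.data$angle)
  tibble::tibble(
    n_manifold_cells = n_hit,
    angle_span = diff(range(mf$angle)),
    v_min = min(mf$v_lo), v_max = max(mf$v_hi),
    max_branches = max(branches$n),
    mean_width = mean(mf$v_hi - mf$v_lo),
    post_adjacent_frac = manifold_post_adjacency(space),
    median_gradient = manifold_edge_gradient(space))
}

# Fraction of manifold cells with a post-hit cell within one step along
# the velocity axis.
manifold_post_adjacency <- function(space) {
  ax <- space_axes(space)
  err <- matrix(space$error, nrow = length(ax$angle), byrow = TRUE)
  ph <- matrix(space$post_hit, nrow = length(ax$angle), byrow = TRUE)
  hit <- err < ax$config$success_threshold & !ph
  if (!any(hit)) return(NA_real_)
  nv <- ncol(ph)
  below <- cbind(FALSE, ph[, -nv, drop = FALSE])  # neighbour one step down
  above <- cbind(ph[, -1, drop = FALSE], FALSE)   # neighbour one step up
  mean((below | above)[hit])
}

# Median |d error / d velocity| on cells bordering the manifold.
manifold_edge_gradient <- function(space) {
  ax <- space_axes(space)
  err <- matrix(space$error, nrow = length(ax$angle), byrow = TRUE)
  ph <- matrix(space$post_hit, nrow = length(ax$angle), byrow = TRUE)
  hit <- err < ax$config$success_threshold & !ph
  if (!any(hit)) return(NA_real_)
  dv <- diff(ax$velocity[1:2])
  nv <- ncol(err)
  grad <- abs(err[, -1, drop = FALSE] - err[, -nv, drop = FALSE]) / dv
  edge <- (hit[, -1, drop = FALSE] & !hit[, -nv, drop = FALSE]) |
          (!hit[, -1, drop = FALSE] & hit[, -nv, drop = FALSE])
  edge <- edge & !ph[, -1, drop = FALSE] & !ph[, -nv, drop = FALSE]
  if (!any(edge)) return(NA_real_)
  stats::median(grad[edge])
}

#' Heatmap of a mapped solution space
#'
#' Reproduces the conventional rendering of the error surface: green for
#' the solution manifold (hits), yellow for near misses, grey shades for
#' larger errors, black for post hits and off-display errors.
#'
#' @param object A `skittler_space`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.skittler_space <- function(object, ...) {
  cfg <- attr(object, "config")
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(
      level = pmin(.data$error, cfg$max_display_error) /
        cfg$max_display_error,
      fill = dplyr::case_when(
        .data$category == "hit" ~ "#00a000",
        .data$category == "near" ~ "#e8e800",
        .data$category == "invalid" ~ "#000000",
        .default = grDevices::grey(0.8 - 0.7 * .data$level)))
  ggplot2::ggplot(df, ggplot2::aes(.data$angle, .data$velocity)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(x = "release angle (deg)",
                  y = "release velocity (deg/s)",
                  title = cfg$name %||% "solution space") +
    ggplot2::theme_minimal()
}
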