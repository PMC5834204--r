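#' Read and write arm trajectory files
#'
#' Trajectories are stored as comma-separated text with columns
#' `time_ms`, `angle_deg`, optionally `angvel_deg_s`, and a `release`
#' column holding 1 on exactly one row (the release sample) and 0
#' elsewhere. Values are written in full precision so a write-then-read
#' round trip reproduces the trajectory exactly. The reader validates
#' uniform sampling and the release marker and reports the offending line
#' on failure.
#'
#' @param path File path.
#' @param sample_rate Expected sampling rate, Hz; inferred from the time
#'   stamps when `NULL`.
#' @return `read_arm_trajectory()`: an [arm_trajectory()].
#' @export
read_arm_trajectory <- function(path, sample_rate = NULL) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0)
    stop("empty trajectory: ", path, " has a header but no samples",
         call. = FALSE)
  need <- c("time_ms", "angle_deg", "release")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("malformed trajectory file ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in intersect(c("time_ms", "angle_deg", "angvel_deg_s"),
                        names(df))) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(vals))
    if (length(bad))
      stop("malformed value in column ", col, " at line ", bad[1] + 1,
           " of ", path, call. = FALSE)
    df[[col]] <- vals
  }
  dt <- diff(df$time_ms)
  if (nrow(df) > 1) {
    bad <- which(abs(dt - dt[1]) > 1e-6)
    if (length(bad))
      stop("non-uniform sampling at line ", bad[1] + 2, " of ", path,
           ": time step ", format(dt[bad[1]]), " ms vs ",
           format(dt[1]), " ms", call. = FALSE)
  }
  ri <- which(df$release == 1)
  if (length(ri) != 1)
    stop("trajectory file ", path, " must mark exactly one release row; ",
         "found ", length(ri), call. = FALSE)
  fs <- sample_rate %||% (1000 / dt[1])
  arm_trajectory(df$angle_deg, release_index = ri, sample_rate = fs,
                 velocity = df$angvel_deg_s,
                 time = df$time_ms / 1000)
}

#' @param traj An [arm_trajectory()], for `write_arm_trajectory()`.
#' @param velocity Whether to store the velocity column.
#' @rdname read_arm_trajectory
#' @export
write_arm_trajectory <- function(traj, path, velocity = TRUE) {
  ri <- attr(traj, "release_index")
  df <- data.frame(time_ms = traj$time * 1000,
                   angle_deg = traj$angle)
  if (velocity) df$angvel_deg_s <- traj$velocity
  df$release <- as.integer(seq_len(nrow(df)) == ri)
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(lapply(df, function(x)
               if (is.double(x)) sprintf("%.17g", x) else
                 as.character(x)), sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Export a mapped solution space as delimited text
#'
#' Writes the error matrix with axis headers (first row: velocity axis;
#' first column: angle axis) plus a sidecar metadata file documenting the
#' category integer codes of the companion category matrix
#' (0 hit, 1 near, 2 miss, 3 invalid).
#'
#' @param space A `skittler_space`.
#' @param path Base path; writes `<path>_error.csv`,
#'   `<path>_category.csv` and `<path>_meta.json`.
#' @return The three paths, invisibly.
#' @export
write_solution_space <- function(space, path) {
  ax <- space_axes(space)
  na <- length(ax$angle); nv <- length(ax$velocity)
  err <- matrix(space$error, nrow = na, byrow = TRUE)
  cat_codes <- matrix(as.integer(space$category) - 1L, nrow = na,
                      byrow = TRUE)
  write_mat <- function(m, file) {
    header <- paste(c("angle_deg\\velocity_deg_s",
                      sprintf("%.10g", ax$velocity)), collapse = ",")
    rows <- vapply(seq_len(na), function(i)
      paste(c(sprintf("%.10g", ax$angle[i]),
              sprintf("%.10g", m[i, ])), collapse = ","), character(1))
    writeLines(c(header, rows), file)
  }
  p_err <- paste0(path, "_error.csv")
  p_cat <- paste0(path, "_category.csv")
  p_meta <- paste0(path, "_meta.json")
  write_mat(err, p_err)
  write_mat(cat_codes, p_cat)
  jsonlite::write_json(list(
    category_codes = list(hit = 0, near = 1, miss = 2, invalid = 3),
    units = list(angle = "deg", velocity = "deg/s", error = "cm"),
    config = unclass(attr(space, "config"))),
    p_meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p_err, p_cat, p_meta))
}

#' Run the full synthetic pipeline
#'
#' Ties the stages together for one simulated cohort on one task:
#' synthesize trajectories, analyze them into per-throw measures,
#' summarize per subject-day, and (when at least four subjects) run the
#' per-day standardized regressions. All outputs are delimited text under
#' `out_dir`, and a JSON run manifest records the configuration (path and
#' MD5 where file-backed), the seed, derived per-subject seeds, package
#' version, stage file listing and timestamps, which suffices to re-run
#' the deterministic stages bit-identically.
#'
#' @param config A [task_config()] or path to a config file.
#' @param out_dir Output directory (created if needed).
#' @param seed Top-level seed.
#' @param n_subjects,days,throws_per_day Cohort size.
#' @param rule Timing reference rule.
#' @param write_trajectories Also write every generated trajectory file
#'   (off by default; sessions can be large).
#' @param ... Passed to [simulate_cohort()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config, out_dir, seed = 1L, n_subjects = 2,
                         days = 2, throws_per_day = 20,
                         rule = timing_rules,
                         write_trajectories = FALSE, ...) {
  rule <- match.arg(rule)
  config_path <- NULL
  if (is.character(config)) {
    config_path <- config
    config <- read_task_config(config)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  coh <- stage("synthesize/analyze",
               simulate_cohort(config, n_subjects = n_subjects,
                               days = days, seed = seed,
                               throws_per_day = throws_per_day,
                               rule = rule,
                               keep_trajectories = write_trajectories,
                               ...))

  throws_file <- file.path(out_dir, "throws.csv")
  summary_file <- file.path(out_dir, "summaries.csv")
  stage("summarize", {
    readr::write_csv(coh$throws, throws_file)
    readr::write_csv(coh$summaries, summary_file)
  })

  outputs <- c(throws_file, summary_file)
  if (n_subjects >= 4) {
    reg_file <- file.path(out_dir, "regressions.csv")
    stage("regress", readr::write_csv(regress_by_day(coh$summaries),
                                      reg_file))
    outputs <- c(outputs, reg_file)
  }
  if (write_trajectories) {
    traj_dir <- file.path(out_dir, "trajectories")
    dir.create(traj_dir, showWarnings = FALSE)
    stage("write-trajectories",
          purrr::iwalk(coh$trajectories, function(tr, nm)
            write_arm_trajectory(tr, file.path(traj_dir,
                                               paste0(nm, ".csv")))))
    outputs <- c(outputs, traj_dir)
  }

  manifest <- list(
    package = "skittler",
    version = as.character(utils::packageVersion("skittler")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    subject_seeds = vapply(seq_len(n_subjects), function(s)
      derive_seed(seed, s), integer(1)),
    seed_derivation = "derive_seed(seed, subject); per-throw seeds via derive_seed(noise_seed, day, throw)",
    config = unclass(config),
    config_path = config_path,
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NULL,
    n_subjects = n_subjects, days = days,
    throws_per_day = throws_per_day, rule = rule,
    outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
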