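# End-to-end drivers behind the command-line front end
# (inst/cli/stepmax.R): simulate -> compute -> report, all file-based and
# deterministic under a fixed seed.

#' Write a simulated cohort to disk
#'
#' Generates a cohort with [generate_cohort()] and writes one event CSV
#' per subject plus the ground-truth manifest (`manifest.json` with the
#' subject table, `truth_bouts.csv`, `truth_daily.csv`).
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [generator_config()].
#' @param n_subjects Number of subjects.
#' @return Invisibly, the vector of event-file paths.
#' @export
run_simulate <- function(out_dir, config = generator_config(), n_subjects = 10) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config, n_subjects)
  paths <- character(0)
  for (sid in names(cohort$streams)) {
    p <- file.path(out_dir, paste0(sid, "_events.csv"))
    write_events(cohort$streams[[sid]], p)
    paths <- c(paths, p)
  }
  manifest <- cohort$manifest
  readr::write_csv(manifest$bouts, file.path(out_dir, "truth_bouts.csv"),
                   progress = FALSE)
  readr::write_csv(manifest$daily, file.path(out_dir, "truth_daily.csv"),
                   progress = FALSE)
  cfg <- unclass(config)
  cfg$start_date <- as.character(cfg$start_date)
  jsonlite::write_json(
    list(config = cfg,
         subjects = manifest$subjects |>
           dplyr::mutate(start_date = as.character(.data$start_date))),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  message(sprintf("simulated %d subject(s) into %s", n_subjects, out_dir))
  invisible(paths)
}

#' Compute per-subject summaries from event files
#'
#' Reads each input event CSV, validates it, and writes the day records
#' and per-subject per-duration summaries. A corrupt input file is skipped
#' with a logged error; the remaining files are still processed.
#'
#' @param inputs Event CSV files, or a directory containing `*_events.csv`.
#' @param out_dir Output directory for `day_records.csv` and
#'   `subject_summaries.csv`.
#' @param durations Window durations in seconds.
#' @param min_hours,min_steps Day-validity thresholds.
#' @return Invisibly, a list with `n_subjects`, `n_failed_files` and the
#'   two output paths.
#' @export
run_compute <- function(inputs, out_dir, durations = default_durations(),
                        min_hours = 10, min_steps = 500) {
  if (length(inputs) == 1L && dir.exists(inputs)) {
    inputs <- list.files(inputs, pattern = "_events\\.csv$", full.names = TRUE)
  }
  if (!length(inputs)) stop("no input event files", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summaries <- list(); days <- list(); failed <- 0L
  for (f in inputs) {
    res <- tryCatch({
      stream <- read_events(f)
      lapply(split(stream, stream$subject_id), function(s) {
        subject_summary(s, durations, min_hours, min_steps)
      })
    }, error = function(e) {
      message(sprintf("skipping %s: %s", f, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { failed <- failed + 1L; next }
    for (ss in res) {
      summaries[[length(summaries) + 1L]] <- ss$summary
      days[[length(days) + 1L]] <- ss$days
    }
  }
  if (!length(summaries)) stop("no valid input files", call. = FALSE)
  summary_tbl <- dplyr::bind_rows(summaries)
  days_tbl <- dplyr::bind_rows(days)
  sp <- file.path(out_dir, "subject_summaries.csv")
  dp <- file.path(out_dir, "day_records.csv")
  readr::write_csv(summary_tbl, sp, progress = FALSE)
  readr::write_csv(days_tbl, dp, progress = FALSE)
  message(sprintf(
    "processed %d subject(s) (%d file(s) skipped); %d/%d day(s) valid",
    length(unique(summary_tbl$subject_id)), failed,
    sum(days_tbl$valid), nrow(days_tbl)
  ))
  invisible(list(n_subjects = length(unique(summary_tbl$subject_id)),
                 n_failed_files = failed, summaries = sp, day_records = dp))
}

#' Build the cohort report from computed summaries
#'
#' Writes the stepping-proportion availability table, per-duration
#' distribution statistics of the maximum step counts, and (for cohorts of
#' at least three subjects with both comparison durations) the cohort
#' tests, as CSV plus a combined `report.json`. Every number in the report
#' is recomputable from the summary file alone; regenerating from the same
#' summaries yields identical output.
#'
#' @param summaries Path to `subject_summaries.csv` from [run_compute()],
#'   or the summary tibble itself.
#' @param out_dir Output directory.
#' @param thresholds Stepping-proportion thresholds in (0, 1].
#' @param durations_pair The two durations compared by [cohort_tests()].
#' @param subjects Optional subject table (`subject_id`, `sex`, `month`)
#'   for group comparisons.
#' @return Invisibly, the report list.
#' @export
run_report <- function(summaries, out_dir, thresholds = c(1, 0.95, 0.90, 0.80),
                       durations_pair = c(120, 360), subjects = NULL) {
  if (is.character(summaries)) {
    summaries <- readr::read_csv(summaries, show_col_types = FALSE,
                                 progress = FALSE)
  }
  if (!nrow(summaries)) stop("empty cohort", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  prop <- stepping_proportion_table(summaries, thresholds)
  readr::write_csv(prop, file.path(out_dir, "proportion_table.csv"),
                   progress = FALSE)

  stats_rows <- lapply(sort(unique(summaries$n_s)), function(n) {
    x <- summaries$step_count[summaries$n_s == n]
    x <- x[!is.na(x)]
    if (length(x) < 3L) return(NULL)
    out <- distribution_stats(x)
    out$n_s <- n
    out
  })
  dist_stats <- dplyr::bind_rows(stats_rows)
  readr::write_csv(dist_stats, file.path(out_dir, "distribution_stats.csv"),
                   progress = FALSE)

  n_subj <- length(unique(summaries$subject_id))
  tests <- NULL
  if (n_subj >= 3L && all(durations_pair %in% summaries$n_s)) {
    tests <- cohort_tests(summaries, subjects, durations_pair)
  } else {
    message("cohort tests suppressed: need >= 3 subjects with both ",
            "comparison durations")
  }

  round_p <- function(df) {
    if (!is.null(df$p)) df$p <- round(df$p, 4)  # report p-values to 4 decimals
    df
  }
  report <- list(
    n_subjects = n_subj,
    proportion_table = prop,
    distribution_stats = dist_stats,
    tests = if (!is.null(tests)) lapply(tests, round_p)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}
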