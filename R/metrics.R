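# Validity filtering, per-subject summaries and cohort-level measures.

#' Flag valid monitoring days
#'
#' A day is valid only if it contains more than `min_hours` hours of
#' classified activity data and more than `min_steps` steps. Both
#' comparisons are strict, so a day with exactly 10 h or exactly 500 steps
#' is invalid. Invalid days are retained (for accounting) but excluded from
#' all maxima downstream. The operation is idempotent and order-invariant.
#'
#' @param days Tibble of day records with `classified_h` and `total_steps`
#'   columns, as produced by [summarise_days()].
#' @param min_hours Validity threshold on classified time, hours.
#' @param min_steps Validity threshold on steps.
#' @return `days` with a logical `valid` column (re)computed.
#' @export
flag_valid_days <- function(days, min_hours = 10, min_steps = 500) {
  days$valid <- days$classified_h > min_hours & days$total_steps > min_steps
  days
}

#' Per-day records, window maxima and bouts for one subject
#'
#' Splits a subject's stream at midnight, then computes for each calendar
#' day the classified time, total steps, stepping bouts and the maximum
#' step count at each search-window duration. Windows are searched within a
#' single day's events, matching the per-valid-day maxima used throughout.
#'
#' @param stream Validated single-subject event tibble.
#' @param durations Window durations in seconds, see [default_durations()].
#' @inheritParams flag_valid_days
#' @return A list with tibbles `days` (one row per day, with `valid`
#'   flag), `windows` (one row per day x duration) and `bouts`.
#' @export
summarise_days <- function(stream, durations = default_durations(),
                           min_hours = 10, min_steps = 500) {
  one_subject(stream)
  dated <- split_into_days(stream)
  per_day <- split(dated, dated$date)
  days <- list(); windows <- list(); bouts <- list()
  for (dname in names(per_day)) {
    dd <- per_day[[dname]]
    date <- dd$date[1L]
    days[[dname]] <- tibble::tibble(
      subject_id = dd$subject_id[1L],
      date = date,
      classified_h = sum(dd$duration_s) / 3600,
      total_steps = sum(dd$steps)
    )
    b <- merge_strides_to_bouts(dd)
    if (nrow(b)) {
      b$date <- date
      bouts[[dname]] <- b
    }
    w <- sweep_window_durations(dd, durations)
    w$subject_id <- dd$subject_id[1L]
    w$date <- date
    windows[[dname]] <- w
  }
  empty_bouts <- merge_strides_to_bouts(stream[0, , drop = FALSE])
  empty_bouts$date <- as.Date(character())
  list(
    days = flag_valid_days(dplyr::bind_rows(days), min_hours, min_steps),
    windows = dplyr::bind_rows(windows),
    bouts = if (length(bouts)) dplyr::bind_rows(bouts) else empty_bouts
  )
}

#' Select the observation period to analyse
#'
#' When a subject participated in two observation periods, only the first
#' observation (by time) with at least `required_days` valid days is
#' analysed; subjects with no qualifying observation are excluded with a
#' recorded reason.
#'
#' @param days Day records for all of the subject's observations, with an
#'   `observation_id` column and a `valid` flag ([flag_valid_days()]).
#' @param required_days Minimum number of valid days (default 7).
#' @return A list: `observation_id` (NA when excluded), `valid_days`,
#'   `excluded`, `reason`.
#' @export
select_observation <- function(days, required_days = 7) {
  if (!"observation_id" %in% names(days)) {
    stop("days must carry an observation_id column", call. = FALSE)
  }
  obs <- unique(days$observation_id[order(days$date)])
  for (o in obs) {
    nv <- sum(days$valid[days$observation_id == o])
    if (nv >= required_days) {
      return(list(observation_id = o, valid_days = nv,
                  excluded = FALSE, reason = NA_character_))
    }
  }
  list(observation_id = NA, valid_days = 0L, excluded = TRUE,
       reason = sprintf("no observation with >= %d valid days", required_days))
}

#' Maximum window over a subject's valid days
#'
#' The per-day maxima's maximum at duration `n`, with the same tie-breaks
#' as the within-day search: largest step count, then shortest accumulation
#' time, then earliest day and time.
#'
#' @param windows Per-day window table from [summarise_days()].
#' @param days Day records with `valid` flags.
#' @param n Window duration in seconds.
#' @return One-row tibble; when the subject has no valid days the counts
#'   are `NA` and `n_valid_days` is 0.
#' @export
max_over_period <- function(windows, days, n) {
  vd <- days$date[days$valid]
  if (!length(vd)) {
    out <- window_result_row(n)
    out$step_count <- NA_integer_
    out$stepping_time_s <- NA_real_
    out$accumulation_time_s <- NA_real_
    out$date <- as.Date(NA)
    out$n_valid_days <- 0L
    return(out)
  }
  cand <- windows[windows$n_s == n & windows$date %in% vd, , drop = FALSE]
  if (!nrow(cand)) {
    stop(sprintf("no window results at duration %s s", format(n)), call. = FALSE)
  }
  o <- order(-cand$step_count, cand$accumulation_time_s,
             as.numeric(cand$date), xtfrm(cand$window_start))
  best <- cand[o[1L], c("n_s", "window_start", "step_count", "stepping_time_s",
                        "accumulation_time_s", "truncated_by_break", "date")]
  best$n_valid_days <- length(vd)
  tibble::as_tibble(best)
}

#' Mean daily count of bouts at least as long as the window
#'
#' For each valid day, counts the distinct stepping bouts whose duration
#' equals or exceeds `n` seconds (inclusive), and averages over valid days.
#'
#' @param bouts Bout table with a `date` column, from [summarise_days()].
#' @param days Day records with `valid` flags.
#' @param n Window duration in seconds.
#' @return Mean count per valid day (`NA` if the subject has none).
#' @export
bouts_per_day <- function(bouts, days, n) {
  vd <- days$date[days$valid]
  if (!length(vd)) return(NA_real_)
  if (!nrow(bouts)) return(0)
  sum(bouts$date %in% vd & bouts$duration_s >= n - .EPS) / length(vd)
}

#' Per-subject summary across window durations
#'
#' The full per-subject pipeline: split into days, flag validity, and for
#' each window duration report the maximum step count over valid days, the
#' step accumulation rate (maximum step count divided by the window
#' duration in minutes), the stepping time within the selected maximal
#' window, and the mean daily count of bouts at least that long. The month
#' of the subject's first valid day is carried for seasonal stratification.
#'
#' @inheritParams summarise_days
#' @return A list with `summary` (one row per duration), plus the `days`,
#'   `windows` and `bouts` tables from [summarise_days()].
#' @export
subject_summary <- function(stream, durations = default_durations(),
                            min_hours = 10, min_steps = 500) {
  ds <- summarise_days(stream, durations, min_hours, min_steps)
  vd <- ds$days$date[ds$days$valid]
  month <- if (length(vd)) as.integer(format(min(vd), "%m")) else NA_integer_
  rows <- lapply(durations, function(n) {
    m <- max_over_period(ds$windows, ds$days, n)
    m$accumulation_rate <- m$step_count / (n / 60)
    m$bouts_per_day <- bouts_per_day(ds$bouts, ds$days, n)
    m
  })
  out <- dplyr::bind_rows(rows)
  out$subject_id <- ds$days$subject_id[1L]
  out$month <- month
  ds$summary <- out[, c("subject_id", "n_s", "step_count", "accumulation_rate",
                        "stepping_time_s", "accumulation_time_s", "window_start",
                        "date", "bouts_per_day", "n_valid_days", "month")]
  ds
}

#' Stepping-proportion availability table
#'
#' For each window duration and each threshold, the proportion of subjects
#' whose stepping time within the window of their maximum n-minute step
#' count was at least `threshold x n`. A subject with no valid days never
#' qualifies but stays in the denominator. By set inclusion the proportion
#' is non-decreasing as the threshold drops at fixed duration.
#'
#' @param summaries Per-subject per-duration summary rows (the `summary`
#'   element of [subject_summary()], bound over subjects).
#' @param thresholds Fractions of the window duration, in (0, 1].
#' @return Tibble with `n_s`, `threshold`, `n_subjects`, `proportion`.
#' @export
stepping_proportion_table <- function(summaries,
                                      thresholds = c(1, 0.95, 0.90, 0.80)) {
  if (!nrow(summaries)) stop("empty cohort", call. = FALSE)
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop("thresholds must lie in (0, 1]", call. = FALSE)
  }
  grid <- expand.grid(n_s = sort(unique(summaries$n_s)),
                      threshold = thresholds, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    n <- grid$n_s[i]; th <- grid$threshold[i]
    x <- summaries$stepping_time_s[summaries$n_s == n]
    tibble::tibble(
      n_s = n, threshold = th, n_subjects = length(x),
      proportion = mean(!is.na(x) & x >= th * n - .EPS)
    )
  })
  dplyr::bind_rows(rows)
}

#' Sample skewness
#'
#' Third standardised moment of a sample. With `corrected = TRUE` (the
#' default) the small-sample-corrected estimator
#' `G1 = g1 * sqrt(n(n-1)) / (n-2)` is used, where `g1 = m3 / m2^(3/2)`;
#' `corrected = FALSE` returns the uncorrected `g1`.
#'
#' @param x Numeric vector (NAs dropped).
#' @param corrected Use the small-sample-corrected estimator.
#' @return Scalar skewness; `NA` for constant input.
#' @export
skewness <- function(x, corrected = TRUE) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  g1 <- mean((x - m)^3) / m2^1.5
  if (corrected) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' Sample excess kurtosis
#'
#' Fourth standardised moment minus 3. With `corrected = TRUE` the
#' small-sample-corrected estimator
#' `G2 = ((n+1) g2 + 6) (n-1) / ((n-2)(n-3))` is used, where
#' `g2 = m4 / m2^2 - 3`; `corrected = FALSE` returns `g2`.
#'
#' @inheritParams skewness
#' @return Scalar excess kurtosis; `NA` for constant input.
#' @export
kurtosis <- function(x, corrected = TRUE) {
  x <- x[!is.na(x)]
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(NA_real_)
  g2 <- mean((x - m)^4) / m2^2 - 3
  if (corrected) ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)) else g2
}

#' Distribution characterisation with the skew/kurtosis normality rule
#'
#' Summarises a vector of per-subject maxima and classifies the
#' distribution as normal when `|skewness| < 2` and excess kurtosis `< 7`.
#' Constant input leaves skewness/kurtosis undefined and is flagged as
#' degenerate.
#'
#' @param x Numeric vector of per-subject values (at least 3 non-missing).
#' @param corrected Use small-sample-corrected moment estimators
#'   (see [skewness()], [kurtosis()]).
#' @return One-row tibble: `n`, `mean`, `sd`, `min`, `max`, `skewness`,
#'   `kurtosis`, `is_normal`, `degenerate`.
#' @export
distribution_stats <- function(x, corrected = TRUE) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) stop("need at least 3 values", call. = FALSE)
  sk <- skewness(x, corrected)
  ku <- kurtosis(x, corrected)
  degenerate <- is.na(sk)
  tibble::tibble(
    n = length(x), mean = mean(x), sd = sd(x), min = min(x), max = max(x),
    skewness = sk, kurtosis = ku,
    is_normal = if (degenerate) NA else abs(sk) < 2 && ku < 7,
    degenerate = degenerate
  )
}

#' Cohort comparisons of maximum step counts
#'
#' The cohort-level statistics reported with the measure: Pearson
#' correlation between per-subject maxima at two window durations, a t test
#' comparing the corresponding step accumulation rates (paired by default;
#' `paired = FALSE` gives the pooled-variance unpaired variant), and, when
#' a subject table with `sex` and/or `month` columns is supplied, a
#' two-sample t test by sex and a one-way ANOVA across months of
#' observation for each duration.
#'
#' @param summaries Per-subject per-duration summary rows (see
#'   [stepping_proportion_table()]).
#' @param subjects Optional tibble with `subject_id` plus grouping columns
#'   `sex` and/or `month`.
#' @param durations Two window durations (seconds) to compare.
#' @param paired Pair the accumulation-rate comparison within subject.
#' @return A list of tidy tibbles: `correlation`, `rate_comparison`,
#'   `group_tests`.
#' @export
cohort_tests <- function(summaries, subjects = NULL,
                         durations = c(120, 360), paired = TRUE) {
  stopifnot(length(durations) == 2L)
  a <- summaries[summaries$n_s == durations[1L],
                 c("subject_id", "step_count", "accumulation_rate")]
  b <- summaries[summaries$n_s == durations[2L],
                 c("subject_id", "step_count", "accumulation_rate")]
  names(a)[-1] <- paste0(names(a)[-1], "_a")
  names(b)[-1] <- paste0(names(b)[-1], "_b")
  wide <- dplyr::left_join(a, b, by = "subject_id")
  ok <- complete.cases(wide)
  if (sum(ok) < 3L) {
    stop("need at least 3 subjects with maxima at both durations", call. = FALSE)
  }
  wide <- wide[ok, , drop = FALSE]

  ct <- cor.test(wide$step_count_a, wide$step_count_b)
  correlation <- tibble::tibble(
    n_a = durations[1L], n_b = durations[2L],
    r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value
  )

  tt <- if (paired) {
    t.test(wide$accumulation_rate_a, wide$accumulation_rate_b, paired = TRUE)
  } else {
    t.test(wide$accumulation_rate_a, wide$accumulation_rate_b, var.equal = TRUE)
  }
  rate_comparison <- tibble::tibble(
    n_a = durations[1L], n_b = durations[2L],
    mean_rate_a = mean(wide$accumulation_rate_a),
    sd_rate_a = sd(wide$accumulation_rate_a),
    mean_rate_b = mean(wide$accumulation_rate_b),
    sd_rate_b = sd(wide$accumulation_rate_b),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    paired = paired
  )

  group_tests <- tibble::tibble(
    grouping = character(), n_s = numeric(), statistic = character(),
    value = numeric(), df1 = numeric(), df2 = numeric(), p = numeric()
  )
  if (!is.null(subjects)) {
    joined <- dplyr::left_join(summaries, subjects, by = "subject_id")
    for (gcol in intersect(c("sex", "month"), names(subjects))) {
      for (nn in unique(summaries$n_s)) {
        sub <- joined[joined$n_s == nn & !is.na(joined$step_count), , drop = FALSE]
        g <- factor(sub[[gcol]])
        sizes <- table(g)
        if (any(sizes < 2)) {
          stop(sprintf("grouping '%s' has group(s) with < 2 subjects: %s", gcol,
                       paste(names(sizes)[sizes < 2], collapse = ", ")),
               call. = FALSE)
        }
        if (nlevels(g) == 2L) {
          tt2 <- t.test(sub$step_count ~ g, var.equal = TRUE)
          row <- tibble::tibble(grouping = gcol, n_s = nn, statistic = "t",
                                value = unname(tt2$statistic),
                                df1 = unname(tt2$parameter), df2 = NA_real_,
                                p = tt2$p.value)
        } else {
          fit <- summary(aov(sub$step_count ~ g))[[1L]]
          row <- tibble::tibble(grouping = gcol, n_s = nn, statistic = "F",
                                value = fit[["F value"]][1L],
                                df1 = fit[["Df"]][1L], df2 = fit[["Df"]][2L],
                                p = fit[["Pr(>F)"]][1L])
        }
        group_tests <- dplyr::bind_rows(group_tests, row)
      }
    }
  }
  list(correlation = correlation, rate_comparison = rate_comparison,
       group_tests = group_tests)
}
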