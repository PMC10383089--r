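test_that("day validity thresholds are strict on both margins", {
  d <- tibble::tibble(
    classified_h = c(10, 10 + 1 / 3600, 24, 9, 24),
    total_steps = c(5000L, 501L, 500L, 5000L, 499L)
  )
  d <- flag_valid_days(d)
  expect_identical(d$valid, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  # idempotent
  expect_identical(flag_valid_days(d)$valid, d$valid)
})

test_that("validity boundaries hold end to end from an event stream", {
  # exactly 10 h of data containing exactly 500 steps: invalid on both counts
  s <- build_stream(span("sedentary", 20000), bout_spans(250, 500),
                    span("sedentary", 15750), origin = "2023-01-02 08:00:00")
  ds <- summarise_days(s, durations = 120)
  expect_equal(ds$days$classified_h, 10)
  expect_identical(ds$days$total_steps, 500L)
  expect_false(ds$days$valid)

  # one second and one stride more: valid
  s <- build_stream(span("sedentary", 20000), bout_spans(251, 502),
                    span("sedentary", 15750), origin = "2023-01-02 08:00:00")
  ds <- summarise_days(s, durations = 120)
  expect_gt(ds$days$classified_h, 10)
  expect_identical(ds$days$total_steps, 502L)
  expect_true(ds$days$valid)
})

test_that("the first observation with enough valid days is analysed", {
  mk <- function(obs, dates, valid) {
    tibble::tibble(observation_id = obs, date = as.Date(dates), valid = valid)
  }
  d1 <- mk("obs1", as.Date("2023-01-02") + 0:7, c(rep(TRUE, 7), FALSE))
  d2 <- mk("obs2", as.Date("2023-06-05") + 0:7, rep(TRUE, 8))

  sel <- select_observation(rbind(d1, d2))
  expect_identical(sel$observation_id, "obs1")
  expect_identical(sel$valid_days, 7L)
  expect_false(sel$excluded)

  # first observation short of valid days: fall through to the second
  d1$valid <- c(rep(TRUE, 5), rep(FALSE, 3))
  sel <- select_observation(rbind(d1, d2))
  expect_identical(sel$observation_id, "obs2")
  expect_identical(sel$valid_days, 8L)

  # neither qualifies: excluded with a reason
  d2$valid <- rep(FALSE, 8)
  sel <- select_observation(rbind(d1, d2))
  expect_true(sel$excluded)
  expect_match(sel$reason, "7 valid days")

  expect_error(select_observation(d1[, c("date", "valid")]), "observation_id")
})

test_that("the period maximum takes the best valid day with tie-breaks", {
  dates <- as.Date("2023-01-02") + 0:3
  days <- tibble::tibble(
    subject_id = "S1", date = dates,
    classified_h = c(20, 20, 20, 20), total_steps = 5000L,
    valid = c(TRUE, TRUE, TRUE, FALSE)
  )
  windows <- tibble::tibble(
    n_s = 120, date = dates, subject_id = "S1",
    window_start = as_timestamp(paste(dates, "10:00:00")),
    step_count = c(200L, 239L, 210L, 400L),
    stepping_time_s = 100, accumulation_time_s = 120,
    truncated_by_break = FALSE
  )
  m <- max_over_period(windows, days, 120)
  expect_identical(m$step_count, 239L)         # the invalid day's 400 ignored
  expect_identical(m$date, dates[2])
  expect_identical(m$n_valid_days, 3L)

  # tie on count: shorter accumulation wins; tie again: earlier day wins
  windows$step_count <- c(239L, 239L, 239L, 400L)
  windows$accumulation_time_s <- c(120, 90, 90, 120)
  m <- max_over_period(windows, days, 120)
  expect_identical(m$date, dates[2])
  windows$accumulation_time_s <- 120
  m <- max_over_period(windows, days, 120)
  expect_identical(m$date, dates[1])

  # no valid days: NA result with zero valid days, never an error
  days$valid <- FALSE
  m <- max_over_period(windows, days, 120)
  expect_true(is.na(m$step_count))
  expect_identical(m$n_valid_days, 0L)
})

test_that("bouts per day counts bouts at least the window duration, inclusive", {
  dates <- as.Date("2023-01-02") + 0:1
  days <- tibble::tibble(date = dates, valid = c(TRUE, TRUE))
  bouts <- tibble::tibble(
    date = dates[c(1, 1, 2)], duration_s = c(130, 90, 120)
  )
  expect_equal(bouts_per_day(bouts, days, 120), 1)    # 130 and exactly 120
  expect_equal(bouts_per_day(bouts, days, 60), 1.5)
  days$valid <- c(TRUE, FALSE)
  expect_equal(bouts_per_day(bouts, days, 120), 1)    # only day one counts
  days$valid <- FALSE
  expect_true(is.na(bouts_per_day(bouts, days, 120)))
  days$valid <- TRUE
  expect_equal(bouts_per_day(bouts[0, ], days, 120), 0)
})

test_that("subject summaries report maxima, rates and bout counts per duration", {
  g <- generate_subject(generator_config(seed = 21), "S1")
  ss <- subject_summary(g$events, durations = c(120, 360))
  expect_identical(nrow(ss$summary), 2L)
  expect_identical(ss$summary$n_s, c(120, 360))
  expect_equal(ss$summary$accumulation_rate,
               ss$summary$step_count / c(2, 6), tolerance = 1e-12)
  expect_true(all(ss$summary$n_valid_days <= 7))
  expect_identical(ss$summary$month, c(1L, 1L))
  # maxima agree with a direct per-day search over the valid days
  vd <- ss$days$date[ss$days$valid]
  direct <- max(vapply(vd, function(dt) {
    dd <- split_into_days(g$events)
    dd <- dd[dd$date == dt, , drop = FALSE]
    max_n_minute_step_count(dd, 120)$step_count
  }, integer(1)))
  expect_identical(ss$summary$step_count[1], direct)
})

test_that("availability proportions respect thresholds and set inclusion", {
  # one subject whose best 6-min window held 5.5 min of stepping qualifies
  # at the 90% and 80% thresholds but not at 95% or 100%
  smry <- tibble::tibble(subject_id = "S1", n_s = 360, stepping_time_s = 330)
  tab <- stepping_proportion_table(smry)
  expect_equal(tab$proportion[tab$threshold == 1.00], 0)
  expect_equal(tab$proportion[tab$threshold == 0.95], 0)
  expect_equal(tab$proportion[tab$threshold == 0.90], 1)
  expect_equal(tab$proportion[tab$threshold == 0.80], 1)

  # exactly threshold x n qualifies; a subject with no valid days stays in
  # the denominator but never qualifies
  smry <- tibble::tibble(
    subject_id = c("S1", "S2", "S3"), n_s = 120,
    stepping_time_s = c(120, 114, NA)
  )
  tab <- stepping_proportion_table(smry, thresholds = c(1, 0.95))
  expect_identical(tab$n_subjects, c(3L, 3L))
  expect_equal(tab$proportion[tab$threshold == 1.00], 1 / 3)
  expect_equal(tab$proportion[tab$threshold == 0.95], 2 / 3)

  # monotone in threshold at fixed duration, on a generated cohort
  sim <- simulate_study(generator_config(seed = 31, days_per_subject = 2),
                        n_subjects = 12, durations = c(120, 360))
  tab <- stepping_proportion_table(sim$summaries)
  for (n in c(120, 360)) {
    sub <- tab[tab$n_s == n, ]
    sub <- sub[order(-sub$threshold), ]
    expect_true(all(diff(sub$proportion) >= 0))
  }

  expect_error(stepping_proportion_table(smry, thresholds = c(0, 1)), "0, 1")
  expect_error(stepping_proportion_table(smry[0, ]), "empty")
})

test_that("moment estimators match reference implementations exactly", {
  set.seed(42)
  for (x in list(rnorm(50), rexp(30), rlnorm(200, 0, 1.5), c(1, 2, 2, 7))) {
    n <- length(x)
    m <- mean(x)
    g1 <- mean((x - m)^3) / mean((x - m)^2)^1.5
    g2 <- mean((x - m)^4) / mean((x - m)^2)^2 - 3
    expect_equal(skewness(x, corrected = FALSE), g1, tolerance = 1e-12)
    expect_equal(kurtosis(x, corrected = FALSE), g2, tolerance = 1e-12)
    expect_equal(skewness(x), g1 * sqrt(n * (n - 1)) / (n - 2),
                 tolerance = 1e-12)
    expect_equal(kurtosis(x), ((n + 1) * g2 + 6) * (n - 1) / ((n - 2) * (n - 3)),
                 tolerance = 1e-12)
    if (requireNamespace("e1071", quietly = TRUE)) {
      expect_equal(skewness(x, corrected = FALSE), e1071::skewness(x, type = 1),
                   tolerance = 1e-12)
      expect_equal(kurtosis(x, corrected = FALSE), e1071::kurtosis(x, type = 1),
                   tolerance = 1e-12)
      expect_equal(skewness(x), e1071::skewness(x, type = 2), tolerance = 1e-12)
      expect_equal(kurtosis(x), e1071::kurtosis(x, type = 2), tolerance = 1e-12)
    }
  }
  # a symmetric sample has zero skewness
  expect_equal(skewness(c(1, 5, 1, 5)), 0, tolerance = 1e-12)
})

test_that("distribution stats classify normality and flag degenerate input", {
  set.seed(7)
  x <- rnorm(100, 800, 60)
  st <- distribution_stats(x)
  expect_identical(st$n, 100L)
  expect_true(st$is_normal)
  expect_false(st$degenerate)

  y <- rlnorm(200, 0, 2)          # heavy tail: rule fires
  st <- distribution_stats(y)
  expect_false(st$is_normal)
  expect_true(abs(st$skewness) >= 2 || st$kurtosis >= 7)

  st <- distribution_stats(rep(5, 10))
  expect_true(st$degenerate)
  expect_true(is.na(st$is_normal))
  expect_equal(st$mean, 5)

  expect_error(distribution_stats(c(1, 2, NA)), "at least 3")
})

test_that("cohort tests report correlation, rate comparison and group tests", {
  set.seed(13)
  n <- 8
  ids <- sprintf("S%d", 1:n)
  counts <- as.integer(round(rnorm(n, 240, 30)))
  smry <- rbind(
    tibble::tibble(subject_id = ids, n_s = 120, step_count = counts,
                   accumulation_rate = counts / 2),
    tibble::tibble(subject_id = ids, n_s = 360, step_count = 2L * counts,
                   accumulation_rate = 2 * counts / 6)
  )
  out <- cohort_tests(smry, durations = c(120, 360))
  expect_equal(out$correlation$r, 1, tolerance = 1e-12)  # perfectly collinear
  expect_equal(out$correlation$df, n - 2, ignore_attr = TRUE)
  # 2-min rate is 1.5x the 6-min rate here: paired t is positive, p small
  expect_gt(out$rate_comparison$t, 0)
  expect_lt(out$rate_comparison$p, 0.01)
  expect_true(out$rate_comparison$paired)

  # identical unpaired samples: t = 0, p = 1
  smry2 <- smry
  smry2$accumulation_rate[smry2$n_s == 360] <- counts / 2
  out <- cohort_tests(smry2, durations = c(120, 360), paired = FALSE)
  expect_equal(out$rate_comparison$t, 0, tolerance = 1e-12)
  expect_equal(out$rate_comparison$p, 1, tolerance = 1e-12)

  # sex t test and month ANOVA with a strong injected group effect
  subjects <- tibble::tibble(
    subject_id = ids,
    sex = rep(c("F", "M"), each = n / 2),
    month = rep(c(1L, 5L, 9L, 9L), 2)
  )
  smry3 <- smry
  boost <- ifelse(subjects$sex[match(smry3$subject_id, subjects$subject_id)]
                  == "M", 400L, 0L)
  smry3$step_count <- smry3$step_count + boost
  out <- cohort_tests(smry3, subjects = subjects, durations = c(120, 360))
  sex_rows <- out$group_tests[out$group_tests$grouping == "sex", ]
  expect_identical(nrow(sex_rows), 2L)
  expect_true(all(sex_rows$statistic == "t"))
  expect_true(all(sex_rows$p < 0.01))
  month_rows <- out$group_tests[out$group_tests$grouping == "month", ]
  expect_true(all(month_rows$statistic == "F"))
  expect_identical(month_rows$df1, c(2, 2))

  # a grouping level with fewer than 2 subjects is refused
  subjects$month <- c(1L, rep(5L, n - 1))
  expect_error(cohort_tests(smry3, subjects = subjects), "< 2 subjects")
  expect_error(cohort_tests(smry[1:4, ]), "at least 3 subjects")
})
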