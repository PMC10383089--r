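# Synthetic free-living behaviour-stream generator.
#
# Each simulated day is a wake window filled by alternating sedentary
# blocks and upright containers; a container is standing gaps interleaved
# with stepping bouts, and a bout is a run of uniform stride events (two
# steps each) at the bout's sampled cadence. Sedentary, standing and bout
# durations are log-normal; cadence is normal truncated above a floor. A
# configurable fraction of "low-opportunity" subjects draw bout durations
# truncated below a cap, which is what makes long continuous stepping rare
# at cohort level while short stepping stays near-universal.

#' Generator configuration
#'
#' Defaults describe a free-living older-adult week: 7 monitored days with
#' a 16 h waking window, median sedentary blocks of 15 min, short standing
#' transitions, log-normal stepping-bout durations with a median near 25 s
#' and a heavy right tail, cadence around 105 steps/min, and 35% of
#' subjects whose bouts are capped below 300 s (no opportunity for
#' prolonged stepping). All randomness is driven by `seed`; identical
#' configuration and seed reproduce the stream exactly.
#'
#' @param seed Integer master seed.
#' @param days_per_subject Monitored days per subject.
#' @param wake_start_h,wake_end_h Waking window, hours from midnight.
#' @param sedentary_meanlog,sedentary_sdlog Log-normal parameters of
#'   sedentary-block durations, seconds.
#' @param standing_meanlog,standing_sdlog Log-normal parameters of
#'   within-container standing gaps, seconds.
#' @param bouts_per_container_lambda Poisson intensity of stepping bouts
#'   per upright container (0 gives standing-only containers and a stream
#'   with no strides).
#' @param bouts_per_container_fixed Optional exact bout count per
#'   container, overriding the Poisson draw (useful for deterministic
#'   fixtures).
#' @param bout_meanlog,bout_sdlog Log-normal parameters of target bout
#'   durations, seconds.
#' @param cadence_mean,cadence_sd,cadence_min Bout cadence distribution,
#'   steps/min: normal truncated below at `cadence_min`.
#' @param frac_low_opportunity Fraction of subjects whose bout durations
#'   are drawn truncated below `low_opportunity_cap_s`.
#' @param low_opportunity_cap_s Bout-duration cap for low-opportunity
#'   subjects, seconds.
#' @param quantize_s Optional time resolution, seconds: event durations are
#'   rounded to this lattice (stride durations to twice it, keeping stride
#'   midpoints on the lattice), emulating the finite sampling resolution of
#'   real monitors. `NULL` keeps continuous durations.
#' @param pad_full_day Pad each day with overnight sedentary time so the
#'   stream covers whole calendar days (required when
#'   `days_per_subject > 1`, since streams must be contiguous).
#' @param start_date First monitored date.
#' @param stagger_months In [generate_cohort()], rotate subjects' start
#'   dates across the twelve months for seasonal analyses.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             days_per_subject = 7L,
                             wake_start_h = 7, wake_end_h = 23,
                             sedentary_meanlog = log(900), sedentary_sdlog = 1.0,
                             standing_meanlog = log(20), standing_sdlog = 0.8,
                             bouts_per_container_lambda = 1.7,
                             bouts_per_container_fixed = NULL,
                             bout_meanlog = log(25), bout_sdlog = 1.1,
                             cadence_mean = 105, cadence_sd = 12, cadence_min = 40,
                             frac_low_opportunity = 0.35,
                             low_opportunity_cap_s = 300,
                             quantize_s = NULL,
                             pad_full_day = TRUE,
                             start_date = as.Date("2023-01-02"),
                             stagger_months = TRUE) {
  cfg <- list(
    seed = as.integer(seed), days_per_subject = as.integer(days_per_subject),
    wake_start_h = wake_start_h, wake_end_h = wake_end_h,
    sedentary_meanlog = sedentary_meanlog, sedentary_sdlog = sedentary_sdlog,
    standing_meanlog = standing_meanlog, standing_sdlog = standing_sdlog,
    bouts_per_container_lambda = bouts_per_container_lambda,
    bouts_per_container_fixed = bouts_per_container_fixed,
    bout_meanlog = bout_meanlog, bout_sdlog = bout_sdlog,
    cadence_mean = cadence_mean, cadence_sd = cadence_sd,
    cadence_min = cadence_min,
    frac_low_opportunity = frac_low_opportunity,
    low_opportunity_cap_s = low_opportunity_cap_s,
    quantize_s = quantize_s, pad_full_day = pad_full_day,
    start_date = as.Date(start_date), stagger_months = isTRUE(stagger_months)
  )
  if (cfg$days_per_subject < 1L) stop("days_per_subject must be >= 1", call. = FALSE)
  if (cfg$wake_end_h <= cfg$wake_start_h ||
      cfg$wake_start_h < 0 || cfg$wake_end_h > 24) {
    stop("waking window must satisfy 0 <= wake_start_h < wake_end_h <= 24",
         call. = FALSE)
  }
  if (cfg$frac_low_opportunity < 0 || cfg$frac_low_opportunity > 1) {
    stop("frac_low_opportunity must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$cadence_min <= 0 || cfg$cadence_mean <= 0 || cfg$cadence_sd < 0) {
    stop("cadence parameters must be positive (sd >= 0)", call. = FALSE)
  }
  if (cfg$bouts_per_container_lambda < 0) {
    stop("bouts_per_container_lambda must be >= 0", call. = FALSE)
  }
  if (!is.null(cfg$quantize_s) && cfg$quantize_s <= 0) {
    stop("quantize_s must be NULL or > 0", call. = FALSE)
  }
  if (!cfg$pad_full_day && cfg$days_per_subject > 1L) {
    stop("pad_full_day = FALSE is only feasible for single-day streams ",
         "(multi-day streams would not be contiguous)", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

rtrunc_norm <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  p0 <- pnorm(lower, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

rtrunc_lnorm_below <- function(n, meanlog, sdlog, cap) {
  qlnorm(runif(n) * plnorm(cap, meanlog, sdlog), meanlog, sdlog)
}

#' Generate one subject's synthetic event stream
#'
#' Realises the behaviour model of [generator_config()] for one subject
#' and returns both the event stream and the generator's own ground-truth
#' bookkeeping (per-bout and per-day tallies recorded as the stream is
#' built, independently of the analysis code), so recovery can be tested
#' exactly.
#'
#' @param config A [generator_config()].
#' @param subject_id Subject identifier.
#' @param seed Seed for this subject (defaults to `config$seed`).
#' @param start_date First monitored date (defaults to
#'   `config$start_date`).
#' @return A list: `events` (validated event tibble) and `truth` with
#'   `subject`, `bouts` (start, duration, strides, steps, cadence) and
#'   `daily` (per-day sedentary/standing/stepping seconds, steps, bout and
#'   container counts).
#' @export
generate_subject <- function(config, subject_id = "S0001",
                             seed = config$seed, start_date = config$start_date) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  low_op <- runif(1) < config$frac_low_opportunity

  q <- config$quantize_s
  qz <- function(x, unit) if (is.null(q)) x else pmax(unit, round(x / unit) * unit)
  wake_start <- config$wake_start_h * 3600
  wake_len <- (config$wake_end_h - config$wake_start_h) * 3600
  day0 <- as.numeric(start_date) * 86400

  draw_bout_target <- function() {
    if (low_op) {
      rtrunc_lnorm_below(1, config$bout_meanlog, config$bout_sdlog,
                         config$low_opportunity_cap_s)
    } else {
      rlnorm(1, config$bout_meanlog, config$bout_sdlog)
    }
  }

  SED <- 1L; STAND <- 2L; BOUT <- 3L
  ev_subject <- list(); truth_bouts <- list(); truth_daily <- list()

  for (d in seq_len(config$days_per_subject) - 1L) {
    day_origin <- day0 + d * 86400
    acts <- integer(0); durs <- numeric(0)
    stride_dur <- numeric(0); n_str <- integer(0)
    t <- 0; n_containers <- 0L
    push <- function(a, dur, sdur = NA_real_, k = NA_integer_) {
      acts[[length(acts) + 1L]] <<- a
      durs[[length(durs) + 1L]] <<- dur
      stride_dur[[length(stride_dur) + 1L]] <<- sdur
      n_str[[length(n_str) + 1L]] <<- k
    }
    day_done <- FALSE
    while (!day_done && t < wake_len - 1e-9) {
      sed <- qz(rlnorm(1, config$sedentary_meanlog, config$sedentary_sdlog),
                if (is.null(q)) 1 else q)
      if (t + sed >= wake_len) { push(SED, wake_len - t); break }
      push(SED, sed); t <- t + sed

      n_containers <- n_containers + 1L
      k <- config$bouts_per_container_fixed %||%
        rpois(1, config$bouts_per_container_lambda)
      gap <- qz(rlnorm(1, config$standing_meanlog, config$standing_sdlog),
                if (is.null(q)) 1 else q)
      if (t + gap >= wake_len) { push(STAND, wake_len - t); break }
      push(STAND, gap); t <- t + gap

      for (b in seq_len(k)) {
        cadence <- rtrunc_norm(1, config$cadence_mean, config$cadence_sd,
                               config$cadence_min)
        sdur <- 120 / cadence
        # stride durations sit on a 2 * quantize_s lattice so that stride
        # midpoints stay on the quantize_s lattice
        if (!is.null(q)) sdur <- max(2 * q, round(sdur / (2 * q)) * (2 * q))
        target <- draw_bout_target()
        ns <- max(1L, as.integer(round(target / sdur)))
        bdur <- ns * sdur
        if (t + bdur >= wake_len) {
          push(STAND, wake_len - t); day_done <- TRUE; break
        }
        truth_bouts[[length(truth_bouts) + 1L]] <- c(
          day = d, start_s = day_origin + wake_start + t,
          duration_s = bdur, n_strides = ns, steps = 2 * ns,
          cadence = 2 * ns / (bdur / 60)
        )
        push(BOUT, bdur, sdur, ns)
        t <- t + bdur
        gap <- qz(rlnorm(1, config$standing_meanlog, config$standing_sdlog),
                  if (is.null(q)) 1 else q)
        if (t + gap >= wake_len) {
          push(STAND, wake_len - t); day_done <- TRUE; break
        }
        push(STAND, gap); t <- t + gap
      }
    }
    acts <- unlist(acts); durs <- unlist(durs)
    stride_dur <- unlist(stride_dur); n_str <- unlist(n_str)

    # expand bouts into uniform stride events
    reps <- ifelse(acts == BOUT, n_str, 1L)
    unit <- ifelse(acts == BOUT, stride_dur, durs)
    act_x <- rep(acts, reps)
    dur_x <- rep(unit, reps)
    if (config$pad_full_day) {
      act_x <- c(SED, act_x, SED)
      dur_x <- c(wake_start, dur_x, 86400 - wake_start - wake_len)
    }
    start_x <- day_origin + if (config$pad_full_day) 0 else wake_start
    starts <- start_x + c(0, cumsum(dur_x))[seq_along(dur_x)]

    # coalesce adjacent same-class non-stride events (overnight + first block)
    same <- c(FALSE, act_x[-1L] == act_x[-length(act_x)]) & act_x != BOUT
    grp <- cumsum(!same)
    first_of <- !same
    dur_c <- as.numeric(rowsum(dur_x, grp))
    act_c <- act_x[first_of]
    starts_c <- starts[first_of]
    activity <- c("sedentary", "standing", "stride")[act_c]
    ev_subject[[d + 1L]] <- tibble::tibble(
      subject_id = subject_id,
      start = as_timestamp(starts_c),
      duration_s = dur_c,
      activity = activity,
      steps = ifelse(activity == "stride", 2L, 0L)
    )

    bout_rows <- acts == BOUT
    truth_daily[[d + 1L]] <- tibble::tibble(
      subject_id = subject_id,
      date = as.Date(day_origin / 86400, origin = "1970-01-01"),
      sedentary_s = sum(durs[acts == SED]) +
        if (config$pad_full_day) 86400 - wake_len else 0,
      standing_s = sum(durs[acts == STAND]),
      stepping_s = sum(durs[bout_rows]),
      steps = 2L * sum(n_str[bout_rows]),
      n_bouts = sum(bout_rows),
      n_containers = n_containers
    )
  }

  events <- dplyr::bind_rows(ev_subject)
  tb <- if (length(truth_bouts)) {
    m <- do.call(rbind, truth_bouts)
    tibble::tibble(
      subject_id = subject_id,
      date = as.Date((day0 / 86400) + m[, "day"], origin = "1970-01-01"),
      start = as_timestamp(m[, "start_s"]),
      duration_s = m[, "duration_s"],
      n_strides = as.integer(m[, "n_strides"]),
      step_count = as.integer(m[, "steps"]),
      cadence = m[, "cadence"]
    )
  } else {
    tibble::tibble(subject_id = character(), date = as.Date(character()),
                   start = as_timestamp(numeric()), duration_s = numeric(),
                   n_strides = integer(), step_count = integer(),
                   cadence = numeric())
  }
  list(
    events = validate_events(events),
    truth = list(
      subject = tibble::tibble(subject_id = subject_id, seed = as.integer(seed),
                               low_opportunity = low_op,
                               start_date = as.Date(start_date)),
      bouts = tb,
      daily = dplyr::bind_rows(truth_daily)
    )
  )
}

#' Generate a synthetic cohort
#'
#' Draws one reproducible sub-seed per subject from the master seed, then
#' runs [generate_subject()] for each. When `config$stagger_months` is
#' set, subjects' start dates rotate through the twelve months of the
#' start year so month-stratified analyses have all strata.
#'
#' @param config A [generator_config()].
#' @param n_subjects Number of subjects (>= 1).
#' @return A list: `streams` (named list of event tibbles) and `manifest`
#'   (the cohort's ground truth: `subjects`, `bouts`, `daily`).
#' @export
generate_cohort <- function(config, n_subjects) {
  stopifnot(inherits(config, "generator_config"), n_subjects >= 1)
  set.seed(config$seed)
  subseeds <- sample.int(2147483646L, n_subjects)
  year <- as.integer(format(config$start_date, "%Y"))
  streams <- list(); subjects <- list(); bouts <- list(); daily <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%04d", i)
    sdate <- if (config$stagger_months) {
      as.Date(sprintf("%d-%02d-02", year, (i - 1L) %% 12L + 1L))
    } else {
      config$start_date
    }
    g <- generate_subject(config, sid, seed = subseeds[i], start_date = sdate)
    streams[[sid]] <- g$events
    subj <- g$truth$subject
    subj$month <- as.integer(format(sdate, "%m"))
    subjects[[sid]] <- subj
    bouts[[sid]] <- g$truth$bouts
    daily[[sid]] <- g$truth$daily
  }
  list(
    streams = streams,
    manifest = list(
      subjects = dplyr::bind_rows(subjects),
      bouts = dplyr::bind_rows(bouts),
      daily = dplyr::bind_rows(daily)
    )
  )
}

#' Simulate a cohort and summarise it subject by subject
#'
#' Memory-lean end-to-end driver: each subject's stream is generated,
#' summarised with [subject_summary()] and discarded, keeping only the
#' summary rows, day records and ground-truth manifest. This is the
#' entry point for cohort-scale simulation studies.
#'
#' @inheritParams generate_cohort
#' @param durations Window durations in seconds.
#' @param min_hours,min_steps Day-validity thresholds, see
#'   [flag_valid_days()].
#' @return A list: `summaries` (per subject x duration), `days`,
#'   `subjects` (with `month` and `low_opportunity`), `truth_bouts`.
#' @export
simulate_study <- function(config, n_subjects,
                           durations = default_durations(),
                           min_hours = 10, min_steps = 500) {
  stopifnot(inherits(config, "generator_config"), n_subjects >= 1)
  set.seed(config$seed)
  subseeds <- sample.int(2147483646L, n_subjects)
  year <- as.integer(format(config$start_date, "%Y"))
  summaries <- list(); days <- list(); subjects <- list(); tb <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%04d", i)
    sdate <- if (config$stagger_months) {
      as.Date(sprintf("%d-%02d-02", year, (i - 1L) %% 12L + 1L))
    } else {
      config$start_date
    }
    g <- generate_subject(config, sid, seed = subseeds[i], start_date = sdate)
    ss <- subject_summary(g$events, durations, min_hours, min_steps)
    summaries[[sid]] <- ss$summary
    days[[sid]] <- ss$days
    subj <- g$truth$subject
    subj$month <- as.integer(format(sdate, "%m"))
    subjects[[sid]] <- subj
    tb[[sid]] <- g$truth$bouts
  }
  list(
    summaries = dplyr::bind_rows(summaries),
    days = dplyr::bind_rows(days),
    subjects = dplyr::bind_rows(subjects),
    truth_bouts = dplyr::bind_rows(tb)
  )
}
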