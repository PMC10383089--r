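# Fixture builders: contiguous single-subject streams from activity spans.

spans_stream <- function(activity, duration_s, subject = "S1",
                         origin = "2023-01-02 00:00:00") {
  event_stream(subject, origin, duration_s, activity)
}

# a uniform-stride bout: `steps` steps spread evenly over `dur` seconds
bout_spans <- function(dur, steps) {
  ns <- steps / 2
  list(activity = rep("stride", ns), duration_s = rep(dur / ns, ns))
}

# splice spans and bout_spans() results into (activity, duration) vectors
splice_spans <- function(...) {
  parts <- list(...)
  act <- unlist(lapply(parts, function(p) p$activity))
  dur <- unlist(lapply(parts, function(p) p$duration_s))
  list(activity = act, duration_s = dur)
}

span <- function(activity, duration_s) {
  list(activity = activity, duration_s = duration_s)
}

build_stream <- function(..., subject = "S1", origin = "2023-01-02 00:00:00") {
  sp <- splice_spans(...)
  spans_stream(sp$activity, sp$duration_s, subject = subject, origin = origin)
}

# short-day generator presets used across property tests
oracle_config <- function(seed, quantize = 0.2) {
  generator_config(
    seed = seed, days_per_subject = 1, wake_start_h = 7, wake_end_h = 7.5,
    sedentary_meanlog = log(120), sedentary_sdlog = 1,
    standing_meanlog = log(15), standing_sdlog = 0.8,
    bouts_per_container_lambda = 1.5,
    bout_meanlog = log(30), bout_sdlog = 1.1,
    quantize_s = quantize, pad_full_day = FALSE
  )
}
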