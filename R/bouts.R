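#' Merge adjacent stride events into stepping bouts
#'
#' A stepping bout is a maximal run of temporally adjacent stride events.
#' Because a validated stream is contiguous, adjacency reduces to
#' consecutive stride rows. Each bout is characterised by its duration,
#' step count (two per stride) and cadence, defined as mean steps per
#' minute over the bout.
#'
#' @param stream Validated single-subject event tibble.
#' @return A tibble with one row per bout: `subject_id`, `bout_id`,
#'   `start`, `end`, `duration_s`, `n_strides`, `step_count`, `cadence`.
#' @examples
#' s <- event_stream("S1", "2023-01-02 08:00:00",
#'                   duration_s = c(60, 1, 1, 1),
#'                   activity = c("standing", rep("stride", 3)))
#' merge_strides_to_bouts(s)  # one bout: 3 s, 6 steps, cadence 120
#' @export
merge_strides_to_bouts <- function(stream) {
  one_subject(stream)
  empty <- tibble::tibble(
    subject_id = character(), bout_id = integer(),
    start = as_timestamp(numeric()), end = as_timestamp(numeric()),
    duration_s = numeric(), n_strides = integer(),
    step_count = integer(), cadence = numeric()
  )
  if (nrow(stream) == 0L) return(empty)
  is_stride <- stream$activity == "stride"
  if (!any(is_stride)) return(empty)
  r <- rle(is_stride)
  run <- rep(seq_along(r$lengths), r$lengths)
  start_s <- as_seconds(stream$start)
  end_s <- start_s + stream$duration_s
  idx <- which(is_stride)
  g <- run[idx]
  first <- idx[!duplicated(g)]
  last <- idx[!duplicated(g, fromLast = TRUE)]
  duration <- end_s[last] - start_s[first]
  steps <- as.integer(rowsum(as.numeric(stream$steps[idx]), g)[, 1])
  tibble::tibble(
    subject_id = stream$subject_id[first],
    bout_id = seq_along(first),
    start = as_timestamp(start_s[first]),
    end = as_timestamp(end_s[last]),
    duration_s = duration,
    n_strides = as.integer(tabulate(match(g, unique(g)))),
    step_count = steps,
    cadence = steps / (duration / 60)
  )
}

#' Build upright containers
#'
#' An upright container is a maximal contiguous block of standing and
#' stepping events uninterrupted by any sedentary (sitting or lying) event;
#' containers are bounded on each side by a sedentary event or the stream
#' boundary. They are the regions over which the step-count search window
#' can accumulate steps without hitting an upright break.
#'
#' @param stream Validated single-subject event tibble.
#' @param bouts Optional bout table from [merge_strides_to_bouts()] on the
#'   same stream; when supplied, the bout bookkeeping is cross-checked
#'   against it (every bout must fall wholly inside one container).
#' @return A tibble with one row per container: `subject_id`,
#'   `container_id`, `start`, `end`, `duration_s`, `standing_s`,
#'   `stepping_s`, `n_bouts`, `step_count`.
#' @export
build_upright_containers <- function(stream, bouts = NULL) {
  one_subject(stream)
  empty <- tibble::tibble(
    subject_id = character(), container_id = integer(),
    start = as_timestamp(numeric()), end = as_timestamp(numeric()),
    duration_s = numeric(), standing_s = numeric(), stepping_s = numeric(),
    n_bouts = integer(), step_count = integer()
  )
  if (nrow(stream) == 0L) return(empty)
  upright <- stream$activity != "sedentary"
  if (!any(upright)) return(empty)
  r <- rle(upright)
  run <- rep(seq_along(r$lengths), r$lengths)
  start_s <- as_seconds(stream$start)
  end_s <- start_s + stream$duration_s
  is_stride <- stream$activity == "stride"
  bout_head <- is_stride & !c(FALSE, is_stride[-length(is_stride)])

  idx <- which(upright)
  g <- run[idx]
  first <- idx[!duplicated(g)]
  last <- idx[!duplicated(g, fromLast = TRUE)]
  ug <- unique(g)
  gi <- match(g, ug)
  standing <- rowsum(ifelse(stream$activity[idx] == "standing",
                            stream$duration_s[idx], 0), gi)[, 1]
  stepping <- rowsum(ifelse(is_stride[idx], stream$duration_s[idx], 0), gi)[, 1]
  steps <- rowsum(as.numeric(stream$steps[idx]), gi)[, 1]
  nb <- rowsum(as.numeric(bout_head[idx]), gi)[, 1]

  out <- tibble::tibble(
    subject_id = stream$subject_id[first],
    container_id = seq_along(first),
    start = as_timestamp(start_s[first]),
    end = as_timestamp(end_s[last]),
    duration_s = end_s[last] - start_s[first],
    standing_s = as.numeric(standing),
    stepping_s = as.numeric(stepping),
    n_bouts = as.integer(nb),
    step_count = as.integer(steps)
  )
  if (!is.null(bouts) && nrow(bouts)) {
    bs <- as_seconds(bouts$start)
    be <- bs + bouts$duration_s
    ci <- findInterval(bs + .EPS, as_seconds(out$start))
    inside <- ci >= 1 & be <= as_seconds(out$end)[pmax(ci, 1L)] + .EPS
    if (!all(inside)) {
      stop("bout(s) not contained in any upright container: ",
           paste(head(which(!inside), 5), collapse = ", "), call. = FALSE)
    }
  }
  out
}
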