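# Internal helpers shared across modules.

# Comparison slack (seconds) for window-boundary arithmetic. Event timings are
# stored as doubles; strict half-open comparisons at lattice boundaries would
# otherwise flip on rounding noise far below monitor resolution.
.EPS <- 1e-6

.ACTIVITIES <- c("sedentary", "standing", "stride")

as_seconds <- function(x) {
  if (inherits(x, "POSIXct")) return(as.numeric(x))
  if (inherits(x, "Date")) return(as.numeric(x) * 86400)
  as.numeric(x)
}

as_timestamp <- function(s) {
  as.POSIXct(s, origin = "1970-01-01", tz = "UTC")
}

# All core operations work on one subject's events at a time.
one_subject <- function(stream) {
  u <- unique(stream$subject_id)
  if (length(u) > 1L) {
    stop("expected events from a single subject, got: ",
         paste(u, collapse = ", "), call. = FALSE)
  }
  invisible(u)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
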