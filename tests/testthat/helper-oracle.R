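# Independent slow reference for the maximum n-second step count: for every
# stride taken as a window anchor, scan all strides and breaks directly.
# Shares no code with the package's vectorised search.

slow_max_step_count <- function(stream, n, eps = 1e-6) {
  st <- stream[stream$activity == "stride", , drop = FALSE]
  if (!nrow(st)) return(0L)
  m <- as.numeric(st$start) + st$duration_s / 2
  steps <- as.integer(st$steps)
  sed <- as.numeric(stream$start[stream$activity == "sedentary"])
  best <- 0L
  for (i in seq_along(m)) {
    w <- m[i]
    cut <- w + n
    brk <- sed[sed >= w - eps & sed < w + n - eps]
    if (length(brk)) cut <- min(brk)
    count <- sum(steps[m >= w - eps & m < cut - eps])
    if (count > best) best <- count
  }
  as.integer(best)
}
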