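#' Validate an R-R interval series
#'
#' An RRI series is an ordered numeric vector of beat-to-beat intervals in
#' milliseconds; every value must be finite and strictly positive. Beat
#' timestamps, when needed, are the cumulative sums of the intervals (the
#' time attached to a beat is the end of its interval).
#'
#' @param values numeric vector of intervals (ms).
#' @return the validated numeric vector.
#' @export
rri_series <- function(values) {
  values <- as.numeric(values)
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad))
    stop(sprintf("non-positive or non-finite RRI value(s) at position(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  values
}

#' Beat timestamps of an RRI series
#'
#' @param values RRI series (ms).
#' @return cumulative beat times in ms (end of each interval).
#' @export
rri_times <- function(values) cumsum(as.numeric(values))

#' Fixed-capacity FIFO buffer of recent beats
#'
#' The training store of the just-in-time interpolator: it holds at most `W`
#' accepted-or-interpolated intervals, evicting the oldest on overflow.
#'
#' @param capacity maximum number of beats `W`.
#' @param values optional initial contents (oldest first); only the newest
#'   `W` are kept.
#' @return an object of class `rri_buffer`.
#' @export
rri_buffer <- function(capacity, values = numeric()) {
  stopifnot(capacity >= 1)
  values <- as.numeric(values)
  if (length(values) > capacity)
    values <- values[(length(values) - capacity + 1):length(values)]
  structure(list(values = values, capacity = capacity), class = "rri_buffer")
}

#' Enqueue beats into a FIFO buffer
#'
#' @param buffer an [rri_buffer()].
#' @param x one or more intervals (ms), oldest first.
#' @return the updated buffer.
#' @export
buffer_push <- function(buffer, x) {
  stopifnot(inherits(buffer, "rri_buffer"))
  v <- c(buffer$values, as.numeric(x))
  if (length(v) > buffer$capacity)
    v <- v[(length(v) - buffer$capacity + 1):length(v)]
  buffer$values <- v
  buffer
}

#' @export
print.rri_buffer <- function(x, ...) {
  cat(sprintf("RRI buffer: %d / %d beats\n", length(x$values), x$capacity))
  invisible(x)
}
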