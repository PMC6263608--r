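#' Configuration of the streaming RRI interpolator
#'
#' @param method interpolator: `"lwpls"` (just-in-time locally weighted PLS,
#'   the default), `"pls"` (a PLS model refitted on the buffer at each
#'   event), `"mean"` (arithmetic mean of the query vector) or `"ed"`
#'   (equal division `r_j / (q + 1)`).
#' @param phi localisation parameter of the LWPLS similarity (> 0).
#' @param K number of latent variables.
#' @param L number of past beats in the query input.
#' @param W buffer capacity in beats; must exceed `L + 1`.
#' @param r_bar detection threshold in ms: a measured interval strictly
#'   greater than `r_bar` is treated as a merged beat. Defaults to 1500 ms,
#'   well above any plausible sinus beat.
#' @param use_current include the halved current measurement `r_j / 2` as
#'   the leading query entry (the standard input layout); `FALSE` drops it
#'   and uses `L` past beats only (ablation variant).
#' @param fallback method used when a detection occurs before the buffer is
#'   full (`"mean"` by default); below `L + 2` stored beats equal division
#'   is always used.
#' @param sd_type distance-SD convention, see [compute_similarity()].
#' @return an `interpolator_config` list.
#' @export
interpolator_config <- function(method = c("lwpls", "pls", "mean", "ed"),
                                phi = 1.3, K = 3, L = 3, W = 500,
                                r_bar = 1500, use_current = TRUE,
                                fallback = "mean",
                                sd_type = "population") {
  method <- match.arg(method)
  stopifnot(phi > 0, K >= 1, L >= 1, W > L + 1, r_bar > 0)
  structure(list(method = method, phi = phi, K = K, L = L, W = W,
                 r_bar = r_bar, use_current = isTRUE(use_current),
                 fallback = fallback, sd_type = sd_type),
            class = "interpolator_config")
}

#' Detect a missed R wave from one interval measurement
#'
#' A measured interval `r_j` strictly greater than the threshold `r_bar` is
#' flagged as a merged beat (two true intervals summed by a missed R wave);
#' the boundary value `r_j = r_bar` is accepted as a normal beat.
#'
#' @param rj measured interval (ms), > 0.
#' @param r_bar threshold (ms).
#' @return `TRUE` if a detection error (missing beat) is flagged.
#' @export
detect_error <- function(rj, r_bar = 1500) {
  stopifnot(all(rj > 0), r_bar > 0)
  rj > r_bar
}

#' Build the query input for a merged measurement
#'
#' The query is `[r_j / (q + 1), r_{j-1}, ..., r_{j-L}]`: the current merged
#' measurement averaged over the `q + 1` underlying beats, followed by the
#' `L` most recent buffer values, newest first. With `use_current = FALSE`
#' the leading entry is dropped and `L` past beats alone form the input.
#'
#' @param buffer_values numeric vector of buffered beats, oldest first.
#' @param rj the merged measurement (ms).
#' @param L number of past beats.
#' @param q number of successive missed R waves (1 for a single missing
#'   beat, giving the leading entry `r_j / 2`).
#' @param use_current include the `r_j / (q + 1)` leading entry.
#' @return numeric query vector of length `L + 1` (or `L`).
#' @export
build_input <- function(buffer_values, rj, L, q = 1, use_current = TRUE) {
  n <- length(buffer_values)
  if (n < L)
    stop(sprintf("buffer holds %d beats but the query needs L = %d", n, L))
  past <- buffer_values[seq(n, n - L + 1)]      # newest first
  if (use_current) c(rj / (q + 1), past) else past
}

#' Build the second query of a two-successive-missing interpolation
#'
#' After the first of two merged-away beats has been estimated as
#' `rhat1`, the remaining sum `r_j - rhat1` covers two beats, so the second
#' query is `[(r_j - rhat1) / 2, rhat1, r_{j-1}, ..., r_{j-L+1}]`: the first
#' estimate takes the most-recent-past slot and one older beat drops off.
#'
#' @param rj the merged measurement covering three R waves (ms).
#' @param rhat1 first interpolated interval, `0 < rhat1 < rj`.
#' @param buffer_values buffered beats, oldest first.
#' @param L number of past beats in the standard query.
#' @return numeric query vector of length `L + 1`.
#' @export
build_input_second <- function(rj, rhat1, buffer_values, L) {
  if (!(rhat1 > 0 && rhat1 < rj))
    stop("first estimate must lie strictly inside (0, rj)")
  n <- length(buffer_values)
  if (n < L - 1)
    stop(sprintf("buffer holds %d beats but the query needs L - 1 = %d",
                 n, L - 1))
  past <- if (L > 1) buffer_values[seq(n, n - L + 2)] else numeric()
  c((rj - rhat1) / 2, rhat1, past)
}

#' Mean interpolator
#'
#' Replaces the missing interval by the arithmetic mean of the query vector
#' (including its leading `r_j / 2` entry when present).
#'
#' @param x query vector.
#' @return scalar estimate (ms).
#' @export
interpolate_mean <- function(x) {
  stopifnot(length(x) >= 1)
  mean(x)
}

#' Equal-division interpolator
#'
#' Splits the merged measurement evenly over the `q + 1` underlying beats.
#'
#' @param rj merged measurement (ms).
#' @param q number of successive missed R waves, `q >= 1`.
#' @return scalar estimate `rj / (q + 1)`.
#' @export
interpolate_ed <- function(rj, q = 1) {
  if (q < 1) stop("q must be at least 1")
  rj / (q + 1)
}

#' Supervised training pairs from a beat buffer
#'
#' The stream never observes the quantity the query leads with (the local
#' two-beat average `r_j / 2`), so clean training rows mimic it: for each
#' interior buffer position `i` the input is
#' `[(r_i + r_{i+1}) / 2, r_{i-1}, ..., r_{i-L}]` and the output is the true
#' `r_i`. With `use_current = FALSE` the input is the `L` past beats alone
#' and every position with `L` predecessors contributes a row.
#'
#' @param buffer_values buffered beats, oldest first.
#' @param L number of past beats per row.
#' @param use_current include the two-beat-average leading column.
#' @return list with matrix `X` and vector `y`.
#' @export
make_training_set <- function(buffer_values, L, use_current = TRUE) {
  b <- as.numeric(buffer_values)
  B <- length(b)
  if (use_current) {
    if (B < L + 2)
      stop(sprintf("buffer holds %d beats; at least L + 2 = %d are needed",
                   B, L + 2))
    E <- stats::embed(b, L + 2)     # row t: b_t, b_{t-1}, ..., b_{t-L-1}
    X <- cbind((E[, 1] + E[, 2]) / 2, E[, 3:(L + 2), drop = FALSE])
    y <- E[, 2]
  } else {
    if (B < L + 1)
      stop(sprintf("buffer holds %d beats; at least L + 1 = %d are needed",
                   B, L + 1))
    E <- stats::embed(b, L + 1)
    X <- E[, 2:(L + 1), drop = FALSE]
    y <- E[, 1]
  }
  list(X = unname(X), y = unname(y))
}

#' Model-based interpolation of one missing beat
#'
#' Forms the supervised training set from the buffer and estimates the
#' missing interval either by a PLS model fitted once for this call
#' (`method = "pls"`) or by a just-in-time locally weighted PLS estimate
#' (`method = "lwpls"`). The number of latent variables is capped at what
#' the training set supports.
#'
#' @param buffer_values buffered beats, oldest first.
#' @param x query vector (layout matching [build_input()] under the same
#'   config).
#' @param config an [interpolator_config()] with method `"pls"` or
#'   `"lwpls"`.
#' @return scalar estimate (ms).
#' @export
interpolate_model <- function(buffer_values, x, config) {
  stopifnot(config$method %in% c("pls", "lwpls"))
  ts <- make_training_set(buffer_values, config$L, config$use_current)
  N <- nrow(ts$X)
  if (N < 2) stop("not enough training rows in the buffer")
  K <- min(config$K, N - 1, ncol(ts$X))
  if (stats::sd(ts$y) == 0) return(ts$y[1])    # constant buffer: exact
  if (config$method == "pls") {
    model <- fit_pls(ts$X, ts$y, K, allow_early_stop = TRUE)
    predict(model, x)
  } else {
    lwpls_estimate(ts$X, ts$y, x, config$phi, K, sd_type = config$sd_type)
  }
}

clamp_estimate <- function(rhat, total) {
  lo <- 0.1 * total; hi <- 0.9 * total
  if (rhat < lo) list(value = lo, clamped = TRUE)
  else if (rhat > hi) list(value = hi, clamped = TRUE)
  else list(value = rhat, clamped = FALSE)
}

empty_events <- function() {
  data.frame(index = integer(), r_observed = numeric(), q = integer(),
             r_hat_1 = numeric(), r_hat_2 = numeric(), r_hat_3 = numeric(),
             method = character(), clamped = logical(),
             long_failure = logical(), stringsAsFactors = FALSE)
}

#' Stream an RRI series through detection and interpolation
#'
#' Processes intervals one at a time. Accepted beats are enqueued into the
#' FIFO buffer and copied to the output. A detection (measured value above
#' `r_bar`, or membership in `known_positions` when supplied) triggers
#' query construction, estimation of the first underlying interval
#' `rhat_j`, the complement `rhat_{j+1} = r_j - rhat_j`, replacement of the
#' merged value by the pair, and enqueueing of both — so the corrected
#' output is longer than the input by one beat per single-missing event.
#'
#' When no `known_positions` are given, the number of successive missed
#' beats is estimated online as `max(1, round(r_j / median(buffer)) - 1)`;
#' two successive missings are reconstructed sequentially via
#' [build_input_second()], and more than two are flagged as a long
#' measurement failure and passed through uninterpolated (long failures
#' call for suspending HRV analysis, not for interpolation).
#'
#' Estimates are clamped into `[0.1 r, 0.9 r]` of the sum they divide, so
#' every reconstructed interval is positive and the pair always sums to the
#' observed merged value exactly.
#'
#' @param series RRI series to correct (ms).
#' @param config an [interpolator_config()].
#' @param initial_buffer beats used to pre-fill the buffer (ms, oldest
#'   first); the paper's protocol stores at least `W` beats before
#'   processing starts, but shorter warm-ups are handled (see
#'   [interpolator_config()]'s `fallback`).
#' @param known_positions optional integer indices into `series` that are
#'   known merged measurements (evaluation mode); detection by threshold is
#'   bypassed and `q` is taken from `known_q` (default 1).
#' @param known_q successive-missing count for each known position.
#' @return list with `corrected` (numeric vector, length = input length +
#'   number of reconstructed extra beats) and `events` (data frame: index,
#'   r_observed, q, r_hat_1, r_hat_2, r_hat_3, method, clamped,
#'   long_failure).
#' @export
process_stream <- function(series, config, initial_buffer = numeric(),
                           known_positions = NULL, known_q = 1L) {
  stopifnot(inherits(config, "interpolator_config"))
  series <- as.numeric(series)
  n <- length(series)
  init <- as.numeric(initial_buffer)
  if (n == 0)
    return(list(corrected = numeric(), events = empty_events()))

  known <- if (is.null(known_positions)) integer() else as.integer(known_positions)
  if (length(known_q) == 1L) known_q <- rep(as.integer(known_q), length(known))

  # `acc` holds warm-up + corrected output; the FIFO buffer is its tail.
  acc <- c(init, numeric(n + max(16L, n %/% 4L)))
  pos <- length(init)                 # index of the newest stored beat
  n_init <- length(init)
  events <- vector("list", 0L)

  for (j in seq_len(n)) {
    r <- series[j]
    if (length(known)) {
      hit <- match(j, known)
      missing <- !is.na(hit)
      q <- if (missing) known_q[hit] else 0L
    } else {
      missing <- r > config$r_bar
      q <- 0L
      if (missing) {
        buf <- acc[seq_len(pos)]
        med <- if (pos > 0) stats::median(buf[max(1, pos - config$W + 1):pos]) else r / 2
        q <- max(1L, as.integer(round(r / med)) - 1L)
      }
    }

    if (pos + 3L > length(acc)) acc <- c(acc, numeric(length(acc)))

    if (!missing) {
      pos <- pos + 1L
      acc[pos] <- r
      next
    }

    if (q > 2L) {
      events[[length(events) + 1L]] <- data.frame(
        index = j, r_observed = r, q = q, r_hat_1 = NA_real_,
        r_hat_2 = NA_real_, r_hat_3 = NA_real_, method = "none",
        clamped = FALSE, long_failure = TRUE, stringsAsFactors = FALSE)
      pos <- pos + 1L
      acc[pos] <- r
      next
    }

    buf_lo <- max(1L, pos - config$W + 1L)
    buf <- acc[buf_lo:pos]
    nb <- length(buf)
    method <- config$method
    if (method %in% c("pls", "lwpls") && nb < config$W) {
      method <- if (nb >= config$L + 2) config$fallback else "ed"
    }
    if (method == "mean" && nb < config$L) method <- "ed"

    est_one <- function(total, qq, buffer_now) {
      if (method == "ed") return(list(value = total / (qq + 1), clamped = FALSE))
      x <- build_input(buffer_now, total, config$L, q = qq,
                       use_current = config$use_current)
      rhat <- switch(method,
                     mean = interpolate_mean(x),
                     interpolate_model(buffer_now, x,
                                       within_config(config, method)))
      clamp_estimate(rhat, total)
    }

    if (q <= 1L) {
      e1 <- est_one(r, 1L, buf)
      rhat1 <- e1$value
      rhat2 <- r - rhat1
      pos <- pos + 1L; acc[pos] <- rhat1
      pos <- pos + 1L; acc[pos] <- rhat2
      events[[length(events) + 1L]] <- data.frame(
        index = j, r_observed = r, q = 1L, r_hat_1 = rhat1, r_hat_2 = rhat2,
        r_hat_3 = NA_real_, method = method, clamped = e1$clamped,
        long_failure = FALSE, stringsAsFactors = FALSE)
    } else {                                   # q == 2: sequential pair
      e1 <- est_one(r, 2L, buf)
      rhat1 <- e1$value
      rem <- r - rhat1
      clamped <- e1$clamped
      if (method %in% c("pls", "lwpls")) {
        x2 <- build_input_second(r, rhat1, buf, config$L)
        rhat2_raw <- interpolate_model(buf, x2, within_config(config, method))
      } else if (method == "mean") {
        rhat2_raw <- interpolate_mean(build_input_second(r, rhat1, buf, config$L))
      } else {
        rhat2_raw <- rem / 2
      }
      e2 <- clamp_estimate(rhat2_raw, rem)
      rhat2 <- e2$value
      rhat3 <- rem - rhat2
      clamped <- clamped || e2$clamped
      pos <- pos + 1L; acc[pos] <- rhat1
      pos <- pos + 1L; acc[pos] <- rhat2
      pos <- pos + 1L; acc[pos] <- rhat3
      events[[length(events) + 1L]] <- data.frame(
        index = j, r_observed = r, q = 2L, r_hat_1 = rhat1, r_hat_2 = rhat2,
        r_hat_3 = rhat3, method = method, clamped = clamped,
        long_failure = FALSE, stringsAsFactors = FALSE)
    }
  }

  list(corrected = acc[(n_init + 1L):pos],
       events = if (length(events)) do.call(rbind, events) else empty_events())
}

# method override that keeps every other setting
within_config <- function(config, method) {
  config$method <- method
  config
}
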