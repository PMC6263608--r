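#' Split one subject's RRI record into study segments
#'
#' Partitions the series into three contiguous, non-overlapping prefixes in
#' order: a parameter-optimization segment, an initial-buffer segment and a
#' validation segment (the reference protocol uses 6000, 500 and 5000
#' beats).
#'
#' @param series RRI series (ms).
#' @param sizes integer vector of the three segment lengths.
#' @return list with `ro`, `rb`, `rv`.
#' @export
split_subject <- function(series, sizes = c(6000, 500, 5000)) {
  x <- as.numeric(series)
  stopifnot(length(sizes) == 3, all(sizes >= 1))
  if (length(x) < sum(sizes))
    stop(sprintf("series has %d beats; %d are required", length(x), sum(sizes)))
  b1 <- sizes[1]; b2 <- sizes[1] + sizes[2]; b3 <- sum(sizes)
  list(ro = x[seq_len(b1)],
       rb = x[(b1 + 1):b2],
       rv = x[(b2 + 1):b3])
}

#' Inject artificial merged beats into a clean series
#'
#' Selects `round(alpha * N)` non-adjacent positions uniformly at random
#' (rejection sampling under the given seed); at each selected position `j`
#' the interval is replaced by `r_j + r_{j+1}` and `r_{j+1}` is removed,
#' emulating one missed R wave. Cumulative duration is unchanged.
#'
#' @param series clean RRI series (ms), length N.
#' @param alpha missing rate as a fraction (e.g. 0.005 for 0.5%).
#' @param seed RNG seed.
#' @param n_missing optional explicit count overriding `round(alpha * N)`.
#' @return list with `degraded` (length `N - count`), `positions` (indices
#'   into the clean series), `degraded_positions` (indices of the merged
#'   values in the degraded series), and `truth` (count x 2 matrix of the
#'   eliminated interval pairs).
#' @export
introduce_missing <- function(series, alpha, seed = NULL, n_missing = NULL) {
  x <- as.numeric(series)
  N <- length(x)
  count <- if (is.null(n_missing)) round(alpha * N) else as.integer(n_missing)
  if (count < 1) stop("alpha * N must be at least 1")
  if (count > floor(N / 2))
    stop("requested missing rate cannot be placed without adjacency")
  if (!is.null(seed)) set.seed(seed)
  for (attempt in seq_len(10000)) {
    pos <- sort(sample.int(N - 1, count))
    if (count == 1 || all(diff(pos) >= 2)) break
    if (attempt == 10000)
      stop("could not place non-adjacent missing positions")
  }
  y <- x
  y[pos] <- x[pos] + x[pos + 1]
  y <- y[-(pos + 1)]
  list(degraded = y,
       positions = pos,
       degraded_positions = pos - (seq_along(pos) - 1L),
       truth = cbind(x[pos], x[pos + 1]))
}

#' Root mean squared error
#'
#' @param truth,estimate equal-length numeric vectors.
#' @return `sqrt(mean((truth - estimate)^2))`.
#' @export
rri_rmse <- function(truth, estimate) {
  stopifnot(length(truth) == length(estimate), length(truth) >= 1)
  sqrt(mean((truth - estimate)^2))
}

# RMSE over the interpolated pairs of one processed stream, given the
# ground-truth record from introduce_missing(). Events are matched to
# injected positions by their index in the degraded series.
event_rmse <- function(events, injection) {
  idx <- match(events$index, injection$degraded_positions)
  if (anyNA(idx)) stop("event at a position that was not injected")
  est <- c(rbind(events$r_hat_1, events$r_hat_2))
  tru <- c(t(injection$truth[idx, , drop = FALSE]))
  rri_rmse(tru, est)
}

#' Grid search for the LWPLS localisation and latent-variable count
#'
#' Injects missing beats (default rate 1%) into each subject's
#' parameter-optimization segment, runs the locally weighted interpolator
#' at every `(phi, K)` grid point with known missing positions, and returns
#' the pair minimising the mean RMSE over subjects. Ties break toward
#' smaller `K`, then smaller `phi`.
#'
#' @param splits list of [split_subject()] results.
#' @param phi_grid,k_grid candidate values.
#' @param alpha injection rate for the optimization segments.
#' @param config base [interpolator_config()] (fixes `L`, `W`, thresholds).
#' @param seed RNG seed for the injections.
#' @return list with `phi`, `K`, and the full `grid` data frame of mean
#'   RMSEs.
#' @export
optimize_parameters <- function(splits,
                                phi_grid = c(0.1, 0.3, 0.5, 0.8, 1.0,
                                             1.3, 1.6, 2.0, 3.0),
                                k_grid = NULL,
                                alpha = 0.01,
                                config = interpolator_config(),
                                seed = 1L) {
  stopifnot(length(phi_grid) >= 1)
  if (is.null(k_grid)) k_grid <- seq_len(config$L + 1)
  injections <- lapply(seq_along(splits), function(s)
    introduce_missing(splits[[s]]$ro, alpha, seed = seed + s))
  grid <- expand.grid(phi = phi_grid, K = k_grid)
  grid$rmse <- vapply(seq_len(nrow(grid)), function(g) {
    cfg <- config
    cfg$method <- "lwpls"
    cfg$phi <- grid$phi[g]
    cfg$K <- grid$K[g]
    mean(vapply(seq_along(splits), function(s) {
      inj <- injections[[s]]
      warm <- utils::tail(splits[[s]]$rb, cfg$W)
      res <- process_stream(inj$degraded, cfg, initial_buffer = warm,
                            known_positions = inj$degraded_positions)
      event_rmse(res$events, inj)
    }, numeric(1)))
  }, numeric(1))
  ord <- order(grid$rmse, grid$K, grid$phi)
  best <- grid[ord[1], ]
  list(phi = best$phi, K = best$K, grid = grid)
}

#' Benchmark the interpolators on a cohort of degraded tachograms
#'
#' For every repetition, missing rate, subject and method: merged beats are
#' injected into the validation segment (a fresh seeded draw per
#' repetition), the buffer is warmed with the subject's buffer segment, the
#' stream is interpolated with the injected positions known (evaluation
#' mode), and the RMSE over the reconstructed interval pairs is recorded.
#' Optionally, the eight HRV features are computed over sliding windows on
#' the true and on the corrected series and a per-feature RMSE is recorded
#' for the methods in `hrv_methods` at the rate `hrv_alpha`.
#'
#' @param splits list of [split_subject()] results, one per subject.
#' @param methods character vector among `"lwpls"`, `"pls"`, `"mean"`,
#'   `"ed"`.
#' @param alphas missing rates (fractions).
#' @param reps number of repetitions (fresh injections each).
#' @param config base [interpolator_config()].
#' @param hrv a [spectral_config()], or `NULL` to skip HRV-level scoring.
#' @param hrv_methods methods scored at the HRV level.
#' @param hrv_alpha the single missing rate used for HRV-level scoring.
#' @param hrv_step sliding-window advance in beats for HRV scoring.
#' @param base_seed seeds are derived deterministically from this, the
#'   repetition, the subject and the rate.
#' @return list of tidy data frames: `rri` (method, alpha, rep, subject,
#'   rmse), `hrv` (method, alpha, rep, subject, feature, rmse; `NULL` if
#'   skipped), and `summary` (mean RMSE by method and alpha).
#' @export
run_benchmark <- function(splits, methods = c("mean", "ed", "pls", "lwpls"),
                          alphas = c(0.003, 0.005, 0.01), reps = 30,
                          config = interpolator_config(),
                          hrv = NULL, hrv_methods = c("mean", "lwpls"),
                          hrv_alpha = 0.005, hrv_step = 25,
                          base_seed = 20181110) {
  stopifnot(reps >= 1, length(splits) >= 1)
  truth_hrv <- NULL
  if (!is.null(hrv)) {
    truth_hrv <- lapply(splits, function(sp) sliding_hrv(sp$rv, hrv, hrv_step))
  }
  rri_rows <- list()
  hrv_rows <- list()
  for (rep_i in seq_len(reps)) {
    for (ai in seq_along(alphas)) {
      alpha <- alphas[ai]
      for (s in seq_along(splits)) {
        sp <- splits[[s]]
        seed <- base_seed + 7919L * rep_i + 101L * s + ai
        inj <- introduce_missing(sp$rv, alpha, seed = seed)
        warm <- utils::tail(sp$rb, config$W)
        for (m in methods) {
          cfg <- within_config(config, m)
          res <- process_stream(inj$degraded, cfg, initial_buffer = warm,
                                known_positions = inj$degraded_positions)
          rri_rows[[length(rri_rows) + 1L]] <- data.frame(
            method = m, alpha = alpha, rep = rep_i, subject = s,
            rmse = event_rmse(res$events, inj), stringsAsFactors = FALSE)
          if (!is.null(hrv) && m %in% hrv_methods && alpha == hrv_alpha) {
            feats <- sliding_hrv(res$corrected, hrv, hrv_step)
            nw <- min(nrow(feats), nrow(truth_hrv[[s]]))
            for (f in hrv_feature_names) {
              a <- feats[[f]][seq_len(nw)]
              b <- truth_hrv[[s]][[f]][seq_len(nw)]
              ok <- is.finite(a) & is.finite(b)
              hrv_rows[[length(hrv_rows) + 1L]] <- data.frame(
                method = m, alpha = alpha, rep = rep_i, subject = s,
                feature = f,
                rmse = if (any(ok)) rri_rmse(b[ok], a[ok]) else NA_real_,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  rri <- do.call(rbind, rri_rows)
  hrv_df <- if (length(hrv_rows)) do.call(rbind, hrv_rows) else NULL
  summary <- stats::aggregate(rmse ~ method + alpha, rri, mean)
  list(rri = rri, hrv = hrv_df, summary = summary)
}
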