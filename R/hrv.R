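#' Spectral-analysis settings for HRV extraction
#'
#' Defaults follow common practice for short-term HRV: the tachogram is
#' cubic-spline resampled at 4 Hz, an autoregressive model of order 40 is
#' fitted to each 3-minute window, and band powers are integrated over the
#' standard LF (0.04-0.15 Hz) and HF (0.15-0.40 Hz) bands, with total power
#' taken over 0.0033-0.40 Hz.
#'
#' @param resample_hz resampling rate of the tachogram (Hz).
#' @param ar_order autoregressive model order.
#' @param lf_band,hf_band,tp_band frequency bands (Hz), each within
#'   (0, resample_hz / 2).
#' @param window_s sliding-window length in seconds.
#' @param ar_method `"burg"` (default) or `"yule-walker"`.
#' @param n_freq number of PSD evaluation points on (0, resample_hz / 2].
#' @return a `spectral_config` list.
#' @export
spectral_config <- function(resample_hz = 4, ar_order = 40,
                            lf_band = c(0.04, 0.15),
                            hf_band = c(0.15, 0.40),
                            tp_band = c(0.0033, 0.40),
                            window_s = 180,
                            ar_method = c("burg", "yule-walker"),
                            n_freq = 4096) {
  ar_method <- match.arg(ar_method)
  nyq <- resample_hz / 2
  stopifnot(all(c(lf_band, hf_band, tp_band) > 0),
            all(c(lf_band, hf_band, tp_band) < nyq),
            ar_order >= 1, ar_order < window_s * resample_hz,
            window_s > 0, n_freq >= 64)
  structure(list(resample_hz = resample_hz, ar_order = ar_order,
                 lf_band = lf_band, hf_band = hf_band, tp_band = tp_band,
                 window_s = window_s, ar_method = ar_method,
                 n_freq = n_freq),
            class = "spectral_config")
}

hrv_feature_names <- c("meanNN", "SDNN", "RMSSD", "NN50",
                       "TP", "LF", "HF", "LF_HF")

#' Time-domain HRV features of one window
#'
#' meanNN and SDNN are the mean and (sample) standard deviation of the
#' intervals, RMSSD the root mean square of successive differences, and
#' NN50 the count of successive differences strictly exceeding 50 ms.
#'
#' @param window RRI values in the window (ms).
#' @return named numeric vector `meanNN`, `SDNN`, `RMSSD`, `NN50`; all `NA`
#'   when fewer than two intervals are available.
#' @export
time_domain <- function(window) {
  x <- as.numeric(window)
  if (length(x) < 2)
    return(c(meanNN = NA_real_, SDNN = NA_real_, RMSSD = NA_real_,
             NN50 = NA_real_))
  dx <- diff(x)
  c(meanNN = mean(x),
    SDNN = stats::sd(x),
    RMSSD = sqrt(mean(dx^2)),
    NN50 = sum(abs(dx) > 50))
}

#' Resample a tachogram onto an even grid
#'
#' Interpolates interval value against cumulative beat time with a cubic
#' spline and evaluates it on a uniform grid at `resample_hz`, spanning the
#' window from the first to the last beat time. Beat times are assigned at
#' the end of each interval.
#'
#' @param window RRI values (ms); at least four beats.
#' @param config a [spectral_config()].
#' @param t_ms optional beat times (ms); default `cumsum(window)`.
#' @return list with `t_ms` (grid times) and `rri` (interpolated values).
#' @export
resample_tachogram <- function(window, config = spectral_config(),
                               t_ms = NULL) {
  x <- as.numeric(window)
  if (length(x) < 4) stop("cubic-spline resampling needs at least 4 beats")
  t <- if (is.null(t_ms)) cumsum(x) else as.numeric(t_ms)
  stopifnot(length(t) == length(x), !is.unsorted(t, strictly = TRUE))
  f <- stats::splinefun(t, x, method = "fmm")
  dt <- 1000 / config$resample_hz
  grid <- seq(t[1], t[length(t)], by = dt)
  list(t_ms = grid, rri = f(grid))
}

# One-sided AR PSD (ms^2 per Hz) on a frequency grid; integrates to the
# series variance over (0, Nyquist].
ar_psd <- function(x, config) {
  x <- x - mean(x)
  fit <- switch(config$ar_method,
                "burg" = stats::ar.burg(x, aic = FALSE,
                                        order.max = config$ar_order,
                                        demean = FALSE),
                "yule-walker" = stats::ar.yw(x, aic = FALSE,
                                             order.max = config$ar_order,
                                             demean = FALSE))
  a <- fit$ar
  dt <- 1 / config$resample_hz
  # |A(e^{-i 2 pi f dt})|^2 on a dense half-spectrum grid via FFT of the
  # AR polynomial: cheap enough to resolve the narrow Burg poles
  nfft <- 2 * config$n_freq
  poly <- c(1, -a, rep(0, nfft - length(a) - 1))
  denom <- abs(stats::fft(poly)[seq_len(config$n_freq + 1)])^2
  f <- (0:config$n_freq) * config$resample_hz / nfft
  list(freq = f, psd = 2 * fit$var.pred * dt / denom)
}

band_power <- function(freq, psd, band) {
  sel <- freq >= band[1] & freq <= band[2]
  if (sum(sel) < 2) return(0)
  f <- freq[sel]; p <- psd[sel]
  sum(diff(f) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Frequency-domain HRV features from a resampled tachogram
#'
#' Removes the mean, fits an autoregressive model (Burg by default),
#' evaluates its one-sided power spectral density on a dense grid, and
#' integrates it numerically over the configured bands.
#'
#' @param resampled evenly sampled tachogram values (ms), e.g. the `rri`
#'   element of [resample_tachogram()].
#' @param config a [spectral_config()].
#' @return named numeric vector `TP`, `LF`, `HF` (ms^2) and `LF_HF`
#'   (dimensionless; `NA` when HF is zero).
#' @export
spectral_features <- function(resampled, config = spectral_config()) {
  x <- as.numeric(resampled)
  if (length(x) <= config$ar_order)
    stop(sprintf("series length %d must exceed the AR order %d",
                 length(x), config$ar_order))
  if (stats::sd(x) < .Machine$double.eps^0.5)   # flat window: no power
    return(c(TP = 0, LF = 0, HF = 0, LF_HF = NA_real_))
  s <- ar_psd(x, config)
  tp <- band_power(s$freq, s$psd, config$tp_band)
  lf <- band_power(s$freq, s$psd, config$lf_band)
  hf <- band_power(s$freq, s$psd, config$hf_band)
  c(TP = tp, LF = lf, HF = hf,
    LF_HF = if (hf > 0) lf / hf else NA_real_)
}

#' Sliding-window HRV features over an RRI series
#'
#' A rectangular window of `window_s` seconds slides over the tachogram,
#' advancing by `step` beats; each window ends at a beat time `t_end` and
#' contains the beats whose cumulative times lie in
#' `(t_end - window_s, t_end]`. Time-domain features are computed from the
#' raw intervals in the window; frequency-domain features from the
#' resampled tachogram when the window supports the AR fit (otherwise they
#' are `NA`).
#'
#' @param series RRI series (ms).
#' @param config a [spectral_config()].
#' @param step window advance in beats.
#' @return data frame with `t_ms` (window end time) and the eight features
#'   `meanNN`, `SDNN`, `RMSSD`, `NN50`, `TP`, `LF`, `HF`, `LF_HF`; zero
#'   rows when the series is shorter than one window.
#' @export
sliding_hrv <- function(series, config = spectral_config(), step = 1) {
  x <- as.numeric(series)
  t <- cumsum(x)
  win_ms <- config$window_s * 1000
  ends <- which(t >= win_ms)
  if (!length(ends))
    return(stats::setNames(
      as.data.frame(matrix(numeric(), 0, 9)),
      c("t_ms", hrv_feature_names)))
  ends <- ends[seq(1, length(ends), by = step)]
  rows <- lapply(ends, function(e) {
    sel <- t > t[e] - win_ms & t <= t[e]
    w <- x[sel]
    td <- time_domain(w)
    fd <- c(TP = NA_real_, LF = NA_real_, HF = NA_real_, LF_HF = NA_real_)
    if (length(w) >= 4) {
      rs <- resample_tachogram(w, config, t_ms = t[sel])
      if (length(rs$rri) > config$ar_order)
        fd <- spectral_features(rs$rri, config)
    }
    c(t_ms = t[e], td, fd)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("t_ms", hrv_feature_names)
  out
}
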