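#' Configuration of the synthetic sinus-rhythm RRI generator
#'
#' The generator emulates an adult resting tachogram: a baseline interval
#' modulated by a low-frequency (Mayer-wave, ~0.1 Hz) and a high-frequency
#' (respiratory, ~0.25 Hz) oscillation, a slow drift, and first-order
#' autoregressive beat-to-beat noise. Oscillators are driven by cumulative
#' beat TIME, not beat index, so their power lands in the stated HRV bands
#' after resampling. Values are clipped to [300, 1500] ms, keeping clean
#' beats below the default 1500 ms detection threshold.
#'
#' @param n_beats number of beats to generate.
#' @param baseline_ms mean interval (ms).
#' @param lf_amp_ms,lf_freq_hz low-frequency oscillation amplitude (ms) and
#'   frequency (Hz).
#' @param hf_amp_ms,hf_freq_hz high-frequency oscillation amplitude (ms)
#'   and frequency (Hz).
#' @param ar1_noise_sd_ms innovation SD of the AR(1) beat noise (ms).
#' @param ar1_coef AR(1) coefficient of the beat noise.
#' @param drift_amp_ms,drift_period_s slow sinusoidal drift amplitude (ms)
#'   and period (s).
#' @param seed RNG seed for this series.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_beats = 2000, baseline_ms = 850,
                             lf_amp_ms = 30, lf_freq_hz = 0.1,
                             hf_amp_ms = 20, hf_freq_hz = 0.25,
                             ar1_noise_sd_ms = 15, ar1_coef = 0.5,
                             drift_amp_ms = 40, drift_period_s = 300,
                             seed = 1L) {
  stopifnot(n_beats >= 1, baseline_ms > 0, lf_amp_ms >= 0, hf_amp_ms >= 0,
            ar1_noise_sd_ms >= 0, drift_amp_ms >= 0,
            abs(ar1_coef) < 1, drift_period_s > 0)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic RRI series
#'
#' Beats are produced sequentially: the i-th interval is the sum of the
#' baseline, the LF/HF sinusoids and the drift evaluated at the current
#' cumulative time, plus AR(1) noise, clipped to [300, 1500] ms; the clock
#' then advances by the generated interval. Deterministic under `seed`.
#'
#' @param config a [synthetic_config()].
#' @return numeric RRI series (ms) of length `n_beats`.
#' @export
generate_rri <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_beats
  out <- numeric(n)
  eps <- stats::rnorm(n, 0, config$ar1_noise_sd_ms)
  t_s <- 0          # time of the previous beat, seconds
  e <- 0
  for (i in seq_len(n)) {
    e <- config$ar1_coef * e + eps[i]
    r <- config$baseline_ms +
      config$lf_amp_ms * sin(2 * pi * config$lf_freq_hz * t_s) +
      config$hf_amp_ms * sin(2 * pi * config$hf_freq_hz * t_s) +
      config$drift_amp_ms * sin(2 * pi * t_s / config$drift_period_s) +
      e
    r <- min(max(r, 300), 1500)
    out[i] <- r
    t_s <- t_s + r / 1000
  }
  out
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject parameters are drawn uniformly within multiplicative jitter
#' ranges around the base configuration (seeded), then one series is
#' generated per subject with its own noise seed.
#'
#' @param n_subjects number of subjects.
#' @param base a [synthetic_config()] giving the cohort-mean parameters.
#' @param jitter named list of fractional half-ranges; each named parameter
#'   `p` is multiplied by a factor drawn from
#'   `U(1 - jitter$p, 1 + jitter$p)`. Default jitters baseline by 10% and
#'   the oscillation/noise amplitudes by 20%.
#' @param seed cohort-level RNG seed.
#' @return list of RRI series, one per subject.
#' @export
generate_cohort <- function(n_subjects, base = synthetic_config(),
                            jitter = list(baseline_ms = 0.1,
                                          lf_amp_ms = 0.2,
                                          hf_amp_ms = 0.2,
                                          ar1_noise_sd_ms = 0.2),
                            seed = 1L) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  factors <- lapply(seq_len(n_subjects), function(s) {
    fs <- lapply(jitter, function(j) stats::runif(1, 1 - j, 1 + j))
    fs
  })
  lapply(seq_len(n_subjects), function(s) {
    cfg <- base
    for (p in names(jitter)) cfg[[p]] <- cfg[[p]] * factors[[s]][[p]]
    cfg$seed <- seed + s
    generate_rri(cfg)
  })
}
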