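test_that("detection flags only intervals strictly above the threshold", {
  expect_false(detect_error(900, 1500))
  expect_true(detect_error(1600, 1500))
  expect_false(detect_error(1500, 1500))   # boundary accepted as a beat
})

test_that("query construction takes the halved measurement then past beats
           newest first", {
  buf <- c(750, 760, 795, 805, 810)
  expect_equal(build_input(buf, 1600, L = 3), c(800, 810, 805, 795))
  expect_equal(build_input(c(700), 1400, L = 1), c(700, 700))
  # two successive missings lead with r/3
  expect_equal(build_input(c(790, 800, 810), 2400, L = 3, q = 2),
               c(800, 810, 800, 790))
  expect_equal(build_input(buf, 1600, L = 3, use_current = FALSE),
               c(810, 805, 795))
  expect_error(build_input(c(800, 810), 1600, L = 3), "buffer holds")
})

test_that("the second successive-missing query embeds the first estimate", {
  expect_equal(build_input_second(2400, 800, c(800, 810), L = 3),
               c(800, 800, 810, 800))
  expect_equal(build_input_second(2400, 790, c(800, 810), L = 3)[1], 805)
  expect_equal(build_input_second(2400, 800, rep(800, 5), L = 3),
               rep(800, 4))
  expect_error(build_input_second(2400, 2400, c(800, 810), L = 3),
               "strictly inside")
})

test_that("baseline interpolators follow their closed forms", {
  expect_equal(interpolate_mean(c(800, 810, 805, 795)), 802.5)
  expect_equal(interpolate_mean(rep(640, 7)), 640)
  expect_equal(interpolate_mean(c(750, 850)), 800)
  expect_equal(interpolate_ed(1800, 1), 900)
  expect_equal(interpolate_ed(1800, 2), 600)
  expect_equal(interpolate_ed(1500, 1), 750)
  expect_error(interpolate_ed(1800, 0), "at least 1")
})

test_that("training pairs pair the two-beat average with the true beat", {
  b <- c(700, 710, 720, 730, 740, 750)
  ts <- make_training_set(b, L = 2)
  # interior positions i = 3, 4, 5: input [(b_i + b_{i+1})/2, b_{i-1}, b_{i-2}]
  expect_equal(dim(ts$X), c(3, 3))
  expect_equal(ts$X[1, ], c((720 + 730) / 2, 710, 700))
  expect_equal(ts$y, c(720, 730, 740))
  ts2 <- make_training_set(b, L = 2, use_current = FALSE)
  expect_equal(dim(ts2$X), c(4, 2))
  expect_equal(ts2$X[1, ], c(710, 700))
  expect_equal(ts2$y, c(720, 730, 740, 750))
  expect_error(make_training_set(c(800, 810), L = 3), "at least")
})

test_that("model interpolation is exact on a constant buffer", {
  buf <- rep(800, 60)
  for (method in c("pls", "lwpls")) {
    cfg <- interpolator_config(method = method, W = 60, L = 3)
    x <- build_input(buf, 1600, 3)
    expect_equal(interpolate_model(buf, x, cfg), 800)
  }
})

test_that("LWPLS and PLS agree where the buffer relation is exactly linear", {
  # on a noiseless periodic buffer the supervised relation is exactly
  # linear, so the locally weighted and the global fit coincide
  buf <- rep(c(700, 900), 30)
  x <- build_input(buf, 1600, 3)
  est_lw <- interpolate_model(buf, x, interpolator_config("lwpls", W = 60))
  est_pls <- interpolate_model(buf, x, interpolator_config("pls", W = 60))
  expect_equal(est_lw, est_pls, tolerance = 1e-10)
})

test_that("a noiseless alternating rhythm is reconstructed to under 1 ms", {
  buf <- rep(c(700, 900), 30)       # ends on 900, so the merged beat is 700
  x <- build_input(buf, 1600, 3)
  for (method in c("pls", "lwpls")) {
    est <- interpolate_model(buf, x,
                             interpolator_config(method, W = 60, L = 3))
    expect_lt(abs(est - 700), 1)
  }
  # OLS oracle on the same supervised pairs agrees; the alternating series
  # makes all lag columns collinear, so regress on the first lag alone
  ts <- make_training_set(buf, 3)
  expect_lt(abs(ols_fit_predict(ts$X[, 2, drop = FALSE], ts$y,
                                matrix(x[2], 1)) - 700), 1e-6)
})

test_that("a stream with one merged beat in a constant rhythm is restored", {
  series <- rep(800, 120); series[60] <- 1600
  res <- process_stream(series, interpolator_config(W = 50),
                        initial_buffer = rep(800, 50))
  expect_equal(nrow(res$events), 1)
  expect_equal(res$events$index, 60)
  expect_equal(res$events$r_hat_1, 800)
  expect_equal(res$events$r_hat_2, 800)
  expect_equal(res$corrected, rep(800, 121))
})

test_that("clean streams pass through untouched with zero events", {
  set.seed(10)
  series <- rnorm(300, 850, 40)
  res <- process_stream(series, interpolator_config(W = 50),
                        initial_buffer = rnorm(50, 850, 40))
  expect_equal(nrow(res$events), 0)
  expect_equal(res$corrected, series)
})

test_that("every event conserves the merged measurement", {
  set.seed(11)
  for (method in c("mean", "ed", "pls", "lwpls")) {
    clean <- generate_rri(synthetic_config(n_beats = 700, seed = 12))
    inj <- introduce_missing(clean, 0.01, seed = 13)
    cfg <- interpolator_config(method = method, W = 100)
    res <- process_stream(inj$degraded, cfg,
                          initial_buffer = generate_rri(
                            synthetic_config(n_beats = 100, seed = 14)))
    expect_equal(nrow(res$events), length(inj$positions))
    expect_true(all(abs(res$events$r_hat_1 + res$events$r_hat_2 -
                          res$events$r_observed) < 1e-9))
    expect_true(all(res$events$r_hat_1 > 0 & res$events$r_hat_2 > 0))
    expect_equal(length(res$corrected),
                 length(inj$degraded) + nrow(res$events))
    # the corrected stream preserves cumulative duration
    expect_equal(sum(res$corrected), sum(clean), tolerance = 1e-6)
  }
})

test_that("only the newest W beats inform the estimate (FIFO discipline)", {
  set.seed(15)
  series <- c(rnorm(200, 850, 30), 1700, rnorm(10, 850, 30))
  cfg <- interpolator_config(W = 80)
  long_init <- rnorm(300, 600, 10)   # old, different regime
  a <- process_stream(series, cfg, initial_buffer = long_init)
  b <- process_stream(series, cfg, initial_buffer = utils::tail(long_init, 80))
  expect_equal(a$corrected, b$corrected)
  expect_equal(a$events, b$events)
})

test_that("estimates outside the admissible range are clamped and flagged", {
  # buffer near 800 ms but the merged measurement is tiny: the mean query
  # estimate exceeds 0.9 * r and must be clamped
  series <- rep(800, 30); series[20] <- 300
  res <- process_stream(series, interpolator_config("mean", W = 20),
                        initial_buffer = rep(800, 20),
                        known_positions = 20L)
  ev <- res$events
  expect_true(ev$clamped)
  expect_equal(ev$r_hat_1, 0.9 * 300)
  expect_equal(ev$r_hat_1 + ev$r_hat_2, 300)
})

test_that("detections before a full buffer fall back to simpler methods", {
  cfg <- interpolator_config("lwpls", W = 100, L = 3)
  # buffer below L + 2: equal division
  r1 <- process_stream(c(800, 1600, 800), cfg, initial_buffer = c(800, 800))
  expect_equal(r1$events$method, "ed")
  expect_equal(r1$events$r_hat_1, 800)
  # buffer between L + 2 and W: the configured fallback (mean)
  r2 <- process_stream(c(rep(800, 30), 1600), cfg,
                       initial_buffer = rep(800, 10))
  expect_equal(r2$events$method, "mean")
})

test_that("two successive missings are reconstructed sequentially", {
  series <- rep(800, 200); series[150] <- 2400   # three beats merged
  res <- process_stream(series, interpolator_config(W = 100),
                        initial_buffer = rep(800, 100))
  ev <- res$events
  expect_equal(ev$q, 2L)
  expect_equal(ev$r_hat_1 + ev$r_hat_2 + ev$r_hat_3, 2400, tolerance = 1e-9)
  expect_equal(c(ev$r_hat_1, ev$r_hat_2, ev$r_hat_3), rep(800, 3),
               tolerance = 1e-6)
  expect_equal(length(res$corrected), 202)
})

test_that("more than two successive missings are flagged, not interpolated", {
  series <- rep(800, 150); series[100] <- 4000   # q ~ 4
  res <- process_stream(series, interpolator_config(W = 100),
                        initial_buffer = rep(800, 100))
  ev <- res$events
  expect_true(ev$long_failure)
  expect_equal(ev$method, "none")
  expect_equal(length(res$corrected), 150)   # passed through
  expect_equal(res$corrected[100], 4000)
})
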