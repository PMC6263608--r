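test_that("subject splitting partitions the record contiguously", {
  x <- seq_len(25)
  sp <- split_subject(x, c(10, 5, 10))
  expect_equal(sp$ro, 1:10)
  expect_equal(sp$rb, 11:15)
  expect_equal(sp$rv, 16:25)
  expect_error(split_subject(seq_len(20), c(10, 5, 10)), "required")
  big <- split_subject(rep(800, 11500), c(6000, 500, 5000))
  expect_equal(lengths(big), c(ro = 6000, rb = 500, rv = 5000))
})

test_that("missing injection merges the stated count of non-adjacent pairs", {
  x <- generate_rri(synthetic_config(n_beats = 1000, seed = 30))
  inj <- introduce_missing(x, 0.01, seed = 31)
  expect_equal(length(inj$positions), 10)
  expect_equal(length(inj$degraded), 990)
  expect_true(all(diff(inj$positions) >= 2))
  # each merged value is the sum of the eliminated pair; duration conserved
  expect_equal(inj$degraded[inj$degraded_positions],
               inj$truth[, 1] + inj$truth[, 2])
  expect_equal(sum(inj$degraded), sum(x))
  # determinism
  inj2 <- introduce_missing(x, 0.01, seed = 31)
  expect_identical(inj$positions, inj2$positions)
  expect_identical(inj$degraded, inj2$degraded)
  expect_error(introduce_missing(x, 0.0001), "at least 1")
})

test_that("RMSE follows its definition", {
  expect_equal(rri_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rri_rmse(c(10, 20), c(13, 23)), 3)
  expect_equal(rri_rmse(c(800, 810), c(790, 820)), 10)
  expect_error(rri_rmse(1:3, 1:4), "length")
})

test_that("a single-point grid is returned as the optimum", {
  co <- generate_cohort(2, synthetic_config(n_beats = 900), seed = 40)
  splits <- lapply(co, split_subject, sizes = c(500, 200, 200))
  cfg <- interpolator_config(W = 150)
  best <- optimize_parameters(splits, phi_grid = 1.3, k_grid = 3,
                              config = cfg, seed = 41)
  expect_equal(best$phi, 1.3)
  expect_equal(best$K, 3)
  expect_equal(nrow(best$grid), 1)
})

test_that("the grid optimum attains the minimum mean RMSE by construction", {
  co <- generate_cohort(2, synthetic_config(n_beats = 900), seed = 42)
  splits <- lapply(co, split_subject, sizes = c(500, 200, 200))
  cfg <- interpolator_config(W = 150)
  best <- optimize_parameters(splits, phi_grid = c(0.5, 1.3),
                              k_grid = c(1, 3), config = cfg, seed = 43)
  sel <- best$grid$phi == best$phi & best$grid$K == best$K
  expect_true(all(best$grid$rmse[sel] <= best$grid$rmse))
})

test_that("MEAN interpolation of a constant cohort has zero RMSE", {
  x <- rep(800, 700)
  splits <- list(split_subject(x, c(100, 150, 450)))
  rep1 <- run_benchmark(splits, methods = "mean", alphas = 0.01, reps = 2,
                        config = interpolator_config(W = 150),
                        base_seed = 50)
  expect_true(all(rep1$rri$rmse == 0))
})

test_that("benchmark reports are bit-identical under the same seeds", {
  co <- generate_cohort(2, synthetic_config(n_beats = 900), seed = 51)
  splits <- lapply(co, split_subject, sizes = c(1, 200, 600))
  cfg <- interpolator_config(W = 150)
  a <- run_benchmark(splits, methods = c("mean", "lwpls"), alphas = 0.01,
                     reps = 2, config = cfg, base_seed = 52)
  b <- run_benchmark(splits, methods = c("mean", "lwpls"), alphas = 0.01,
                     reps = 2, config = cfg, base_seed = 52)
  expect_identical(a$rri, b$rri)
  expect_identical(a$summary, b$summary)
})

test_that("aggregate RMSE is invariant to subject and repetition order", {
  co <- generate_cohort(3, synthetic_config(n_beats = 900), seed = 53)
  splits <- lapply(co, split_subject, sizes = c(1, 200, 600))
  cfg <- interpolator_config(W = 150)
  r <- run_benchmark(splits, methods = "lwpls", alphas = 0.01, reps = 3,
                     config = cfg, base_seed = 54)
  set.seed(55)
  shuffled <- r$rri[sample(nrow(r$rri)), ]
  expect_equal(mean(shuffled$rmse), r$summary$rmse[1])
})

test_that("threshold detection agrees with known positions when separable", {
  clean <- generate_rri(synthetic_config(n_beats = 800, seed = 56))
  expect_true(all(clean <= 1500))         # clipping keeps clean beats below
  inj <- introduce_missing(clean, 0.01, seed = 57)
  stopifnot(all(inj$degraded[inj$degraded_positions] > 1500))
  cfg <- interpolator_config(W = 150)
  warm <- generate_rri(synthetic_config(n_beats = 150, seed = 58))
  known <- process_stream(inj$degraded, cfg, initial_buffer = warm,
                          known_positions = inj$degraded_positions)
  auto <- process_stream(inj$degraded, cfg, initial_buffer = warm)
  expect_equal(auto$corrected, known$corrected)
  expect_equal(auto$events$index, known$events$index)
})
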