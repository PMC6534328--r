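test_that("bounded simplex search finds box-interior and boundary optima", {
  # interior quadratic
  res <- fminsearch_bounded(function(p) sum((p - c(1, -2))^2),
                            lower = c(-5, -5), upper = c(5, 5),
                            n_starts = 4L, rng_seed = 1)
  expect_equal(res$par, c(1, -2), tolerance = 1e-4)
  # optimum outside the box lands on the bound
  res2 <- fminsearch_bounded(function(p) (p - 10)^2, lower = 0, upper = 2,
                             n_starts = 3L, rng_seed = 2)
  expect_equal(res2$par, 2, tolerance = 1e-4)
  # deterministic under the seed
  res3 <- fminsearch_bounded(function(p) sum((p - c(1, -2))^2),
                             lower = c(-5, -5), upper = c(5, 5),
                             n_starts = 4L, rng_seed = 1)
  expect_identical(res, res3)
})

test_that("AICc follows the corrected formula and its limits", {
  expect_equal(aicc(100, 4, 162), 208 + 40 / 157)
  # AICc -> AIC as n grows, and always exceeds AIC at finite n
  expect_equal(aicc(50, 3, 1e9), 2 * 50 + 2 * 3, tolerance = 1e-6)
  expect_gt(aicc(50, 3, 30), 2 * 50 + 2 * 3)
  expect_error(aicc(10, 5, 6), "n > k")
})

test_that("delta AICc is zero-referenced per subject and sums correctly", {
  fits <- data.frame(
    subject = rep(1:16, each = 2),
    model = rep(c("A", "B"), 16),
    aicc = rep(c(100, 102), 16)
  )
  da <- delta_aicc(fits)
  expect_equal(unname(da$summed), c(0, 32))
  expect_true(all(apply(da$delta, 1L, min) == 0))
  # invariant to per-subject constant shifts
  fits2 <- fits
  fits2$aicc <- fits2$aicc + rep(rnorm(16), each = 2)
  expect_equal(delta_aicc(fits2)$summed, da$summed)
  # single model: all zeros
  one <- delta_aicc(fits[fits$model == "A", ])
  expect_true(all(one$summed == 0))
  expect_error(delta_aicc(fits[-1, ]), "missing fits")
})

test_that("group BMS is symmetric under identical evidence", {
  lme <- matrix(0, 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  g <- group_bms(lme, rng_seed = 4)
  expect_equal(sum(g$ep), 1, tolerance = 1e-3)
  expect_equal(sum(g$pxp), 1, tolerance = 1e-3)
  expect_equal(unname(g$pxp), rep(1 / 3, 3), tolerance = 0.02)
  # with no information the omnibus risk should be high
  expect_gt(g$bor, 0.5)
})

test_that("a dominant model attains protected exceedance near 1", {
  lme <- matrix(0, 15, 2, dimnames = list(NULL, c("win", "lose")))
  lme[, 1] <- 10
  g <- group_bms(lme, rng_seed = 5)
  expect_gt(g$pxp[["win"]], 0.99)
  expect_equal(g$pxp[["win"]] ,
               (1 - g$bor) * g$ep[["win"]] + g$bor / 2, tolerance = 1e-12)
  expect_error(group_bms(matrix(0, 5, 1)), "two models")
})

test_that("grid search degenerates to a plain fit on a single point", {
  d <- build_design("E1", 4)
  stim <- sample_stimuli(d, 5)
  stim$positions <- stim$positions[1:25, , drop = FALSE]
  resp <- simulate_responses(stim, 0.5, response_params(0, 1, 2),
                             response_params(0, 1, 1.5), rng_seed = 6)
  cache <- ensemble_cache(stim, 0.5, R = 100, rng_seed = 7)
  f1 <- fit_cos_mode(resp$y_mode, cache, n_starts = 3, rng_seed = 8)
  expect_equal(f1$grid_value, 0.5)
  expect_equal(f1$k_params, 4L)
  f2 <- fit_cos_mode(resp$y_mode, cache, n_starts = 3, rng_seed = 8)
  expect_identical(f1, f2)
  # best-grid value minimises over any sub-grid by construction
  cache2 <- ensemble_cache(stim, c(0.1, 0.5), R = 100, rng_seed = 7)
  f3 <- fit_cos_mode(resp$y_mode, cache2, n_starts = 3, rng_seed = 8)
  expect_lte(f3$neg_loglik, f1$neg_loglik + 1e-6)
})

test_that("linear-generator data recover their coefficients", {
  # GT model on y = 2 + 1 * truth + N(0,1)
  st <- withr::with_seed(10, data.frame(
    trial = 1:120, true_mean = rnorm(120, 0, 4),
    true_skewness = rnorm(120), true_mode = rnorm(120, 0, 5)))
  y <- withr::with_seed(11, 2 + st$true_mode + rnorm(120))
  f <- fit_moment_model(y, "GT", st, "mode")
  ref <- summary(lm(y ~ st$true_mode))
  se <- ref$coefficients[, 2]
  expect_lt(abs(f$params[["beta0"]] - 2), 3 * se[1])
  expect_lt(abs(f$params[["beta_true_mode"]] - 1), 3 * se[2])
  expect_equal(f$k_params, 3L)
})
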