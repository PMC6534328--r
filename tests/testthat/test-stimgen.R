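test_that("designs enumerate the stated trial counts and compositions", {
  e1 <- build_design("E1", 1)
  expect_equal(nrow(e1$trials), 162L)
  expect_equal(sort(unique(e1$trials$weight_label)),
               sort(c("235", "325", "253", "352", "523", "532")))
  expect_true(all(table(e1$trials$shape) == 54L))

  e2 <- build_design("E2", 1)
  expect_equal(nrow(e2$trials), 144L)
  expect_equal(length(unique(e2$trials$weight_label)), 24L)
  expect_true(all(e2$trials$n_components == 4L))

  e3 <- build_design("E3", 7)
  expect_equal(nrow(e3$trials), 144L)
  expect_equal(sum(e3$trials$n_components == 3L), 72L)
  expect_equal(sum(e3$trials$n_components == 4L), 72L)
  blocks <- split(e3$trials, e3$trials$block)
  expect_length(blocks, 12L)
  sizes <- vapply(blocks, nrow, 0L)
  expect_true(all(sizes >= 10L & sizes <= 14L))
  # each mini-block holds one mixture type, alternating
  types <- vapply(blocks, function(b) unique(b$n_components), 0L)
  expect_true(all(abs(diff(types)) == 1L))

  expect_error(build_design("E9"), "unknown experiment")
})

test_that("condition invariants hold and bad weights are rejected", {
  cond <- bmx_condition("LocalSym", c(0.5, 0.2, 0.3))
  expect_equal(cond$alpha_beta, c(2.9, 2.9))
  expect_equal(sum(cond$weights), 1, tolerance = 1e-12)
  expect_error(bmx_condition("LocalNeg", c(0.4, 0.3, 0.3)), "permutation")
})

test_that("the three component shapes share variance, SD/width ~ 0.19", {
  beta_sd <- function(a, b) sqrt(a * b / ((a + b)^2 * (a + b + 1)))
  sds <- c(beta_sd(3.1, 1.1), beta_sd(2.9, 2.9), beta_sd(1.1, 3.1))
  expect_equal(round(sds, 2), rep(0.19, 3))
  expect_lt(diff(range(sds)) / mean(sds), 0.01)
})

test_that("sampled trials are scaled, bounded, and affine-safe", {
  d <- build_design("E1", 3)
  for (i in c(1L, 50L)) {
    tr <- sample_trial(d$conditions[[i]], d, rng_seed = 100 + i)
    expect_length(tr$positions, 70L)
    expect_equal(sd(tr$positions), 7.27, tolerance = 1e-9)
    expect_true(all(tr$positions >= -20 & tr$positions <= 20))
    expect_gte(mean(tr$positions), -3.8)
    expect_lte(mean(tr$positions), 3.8)
  }
  d2 <- build_design("E2", 3)
  tr2 <- sample_trial(d2$conditions[[1L]], d2, rng_seed = 9)
  expect_equal(sd(tr2$positions), 7.20, tolerance = 1e-9)

  # scaling + jitter is affine, so skewness of the raw mixture draw is
  # preserved exactly
  skew <- cosens:::sample_skewness
  x <- rbeta(70, 1.1, 3.1)
  expect_equal(skew(2 + 5 * x), skew(x), tolerance = 1e-12)
})

test_that("per-component sample counts equal 70 x phi exactly", {
  cond <- bmx_condition("LocalSym", c(0.2, 0.3, 0.5))
  expect_equal(70 * cond$weights, c(14, 21, 35))
  # stratified allocation: every trial of a condition carries exactly
  # round(70 * phi_i) samples per component
  d <- build_design("E1", 5)
  idx <- which(d$trials$weight_label == "235" &
               d$trials$shape == "LocalSym")[1:3]
  for (i in idx) {
    tr <- sample_trial(d$conditions[[i]], d, rng_seed = 300 + i)
    expect_equal(tabulate(tr$component, 3L), c(14L, 21L, 35L))
  }
  tr4 <- sample_trial(bmx_condition("LocalPos", c(0.4, 0.1, 0.2, 0.3)),
                      build_design("E2", 5), rng_seed = 77)
  expect_equal(tabulate(tr4$component, 4L), c(28L, 7L, 14L, 21L))
})

test_that("diffusion KDE normalises, respects symmetry, finds peaks", {
  x <- withr::with_seed(1, rnorm(20000))
  k <- diffusion_kde(x, range = c(-6, 6))
  expect_equal(sum(k$y) * diff(k$x[1:2]), 1, tolerance = 1e-3)
  expect_lt(abs(k$x[which.max(k$y)]), 0.1)
  # and it agrees with an independent fixed-bandwidth estimate's peak
  ref <- density(x, n = 2048)
  expect_lt(abs(k$x[which.max(k$y)] - ref$x[which.max(ref$y)]), 0.1)

  # mirror-symmetric input snapped to mesh points -> symmetric density
  h <- 8 / 1023
  snap <- function(v) -4 + round((v + 4) / h) * h
  xs <- snap(c(-3, -1.5, -0.5, 0.5, 1.5, 3))
  xs <- sort(unique(c(xs, -xs)))
  ks <- diffusion_kde(xs, range = c(-4, 4), n = 1024L)
  expect_equal(ks$y, rev(ks$y), tolerance = 1e-6)

  expect_error(diffusion_kde(rep(1, 5)), "degenerate")
  expect_error(diffusion_kde(1), "at least 2")
})

test_that("true_stats computes mean, skewness and KDE mode", {
  stim <- tiny_stimuli(rbind(
    c(0, 1, 2, rep(1, 67)),                             # mean 1
    c(seq(-3, 3, length.out = 70)),                     # symmetric
    c(rnorm(60, -5, 1), rnorm(10, 5, 1))                # bimodal at -5
  ))
  st <- true_stats(stim)
  expect_equal(st$true_mean[1], mean(stim$positions[1, ]))
  expect_lt(abs(st$true_skewness[2]), 1e-12)
  expect_lt(abs(st$true_mode[3] - (-5)), 0.5)
})
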