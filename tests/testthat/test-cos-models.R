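# helper: minimal ensemble with given draws (centroid/weight matrices)
fake_ensemble <- function(centroids, weights, cstar = NULL,
                          posterior = NULL) {
  R <- nrow(centroids)
  K <- rowSums(!is.na(centroids))
  structure(list(K = K, sizes = NULL, centroids = centroids,
                 weights = weights, cstar = cstar, gamma = NA_real_,
                 R = R, n = NA_integer_, rng_seed = NA_integer_,
                 posterior_weights = posterior),
            class = "cos_ensemble")
}

test_that("mode read-out picks the heaviest cluster, ties uniformly", {
  expect_equal(mode_point(toy_rep(3.2, 4L)), 3.2)
  expect_equal(mode_point(toy_rep(c(-5, 0, 5), c(14L, 21L, 35L))), 5)
  tie <- toy_rep(c(-1, 1), c(5L, 5L))
  picks <- withr::with_seed(8, replicate(2e4, mode_point(tie)))
  expect_equal(mean(picks == 1), 0.5, tolerance = 0.02)
})

test_that("Mode likelihood is the Monte-Carlo Gaussian mixture", {
  pars <- response_params(0, 1, 1)
  e1 <- fake_ensemble(matrix(2), matrix(1), cstar = 2)
  expect_equal(mode_loglik(1.2, e1, pars), dnorm(1.2, 2, 1, log = TRUE))
  # all draws equal collapses to the single-draw case
  e3 <- fake_ensemble(matrix(2, 3, 1), matrix(1, 3, 1), cstar = rep(2, 3))
  expect_equal(mode_loglik(1.2, e3, pars), dnorm(1.2, 2, 1, log = TRUE))
  # symmetric two-draw mixture at y = 1: log phi(1)
  e2 <- fake_ensemble(matrix(c(0, 2), 2, 1), matrix(1, 2, 1),
                      cstar = c(0, 2))
  expect_equal(mode_loglik(1, e2, pars), dnorm(1, log = TRUE))
  expect_error(response_params(0, 1, 0), "positive")
})

test_that("clustering posterior normalises and concentrates as noise -> 0", {
  cs <- c(-3, 0, 4)
  ens <- fake_ensemble(matrix(cs, 3, 1), matrix(1, 3, 1), cstar = cs)
  u <- set_posterior(2, ens, sigma_mode = 100)
  expect_equal(sum(u$posterior_weights), 1, tolerance = 1e-12)
  expect_equal(u$posterior_weights, rep(1 / 3, 3), tolerance = 1e-3)
  sharp <- set_posterior(3.8, ens, sigma_mode = 1e-3)
  expect_equal(sharp$posterior_weights[3], 1, tolerance = 1e-12)
  same <- set_posterior(1, fake_ensemble(matrix(2, 4, 1),
                                         matrix(1, 4, 1),
                                         cstar = rep(2, 4)), 1)
  expect_equal(same$posterior_weights, rep(0.25, 4))
})

test_that("subjective weights reduce to raw weights in the limits", {
  rep3 <- toy_rep(c(-5, 0, 5), c(14L, 21L, 35L))
  # alpha = 1 and sigma_LI -> infinity: denominator = sum(w) = 1
  expect_equal(subjective_weights(rep3, 1, 1e9), rep3$weights,
               tolerance = 1e-9)
  # both transforms lesioned: theta = w exactly
  off <- cos_lesions(use_power = FALSE, use_li = FALSE)
  expect_equal(subjective_weights(rep3, 0.3, 0.5, off), rep3$weights)
  # symmetric two-cluster case stays symmetric under LI
  rep2 <- toy_rep(c(-1, 1), c(10L, 10L))
  expect_equal(subjective_weights(rep2, 1, 1), c(0.5, 0.5))
})

test_that("Mean read-out matches hand-evaluated transforms", {
  rep3 <- toy_rep(c(-5, 0, 5), c(14L, 21L, 35L))
  # power alpha = 0.5, no lateral inhibition: hand evaluation
  th <- rep3$weights^0.5 / sum(rep3$weights^0.5)
  no_li <- cos_lesions(use_power = TRUE, use_li = FALSE)
  expect_equal(mean_point(rep3, 0.5, Inf, no_li), sum(th * rep3$centroids))
  # single cluster -> its centroid whatever the parameters
  expect_equal(mean_point(toy_rep(2.4, 7L), 0.3, 0.7), 2.4)
})

test_that("clustering conserves the sample mean exactly", {
  # Sum_k c_k w_k = sample mean for any partition at machine precision
  for (s in 1:25) {
    x <- withr::with_seed(s, runif(70, -15, 15))
    gam <- withr::with_seed(100 + s, runif(1, 0.02, 2))
    rep_s <- sample_partition(x, gam, rng_seed = s)$representation
    expect_equal(sum(rep_s$centroids * rep_s$weights), mean(x),
                 tolerance = 1e-13)
    # hence the lesioned (theta = w) Mean read-out is the sample mean
    off <- cos_lesions(FALSE, FALSE)
    expect_equal(mean_point(rep_s, 1, Inf, off), mean(x),
                 tolerance = 1e-12)
  }
})

test_that("ensemble mean points agree with the per-representation path", {
  x <- withr::with_seed(11, runif(70, -12, 12))
  ens <- build_ensemble(x, 0.4, R = 20, rng_seed = 2)
  les <- cos_lesions()
  vec <- cosens:::ensemble_mean_points(ens, 0.6, 3, les)
  # the compiled fast path used inside the likelihood agrees with the
  # reference vectorised path
  fast <- cosens:::cpp_mean_points(ens$centroids, ens$weights, 0.6, 3,
                                   TRUE, TRUE)
  expect_equal(fast, vec, tolerance = 1e-12)
  for (r in c(1L, 7L, 20L)) {
    k <- ens$K[r]
    rep_r <- toy_rep(ens$centroids[r, seq_len(k)],
                     as.integer(ens$sizes[r, seq_len(k)]))
    expect_equal(vec[r], mean_point(rep_r, 0.6, 3, les),
                 tolerance = 1e-12)
  }
})

test_that("Mean likelihood mixes draws by their posterior", {
  cmat <- matrix(c(-2, NA, 1, 3), 2, 2, byrow = TRUE)
  wmat <- matrix(c(1, 0, 0.5, 0.5), 2, 2, byrow = TRUE)
  pars <- response_params(0, 1, 1)
  ens <- fake_ensemble(cmat, wmat, posterior = c(0.75, 0.25))
  # theta = w lesion makes M* = (-2, 2); evaluate the 2-term mixture
  off <- cos_lesions(FALSE, FALSE)
  ll <- mean_loglik(0.5, ens, 1, Inf, pars, off)
  by_hand <- log(0.75 * dnorm(0.5, -2, 1) + 0.25 * dnorm(0.5, 2, 1))
  expect_equal(ll, by_hand, tolerance = 1e-12)
  # degenerate posterior: single Gaussian
  ens2 <- fake_ensemble(cmat, wmat, posterior = c(1, 0))
  expect_equal(mean_loglik(0.5, ens2, 1, Inf, pars, off),
               dnorm(0.5, -2, 1, log = TRUE), tolerance = 1e-12)
  # missing posterior without the prior lesion is an error
  ens3 <- fake_ensemble(cmat, wmat)
  expect_error(mean_loglik(0.5, ens3, 1, Inf, pars), "posterior")
  # uniform mixture under the no-prior lesion
  nop <- cos_lesions(FALSE, FALSE, use_mode_prior = FALSE)
  expect_equal(mean_loglik(0.5, ens3, 1, Inf, pars, nop),
               log(mean(dnorm(0.5, c(-2, 2), 1))), tolerance = 1e-12)
})

test_that("subjective weighting without clustering behaves as expected", {
  # two samples: symmetric weights, midpoint estimate
  sw <- sw_mean_point(c(-1, 3), 2)
  expect_equal(sw$theta, c(0.5, 0.5))
  expect_equal(sw$mstar, 1)
  # sigma_LI -> 0: only the self term survives, estimate -> sample mean
  x <- c(0, 1, 10)
  expect_equal(sw_mean_point(x, 1e-4)$mstar, mean(x), tolerance = 1e-9)
  # positively skewed triple: dense pair down-weighted, estimate > mean
  expect_gt(sw_mean_point(x, 2)$mstar, mean(x))
  # likelihood is the single Gaussian at the transformed estimate
  pars <- response_params(0.5, 1.1, 2)
  m <- sw_mean_point(x, 2)$mstar
  expect_equal(sw_mean_loglik(4, x, 2, pars),
               dnorm(4, 0.5 + 1.1 * m, 2, log = TRUE))
})

test_that("response simulation is seeded and exact in the noise-free limit", {
  d <- build_design("E1", 2)
  stim <- sample_stimuli(d, 3)
  stim$positions <- stim$positions[1:6, , drop = FALSE]
  r1 <- simulate_responses(stim, 0.5, response_params(0, 1, 2),
                           response_params(0, 1, 1.5), alpha = 0.7,
                           sigma_li = 4, rng_seed = 31)
  r2 <- simulate_responses(stim, 0.5, response_params(0, 1, 2),
                           response_params(0, 1, 1.5), alpha = 0.7,
                           sigma_li = 4, rng_seed = 31)
  expect_identical(r1, r2)
  # two-sample trials force a single cluster; with a noiseless identity
  # response both estimates equal the sample mean
  stim2 <- tiny_stimuli(matrix(c(-3, 5, 0, 2, -7, -1), 3, 2,
                               byrow = TRUE))
  r0 <- simulate_responses(stim2, 0.5, response_params(0, 1, 1e-12),
                           response_params(0, 1, 1e-12), rng_seed = 5)
  expect_equal(r0$y_mode, rowMeans(stim2$positions), tolerance = 1e-6)
  expect_equal(r0$y_mean, rowMeans(stim2$positions), tolerance = 1e-6)
})
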