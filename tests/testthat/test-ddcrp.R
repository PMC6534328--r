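test_that("join probabilities are row-stochastic and distance-ordered", {
  p <- join_probabilities(c(0, 1, 2), 1)
  expect_equal(p[2, ], c(0.5, 0, 0.5))  # middle sample equidistant
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-12)
  expect_equal(diag(p), rep(0, 3))

  # direct evaluation of the exponential decay: log-ratio = (d2^2-d1^2)/g
  p2 <- join_probabilities(c(0, 1, 10), 1)
  expect_equal(log(p2[1, 2]) - log(p2[1, 3]), 99, tolerance = 1e-9)

  expect_error(join_probabilities(5, 1), "at least 2")
  expect_error(join_probabilities(c(0, 1), 0), "positive")
})

test_that("gamma limits: uniform joining and nearest-neighbour joining", {
  x <- c(-8, -2, 0.5, 7)
  p_inf <- join_probabilities(x, 1e12)
  off <- p_inf[row(p_inf) != col(p_inf)]
  expect_true(all(abs(off - 1 / 3) < 1e-6))

  p0 <- join_probabilities(x, 1e-3)
  nn <- apply(p0, 1L, which.max)
  d <- abs(outer(x, x, "-")); diag(d) <- Inf
  expect_equal(nn, apply(d, 1L, which.min))
  expect_true(all(p0[cbind(seq_along(x), nn)] > 1 - 1e-10))
})

test_that("sampled partitions have no singletons and honour n = 2", {
  for (s in 1:20) {
    out <- sample_partition(c(0, 3), 0.5, rng_seed = s)
    expect_equal(out$representation$K, 1L)
    expect_equal(out$representation$weights, 1)
    expect_equal(out$representation$centroids, 1.5)
  }
  out <- sample_partition(runif(30, -10, 10), 0.3, rng_seed = 4)
  expect_true(all(out$representation$sizes >= 2L))
  expect_equal(sum(out$representation$weights), 1, tolerance = 1e-12)
})

test_that("exact enumeration: n = 2 and n = 3 degenerate correctly", {
  en2 <- enumerate_partitions(c(0, 1), 5)
  expect_equal(en2$prob, 1)
  # any join graph on 3 nodes with no self-joins is connected
  en3 <- enumerate_partitions(c(0, 2, 5), 1)
  expect_equal(sum(en3$prob), 1, tolerance = 1e-10)
  expect_equal(en3$prob[en3$key == "1.1.1"], 1, tolerance = 1e-12)
  expect_error(enumerate_partitions(1:9, 1), "n must be <= 8")
})

test_that("Monte-Carlo partition distribution matches the exact oracle", {
  x <- c(0, 1, 2, 3)
  en <- enumerate_partitions(x, 1)
  expect_equal(sum(en$prob), 1, tolerance = 1e-10)
  mc <- mc_partition_probs(x, 1, n_draws = 2e5, seed = 21)
  all_keys <- union(en$key, names(mc))
  pe <- setNames(rep(0, length(all_keys)), all_keys)
  pm <- pe
  pe[en$key] <- en$prob
  pm[names(mc)] <- mc
  expect_lt(0.5 * sum(abs(pe - pm)), 0.01)
})

test_that("permutation equivariance of the induced partition law", {
  x <- c(0, 0.7, 2.5, 3.1, 5)
  perm <- c(3, 1, 5, 2, 4)
  en1 <- enumerate_partitions(x, 0.8)
  en2 <- enumerate_partitions(x[perm], 0.8)
  # compare distributions over size multisets (label-free view)
  sizes_of <- function(en) {
    key <- vapply(seq_len(nrow(en$labels)), function(i) {
      paste(sort(tabulate(en$labels[i, ])), collapse = "-")
    }, "")
    tapply(en$prob, key, sum)
  }
  s1 <- sizes_of(en1); s2 <- sizes_of(en2)
  expect_equal(names(s1), names(s2))
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-10)
})

test_that("well-separated pairs cluster together almost surely", {
  x <- c(0, 0.1, 100, 100.1)
  en <- enumerate_partitions(x, 0.01)
  two_pairs <- en$key == "1.1.2.2"
  expect_gt(en$prob[two_pairs], 0.999)
})

test_that("ensembles are seed-reproducible and R = 1 is a single draw", {
  x <- withr::with_seed(3, runif(40, -10, 10))
  e1 <- build_ensemble(x, 0.5, R = 100, rng_seed = 7)
  e2 <- build_ensemble(x, 0.5, R = 100, rng_seed = 7)
  expect_identical(e1, e2)
  e3 <- build_ensemble(x, 0.5, R = 1, rng_seed = 9)
  expect_equal(e3$R, 1L)
  expect_equal(sum(e3$weights[1, seq_len(e3$K[1])]), 1, tolerance = 1e-12)
  # every cluster in every draw has >= 2 members
  s <- e1$sizes
  expect_true(all(s[s > 0] >= 2L))
})

test_that("cluster-size histogram normalises and reflects the draws", {
  # all draws identical: two clusters of 2 out of n = 4
  x <- c(0, 0.1, 100, 100.1)
  ens <- build_ensemble(x, 0.001, R = 50, rng_seed = 1)
  h <- cluster_size_histogram(list(ens))
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_equal(unname(h[2]), 1)
})
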