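# shared small fixtures, built in code

# a tiny pseudo-stimulus object wrapping arbitrary position rows, so model
# fitters can be exercised without a full design
tiny_stimuli <- function(positions, position_range = c(-20, 20)) {
  design <- structure(
    list(experiment = "toy",
         trials = data.frame(trial = seq_len(nrow(positions))),
         conditions = list(), target_sd = NA_real_,
         position_range = position_range,
         mean_range = c(-3.8, 3.8), rng_seed = NA_integer_),
    class = "bmx_design")
  structure(list(design = design, positions = positions,
                 seeds = rep(NA_integer_, nrow(positions)),
                 rng_seed = NA_integer_),
            class = "bmx_stimuli")
}

# hand-built CoS representation
toy_rep <- function(centroids, sizes) {
  structure(list(centroids = centroids,
                 weights = sizes / sum(sizes),
                 sizes = sizes, K = length(sizes)),
            class = "cos_representation")
}

# empirical partition distribution from Monte-Carlo join draws, keyed the
# same way as enumerate_partitions()
mc_partition_probs <- function(positions, gamma, n_draws, seed) {
  p <- join_probabilities(positions, gamma)
  n <- length(positions)
  withr::with_seed(seed, {
    joins <- matrix(0L, n, n_draws)
    for (i in seq_len(n)) {
      joins[i, ] <- sample.int(n, n_draws, replace = TRUE, prob = p[i, ])
    }
  })
  labels <- cosens:::cpp_components(joins)
  key <- apply(labels, 2L, paste, collapse = ".")
  tab <- table(key) / n_draws
  setNames(as.numeric(tab), names(tab))
}
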