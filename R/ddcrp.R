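#' Pairwise join probabilities of the ddCRP
#'
#' Under the distance-dependent Chinese Restaurant Process used here, each
#' sample j joins exactly one other sample l (never itself, so no sample
#' stays alone) with probability proportional to
#' \eqn{\exp(-d_{jl}^2 / \gamma)}, where \eqn{d_{jl}} is the absolute
#' positional difference and \eqn{\gamma} (cm^2) sets how fast affinity
#' decays with distance. Rows are normalised with a max-subtracted exponent
#' so small \eqn{\gamma} cannot underflow.
#'
#' @param positions numeric vector (>= 2 values)
#' @param gamma positive distance scale (cm^2)
#' @return an n x n row-stochastic matrix with a zero diagonal
#' @examples
#' join_probabilities(c(0, 1, 10), gamma = 1)
#' @export
join_probabilities <- function(positions, gamma) {
  n <- length(positions)
  if (n < 2L) stop("clustering impossible: need at least 2 samples",
                   call. = FALSE)
  if (!is.numeric(gamma) || gamma <= 0) {
    stop("gamma must be a positive real", call. = FALSE)
  }
  d2 <- outer(positions, positions, "-")^2
  logp <- -d2 / gamma
  diag(logp) <- -Inf
  mx <- apply(logp, 1L, max)
  p <- exp(logp - mx)
  p / rowSums(p)
}

# canonical first-appearance relabelling of an assignment vector
canonical_labels <- function(z) {
  match(z, unique(z))
}

#' Cluster summary of a partition
#'
#' Reduces a clustering of positions to the Clusters-of-Samples
#' representation: centroids c_k (member means), relative weights
#' w_k = size_k / n, sizes, and the number of clusters K.
#'
#' @param assignment integer cluster labels, one per sample
#' @param positions numeric sample positions
#' @return list of class \code{"cos_representation"}
#' @export
cos_representation <- function(assignment, positions) {
  z <- canonical_labels(assignment)
  sizes <- tabulate(z)
  centroids <- as.numeric(rowsum(positions, z) / sizes)
  structure(
    list(centroids = centroids, weights = sizes / length(z),
         sizes = sizes, K = length(sizes)),
    class = "cos_representation"
  )
}

#' Draw one ddCRP partition
#'
#' Each sample independently draws a join target from its row of
#' \code{\link{join_probabilities}}; clusters are the connected components
#' of the resulting join graph. Because no sample may join itself, every
#' cluster has at least two members.
#'
#' @inheritParams join_probabilities
#' @param rng_seed optional integer seed; if \code{NULL} the current RNG
#'   stream is used
#' @return list with \code{partition} (fields \code{assignment},
#'   \code{join_target}) and \code{representation}
#'   (a \code{\link{cos_representation}})
#' @export
sample_partition <- function(positions, gamma, rng_seed = NULL) {
  p <- join_probabilities(positions, gamma)
  n <- length(positions)
  draw <- function() {
    vapply(seq_len(n),
           function(i) sample.int(n, 1L, prob = p[i, ]), 0L)
  }
  joins <- if (is.null(rng_seed)) draw() else
    withr::with_seed(rng_seed, draw())
  labels <- as.integer(cpp_components(matrix(joins, ncol = 1L)))
  list(
    partition = list(assignment = labels, join_target = joins),
    representation = cos_representation(labels, positions)
  )
}

#' Exact ddCRP partition distribution (small-n oracle)
#'
#' Enumerates all \eqn{(n-1)^n} join vectors, accumulating the product of
#' join probabilities for each induced set partition. Exponential in n;
#' intended as an exact reference for validating the Monte-Carlo sampler on
#' tiny problems (n <= 8).
#'
#' @inheritParams join_probabilities
#' @return list with \code{labels} (a matrix, one canonical partition per
#'   row), \code{prob} (their probabilities, summing to 1), and
#'   \code{key} (a compact per-partition string id)
#' @export
enumerate_partitions <- function(positions, gamma) {
  n <- length(positions)
  if (n > 8L) stop("oracle size limit: n must be <= 8", call. = FALSE)
  p <- join_probabilities(positions, gamma)
  choices <- lapply(seq_len(n), function(i) seq_len(n)[-i])
  joins <- as.matrix(expand.grid(choices, KEEP.OUT.ATTRS = FALSE))
  m <- nrow(joins)
  prob <- rep(1, m)
  for (i in seq_len(n)) prob <- prob * p[i, joins[, i]]
  labels <- cpp_components(t(joins))          # n x m canonical labels
  key <- apply(labels, 2L, paste, collapse = ".")
  agg <- rowsum(prob, key)
  keys <- rownames(agg)
  first <- match(keys, key)
  list(labels = t(labels[, first, drop = FALSE]),
       prob = as.numeric(agg), key = keys)
}

#' Monte-Carlo ensemble of CoS representations
#'
#' Runs the ddCRP clustering R times for one trial and a given gamma, and
#' stores the per-draw cluster summaries in padded matrix form, together
#' with the per-draw mode read-out C* (centroid of the heaviest cluster,
#' exact weight ties broken uniformly at random). The ensemble is the
#' Monte-Carlo approximation of the distribution over CoS representations
#' that a stochastic clusterer induces for a single stimulus.
#'
#' @inheritParams join_probabilities
#' @param R number of Monte-Carlo clusterings (1000 in the reference
#'   analyses)
#' @param rng_seed integer seed; identical seeds reproduce the ensemble
#'   bit for bit
#' @return list of class \code{"cos_ensemble"}: \code{K} (per-draw cluster
#'   counts), \code{sizes} and \code{centroids} (R x Kmax padded matrices),
#'   \code{weights}, \code{cstar}, \code{gamma}, \code{R}, \code{n},
#'   \code{rng_seed}, and \code{posterior_weights} (NULL until set by
#'   \code{\link{set_posterior}})
#' @export
build_ensemble <- function(positions, gamma, R = 1000L, rng_seed = 1L) {
  stopifnot(R >= 1L)
  n <- length(positions)
  p <- join_probabilities(positions, gamma)
  withr::with_seed(rng_seed, {
    joins <- matrix(0L, n, R)
    for (i in seq_len(n)) {
      joins[i, ] <- sample.int(n, R, replace = TRUE, prob = p[i, ])
    }
    labels <- cpp_components(joins)
    st <- cpp_cluster_stats(labels, positions)
    sizes <- st$sizes
    # heaviest cluster per draw; ties.method = "random" draws from the
    # same seeded stream, giving each tied cluster equal probability
    pick <- max.col(sizes, ties.method = "random")
  })
  cstar <- st$centroids[cbind(seq_len(R), pick)]
  structure(
    list(K = st$K, sizes = sizes, centroids = st$centroids,
         weights = sizes / n, cstar = cstar, gamma = gamma, R = R,
         n = n, rng_seed = rng_seed, posterior_weights = NULL),
    class = "cos_ensemble"
  )
}

#' Cluster-size frequency histogram
#'
#' Relative frequency of each cluster size (1..n samples per cluster),
#' averaged first across the Monte-Carlo clusterings of each trial
#' (optionally weighted by their posterior probabilities) and then across
#' trials. In multimodal designs the histogram peaks at the component
#' sample counts (e.g. 14/21/35 for weights 0.2/0.3/0.5 of 70 samples),
#' showing that the clustering partly recovers the mixture structure.
#'
#' @param ensembles list of \code{\link{build_ensemble}} objects
#' @param use_posterior if TRUE, weight each draw by the ensemble's
#'   \code{posterior_weights}
#' @return named numeric vector of relative frequencies over sizes 1..n,
#'   summing to 1
#' @export
cluster_size_histogram <- function(ensembles, use_posterior = FALSE) {
  stopifnot(length(ensembles) >= 1L)
  n <- ensembles[[1L]]$n
  acc <- numeric(n)
  for (ens in ensembles) {
    w_rep <- if (use_posterior && !is.null(ens$posterior_weights)) {
      ens$posterior_weights
    } else {
      rep(1 / ens$R, ens$R)
    }
    freq <- numeric(n)
    for (r in seq_len(ens$R)) {
      s <- ens$sizes[r, seq_len(ens$K[r])]
      tab <- tabulate(s, nbins = n) / ens$K[r]
      freq <- freq + w_rep[r] * tab
    }
    acc <- acc + freq / sum(freq)
  }
  out <- acc / length(ensembles)
  names(out) <- seq_len(n)
  out
}
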