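#' Beta-mixture stimulus conditions
#'
#' A trial's underlying distribution is a mixture of 3 or 4 beta-shaped
#' components of equal width whose supports adjoin end to end. The shape
#' parameters (alpha, beta) are shared by all components of a trial and set
#' its "local" skewness; the mixture weights (ordered left to right) set the
#' "global" skewness. Shapes are one of (3.1, 1.1) (negatively skewed,
#' \code{"LocalNeg"}), (2.9, 2.9) (symmetric, \code{"LocalSym"}) or
#' (1.1, 3.1) (positively skewed, \code{"LocalPos"}); all three have equal
#' component variance (SD about 0.19 of the component width). Weights are a
#' permutation of (0.2, 0.3, 0.5) for 3-component mixtures or of
#' (0.1, 0.2, 0.3, 0.4) for 4-component mixtures.
#'
#' @param shape one of "LocalNeg", "LocalSym", "LocalPos"
#' @param weights numeric vector of mixture weights, left to right
#' @return a list of class \code{"bmx_condition"} with elements
#'   \code{n_components}, \code{shape}, \code{alpha_beta} and \code{weights}
#' @examples
#' cond <- bmx_condition("LocalNeg", c(0.2, 0.3, 0.5))
#' cond$alpha_beta
#' @export
bmx_condition <- function(shape, weights) {
  shape <- match.arg(shape, c("LocalNeg", "LocalSym", "LocalPos"))
  weights <- as.numeric(weights)
  m <- length(weights)
  if (!m %in% c(3L, 4L)) {
    stop("weights must have 3 or 4 components", call. = FALSE)
  }
  base <- if (m == 3L) c(0.2, 0.3, 0.5) else c(0.1, 0.2, 0.3, 0.4)
  if (!isTRUE(all.equal(sort(weights), base, tolerance = 1e-12))) {
    stop("weights must be a permutation of (",
         paste(base, collapse = ", "), ")", call. = FALSE)
  }
  if (abs(sum(weights) - 1) > 1e-12) {
    stop("weights must sum to 1", call. = FALSE)
  }
  ab <- switch(shape,
    LocalNeg = c(3.1, 1.1),
    LocalSym = c(2.9, 2.9),
    LocalPos = c(1.1, 3.1)
  )
  structure(
    list(n_components = m, shape = shape, alpha_beta = ab,
         weights = weights),
    class = "bmx_condition"
  )
}

# compact label for a weight permutation, e.g. c(.2,.3,.5) -> "235"
weight_label <- function(weights) {
  paste(round(weights * 10), collapse = "")
}

# all permutations of a short vector, in lexicographic index order
all_permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Enumerate an experiment design
#'
#' Builds the full, randomised trial list for one of the four experiment
#' designs: \code{"E1"} (3-beta mixtures, 3 shapes x 6 weight permutations x
#' 9 repetitions = 162 trials), \code{"E2"} (4-beta, 3 x 24 x 2 = 144
#' trials), \code{"E3"} (72 3-beta trials, 3 x 6 x 4, and 72 4-beta trials,
#' 3 x 24 x 1, interleaved in 12 mini-blocks of 10--14 trials alternating
#' between mixture types) and \code{"S1"} (the E1 design on an orientation
#' scale in degrees). Samples are expressed in cm on screen within
#' [-20, 20] with the per-trial sample mean confined to [-3.8, 3.8]; the
#' target sample SD is 7.27, 7.20 and 7.55 cm for E1/S1, E2 and E3.
#'
#' @param experiment_id one of "E1", "E2", "E3", "S1"
#' @param rng_seed integer seed controlling trial-order randomisation and,
#'   for E3, mini-block sizes
#' @return a list of class \code{"bmx_design"}: a \code{trials} data frame
#'   (trial, n_components, shape, weight_label, block), the per-trial
#'   \code{conditions} list, and the scalars \code{target_sd},
#'   \code{position_range}, \code{mean_range}
#' @examples
#' d <- build_design("E1", rng_seed = 1)
#' nrow(d$trials)  # 162
#' @export
build_design <- function(experiment_id, rng_seed = 1L) {
  if (!is.character(experiment_id) ||
      !experiment_id %in% c("E1", "E2", "E3", "S1")) {
    stop("unknown experiment_id; must be one of E1, E2, E3, S1",
         call. = FALSE)
  }
  shapes <- c("LocalNeg", "LocalSym", "LocalPos")
  w3 <- all_permutations(c(0.2, 0.3, 0.5))
  w4 <- all_permutations(c(0.1, 0.2, 0.3, 0.4))

  grid_conditions <- function(wlist, reps) {
    conds <- list()
    for (s in shapes) {
      for (w in wlist) {
        for (r in seq_len(reps)) {
          conds[[length(conds) + 1L]] <- bmx_condition(s, w)
        }
      }
    }
    conds
  }

  target_sd <- switch(experiment_id,
                      E1 = 7.27, S1 = 7.27, E2 = 7.20, E3 = 7.55)
  if (experiment_id == "S1") {
    position_range <- c(0, 180)
    mean_range <- 90 + c(-3.8, 3.8)
  } else {
    position_range <- c(-20, 20)
    mean_range <- c(-3.8, 3.8)
  }

  withr::with_seed(rng_seed, {
    if (experiment_id %in% c("E1", "S1")) {
      conds <- grid_conditions(w3, 9L)
      ord <- sample(length(conds))
      conds <- conds[ord]
      block <- rep(NA_integer_, length(conds))
    } else if (experiment_id == "E2") {
      conds <- grid_conditions(w4, 2L)
      ord <- sample(length(conds))
      conds <- conds[ord]
      block <- rep(NA_integer_, length(conds))
    } else { # E3: 12 alternating mini-blocks, 72 trials of each type
      c3 <- grid_conditions(w3, 4L)
      c4 <- grid_conditions(w4, 1L)
      c3 <- c3[sample(length(c3))]
      c4 <- c4[sample(length(c4))]
      sizes3 <- miniblock_sizes(72L, 6L)
      sizes4 <- miniblock_sizes(72L, 6L)
      start3 <- sample(c(TRUE, FALSE), 1L)
      conds <- list(); block <- integer(0)
      i3 <- 0L; i4 <- 0L
      for (b in seq_len(12L)) {
        is3 <- xor(start3, b %% 2L == 0L)
        if (is3) {
          k <- sizes3[(b + 1L) %/% 2L]
          take <- c3[i3 + seq_len(k)]; i3 <- i3 + k
        } else {
          k <- sizes4[(b + 1L) %/% 2L]
          take <- c4[i4 + seq_len(k)]; i4 <- i4 + k
        }
        conds <- c(conds, take)
        block <- c(block, rep(b, k))
      }
    }
  })

  trials <- data.frame(
    trial = seq_along(conds),
    n_components = vapply(conds, function(cc) cc$n_components, 0L),
    shape = vapply(conds, function(cc) cc$shape, ""),
    weight_label = vapply(conds, function(cc) weight_label(cc$weights), ""),
    block = block,
    stringsAsFactors = FALSE
  )
  structure(
    list(experiment = experiment_id, trials = trials, conditions = conds,
         target_sd = target_sd, position_range = position_range,
         mean_range = mean_range, rng_seed = rng_seed),
    class = "bmx_design"
  )
}

# random sizes in 10..14 for n_blocks mini-blocks summing to `total`
miniblock_sizes <- function(total, n_blocks) {
  repeat {
    s <- sample(10:14, n_blocks, replace = TRUE)
    excess <- sum(s) - total
    if (excess == 0L) return(s)
    # nudge towards the target instead of rejection-sampling forever
    while (excess != 0L) {
      i <- sample(n_blocks, 1L)
      step <- sign(excess)
      if (s[i] - step >= 10L && s[i] - step <= 14L) {
        s[i] <- s[i] - step
        excess <- excess - step
      }
    }
    return(s)
  }
}

#' Draw one trial's 70 samples from its beta mixture
#'
#' The mixture components occupy contiguous unit-width intervals
#' [0,1], [1,2], ... before scaling; a sample picks component i with
#' probability \eqn{\phi_i} and falls at the interval start plus a
#' Beta(alpha, beta) draw. The 70 draws are then linearly rescaled so the
#' sample SD equals the design's target SD exactly, and shifted by a jitter
#' drawn uniformly over the largest interval that keeps the sample mean in
#' the design's mean range and every sample within the position range.
#'
#' @param condition a \code{\link{bmx_condition}}
#' @param design the \code{\link{build_design}} the trial belongs to
#' @param rng_seed integer seed
#' @param n_samples number of samples per trial (70 in all designs)
#' @return list of class \code{"bmx_trial"}: \code{condition},
#'   \code{positions} (length-\code{n_samples} numeric), \code{component}
#'   (which mixture component generated each sample), \code{rng_seed}
#' @export
sample_trial <- function(condition, design, rng_seed, n_samples = 70L) {
  stopifnot(inherits(condition, "bmx_condition"),
            inherits(design, "bmx_design"))
  ab <- condition$alpha_beta
  w <- condition$weights
  pr <- design$position_range
  mr <- design$mean_range
  # exact per-component allocation: component i contributes
  # round(n * phi_i) samples, so cluster-level structure (e.g. 14/21/35
  # samples per bump at n = 70) is identical on every trial
  counts <- round(n_samples * w)
  counts[which.max(counts)] <- n_samples - sum(counts[-which.max(counts)])
  positions <- withr::with_seed(rng_seed, {
    for (attempt in seq_len(100L)) {
      comp <- sample(rep.int(seq_along(w), counts))
      x <- (comp - 1L) + rbeta(n_samples, ab[1], ab[2])
      x <- (x - mean(x)) * (design$target_sd / sd(x))
      # feasible jitter interval for the (currently zero) sample mean
      lo <- max(mr[1], pr[1] - min(x))
      hi <- min(mr[2], pr[2] - max(x))
      if (lo <= hi) {
        x <- x + runif(1L, lo, hi)
        break
      }
      x <- NULL
    }
    if (is.null(x)) stop("degenerate draw: no feasible jitter after 100 ",
                         "attempts", call. = FALSE)
    list(x = x, comp = comp)
  })
  structure(list(condition = condition, positions = positions$x,
                 component = positions$comp, rng_seed = rng_seed),
            class = "bmx_trial")
}

#' Generate the full sample set for a design
#'
#' Draws every trial of a design with per-trial child seeds derived from one
#' master seed. The same sample set is intended to be reused across
#' simulated subjects (only trial order and responses differ by subject),
#' mirroring how such experiments share stimuli across observers.
#'
#' @param design a \code{\link{build_design}}
#' @param rng_seed master integer seed
#' @param n_samples samples per trial
#' @return list of class \code{"bmx_stimuli"}: the \code{design}, a
#'   \code{positions} matrix (trials x samples) and the trial seeds
#' @examples
#' d <- build_design("E1", 1)
#' stim <- sample_stimuli(d, rng_seed = 2)
#' dim(stim$positions)
#' @export
sample_stimuli <- function(design, rng_seed = 1L, n_samples = 70L) {
  n_trials <- nrow(design$trials)
  seeds <- vapply(seq_len(n_trials),
                  function(i) seed_child(rng_seed, 11L, i), 0L)
  positions <- matrix(NA_real_, n_trials, n_samples)
  for (i in seq_len(n_trials)) {
    tr <- sample_trial(design$conditions[[i]], design, seeds[i], n_samples)
    positions[i, ] <- tr$positions
  }
  structure(list(design = design, positions = positions, seeds = seeds,
                 rng_seed = rng_seed),
            class = "bmx_stimuli")
}

#' Kernel density estimate by diffusion
#'
#' Density estimation via the diffusion (heat-equation) smoother with the
#' plug-in fixed-point bandwidth rule, computed on a dyadic grid with the
#' discrete cosine transform. The diffusion estimator adapts well to
#' multimodal data, which is why it is used here to define the "true mode"
#' of a trial's samples.
#'
#' @param positions numeric vector of at least 2 distinct values
#' @param range length-2 numeric, the estimation interval; defaults to the
#'   data range expanded by 10\% on each side
#' @param n number of grid points (rounded up to a power of two)
#' @return list with \code{x} (grid), \code{y} (density values, integrating
#'   to 1 over \code{range}) and \code{bandwidth}
#' @references Botev, Grotowski and Kroese (2010) Kernel density estimation
#'   via diffusion. Annals of Statistics 38(5):2916-2957.
#' @examples
#' k <- diffusion_kde(rnorm(500), range = c(-5, 5))
#' k$x[which.max(k$y)]  # close to 0
#' @export
diffusion_kde <- function(positions, range = NULL, n = 4096L) {
  positions <- as.numeric(positions)
  if (length(positions) < 2L) {
    stop("need at least 2 positions", call. = FALSE)
  }
  if (diff(base::range(positions)) == 0) {
    stop("degenerate input: all positions identical", call. = FALSE)
  }
  if (is.null(range)) {
    r <- base::range(positions)
    pad <- 0.1 * diff(r)
    range <- c(r[1] - pad, r[2] + pad)
  }
  n <- 2L^ceiling(log2(n))
  lo <- range[1]; hi <- range[2]
  width <- hi - lo
  xmesh <- lo + width * (0:(n - 1L)) / (n - 1L)
  N <- length(unique(positions))
  # nearest-mesh-point binning (bins centred on the mesh, so mirrored
  # data yield mirrored counts)
  step <- width / (n - 1L)
  h <- graphics::hist(positions, breaks = c(xmesh - step / 2,
                                            hi + step / 2),
                      plot = FALSE, right = FALSE)
  initial <- h$counts / length(positions)
  a <- dct1d(initial)
  I <- (1:(n - 1L))^2
  a2 <- (a[2:n] / 2)^2
  t_star <- tryCatch(
    stats::uniroot(function(t) fixed_point_t(t, N, I, a2),
                   lower = .Machine$double.eps, upper = 0.1,
                   tol = 1e-12)$root,
    error = function(e) 0.28 * N^(-2 / 5)
  )
  a_t <- a * exp(-(0:(n - 1L))^2 * pi^2 * t_star / 2)
  dens <- idct1d(a_t) / width
  dens[dens < 0] <- 0
  list(x = xmesh, y = dens, bandwidth = sqrt(t_star) * width)
}

# t - zeta * gamma^[l](t): the fixed-point functional of the diffusion
# bandwidth rule, with l = 7 stages as in the reference algorithm
fixed_point_t <- function(t, N, I, a2) {
  l <- 7
  f <- 2 * pi^(2 * l) * sum(I^l * a2 * exp(-I * pi^2 * t))
  for (s in (l - 1):2) {
    K0 <- prod(seq(1, 2 * s - 1, by = 2)) / sqrt(2 * pi)
    cst <- (1 + (1 / 2)^(s + 1 / 2)) / 3
    tt <- (2 * cst * K0 / (N * f))^(2 / (3 + 2 * s))
    f <- 2 * pi^(2 * s) * sum(I^s * a2 * exp(-I * pi^2 * tt))
  }
  t - (2 * N * sqrt(pi) * f)^(-2 / 5)
}

dct1d <- function(x) {
  n <- length(x)
  weight <- c(1, 2 * exp(-1i * (1:(n - 1)) * pi / (2 * n)))
  x <- c(x[seq(1, n, by = 2)], x[seq(n, 2, by = -2)])
  Re(weight * stats::fft(x))
}

idct1d <- function(x) {
  n <- length(x)
  weight <- n * exp(1i * (0:(n - 1)) * pi / (2 * n))
  x <- Re(stats::fft(weight * x, inverse = TRUE)) / n
  out <- numeric(n)
  out[seq(1, n, by = 2)] <- x[1:(n / 2)]
  out[seq(2, n, by = 2)] <- x[n:(n / 2 + 1)]
  out
}

# population (biased) standardized third central moment
sample_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m3 / m2^1.5
}

#' True statistics of a trial's samples
#'
#' The "true" mean and skewness are the arithmetic mean and the population
#' standardized third moment of the samples a subject actually saw; the
#' "true" mode is the highest peak of the diffusion kernel density estimate
#' of those samples (ties resolved to the lowest coordinate).
#'
#' @param stimuli a \code{\link{sample_stimuli}} object (or a
#'   \code{bmx_trial})
#' @param kde_n number of KDE grid points
#' @return data frame with columns trial, true_mean, true_skewness,
#'   true_mode
#' @export
true_stats <- function(stimuli, kde_n = 4096L) {
  if (inherits(stimuli, "bmx_trial")) {
    pos <- matrix(stimuli$positions, nrow = 1L)
    rng <- NULL
  } else {
    stopifnot(inherits(stimuli, "bmx_stimuli"))
    pos <- stimuli$positions
    rng <- stimuli$design$position_range
  }
  n_trials <- nrow(pos)
  out <- data.frame(trial = seq_len(n_trials), true_mean = NA_real_,
                    true_skewness = NA_real_, true_mode = NA_real_)
  for (i in seq_len(n_trials)) {
    x <- pos[i, ]
    out$true_mean[i] <- mean(x)
    out$true_skewness[i] <- sample_skewness(x)
    k <- diffusion_kde(x, range = rng, n = kde_n)
    out$true_mode[i] <- k$x[which.max(k$y)]
  }
  out
}
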