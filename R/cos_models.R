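#' Response-model parameters
#'
#' All observer models share a response stage: the internal estimate is
#' linearly transformed (capturing regression to the mean of magnitude
#' estimates) and perturbed by Gaussian noise,
#' \eqn{Y = \beta_0 + \beta_1 X^* + N(0, \sigma^2)}.
#'
#' @param beta0 intercept (cm)
#' @param beta1 slope (dimensionless)
#' @param sigma positive response noise SD (cm)
#' @return list of class \code{"response_params"}
#' @export
response_params <- function(beta0 = 0, beta1 = 1, sigma = 1) {
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("sigma must be positive", call. = FALSE)
  }
  structure(list(beta0 = beta0, beta1 = beta1, sigma = sigma),
            class = "response_params")
}

#' Lesion flags for the CoS Mean model
#'
#' Switches for the model-lesion analysis: \code{use_power} applies the
#' power transform w^alpha (probability distortion); \code{use_li} applies
#' the Gaussian-distance shunting (lateral inhibition) denominator;
#' \code{use_mode_prior} reuses the clustering posterior inferred from the
#' Mode response of the same trial ("shared representation"). With all
#' three off, subjective weights reduce to the raw cluster weights and the
#' Mean read-out is exactly the sample mean.
#'
#' @param use_power,use_li,use_mode_prior logical flags
#' @return list of class \code{"cos_lesions"}
#' @export
cos_lesions <- function(use_power = TRUE, use_li = TRUE,
                        use_mode_prior = TRUE) {
  structure(list(use_power = use_power, use_li = use_li,
                 use_mode_prior = use_mode_prior),
            class = "cos_lesions")
}

#' Mode read-out of one CoS representation
#'
#' The observer reports the centroid of the heaviest cluster, C*. Exact
#' weight ties are broken uniformly at random.
#'
#' @param rep a \code{\link{cos_representation}}
#' @return scalar centroid C*
#' @export
mode_point <- function(rep) {
  w <- rep$weights
  top <- which(w == max(w))
  if (length(top) > 1L) top <- top[sample.int(length(top), 1L)]
  rep$centroids[top]
}

#' Log-likelihood of a Mode response under the CoS model
#'
#' The Mode response density is a Monte-Carlo mixture over the ensemble's
#' per-draw read-outs: \eqn{(1/R) \sum_j N(y; \beta_0 + \beta_1 C^*_j,
#' \sigma^2)}, evaluated with log-sum-exp.
#'
#' @param y_mode observed Mode response (cm)
#' @param ensemble a \code{\link{build_ensemble}}
#' @param params a \code{\link{response_params}}
#' @return scalar log-likelihood
#' @export
mode_loglik <- function(y_mode, ensemble, params) {
  if (params$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  lp <- dnorm(y_mode, params$beta0 + params$beta1 * ensemble$cstar,
              params$sigma, log = TRUE)
  logsumexp(lp) - log(ensemble$R)
}

#' Posterior over clusterings given the Mode response
#'
#' Having seen the subject's Mode response, the probability that the j-th
#' Monte-Carlo clustering was the representation in use is proportional to
#' \eqn{N(y_{mode}; C^*_j, \sigma_{mode}^2)} (the response transform is not
#' applied at this stage). The returned ensemble carries these normalised
#' posterior weights, which the Mean model mixes over — the "shared
#' representation" assumption linking the two tasks.
#'
#' @param y_mode observed Mode response
#' @param ensemble a \code{\link{build_ensemble}}
#' @param sigma_mode positive Mode response noise (cm)
#' @return the ensemble with \code{posterior_weights} filled in
#' @export
set_posterior <- function(y_mode, ensemble, sigma_mode) {
  stopifnot(sigma_mode > 0)
  lw <- dnorm(y_mode, ensemble$cstar, sigma_mode, log = TRUE)
  w <- exp(lw - max(lw))
  ensemble$posterior_weights <- w / sum(w)
  ensemble
}

#' Subjective cluster weights (power transform + lateral inhibition)
#'
#' Transforms the relative weights of a CoS representation into subjective
#' weights \eqn{\theta_k \propto w_k^\alpha / \sum_j w_j
#' \exp(-(c_j - c_k)^2 / (2\sigma_{LI}^2))}. The power transform
#' over/under-weights small/large clusters; the shunting denominator
#' down-weights clusters with close, heavy neighbours. Lesion flags drop
#' either transform (alpha := 1, or denominator := 1).
#'
#' @param rep a \code{\link{cos_representation}}
#' @param alpha positive power exponent
#' @param sigma_li positive lateral-inhibition length scale (cm)
#' @param lesions a \code{\link{cos_lesions}}
#' @return normalised weight vector theta (sums to 1)
#' @export
subjective_weights <- function(rep, alpha, sigma_li,
                               lesions = cos_lesions()) {
  w <- rep$weights
  cc <- rep$centroids
  num <- if (lesions$use_power) w^alpha else w
  if (lesions$use_li) {
    d2 <- outer(cc, cc, "-")^2
    den <- as.numeric(exp(-d2 / (2 * sigma_li^2)) %*% w)
  } else {
    den <- rep(1, length(w))
  }
  th <- num / den
  th / sum(th)
}

#' Mean read-out of one CoS representation
#'
#' \eqn{M^* = \sum_k c_k \theta_k} with subjective weights from
#' \code{\link{subjective_weights}}. With both transforms lesioned,
#' \eqn{\theta = w} and M* equals the sample mean exactly, because
#' clustering conserves total sample weight.
#'
#' @inheritParams subjective_weights
#' @return scalar M*
#' @export
mean_point <- function(rep, alpha, sigma_li, lesions = cos_lesions()) {
  th <- subjective_weights(rep, alpha, sigma_li, lesions)
  sum(rep$centroids * th)
}

# Vectorised M* for every draw of an ensemble (padded-matrix arithmetic).
ensemble_mean_points <- function(ensemble, alpha, sigma_li,
                                 lesions = cos_lesions()) {
  W <- ensemble$weights      # R x Kmax, NA-free but 0-padded
  C <- ensemble$centroids    # NA beyond K
  kmax <- ncol(W)
  num <- if (lesions$use_power) W^alpha else W
  num[W == 0] <- 0
  if (lesions$use_li) {
    den <- matrix(0, nrow(W), kmax)
    s2 <- 2 * sigma_li^2
    for (k in seq_len(kmax)) {
      d2 <- (C - C[, k])^2
      kern <- exp(-d2 / s2)
      kern[is.na(kern)] <- 0
      den[, k] <- rowSums(W * kern, na.rm = TRUE)
    }
    den[den == 0] <- 1
  } else {
    den <- 1
  }
  th <- num / den
  th <- th / rowSums(th, na.rm = TRUE)
  rowSums(C * th, na.rm = TRUE)
}

#' Log-likelihood of a Mean response under the CoS model
#'
#' The Mean response density mixes the per-draw read-outs
#' \eqn{M^*_j} over the clustering posterior inferred from the Mode
#' response: \eqn{\log \sum_j P_{set}(j) N(y; \beta_0 + \beta_1 M^*_j,
#' \sigma^2)}. With \code{use_mode_prior} off (the "w/o Prior" lesion) the
#' mixture is uniform over draws.
#'
#' @param y_mean observed Mean response (cm)
#' @param ensemble ensemble, with \code{posterior_weights} set unless
#'   \code{use_mode_prior} is off
#' @param alpha,sigma_li transform parameters
#' @param params a \code{\link{response_params}} (sigma = sigma_mean)
#' @param lesions a \code{\link{cos_lesions}}
#' @return scalar log-likelihood
#' @export
mean_loglik <- function(y_mean, ensemble, alpha, sigma_li, params,
                        lesions = cos_lesions()) {
  if (params$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  pw <- if (lesions$use_mode_prior) {
    if (is.null(ensemble$posterior_weights)) {
      stop("posterior_weights missing: call set_posterior() first or ",
           "lesion use_mode_prior", call. = FALSE)
    }
    ensemble$posterior_weights
  } else {
    rep(1 / ensemble$R, ensemble$R)
  }
  mstar <- ensemble_mean_points(ensemble, alpha, sigma_li, lesions)
  lp <- dnorm(y_mean, params$beta0 + params$beta1 * mstar, params$sigma,
              log = TRUE) + log(pw)
  logsumexp(lp)
}

#' Subjective-weighting model (no clustering)
#'
#' The baseline Mean model without clustering: every sample starts with
#' weight 1/N, and only lateral inhibition between samples remains (the
#' power transform of a constant weight is absorbed by normalisation):
#' \eqn{\theta_i \propto 1 / \sum_j \exp(-(x_j - x_i)^2 /
#' (2\sigma_{LI}^2))}. Samples in dense regions are down-weighted, which
#' biases the weighted mean away from heavy clumps.
#'
#' @param positions numeric sample positions
#' @param sigma_li positive lateral-inhibition scale (cm)
#' @return list with \code{theta} and the point estimate \code{mstar}
#' @export
sw_mean_point <- function(positions, sigma_li) {
  d2 <- outer(positions, positions, "-")^2
  den <- rowSums(exp(-d2 / (2 * sigma_li^2)))
  th <- (1 / den) / sum(1 / den)
  list(theta = th, mstar = sum(positions * th))
}

#' @rdname sw_mean_point
#' @param y_mean observed Mean response
#' @param params a \code{\link{response_params}}
#' @return \code{sw_mean_loglik}: scalar Gaussian log-likelihood
#' @export
sw_mean_loglik <- function(y_mean, positions, sigma_li, params) {
  if (params$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  m <- sw_mean_point(positions, sigma_li)$mstar
  dnorm(y_mean, params$beta0 + params$beta1 * m, params$sigma, log = TRUE)
}

#' Simulate Mode and Mean responses from the CoS observer
#'
#' For each trial, one ddCRP partition is drawn and used as the shared
#' representation for both tasks: the Mode response is the transformed,
#' noise-perturbed C* and the Mean response the transformed,
#' noise-perturbed M*.
#'
#' @param stimuli a \code{\link{sample_stimuli}} object
#' @param gamma ddCRP distance scale (cm^2)
#' @param mode_params,mean_params \code{\link{response_params}} for the two
#'   tasks
#' @param alpha,sigma_li subjective-weight transform parameters
#' @param lesions a \code{\link{cos_lesions}}
#' @param rng_seed integer seed
#' @return data frame with columns trial, y_mode, y_mean
#' @export
simulate_responses <- function(stimuli, gamma, mode_params, mean_params,
                               alpha = 1, sigma_li = Inf,
                               lesions = cos_lesions(), rng_seed = 1L) {
  stopifnot(inherits(stimuli, "bmx_stimuli"))
  n_trials <- nrow(stimuli$positions)
  y_mode <- y_mean <- numeric(n_trials)
  withr::with_seed(rng_seed, {
    for (i in seq_len(n_trials)) {
      x <- stimuli$positions[i, ]
      rep_i <- sample_partition(x, gamma)$representation
      cs <- mode_point(rep_i)
      ms <- mean_point(rep_i, alpha, sigma_li, lesions)
      y_mode[i] <- mode_params$beta0 + mode_params$beta1 * cs +
        rnorm(1L, 0, mode_params$sigma)
      y_mean[i] <- mean_params$beta0 + mean_params$beta1 * ms +
        rnorm(1L, 0, mean_params$sigma)
    }
  })
  data.frame(trial = seq_len(n_trials), y_mode = y_mode, y_mean = y_mean)
}
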