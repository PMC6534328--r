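#' Configuration of the DPMM ideal observer
#'
#' The ideal observer assumes the samples arise from a Dirichlet-process
#' mixture of equal-precision Gaussians: cluster means are drawn from a
#' uniform base measure on [a, b]; the shared precision tau has a
#' Gamma(alpha_tau, beta_tau) prior with a Gamma(1, 1) hyperprior on the
#' rate beta_tau; and the concentration parameter has a Gamma(alpha_c, 1)
#' prior (alpha_c is the model's free stochastic parameter, fitted by grid
#' search). Inference runs several Gibbs chains and retains the
#' post-burn-in states.
#'
#' @param base_low,base_high support of the uniform base measure (cm);
#'   must cover all sample values
#' @param alpha_tau shape of the precision prior (fixed at 1)
#' @param alpha_c shape of the Gamma(alpha_c, 1) concentration prior
#' @param chains,iters,burn_in MCMC schedule; the defaults retain
#'   chains x (iters - burn_in) = 1000 draws
#' @param m_aux number of auxiliary components in the non-conjugate
#'   assignment update
#' @param grid_step step (cm) of the grid on which mixture modes are read
#'   off
#' @return list of class \code{"dpmm_config"}
#' @export
dpmm_config <- function(base_low = -20, base_high = 20, alpha_tau = 1,
                        alpha_c = 1, chains = 4L, iters = 500L,
                        burn_in = 250L, m_aux = 3L, grid_step = 0.01) {
  stopifnot(base_low < base_high, alpha_tau > 0, alpha_c > 0,
            chains >= 1L, iters > burn_in, burn_in >= 0L, m_aux >= 1L,
            grid_step > 0)
  structure(list(base_low = base_low, base_high = base_high,
                 alpha_tau = alpha_tau, alpha_c = alpha_c,
                 chains = as.integer(chains), iters = as.integer(iters),
                 burn_in = as.integer(burn_in), m_aux = as.integer(m_aux),
                 grid_step = grid_step),
            class = "dpmm_config")
}

#' Posterior sampling for the DPMM ideal observer
#'
#' Gibbs sampler for the non-conjugate DP mixture (uniform base measure):
#' cluster assignments are updated with the auxiliary-component scheme,
#' cluster means from truncated-Gaussian conditionals, the shared precision
#' and its rate hyperparameter from gamma conditionals, and the
#' concentration parameter by the beta-augmentation auxiliary-variable
#' update. Each retained state contributes a mixture mean
#' \eqn{\sum_k (n_k/N)\mu_k} and a mixture mode (grid argmax of the mixture
#' density, ties to the lowest coordinate).
#'
#' @param positions numeric samples, all within [base_low, base_high]
#' @param config a \code{\link{dpmm_config}}
#' @param rng_seed integer seed
#' @return list of class \code{"dpmm_draws"}: per_draw_mean, per_draw_mode,
#'   traces of alpha, tau, beta_tau and K, the posterior-averaged mixture
#'   density \code{avg_density} on \code{grid}, and \code{n_draws}
#' @export
dpmm_mcmc <- function(positions, config = dpmm_config(), rng_seed = 1L) {
  if (any(positions < config$base_low | positions > config$base_high)) {
    stop("base-support violation: samples outside [base_low, base_high]",
         call. = FALSE)
  }
  grid <- seq(config$base_low, config$base_high, by = config$grid_step)
  out <- withr::with_seed(rng_seed, {
    cpp_dpmm_gibbs(positions, config$base_low, config$base_high,
                   config$alpha_tau, config$alpha_c, config$chains,
                   config$iters, config$burn_in, config$m_aux, grid)
  })
  out$grid <- grid
  out$n_draws <- length(out$per_draw_mean)
  out$config <- config
  class(out) <- "dpmm_draws"
  out
}

#' Mean and mode of one Gaussian-mixture state
#'
#' @param state list with \code{sizes} (cluster sample counts), \code{mu}
#'   (cluster means) and \code{tau} (shared precision)
#' @param grid numeric grid on which the mode is read off
#' @return list with \code{mean} and \code{mode}
#' @export
mixture_stats <- function(state, grid) {
  n <- sum(state$sizes)
  w <- state$sizes / n
  m <- sum(w * state$mu)
  sdv <- 1 / sqrt(state$tau)
  dens <- colSums(w * t(vapply(state$mu,
                               function(mu) dnorm(grid, mu, sdv),
                               numeric(length(grid)))))
  list(mean = m, mode = grid[which.max(dens)])
}

#' Posterior-averaged estimates of the ideal observer
#'
#' The ideal observer reports the average over retained posterior draws of
#' the per-draw mixture mean and mode.
#'
#' @param draws a \code{\link{dpmm_mcmc}} result
#' @return list with \code{mean_hat} and \code{mode_hat}
#' @export
io_estimates <- function(draws) {
  stopifnot(length(draws$per_draw_mean) >= 1L)
  list(mean_hat = mean(draws$per_draw_mean),
       mode_hat = mean(draws$per_draw_mode))
}

#' Response log-likelihood around a deterministic estimate
#'
#' For observers whose internal estimate is deterministic given the
#' stimulus (ideal observer, ground truth, moment regressions), the
#' response density is a single Gaussian after the linear response
#' transform.
#'
#' @param y observed response
#' @param estimate internal point estimate
#' @param params a \code{\link{response_params}}
#' @return scalar log-likelihood
#' @export
io_loglik <- function(y, estimate, params) {
  if (params$sigma <= 0) stop("sigma must be positive", call. = FALSE)
  dnorm(y, params$beta0 + params$beta1 * estimate, params$sigma,
        log = TRUE)
}
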