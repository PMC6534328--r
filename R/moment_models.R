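#' Predictor matrix of a moment-regression model
#'
#' The ground-truth and moment-based baselines model the response as a
#' linear function of per-trial summary statistics plus Gaussian noise,
#' \eqn{Y = \beta_0 + \sum_j \beta_j Z_j + N(0, \sigma^2)}. The predictor
#' set is named by the model id: \code{"GT"} uses only the task's true
#' statistic (true mode for the Mode task, true mean for the Mean task);
#' \code{"MoMe"}, \code{"MeSk"}, \code{"MoSk"} and \code{"MoMeSk"} combine
#' true mode, mean and skewness. Variance is never a predictor (all
#' stimulus distributions share the same SD by construction).
#'
#' @param model_id one of "GT", "MoMe", "MeSk", "MoSk", "MoMeSk"
#' @param stats per-trial \code{\link{true_stats}} data frame
#' @param task "mode" or "mean"
#' @return numeric matrix, one column per predictor in model order
#' @export
moment_design <- function(model_id, stats, task = c("mode", "mean")) {
  task <- match.arg(task)
  cols <- switch(model_id,
    GT     = if (task == "mode") "true_mode" else "true_mean",
    MoMe   = c("true_mode", "true_mean"),
    MeSk   = c("true_mean", "true_skewness"),
    MoSk   = c("true_mode", "true_skewness"),
    MoMeSk = c("true_mode", "true_mean", "true_skewness"),
    stop("unknown model_id: ", model_id, call. = FALSE)
  )
  as.matrix(stats[, cols, drop = FALSE])
}

#' Gaussian log-likelihood of a moment-regression model
#'
#' @param y response vector
#' @param X predictor matrix from \code{\link{moment_design}}
#' @param beta coefficient vector (intercept first, then one per column of
#'   X)
#' @param sigma positive residual SD
#' @return summed log-likelihood
#' @export
moment_loglik <- function(y, X, beta, sigma) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (length(beta) != ncol(X) + 1L) {
    stop("dimension mismatch: beta must have ncol(X) + 1 entries",
         call. = FALSE)
  }
  mu <- beta[1] + as.numeric(X %*% beta[-1])
  sum(dnorm(y, mu, sigma, log = TRUE))
}

# Closed-form MLE of a moment regression: OLS coefficients with the
# biased (1/n) residual variance. sigma is floored to keep the likelihood
# finite on noise-free simulations.
fit_moment_ols <- function(y, X, sigma_floor = 1e-3) {
  Xd <- cbind(1, X)
  fit <- stats::lm.fit(Xd, y)
  beta <- unname(fit$coefficients)
  beta[is.na(beta)] <- 0
  sigma <- max(sqrt(mean(fit$residuals^2)), sigma_floor)
  nll <- -moment_loglik(y, X, beta, sigma)
  list(beta = beta, sigma = sigma, neg_loglik = nll)
}
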