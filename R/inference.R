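#' Bounded Nelder-Mead minimisation with multiple starts
#'
#' Minimises a function subject to box constraints by the Nelder-Mead
#' simplex run in an unconstrained space, with parameters mapped through a
#' sine transform onto the bounds (the classic bounded-simplex device).
#' Starts are dispersed over the box by a Latin-hypercube design; extra
#' user-supplied starts can be appended (e.g. warm starts along a grid).
#'
#' @param fn objective taking a numeric vector on the original scale
#' @param lower,upper numeric bound vectors
#' @param n_starts number of Latin-hypercube starts
#' @param rng_seed integer seed (controls the start design)
#' @param extra_starts optional list of start vectors on the original scale
#' @param maxit Nelder-Mead iteration cap per start
#' @return list with \code{par}, \code{value}, \code{convergence},
#'   \code{n_starts}
#' @export
fminsearch_bounded <- function(fn, lower, upper, n_starts = 10L,
                               rng_seed = 1L, extra_starts = NULL,
                               maxit = 500L) {
  stopifnot(length(lower) == length(upper), all(upper > lower),
            all(is.finite(lower)), all(is.finite(upper)))
  p <- length(lower)
  to_par <- function(z) lower + (upper - lower) * (sin(z) + 1) / 2
  to_z <- function(par) {
    frac <- pmin(pmax((par - lower) / (upper - lower), 1e-8), 1 - 1e-8)
    asin(2 * frac - 1)
  }
  obj <- function(z) {
    v <- fn(to_par(z))
    if (!is.finite(v)) 1e10 else v
  }
  starts <- withr::with_seed(rng_seed, {
    u <- lhs::randomLHS(max(n_starts, 1L), p)
    lapply(seq_len(nrow(u)), function(i) lower + (upper - lower) * u[i, ])
  })
  starts <- c(starts, extra_starts)
  best <- NULL
  for (s in starts) {
    res <- tryCatch(
      suppressWarnings(
        optim(to_z(s), obj, method = "Nelder-Mead",
              control = list(maxit = maxit, reltol = 1e-10))
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("optimization failure: no start converged", call. = FALSE)
  }
  list(par = to_par(best$par), value = best$value,
       convergence = best$convergence, n_starts = length(starts))
}

#' Finite-sample-corrected Akaike information criterion
#'
#' \eqn{AICc = 2 NLL + 2k + 2k(k+1)/(n-k-1)}.
#'
#' @param neg_loglik minimised negative log-likelihood
#' @param k number of free parameters
#' @param n number of observations (trials)
#' @return scalar AICc
#' @examples
#' aicc(100, 4, 162)  # 208 + 40/157
#' @export
aicc <- function(neg_loglik, k, n) {
  if (n <= k + 1) {
    stop("AICc undefined: need n > k + 1", call. = FALSE)
  }
  2 * neg_loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Per-subject and summed AICc differences
#'
#' The delta-AICc of a model for a subject is its AICc minus the lowest
#' AICc among that subject's fitted models; the group summary sums deltas
#' over subjects (0 means the model is best for everyone).
#'
#' @param fits data frame with columns subject, model, aicc (one row per
#'   subject x model)
#' @return list with \code{delta} (subjects x models matrix) and
#'   \code{summed} (named vector)
#' @export
delta_aicc <- function(fits) {
  tab <- tapply(fits$aicc, list(fits$subject, fits$model), identity)
  if (anyNA(tab)) stop("missing fits: every subject needs every model",
                       call. = FALSE)
  delta <- tab - apply(tab, 1L, min)
  list(delta = delta, summed = colSums(delta))
}

#' Group-level random-effects Bayesian model selection
#'
#' Treats the best-fitting model as a random effect across subjects:
#' model frequencies get a Dirichlet prior, updated by variational Bayes
#' from per-subject log-evidence (here approximated as -AICc/2).
#' Exceedance probabilities (EP, the posterior probability that a model is
#' the most frequent) are computed by Monte-Carlo sampling of the Dirichlet
#' posterior. The Bayes omnibus risk (BOR) is the posterior probability of
#' the null that all models are equally frequent, and the protected
#' exceedance probability shrinks EP towards chance accordingly:
#' \eqn{PXP = (1 - BOR) EP + BOR / K}.
#'
#' @param log_evidence subjects x models matrix of log model evidence
#' @param alpha0 Dirichlet prior count per model
#' @param n_samples Monte-Carlo draws for the exceedance probabilities
#' @param rng_seed integer seed
#' @return list of class \code{"group_bms"}: \code{alpha} (posterior
#'   Dirichlet counts), \code{exp_r} (expected frequencies), \code{ep},
#'   \code{bor}, \code{pxp}
#' @references Stephan et al. (2009) NeuroImage 46:1004-1017; Rigoux et
#'   al. (2014) NeuroImage 84:971-985.
#' @export
group_bms <- function(log_evidence, alpha0 = 1, n_samples = 1e5L,
                      rng_seed = 1L) {
  lme <- as.matrix(log_evidence)
  K <- ncol(lme)
  if (K < 2L) stop("degenerate input: need at least two models",
                   call. = FALSE)
  if (any(!is.finite(lme))) stop("log evidence must be finite",
                                 call. = FALSE)
  n <- nrow(lme)
  a0 <- rep(alpha0, K)
  alpha <- a0 + n / K
  g <- matrix(1 / K, n, K)
  for (iter in seq_len(500L)) {
    elogr <- digamma(alpha) - digamma(sum(alpha))
    lg <- sweep(lme, 2L, elogr, "+")
    lg <- lg - apply(lg, 1L, max)
    g <- exp(lg)
    g <- g / rowSums(g)
    alpha_new <- a0 + colSums(g)
    if (max(abs(alpha_new - alpha)) < 1e-9) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  # exceedance probabilities by Dirichlet posterior sampling
  ep <- withr::with_seed(rng_seed, {
    draws <- matrix(rgamma(n_samples * K, shape = rep(alpha,
                                                      each = n_samples)),
                    n_samples, K)
    win <- max.col(draws, ties.method = "first")
    tabulate(win, nbins = K) / n_samples
  })
  # Bayes omnibus risk: null (equal frequencies) vs the fitted H1
  f0 <- sum(row_logsumexp(lme) - log(K))
  elogr <- digamma(alpha) - digamma(sum(alpha))
  elj <- lgamma(sum(a0)) - sum(lgamma(a0)) + sum((a0 - 1) * elogr) +
    sum(g * (sweep(lme, 2L, elogr, "+")))
  sqf <- sum(lgamma(alpha)) - lgamma(sum(alpha)) -
    sum((alpha - 1) * elogr)
  sqm <- -sum(g[g > 0] * log(g[g > 0]))
  f1 <- elj + sqf + sqm
  bor <- 1 / (1 + exp(f1 - f0))
  pxp <- (1 - bor) * ep + bor / K
  mods <- colnames(lme)
  if (!is.null(mods)) {
    names(ep) <- names(pxp) <- names(alpha) <- mods
  }
  structure(list(alpha = alpha, exp_r = alpha / sum(alpha), ep = ep,
                 bor = bor, pxp = pxp),
            class = "group_bms")
}

# ---- parameter bounds ---------------------------------------------------

#' Default fitting bounds
#'
#' Box bounds used by the bounded simplex search: intercept beta0 in
#' [-10, 10] cm, slope beta1 in [0, 3], response noise sigma in
#' [1e-3, 20] cm (the floor keeps likelihoods finite on noise-free data),
#' power exponent alpha in [0.05, 5], lateral-inhibition scale sigma_li in
#' [0.1, 50] cm.
#'
#' @return named list of c(lower, upper) pairs
#' @export
default_bounds <- function() {
  list(beta0 = c(-10, 10), beta1 = c(0, 3), sigma = c(1e-3, 20),
       alpha = c(0.05, 5), sigma_li = c(0.1, 50))
}

# ---- shared caches ------------------------------------------------------

#' Precompute ddCRP ensembles along a gamma grid
#'
#' Ensembles depend only on the stimuli, gamma, R and the seed, so they are
#' shared by every subject fitted on the same sample set; building them
#' once per gamma is what makes the grid search tractable.
#'
#' @param stimuli a \code{\link{sample_stimuli}} object
#' @param gammas numeric grid of distance scales (cm^2)
#' @param R clusterings per ensemble
#' @param rng_seed master seed; child seeds are derived per (trial, gamma)
#' @return list of class \code{"ensemble_cache"}: \code{gammas} and
#'   \code{ens[[gamma index]][[trial]]}
#' @export
ensemble_cache <- function(stimuli, gammas, R = 1000L, rng_seed = 1L) {
  stopifnot(inherits(stimuli, "bmx_stimuli"), length(gammas) >= 1L)
  n_trials <- nrow(stimuli$positions)
  ens <- vector("list", length(gammas))
  for (gi in seq_along(gammas)) {
    ens[[gi]] <- lapply(seq_len(n_trials), function(i) {
      build_ensemble(stimuli$positions[i, ], gammas[gi], R = R,
                     rng_seed = seed_child(rng_seed, 23L, gi, i))
    })
  }
  structure(list(gammas = gammas, ens = ens, R = R, rng_seed = rng_seed),
            class = "ensemble_cache")
}

#' Precompute ideal-observer estimates along an alpha_c grid
#'
#' The DPMM posterior depends only on the stimulus and alpha_c, so the
#' per-trial posterior-averaged estimates are computed once and shared
#' across subjects and across the two tasks.
#'
#' @param stimuli a \code{\link{sample_stimuli}} object
#' @param alpha_c_grid numeric grid for the concentration-prior shape
#' @param config a \code{\link{dpmm_config}} (its alpha_c is overridden)
#' @param rng_seed master seed
#' @return list of class \code{"io_cache"}: \code{alpha_c_grid} and
#'   \code{est[[grid index]]} with per-trial \code{mode_hat} and
#'   \code{mean_hat} vectors
#' @export
io_cache <- function(stimuli, alpha_c_grid, config = dpmm_config(),
                     rng_seed = 1L) {
  stopifnot(inherits(stimuli, "bmx_stimuli"))
  n_trials <- nrow(stimuli$positions)
  est <- vector("list", length(alpha_c_grid))
  for (ai in seq_along(alpha_c_grid)) {
    cfg <- config
    cfg$alpha_c <- alpha_c_grid[ai]
    mode_hat <- mean_hat <- numeric(n_trials)
    for (i in seq_len(n_trials)) {
      dr <- dpmm_mcmc(stimuli$positions[i, ], cfg,
                      rng_seed = seed_child(rng_seed, 31L, ai, i))
      e <- io_estimates(dr)
      mode_hat[i] <- e$mode_hat
      mean_hat[i] <- e$mean_hat
    }
    est[[ai]] <- list(mode_hat = mode_hat, mean_hat = mean_hat)
  }
  structure(list(alpha_c_grid = alpha_c_grid, est = est,
                 rng_seed = rng_seed),
            class = "io_cache")
}

# ---- model-specific fitters --------------------------------------------

# OLS closed form for models with a deterministic internal estimate
fit_linear_model <- function(y, X) {
  fit_moment_ols(y, X)
}

make_fit <- function(subject_id, model_id, task, params, neg_loglik,
                     n_trials, k_params, grid_value = NA_real_,
                     rng_seed = NA_integer_, se = NULL) {
  structure(
    list(subject_id = subject_id, model_id = model_id, task = task,
         params = params, neg_loglik = neg_loglik, n_trials = n_trials,
         k_params = k_params, aicc = aicc(neg_loglik, k_params, n_trials),
         grid_value = grid_value, rng_seed = rng_seed, se = se),
    class = "cos_fit"
  )
}

# asymptotic standard errors from the observed information at the MLE;
# NA where the Hessian is not usable (e.g. parameters pinned at bounds)
fit_se <- function(fn, par) {
  tryCatch({
    h <- stats::optimHess(par, fn)
    v <- diag(solve(h))
    ifelse(v > 0, sqrt(v), NA_real_)
  }, error = function(e) rep(NA_real_, length(par)))
}

# negative log-likelihood of the CoS Mode model over all trials, given the
# n_trials x R matrix of per-draw C* values
cos_mode_nll <- function(par, y, cstar_mat) {
  b0 <- par[1]; b1 <- par[2]; sig <- par[3]
  lp <- dnorm(y, b0 + b1 * cstar_mat, sig, log = TRUE)
  -sum(row_logsumexp(lp) - log(ncol(cstar_mat)))
}

#' Fit the CoS Mode model by grid search over gamma
#'
#' For each gamma on the grid, the response parameters (beta0, beta1,
#' sigma_mode) are optimised by bounded simplex against the Monte-Carlo
#' mixture likelihood; the gamma with the lowest minimised negative
#' log-likelihood wins. The previous grid point's optimum seeds the next
#' search as a warm start.
#'
#' @param y_mode per-trial Mode responses (aligned with the cache's trials)
#' @param cache an \code{\link{ensemble_cache}}
#' @param subject_id identifier stored in the fit record
#' @param n_starts Latin-hypercube starts per grid point
#' @param rng_seed integer seed
#' @param bounds see \code{\link{default_bounds}}
#' @param maxit simplex iteration cap
#' @return a \code{"cos_fit"} record; \code{grid_value} holds the chosen
#'   gamma
#' @export
fit_cos_mode <- function(y_mode, cache, subject_id = 1L, n_starts = 5L,
                         rng_seed = 1L, bounds = default_bounds(),
                         maxit = 400L) {
  stopifnot(inherits(cache, "ensemble_cache"))
  lower <- c(bounds$beta0[1], bounds$beta1[1], bounds$sigma[1])
  upper <- c(bounds$beta0[2], bounds$beta1[2], bounds$sigma[2])
  best <- NULL
  warm <- NULL
  for (gi in seq_along(cache$gammas)) {
    cstar_mat <- do.call(rbind, lapply(cache$ens[[gi]], `[[`, "cstar"))
    res <- fminsearch_bounded(
      function(p) cos_mode_nll(p, y_mode, cstar_mat),
      lower, upper, n_starts = n_starts,
      rng_seed = seed_child(rng_seed, 41L, gi),
      extra_starts = warm, maxit = maxit
    )
    warm <- list(res$par)
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$gamma <- cache$gammas[gi]
    }
  }
  params <- c(gamma = best$gamma, beta0 = best$par[1],
              beta1 = best$par[2], sigma_mode = best$par[3])
  gi_best <- which(cache$gammas == best$gamma)
  cstar_best <- do.call(rbind, lapply(cache$ens[[gi_best]], `[[`,
                                      "cstar"))
  se <- fit_se(function(p) cos_mode_nll(p, y_mode, cstar_best),
               best$par)
  make_fit(subject_id, "CoS", "mode", params, best$value,
           length(y_mode), 4L, grid_value = best$gamma,
           rng_seed = rng_seed,
           se = setNames(se, c("beta0", "beta1", "sigma_mode")))
}

# Precomputed per-trial structures for the CoS Mean likelihood at the
# best-fit gamma: ensembles plus log posterior weights over draws.
cos_mean_data <- function(y_mode, ensembles, sigma_mode,
                          use_mode_prior = TRUE) {
  lapply(seq_along(ensembles), function(i) {
    ens <- ensembles[[i]]
    if (use_mode_prior) {
      ens <- set_posterior(y_mode[i], ens, sigma_mode)
      lpw <- log(pmax(ens$posterior_weights, 1e-300))
    } else {
      lpw <- rep(-log(ens$R), ens$R)
    }
    list(ens = ens, lpw = lpw)
  })
}

cos_mean_nll <- function(par, y_mean, dat, lesions) {
  # par layout depends on lesions: optional alpha, optional sigma_li,
  # then beta0, beta1, sigma
  i <- 1L
  if (lesions$use_power) { alpha <- par[i]; i <- i + 1L } else alpha <- 1
  if (lesions$use_li) { sli <- par[i]; i <- i + 1L } else sli <- Inf
  b0 <- par[i]; b1 <- par[i + 1L]; sig <- par[i + 2L]
  total <- 0
  for (ti in seq_along(dat)) {
    ens <- dat[[ti]]$ens
    mstar <- cpp_mean_points(ens$centroids, ens$weights, alpha,
                             if (is.finite(sli)) sli else 1e12,
                             lesions$use_power, lesions$use_li)
    lp <- dnorm(y_mean[ti], b0 + b1 * mstar, sig, log = TRUE) +
      dat[[ti]]$lpw
    total <- total - logsumexp(lp)
  }
  total
}

#' Fit the CoS Mean model (or a lesioned variant)
#'
#' Uses the clustering ensembles at the Mode fit's best gamma and, unless
#' the prior lesion is active, the per-trial posterior over clusterings
#' implied by the subject's Mode responses and fitted sigma_mode. Free
#' parameters are (alpha, sigma_li, beta0, beta1, sigma_mean), minus any
#' lesioned transform.
#'
#' @param y_mean,y_mode per-trial responses
#' @param ensembles list of per-trial ensembles at the chosen gamma
#' @param mode_fit the subject's \code{\link{fit_cos_mode}} record
#' @param lesions a \code{\link{cos_lesions}}
#' @param model_id label stored in the fit record ("CoS", "CoS_noLI", ...)
#' @inheritParams fit_cos_mode
#' @return a \code{"cos_fit"} record
#' @export
fit_cos_mean <- function(y_mean, y_mode, ensembles, mode_fit,
                         lesions = cos_lesions(), model_id = "CoS",
                         subject_id = 1L, n_starts = 5L, rng_seed = 1L,
                         bounds = default_bounds(), maxit = 400L) {
  dat <- cos_mean_data(y_mode, ensembles,
                       sigma_mode = mode_fit$params[["sigma_mode"]],
                       use_mode_prior = lesions$use_mode_prior)
  lower <- upper <- numeric(0)
  nm <- character(0)
  if (lesions$use_power) {
    lower <- c(lower, bounds$alpha[1]); upper <- c(upper, bounds$alpha[2])
    nm <- c(nm, "alpha")
  }
  if (lesions$use_li) {
    lower <- c(lower, bounds$sigma_li[1])
    upper <- c(upper, bounds$sigma_li[2])
    nm <- c(nm, "sigma_li")
  }
  lower <- c(lower, bounds$beta0[1], bounds$beta1[1], bounds$sigma[1])
  upper <- c(upper, bounds$beta0[2], bounds$beta1[2], bounds$sigma[2])
  nm <- c(nm, "beta0", "beta1", "sigma_mean")
  # the likelihood surface is multimodal in (alpha, sigma_li); seed the
  # simplex from a coarse transform grid with OLS-initialised response
  # parameters at each grid point
  clamp <- function(v, b) pmin(pmax(v, b[1] + 1e-6), b[2] - 1e-6)
  grid_a <- if (lesions$use_power) c(0.3, 0.7, 1, 1.5) else NA
  grid_s <- if (lesions$use_li) c(1, 2, 4, 8, 16, 40) else NA
  starts <- list()
  for (a in grid_a) for (sl in grid_s) {
    mbar <- vapply(seq_along(dat), function(ti) {
      ens <- dat[[ti]]$ens
      ms <- cpp_mean_points(ens$centroids, ens$weights,
                            if (is.na(a)) 1 else a,
                            if (is.na(sl)) 1e12 else sl,
                            lesions$use_power, lesions$use_li)
      sum(exp(dat[[ti]]$lpw) * ms)
    }, 0)
    ols <- fit_moment_ols(y_mean, matrix(mbar, ncol = 1L))
    st <- c(if (lesions$use_power) clamp(a, bounds$alpha),
            if (lesions$use_li) clamp(sl, bounds$sigma_li),
            clamp(ols$beta[1], bounds$beta0),
            clamp(ols$beta[2], bounds$beta1),
            clamp(ols$sigma * 1.2, bounds$sigma))
    nll <- cos_mean_nll(st, y_mean, dat, lesions)
    starts[[length(starts) + 1L]] <- list(par = st, nll = nll)
  }
  ord <- order(vapply(starts, `[[`, 0, "nll"))
  best_starts <- lapply(starts[head(ord, 3L)], `[[`, "par")
  res <- fminsearch_bounded(
    function(p) cos_mean_nll(p, y_mean, dat, lesions),
    lower, upper, n_starts = max(1L, n_starts - 2L),
    rng_seed = seed_child(rng_seed, 43L), extra_starts = best_starts,
    maxit = maxit
  )
  params <- setNames(res$par, nm)
  se <- fit_se(function(p) cos_mean_nll(p, y_mean, dat, lesions),
               res$par)
  make_fit(subject_id, model_id, "mean", params, res$value,
           length(y_mean), length(nm), grid_value = mode_fit$grid_value,
           rng_seed = rng_seed, se = setNames(se, nm))
}

#' Fit the subjective-weighting Mean model
#'
#' Free parameters (sigma_li, beta0, beta1, sigma_mean); the internal
#' estimate for a given sigma_li is deterministic, so the likelihood is a
#' single Gaussian per trial.
#'
#' @param y_mean per-trial Mean responses
#' @param stimuli a \code{\link{sample_stimuli}} object
#' @inheritParams fit_cos_mode
#' @return a \code{"cos_fit"} record
#' @export
fit_sw_mean <- function(y_mean, stimuli, subject_id = 1L, n_starts = 5L,
                        rng_seed = 1L, bounds = default_bounds(),
                        maxit = 400L) {
  pos <- stimuli$positions
  n_trials <- nrow(pos)
  # pairwise squared distances are parameter-free: compute once
  d2 <- lapply(seq_len(n_trials),
               function(i) outer(pos[i, ], pos[i, ], "-")^2)
  last <- new.env(parent = emptyenv())
  last$sli <- NA_real_
  mstars <- function(sli) {
    if (!identical(sli, last$sli)) {
      last$m <- vapply(seq_len(n_trials), function(i) {
        den <- rowSums(exp(-d2[[i]] / (2 * sli^2)))
        th <- (1 / den) / sum(1 / den)
        sum(pos[i, ] * th)
      }, 0)
      last$sli <- sli
    }
    last$m
  }
  nll <- function(par) {
    m <- mstars(par[1])
    -sum(dnorm(y_mean, par[2] + par[3] * m, par[4], log = TRUE))
  }
  # coarse sigma_li grid with OLS response starts; the response
  # parameters are conditionally linear so only sigma_li is hard
  clamp <- function(v, b) pmin(pmax(v, b[1] + 1e-6), b[2] - 1e-6)
  warm <- lapply(c(1, 2, 4, 8, 16, 40), function(sl) {
    ols <- fit_moment_ols(y_mean, matrix(mstars(sl), ncol = 1L))
    c(clamp(sl, bounds$sigma_li), clamp(ols$beta[1], bounds$beta0),
      clamp(ols$beta[2], bounds$beta1), clamp(ols$sigma, bounds$sigma))
  })
  warm <- warm[order(vapply(warm, nll, 0))][1:2]
  res <- fminsearch_bounded(
    nll,
    c(bounds$sigma_li[1], bounds$beta0[1], bounds$beta1[1],
      bounds$sigma[1]),
    c(bounds$sigma_li[2], bounds$beta0[2], bounds$beta1[2],
      bounds$sigma[2]),
    n_starts = max(1L, n_starts - 1L),
    rng_seed = seed_child(rng_seed, 47L),
    extra_starts = warm, maxit = maxit
  )
  params <- setNames(res$par, c("sigma_li", "beta0", "beta1",
                                "sigma_mean"))
  make_fit(subject_id, "SW", "mean", params, res$value, length(y_mean),
           4L, rng_seed = rng_seed)
}

#' Fit the ideal-observer model
#'
#' For the Mode task, alpha_c is grid-searched and the response parameters
#' have a closed-form (OLS) maximum-likelihood solution at each grid point
#' (k = 4). For the Mean task the Mode fit's alpha_c is inherited and only
#' the response parameters are free (k = 3).
#'
#' @param y per-trial responses
#' @param cache an \code{\link{io_cache}}
#' @param task "mode" or "mean"
#' @param mode_fit required for the Mean task: the subject's ideal-observer
#'   Mode fit, whose alpha_c is reused
#' @inheritParams fit_cos_mode
#' @return a \code{"cos_fit"} record
#' @export
fit_io <- function(y, cache, task = c("mode", "mean"), mode_fit = NULL,
                   subject_id = 1L, rng_seed = 1L) {
  task <- match.arg(task)
  stopifnot(inherits(cache, "io_cache"))
  if (task == "mode") {
    best <- NULL
    for (ai in seq_along(cache$alpha_c_grid)) {
      est <- cache$est[[ai]]$mode_hat
      f <- fit_linear_model(y, matrix(est, ncol = 1L))
      if (is.null(best) || f$neg_loglik < best$neg_loglik) {
        best <- f
        best$alpha_c <- cache$alpha_c_grid[ai]
      }
    }
    params <- c(alpha_c = best$alpha_c, beta0 = best$beta[1],
                beta1 = best$beta[2], sigma_mode = best$sigma)
    make_fit(subject_id, "IO", "mode", params, best$neg_loglik,
             length(y), 4L, grid_value = best$alpha_c,
             rng_seed = rng_seed)
  } else {
    if (is.null(mode_fit)) {
      stop("the Mean task inherits alpha_c from the Mode fit; supply ",
           "mode_fit", call. = FALSE)
    }
    ai <- which.min(abs(cache$alpha_c_grid - mode_fit$grid_value))
    est <- cache$est[[ai]]$mean_hat
    f <- fit_linear_model(y, matrix(est, ncol = 1L))
    params <- c(beta0 = f$beta[1], beta1 = f$beta[2],
                sigma_mean = f$sigma)
    make_fit(subject_id, "IO", "mean", params, f$neg_loglik, length(y),
             3L, grid_value = mode_fit$grid_value, rng_seed = rng_seed)
  }
}

#' Fit a ground-truth or moment-regression model
#'
#' Closed-form (OLS) maximum likelihood with the biased residual variance;
#' k = q + 2 free parameters for q predictors.
#'
#' @param y per-trial responses
#' @param model_id one of "GT", "MoMe", "MeSk", "MoSk", "MoMeSk"
#' @param stats per-trial \code{\link{true_stats}}
#' @param task "mode" or "mean"
#' @param subject_id identifier stored in the fit record
#' @return a \code{"cos_fit"} record
#' @export
fit_moment_model <- function(y, model_id, stats, task = c("mode", "mean"),
                             subject_id = 1L) {
  task <- match.arg(task)
  X <- moment_design(model_id, stats, task)
  f <- fit_linear_model(y, X)
  params <- setNames(c(f$beta, f$sigma),
                     c("beta0", paste0("beta_", colnames(X)), "sigma"))
  make_fit(subject_id, model_id, task, params, f$neg_loglik, length(y),
           ncol(X) + 2L)
}
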