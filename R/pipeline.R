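#' Generating parameters for a simulated cohort
#'
#' Base observer parameters used when simulating subjects, chosen to sit
#' well inside the fitted ranges typical of this task family: a moderate
#' clustering scale, mild regression to the mean, and response noise of a
#' couple of centimetres. Per-subject variability multiplies positive
#' parameters by U(1 - jitter, 1 + jitter) and shifts beta0 by
#' U(-0.5, 0.5) cm.
#'
#' @param gamma ddCRP distance scale (cm^2)
#' @param alpha power-transform exponent
#' @param sigma_li lateral-inhibition scale (cm)
#' @param beta0,beta1 response transform
#' @param sigma_mode,sigma_mean response noise SDs (cm)
#' @param jitter relative half-width of the per-subject jitter
#' @return named list
#' @export
cohort_params <- function(gamma = 0.5, alpha = 0.7, sigma_li = 4,
                          beta0 = 0, beta1 = 1, sigma_mode = 2,
                          sigma_mean = 1.5, jitter = 0.1) {
  list(gamma = gamma, alpha = alpha, sigma_li = sigma_li, beta0 = beta0,
       beta1 = beta1, sigma_mode = sigma_mode, sigma_mean = sigma_mean,
       jitter = jitter)
}

# one subject's jittered parameter set
jitter_params <- function(p, rng_seed) {
  withr::with_seed(rng_seed, {
    jit <- function(v) v * runif(1L, 1 - p$jitter, 1 + p$jitter)
    list(gamma = p$gamma, alpha = jit(p$alpha),
         sigma_li = jit(p$sigma_li),
         beta0 = p$beta0 + runif(1L, -0.5, 0.5), beta1 = jit(p$beta1),
         sigma_mode = jit(p$sigma_mode), sigma_mean = jit(p$sigma_mean))
  })
}

#' Simulate a cohort of observers
#'
#' Generates per-subject Mode and Mean responses to a shared sample set
#' from one of the implemented observer families: \code{"cos"} (the full
#' Clusters-of-Samples observer with one shared clustering per trial),
#' \code{"gt"} (responses are noisy linear transforms of the true
#' statistics), \code{"momesk"} (noisy linear combination of true mode,
#' mean and skewness), or \code{"sw"} (Mean from the subjective-weighting
#' model, Mode from ground truth).
#'
#' @param stimuli a \code{\link{sample_stimuli}} object
#' @param n_subjects cohort size
#' @param generator generating model family
#' @param params a \code{\link{cohort_params}} list
#' @param stats optional precomputed \code{\link{true_stats}} (required by
#'   the gt/momesk/sw generators; computed if missing)
#' @param rng_seed master seed
#' @return data frame with columns subject, trial, y_mode, y_mean, plus a
#'   \code{"subject_params"} attribute (list of the jittered true
#'   parameters)
#' @export
simulate_cohort <- function(stimuli, n_subjects = 16L,
                            generator = c("cos", "gt", "momesk", "sw"),
                            params = cohort_params(), stats = NULL,
                            rng_seed = 1L) {
  generator <- match.arg(generator)
  if (generator != "cos" && is.null(stats)) stats <- true_stats(stimuli)
  n_trials <- nrow(stimuli$positions)
  out <- vector("list", n_subjects)
  sp <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    ps <- jitter_params(params, seed_child(rng_seed, 53L, s))
    sp[[s]] <- ps
    seed_s <- seed_child(rng_seed, 59L, s)
    if (generator == "cos") {
      resp <- simulate_responses(
        stimuli, ps$gamma,
        response_params(ps$beta0, ps$beta1, ps$sigma_mode),
        response_params(ps$beta0, ps$beta1, ps$sigma_mean),
        alpha = ps$alpha, sigma_li = ps$sigma_li, rng_seed = seed_s
      )
    } else {
      resp <- withr::with_seed(seed_s, {
        mu_mode <- switch(generator,
          gt = ps$beta0 + ps$beta1 * stats$true_mode,
          momesk = ps$beta0 + ps$beta1 * stats$true_mode +
            0.1 * stats$true_mean + 0.5 * stats$true_skewness,
          sw = ps$beta0 + ps$beta1 * stats$true_mode
        )
        mu_mean <- switch(generator,
          gt = ps$beta0 + ps$beta1 * stats$true_mean,
          momesk = ps$beta0 + ps$beta1 * stats$true_mean +
            0.1 * stats$true_mode + 0.5 * stats$true_skewness,
          sw = ps$beta0 + ps$beta1 *
            vapply(seq_len(n_trials), function(i) {
              sw_mean_point(stimuli$positions[i, ], ps$sigma_li)$mstar
            }, 0)
        )
        data.frame(
          trial = seq_len(n_trials),
          y_mode = mu_mode + rnorm(n_trials, 0, ps$sigma_mode),
          y_mean = mu_mean + rnorm(n_trials, 0, ps$sigma_mean)
        )
      })
    }
    resp$subject <- s
    out[[s]] <- resp[, c("subject", "trial", "y_mode", "y_mean")]
  }
  res <- do.call(rbind, out)
  attr(res, "subject_params") <- sp
  res
}

# fit-record list -> tidy data frame
fits_to_df <- function(fits) {
  do.call(rbind, lapply(fits, function(f) {
    data.frame(subject = f$subject_id, model = f$model_id, task = f$task,
               neg_loglik = f$neg_loglik, k = f$k_params,
               n = f$n_trials, aicc = f$aicc, grid_value = f$grid_value,
               stringsAsFactors = FALSE)
  }))
}

#' Fit a set of models to every subject of a cohort
#'
#' Fits the requested Mode-task and Mean-task models per subject, sharing
#' the clustering and ideal-observer caches across subjects. The CoS and
#' IO Mean models inherit their stochastic grid parameter (gamma, alpha_c)
#' and, for CoS, the clustering posterior from the same subject's Mode
#' fit, so those Mode fits are added automatically when needed.
#'
#' @param responses cohort data frame (subject, trial, y_mode, y_mean)
#' @param stimuli the shared \code{\link{sample_stimuli}}
#' @param models_mode,models_mean character vectors over "GT", "IO",
#'   "MoMe", "MeSk", "MoSk", "MoMeSk", "CoS" (+"SW" and lesioned
#'   "CoS_noLI", "CoS_noPT", "CoS_noLIPT", "CoS_noPrior" for the Mean task)
#' @param ens_cache an \code{\link{ensemble_cache}} (needed for CoS)
#' @param io_est an \code{\link{io_cache}} (needed for IO)
#' @param stats optional precomputed \code{\link{true_stats}}
#' @param n_starts,rng_seed,maxit optimisation controls
#' @return list with \code{fits} (data frame) and \code{records} (list of
#'   fit records)
#' @export
fit_cohort <- function(responses, stimuli,
                       models_mode = c("GT", "MoMe", "MeSk", "MoSk",
                                       "MoMeSk", "CoS"),
                       models_mean = c("GT", "MoMe", "MeSk", "MoSk",
                                       "MoMeSk", "CoS", "SW"),
                       ens_cache = NULL, io_est = NULL, stats = NULL,
                       n_starts = 4L, rng_seed = 1L, maxit = 400L) {
  need_cos <- any(c(models_mode, models_mean) %in%
                  c("CoS", "CoS_noLI", "CoS_noPT", "CoS_noLIPT",
                    "CoS_noPrior"))
  need_io <- "IO" %in% c(models_mode, models_mean)
  if (need_cos && is.null(ens_cache)) {
    stop("CoS models need an ensemble_cache", call. = FALSE)
  }
  if (need_io && is.null(io_est)) {
    stop("IO models need an io_cache", call. = FALSE)
  }
  moment_ids <- c("GT", "MoMe", "MeSk", "MoSk", "MoMeSk")
  if (is.null(stats) &&
      any(c(models_mode, models_mean) %in% moment_ids)) {
    stats <- true_stats(stimuli)
  }
  subjects <- sort(unique(responses$subject))
  records <- list()
  add <- function(f) records[[length(records) + 1L]] <<- f

  lesion_spec <- list(
    CoS        = cos_lesions(TRUE, TRUE, TRUE),
    CoS_noLI   = cos_lesions(TRUE, FALSE, TRUE),
    CoS_noPT   = cos_lesions(FALSE, TRUE, TRUE),
    CoS_noLIPT = cos_lesions(FALSE, FALSE, TRUE),
    CoS_noPrior = cos_lesions(TRUE, TRUE, FALSE)
  )

  for (s in subjects) {
    rs <- responses[responses$subject == s, ]
    rs <- rs[order(rs$trial), ]
    seed_s <- seed_child(rng_seed, 61L, s)
    cos_mode_fit <- NULL
    io_mode_fit <- NULL
    if (need_cos) {
      cos_mode_fit <- fit_cos_mode(rs$y_mode, ens_cache, subject_id = s,
                                   n_starts = n_starts,
                                   rng_seed = seed_s, maxit = maxit)
    }
    if (need_io) {
      io_mode_fit <- fit_io(rs$y_mode, io_est, "mode", subject_id = s,
                            rng_seed = seed_s)
    }
    for (m in models_mode) {
      if (m == "CoS") add(cos_mode_fit)
      else if (m == "IO") add(io_mode_fit)
      else add(fit_moment_model(rs$y_mode, m, stats, "mode",
                                subject_id = s))
    }
    if (length(models_mean)) {
      gi <- if (need_cos) {
        which.min(abs(ens_cache$gammas - cos_mode_fit$grid_value))
      } else NA_integer_
      for (m in models_mean) {
        if (m %in% names(lesion_spec)) {
          add(fit_cos_mean(rs$y_mean, rs$y_mode, ens_cache$ens[[gi]],
                           cos_mode_fit, lesions = lesion_spec[[m]],
                           model_id = m, subject_id = s,
                           n_starts = n_starts, rng_seed = seed_s,
                           maxit = maxit))
        } else if (m == "IO") {
          add(fit_io(rs$y_mean, io_est, "mean", mode_fit = io_mode_fit,
                     subject_id = s, rng_seed = seed_s))
        } else if (m == "SW") {
          add(fit_sw_mean(rs$y_mean, stimuli, subject_id = s,
                          n_starts = n_starts, rng_seed = seed_s,
                          maxit = maxit))
        } else {
          add(fit_moment_model(rs$y_mean, m, stats, "mean",
                               subject_id = s))
        }
      }
    }
  }
  list(fits = fits_to_df(records), records = records)
}

#' Model comparison summary for one task
#'
#' Computes per-model summed delta-AICc and the group-level
#' random-effects selection (expected frequencies, exceedance and
#' protected exceedance probabilities) from a cohort's fit table, using
#' -AICc/2 as the per-subject log model evidence.
#'
#' @param fits fit data frame from \code{\link{fit_cohort}}
#' @param task "mode" or "mean"
#' @param rng_seed seed for the exceedance-probability sampler
#' @return list with \code{summed_delta_aicc} and \code{bms}
#' @export
compare_models <- function(fits, task = c("mode", "mean"),
                           rng_seed = 1L) {
  task <- match.arg(task)
  ft <- fits[fits$task == task, ]
  da <- delta_aicc(ft)
  lme <- tapply(-ft$aicc / 2, list(ft$subject, ft$model), identity)
  bms <- group_bms(lme, rng_seed = rng_seed)
  list(summed_delta_aicc = da$summed, delta = da$delta, bms = bms)
}

#' End-to-end model- and parameter-recovery run
#'
#' Simulates a cohort from a chosen generator, fits the requested model
#' sets to both tasks, and summarises model comparison per task. Used as
#' the package's recovery harness: a cohort generated by the CoS observer
#' should be best recovered by the CoS model, and the fitted parameters
#' should track the generating ones.
#'
#' @param stimuli shared \code{\link{sample_stimuli}}
#' @param generator,params,n_subjects see \code{\link{simulate_cohort}}
#' @param gamma_grid grid for the CoS distance scale
#' @param alpha_c_grid grid for the ideal-observer concentration shape
#'   (NULL drops the IO model)
#' @param R Monte-Carlo clusterings per ensemble
#' @param dpmm dpmm_config for the ideal observer
#' @param models_mode,models_mean model sets (defaults: full set)
#' @param n_starts,maxit optimisation controls
#' @param rng_seed master seed; the whole run is reproducible from it
#' @return list with \code{responses}, \code{fits}, \code{records},
#'   \code{mode}/\code{mean} comparison summaries, \code{stats}, and the
#'   generating \code{subject_params}
#' @export
run_recovery <- function(stimuli, generator = "cos",
                         params = cohort_params(), n_subjects = 8L,
                         gamma_grid = c(0.02, 0.05, 0.1, 0.2, 0.35, 0.5,
                                        0.75, 1, 1.5, 2),
                         alpha_c_grid = c(0.5, 1.5, 3),
                         R = 200L, dpmm = dpmm_config(),
                         models_mode = NULL, models_mean = NULL,
                         n_starts = 4L, maxit = 400L, rng_seed = 1L) {
  include_io <- !is.null(alpha_c_grid)
  if (is.null(models_mode)) {
    models_mode <- c("GT", if (include_io) "IO", "MoMe", "MeSk", "MoSk",
                     "MoMeSk", "CoS")
  }
  if (is.null(models_mean)) {
    models_mean <- c("GT", if (include_io) "IO", "MoMe", "MeSk", "MoSk",
                     "MoMeSk", "CoS", "SW")
  }
  stats <- true_stats(stimuli)
  responses <- simulate_cohort(stimuli, n_subjects, generator, params,
                               stats = stats,
                               rng_seed = seed_child(rng_seed, 67L))
  ens <- if (any(grepl("^CoS", c(models_mode, models_mean)))) {
    ensemble_cache(stimuli, gamma_grid, R = R,
                   rng_seed = seed_child(rng_seed, 71L))
  } else NULL
  io_est <- if (include_io && "IO" %in% c(models_mode, models_mean)) {
    io_cache(stimuli, alpha_c_grid, dpmm,
             rng_seed = seed_child(rng_seed, 73L))
  } else NULL
  fc <- fit_cohort(responses, stimuli, models_mode, models_mean,
                   ens_cache = ens, io_est = io_est, stats = stats,
                   n_starts = n_starts, maxit = maxit,
                   rng_seed = seed_child(rng_seed, 79L))
  list(
    responses = responses, fits = fc$fits, records = fc$records,
    mode = compare_models(fc$fits, "mode",
                          rng_seed = seed_child(rng_seed, 83L)),
    mean = compare_models(fc$fits, "mean",
                          rng_seed = seed_child(rng_seed, 89L)),
    stats = stats,
    subject_params = attr(responses, "subject_params"),
    ens_cache = ens
  )
}

#' Behavioural error summary by condition
#'
#' Per (task, shape condition, weight condition) cell: the mean signed
#' error (response minus the trial's true statistic), first averaged
#' within subject and then across subjects, with the between-subject
#' standard error. Weight conditions are ordered by increasing global
#' skewness (the mean true skewness of their trials), matching the
#' conventional abscissa for these designs.
#'
#' @param responses cohort data frame (subject, trial, y_mode, y_mean)
#' @param stats per-trial \code{\link{true_stats}}
#' @param design the \code{\link{build_design}}
#' @return data frame with columns task, shape, weight_label,
#'   global_skew, mean_error, se, n_subjects; weight_label is a factor
#'   ordered by global skewness
#' @export
error_summary <- function(responses, stats, design) {
  tr <- design$trials
  df <- merge(responses, stats, by = "trial")
  df <- merge(df, tr[, c("trial", "shape", "weight_label")], by = "trial")
  df$err_mode <- df$y_mode - df$true_mode
  df$err_mean <- df$y_mean - df$true_mean
  sk <- tapply(stats$true_skewness[tr$trial], tr$weight_label, mean)
  lev <- names(sort(sk))
  out <- list()
  for (task in c("mode", "mean")) {
    v <- if (task == "mode") df$err_mode else df$err_mean
    per_subj <- aggregate(
      v, by = list(subject = df$subject, shape = df$shape,
                   weight_label = df$weight_label), FUN = mean)
    cell <- aggregate(per_subj$x,
                      by = list(shape = per_subj$shape,
                                weight_label = per_subj$weight_label),
                      FUN = function(z) c(mean(z), sd(z) / sqrt(length(z)),
                                          length(z)))
    out[[task]] <- data.frame(
      task = task, shape = cell$shape, weight_label = cell$weight_label,
      global_skew = as.numeric(sk[cell$weight_label]),
      mean_error = cell$x[, 1], se = cell$x[, 2],
      n_subjects = cell$x[, 3], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$weight_label <- factor(res$weight_label, levels = lev,
                             ordered = TRUE)
  rownames(res) <- NULL
  res
}

#' Lesion battery for the CoS Mean model
#'
#' Fits the full CoS Mean model, its four lesioned variants (without
#' lateral inhibition, without the power transform, without both, without
#' the Mode-derived clustering posterior) and the no-clustering
#' subjective-weighting model to every subject's Mean responses, and
#' summarises the comparison.
#'
#' @inheritParams fit_cohort
#' @return list with \code{fits}, \code{summary}
#'   (\code{\link{compare_models}} output for the Mean task)
#' @export
lesion_battery <- function(responses, stimuli, ens_cache, stats = NULL,
                           n_starts = 4L, rng_seed = 1L, maxit = 400L) {
  battery <- c("CoS", "CoS_noLI", "CoS_noPT", "CoS_noLIPT", "CoS_noPrior",
               "SW")
  fc <- fit_cohort(responses, stimuli, models_mode = character(0),
                   models_mean = battery, ens_cache = ens_cache,
                   stats = stats, n_starts = n_starts,
                   rng_seed = rng_seed, maxit = maxit)
  list(fits = fc$fits,
       summary = compare_models(fc$fits, "mean",
                                rng_seed = seed_child(rng_seed, 97L)))
}

#' Multimodality check of joint Mode/Mean responses
#'
#' Fits bivariate Gaussian mixtures with 1..max_components full-covariance
#' components to the joint (Mode, Mean) responses of each condition and
#' selects the number of components by the integrated completed likelihood
#' (ICL) criterion, which penalises uncertain assignments. A selected
#' count above 1 flags a multimodal response distribution — the signature
#' that separates clustering-based observers from moment observers.
#'
#' @param responses data frame with columns y_mode, y_mean and a grouping
#'   column named \code{condition}
#' @param max_components largest number of mixture components tried
#' @return data frame with columns condition, n_components, icl,
#'   icl_1, multimodal (ICL prefers >1 component), n
#' @importFrom mclust mclustICL mclustBIC Mclust
#' @export
icl_multimodality <- function(responses, max_components = 3L) {
  stopifnot(all(c("y_mode", "y_mean", "condition") %in% names(responses)))
  conds <- unique(responses$condition)
  rows <- lapply(conds, function(cc) {
    d <- responses[responses$condition == cc, c("y_mode", "y_mean")]
    if (nrow(d) < 10L) {
      stop("need at least 10 response pairs per condition", call. = FALSE)
    }
    icl <- suppressWarnings(
      mclust::mclustICL(d, G = seq_len(max_components),
                        modelNames = "VVV", verbose = FALSE)
    )
    vals <- icl[seq_len(max_components), "VVV"]
    g <- which.max(vals)
    data.frame(condition = cc, n_components = g,
               icl = vals[g], icl_1 = vals[1L],
               multimodal = g > 1L && vals[g] > vals[1L],
               n = nrow(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
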