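#' Average causal effect from counterfactual predictions
#'
#' The G-computation estimator: the arithmetic mean of the per-individual
#' differences between the predicted outcome probability under exposure and
#' under non-exposure.
#'
#' @param y1_hat predicted outcome probabilities with exposure set to 1.
#' @param y0_hat predicted outcome probabilities with exposure set to 0.
#' @return the estimated ACE, a risk difference in [-1, 1].
#' @export
estimate_ace <- function(y1_hat, y0_hat) {
  if (length(y1_hat) == 0) stop("empty counterfactual predictions", call. = FALSE)
  if (length(y1_hat) != length(y0_hat))
    stop("counterfactual prediction lengths differ", call. = FALSE)
  mean(y1_hat - y0_hat)
}

# fit the configured Q-model (single learner or SL) on a cohort;
# fixed_params skips tuning (bootstrap path)
.fit_qmodel <- function(cohort, config, seed, fixed_params = NULL,
                        allow_reduce = FALSE) {
  # resampling refits (fixed_params set) skip the provenance table
  design <- fit_design(cohort, config$design,
                       with_meta = is.null(fixed_params))
  if (config$learner_id == "SL") {
    plan <- cv_plan(cohort$outcome, v = config$n_folds, seed = seed,
                    allow_reduce = allow_reduce)
    model <- fit_superlearner(design, cohort$outcome,
                              library = config$sl_library, plan = plan,
                              grid_length = config$grid_length, seed = seed,
                              combine = config$sl_combine,
                              fixed_params = fixed_params)
  } else if (!is.null(fixed_params)) {
    fit <- .fit_backend(config$learner_id, design$matrix, cohort$outcome,
                        fixed_params, seed = seed, design = design)
    model <- structure(list(learner_id = config$learner_id,
                            chosen_params = fixed_params, fit = fit,
                            cv_auc = NA_real_, seed = as.integer(seed)),
                       class = "gcml_model")
  } else {
    spec <- learner_spec(config$learner_id)
    if (length(spec$params) == 0) {
      fit <- .fit_backend(config$learner_id, design$matrix, cohort$outcome,
                          list(), seed = seed, design = design)
      model <- structure(list(learner_id = config$learner_id,
                              chosen_params = list(), fit = fit,
                              cv_auc = NA_real_, seed = as.integer(seed)),
                         class = "gcml_model")
    } else {
      plan <- cv_plan(cohort$outcome, v = config$n_folds, seed = seed,
                      allow_reduce = allow_reduce)
      model <- tune_learner(design, cohort$outcome, spec, plan,
                            grid_length = config$grid_length, seed = seed)
    }
  }
  list(design = design, model = model)
}

.counterfactuals <- function(fitted, cohort) {
  X1 <- transform_design(fitted$design, cohort, "all_one")
  X0 <- transform_design(fitted$design, cohort, "all_zero")
  list(y1_hat = predict_proba(fitted$model, X1),
       y0_hat = predict_proba(fitted$model, X0))
}

#' G-computation point estimate
#'
#' Fits the configured Q-model on the full cohort (with tuning-parameter
#' selection by cross-validated AUC), predicts each individual's outcome
#' probability with the exposure set to 1 and to 0 while keeping the
#' covariates at their observed values, and averages the differences.
#'
#' @param cohort a \code{gcml_cohort}.
#' @param config a \code{gcml_config}.
#' @return list with \code{model} (the fitted Q-model), \code{design},
#'   \code{y1_hat}, \code{y0_hat} and \code{ace_hat}.
#' @export
gc_point_estimate <- function(cohort, config) {
  stopifnot(inherits(cohort, "gcml_cohort"), inherits(config, "gcml_config"))
  fitted <- .fit_qmodel(cohort, config, seed = config$seed)
  cf <- .counterfactuals(fitted, cohort)
  list(model = fitted$model, design = fitted$design,
       y1_hat = cf$y1_hat, y0_hat = cf$y0_hat,
       ace_hat = estimate_ace(cf$y1_hat, cf$y0_hat))
}

# bootstrap index draw; exposed internally so the out-of-bag geometry can
# be studied in isolation
.boot_indices <- function(n) sample.int(n, n, replace = TRUE)

.subset_cohort <- function(cohort, idx) {
  # column-wise subset avoids rowname deduplication on resampled rows
  cov_sub <- lapply(cohort$covariates, `[`, idx)
  attributes(cov_sub) <- list(names = names(cohort$covariates),
                              class = "data.frame",
                              row.names = seq_along(idx))
  structure(list(outcome = cohort$outcome[idx],
                 exposure = cohort$exposure[idx],
                 covariates = cov_sub,
                 covariate_types = cohort$covariate_types,
                 row_id = cohort$row_id[idx],
                 n = length(idx), k = cohort$k),
            class = "gcml_cohort")
}

#' Bootstrap cross-validation variance of the ACE
#'
#' Tuning parameters are chosen once on the entire sample and frozen. Then,
#' for each of B iterations, n rows are drawn with replacement, the Q-model
#' is retrained on the bootstrap sample (for the super learner the members
#' are refit and the ensemble weights re-estimated at the frozen tuning
#' parameters, unless \code{sl_freeze_weights}), and the ACE is estimated
#' on the out-of-bag individuals only — the rows not drawn — which guards
#' the variance estimate against overfitting. The standard error is the
#' sample SD of the B draws; the confidence interval is the percentile
#' interval by default.
#'
#' Resamples in which the outcome or the exposure collapses to a single
#' class, or whose out-of-bag set is empty, are redrawn (at most 100
#' attempts per iteration); redraws are counted in the result.
#'
#' @param cohort a \code{gcml_cohort}.
#' @param config a \code{gcml_config}; \code{config$n_boot} is B.
#' @param point optional result of \code{\link{gc_point_estimate}} on the
#'   same cohort/config (recomputed if missing); supplies the frozen
#'   tuning parameters and the reported point estimate.
#' @return object of class \code{gcml_ace} with \code{ace_hat} (full-sample
#'   estimate), \code{boot_draws}, \code{se}, \code{ci_lo}, \code{ci_hi},
#'   \code{ci_level}, \code{n_boot_completed}, \code{n_redraws},
#'   \code{learner_id}, \code{seed}.
#' @export
bootstrap_ace <- function(cohort, config, point = NULL) {
  stopifnot(inherits(cohort, "gcml_cohort"), inherits(config, "gcml_config"))
  if (is.null(point)) point <- gc_point_estimate(cohort, config)
  fixed <- if (config$learner_id == "SL") {
    lapply(point$model$members, function(m) m$chosen_params)
  } else {
    point$model$chosen_params
  }
  frozen_weights <- if (config$learner_id == "SL" && config$sl_freeze_weights)
    point$model$weights else NULL
  B <- config$n_boot
  n <- cohort$n
  draws <- numeric(B)
  redraws <- 0L
  set.seed(config$seed)
  for (b in seq_len(B)) {
    ok <- FALSE
    for (attempt in seq_len(100)) {
      idx <- .boot_indices(n)
      oob <- setdiff(seq_len(n), unique(idx))
      ys <- cohort$outcome[idx]; zs <- cohort$exposure[idx]
      if (length(oob) > 0 && length(unique(ys)) == 2 &&
          length(unique(zs)) == 2) { ok <- TRUE; break }
      redraws <- redraws + 1L
    }
    if (!ok)
      stop("bootstrap iteration ", b,
           ": 100 consecutive degenerate resamples", call. = FALSE)
    boot_cohort <- .subset_cohort(cohort, idx)
    fitted <- .fit_qmodel(boot_cohort, config,
                          seed = config$seed + 7919L * b,
                          fixed_params = fixed, allow_reduce = TRUE)
    if (!is.null(frozen_weights)) fitted$model$weights <- frozen_weights
    oob_cohort <- .subset_cohort(cohort, oob)
    cf <- .counterfactuals(fitted, oob_cohort)
    draws[b] <- estimate_ace(cf$y1_hat, cf$y0_hat)
  }
  alpha <- 1 - config$ci_level
  if (config$ci_type == "percentile") {
    ci <- stats::quantile(draws, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    ci <- point$ace_hat + c(-1, 1) * z * stats::sd(draws)
    ci <- pmin(pmax(ci, -1), 1)
  }
  structure(list(ace_hat = point$ace_hat,
                 boot_draws = draws,
                 se = stats::sd(draws),
                 ci_lo = ci[1], ci_hi = ci[2],
                 ci_level = config$ci_level,
                 n_boot_completed = B,
                 n_redraws = redraws,
                 learner_id = config$learner_id,
                 seed = config$seed),
            class = "gcml_ace")
}

#' One-call ACE estimation: point estimate plus bootstrap interval
#'
#' @param cohort a \code{gcml_cohort}.
#' @param config a \code{gcml_config}.
#' @return a \code{gcml_ace} (see \code{\link{bootstrap_ace}}), with the
#'   fitted point-estimate object attached as attribute \code{"point"}.
#' @export
gc_estimate <- function(cohort, config) {
  point <- gc_point_estimate(cohort, config)
  est <- bootstrap_ace(cohort, config, point = point)
  attr(est, "point") <- point
  est
}

#' @export
print.gcml_ace <- function(x, ...) {
  cat("gcml ACE estimate (", x$learner_id, ")\n", sep = "")
  cat(sprintf("  ACE = %.4f, SE = %.4f, %g%% CI [%.4f, %.4f]\n",
              x$ace_hat, x$se, 100 * x$ci_level, x$ci_lo, x$ci_hi))
  cat("  bootstrap iterations:", x$n_boot_completed,
      "| redraws:", x$n_redraws, "| seed:", x$seed, "\n")
  invisible(x)
}
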