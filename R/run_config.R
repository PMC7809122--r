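#' Run configuration for an ACE estimation
#'
#' Bundles every analysis choice: which Q-model learner to use, the
#' cross-validation fold count used for tuning, the tuning-grid length, the
#' number of bootstrap iterations for the variance, the confidence level,
#' the master seed, and (for the super learner) the library of members.
#'
#' @param learner_id one of \code{"LLR"} (lasso logistic regression),
#'   \code{"ELR"} (elastic-net), \code{"NN"} (single-hidden-layer neural
#'   network), \code{"SVM"} (radial-kernel support vector machine),
#'   \code{"BCART"} (boosted classification trees), \code{"SL"} (AUC-weighted
#'   super learner) or \code{"GLM"} (plain unpenalized logistic regression on
#'   raw covariates, the correctly-specified comparator).
#' @param n_folds folds for cross-validated tuning (default 10).
#' @param grid_length number of candidate tuning combinations per learner
#'   (default 20).
#' @param n_boot bootstrap iterations for the variance (default 500).
#' @param ci_level confidence level (default 0.95).
#' @param seed master seed; every random draw traces to it.
#' @param sl_library super-learner members, a subset of
#'   \code{c("LLR","ELR","NN","SVM")}; boosted trees are excluded from the
#'   ensemble for computational reasons.
#' @param design a \code{\link{design_spec}}; defaults depend on the learner
#'   (\code{GLM} uses a plain main-effects design, all others the flexible
#'   spline + interaction design).
#' @param ci_type \code{"percentile"} (default) or \code{"normal"}.
#' @param sl_freeze_weights if TRUE, super-learner weights estimated on the
#'   full sample are reused in every bootstrap resample instead of being
#'   re-estimated (default FALSE: weights are re-estimated per resample,
#'   member tuning parameters stay frozen either way).
#' @param sl_combine \code{"logit"} (default: convex combination of member
#'   logits) or \code{"prob"} (probability-scale averaging).
#' @return an object of class \code{gcml_config}.
#' @export
run_config <- function(learner_id = "SL",
                       n_folds = 10L,
                       grid_length = 20L,
                       n_boot = 500L,
                       ci_level = 0.95,
                       seed = 1L,
                       sl_library = c("LLR", "ELR", "NN", "SVM"),
                       design = NULL,
                       ci_type = c("percentile", "normal"),
                       sl_freeze_weights = FALSE,
                       sl_combine = c("logit", "prob")) {
  ci_type <- match.arg(ci_type)
  sl_combine <- match.arg(sl_combine)
  known <- c("LLR", "ELR", "NN", "SVM", "BCART", "SL", "GLM")
  if (!(length(learner_id) == 1 && learner_id %in% known))
    stop("unknown learner_id '", learner_id, "'; must be one of ",
         paste(known, collapse = ", "), call. = FALSE)
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  if (grid_length < 1) stop("grid_length must be >= 1", call. = FALSE)
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  if (!(ci_level > 0 && ci_level < 1))
    stop("ci_level must be in (0,1)", call. = FALSE)
  if (length(sl_library) == 0)
    stop("sl_library must be non-empty", call. = FALSE)
  if (!all(sl_library %in% c("LLR", "ELR", "NN", "SVM")))
    stop("sl_library must be a subset of LLR, ELR, NN, SVM ",
         "(BCART is excluded from the ensemble)", call. = FALSE)
  if (is.null(design)) {
    design <- if (learner_id == "GLM") {
      design_spec(spline_df = 0L, include_interactions = FALSE)
    } else {
      design_spec()
    }
  }
  structure(list(learner_id = learner_id,
                 n_folds = as.integer(n_folds),
                 grid_length = as.integer(grid_length),
                 n_boot = as.integer(n_boot),
                 ci_level = ci_level,
                 seed = as.integer(seed),
                 sl_library = sl_library,
                 design = design,
                 ci_type = ci_type,
                 sl_freeze_weights = isTRUE(sl_freeze_weights),
                 sl_combine = sl_combine),
            class = "gcml_config")
}

#' Read a run configuration from a flat YAML file
#'
#' The file mirrors the fields of \code{\link{run_config}}; absent fields
#' take the documented defaults.
#'
#' @param path YAML file path.
#' @return a \code{gcml_config}.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  allowed <- c("learner_id", "n_folds", "grid_length", "n_boot", "ci_level",
               "seed", "sl_library", "ci_type", "sl_freeze_weights",
               "sl_combine")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(run_config, raw)
}

#' @export
print.gcml_config <- function(x, ...) {
  cat("gcml run config\n")
  cat("  learner:", x$learner_id,
      if (x$learner_id == "SL")
        paste0("(library: ", paste(x$sl_library, collapse = ", "), ")")
      else "", "\n")
  cat("  tuning: ", x$n_folds, "-fold CV, grid length ", x$grid_length, "\n",
      sep = "")
  cat("  bootstrap:", x$n_boot, "iterations,",
      paste0(100 * x$ci_level, "% "), x$ci_type, "CI\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
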