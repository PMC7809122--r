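#' Estimate AUC-maximising super-learner weights
#'
#' Finds simplex-constrained weights for the convex combination of member
#' scores that maximise the AUC against the outcome. Because the AUC is a
#' piecewise-constant, gradient-free objective, the search is a seeded
#' multi-start over the simplex: every vertex (each single member), the
#' uniform point, random Dirichlet draws, and a Nelder-Mead polish on the
#' softmax parameterisation started from the best candidate. Ties (within
#' 1e-12 of the best AUC) are broken towards the weight vector closest to
#' uniform, so identical members yield uniform weights.
#'
#' @param scores n x m matrix of member scores (logits or probabilities;
#'   the AUC only uses their ranks after combination).
#' @param labels 0/1 outcome vector.
#' @param seed integer seed for the random starts.
#' @param n_starts number of random Dirichlet starts (default 25).
#' @return list with \code{weights} (sums to one, all non-negative) and
#'   \code{auc} of the combination.
#' @export
optimize_sl_weights <- function(scores, labels, seed = 1L, n_starts = 25L) {
  scores <- as.matrix(scores)
  m <- ncol(scores)
  obj <- function(w) auc(as.numeric(scores %*% w), labels)
  cands <- c(lapply(seq_len(m), function(j) { w <- numeric(m); w[j] <- 1; w }),
             list(rep(1 / m, m)))
  if (m > 1) {
    set.seed(seed)
    for (i in seq_len(n_starts)) {
      g <- stats::rexp(m)
      cands[[length(cands) + 1]] <- g / sum(g)
    }
  }
  aucs <- vapply(cands, obj, numeric(1))
  best <- which.max(aucs)
  if (m > 1) {
    # polish from the best start on the softmax scale
    softmax <- function(t) { e <- exp(t - max(t)); e / sum(e) }
    theta0 <- log(pmax(cands[[best]], 1e-3))
    opt <- stats::optim(theta0, function(t) -obj(softmax(t)),
                        method = "Nelder-Mead",
                        control = list(maxit = 200L, reltol = 1e-10))
    cands[[length(cands) + 1]] <- softmax(opt$par)
    aucs <- c(aucs, -opt$value)
  }
  top <- max(aucs)
  tied <- which(aucs >= top - 1e-12)
  uni <- rep(1 / m, m)
  dist_to_uni <- vapply(tied, function(i) sum((cands[[i]] - uni)^2), numeric(1))
  pick <- tied[which.min(dist_to_uni)]
  list(weights = cands[[pick]], auc = aucs[pick])
}

#' Fit the AUC-weighted super learner
#'
#' Tunes each library member by cross-validated AUC on a shared fold plan,
#' collects their out-of-fold predictions at the chosen tuning parameters,
#' and estimates simplex weights by maximising the AUC of the convex
#' combination of the out-of-fold member logits (or probabilities, per
#' \code{combine}). Members are refit on all rows for prediction.
#'
#' @param design a fitted \code{gcml_design}.
#' @param outcome 0/1 vector.
#' @param library character vector of member learner ids (subset of LLR,
#'   ELR, NN, SVM) or a list of \code{gcml_learner_spec}s.
#' @param plan shared \code{gcml_cv_plan}.
#' @param grid_length tuning candidates per member.
#' @param seed integer seed.
#' @param combine \code{"logit"} (default) or \code{"prob"}.
#' @param fixed_params optional named list (by member id) of tuning
#'   parameters to reuse instead of re-tuning — used inside the bootstrap,
#'   where tuning parameters are frozen from the full sample.
#' @return object of class \code{gcml_sl}: \code{members} (named list of
#'   \code{gcml_model}), \code{weights}, \code{cv_auc} (out-of-fold AUC of
#'   the combination), \code{combine}.
#' @export
fit_superlearner <- function(design, outcome, library = c("LLR", "ELR", "NN", "SVM"),
                             plan, grid_length = 20L, seed = 1L,
                             combine = c("logit", "prob"),
                             fixed_params = NULL) {
  combine <- match.arg(combine)
  if (is.character(library)) library <- lapply(library, learner_spec)
  if (length(library) == 0) stop("super-learner library is empty", call. = FALSE)
  ids <- vapply(library, function(s) s$learner_id, character(1))
  if (any(ids == "BCART"))
    stop("BCART is excluded from the super-learner library", call. = FALSE)
  members <- vector("list", length(library))
  names(members) <- ids
  for (i in seq_along(library)) {
    if (!is.null(fixed_params) && ids[i] %in% names(fixed_params)) {
      members[[i]] <- .cv_fit_fixed(design, outcome, library[[i]],
                                    fixed_params[[ids[i]]], plan,
                                    seed = seed + i)
    } else {
      members[[i]] <- tune_learner(design, outcome, library[[i]], plan,
                                   grid_length = grid_length, seed = seed + i)
    }
  }
  P <- vapply(members, function(m) m$cv_predictions, numeric(length(outcome)))
  S <- if (combine == "logit") stats::qlogis(P) else P
  w <- optimize_sl_weights(S, outcome, seed = seed)
  structure(list(members = members, weights = w$weights, cv_auc = w$auc,
                 combine = combine, seed = as.integer(seed)),
            class = "gcml_sl")
}

# fit at fixed tuning parameters but still collect out-of-fold predictions
# (needed for weight re-estimation inside bootstrap resamples)
.cv_fit_fixed <- function(design, outcome, spec, params, plan, seed = 1L) {
  M <- design$matrix
  oof <- rep(NA_real_, length(outcome))
  for (f in seq_len(plan$v)) {
    tr <- plan$fold != f
    m <- .fit_backend(spec$learner_id, M[tr, , drop = FALSE], outcome[tr],
                      params, seed = seed + 31L * f, design = design)
    oof[!tr] <- .predict_raw(m, M[!tr, , drop = FALSE])
  }
  fit <- .fit_backend(spec$learner_id, M, outcome, params, seed = seed,
                      design = design)
  structure(list(learner_id = spec$learner_id, chosen_params = params,
                 cv_auc = auc(oof, outcome), cv_predictions = .clip(oof),
                 fit = fit, seed = as.integer(seed)),
            class = "gcml_model")
}

#' @export
predict_proba.gcml_sl <- function(model, X) {
  P <- vapply(model$members, function(m) predict_proba(m, X),
              numeric(nrow(X)))
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  if (model$combine == "logit") {
    .clip(stats::plogis(as.numeric(stats::qlogis(P) %*% model$weights)))
  } else {
    .clip(as.numeric(P %*% model$weights))
  }
}

#' @export
print.gcml_sl <- function(x, ...) {
  cat("gcml super learner | out-of-fold AUC =", round(x$cv_auc, 4), "\n")
  cat("  weights:",
      paste(names(x$members), round(x$weights, 3), sep = " = ",
            collapse = ", "), "\n")
  invisible(x)
}
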