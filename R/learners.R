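#' Candidate Q-model learners and their tuning ranges
#'
#' Returns the tuning specification of one of the candidate learners. The
#' ranges are package defaults (configurable via \code{override}):
#' penalties and SVM cost are searched on a log scale, the neural-network
#' hidden-layer size over consecutive integers, and the SVM kernel width as
#' a multiplier of the median-heuristic width computed from the training
#' data.
#'
#' @param learner_id one of \code{"LLR"}, \code{"ELR"}, \code{"NN"},
#'   \code{"SVM"}, \code{"BCART"}, \code{"GLM"}.
#' @param override named list of range overrides, each a length-2 numeric
#'   \code{c(min, max)}.
#' @return object of class \code{gcml_learner_spec} with \code{learner_id},
#'   \code{params} (named list of ranges with scale and integrality) and
#'   \code{complexity} (parameter ordering used to break tuning ties
#'   towards the least complex model).
#' @export
learner_spec <- function(learner_id, override = list()) {
  ranges <- switch(
    learner_id,
    GLM = list(),
    # penalty strength; larger lambda = simpler model
    LLR = list(lambda = list(range = c(1e-4, 1e2), scale = "log",
                             integer = FALSE, simpler = "high")),
    ELR = list(lambda = list(range = c(1e-4, 1e2), scale = "log",
                             integer = FALSE, simpler = "high"),
               alpha = list(range = c(0, 1), scale = "linear",
                            integer = FALSE, simpler = "high")),
    NN = list(size = list(range = c(1, 20), scale = "linear",
                          integer = TRUE, simpler = "low")),
    SVM = list(cost = list(range = c(2^-5, 2^10), scale = "log",
                           integer = FALSE, simpler = "low"),
               sigma_mult = list(range = c(2^-3, 2^3), scale = "log",
                                 integer = FALSE, simpler = "low")),
    BCART = list(n_trees = list(range = c(50, 1000), scale = "linear",
                                integer = TRUE, simpler = "low"),
                 depth = list(range = c(1, 4), scale = "linear",
                              integer = TRUE, simpler = "low"),
                 learning_rate = list(range = c(0.001, 0.3), scale = "log",
                                      integer = FALSE, simpler = "low"),
                 min_node = list(range = c(5, 20), scale = "linear",
                                 integer = TRUE, simpler = "high")),
    stop("unknown learner_id '", learner_id, "'", call. = FALSE))
  for (nm in names(override)) {
    if (!nm %in% names(ranges))
      stop("no tunable parameter '", nm, "' for ", learner_id, call. = FALSE)
    stopifnot(length(override[[nm]]) == 2)
    ranges[[nm]]$range <- as.numeric(override[[nm]])
  }
  for (nm in names(ranges)) {
    r <- ranges[[nm]]$range
    if (ranges[[nm]]$scale == "log" && any(r <= 0))
      stop("range of '", nm, "' must be strictly positive", call. = FALSE)
    if (r[1] > r[2]) stop("range of '", nm, "' is reversed", call. = FALSE)
  }
  structure(list(learner_id = learner_id, params = ranges),
            class = "gcml_learner_spec")
}

#' Build a tuning grid
#'
#' Single-parameter learners get \code{grid_length} distinct values
#' spanning the range: log-spaced for penalties/cost/kernel width,
#' consecutive integers for the hidden-layer size. Multi-parameter learners
#' get \code{grid_length} combinations by a seeded Latin-hypercube over the
#' ranges (per-parameter Cartesian products would explode for the
#' four-parameter boosted trees). \code{grid_length = 1} yields the range
#' midpoints. Deterministic given the seed.
#'
#' @param spec a \code{gcml_learner_spec}.
#' @param grid_length number of candidate combinations.
#' @param seed integer seed for the Latin-hypercube draw.
#' @return data.frame, one row per candidate combination.
#' @export
make_tuning_grid <- function(spec, grid_length = 20L, seed = 1L) {
  stopifnot(inherits(spec, "gcml_learner_spec"), grid_length >= 1)
  p <- spec$params
  if (length(p) == 0) return(data.frame(.empty = NA)[, 0, drop = FALSE][1, , drop = FALSE])
  from_unit <- function(u, par) {
    r <- par$range
    v <- if (par$scale == "log") exp(log(r[1]) + u * (log(r[2]) - log(r[1])))
         else r[1] + u * (r[2] - r[1])
    if (par$integer) v <- round(v)
    v
  }
  if (grid_length == 1) {
    g <- as.data.frame(lapply(p, function(par) from_unit(0.5, par)))
    names(g) <- names(p)
    return(g)
  }
  if (length(p) == 1) {
    par <- p[[1]]
    v <- if (par$integer) {
      lo <- round(par$range[1])
      seq(lo, by = 1L, length.out = grid_length)  # consecutive integer sizes
    } else {
      from_unit(seq(0, 1, length.out = grid_length), par)
    }
    g <- data.frame(v)
    names(g) <- names(p)
    return(g)
  }
  set.seed(seed)
  U <- lhs::randomLHS(grid_length, length(p))
  g <- as.data.frame(mapply(function(u, par) from_unit(u, par),
                            as.data.frame(U), p, SIMPLIFY = FALSE))
  names(g) <- names(p)
  unique(g)
}

# lexicographic complexity key: smaller = simpler; used to break AUC ties
.complexity_key <- function(spec, grid) {
  if (length(spec$params) == 0) return(matrix(0, nrow(grid), 1))
  keys <- sapply(names(spec$params), function(nm) {
    v <- grid[[nm]]
    if (spec$params[[nm]]$simpler == "high") -v else v
  })
  matrix(keys, nrow = nrow(grid))
}

# median-heuristic RBF width: 1 / median squared distance between rows
# (subsampled for large n); deterministic
.sigma0 <- function(X, max_rows = 200L) {
  n <- nrow(X)
  idx <- if (n > max_rows) round(seq(1, n, length.out = max_rows)) else seq_len(n)
  d2 <- as.numeric(stats::dist(X[idx, , drop = FALSE]))^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) m <- 1
  1 / m
}

# --- learner backends -------------------------------------------------------
# fit on a numeric design matrix X and 0/1 outcome y at fixed parameters;
# return an object honouring .predict_raw()

.fit_backend <- function(learner_id, X, y, params, seed = 1L, design = NULL) {
  switch(
    learner_id,
    GLM = {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(`(Intercept)` = 1, X), y,
                       family = stats::binomial(),
                       control = stats::glm.control(epsilon = 1e-12,
                                                    maxit = 100)))
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      structure(list(beta = beta), class = "gcml_fit_glm")
    },
    LLR = .fit_glmnet(X, y, alpha = 1, lambda = params$lambda),
    ELR = .fit_glmnet(X, y, alpha = params$alpha, lambda = params$lambda),
    NN = {
      Xs <- standardize_matrix(design, X)
      set.seed(seed)
      fit <- nnet::nnet(x = Xs, y = y, size = params$size, decay = 1e-4,
                        maxit = 300, entropy = TRUE, trace = FALSE,
                        MaxNWts = 1e5)
      structure(list(fit = fit, design = design), class = "gcml_fit_nn")
    },
    SVM = {
      Xs <- standardize_matrix(design, X)
      sigma <- .sigma0(Xs) * params$sigma_mult
      set.seed(seed)
      fit <- kernlab::ksvm(x = Xs, y = factor(y, levels = c(0, 1)),
                           type = "C-svc", kernel = "rbfdot",
                           kpar = list(sigma = sigma), C = params$cost,
                           prob.model = TRUE)
      structure(list(fit = fit, design = design), class = "gcml_fit_svm")
    },
    BCART = {
      dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
      set.seed(seed)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$depth,
                      eta = params$learning_rate,
                      min_child_weight = params$min_node,
                      nthread = 1),
        data = dtrain, nrounds = params$n_trees, verbose = 0)
      structure(list(fit = fit), class = "gcml_fit_bcart")
    },
    stop("no backend for learner '", learner_id, "'", call. = FALSE))
}

.fit_glmnet <- function(X, y, alpha, lambda) {
  # fit a short decreasing path ending exactly at the target lambda so the
  # prediction at s = lambda is exact, not interpolated
  path <- sort(unique(lambda * c(16, 8, 4, 2, 1)), decreasing = TRUE)
  # coordinate-descent convergence warnings at near-zero penalties are
  # routine on small resamples; the returned path still covers the target
  fit <- suppressWarnings(
    glmnet::glmnet(X, y, family = "binomial", alpha = alpha,
                   lambda = path, standardize = TRUE))
  structure(list(fit = fit, lambda = lambda), class = "gcml_fit_glmnet")
}

.predict_raw <- function(model, X) UseMethod(".predict_raw")

#' @export
.predict_raw.gcml_fit_glm <- function(model, X) {
  as.numeric(stats::plogis(cbind(1, X) %*% model$beta))
}
#' @export
.predict_raw.gcml_fit_glmnet <- function(model, X) {
  as.numeric(stats::predict(model$fit, newx = X, s = model$lambda,
                            type = "response", exact = FALSE))
}
#' @export
.predict_raw.gcml_fit_nn <- function(model, X) {
  as.numeric(stats::predict(model$fit, standardize_matrix(model$design, X)))
}
#' @export
.predict_raw.gcml_fit_svm <- function(model, X) {
  p <- kernlab::predict(model$fit, standardize_matrix(model$design, X),
                        type = "probabilities")
  as.numeric(p[, "1"])
}
#' @export
.predict_raw.gcml_fit_bcart <- function(model, X) {
  as.numeric(stats::predict(model$fit, xgboost::xgb.DMatrix(X, nthread = 1)))
}

#' Predict outcome probabilities from a tuned model or ensemble
#'
#' All outputs are clipped to [1e-6, 1 - 1e-6] so logits stay finite in the
#' super-learner combination. For the super learner, member logits are
#' combined with the simplex weights and passed through the inverse logit
#' (or member probabilities are averaged when the ensemble was built on the
#' probability scale).
#'
#' @param model a \code{gcml_model} (from \code{\link{tune_learner}}) or
#'   \code{gcml_sl} (from \code{\link{fit_superlearner}}).
#' @param X design matrix from \code{\link{transform_design}}.
#' @return vector of probabilities strictly inside (0, 1).
#' @export
predict_proba <- function(model, X) UseMethod("predict_proba")

.clip <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' @export
predict_proba.gcml_model <- function(model, X) {
  if (is.null(model$fit)) stop("model is not fitted", call. = FALSE)
  .clip(.predict_raw(model$fit, X))
}

#' Tune a learner by cross-validated AUC
#'
#' For every candidate combination in the tuning grid, fits the learner on
#' V-1 folds, scores the held-out fold, and averages the AUC over folds.
#' The combination maximising the mean AUC is selected — ties broken
#' towards the least complex combination (largest penalty, smallest network
#' size, smallest cost, fewest trees) — and the learner is refit on all
#' rows at the chosen parameters. For the penalized regressions the whole
#' lambda sub-grid sharing an alpha is fit in one regularisation path per
#' fold.
#'
#' @param design a fitted \code{gcml_design}.
#' @param outcome 0/1 vector aligned with the design rows.
#' @param spec a \code{gcml_learner_spec}.
#' @param plan a \code{gcml_cv_plan} on the same rows.
#' @param grid_length candidates per learner (default 20).
#' @param seed seed controlling the grid draw and stochastic backends.
#' @return object of class \code{gcml_model}: \code{learner_id},
#'   \code{chosen_params}, \code{cv_auc} (mean fold AUC at the chosen
#'   combination), \code{cv_predictions} (out-of-fold predictions at the
#'   chosen combination, aligned to rows), \code{fit} (full-data refit),
#'   \code{grid}, \code{grid_auc}.
#' @export
tune_learner <- function(design, outcome, spec, plan, grid_length = 20L,
                         seed = 1L) {
  stopifnot(inherits(design, "gcml_design"), inherits(plan, "gcml_cv_plan"))
  M <- design$matrix
  if (nrow(M) != length(outcome))
    stop("design and outcome are not aligned", call. = FALSE)
  grid <- make_tuning_grid(spec, grid_length, seed = seed)
  G <- nrow(grid)
  v <- plan$v
  fold_auc <- matrix(NA_real_, G, v)
  oof <- matrix(NA_real_, length(outcome), G)

  glmnet_like <- spec$learner_id %in% c("LLR", "ELR")
  for (f in seq_len(v)) {
    tr <- plan$fold != f
    te <- !tr
    y_te <- outcome[te]
    if (length(unique(y_te)) < 2)
      stop("held-out fold ", f, " has a single outcome class", call. = FALSE)
    if (glmnet_like) {
      alpha_col <- if (spec$learner_id == "LLR") rep(1, G) else grid$alpha
      for (a in unique(alpha_col)) {
        rows <- which(alpha_col == a)
        lams <- grid$lambda[rows]
        path <- sort(unique(lams), decreasing = TRUE)
        fit <- suppressWarnings(
          glmnet::glmnet(M[tr, , drop = FALSE], outcome[tr],
                         family = "binomial", alpha = a, lambda = path,
                         standardize = TRUE))
        P <- stats::predict(fit, newx = M[te, , drop = FALSE], s = lams,
                            type = "response", exact = FALSE)
        for (i in seq_along(rows)) {
          oof[te, rows[i]] <- P[, i]
          fold_auc[rows[i], f] <- auc(P[, i], y_te)
        }
      }
    } else {
      for (g in seq_len(G)) {
        m <- .fit_backend(spec$learner_id, M[tr, , drop = FALSE], outcome[tr],
                          as.list(grid[g, , drop = FALSE]),
                          seed = seed + 31L * f + g, design = design)
        p <- .predict_raw(m, M[te, , drop = FALSE])
        oof[te, g] <- p
        fold_auc[g, f] <- auc(p, y_te)
      }
    }
  }
  mean_auc <- rowMeans(fold_auc)
  best_auc <- max(mean_auc)
  cand <- which(mean_auc >= best_auc - 1e-12)
  if (length(cand) > 1) {
    key <- .complexity_key(spec, grid)[cand, , drop = FALSE]
    ord <- do.call(order, as.data.frame(key))
    cand <- cand[ord]
  }
  best <- cand[1]
  chosen <- as.list(grid[best, , drop = FALSE])
  fit <- .fit_backend(spec$learner_id, M, outcome, chosen,
                      seed = seed, design = design)
  structure(list(learner_id = spec$learner_id,
                 chosen_params = chosen,
                 cv_auc = mean_auc[best],
                 cv_predictions = .clip(oof[, best]),
                 fit = fit,
                 grid = grid,
                 grid_auc = mean_auc,
                 seed = as.integer(seed)),
            class = "gcml_model")
}

#' @export
print.gcml_model <- function(x, ...) {
  cat("gcml tuned model:", x$learner_id,
      "| cv AUC =", round(x$cv_auc, 4), "\n")
  if (length(x$chosen_params))
    cat("  chosen:",
        paste(names(x$chosen_params),
              signif(unlist(x$chosen_params), 4), sep = " = ",
              collapse = ", "), "\n")
  invisible(x)
}
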