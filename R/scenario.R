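#' Define a logit-linear data-generating scenario
#'
#' A scenario lists, in order: covariates (standard-normal or Bernoulli
#' marginals, each optionally depending linearly — on the mean or logit
#' scale — on previously generated covariates, so the graph is acyclic by
#' construction), a logit-linear exposure model, and a logit-linear outcome
#' model whose covariate effects may be linear, centered-quadratic or step
#' functions, plus optional exposure-by-covariate interactions.
#'
#' @param name scenario label.
#' @param covariates list; each element a list with \code{name},
#'   \code{family} (\code{"normal"} or \code{"bernoulli"}),
#'   \code{intercept} (mean shift / logit intercept, default 0) and
#'   \code{dep} (named numeric vector of coefficients on earlier
#'   covariates, default none).
#' @param exposure list with \code{intercept} and \code{coefs} (named
#'   numeric vector on covariates), both on the logit scale.
#' @param outcome list with \code{intercept}, \code{z_coef} (exposure main
#'   effect), \code{terms} (list of \code{list(cov, type, coef,
#'   threshold/center)}, type one of \code{"linear"}, \code{"quadratic"}
#'   — a centered square — or \code{"step"} — an indicator of exceeding
#'   the threshold) and \code{interactions} (list of \code{list(cov,
#'   coef)}, each contributing \code{coef * z * x}).
#' @return object of class \code{gcml_scenario}.
#' @export
scenario_config <- function(name, covariates, exposure, outcome) {
  seen <- character(0)
  for (cv in covariates) {
    stopifnot(is.character(cv$name), cv$family %in% c("normal", "bernoulli"))
    dep <- cv$dep
    if (!is.null(dep) && length(dep)) {
      bad <- setdiff(names(dep), seen)
      if (length(bad))
        stop("covariate '", cv$name, "' depends on '", bad[1],
             "', which is not generated earlier", call. = FALSE)
    }
    seen <- c(seen, cv$name)
  }
  fam <- stats::setNames(vapply(covariates, `[[`, character(1), "family"),
                         vapply(covariates, `[[`, character(1), "name"))
  bad <- setdiff(names(exposure$coefs), names(fam))
  if (length(bad)) stop("exposure model names unknown covariate '", bad[1],
                        "'", call. = FALSE)
  for (tm in outcome$terms) {
    if (!tm$cov %in% names(fam))
      stop("outcome term names unknown covariate '", tm$cov, "'",
           call. = FALSE)
    if (!tm$type %in% c("linear", "quadratic", "step"))
      stop("unknown outcome effect type '", tm$type, "'", call. = FALSE)
    if (tm$type %in% c("quadratic", "step") && fam[tm$cov] != "normal")
      stop("effect type '", tm$type, "' requires a continuous covariate ('",
           tm$cov, "' is ", fam[tm$cov], ")", call. = FALSE)
  }
  for (it in outcome$interactions %||% list())
    if (!it$cov %in% names(fam))
      stop("interaction names unknown covariate '", it$cov, "'", call. = FALSE)
  structure(list(name = name, covariates = covariates, exposure = exposure,
                 outcome = outcome),
            class = "gcml_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.simulate_X <- function(scenario, n) {
  X <- as.data.frame(matrix(0, n, length(scenario$covariates)))
  names(X) <- vapply(scenario$covariates, `[[`, character(1), "name")
  for (cv in scenario$covariates) {
    lp <- rep(cv$intercept %||% 0, n)
    for (nm in names(cv$dep %||% numeric(0)))
      lp <- lp + cv$dep[[nm]] * X[[nm]]
    X[[cv$name]] <- if (cv$family == "normal") {
      stats::rnorm(n, mean = lp, sd = 1)
    } else {
      stats::rbinom(n, 1, stats::plogis(lp))
    }
  }
  X
}

.exposure_linpred <- function(scenario, X) {
  lp <- rep(scenario$exposure$intercept, nrow(X))
  for (nm in names(scenario$exposure$coefs))
    lp <- lp + scenario$exposure$coefs[[nm]] * X[[nm]]
  lp
}

.outcome_linpred <- function(scenario, X, z) {
  out <- scenario$outcome
  lp <- rep(out$intercept, nrow(X)) + out$z_coef * z
  for (tm in out$terms) {
    x <- X[[tm$cov]]
    g <- switch(tm$type,
                linear = x,
                quadratic = (x - (tm$center %||% 0))^2,
                step = as.numeric(x > tm$threshold))
    lp <- lp + tm$coef * g
  }
  for (it in out$interactions %||% list())
    lp <- lp + it$coef * z * X[[it$cov]]
  lp
}

.covariate_types_of <- function(scenario) {
  ifelse(vapply(scenario$covariates, `[[`, character(1), "family") == "normal",
         "continuous", "binary")
}

#' Simulate one cohort from a scenario
#'
#' Draws the covariates sequentially, then the exposure and the outcome
#' from Bernoulli distributions whose logits are the scenario's linear
#' functions of X and (X, Z).
#'
#' @param scenario a \code{gcml_scenario}.
#' @param n sample size (>= 20).
#' @param seed integer seed; the draw is reproducible given the seed.
#' @param max_attempts redraws allowed when a small sample lands with a
#'   single outcome class or exposure group (the cohort contract requires
#'   both present).
#' @return a \code{gcml_cohort} with attributes \code{"seed"} and
#'   \code{"scenario"}.
#' @export
simulate_cohort <- function(scenario, n, seed = 1L, max_attempts = 100L) {
  stopifnot(inherits(scenario, "gcml_scenario"), n >= 20)
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    X <- .simulate_X(scenario, n)
    z <- stats::rbinom(n, 1, stats::plogis(.exposure_linpred(scenario, X)))
    y <- stats::rbinom(n, 1, stats::plogis(.outcome_linpred(scenario, X, z)))
    if (length(unique(z)) == 2 && length(unique(y)) == 2) {
      cohort <- cohort_table(outcome = y, exposure = z, covariates = X,
                             covariate_types = .covariate_types_of(scenario))
      attr(cohort, "seed") <- as.integer(seed)
      attr(cohort, "scenario") <- scenario$name
      return(cohort)
    }
  }
  stop("could not draw a non-degenerate cohort in ", max_attempts,
       " attempts", call. = FALSE)
}

#' Monte-Carlo theoretical ACE of a scenario
#'
#' The scenario's true marginal effect: datasets are generated as in
#' \code{\link{simulate_cohort}} except that the exposure is drawn
#' Bernoulli(\code{z_prob}) independently of the covariates; on each
#' dataset a univariate logistic model of Y on Z alone is fitted and
#' expit(b0 + b1) - expit(b0) recorded; the average over datasets is
#' returned with its Monte-Carlo standard error. (With a binary Z the
#' univariate logistic MLE contrast equals the difference of the two
#' group outcome means exactly, which is how it is computed.)
#'
#' @param scenario a \code{gcml_scenario}.
#' @param n_datasets number of simulated datasets (default 1000).
#' @param n_per_dataset rows per dataset (default 10000).
#' @param z_prob randomised exposure probability (default 0.5).
#' @param seed integer seed.
#' @return list with \code{ace}, \code{mc_se}, \code{n_datasets},
#'   \code{n_skipped} (single-class datasets replaced).
#' @export
theoretical_ace <- function(scenario, n_datasets = 1000L,
                            n_per_dataset = 10000L, z_prob = 0.5, seed = 1L) {
  stopifnot(n_datasets >= 1)
  set.seed(seed)
  vals <- numeric(n_datasets)
  skipped <- 0L
  d <- 1L
  while (d <= n_datasets) {
    X <- .simulate_X(scenario, n_per_dataset)
    z <- stats::rbinom(n_per_dataset, 1, z_prob)
    y <- stats::rbinom(n_per_dataset, 1,
                       stats::plogis(.outcome_linpred(scenario, X, z)))
    if (length(unique(z)) < 2 || length(unique(y)) < 2) {
      skipped <- skipped + 1L
      if (skipped > 100L * n_datasets)
        stop("scenario keeps producing single-class datasets", call. = FALSE)
      next
    }
    # exact MLE of the Y ~ Z univariate logistic contrast
    vals[d] <- mean(y[z == 1]) - mean(y[z == 0])
    d <- d + 1L
  }
  list(ace = mean(vals),
       mc_se = stats::sd(vals) / sqrt(n_datasets),
       n_datasets = n_datasets,
       n_skipped = skipped)
}

#' Deterministic per-replicate seeds
#'
#' Derived from (master seed, replicate index) only — never from execution
#' order — so replicate streams are reproducible and parallelisable.
#'
#' @param master_seed integer.
#' @param n_reps number of replicates.
#' @return integer vector of length \code{n_reps}, all below 2^31.
#' @export
replicate_seeds <- function(master_seed, n_reps) {
  as.integer((as.numeric(master_seed) + 1000003 * seq_len(n_reps)) %% 2147483587L + 1)
}

#' Stream of simulated replicate datasets
#'
#' @param scenario a \code{gcml_scenario}.
#' @param n rows per replicate.
#' @param n_reps number of replicates.
#' @param master_seed master seed from which per-replicate seeds are
#'   derived deterministically.
#' @return list with \code{seeds} and \code{dataset(i)}, a function
#'   returning the i-th replicate cohort.
#' @export
generate_replicates <- function(scenario, n, n_reps, master_seed = 1L) {
  seeds <- replicate_seeds(master_seed, n_reps)
  list(seeds = seeds,
       n_reps = n_reps,
       dataset = function(i) {
         stopifnot(i >= 1, i <= n_reps)
         simulate_cohort(scenario, n, seed = seeds[i])
       })
}

#' @export
print.gcml_scenario <- function(x, ...) {
  cat("gcml scenario '", x$name, "': ", length(x$covariates),
      " covariates\n", sep = "")
  cat("  outcome terms:", length(x$outcome$terms),
      "| interactions:", length(x$outcome$interactions %||% list()),
      "| exposure effect:", x$outcome$z_coef, "\n")
  invisible(x)
}
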