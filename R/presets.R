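#' Shipped simulation scenario presets
#'
#' Two contrasting data-generating mechanisms used throughout the
#' simulation study:
#' \describe{
#'   \item{\code{"realistic"}}{22 sequentially dependent covariates (a mix
#'     of standard-normal and Bernoulli), nine of which enter the outcome
#'     model — four linearly, three as centered quadratics, two as step
#'     functions — plus exactly one exposure-by-covariate interaction.}
#'   \item{\code{"simplistic"}}{nine mutually independent covariates, six
#'     of which enter the outcome model linearly; no interaction.}
#' }
#'
#' The coefficient values shipped here are synthetic: they reproduce the
#' documented structure (counts and types of effects, dependence pattern,
#' realistic marginal prevalences of exposure and outcome) but are this
#' package's own calibration, not transcribed from any external source.
#' The scenario \code{name} carries the \code{"-synthetic"} suffix to make
#' that explicit.
#'
#' @param which \code{"realistic"} or \code{"simplistic"}.
#' @return a \code{gcml_scenario}.
#' @export
scenario_preset <- function(which = c("realistic", "simplistic")) {
  which <- match.arg(which)
  if (which == "simplistic") return(.preset_simplistic())
  .preset_realistic()
}

.norm_cov <- function(name, intercept = 0, dep = NULL)
  list(name = name, family = "normal", intercept = intercept, dep = dep)
.bern_cov <- function(name, intercept = 0, dep = NULL)
  list(name = name, family = "bernoulli", intercept = intercept, dep = dep)

.preset_simplistic <- function() {
  covs <- c(lapply(paste0("X", 1:5), .norm_cov),
            lapply(paste0("X", 6:9), .bern_cov))
  scenario_config(
    name = "simplistic-synthetic",
    covariates = covs,
    exposure = list(intercept = -0.5,
                    coefs = c(X1 = 0.4, X2 = -0.4, X3 = 0.3,
                              X5 = 0.35, X6 = 0.5, X7 = -0.5)),
    outcome = list(
      intercept = -0.9, z_coef = 0.5,
      terms = list(
        list(cov = "X1", type = "linear", coef = 0.5),
        list(cov = "X2", type = "linear", coef = 0.4),
        list(cov = "X3", type = "linear", coef = -0.4),
        list(cov = "X5", type = "linear", coef = 0.3),
        list(cov = "X6", type = "linear", coef = 0.6),
        list(cov = "X8", type = "linear", coef = -0.5)),
      interactions = list()))
}

.preset_realistic <- function() {
  covs <- list(
    .norm_cov("X1"),
    .bern_cov("X2", 0.0, c(X1 = 0.5)),
    .norm_cov("X3", 0, c(X1 = 0.4, X2 = -0.3)),
    .bern_cov("X4", -0.3, c(X3 = 0.4)),
    .norm_cov("X5", 0, c(X2 = 0.5, X4 = 0.3)),
    .norm_cov("X6", 0, c(X5 = 0.3)),
    .bern_cov("X7", 0.2, c(X6 = -0.4, X2 = 0.3)),
    .norm_cov("X8", 0, c(X7 = 0.4, X1 = -0.2)),
    .norm_cov("X9", 0, c(X3 = 0.3, X8 = 0.2)),
    .bern_cov("X10", -0.2, c(X9 = 0.3)),
    .norm_cov("X11", 0, c(X10 = 0.2, X5 = 0.2)),
    .norm_cov("X12", 0, c(X11 = 0.3)),
    .bern_cov("X13", 0.1, c(X12 = 0.3, X4 = -0.3)),
    .norm_cov("X14", 0, c(X13 = 0.2, X9 = 0.3)),
    .norm_cov("X15", 0, c(X14 = 0.25, X7 = -0.2)),
    .bern_cov("X16", -0.1, c(X15 = 0.4)),
    .norm_cov("X17", 0, c(X16 = 0.3, X11 = 0.2)),
    .bern_cov("X18", 0, c(X17 = 0.2)),
    .norm_cov("X19", 0, c(X18 = 0.2, X13 = 0.25)),
    .norm_cov("X20", 0, c(X19 = 0.3)),
    .bern_cov("X21", -0.2, c(X20 = 0.3, X16 = 0.2)),
    .norm_cov("X22", 0, c(X21 = 0.2, X17 = 0.2)))
  scenario_config(
    name = "realistic-synthetic",
    covariates = covs,
    exposure = list(
      intercept = -0.4,
      coefs = c(X1 = 0.35, X3 = 0.3, X5 = -0.3, X6 = 0.3, X8 = 0.25,
                X10 = 0.45, X14 = -0.25, X16 = 0.4, X19 = 0.3, X21 = -0.35)),
    outcome = list(
      intercept = -1.0, z_coef = 0.45,
      terms = list(
        # four linear effects
        list(cov = "X1", type = "linear", coef = 0.4),
        list(cov = "X5", type = "linear", coef = 0.35),
        list(cov = "X10", type = "linear", coef = 0.5),
        list(cov = "X16", type = "linear", coef = -0.45),
        # three centered quadratics
        list(cov = "X3", type = "quadratic", coef = 0.25, center = 0),
        list(cov = "X8", type = "quadratic", coef = -0.2, center = 0),
        list(cov = "X14", type = "quadratic", coef = 0.2, center = 0),
        # two step functions
        list(cov = "X6", type = "step", coef = 0.5, threshold = 0),
        list(cov = "X19", type = "step", coef = -0.45, threshold = 0.5)),
      interactions = list(list(cov = "X1", coef = 0.3))))
}

#' Read or write a scenario as a flat YAML file
#'
#' The on-disk format mirrors \code{\link{scenario_config}}: one block per
#' covariate, one exposure block, one outcome block.
#'
#' @param path YAML file path.
#' @return \code{read_scenario_yaml} returns a \code{gcml_scenario}.
#' @export
read_scenario_yaml <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  raw$covariates <- lapply(raw$covariates, function(cv) {
    if (!is.null(cv$dep)) cv$dep <- unlist(cv$dep)
    cv
  })
  raw$exposure$coefs <- unlist(raw$exposure$coefs)
  scenario_config(name = raw$name, covariates = raw$covariates,
                  exposure = raw$exposure, outcome = raw$outcome)
}

#' @rdname read_scenario_yaml
#' @param scenario a \code{gcml_scenario}.
#' @export
write_scenario_yaml <- function(scenario, path) {
  stopifnot(inherits(scenario, "gcml_scenario"))
  obj <- unclass(scenario)
  obj$exposure$coefs <- as.list(obj$exposure$coefs)
  obj$covariates <- lapply(obj$covariates, function(cv) {
    if (!is.null(cv$dep)) cv$dep <- as.list(cv$dep)
    cv
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}
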