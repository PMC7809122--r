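#' Specification of the flexible Q-model design
#'
#' Controls how the cohort is expanded into the feature matrix of the
#' outcome model: b-spline expansion of continuous covariates, inclusion of
#' all exposure-by-covariate interactions, and standardization behaviour for
#' scale-sensitive learners.
#'
#' @param spline_degree polynomial degree of the b-splines (default 3,
#'   cubic).
#' @param spline_df degrees of freedom (returned basis columns, constant
#'   excluded) per continuous covariate. Default 3: cubic with no interior
#'   knots, the minimal flexible expansion, which keeps the number of
#'   parameters manageable at n = 100. \code{spline_df = 0} disables
#'   expansion (raw covariates), as used by the plain-GLM comparator.
#' @param include_interactions include an exposure interaction for every
#'   covariate (basis) column (default TRUE).
#' @param standardize_for learners whose inputs are z-scored with
#'   training-data parameters; penalized regressions standardize internally
#'   per their own convention, so only the scale-sensitive learners are
#'   listed by default.
#' @return an object of class \code{gcml_design_spec}.
#' @export
design_spec <- function(spline_degree = 3L, spline_df = 3L,
                        include_interactions = TRUE,
                        standardize_for = c("NN", "SVM")) {
  spline_degree <- as.integer(spline_degree)
  spline_df <- as.integer(spline_df)
  if (spline_df != 0L && spline_df < spline_degree)
    stop("spline_df must be >= spline_degree (or 0 to disable expansion)",
         call. = FALSE)
  structure(list(spline_degree = spline_degree,
                 spline_df = spline_df,
                 boundary_policy = "clamp",
                 include_interactions = isTRUE(include_interactions),
                 standardize_for = standardize_for),
            class = "gcml_design_spec")
}

#' Evaluate a b-spline basis with the constant column dropped
#'
#' Returns the b-spline basis over the given full knot vector (boundary
#' knots repeated degree+1 times) with the first basis function excluded,
#' so the intercept is left to the learner. All entries lie in [0,1]; the
#' full basis (including the dropped column) is a partition of unity, so
#' the dropped column equals 1 minus the row sum of the returned columns.
#'
#' @param x numeric vector, assumed already inside the boundary knots
#'   (callers clamp first).
#' @param knots full non-decreasing knot vector with boundary multiplicity
#'   degree + 1.
#' @param degree spline degree.
#' @return matrix with \code{length(knots) - degree - 2} columns.
#' @export
spline_basis <- function(x, knots, degree) {
  if (is.unsorted(knots)) stop("knots must be non-decreasing", call. = FALSE)
  lo <- knots[1]; hi <- knots[length(knots)]
  if (sum(knots == lo) < degree + 1 || sum(knots == hi) < degree + 1)
    stop("boundary knots need multiplicity >= degree + 1", call. = FALSE)
  full <- splines::splineDesign(knots, x, ord = degree + 1)
  # right boundary: splineDesign puts mass on the last function already
  full[, -1, drop = FALSE]
}

# knot vector for df returned columns: df - degree interior knots at
# equally spaced quantiles of the training values
.make_knots <- function(x, df, degree) {
  lo <- min(x); hi <- max(x)
  m <- df - degree
  interior <- if (m > 0) {
    stats::quantile(x, probs = seq_len(m) / (m + 1), names = FALSE, type = 7)
  } else numeric(0)
  c(rep(lo, degree + 1), interior, rep(hi, degree + 1))
}

#' Fit the Q-model design on a training cohort
#'
#' Places boundary knots at the training minimum/maximum and interior knots
#' at training quantiles for each continuous covariate, passes binary
#' covariates through unexpanded, builds one exposure main-effect column
#' plus (optionally) one interaction column per covariate basis column, and
#' records training means/SDs for standardization. All fitted state comes
#' from the training data only.
#'
#' @param cohort a \code{gcml_cohort}.
#' @param spec a \code{\link{design_spec}}.
#' @param with_meta build the per-column provenance table (default TRUE;
#'   refits inside resampling loops skip it).
#' @return an object of class \code{gcml_design} with the expanded training
#'   matrix (\code{$matrix}), per-column provenance (\code{$column_meta}),
#'   and fitted state (knots, centers, scales).
#' @export
fit_design <- function(cohort, spec = design_spec(), with_meta = TRUE) {
  if (!inherits(cohort, "gcml_cohort") || !inherits(spec, "gcml_design_spec"))
    stop("fit_design needs a gcml_cohort and a gcml_design_spec",
         call. = FALSE)
  knots <- vector("list", cohort$k)
  names(knots) <- names(cohort$covariates)
  for (j in seq_len(cohort$k)) {
    if (cohort$covariate_types[j] == "continuous") {
      x <- cohort$covariates[[j]]
      if (length(unique(x)) < 2)
        stop("continuous covariate '", names(cohort$covariates)[j],
             "' is constant in the training data", call. = FALSE)
      if (spec$spline_df > 0)
        knots[[j]] <- .make_knots(x, spec$spline_df, spec$spline_degree)
    }
  }
  fitted <- structure(
    list(spec = spec,
         knots = knots,
         covariate_names = names(cohort$covariates),
         covariate_types = cohort$covariate_types,
         center = NULL, scale = NULL,
         column_meta = NULL, matrix = NULL),
    class = "gcml_design")
  M <- transform_design(fitted, cohort, z_override = "observed",
                        with_meta = with_meta)
  fitted$column_meta <- attr(M, "column_meta")
  attr(M, "column_meta") <- NULL
  fitted$matrix <- M
  mu <- colMeans(M)
  sd_ <- apply(M, 2, stats::sd)
  sd_[!is.finite(sd_) | sd_ == 0] <- 1
  fitted$center <- mu
  fitted$scale <- sd_
  fitted
}

#' Build the feature matrix for a cohort under an exposure override
#'
#' Re-evaluates the fitted design on (possibly new) cohort rows. Continuous
#' covariate values outside the training boundary knots are clamped to the
#' boundary before basis evaluation, which avoids wild cubic extrapolation
#' on resampled or out-of-bag rows. The exposure main-effect column and all
#' interaction columns reflect the override; covariate-only columns are
#' identical across overrides.
#'
#' @param fitted a \code{gcml_design} from \code{\link{fit_design}}.
#' @param cohort a \code{gcml_cohort} with the same covariate schema.
#' @param z_override \code{"observed"}, \code{"all_one"} or
#'   \code{"all_zero"}.
#' @param with_meta attach the per-column provenance table as attribute
#'   \code{column_meta} (default FALSE; \code{\link{fit_design}} stores it
#'   once, so repeated transforms skip rebuilding it).
#' @return numeric matrix.
#' @export
transform_design <- function(fitted, cohort,
                             z_override = c("observed", "all_one", "all_zero"),
                             with_meta = FALSE) {
  z_override <- match.arg(z_override)
  if (!inherits(fitted, "gcml_design"))
    stop("fitted must be a gcml_design", call. = FALSE)
  if (!identical(names(cohort$covariates), fitted$covariate_names) ||
      !identical(cohort$covariate_types, fitted$covariate_types))
    stop("cohort covariate schema does not match the fitted design",
         call. = FALSE)
  spec <- fitted$spec
  z <- switch(z_override,
              observed = cohort$exposure,
              all_one  = rep(1, cohort$n),
              all_zero = rep(0, cohort$n))
  blocks <- list(Z = matrix(z, ncol = 1, dimnames = list(NULL, "Z")))
  meta_rows <- if (with_meta) list(data.frame(
    column = "Z", source = "Z", basis_index = NA_integer_,
    is_exposure_main = TRUE, interacts_with_z = FALSE,
    stringsAsFactors = FALSE)) else NULL
  cov_cols <- vector("list", cohort$k)
  names(cov_cols) <- fitted$covariate_names
  for (j in seq_len(cohort$k)) {
    nm <- fitted$covariate_names[j]
    x <- cohort$covariates[[j]]
    if (fitted$covariate_types[j] == "continuous" && spec$spline_df > 0) {
      kn <- fitted$knots[[nm]]
      x_cl <- pmin(pmax(x, kn[1]), kn[length(kn)])
      B <- spline_basis(x_cl, kn, spec$spline_degree)
      colnames(B) <- paste0(nm, "_bs", seq_len(ncol(B)))
      cov_cols[[nm]] <- B
      if (with_meta) meta_rows[[length(meta_rows) + 1]] <- data.frame(
        column = colnames(B), source = nm, basis_index = seq_len(ncol(B)),
        is_exposure_main = FALSE, interacts_with_z = FALSE)
    } else {
      B <- matrix(x, ncol = 1, dimnames = list(NULL, nm))
      cov_cols[[nm]] <- B
      if (with_meta) meta_rows[[length(meta_rows) + 1]] <- data.frame(
        column = nm, source = nm, basis_index = NA_integer_,
        is_exposure_main = FALSE, interacts_with_z = FALSE)
    }
  }
  blocks <- c(blocks, cov_cols)
  if (spec$include_interactions && cohort$k > 0) {
    for (nm in names(cov_cols)) {
      B <- cov_cols[[nm]] * z
      colnames(B) <- paste0(colnames(cov_cols[[nm]]), ":Z")
      blocks[[paste0(nm, ":Z")]] <- B
      if (with_meta) meta_rows[[length(meta_rows) + 1]] <- data.frame(
        column = colnames(B), source = nm,
        basis_index = if (ncol(B) > 1) seq_len(ncol(B)) else NA_integer_,
        is_exposure_main = FALSE, interacts_with_z = TRUE)
    }
  }
  M <- do.call(cbind, blocks)
  rownames(M) <- NULL
  if (with_meta) attr(M, "column_meta") <- do.call(rbind, meta_rows)
  M
}

#' Standardize a design matrix with training parameters
#'
#' z-scores every column with the training means/SDs stored in the fitted
#' design. \code{unstandardize_matrix} is its exact inverse.
#'
#' @param fitted a \code{gcml_design}.
#' @param M matrix with the fitted design's columns.
#' @return matrix of the same shape.
#' @export
standardize_matrix <- function(fitted, M) {
  sweep(sweep(M, 2, fitted$center, "-"), 2, fitted$scale, "/")
}

#' @rdname standardize_matrix
#' @export
unstandardize_matrix <- function(fitted, M) {
  sweep(sweep(M, 2, fitted$scale, "*"), 2, fitted$center, "+")
}

#' @export
print.gcml_design <- function(x, ...) {
  cat("gcml fitted design:", ncol(x$matrix), "columns from",
      length(x$covariate_names), "covariates\n")
  cat("  spline df:", x$spec$spline_df,
      "| interactions:", x$spec$include_interactions, "\n")
  invisible(x)
}
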