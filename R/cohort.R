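#' Construct and validate a cohort table
#'
#' The canonical data object of the package: one binary outcome \code{Y},
#' one binary exposure \code{Z} (1 = exposed) and \code{k} pre-exposure
#' covariates, each explicitly tagged continuous or binary. No missing
#' values are tolerated anywhere; rejection is preferred over imputation.
#'
#' @param outcome integer/numeric vector of 0/1 outcomes.
#' @param exposure integer/numeric vector of 0/1 exposure statuses.
#' @param covariates data.frame (possibly zero-column) of covariates.
#' @param covariate_types character vector, one of \code{"continuous"} or
#'   \code{"binary"} per covariate column. Tagging is explicit, never
#'   inferred, so a 0/1-coded continuous score cannot be silently
#'   misclassified.
#' @param row_id optional stable row identifiers (default \code{1:n}).
#'
#' @return An object of class \code{gcml_cohort} with elements
#'   \code{outcome}, \code{exposure}, \code{covariates},
#'   \code{covariate_types}, \code{row_id}, \code{n}, \code{k}.
#' @export
cohort_table <- function(outcome, exposure, covariates,
                         covariate_types = character(), row_id = NULL) {
  covariates <- as.data.frame(covariates)
  n <- length(outcome)
  if (is.null(row_id)) row_id <- seq_len(n)
  obj <- structure(
    list(outcome = as.numeric(outcome),
         exposure = as.numeric(exposure),
         covariates = covariates,
         covariate_types = covariate_types,
         row_id = row_id,
         n = n,
         k = ncol(covariates)),
    class = "gcml_cohort")
  validate_cohort(obj)
  obj
}

#' Validate a cohort table
#'
#' Checks every structural invariant: 0/1 coding of outcome and exposure,
#' absence of missing values, minimum sample size (n >= 20, so that folds
#' and bootstrap out-of-bag sets are non-degenerate), non-empty exposure
#' groups and outcome classes, 0/1 coding of binary-tagged covariates and
#' non-constancy of continuous-tagged ones.
#'
#' @param x a \code{gcml_cohort}.
#' @return \code{x}, invisibly; errors with an informative message otherwise.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "gcml_cohort"))
  n <- x$n
  if (length(x$exposure) != n)
    stop("outcome and exposure lengths differ", call. = FALSE)
  if (nrow(x$covariates) != n && x$k > 0)
    stop("covariate rows do not match outcome length", call. = FALSE)
  .check_binary_col(x$outcome, "outcome")
  .check_binary_col(x$exposure, "exposure")
  if (n < 20)
    stop("cohort has n = ", n, " rows; at least 20 are required", call. = FALSE)
  if (length(unique(x$outcome)) < 2)
    stop("outcome has a single class; both 0 and 1 must be present",
         call. = FALSE)
  if (length(unique(x$exposure)) < 2)
    stop("exposure has a single group; both exposed and unexposed must be present",
         call. = FALSE)
  if (length(x$covariate_types) != x$k)
    stop("covariate_types must give one tag per covariate column", call. = FALSE)
  if (x$k > 0 && !all(x$covariate_types %in% c("continuous", "binary")))
    stop("covariate_types must be 'continuous' or 'binary'", call. = FALSE)
  for (j in seq_len(x$k)) {
    col <- x$covariates[[j]]
    nm <- names(x$covariates)[j]
    if (!is.numeric(col))
      stop("covariate '", nm, "' is not numeric", call. = FALSE)
    if (anyNA(col)) {
      row <- which(is.na(col))[1]
      stop("missing value in covariate '", nm, "' at row ", row,
           "; no imputation is performed", call. = FALSE)
    }
    if (x$covariate_types[j] == "binary") {
      bad <- which(!(col %in% c(0, 1)))
      if (length(bad))
        stop("binary covariate '", nm, "' has non-0/1 value at row ", bad[1],
             call. = FALSE)
    } else {
      if (length(unique(col)) < 2)
        stop("continuous covariate '", nm, "' has fewer than 2 distinct values",
             call. = FALSE)
    }
  }
  invisible(x)
}

.check_binary_col <- function(col, name) {
  if (anyNA(col)) {
    row <- which(is.na(col))[1]
    stop("missing value in ", name, " at row ", row, call. = FALSE)
  }
  bad <- which(!(col %in% c(0, 1)))
  if (length(bad))
    stop(name, " contains non-0/1 value at row ", bad[1], call. = FALSE)
  invisible(NULL)
}

#' Read a cohort from a CSV file
#'
#' Reads an RFC-4180 CSV with a header row and assembles a validated
#' \code{gcml_cohort}. Column order in the file is preserved for the
#' covariates, and reading the same file twice yields identical tables.
#'
#' @param path path to the CSV file.
#' @param outcome_col name of the 0/1 outcome column.
#' @param exposure_col name of the 0/1 exposure column.
#' @param covariate_cols named character vector: names are covariate column
#'   names, values their type tags (\code{"continuous"}/\code{"binary"}).
#'   May be empty for an exposure-only model.
#' @return a \code{gcml_cohort}.
#' @export
read_cohort_csv <- function(path, outcome_col, exposure_col,
                            covariate_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  needed <- c(outcome_col, exposure_col, names(covariate_cols))
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("column(s) not found in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  cohort_table(outcome = df[[outcome_col]],
               exposure = df[[exposure_col]],
               covariates = df[names(covariate_cols)],
               covariate_types = unname(covariate_cols))
}

#' @export
print.gcml_cohort <- function(x, ...) {
  cat("gcml cohort: n =", x$n, ", k =", x$k, "covariates\n")
  cat("  outcome prevalence:", round(mean(x$outcome), 3),
      "| exposed fraction:", round(mean(x$exposure), 3), "\n")
  if (x$k > 0)
    cat("  covariates:",
        paste0(names(x$covariates), " (", x$covariate_types, ")",
               collapse = ", "), "\n")
  invisible(x)
}

#' Write an ACE estimate report
#'
#' Serialises an ACE estimate to a flat two-column key/value CSV that
#' round-trips losslessly at 12 significant digits, including the seed for
#' reproducibility.
#'
#' @param estimate a \code{gcml_ace} (see \code{\link{bootstrap_ace}}).
#' @param path output file path.
#' @export
write_estimate_report <- function(estimate, path) {
  stopifnot(inherits(estimate, "gcml_ace"))
  fields <- list(
    ace_hat = estimate$ace_hat,
    se = estimate$se,
    ci_lo = estimate$ci_lo,
    ci_hi = estimate$ci_hi,
    n_boot = estimate$n_boot_completed,
    ci_level = estimate$ci_level,
    learner_id = estimate$learner_id,
    seed = estimate$seed)
  vals <- vapply(fields, function(v) {
    if (is.numeric(v)) formatC(v, digits = 12, format = "g") else as.character(v)
  }, character(1))
  df <- data.frame(key = names(fields), value = unname(vals),
                   stringsAsFactors = FALSE)
  ok <- tryCatch({utils::write.csv(df, path, row.names = FALSE); TRUE},
                 error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write report to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read back an ACE estimate report
#'
#' @param path path written by \code{\link{write_estimate_report}}.
#' @return named list with numeric fields parsed back.
#' @export
read_estimate_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("character", "character"))
  out <- as.list(df$value)
  names(out) <- df$key
  for (nm in c("ace_hat", "se", "ci_lo", "ci_hi", "n_boot", "ci_level", "seed"))
    out[[nm]] <- as.numeric(out[[nm]])
  out
}
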