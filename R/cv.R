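#' Outcome-stratified cross-validation plan
#'
#' Assigns every row a fold label in 1..V, stratifying on the outcome so
#' that within each outcome class the fold sizes differ by at most one.
#' With stratified assignment a held-out fold can lack an outcome class
#' only when that class has fewer members than folds; in that case a
#' second stratification attempt is made and, if still degenerate, an
#' error is raised (unless \code{allow_reduce} permits shrinking V to the
#' minority-class count, as used inside bootstrap resamples).
#'
#' @param outcome 0/1 vector.
#' @param v number of folds.
#' @param seed integer seed.
#' @param allow_reduce shrink V instead of erroring when a class has fewer
#'   members than folds (default FALSE).
#' @return object of class \code{gcml_cv_plan} with \code{fold} (labels),
#'   \code{v} and \code{seed}.
#' @export
cv_plan <- function(outcome, v = 10L, seed = 1L, allow_reduce = FALSE) {
  stopifnot(all(outcome %in% c(0, 1)), v >= 2)
  v <- as.integer(v)
  min_class <- min(sum(outcome == 1), sum(outcome == 0))
  if (min_class < v) {
    if (allow_reduce) {
      v <- max(2L, as.integer(min_class))
    } else if (min_class < v) {
      # re-stratification cannot create class members; fail informatively
      stop("cannot build ", v, "-fold outcome-stratified plan: minority ",
           "class has only ", min_class, " members", call. = FALSE)
    }
  }
  assign_once <- function(s) {
    fold <- integer(length(outcome))
    set.seed(s)
    for (cls in c(0, 1)) {
      idx <- which(outcome == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(v), length(idx))
    }
    fold
  }
  fold <- assign_once(seed)
  degenerate <- function(f) {
    any(vapply(seq_len(v), function(i)
      length(unique(outcome[f == i])) < 2, logical(1)))
  }
  if (degenerate(fold)) fold <- assign_once(seed + 1L)
  structure(list(fold = fold, v = v, seed = as.integer(seed)),
            class = "gcml_cv_plan")
}
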