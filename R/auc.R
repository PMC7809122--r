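#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney AUC: the fraction of (positive, negative) pairs in which
#' the positive scores higher, with tied pairs counting 1/2. Computed via
#' midranks, which is exactly equivalent to pairwise concordance.
#'
#' @param scores numeric predictions (any monotone scale).
#' @param labels 0/1 vector of the same length.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels lengths differ", call. = FALSE)
  if (anyNA(scores) || anyNA(labels))
    stop("scores/labels must not contain NA", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0/1", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
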