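#' Score replicate ACE estimates against the true value
#'
#' Computes the seven standard simulation performance criteria from a set
#' of replicate estimates and their bootstrap standard errors and
#' confidence intervals:
#' \describe{
#'   \item{mb_pct}{mean bias, 100 x mean(ace_hat - true_ace) — percentage
#'     points on the risk-difference scale.}
#'   \item{rmse}{root mean square error, with the uncorrected (n)
#'     denominator.}
#'   \item{esd}{empirical SD of the estimates (n - 1 denominator; the
#'     uncorrected variant is also returned as \code{esd_uncorrected} so
#'     the decomposition rmse^2 = mean_bias^2 + esd_uncorrected^2 holds
#'     exactly).}
#'   \item{asd}{asymptotic SD: the mean of the per-replicate bootstrap
#'     standard errors.}
#'   \item{veb_pct}{variance estimation bias, 100 x (asd - esd)/esd on the
#'     SD scale (variance-scale variant via \code{veb_scale}).}
#'   \item{coverage_pct}{percentage of CIs containing the true ACE.}
#'   \item{power_pct}{percentage of CIs excluding zero.}
#' }
#'
#' @param results data.frame with columns \code{ace_hat}, \code{se},
#'   \code{ci_lo}, \code{ci_hi} (one row per replicate), or a list of
#'   \code{gcml_ace} objects.
#' @param true_ace the scenario's theoretical ACE.
#' @param veb_scale \code{"sd"} (default) or \code{"variance"}.
#' @return object of class \code{gcml_perf} (a one-row data.frame with the
#'   criteria plus \code{n_reps}).
#' @export
compute_report <- function(results, true_ace, veb_scale = c("sd", "variance")) {
  veb_scale <- match.arg(veb_scale)
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(ace_hat = r$ace_hat, se = r$se,
                 ci_lo = r$ci_lo, ci_hi = r$ci_hi)))
  }
  needed <- c("ace_hat", "se", "ci_lo", "ci_hi")
  if (!all(needed %in% names(results)))
    stop("results must have columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  if (any(results$ci_lo > results$ci_hi))
    stop("ci_lo > ci_hi in results", call. = FALSE)
  n <- nrow(results)
  if (n < 2) stop("need at least 2 replicate results (SDs undefined)",
                  call. = FALSE)
  err <- results$ace_hat - true_ace
  mb <- mean(err)
  rmse <- sqrt(mean(err^2))
  esd <- stats::sd(results$ace_hat)
  esd_unc <- sqrt(mean((results$ace_hat - mean(results$ace_hat))^2))
  asd <- mean(results$se)
  veb <- if (veb_scale == "sd") 100 * (asd - esd) / esd
         else 100 * (asd^2 - esd^2) / esd^2
  coverage <- 100 * mean(results$ci_lo <= true_ace & true_ace <= results$ci_hi)
  power <- 100 * mean(results$ci_lo > 0 | results$ci_hi < 0)
  out <- data.frame(mb_pct = 100 * mb, rmse = rmse, esd = esd,
                    esd_uncorrected = esd_unc, asd = asd, veb_pct = veb,
                    coverage_pct = coverage, power_pct = power,
                    true_ace = true_ace, n_reps = n)
  class(out) <- c("gcml_perf", "data.frame")
  out
}

#' Calibration curve of predicted outcome probabilities
#'
#' Bins predictions into equal-frequency (quantile) bins and reports, per
#' bin, the mean predicted probability, the observed event rate, and the
#' bin count. When there are fewer distinct predictions than requested
#' bins, bins are merged (with a message).
#'
#' @param predicted probability vector.
#' @param observed 0/1 vector of the same length.
#' @param n_bins number of bins (default 10).
#' @return data.frame with columns \code{mean_predicted},
#'   \code{event_rate}, \code{count}; counts sum to the input length.
#' @export
calibration_curve <- function(predicted, observed, n_bins = 10L) {
  stopifnot(length(predicted) == length(observed), n_bins >= 2,
            all(observed %in% c(0, 1)))
  brk <- unique(stats::quantile(predicted, probs = seq(0, 1,
                                                       length.out = n_bins + 1),
                                names = FALSE, type = 7))
  if (length(brk) - 1 < n_bins)
    message("calibration_curve: fewer distinct predictions than bins; ",
            "merged to ", max(1, length(brk) - 1), " bins")
  if (length(brk) == 1) {
    return(data.frame(mean_predicted = mean(predicted),
                      event_rate = mean(observed),
                      count = length(observed)))
  }
  bin <- cut(predicted, breaks = brk, include.lowest = TRUE, labels = FALSE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(mean_predicted = mean(predicted[sel]),
               event_rate = mean(observed[sel]),
               count = sum(sel))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.gcml_perf <- function(x, ...) {
  cat("gcml performance over", x$n_reps, "replicates (true ACE =",
      signif(x$true_ace, 4), ")\n")
  cat(sprintf("  MB = %.2f%%  RMSE = %.4f  ESD = %.4f  ASD = %.4f\n",
              x$mb_pct, x$rmse, x$esd, x$asd))
  cat(sprintf("  VEB = %.1f%%  coverage = %.1f%%  power = %.1f%%\n",
              x$veb_pct, x$coverage_pct, x$power_pct))
  invisible(x)
}
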