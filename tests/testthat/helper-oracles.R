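# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration and textbook recursions.

`%||%` <- function(a, b) if (is.null(a)) b else a

# pairwise-concordance AUC: loop over every (positive, negative) pair
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Cox-de Boor recursion for a single B-spline basis function B_{i,k}(x)
# over knot vector t (0-based index i, degree k)
deboor_basis <- function(x, t, i, k) {
  if (k == 0) {
    # half-open support, closed at the right end of the basis range
    last_int <- max(which(t < t[length(t)])) # final non-degenerate interval
    inside <- (x >= t[i + 1] & x < t[i + 2]) |
      (x == t[length(t)] & i + 1 == last_int)
    return(as.numeric(inside))
  }
  d1 <- t[i + k + 1] - t[i + 1]
  d2 <- t[i + k + 2] - t[i + 2]
  a <- if (d1 > 0) (x - t[i + 1]) / d1 * deboor_basis(x, t, i, k - 1) else 0
  b <- if (d2 > 0) (t[i + k + 2] - x) / d2 * deboor_basis(x, t, i + 1, k - 1) else 0
  a + b
}

# full B-spline basis matrix via the recursion above
deboor_full_basis <- function(x, knots, degree) {
  nb <- length(knots) - degree - 1
  sapply(seq_len(nb) - 1, function(i) deboor_basis(x, knots, i, degree))
}

# exact nonparametric standardization over covariate strata:
# sum_x Phat(X = x) [ p(Y | Z = 1, x) - p(Y | Z = 0, x) ]
stratified_standardization <- function(y, z, x) {
  levels_x <- unique(x)
  tot <- 0
  for (v in levels_x) {
    w <- mean(x == v)
    p1 <- mean(y[z == 1 & x == v])
    p0 <- mean(y[z == 0 & x == v])
    tot <- tot + w * (p1 - p0)
  }
  tot
}

# exhaustive grid search over the weight simplex (step 0.05), the oracle
# for the super-learner weight optimiser with small libraries
simplex_grid_best_auc <- function(scores, labels, step = 0.05) {
  m <- ncol(scores)
  ticks <- seq(0, 1, by = step)
  best <- -Inf
  grid_rec <- function(prefix, remaining, left) {
    if (remaining == 1) {
      w <- c(prefix, left)
      a <- brute_force_auc(as.numeric(scores %*% w), labels)
      if (a > best) best <<- a
      return(invisible(NULL))
    }
    for (v in ticks[ticks <= left + 1e-12])
      grid_rec(c(prefix, v), remaining - 1, left - v)
  }
  grid_rec(numeric(0), m, 1)
  best
}

# small random-but-structured cohort generator for property tests
random_cohort <- function(n, seed, k_cont = 2, k_bin = 1, beta_z = 0.6) {
  set.seed(seed)
  repeat {
    Xc <- matrix(rnorm(n * k_cont), n, k_cont)
    Xb <- matrix(rbinom(n * k_bin, 1, 0.5), n, k_bin)
    c1 <- if (k_cont > 0) Xc[, 1] else 0
    b1 <- if (k_bin > 0) Xb[, 1] else 0
    lp_z <- 0.3 * c1 + 0.4 * b1
    z <- rbinom(n, 1, plogis(lp_z))
    lp_y <- -0.3 + beta_z * z + 0.6 * c1 - 0.4 * b1
    y <- rbinom(n, 1, plogis(lp_y))
    if (length(unique(y)) == 2 && length(unique(z)) == 2) break
  }
  X <- data.frame(Xc, Xb)
  names(X) <- paste0("X", seq_len(k_cont + k_bin))
  cohort_table(y, z, X,
               covariate_types = c(rep("continuous", k_cont),
                                   rep("binary", k_bin)))
}

write_cohort_csv <- function(cohort, path) {
  df <- cbind(Y = cohort$outcome, Z = cohort$exposure, cohort$covariates)
  utils::write.csv(df, path, row.names = FALSE)
  path
}
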