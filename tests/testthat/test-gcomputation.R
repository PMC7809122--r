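test_that("estimate_ace is the mean counterfactual difference", {
  expect_equal(estimate_ace(c(0.5, 0.5), c(0.5, 0.5)), 0.0)
  expect_equal(estimate_ace(c(0.8, 0.6, 0.7), c(0.5, 0.5, 0.4)),
               mean(c(0.3, 0.1, 0.3)))
  y1 <- runif(10); y0 <- runif(10)
  expect_equal(estimate_ace(y1, y0), -estimate_ace(y0, y1))
  expect_error(estimate_ace(numeric(0), numeric(0)), "empty")
  expect_error(estimate_ace(y1, y0[1:5]), "lengths differ")
})

test_that("a saturated logistic Q-model reproduces exact standardization", {
  # one binary covariate: intercept + Z + X + Z:X saturates the 4 cells
  set.seed(81)
  repeat {
    x <- rbinom(40, 1, 0.5)
    z <- rbinom(40, 1, plogis(-0.4 + 0.9 * x))
    y <- rbinom(40, 1, plogis(-0.6 + 0.8 * z + 0.7 * x))
    cells <- table(z, x)
    if (all(dim(cells) == c(2, 2)) && all(cells > 2) &&
        length(unique(y)) == 2) break
  }
  co <- cohort_table(y, z, data.frame(X1 = x), "binary")
  cfg <- run_config(learner_id = "GLM", seed = 1,
                    design = design_spec(spline_df = 0,
                                         include_interactions = TRUE))
  got <- gc_point_estimate(co, cfg)
  oracle <- stratified_standardization(y, z, x)
  expect_equal(got$ace_hat, oracle, tolerance = 1e-10)
})

test_that("an exposure-only Q-model collapses to the difference in means", {
  set.seed(82)
  z <- rep(c(1, 0), each = 30)
  y <- c(rbinom(30, 1, 0.7), rbinom(30, 1, 0.4))
  y[1:2] <- c(1, 0); y[31:32] <- c(1, 0)
  co <- cohort_table(y, z, data.frame()[seq_along(y), , drop = FALSE],
                     character())
  cfg <- run_config(learner_id = "GLM", seed = 1)
  got <- gc_point_estimate(co, cfg)
  expect_equal(got$ace_hat, mean(y[z == 1]) - mean(y[z == 0]),
               tolerance = 1e-10)
})

test_that("point estimation is deterministic given the seed", {
  co <- random_cohort(100, seed = 83)
  cfg <- run_config(learner_id = "LLR", n_folds = 5, grid_length = 5,
                    seed = 7)
  a <- gc_point_estimate(co, cfg)$ace_hat
  b <- gc_point_estimate(co, cfg)$ace_hat
  expect_identical(a, b)
})

test_that("bootstrap draws, SE and percentile interval follow their definitions", {
  co <- random_cohort(60, seed = 91)
  cfg <- run_config(learner_id = "GLM", n_boot = 40, seed = 11)
  est <- bootstrap_ace(co, cfg)
  expect_length(est$boot_draws, 40)
  expect_equal(est$n_boot_completed, 40)
  expect_equal(est$se, sd(est$boot_draws))
  expect_equal(c(est$ci_lo, est$ci_hi),
               unname(quantile(est$boot_draws, c(0.025, 0.975))))
  expect_lte(est$ci_lo, est$ci_hi)
  # the reported point estimate is the full-sample fit, not the draw mean
  expect_equal(est$ace_hat, gc_point_estimate(co, cfg)$ace_hat)

  # reproducible under the same seed
  est2 <- bootstrap_ace(co, cfg)
  expect_identical(est$boot_draws, est2$boot_draws)

  # normal-approximation interval behind the flag
  cfgn <- run_config(learner_id = "GLM", n_boot = 40, seed = 11,
                     ci_type = "normal")
  estn <- bootstrap_ace(co, cfgn)
  expect_equal(estn$ci_hi - estn$ci_lo, 2 * qnorm(0.975) * estn$se,
               tolerance = 1e-10)
})

test_that("a null DGP with randomized exposure yields a centred estimator", {
  # no covariate effects, Z independent of X: the mean point estimate over
  # 1000 replicates must sit within 3 Monte-Carlo SEs of zero
  sc <- scenario_preset("simplistic")
  sc$outcome$z_coef <- 0
  sc$exposure$coefs[] <- 0
  for (i in seq_along(sc$outcome$terms)) sc$outcome$terms[[i]]$coef <- 0
  seeds <- replicate_seeds(808001, 1000)
  vals <- vapply(seq_along(seeds), function(i) {
    co <- simulate_cohort(sc, 200, seed = seeds[i])
    cfg <- run_config(learner_id = "GLM", seed = seeds[i])
    gc_point_estimate(co, cfg)$ace_hat
  }, numeric(1))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})

test_that("standard errors shrink with the sample size under a fixed DGP", {
  sc <- scenario_preset("simplistic")
  ses <- vapply(c(200, 800, 3200), function(n) {
    co <- simulate_cohort(sc, n, seed = 100 + n)
    cfg <- run_config(learner_id = "GLM", n_boot = 30, seed = 1)
    bootstrap_ace(co, cfg)$se
  }, numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("SL tuning parameters freeze inside the bootstrap while weights refresh", {
  co <- random_cohort(80, seed = 95)
  cfg <- run_config(learner_id = "SL", sl_library = c("LLR", "NN"),
                    n_folds = 4, grid_length = 2, n_boot = 3, seed = 13)
  point <- gc_point_estimate(co, cfg)
  est <- bootstrap_ace(co, cfg, point = point)
  expect_length(est$boot_draws, 3)
  expect_true(all(abs(est$boot_draws) <= 1))
  # frozen-weight variant is also accepted and reproducible
  cfg2 <- run_config(learner_id = "SL", sl_library = c("LLR", "NN"),
                     n_folds = 4, grid_length = 2, n_boot = 3, seed = 13,
                     sl_freeze_weights = TRUE)
  est2 <- bootstrap_ace(co, cfg2, point = point)
  expect_length(est2$boot_draws, 3)
})
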