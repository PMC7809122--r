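test_that("presets have the documented structure", {
  r <- scenario_preset("realistic")
  expect_equal(length(r$covariates), 22)
  types <- vapply(r$outcome$terms, `[[`, character(1), "type")
  expect_equal(sum(types == "linear"), 4)
  expect_equal(sum(types == "quadratic"), 3)
  expect_equal(sum(types == "step"), 2)
  expect_equal(length(r$outcome$interactions), 1)
  # sequential dependence present
  expect_true(any(vapply(r$covariates,
                         function(cv) length(cv$dep %||% numeric(0)) > 0,
                         logical(1))))

  s <- scenario_preset("simplistic")
  expect_equal(length(s$covariates), 9)
  expect_equal(length(s$outcome$terms), 6)
  expect_true(all(vapply(s$outcome$terms, `[[`, character(1), "type") ==
                    "linear"))
  expect_equal(length(s$outcome$interactions), 0)
  expect_true(all(vapply(s$covariates,
                         function(cv) length(cv$dep %||% numeric(0)) == 0,
                         logical(1))))

  co <- simulate_cohort(r, 100, seed = 1)
  expect_equal(co$k, 22)
})

test_that("simplistic covariates are mutually independent in large samples", {
  co <- simulate_cohort(scenario_preset("simplistic"), 10000, seed = 5)
  C <- cor(as.matrix(co$covariates))
  off <- C[upper.tri(C)]
  expect_lt(max(abs(off)), 0.05)
})

test_that("null coefficients give Bernoulli(1/2) exposure and outcome", {
  sc <- scenario_config(
    name = "flat",
    covariates = list(list(name = "X1", family = "normal", intercept = 0)),
    exposure = list(intercept = 0, coefs = c(X1 = 0)),
    outcome = list(intercept = 0, z_coef = 0,
                   terms = list(list(cov = "X1", type = "linear", coef = 0)),
                   interactions = list()))
  co <- simulate_cohort(sc, 10000, seed = 6)
  expect_lt(abs(mean(co$exposure) - 0.5), 0.015)
  expect_lt(abs(mean(co$outcome) - 0.5), 0.015)
})

test_that("scenario validation rejects acyclicity and typing violations", {
  expect_error(scenario_config(
    "bad",
    covariates = list(list(name = "X1", family = "normal",
                           dep = c(X2 = 0.5)),
                      list(name = "X2", family = "normal")),
    exposure = list(intercept = 0, coefs = c(X1 = 0)),
    outcome = list(intercept = 0, z_coef = 0, terms = list(),
                   interactions = list())),
    "not generated earlier")
  expect_error(scenario_config(
    "bad2",
    covariates = list(list(name = "X1", family = "bernoulli")),
    exposure = list(intercept = 0, coefs = c(X1 = 0)),
    outcome = list(intercept = 0, z_coef = 0,
                   terms = list(list(cov = "X1", type = "quadratic",
                                     coef = 1)),
                   interactions = list())),
    "requires a continuous covariate")
})

test_that("generating models are recovered by correctly specified regressions", {
  sc <- scenario_preset("simplistic")
  co <- simulate_cohort(sc, 50000, seed = 7)
  X <- as.matrix(co$covariates)

  # exposure model: logistic regression of Z on X recovers alpha
  fz <- glm(co$exposure ~ X, family = binomial())
  alpha_true <- c(sc$exposure$intercept,
                  vapply(names(co$covariates),
                         function(nm) {
                           v <- sc$exposure$coefs[nm]
                           if (is.na(v)) 0 else unname(v)
                         }, numeric(1)))
  se_z <- sqrt(diag(vcov(fz)))
  expect_true(all(abs(coef(fz) - alpha_true) <= 3 * se_z))

  # outcome model: logistic regression of Y on g(X, Z) recovers beta
  cols <- vapply(sc$outcome$terms, `[[`, character(1), "cov")
  G <- cbind(Z = co$exposure, X[, cols])
  fy <- glm(co$outcome ~ G, family = binomial())
  beta_true <- c(sc$outcome$intercept, sc$outcome$z_coef,
                 vapply(sc$outcome$terms, `[[`, numeric(1), "coef"))
  se_y <- sqrt(diag(vcov(fy)))
  expect_true(all(abs(coef(fy) - beta_true) <= 3 * se_y))
})

test_that("theoretical ACE matches the closed form and is stable in z_prob", {
  sc <- scenario_config(
    name = "closed-form",
    covariates = list(list(name = "X1", family = "normal")),
    exposure = list(intercept = 0, coefs = c(X1 = 0.8)),
    outcome = list(intercept = -1, z_coef = 1,
                   terms = list(list(cov = "X1", type = "linear", coef = 0)),
                   interactions = list()))
  closed <- plogis(0) - plogis(-1)  # 0.5 - expit(-1) = 0.23106
  ta <- theoretical_ace(sc, n_datasets = 60, n_per_dataset = 4000, seed = 8)
  expect_lt(abs(ta$ace - closed), 3 * ta$mc_se)
  expect_equal(closed, 0.23106, tolerance = 1e-4)

  # invariant to the randomised exposure probability, within MC error
  for (zp in c(0.3, 0.7)) {
    ta2 <- theoretical_ace(sc, n_datasets = 60, n_per_dataset = 4000,
                           z_prob = zp, seed = 9)
    expect_lt(abs(ta2$ace - closed), 3 * ta2$mc_se)
  }

  # null exposure effect: zero within MC error
  sc0 <- sc; sc0$outcome$z_coef <- 0
  ta0 <- theoretical_ace(sc0, n_datasets = 60, n_per_dataset = 4000, seed = 10)
  expect_lt(abs(ta0$ace), 3 * ta0$mc_se)
})

test_that("theoretical-ACE Monte-Carlo error shrinks as 1/sqrt(datasets)", {
  sc <- scenario_config(
    name = "se-scaling",
    covariates = list(list(name = "X1", family = "normal")),
    exposure = list(intercept = 0, coefs = c(X1 = 0)),
    outcome = list(intercept = -0.5, z_coef = 0.6,
                   terms = list(list(cov = "X1", type = "linear", coef = 0.4)),
                   interactions = list()))
  t100 <- theoretical_ace(sc, n_datasets = 100, n_per_dataset = 800, seed = 11)
  t400 <- theoretical_ace(sc, n_datasets = 400, n_per_dataset = 800, seed = 11)
  expect_equal(t100$mc_se / t400$mc_se, 2, tolerance = 0.5)
})

test_that("replicate streams are deterministic and independent", {
  sc <- scenario_preset("simplistic")
  g1 <- generate_replicates(sc, 50, 3, master_seed = 12)
  g2 <- generate_replicates(sc, 50, 3, master_seed = 12)
  expect_identical(g1$seeds, g2$seeds)
  expect_equal(length(unique(g1$seeds)), 3)
  d1 <- g1$dataset(2); d2 <- g2$dataset(2)
  expect_identical(d1$outcome, d2$outcome)
  expect_identical(d1$covariates, d2$covariates)
  d3 <- g1$dataset(3)
  expect_false(identical(d1$outcome, d3$outcome))
  expect_identical(names(d1$covariates), names(d3$covariates))
  expect_true(all(replicate_seeds(2^30, 100) < 2^31))
})

test_that("scenarios round-trip through YAML", {
  sc <- scenario_preset("realistic")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_yaml(sc, path)
  back <- read_scenario_yaml(path)
  co1 <- simulate_cohort(sc, 100, seed = 3)
  co2 <- simulate_cohort(back, 100, seed = 3)
  expect_identical(co1$outcome, co2$outcome)
  expect_identical(co1$covariates, co2$covariates)
})
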