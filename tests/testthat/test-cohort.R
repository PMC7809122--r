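test_that("CSV cohorts parse with order preserved and deterministically", {
  co <- random_cohort(24, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  types <- c(X1 = "continuous", X2 = "continuous", X3 = "binary")
  got <- read_cohort_csv(path, "Y", "Z", types)
  expect_equal(got$n, 24)
  expect_equal(got$k, 3)
  expect_identical(names(got$covariates), c("X1", "X2", "X3"))
  expect_equal(got$outcome, co$outcome)
  expect_equal(got$covariates$X1, co$covariates$X1)
  again <- read_cohort_csv(path, "Y", "Z", types)
  expect_identical(got, again)
})

test_that("validation rejects malformed cohorts with precise messages", {
  co <- random_cohort(24, seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  types <- c(X1 = "continuous", X2 = "continuous", X3 = "binary")

  df <- cbind(Y = co$outcome, Z = co$exposure, co$covariates)
  df$Y[3] <- 2
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort_csv(path, "Y", "Z", types), "non-0/1 value at row 3")

  df <- cbind(Y = co$outcome, Z = co$exposure, co$covariates)
  df$X1[5] <- NA
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort_csv(path, "Y", "Z", types),
               "missing value in covariate 'X1' at row 5")

  write_cohort_csv(co, path)
  expect_error(read_cohort_csv(path, "Y", "Znope", types), "not found")
  expect_error(read_cohort_csv("no/such/file.csv", "Y", "Z", types),
               "file not found")

  # structural invariants
  expect_error(cohort_table(co$outcome[1:10], co$exposure[1:10],
                            co$covariates[1:10, ],
                            c("continuous", "continuous", "binary")),
               "at least 20")
  expect_error(cohort_table(rep(1, 24), co$exposure, co$covariates,
                            c("continuous", "continuous", "binary")),
               "single class")
  expect_error(cohort_table(co$outcome, co$exposure,
                            data.frame(X1 = rep(1, 24)), "continuous"),
               "fewer than 2 distinct")
  expect_error(cohort_table(co$outcome, co$exposure,
                            data.frame(X1 = rep(c(0, 2), 12)), "binary"),
               "non-0/1")
})

test_that("randomly generated tables are accepted iff all invariants hold", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(20:60, 1)
    y <- rbinom(n, 1, 0.5); y[1:2] <- c(0, 1)
    z <- rbinom(n, 1, 0.5); z[1:2] <- c(0, 1)
    X <- data.frame(X1 = rnorm(n), X2 = rbinom(n, 1, 0.5))
    expect_silent(co <- cohort_table(y, z, X, c("continuous", "binary")))
    # now break exactly one invariant and expect rejection
    breakage <- s %% 4
    if (breakage == 0) y2 <- rep(0, n) else y2 <- y
    if (breakage == 1) z2 <- rep(1, n) else z2 <- z
    X2 <- X
    if (breakage == 2) X2$X1 <- rep(3.3, n)
    if (breakage == 3) X2$X2[n] <- 5
    expect_error(cohort_table(y2, z2, X2, c("continuous", "binary")))
  }
})

test_that("estimate reports round-trip losslessly with seed metadata", {
  est <- structure(list(ace_hat = 0.123456789012, boot_draws = numeric(0),
                        se = 0.0456, ci_lo = -0.01, ci_hi = 0.21,
                        ci_level = 0.95, n_boot_completed = 500L,
                        n_redraws = 0L, learner_id = "SL", seed = 42L),
                   class = "gcml_ace")
  path <- withr::local_tempfile(fileext = ".csv")
  write_estimate_report(est, path)
  back <- read_estimate_report(path)
  expect_equal(back$ace_hat, est$ace_hat, tolerance = 1e-12)
  expect_equal(back$se, est$se)
  expect_equal(back$ci_lo, est$ci_lo)
  expect_equal(back$ci_hi, est$ci_hi)
  expect_equal(back$n_boot, 500)
  expect_equal(back$seed, 42)
  expect_identical(back$learner_id, "SL")

  est$ace_hat <- 0.0
  write_estimate_report(est, path)
  expect_equal(read_estimate_report(path)$ace_hat, 0.0)
  suppressWarnings(
    expect_error(write_estimate_report(est, "no/such/dir/report.csv"),
                 "cannot write"))
})

test_that("run configs validate fields and read from YAML", {
  cfg <- run_config()
  expect_equal(cfg$n_folds, 10L)
  expect_equal(cfg$grid_length, 20L)
  expect_equal(cfg$n_boot, 500L)
  expect_equal(cfg$ci_level, 0.95)
  expect_setequal(cfg$sl_library, c("LLR", "ELR", "NN", "SVM"))
  expect_error(run_config(learner_id = "RF"), "unknown learner")
  expect_error(run_config(n_folds = 1), "n_folds")
  expect_error(run_config(ci_level = 1), "ci_level")
  expect_error(run_config(sl_library = character()), "non-empty")
  expect_error(run_config(sl_library = c("LLR", "BCART")), "BCART")

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("learner_id: LLR", "n_boot: 50", "seed: 9"), path)
  cfg2 <- read_run_config(path)
  expect_identical(cfg2$learner_id, "LLR")
  expect_equal(cfg2$n_boot, 50L)
  expect_equal(cfg2$seed, 9L)
  writeLines("bogus_field: 1", path)
  expect_error(read_run_config(path), "unknown config field")
})
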