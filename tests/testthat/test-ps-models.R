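# PS model assembly, penalized logistic fitting, concordance.

test_that("c-statistic matches pair enumeration, with tie handling", {
  scores <- c(0.9, 0.8, 0.7, 0.8)
  expo <- c(1, 1, 0, 0)
  expect_equal(c_statistic(scores, expo), 0.875)
  expect_equal(c_statistic(rep(0.4, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(c_statistic(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_error(c_statistic(c(0.5), c(1)), "non-empty")

  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:25, 1)
    s <- sample(seq(0.1, 0.9, by = 0.1), n, replace = TRUE)  # ties likely
    e <- rbinom(n, 1, 0.5)
    if (length(unique(e)) < 2) next
    expect_equal(c_statistic(s, e, method = "rank"), oracle_cstat(s, e))
    expect_equal(c_statistic(s, e, method = "pairwise"), oracle_cstat(s, e))
  }
})

test_that("c-statistic complement identity holds on tie-free scores", {
  set.seed(12)
  for (i in 1:20) {
    s <- runif(30)
    e <- rbinom(30, 1, 0.4)
    if (length(unique(e)) < 2) next
    expect_equal(c_statistic(s, e) + c_statistic(1 - s, e), 1)
  }
})

test_that("intercept-only fit returns the exposed fraction everywhere", {
  e <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)
  fit <- fit_propensity(matrix(numeric(0), nrow = 10, ncol = 0), e)
  expect_equal(unname(fit$score), rep(0.3, 10), tolerance = 1e-6)
  expect_equal(fit$c_statistic, 0.5)
})

test_that("a covariate identical to exposure separates under the penalty ladder", {
  e <- rep(c(1L, 0L), each = 10)
  X <- cbind(z = e)
  fit <- fit_propensity(X, e)
  expect_true(all(fit$score[e == 1] > 0.95))
  expect_true(all(fit$score[e == 0] < 0.05))
  expect_gt(fit$c_statistic, 0.99)
  expect_error(fit_propensity(X, rep(1L, 20)), "one level")
})

test_that("IRLS coefficients match an independent BFGS maximizer", {
  # 4-patient worked example
  X <- cbind(x = c(1, 0, 1, 0))
  y <- c(1, 1, 0, 0)
  fit <- fit_propensity(X, y, lambda_ladder = 1e-6)
  oracle <- oracle_ridge_logistic(X, y, 1e-6)
  expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-6)

  set.seed(33)
  for (i in 1:25) {
    n <- sample(20:60, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, plogis(X %*% rnorm(p)))
    if (length(unique(y)) < 2) next
    fit <- fit_propensity(X, y, lambda_ladder = 1e-6)
    oracle <- oracle_ridge_logistic(X, y, 1e-6)
    expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-5)
  }
})

test_that("design assembly respects strategy, source and blinding", {
  sim <- generate_cohort(tiny_scenario(n = 500L, seed = 61L, missing = FALSE))
  co <- sim$cohort

  inv_claims <- assemble_design(ps_model_spec("investigator", "claims"),
                                co, claims = sim$claims)
  expect_false(any(grepl("^reg_", colnames(inv_claims))))
  inv_reg <- assemble_design(ps_model_spec("investigator", "registry"),
                             co, registry = sim$registry)
  expect_false(any(grepl("^cond_code|^util_", colnames(inv_reg))))
  expect_true(any(grepl("^age_", colnames(inv_reg))))

  full <- hdps_rank(co, claims = sim$claims, registry = sim$registry,
                    source = "both", k = 40L)
  blind <- hdps_exclude(full, "high_surgical_risk")
  d_both <- assemble_design(ps_model_spec("hdps", "both", k = 40L), co,
                            claims = sim$claims, registry = sim$registry,
                            ranking = full)
  d_blind <- assemble_design(ps_model_spec("hdps", "both_minus_risk", k = 40L),
                             co, claims = sim$claims, registry = sim$registry,
                             ranking = blind)
  extra <- setdiff(colnames(d_both), colnames(d_blind))
  expect_true(all(grepl("^high_surgical_risk\\|", extra)))
  expect_false(any(grepl("^high_surgical_risk\\|", colnames(d_blind))))
  # blinded variant refuses an unblinded ranking
  expect_error(
    assemble_design(ps_model_spec("hdps", "both_minus_risk", k = 40L), co,
                    claims = sim$claims, registry = sim$registry,
                    ranking = full),
    "exclude_dimensions")
  expect_error(ps_model_spec("investigator", "both_minus_risk"),
               "only defined for the hdps")
})

test_that("hdps design takes the top-k covariates after the forced set", {
  sim <- generate_cohort(tiny_scenario(n = 500L, seed = 62L, missing = FALSE))
  rk <- hdps_rank(sim$cohort, registry = sim$registry, source = "registry",
                  k = 10L)
  X <- assemble_design(ps_model_spec("hdps", "registry", k = 3L),
                       sim$cohort, registry = sim$registry, ranking = rk)
  hd_cols <- grep("\\|", colnames(X), value = TRUE)
  expect_identical(hd_cols,
                   paste(rk$ranking$dimension, rk$ranking$code,
                         rk$ranking$level, sep = "|")[1:3])
})

test_that("models seeing the risk composite discriminate better", {
  sim <- generate_cohort(tiny_scenario(n = 1500L, seed = 63L, missing = FALSE))
  co <- sim$cohort
  with_risk <- fit_propensity(
    assemble_design(ps_model_spec("investigator", "registry"), co,
                    registry = sim$registry), co$exposure)
  claims_only <- fit_propensity(
    assemble_design(ps_model_spec("investigator", "claims"), co,
                    claims = sim$claims), co$exposure)
  expect_gt(with_risk$c_statistic, claims_only$c_statistic)
})
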