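# Cohort generator: contracts, determinism, planted structure.

test_that("generator output satisfies its schema invariants", {
  sim <- generate_cohort(tiny_scenario(seed = 11L))
  co <- sim$cohort
  expect_false(anyDuplicated(co$patient_id) > 0)
  expect_true(all(co$followup_days > 0))
  expect_true(all(co$exposure %in% 0:1))
  expect_true(all(co$event %in% 0:1))
  cl <- sim$claims
  expect_true(all(cl$count >= 1))
  expect_false(anyDuplicated(cl[, c("patient_id", "dimension", "code")]) > 0)
  expect_true(all(cl$dimension %in% CLAIMS_DIMENSIONS))
  rg <- sim$registry
  expect_false(anyDuplicated(rg[, c("patient_id", "variable")]) > 0)
  expect_true(all(rg$dimension %in% REGISTRY_DIMENSIONS))
  expect_true(all(is.na(rg$value[rg$missing])))
  expect_true(all(!is.na(rg$value[!rg$missing])))
  tp <- sim$truth$true_propensity
  expect_true(all(tp > 0 & tp < 1))
})

test_that("identical config and seed give byte-identical tables", {
  sc <- tiny_scenario(seed = 99L)
  a <- generate_cohort(sc)
  b <- generate_cohort(sc)
  expect_identical(a$cohort, b$cohort)
  expect_identical(a$claims, b$claims)
  expect_identical(a$registry, b$registry)
  c2 <- generate_cohort(tiny_scenario(seed = 100L))
  expect_false(identical(a$cohort$followup_days, c2$cohort$followup_days))
})

test_that("null treatment model gives ~50% exposure and stores the true effect", {
  sc <- tiny_scenario(n = 5000L, seed = 21L)
  for (k in seq_along(sc$confounder_spec)) sc$confounder_spec[[k]]$trt_log_odds <- 0
  sc$treat_intercept <- 0
  sim <- generate_cohort(sc)
  p <- mean(sim$cohort$exposure)
  se <- sqrt(0.25 / 5000)
  expect_lt(abs(p - 0.5), 3 * se)
  expect_identical(sim$truth$true_log_hr, 0)
})

test_that("full claims sensitivity with no noise reproduces every condition in every dimension", {
  sc <- tiny_scenario(n = 300L, seed = 5L, n_noise = 0L, missing = FALSE)
  for (k in seq_along(sc$confounder_spec)) {
    sc$confounder_spec[[k]]$claims_sensitivity[] <- 1
  }
  sim <- generate_cohort(sc)
  C <- sim$truth$conditions
  for (k in seq_along(sc$confounder_spec)) {
    affected <- sim$truth$patient_id[C[[k]] == 1]
    for (d in CLAIMS_DIMENSIONS) {
      got <- sim$claims$patient_id[sim$claims$dimension == d &
                                     sim$claims$code == hdpsbench:::condition_code(d, k)]
      expect_setequal(got, affected)
    }
  }
})

test_that("raising claims sensitivity never decreases distinct true-code capture", {
  counts <- sapply(c(0.2, 0.5, 0.9), function(s) {
    sc <- tiny_scenario(n = 800L, seed = 31L, n_noise = 0L, missing = FALSE)
    for (k in seq_along(sc$confounder_spec)) {
      sc$confounder_spec[[k]]$claims_sensitivity[] <- s
    }
    sim <- generate_cohort(sc)
    true_codes <- sim$truth$code_map$code
    n_affected <- sum(unlist(sim$truth$conditions))
    sum(sim$claims$code %in% true_codes) / n_affected
  })
  expect_true(all(diff(counts) > 0))
})

test_that("degenerate outcome configurations are rejected", {
  sc <- tiny_scenario(seed = 1L)
  sc$baseline_hazard <- 1e4
  expect_error(generate_cohort(sc), "degenerate outcome")
})

test_that("missingness honours rates, zero and one included", {
  sim <- generate_cohort(tiny_scenario(n = 400L, seed = 8L, missing = FALSE))
  rg <- sim$registry
  expect_identical(apply_missingness(rg, list(), seed = 1L), rg)
  out0 <- apply_missingness(rg, list(cardiac = 0), seed = 2L)
  expect_identical(out0, rg)
  out1 <- apply_missingness(rg, list(cardiac = 1), seed = 3L)
  expect_true(all(out1$missing[out1$variable == "cardiac"]))
  expect_identical(out1[out1$variable != "cardiac", ],
                   rg[rg$variable != "cardiac", ])
  expect_identical(nrow(out1), nrow(rg))
  expect_error(apply_missingness(rg, list(nope = 0.1), seed = 1L),
               "unknown registry variable")
})

test_that("a 17.6% missingness rate is realized within binomial error at n = 10000", {
  sim <- generate_cohort(tiny_scenario(n = 10000L, seed = 13L, missing = FALSE))
  out <- apply_missingness(sim$registry, list(sympt = 0.176), seed = 14L)
  frac <- mean(out$missing[out$variable == "sympt"])
  se <- sqrt(0.176 * (1 - 0.176) / 10000)
  expect_lt(abs(frac - 0.176), 3 * se)
})

test_that("MAR option tilts missingness toward the exposed arm", {
  sim <- generate_cohort(tiny_scenario(n = 8000L, seed = 17L, missing = FALSE))
  expo <- setNames(sim$cohort$exposure, sim$cohort$patient_id)
  out <- apply_missingness(sim$registry, list(cardiac = 0.2), seed = 18L,
                           mechanism = "mar", mar_odds_ratio = 3,
                           exposure = expo)
  rows <- out[out$variable == "cardiac", ]
  m1 <- mean(rows$missing[expo[rows$patient_id] == 1])
  m0 <- mean(rows$missing[expo[rows$patient_id] == 0])
  expect_gt(m1, m0)
})

test_that("the default scenario plants upward confounding by indication", {
  sim <- generate_cohort(default_scenario(seed = 424L))
  est <- fit_cox(sim$cohort, cluster_ids = sim$cohort$hospital_id)
  expect_gt(est$hr, 1.3)
  arms <- mean(sim$cohort$exposure)
  expect_lt(abs(arms - 1999 / 5254), 0.03)
})

test_that("scenario configs round-trip through JSON and YAML", {
  sc <- default_scenario(seed = 314L)
  for (ext in c("json", "yaml")) {
    if (ext == "yaml" && !requireNamespace("yaml", quietly = TRUE)) next
    p <- withr::local_tempfile(fileext = paste0(".", ext))
    write_scenario(sc, p)
    back <- read_scenario(p)
    expect_equal(back, sc)
    expect_identical(generate_cohort(back)$cohort, generate_cohort(sc)$cohort)
  }
})
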