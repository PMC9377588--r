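# Matching, quintile stratification, asymmetric trimming, balance.

test_that("greedy caliper matching follows the hand trace", {
  ps <- c(0.9, 0.5, 0.52, 0.55, 0.95)
  expo <- c(1, 1, 0, 0, 0)
  ids <- c("e1", "e2", "u1", "u2", "u3")
  mr <- match_1to1(ps, expo, caliper_mult = 10, ids = ids)
  expect_identical(mr$pairs$exposed_id, c("e1", "e2"))
  expect_identical(mr$pairs$unexposed_id, c("u3", "u1"))
  expect_identical(mr$n_unmatched_exposed, 0L)
  expect_true(all(mr$pairs$logit_distance <= mr$caliper_width + 1e-12))
})

test_that("a zero caliper only matches exact logit ties", {
  ps <- c(0.3, 0.4, 0.3, 0.6)
  expo <- c(1, 1, 0, 0)
  mr <- match_1to1(ps, expo, caliper_mult = 0)
  expect_identical(nrow(mr$pairs), 1L)
  expect_identical(mr$pairs$exposed_id, "1")
  expect_identical(mr$pairs$unexposed_id, "3")
})

test_that("matching equals the brute-force greedy oracle on small instances", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    ps <- round(runif(n, 0.05, 0.95), 2)
    expo <- rbinom(n, 1, 0.45)
    if (sum(expo) == 0 || sum(1 - expo) == 0) next
    ids <- sprintf("P%02d", sample(n))
    cm <- sample(c(0.1, 0.2, 0.5, 2), 1)
    mr <- match_1to1(ps, expo, caliper_mult = cm, ids = ids)
    width <- cm * sd(log(ps / (1 - ps)))
    oracle <- oracle_greedy_match(ps, expo, width, ids)
    if (is.null(oracle)) {
      expect_identical(nrow(mr$pairs), 0L)
    } else {
      expect_identical(mr$pairs$exposed_id, oracle$exposed_id)
      expect_identical(mr$pairs$unexposed_id, oracle$unexposed_id)
    }
    # no reuse, caliper respected
    all_ids <- c(mr$pairs$exposed_id, mr$pairs$unexposed_id)
    expect_false(anyDuplicated(all_ids) > 0)
    expect_true(all(mr$pairs$logit_distance <= width + 1e-12))
  }
})

test_that("quintile cuts use interpolated percentiles and lower-stratum ties", {
  ps <- seq(0.05, 0.5, by = 0.05)
  q <- assign_quintiles(ps)
  expect_identical(as.integer(table(q$labels)), rep(2L, 5))
  expect_false(is.unsorted(q$labels[order(ps)]))
  expect_equal(q$cut_points, oracle_pctile(ps, c(0.2, 0.4, 0.6, 0.8)))

  # a score equal to a cut point goes to the lower stratum
  q2 <- assign_quintiles(c(0.1, 0.2, 0.3, 0.4, 0.5))
  expect_identical(q2$labels[2], sum(q2$cut_points < 0.2) + 1L)
  expect_error(assign_quintiles(rep(c(0.1, 0.2), 5)), "distinct")

  set.seed(6)
  for (i in 1:100) {
    x <- runif(sample(5:40, 1))
    if (length(unique(x)) < 5) next
    q <- assign_quintiles(x)
    expect_equal(q$cut_points, oracle_pctile(x, c(0.2, 0.4, 0.6, 0.8)))
    expect_identical(q$labels,
                     1L + vapply(x, function(s) sum(q$cut_points < s), integer(1)))
    expect_true(all(q$labels %in% 1:5))
  }
})

test_that("asymmetric trimming removes contrary-to-prediction tails only", {
  ps_e <- seq(0.30, 0.87, by = 0.03)   # 20 equally spaced exposed
  ps_u <- rep(0.5, 15)
  ps <- c(ps_e, ps_u)
  expo <- c(rep(1, 20), rep(0, 15))
  tr <- asymmetric_trim(ps, expo, alpha = 0.05)
  removed <- which(!tr$retained)
  expect_identical(removed, 1L)  # exactly the lowest-PS exposed patient
  expect_true(all(ps[tr$retained & expo == 1] >= tr$lower_cut))
  expect_true(all(ps[tr$retained & expo == 0] <= tr$upper_cut))

  tr0 <- asymmetric_trim(ps, expo, alpha = 0)
  expect_true(all(tr0$retained))

  # idempotence with cached cuts
  keep <- tr$retained
  tr2 <- asymmetric_trim(ps[keep], expo[keep], alpha = 0.05,
                         cuts = c(tr$lower_cut, tr$upper_cut))
  expect_true(all(tr2$retained))

  expect_error(asymmetric_trim(c(0.2, 0.8), c(1, 1), alpha = 0.05), "non-empty")
})

test_that("standardized differences match the closed form and its edge cases", {
  X <- cbind(a = c(1, 0, 1, 0), b = rep(1, 4))
  expo <- c(1, 1, 0, 0)
  bal <- standardized_differences(X, expo)
  expect_equal(bal$smd_before[1], 0)   # identical arms
  expect_equal(bal$smd_before[2], 0)   # constant, equal means
  expect_false(any(bal$degenerate))

  # 96.7% vs 44.5% prevalence gap
  x <- c(rep(1, 967), rep(0, 33), rep(1, 445), rep(0, 555))
  e <- rep(c(1, 0), each = 1000)
  bal2 <- standardized_differences(cbind(risk = x), e)
  expect_equal(bal2$smd_before,
               (0.967 - 0.445) / sqrt((0.967 * 0.033 + 0.445 * 0.555) / 2),
               tolerance = 1e-12)
  expect_equal(bal2$smd_before, 1.40, tolerance = 0.005)

  # zero variance with unequal means is flagged
  bal3 <- standardized_differences(cbind(z = c(1, 1, 0, 0)), expo)
  expect_true(bal3$degenerate)
})

test_that("matching on a confounder-informed score improves its balance", {
  worse <- 0
  for (r in 1:20) {
    sim <- generate_cohort(tiny_scenario(n = 500L, seed = 200L + r,
                                         missing = FALSE))
    co <- sim$cohort
    X <- assemble_design(ps_model_spec("investigator", "registry"), co,
                         registry = sim$registry)
    fit <- fit_propensity(X, co$exposure)
    mr <- match_1to1(fit$score, co$exposure, ids = co$patient_id)
    bal <- standardized_differences(X, co$exposure, match = mr,
                                    ids = co$patient_id)
    j <- which(bal$covariate == "reg_risk_composite")
    if (abs(bal$smd_after[j]) > abs(bal$smd_before[j])) worse <- worse + 1
  }
  expect_lte(worse, 4)  # |SMD| does not increase on average
})
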