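# hdPS covariate engine: candidate screening, recurrence expansion,
# Bross prioritization, selection.

make_code_table <- function(presence) {
  # presence: named list code -> patient indices with the code
  do.call(rbind, lapply(names(presence), function(cd) {
    if (!length(presence[[cd]])) return(NULL)
    data.frame(patient_id = sprintf("P%02d", presence[[cd]]),
               dimension = "inpatient_dx", code = cd, count = 1L,
               stringsAsFactors = FALSE)
  }))
}

test_that("candidate screening filters by prevalence and ranks by deviation from ubiquity", {
  ids <- sprintf("P%02d", 1:20)
  # prevalences 0.05, 0.10, ..., 0.50 across ten codes
  presence <- setNames(lapply(1:10, function(k) seq_len(k)),
                       sprintf("C%02d", 1:10))
  tab <- make_code_table(presence)
  spec <- dimension_spec("inpatient_dx", "claims", top_n_codes = 3L,
                         min_prevalence = 0.01)
  got <- identify_candidates(tab, spec, ids)
  expect_identical(got$code, c("C10", "C09", "C08"))
  expect_equal(got$prevalence, c(0.50, 0.45, 0.40))

  # absent code excluded; ubiquitous code passes the floor but ranks last
  presence2 <- list(A = integer(0), B = 1:20, C = 1:10)
  spec2 <- dimension_spec("inpatient_dx", "claims", top_n_codes = 10L,
                          min_prevalence = 0.01)
  got2 <- identify_candidates(make_code_table(presence2), spec2, ids)
  expect_false("A" %in% got2$code)
  expect_identical(got2$code, c("C", "B"))

  # below-floor code dropped
  spec3 <- dimension_spec("inpatient_dx", "claims", min_prevalence = 0.3)
  got3 <- identify_candidates(make_code_table(presence2), spec3, ids)
  expect_identical(sort(got3$code), c("B", "C"))

  expect_warning(identify_candidates(make_code_table(presence2),
                                     dimension_spec("carrier", "claims"), ids),
                 "no codes")
})

test_that("recurrence expansion uses interpolated quantiles of positive counts", {
  lv <- expand_recurrence("X", c(0, 1, 1, 2, 5))
  expect_named(lv, c("once", "sporadic", "frequent"))
  expect_identical(lv$once, c(0L, 1L, 1L, 1L, 1L))
  expect_identical(lv$sporadic, c(0L, 0L, 0L, 1L, 1L))
  expect_identical(lv$frequent, c(0L, 0L, 0L, 0L, 1L))
  thr <- attr(lv, "thresholds")
  expect_equal(unname(thr), c(1, 1.5, 2.75))

  # degenerate collapse: median = q75 = 1 duplicates the once level
  lv2 <- expand_recurrence("X", c(0, 1, 1, 1))
  expect_named(lv2, "once")

  # constant positive counts collapse to a single covariate
  lv3 <- expand_recurrence("X", c(3, 3, 3))
  expect_named(lv3, "once")
  expect_identical(lv3$once, c(1L, 1L, 1L))

  expect_error(expand_recurrence("X", c(0, 0, 0)), "all-zero")
  expect_error(expand_recurrence("X", c(-1, 2)), "nonnegative")
})

test_that("the Bross multiplier matches hand arithmetic and its null cases", {
  expect_equal(bias_multiplier(0.2, 0.1, 2.0), 1.2 / 1.1)
  expect_equal(abs(log(bias_multiplier(0.2, 0.1, 2.0))), 0.08701,
               tolerance = 1e-4)
  expect_equal(bias_multiplier(0.7, 0.2, 1.0), 1.0)
  expect_equal(bias_multiplier(0.3, 0.3, 5.0), 1.0)
  expect_error(bias_multiplier(0.2, 0.1, -1), "rr_cd")
  expect_error(bias_multiplier(NaN, 0.1, 2), "NaN")
})

test_that("the multiplier is reciprocal under arm swap, so |log bias| is symmetric", {
  set.seed(42)
  for (i in 1:100) {
    pc1 <- runif(1); pc0 <- runif(1); rr <- exp(rnorm(1))
    m <- bias_multiplier(pc1, pc0, rr, clamp_rr = FALSE)
    m_swap <- bias_multiplier(pc0, pc1, rr, clamp_rr = FALSE)
    expect_equal(m * m_swap, 1, tolerance = 1e-12)
    expect_equal(bias_multiplier(pc1, pc0, rr), oracle_bross(pc1, pc0, rr),
                 tolerance = 1e-12)
  }
})

test_that("ranking sorts by |log bias| with deterministic tie-breaks and respects k", {
  cov <- data.frame(
    dimension = "d", code = c("a", "b", "c"), level = "once",
    abs_log_bias = c(0.3, 0.0, 0.1), stringsAsFactors = FALSE)
  got <- rank_and_select(cov, k = 2L)
  expect_identical(got$code, c("a", "c", "b"))
  expect_identical(got$selected, c(TRUE, TRUE, FALSE))
  all_sel <- rank_and_select(cov, k = 10L)
  expect_true(all(all_sel$selected))
  expect_error(rank_and_select(cov, k = 0L), "k must be")

  # brute-force re-sort oracle on random instances
  set.seed(7)
  for (i in 1:100) {
    n <- sample(3:12, 1)
    cv <- data.frame(
      dimension = sample(letters[1:3], n, replace = TRUE),
      code = sample(sprintf("c%02d", 1:6), n, replace = TRUE),
      level = sample(c("once", "sporadic", "frequent"), n, replace = TRUE),
      abs_log_bias = sample(round(runif(4), 2), n, replace = TRUE),
      stringsAsFactors = FALSE)
    cv <- cv[!duplicated(cv[, 1:3]), ]
    got <- rank_and_select(cv, k = 3L)
    ord <- order(-cv$abs_log_bias, cv$dimension, cv$code, cv$level)
    expect_identical(got$code, cv$code[ord])
    expect_false(is.unsorted(rev(got$abs_log_bias)))
    expect_false(anyDuplicated(got$rank) > 0)
  }
})

test_that("zero outcome cells get the continuity correction", {
  cov <- c(1, 1, 0, 0)
  death <- c(1, 1, 1, 1)   # no survivors: two zero cells
  rr <- hdpsbench:::covariate_outcome_rr(cov, death)
  expect_true(is.finite(rr) && rr > 0)
  expect_equal(rr, (2.1 / 2.2) / (2.1 / 2.2))
})

test_that("end-to-end ranking finds a planted confounder and excludes dimensions", {
  sim <- generate_cohort(tiny_scenario(n = 900L, seed = 77L, missing = FALSE))
  rk <- hdps_rank(sim$cohort, claims = sim$claims, registry = sim$registry,
                  source = "both", k = 30L)
  expect_s3_class(rk$ranking, "data.frame")
  expect_false(is.unsorted(rev(rk$ranking$abs_log_bias)))
  expect_identical(colnames(rk$indicators),
                   paste(rk$ranking$dimension, rk$ranking$code,
                         rk$ranking$level, sep = "|"))
  # the registry's risk composite is a strong treatment driver: top 5
  hsr_rows <- which(rk$ranking$dimension == "high_surgical_risk")
  expect_lte(min(rk$ranking$rank[hsr_rows]), 5L)

  excl <- hdps_rank(sim$cohort, claims = sim$claims, registry = sim$registry,
                    source = "both", k = 30L,
                    exclude_dimensions = "high_surgical_risk")
  expect_false("high_surgical_risk" %in% excl$ranking$dimension)
  # deriving the exclusion from the full ranking is equivalent
  derived <- hdps_exclude(rk, "high_surgical_risk", k = 30L)
  expect_equal(derived$ranking[, c("dimension", "code", "level", "rank")],
               excl$ranking[, c("dimension", "code", "level", "rank")])
})
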