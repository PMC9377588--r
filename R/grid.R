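# Full study-design grid: every (PS strategy x data source x adjustment)
# cell estimated against the benchmark hazard ratio, plus a replication
# engine reporting bias, empirical SE, RMSE and coverage per cell.

#' The seven shipped PS model variants
#'
#' Investigator-specified models on claims, registry, and both sources,
#' and hdPS models on claims, registry, both-minus-high-surgical-risk,
#' and both.
#'
#' @param k hdPS selection size.
#' @return list of [ps_model_spec()].
#' @export
default_model_specs <- function(k = 500L) {
  list(
    ps_model_spec("investigator", "claims"),
    ps_model_spec("investigator", "registry"),
    ps_model_spec("investigator", "both"),
    ps_model_spec("hdps", "claims", k = k),
    ps_model_spec("hdps", "registry", k = k),
    ps_model_spec("hdps", "both_minus_risk", k = k),
    ps_model_spec("hdps", "both", k = k)
  )
}

#' Specify the evaluation grid
#'
#' @param models list of [ps_model_spec()]; default the seven shipped
#'   variants.
#' @param adjustments subset of `c("quintiles", "quintiles_trimmed",
#'   "matched")`.
#' @param benchmark_hr the hazard ratio a valid adjustment should
#'   recover (default 1.0).
#' @param m number of imputations (default 5).
#' @param caliper_mult matching caliper multiplier.
#' @param trim_alpha asymmetric trimming fraction.
#' @param top_n_codes,min_prevalence hdPS screening parameters.
#' @param quintiles_as_strata enter quintiles as baseline-hazard strata
#'   instead of indicator terms.
#' @param compute_balance also compute covariate balance for the
#'   matched design of each model.
#' @return a `grid_spec`.
#' @export
grid_spec <- function(models = default_model_specs(),
                      adjustments = c("quintiles", "quintiles_trimmed",
                                      "matched"),
                      benchmark_hr = 1.0, m = 5L, caliper_mult = 0.2,
                      trim_alpha = 0.05, top_n_codes = 200L,
                      min_prevalence = 0.01, quintiles_as_strata = FALSE,
                      compute_balance = FALSE) {
  if (!length(models) || !length(adjustments)) {
    stop("need at least one model and one adjustment", call. = FALSE)
  }
  adjustments <- match.arg(adjustments,
                           c("quintiles", "quintiles_trimmed", "matched"),
                           several.ok = TRUE)
  structure(list(models = models, adjustments = adjustments,
                 benchmark_hr = benchmark_hr, m = as.integer(m),
                 caliper_mult = caliper_mult, trim_alpha = trim_alpha,
                 top_n_codes = top_n_codes, min_prevalence = min_prevalence,
                 quintiles_as_strata = quintiles_as_strata,
                 compute_balance = compute_balance),
            class = "grid_spec")
}

# one adjusted Cox estimate for a fitted score vector
adjusted_estimate <- function(cohort, score, adjustment, spec, model_id) {
  if (adjustment == "matched") {
    mr <- match_1to1(score, cohort$exposure, spec$caliper_mult,
                     ids = cohort$patient_id)
    if (nrow(mr$pairs) < 2L) stop("too few matched pairs", call. = FALSE)
    ei <- match(mr$pairs$exposed_id, cohort$patient_id)
    ui <- match(mr$pairs$unexposed_id, cohort$patient_id)
    dat <- cohort[c(ei, ui), , drop = FALSE]
    pair <- rep(mr$pairs$pair_id, 2L)
    est <- fit_cox(dat, terms = "exposure", cluster_ids = pair,
                   adjustment = "matched", model_id = model_id)
    est$match <- mr
    return(est)
  }
  rows <- rep(TRUE, nrow(cohort))
  if (adjustment == "quintiles_trimmed") {
    tr <- asymmetric_trim(score, cohort$exposure, spec$trim_alpha,
                          ids = cohort$patient_id)
    rows <- tr$retained
  }
  dat <- cohort[rows, , drop = FALSE]
  q <- assign_quintiles(score[rows])
  if (spec$quintiles_as_strata) {
    dat$ps_quintile <- q$labels
    est <- fit_cox(dat, terms = "exposure", cluster_ids = dat$hospital_id,
                   strata = "ps_quintile", adjustment = adjustment,
                   model_id = model_id)
  } else {
    terms <- "exposure"
    for (lv in 2:5) {
      col <- paste0("ps_q", lv)
      dat[[col]] <- as.integer(q$labels == lv)
      if (any(dat[[col]] == 1)) terms <- c(terms, col)
    }
    est <- fit_cox(dat, terms = terms, cluster_ids = dat$hospital_id,
                   adjustment = adjustment, model_id = model_id)
  }
  est
}

#' Run the full design grid on one cohort
#'
#' Imputes the registry `m` times, fits every PS model variant within
#' each completed dataset (claims-only models do not depend on the
#' imputation and are fitted once), applies every adjustment, estimates
#' the exposure hazard ratio per cell with cluster-robust variance, and
#' pools across imputations by Rubin's rules.  Grid cells share the
#' same imputation set so cell differences reflect the PS design only.
#' Per-cell failures are recorded, not fatal.
#'
#' @param cohort,claims,registry linked tables from [generate_cohort()].
#' @param spec a [grid_spec()].
#' @param seed integer seed driving imputation draws.
#' @return object of class `grid_result`: data.frame `cells`, the
#'   `crude` hazard estimate, `c_statistics`, the claims/registry
#'   `rankings`, optional `balance`, and the `seed`.
#' @export
run_grid <- function(cohort, claims, registry, spec = grid_spec(),
                     seed = 1L) {
  imp <- impute_registry(registry, cohort, m = spec$m, seed = child_seed(seed, 1L))

  needs_hdps <- vapply(spec$models, function(ms) ms$strategy == "hdps", logical(1))
  hdps_sources <- unique(vapply(spec$models[needs_hdps], `[[`, character(1), "source"))
  kmax <- if (any(needs_hdps)) max(vapply(spec$models[needs_hdps], `[[`,
                                          integer(1), "k")) else 500L
  rank_args <- list(top_n_codes = spec$top_n_codes,
                    min_prevalence = spec$min_prevalence, k = kmax)

  ranking_claims <- if (any(hdps_sources == "claims")) {
    do.call(hdps_rank, c(list(cohort, claims = claims, source = "claims"),
                         rank_args))
  }

  # per-imputation rankings, cached by (source, imputation); the blinded
  # variant is derived from the cached "both" ranking
  rank_cache <- new.env(parent = emptyenv())
  rank_for <- function(src, ii) {
    if (src == "claims") return(ranking_claims)
    key <- paste(src, ii, sep = "#")
    if (!is.null(rank_cache[[key]])) return(rank_cache[[key]])
    val <- if (src == "both_minus_risk") {
      hdps_exclude(rank_for("both", ii), "high_surgical_risk")
    } else {
      do.call(hdps_rank, c(list(cohort, claims = claims,
                                registry = imp$completed[[ii]], source = src),
                           rank_args))
    }
    rank_cache[[key]] <- val
    val
  }

  fits <- vector("list", length(spec$models))
  names(fits) <- vapply(spec$models, `[[`, character(1), "model_id")
  for (mi in seq_along(spec$models)) {
    ms <- spec$models[[mi]]
    uses_registry <- ms$source != "claims"
    n_fit <- if (uses_registry) spec$m else 1L
    per_imp <- vector("list", n_fit)
    for (ii in seq_len(n_fit)) {
      reg <- imp$completed[[ii]]
      ranking <- if (ms$strategy == "hdps") rank_for(ms$source, ii) else NULL
      X <- assemble_design(ms, cohort, claims = claims, registry = reg,
                           ranking = ranking)
      per_imp[[ii]] <- list(fit = fit_propensity(X, cohort$exposure),
                            design = X, ranking = ranking)
    }
    fits[[mi]] <- list(spec = ms, per_imp = per_imp,
                       uses_registry = uses_registry)
  }

  crude <- fit_cox(cohort, terms = "exposure",
                   cluster_ids = cohort$hospital_id,
                   adjustment = "crude", model_id = "crude")

  cells <- list()
  balance <- list()
  for (mf in fits) {
    ms <- mf$spec
    cstat <- mean(vapply(mf$per_imp, function(pi) pi$fit$c_statistic, numeric(1)))
    for (adj in spec$adjustments) {
      res <- tryCatch({
        ests <- lapply(seq_len(spec$m), function(ii) {
          pi <- mf$per_imp[[min(ii, length(mf$per_imp))]]
          adjusted_estimate(cohort, pi$fit$score, adj, spec, ms$model_id)
        })
        pooled <- pool_rubin(vapply(ests, `[[`, numeric(1), "log_hr"),
                             vapply(ests, function(e) e$se_log_hr^2, numeric(1)))
        nmat <- round(rowMeans(vapply(ests, `[[`, numeric(2), "n")))
        emat <- round(rowMeans(vapply(ests, `[[`, numeric(2), "events")))
        data.frame(
          model_id = ms$model_id, strategy = ms$strategy, source = ms$source,
          adjustment = adj, c_statistic = cstat,
          n_exposed = nmat[["exposed"]], n_unexposed = nmat[["unexposed"]],
          events_exposed = emat[["exposed"]],
          events_unexposed = emat[["unexposed"]],
          hr = pooled$hr, ci_lo = pooled$ci95[1], ci_hi = pooled$ci95[2],
          se_log_hr = sqrt(pooled$T), log_hr = pooled$log_hr,
          error = NA_character_, stringsAsFactors = FALSE)
      }, error = function(e) {
        data.frame(
          model_id = ms$model_id, strategy = ms$strategy, source = ms$source,
          adjustment = adj, c_statistic = cstat,
          n_exposed = NA_real_, n_unexposed = NA_real_,
          events_exposed = NA_real_, events_unexposed = NA_real_,
          hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
          se_log_hr = NA_real_, log_hr = NA_real_,
          error = conditionMessage(e), stringsAsFactors = FALSE)
      })
      cells[[length(cells) + 1L]] <- res
    }
    if (isTRUE(spec$compute_balance)) {
      pi1 <- mf$per_imp[[1L]]
      bal <- tryCatch({
        mr <- match_1to1(pi1$fit$score, cohort$exposure, spec$caliper_mult,
                         ids = cohort$patient_id)
        standardized_differences(pi1$design, cohort$exposure, match = mr,
                                 ids = cohort$patient_id)
      }, error = function(e) NULL)
      balance[[ms$model_id]] <- bal
    }
  }

  structure(list(
    cells = do.call(rbind, cells),
    crude = crude,
    c_statistics = data.frame(
      model_id = names(fits),
      c_statistic = vapply(fits, function(mf)
        mean(vapply(mf$per_imp, function(pi) pi$fit$c_statistic, numeric(1))),
        numeric(1)),
      n_covariates = vapply(fits, function(mf)
        mf$per_imp[[1L]]$fit$n_covariates, numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE),
    rankings = list(
      claims = ranking_claims,
      registry = rank_cache[["registry#1"]],
      both = rank_cache[["both#1"]]),
    balance = if (length(balance)) balance,
    benchmark_hr = spec$benchmark_hr,
    seed = as.integer(seed)
  ), class = "grid_result")
}

#' Replicate the design grid over independent cohorts
#'
#' Generates `n_reps` independent cohorts from the scenario (seeds
#' derived from `base_seed`), runs the grid on each, and summarizes
#' per-cell log-HR bias against the benchmark, empirical SE, RMSE, and
#' 95% CI coverage.  Cells failing in more than 20% of replicates are
#' flagged invalid.
#'
#' @param scenario a [scenario_config()].
#' @param spec a [grid_spec()].
#' @param n_reps number of replicates (>= 2).
#' @param base_seed integer base seed.
#' @param progress print per-replicate progress to stderr.
#' @return object of class `replication_summary`: `summary` data.frame
#'   (one row per cell incl. crude), `per_rep` data.frame of every
#'   cell estimate, and the `seeds` used.
#' @export
replicate_grid <- function(scenario, spec = grid_spec(), n_reps = 50L,
                           base_seed = 1L, progress = FALSE) {
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  seeds <- vapply(seq_len(n_reps), function(i) child_seed(base_seed, i),
                  integer(1))
  per_rep <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    sc <- scenario
    sc$seed <- seeds[i]
    sim <- generate_cohort(sc)
    gr <- run_grid(sim$cohort, sim$claims, sim$registry, spec,
                   seed = child_seed(seeds[i], 7L))
    rows <- gr$cells[, c("model_id", "adjustment", "log_hr", "hr",
                         "ci_lo", "ci_hi", "error")]
    rows <- rbind(rows, data.frame(
      model_id = "crude", adjustment = "crude", log_hr = gr$crude$log_hr,
      hr = gr$crude$hr, ci_lo = gr$crude$ci95[1], ci_hi = gr$crude$ci95[2],
      error = NA_character_, stringsAsFactors = FALSE))
    rows$rep <- i
    per_rep[[i]] <- rows
    if (progress) message(sprintf("replicate %d/%d done", i, n_reps))
  }
  per_rep <- do.call(rbind, per_rep)
  bench <- log(spec$benchmark_hr)
  key <- paste(per_rep$model_id, per_rep$adjustment, sep = "::")
  summ <- lapply(split(per_rep, key), function(d) {
    ok <- is.na(d$error) & is.finite(d$log_hr)
    x <- d$log_hr[ok]
    data.frame(
      model_id = d$model_id[1L], adjustment = d$adjustment[1L],
      n_ok = sum(ok), n_fail = sum(!ok),
      mean_log_hr = mean(x),
      bias = mean(x) - bench,
      abs_bias = abs(mean(x) - bench),
      empirical_se = stats::sd(x),
      rmse = sqrt(mean((x - bench)^2)),
      coverage = mean(d$ci_lo[ok] <= exp(bench) & d$ci_hi[ok] >= exp(bench)),
      invalid = sum(!ok) > 0.2 * nrow(d),
      stringsAsFactors = FALSE)
  })
  structure(list(summary = do.call(rbind, c(summ, list(make.row.names = FALSE))),
                 per_rep = per_rep, seeds = seeds,
                 benchmark_hr = spec$benchmark_hr),
            class = "replication_summary")
}
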