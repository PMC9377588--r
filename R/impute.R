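# Multiple imputation of missing registry covariates and Rubin's-rules
# pooling of hazard estimates across completed datasets.

#' Multiply impute missing registry values
#'
#' `draw_from_conditional` fills each missing binary/categorical value
#' by sampling the observed distribution of that variable within cells
#' of exposure x event (falling back to the marginal distribution, with
#' a warning, when a cell has no observed values); `mode_fill` is the
#' deterministic fallback that fills with the within-cell mode.
#' Deterministic given `seed`.
#'
#' @param registry registry table with `missing` flags.
#' @param cohort cohort table supplying `exposure` and `event`.
#' @param m number of imputations (default 5).
#' @param method `"draw_from_conditional"` or `"mode_fill"`.
#' @param seed integer seed.
#' @return object of class `imputation_set`: list `completed` of m
#'   registry tables with zero missing values, plus `m`, `method`,
#'   `seed`.
#' @export
impute_registry <- function(registry, cohort, m = 5L,
                            method = c("draw_from_conditional", "mode_fill"),
                            seed = 1L) {
  method <- match.arg(method)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  cell <- paste(cohort$exposure, cohort$event, sep = ":")
  names(cell) <- cohort$patient_id
  miss_idx <- which(registry$missing)
  completed <- with_local_seed(seed, {
    lapply(seq_len(m), function(imp) {
      out <- registry
      if (!length(miss_idx)) return(out)
      for (v in unique(registry$variable[miss_idx])) {
        rows <- miss_idx[registry$variable[miss_idx] == v]
        obs_rows <- which(registry$variable == v & !registry$missing)
        obs_val <- registry$value[obs_rows]
        obs_cell <- cell[registry$patient_id[obs_rows]]
        fill_cell <- cell[registry$patient_id[rows]]
        for (cl in unique(fill_cell)) {
          tgt <- rows[fill_cell == cl]
          pool <- obs_val[obs_cell == cl]
          if (!length(pool)) {
            if (!length(obs_val)) {
              warning(sprintf(
                "variable '%s' has no observed values; filling with 0", v),
                call. = FALSE)
              pool <- 0L
            } else {
              warning(sprintf(
                "variable '%s' unobserved in cell %s; marginal fallback", v, cl),
                call. = FALSE)
              pool <- obs_val
            }
          }
          fill <- if (method == "draw_from_conditional") {
            pool[sample.int(length(pool), length(tgt), replace = TRUE)]
          } else {
            tab <- sort(table(pool), decreasing = TRUE)
            rep(utils::type.convert(names(tab)[1L], as.is = TRUE), length(tgt))
          }
          out$value[tgt] <- fill
        }
      }
      out$missing <- FALSE
      out
    })
  })
  structure(list(completed = completed, m = as.integer(m),
                 method = method, seed = as.integer(seed)),
            class = "imputation_set")
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled point estimate = mean of the per-imputation log hazard
#' ratios; total variance `T = W + (1 + 1/m) B` with `W` the mean
#' within-imputation variance and `B` the between-imputation sample
#' variance; CI from the t distribution with Rubin's degrees of freedom
#' `(m - 1) (1 + W / ((1 + 1/m) B))^2` (infinite when `B = 0`).
#'
#' @param log_hrs per-imputation log hazard ratios.
#' @param variances per-imputation squared standard errors.
#' @return object of class `pooled_estimate`: `log_hr`, `hr`, `ci95`,
#'   `W`, `B`, `T`, `df`, `m`.
#' @export
pool_rubin <- function(log_hrs, variances) {
  m <- length(log_hrs)
  if (m < 1) stop("need at least one estimate", call. = FALSE)
  if (length(variances) != m) stop("length mismatch", call. = FALSE)
  q <- mean(log_hrs)
  W <- mean(variances)
  B <- if (m > 1) stats::var(log_hrs) else 0
  Tv <- W + (1 + 1 / m) * B
  df <- if (B > 0 && m > 1) (m - 1) * (1 + W / ((1 + 1 / m) * B))^2 else Inf
  tq <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  structure(list(
    log_hr = q, hr = exp(q),
    ci95 = exp(c(q - tq * sqrt(Tv), q + tq * sqrt(Tv))),
    W = W, B = B, T = Tv, df = df, m = m
  ), class = "pooled_estimate")
}
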