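# Propensity-score model variants (investigator-specified vs automated
# data-adaptive) and fitting with discrimination diagnostics.

#' Specify one propensity-score model variant
#'
#' @param strategy `"investigator"` (pre-specified variable lists) or
#'   `"hdps"` (automated data-adaptive selection).
#' @param source data source the model may see: `"claims"`,
#'   `"registry"`, `"both"`, or `"both_minus_risk"` (hdPS only: both
#'   sources but blinded to the high-surgical-risk dimension).
#' @param k hdPS selection size.
#' @param forced_covariates demographics always included.
#' @return a `ps_model_spec`.
#' @export
ps_model_spec <- function(strategy = c("investigator", "hdps"),
                          source = c("claims", "registry", "both",
                                     "both_minus_risk"),
                          k = 500L,
                          forced_covariates = c("age_group", "female",
                                                "white", "year")) {
  strategy <- match.arg(strategy)
  source <- match.arg(source)
  if (source == "both_minus_risk" && strategy != "hdps") {
    stop("both_minus_risk is only defined for the hdps strategy", call. = FALSE)
  }
  structure(list(strategy = strategy, source = source, k = as.integer(k),
                 forced_covariates = forced_covariates,
                 model_id = paste(strategy, source, sep = "_")),
            class = "ps_model_spec")
}

# indicator expansion of the forced demographic covariates; reference
# levels dropped; deterministic column order
forced_design <- function(cohort, forced_covariates) {
  cols <- list()
  if ("age_group" %in% forced_covariates) {
    lv <- sort(unique(cohort$age_group))
    for (l in lv[-1]) cols[[paste0("age_", l)]] <- as.integer(cohort$age_group == l)
  }
  if ("female" %in% forced_covariates) cols[["female"]] <- cohort$female
  if ("white" %in% forced_covariates) cols[["white"]] <- cohort$white
  if ("year" %in% forced_covariates) {
    lv <- sort(unique(cohort$year))
    for (l in lv[-1]) cols[[paste0("year_", l)]] <- as.integer(cohort$year == l)
  }
  if (!length(cols)) return(NULL)
  do.call(cbind, cols)
}

# Investigator-specified claims variables: any-occurrence indicators of
# each clinically named code group (the simulator numbers clinical-concept
# codes below 1000; noise codes from 1000 up, mirroring an investigator
# who pre-specifies known comorbidity codes but not arbitrary service
# codes), plus utilization measures derived from the claims stream.
investigator_claims_design <- function(cohort, claims) {
  ids <- cohort$patient_id
  num <- as.integer(sub("^[A-Z]+", "", claims$code))
  clinical <- claims[num < 1000L, , drop = FALSE]
  group <- as.integer(sub("^[A-Z]+", "", clinical$code))
  cols <- list()
  for (g in sort(unique(group))) {
    with_g <- unique(clinical$patient_id[group == g])
    cols[[sprintf("cond_code_%02d", g)]] <- as.integer(ids %in% with_g)
  }
  tot <- tapply(claims$count, claims$patient_id, sum)
  ncode <- tapply(claims$code, claims$patient_id, function(x) length(unique(x)))
  nh <- unique(claims$patient_id[claims$dimension == "nursing_home"])
  cols[["util_log_total_claims"]] <-
    log1p(unname(ifelse(is.na(tot[ids]), 0, tot[ids])))
  cols[["util_log_distinct_codes"]] <-
    log1p(unname(ifelse(is.na(ncode[ids]), 0, ncode[ids])))
  cols[["util_any_nursing_home"]] <- as.integer(ids %in% nh)
  do.call(cbind, cols)
}

# Investigator-specified registry variables: every registry variable as
# a binary indicator (missing treated as absent; impute first)
investigator_registry_design <- function(cohort, registry) {
  codes <- registry_as_codes(registry)
  vars <- sort(unique(registry$variable))
  ids <- cohort$patient_id
  cols <- lapply(vars, function(v) {
    with_v <- codes$patient_id[codes$code == v]
    as.integer(ids %in% with_v)
  })
  m <- do.call(cbind, cols)
  colnames(m) <- paste0("reg_", vars)
  m
}

#' Assemble the design matrix for a PS model variant
#'
#' Binds the forced demographic indicators with either the
#' investigator-specified variable set for the requested source or the
#' top-k hdPS covariates from a ranking.  The `both_minus_risk` variant
#' must be given a ranking built with
#' `exclude_dimensions = "high_surgical_risk"` so the blinding happens
#' before selection.
#'
#' @param spec a [ps_model_spec()].
#' @param cohort,claims,registry data tables.
#' @param ranking an `hdps_ranking` (required for `strategy = "hdps"`);
#'   its source must match the spec.
#' @return numeric design matrix (no intercept), deterministic column
#'   order, duplicate columns removed.
#' @export
assemble_design <- function(spec, cohort, claims = NULL, registry = NULL,
                            ranking = NULL) {
  parts <- list(forced_design(cohort, spec$forced_covariates))
  if (spec$strategy == "investigator") {
    if (spec$source %in% c("claims", "both")) {
      parts <- c(parts, list(investigator_claims_design(cohort, claims)))
    }
    if (spec$source %in% c("registry", "both")) {
      parts <- c(parts, list(investigator_registry_design(cohort, registry)))
    }
  } else {
    if (is.null(ranking) || !inherits(ranking, "hdps_ranking")) {
      stop("hdps strategy needs an hdps_ranking", call. = FALSE)
    }
    if (spec$source == "both_minus_risk" &&
        "high_surgical_risk" %in% ranking$ranking$dimension) {
      stop("both_minus_risk needs a ranking built with exclude_dimensions = ",
           "'high_surgical_risk'", call. = FALSE)
    }
    sel <- ranking$ranking$selected
    take <- utils::head(which(sel), spec$k)
    parts <- c(parts, list(ranking$indicators[, take, drop = FALSE]))
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  X <- do.call(cbind, parts)
  if (is.null(X) || !ncol(X)) stop("empty design", call. = FALSE)
  storage.mode(X) <- "double"
  # drop exact duplicate columns (keep first) and constants
  dup <- duplicated(t(X))
  const <- apply(X, 2, function(x) length(unique(x)) == 1L)
  keep <- !(dup | const)
  if (!any(keep)) stop("empty design after pruning", call. = FALSE)
  X[, keep, drop = FALSE]
}

#' Fit a propensity score by ridge-penalized logistic regression
#'
#' Penalized maximum likelihood via iteratively reweighted least
#' squares with a small ridge penalty on the non-intercept coefficients
#' (lambda = 1e-6 by default).  When the fit fails to converge —
#' quasi-separation is expected when treatment indication is nearly
#' deterministic — the penalty escalates through 1e-3 and 1e-1.
#' Scores are clipped away from 0/1 by 1e-12.
#'
#' @param design numeric design matrix without intercept.
#' @param exposure 0/1 vector.
#' @param lambda_ladder increasing ridge penalties tried in order.
#' @return object of class `ps_fit`: `score`, `linear_predictor`,
#'   `c_statistic`, `n_covariates`, `convergence`, `lambda`,
#'   `coefficients`.
#' @export
fit_propensity <- function(design, exposure,
                           lambda_ladder = c(1e-6, 1e-3, 1e-1)) {
  if (length(unique(exposure)) < 2L) stop("exposure has one level", call. = FALSE)
  if (nrow(design) != length(exposure)) stop("dimension mismatch", call. = FALSE)
  X <- cbind(`(intercept)` = 1, design)
  p <- ncol(X)
  pen <- c(0, rep(1, p - 1L))  # intercept unpenalized
  fit <- NULL
  for (lambda in lambda_ladder) {
    fit <- ridge_logistic_irls(X, exposure, lambda * pen)
    if (fit$converged) break
  }
  lp <- unname(drop(X %*% fit$beta))
  score <- pmin(pmax(expit(lp), 1e-12), 1 - 1e-12)
  structure(list(
    score = score,
    linear_predictor = lp,
    c_statistic = c_statistic(score, exposure),
    n_covariates = ncol(design),
    convergence = fit$converged,
    lambda = fit$lambda,
    coefficients = stats::setNames(fit$beta, colnames(X))
  ), class = "ps_fit")
}

# IRLS for ridge-penalized logistic log-likelihood
#   l(b) - (1/2) * sum_j pen_j * b_j^2
ridge_logistic_irls <- function(X, y, pen, max_iter = 60L, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  lambda <- max(pen)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    eta <- pmin(pmax(eta, -30), 30)
    mu <- expit(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    H <- crossprod(X * sqrt(w))
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    beta_new <- beta + step
    if (max(abs(step)) < tol * (1 + max(abs(beta)))) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
  }
  list(beta = beta, converged = converged, lambda = lambda, iterations = it)
}

#' Concordance (c-) statistic of a propensity model
#'
#' The probability that a randomly chosen exposed patient has a higher
#' score than a randomly chosen unexposed one, ties counted 1/2.  The
#' default rank-based path is O(n log n); `method = "pairwise"` is the
#' literal O(n1*n0) enumeration kept as a cross-check.
#'
#' @param scores numeric scores.
#' @param exposure 0/1 vector.
#' @param method `"rank"` or `"pairwise"`.
#' @return concordance in \[0, 1\].
#' @export
c_statistic <- function(scores, exposure, method = c("rank", "pairwise")) {
  method <- match.arg(method)
  s1 <- scores[exposure == 1]
  s0 <- scores[exposure == 0]
  if (!length(s1) || !length(s0)) stop("both arms must be non-empty", call. = FALSE)
  if (method == "pairwise") {
    total <- 0
    for (a in s1) total <- total + sum(a > s0) + 0.5 * sum(a == s0)
    return(total / (length(s1) * length(s0)))
  }
  r <- rank(c(s1, s0), ties.method = "average")
  (sum(r[seq_along(s1)]) - length(s1) * (length(s1) + 1) / 2) /
    (length(s1) * length(s0))
}
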