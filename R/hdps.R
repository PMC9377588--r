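# Automated data-adaptive (high-dimensional PS) covariate engine:
# (1) empirical candidate identification per data dimension,
# (2) recurrence expansion (once / sporadic / frequent),
# (3) Bross bias-multiplier prioritization and top-k selection.

#' Specify screening parameters for one data dimension
#'
#' @param name dimension name.
#' @param source `"claims"` or `"registry"`.
#' @param top_n_codes maximum number of candidate codes retained per
#'   dimension (default 200), ranked by deviation from ubiquity
#'   `min(p, 1 - p)`.
#' @param min_prevalence prevalence floor for candidacy (default 0.01).
#' @return a `dimension_spec` list.
#' @export
dimension_spec <- function(name, source = c("claims", "registry"),
                           top_n_codes = 200L, min_prevalence = 0.01) {
  source <- match.arg(source)
  if (top_n_codes < 1) stop("top_n_codes must be >= 1", call. = FALSE)
  if (min_prevalence < 0 || min_prevalence > 0.5) {
    stop("min_prevalence must be in [0, 0.5]", call. = FALSE)
  }
  structure(list(name = name, source = source,
                 top_n_codes = as.integer(top_n_codes),
                 min_prevalence = min_prevalence),
            class = "dimension_spec")
}

#' Identify candidate codes within a data dimension
#'
#' Keeps codes whose patient-level prevalence (fraction of cohort
#' patients with count >= 1) is at least `spec$min_prevalence`, then
#' retains the `top_n_codes` with the largest deviation from ubiquity
#' `min(p, 1 - p)`, ties broken lexicographically by code.
#'
#' @param codes long table with columns `patient_id`, `dimension`,
#'   `code`, `count`.
#' @param spec a [dimension_spec()].
#' @param patient_ids character vector of all cohort patient ids (the
#'   prevalence denominator).
#' @return data.frame with columns `code`, `prevalence`.
#' @export
identify_candidates <- function(codes, spec, patient_ids) {
  n <- length(patient_ids)
  rows <- codes[codes$dimension == spec$name & codes$count >= 1, , drop = FALSE]
  if (!nrow(rows)) {
    warning(sprintf("dimension '%s' has no codes", spec$name), call. = FALSE)
    return(data.frame(code = character(0), prevalence = numeric(0)))
  }
  tab <- table(unique(rows[, c("patient_id", "code")])$code)
  prev <- as.numeric(tab) / n
  code <- names(tab)
  keep <- prev >= spec$min_prevalence
  code <- code[keep]; prev <- prev[keep]
  dev <- pmin(prev, 1 - prev)
  ord <- order(-dev, code)
  take <- utils::head(ord, spec$top_n_codes)
  data.frame(code = code[take], prevalence = prev[take],
             stringsAsFactors = FALSE)
}

#' Expand a code into recurrence-level covariates
#'
#' Builds up to three binary covariates from a patient-level count
#' vector: occurred at least once, at least "sporadically" (count >=
#' median of the positive counts), and at least "frequently" (count >=
#' 75th percentile of the positive counts), quantiles computed with
#' linear interpolation over patients with count >= 1.  Levels whose
#' indicator duplicates a lower level are dropped.
#'
#' @param code code token (used for naming only).
#' @param counts nonnegative integer counts over all cohort patients.
#' @return named list of 0/1 integer vectors, names in
#'   `c("once", "sporadic", "frequent")`.
#' @export
expand_recurrence <- function(code, counts) {
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  pos <- counts[counts >= 1]
  if (!length(pos)) {
    stop(sprintf("code '%s' has all-zero counts; filter upstream", code),
         call. = FALSE)
  }
  thr <- c(once = 1,
           sporadic = pctile(pos, 0.5),
           frequent = pctile(pos, 0.75))
  out <- list(once = as.integer(counts >= thr[["once"]]))
  spor <- as.integer(counts >= thr[["sporadic"]])
  if (!identical(spor, out$once)) out$sporadic <- spor
  freq <- as.integer(counts >= thr[["frequent"]])
  last <- out[[length(out)]]
  if (!identical(freq, last)) out$frequent <- freq
  attr(out, "thresholds") <- thr
  out
}

#' Bross bias multiplier of a binary covariate
#'
#' The multiplicative confounding bias a binary covariate could induce
#' on the exposure-outcome association:
#' `(pc1 * (rr - 1) + 1) / (pc0 * (rr - 1) + 1)`, where `pc1`/`pc0` are
#' the covariate prevalences among exposed/unexposed and `rr` its crude
#' relative risk on the outcome.  By default `rr` is first clamped to
#' `max(rr, 1/rr)` so protective proxies rank symmetrically with harmful
#' ones; covariates are prioritized by `|log|` of the multiplier.
#'
#' @param pc1,pc0 covariate prevalence among exposed / unexposed.
#' @param rr_cd crude covariate-outcome relative risk (> 0).
#' @param clamp_rr clamp `rr_cd` to `max(rr, 1/rr)` (default TRUE).
#' @return the bias multiplier (vectorized).
#' @export
bias_multiplier <- function(pc1, pc0, rr_cd, clamp_rr = TRUE) {
  if (any(!is.finite(pc1)) || any(!is.finite(pc0)) || any(!is.finite(rr_cd))) {
    stop("NaN/Inf inputs to bias_multiplier", call. = FALSE)
  }
  stopifnot_prob(pc1, "pc1"); stopifnot_prob(pc0, "pc0")
  if (any(rr_cd <= 0)) stop("rr_cd must be > 0", call. = FALSE)
  if (clamp_rr) rr_cd <- pmax(rr_cd, 1 / rr_cd)
  (pc1 * (rr_cd - 1) + 1) / (pc0 * (rr_cd - 1) + 1)
}

# crude covariate-outcome relative risk on the binary any-death outcome,
# with +0.1 added to all four cells when any cell is zero
covariate_outcome_rr <- function(cov, death) {
  a <- sum(cov == 1 & death == 1); b <- sum(cov == 1 & death == 0)
  c_ <- sum(cov == 0 & death == 1); d <- sum(cov == 0 & death == 0)
  if (min(a, b, c_, d) == 0) {
    a <- a + 0.1; b <- b + 0.1; c_ <- c_ + 0.1; d <- d + 0.1
  }
  (a / (a + b)) / (c_ / (c_ + d))
}

#' Rank covariates by confounding potential and select the top k
#'
#' Sorts by `abs_log_bias` descending, ties broken lexicographically by
#' (dimension, code, level), and flags the first `min(k, n)` as
#' selected.
#'
#' @param covariates data.frame with at least columns `dimension`,
#'   `code`, `level`, `abs_log_bias`.
#' @param k number to select (default 500).
#' @return the data.frame reordered, with `rank` and `selected` columns.
#' @export
rank_and_select <- function(covariates, k = 500L) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  ord <- order(-covariates$abs_log_bias, covariates$dimension,
               covariates$code, covariates$level)
  out <- covariates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$selected <- out$rank <= min(k, nrow(out))
  rownames(out) <- NULL
  out
}

# registry long table -> claims-like long count table (counts in {0,1});
# missing values count as absent; continuous variables are binarized at
# the cohort median beforehand
registry_as_codes <- function(registry) {
  val <- registry$value
  if (!is.numeric(val)) val <- suppressWarnings(as.numeric(val))
  bin <- integer(length(val))
  for (v in unique(registry$variable)) {
    idx <- which(registry$variable == v)
    x <- val[idx]
    obs <- x[!is.na(x)]
    if (length(unique(obs)) > 2) {
      cut <- stats::median(obs)
      bin[idx] <- as.integer(!is.na(x) & x > cut)
    } else {
      bin[idx] <- as.integer(!is.na(x) & x != 0)
    }
  }
  out <- data.frame(patient_id = registry$patient_id,
                    dimension = registry$dimension,
                    code = registry$variable,
                    count = bin, stringsAsFactors = FALSE)
  out[out$count >= 1, , drop = FALSE]
}

# patients x codes count matrix for one dimension's candidate codes
dimension_count_matrix <- function(codes, dimension, candidate_codes, patient_ids) {
  m <- matrix(0L, length(patient_ids), length(candidate_codes),
              dimnames = list(patient_ids, candidate_codes))
  rows <- codes[codes$dimension == dimension &
                  codes$code %in% candidate_codes, , drop = FALSE]
  if (nrow(rows)) {
    i <- match(rows$patient_id, patient_ids)
    j <- match(rows$code, candidate_codes)
    m[cbind(i, j)] <- as.integer(rows$count)
  }
  m
}

#' Run the full hdPS covariate engine
#'
#' Scans the requested data dimensions, identifies candidate codes,
#' expands them by recurrence level, computes exposure/outcome
#' associations and Bross bias multipliers on the binary
#' any-death-during-follow-up outcome, and returns the prioritized
#' covariate ranking together with the patient-by-covariate indicator
#' matrix.
#'
#' @param cohort cohort table (`patient_id`, `exposure`, `event`).
#' @param claims claims long table (may be NULL when `source =
#'   "registry"`).
#' @param registry registry long table (may be NULL when `source =
#'   "claims"`); missing values are treated as absent, so impute first
#'   when missingness matters.
#' @param source `"claims"`, `"registry"`, or `"both"`.
#' @param k number of covariates to select (default 500).
#' @param top_n_codes,min_prevalence screening parameters applied to
#'   every dimension.
#' @param exclude_dimensions dimensions dropped before selection (e.g.
#'   `"high_surgical_risk"` for the risk-blinded model).
#' @param clamp_rr see [bias_multiplier()].
#' @return list of class `hdps_ranking` with elements `ranking`
#'   (data.frame: dimension, code, level, prevalence, pc1, pc0, rr_cd,
#'   bias_multiplier, abs_log_bias, rank, selected) and `indicators`
#'   (0/1 matrix, columns `dimension|code|level` in ranking order).
#' @export
hdps_rank <- function(cohort, claims = NULL, registry = NULL,
                      source = c("claims", "registry", "both"),
                      k = 500L, top_n_codes = 200L, min_prevalence = 0.01,
                      exclude_dimensions = NULL, clamp_rr = TRUE) {
  source <- match.arg(source)
  patient_ids <- cohort$patient_id
  exposure <- cohort$exposure
  death <- cohort$event

  sources <- list()
  if (source %in% c("claims", "both")) {
    if (is.null(claims)) stop("claims table required", call. = FALSE)
    sources$claims <- list(table = claims, dims = CLAIMS_DIMENSIONS)
  }
  if (source %in% c("registry", "both")) {
    if (is.null(registry)) stop("registry table required", call. = FALSE)
    sources$registry <- list(table = registry_as_codes(registry),
                             dims = REGISTRY_DIMENSIONS)
  }

  cov_cols <- list()
  meta <- list()
  for (src in names(sources)) {
    tab <- sources[[src]]$table
    for (d in setdiff(sources[[src]]$dims, exclude_dimensions)) {
      spec <- dimension_spec(d, source = src, top_n_codes = top_n_codes,
                             min_prevalence = min_prevalence)
      cand <- withCallingHandlers(
        identify_candidates(tab, spec, patient_ids),
        warning = function(w) invokeRestart("muffleWarning")
      )
      if (!nrow(cand)) next
      cm <- dimension_count_matrix(tab, d, cand$code, patient_ids)
      for (ci in seq_len(ncol(cm))) {
        levels <- expand_recurrence(cand$code[ci], cm[, ci])
        for (lv in names(levels)) {
          cov_cols[[length(cov_cols) + 1L]] <- levels[[lv]]
          meta[[length(meta) + 1L]] <- data.frame(
            dimension = d, code = cand$code[ci], level = lv,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(cov_cols)) stop("no hdPS candidate covariates found", call. = FALSE)

  ind <- do.call(cbind, cov_cols)
  meta <- do.call(rbind, meta)
  colnames(ind) <- paste(meta$dimension, meta$code, meta$level, sep = "|")
  rownames(ind) <- patient_ids

  e1 <- exposure == 1
  n1 <- sum(e1); n0 <- sum(!e1)
  pc1 <- colSums(ind[e1, , drop = FALSE]) / n1
  pc0 <- colSums(ind[!e1, , drop = FALSE]) / n0
  rr <- vapply(seq_len(ncol(ind)), function(j)
    covariate_outcome_rr(ind[, j], death), numeric(1))
  bm <- bias_multiplier(pc1, pc0, rr, clamp_rr = clamp_rr)

  ranking <- data.frame(
    meta,
    prevalence = colMeans(ind),
    pc1 = pc1, pc0 = pc0, rr_cd = rr,
    bias_multiplier = bm,
    abs_log_bias = abs(log(bm)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  ranking <- rank_and_select(ranking, k = k)
  key <- paste(ranking$dimension, ranking$code, ranking$level, sep = "|")
  ind <- ind[, key, drop = FALSE]
  structure(list(ranking = ranking, indicators = ind, k = as.integer(k),
                 source = source),
            class = "hdps_ranking")
}

#' Re-rank an hdPS covariate set after excluding dimensions
#'
#' Drops every covariate from the excluded dimensions and recomputes the
#' ranking and top-k selection.  Because prioritization scores are
#' per-covariate, this equals running [hdps_rank()] with
#' `exclude_dimensions` from scratch; it exists so the blinded variant
#' can reuse an already-assessed covariate set.
#'
#' @param ranking an `hdps_ranking`.
#' @param exclude_dimensions dimensions to remove.
#' @param k selection size; defaults to the original k.
#' @return a new `hdps_ranking`.
#' @export
hdps_exclude <- function(ranking, exclude_dimensions, k = ranking$k) {
  keep <- !(ranking$ranking$dimension %in% exclude_dimensions)
  if (!any(keep)) stop("exclusion removed every covariate", call. = FALSE)
  rk <- ranking$ranking[keep, , drop = FALSE]
  rk$rank <- NULL; rk$selected <- NULL
  rk <- rank_and_select(rk, k = k)
  key <- paste(rk$dimension, rk$code, rk$level, sep = "|")
  structure(list(ranking = rk,
                 indicators = ranking$indicators[, key, drop = FALSE],
                 k = as.integer(k), source = ranking$source),
            class = "hdps_ranking")
}
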