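# PS adjustment approaches: 1:1 caliper matching on the logit scale,
# quintile stratification, and 5% asymmetric trimming, plus covariate
# balance diagnostics.

#' 1:1 nearest-neighbor propensity matching with a caliper
#'
#' Greedy matching without replacement on the logit of the propensity
#' score.  The caliper is `caliper_mult` times the SD of the logit PS
#' over the whole cohort (the standard reading of "0.2 times the logit
#' of the propensity score"); `caliper_absolute = TRUE` instead treats
#' `caliper_mult` as an absolute logit distance.  Exposed patients are
#' processed in descending PS order (ties by patient id); candidate
#' distance ties go to the smaller unexposed id.
#'
#' @param ps scores in (0, 1), aligned with `exposure` and `ids`.
#' @param exposure 0/1 vector.
#' @param caliper_mult caliper multiplier (default 0.2).
#' @param ids patient ids; defaults to indices.
#' @param caliper_absolute treat `caliper_mult` as an absolute width.
#' @return object of class `match_result`: data.frame `pairs`
#'   (`exposed_id`, `unexposed_id`, `logit_distance`, `pair_id`),
#'   `caliper_width`, `n_unmatched_exposed`.
#' @export
match_1to1 <- function(ps, exposure, caliper_mult = 0.2, ids = NULL,
                       caliper_absolute = FALSE) {
  if (any(ps <= 0 | ps >= 1)) stop("scores must lie strictly in (0,1)", call. = FALSE)
  if (!any(exposure == 1) || !any(exposure == 0)) {
    stop("both arms must be non-empty", call. = FALSE)
  }
  if (is.null(ids)) ids <- as.character(seq_along(ps))
  lp <- logit(ps)
  width <- if (caliper_absolute) caliper_mult else caliper_mult * stats::sd(lp)

  ei <- which(exposure == 1)
  ui <- which(exposure == 0)
  ei <- ei[order(-ps[ei], ids[ei])]
  u_lp <- lp[ui]
  u_ids <- ids[ui]
  u_rank <- order(u_ids)           # for smaller-id tie-breaks
  id_pos <- integer(length(ui)); id_pos[u_rank] <- seq_along(ui)
  available <- rep(TRUE, length(ui))

  pairs <- vector("list", length(ei))
  n_pairs <- 0L
  for (e in ei) {
    cand <- which(available)
    if (!length(cand)) break
    d <- abs(u_lp[cand] - lp[e])
    ok <- d <= width + 1e-12
    if (!any(ok)) next
    cand <- cand[ok]; d <- d[ok]
    best <- cand[order(d, id_pos[cand])][1L]
    available[best] <- FALSE
    n_pairs <- n_pairs + 1L
    pairs[[n_pairs]] <- data.frame(
      exposed_id = ids[e], unexposed_id = u_ids[best],
      logit_distance = abs(u_lp[best] - lp[e]),
      stringsAsFactors = FALSE)
  }
  pairs <- if (n_pairs) do.call(rbind, pairs[seq_len(n_pairs)]) else
    data.frame(exposed_id = character(0), unexposed_id = character(0),
               logit_distance = numeric(0))
  pairs$pair_id <- seq_len(nrow(pairs))
  structure(list(pairs = pairs, caliper_width = width,
                 n_unmatched_exposed = length(ei) - nrow(pairs)),
            class = "match_result")
}

#' Assign propensity-score quintiles
#'
#' Cut points at the 20/40/60/80th percentiles (linear interpolation) of
#' the analysis sample's scores; label = 1 + number of cut points
#' strictly below the score, so scores equal to a cut point fall in the
#' lower stratum.
#'
#' @param ps numeric scores with at least 5 distinct values.
#' @return object of class `strata_assignment`: integer `labels` (1-5)
#'   and `cut_points` (4 reals).
#' @export
assign_quintiles <- function(ps) {
  if (length(unique(ps)) < 5L) {
    stop("need at least 5 distinct scores for quintiles", call. = FALSE)
  }
  cuts <- pctile(ps, c(0.2, 0.4, 0.6, 0.8))
  labels <- 1L + vapply(ps, function(s) sum(cuts < s), integer(1))
  structure(list(labels = labels, cut_points = cuts),
            class = "strata_assignment")
}

#' Asymmetric trimming of non-overlap regions
#'
#' Removes exposed patients with PS below the `alpha` quantile of the
#' exposed PS distribution and unexposed patients with PS above the
#' `1 - alpha` quantile of the unexposed PS distribution — the tails
#' where treatment received is contrary to prediction.  The PS is not
#' re-estimated on the trimmed sample unless the caller refits.
#'
#' @param ps scores aligned with `exposure` and `ids`.
#' @param exposure 0/1 vector.
#' @param alpha trimming fraction (default 0.05).
#' @param ids patient ids; defaults to indices.
#' @param cuts optional cached `c(lower, upper)` cut points (for
#'   idempotent re-trimming).
#' @return object of class `trim_result`: `retained_ids`, `lower_cut`,
#'   `upper_cut`, `retained` (logical vector).
#' @export
asymmetric_trim <- function(ps, exposure, alpha = 0.05, ids = NULL,
                            cuts = NULL) {
  if (!any(exposure == 1) || !any(exposure == 0)) {
    stop("both arms must be non-empty", call. = FALSE)
  }
  if (alpha < 0 || alpha >= 0.5) stop("alpha must be in [0, 0.5)", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_along(ps))
  if (is.null(cuts)) {
    lower <- if (alpha > 0) pctile(ps[exposure == 1], alpha) else -Inf
    upper <- if (alpha > 0) pctile(ps[exposure == 0], 1 - alpha) else Inf
  } else {
    lower <- cuts[1]; upper <- cuts[2]
  }
  retained <- ifelse(exposure == 1, ps >= lower, ps <= upper)
  if (!any(retained & exposure == 1) || !any(retained & exposure == 0)) {
    stop("trimming emptied an arm", call. = FALSE)
  }
  structure(list(retained_ids = ids[retained], lower_cut = lower,
                 upper_cut = upper, retained = retained),
            class = "trim_result")
}

#' Standardized mean differences before and after adjustment
#'
#' Per-covariate standardized difference of means between arms with the
#' pooled-SD denominator `sqrt((v1 + v0) / 2)` (population variances, so
#' binary covariates use p(1-p)).  "After" is computed on a matched
#' sample (via `match`) or as the stratum-size-weighted mean of
#' within-stratum differences (via `strata`).  Zero-variance covariates
#' report 0 when the means agree and are flagged otherwise.
#'
#' @param design numeric matrix of covariates.
#' @param exposure 0/1 vector.
#' @param match optional `match_result`; `ids` must then be supplied.
#' @param strata optional `strata_assignment`.
#' @param ids patient ids aligned with `design` rows.
#' @return data.frame: `covariate`, `smd_before`, `smd_after`,
#'   `degenerate`.
#' @export
standardized_differences <- function(design, exposure, match = NULL,
                                     strata = NULL, ids = NULL) {
  smd_of <- function(rows, weights = NULL) {
    X1 <- design[rows & exposure == 1, , drop = FALSE]
    X0 <- design[rows & exposure == 0, , drop = FALSE]
    m1 <- colMeans(X1); m0 <- colMeans(X0)
    v1 <- colMeans(X1^2) - m1^2
    v0 <- colMeans(X0^2) - m0^2
    denom <- sqrt((v1 + v0) / 2)
    out <- (m1 - m0) / denom
    flat <- denom == 0
    out[flat & abs(m1 - m0) < 1e-12] <- 0
    out[flat & abs(m1 - m0) >= 1e-12] <- Inf
    out
  }
  all_rows <- rep(TRUE, nrow(design))
  before <- smd_of(all_rows)
  after <- rep(NA_real_, ncol(design))
  if (!is.null(match)) {
    if (is.null(ids)) stop("matched SMDs need ids", call. = FALSE)
    rows <- ids %in% c(match$pairs$exposed_id, match$pairs$unexposed_id)
    after <- smd_of(rows)
  } else if (!is.null(strata)) {
    lab <- strata$labels
    acc <- rep(0, ncol(design)); wsum <- 0
    for (q in sort(unique(lab))) {
      rows <- lab == q
      if (!any(rows & exposure == 1) || !any(rows & exposure == 0)) next
      w <- sum(rows)
      s <- smd_of(rows)
      s[!is.finite(s)] <- 0
      acc <- acc + w * s
      wsum <- wsum + w
    }
    after <- if (wsum > 0) acc / wsum else after
  }
  data.frame(
    covariate = colnames(design),
    smd_before = before,
    smd_after = after,
    degenerate = !is.finite(before) | (!is.na(after) & !is.finite(after)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
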