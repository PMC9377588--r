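# Survival estimation: Kaplan-Meier cumulative incidence and Cox
# proportional-hazards ratios with cluster-robust variance.  The
# product-limit and partial-likelihood machinery comes from the
# survival package; independent brute-force oracles live in the tests.

#' Kaplan-Meier cumulative incidence at a horizon
#'
#' Product-limit survival with Greenwood variance and log(-log)
#' confidence limits; cumulative incidence is `1 - S(horizon)`.
#'
#' @param times positive follow-up times.
#' @param events 0/1 event indicators.
#' @param horizon evaluation time (days).
#' @param confidence confidence level (default 0.95).
#' @return object of class `km_estimate`: `horizon`, `incidence`,
#'   `ci` (length-2), `degenerate` flag (no information by the
#'   horizon), and an `at_risk` trace (`time`, `n_risk`, `n_event`).
#' @export
km_risk <- function(times, events, horizon, confidence = 0.95) {
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(events %in% c(0, 1))) stop("events must be binary", call. = FALSE)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = confidence)
  sm <- summary(fit, times = horizon, extend = TRUE)
  inc <- 1 - sm$surv
  ci <- c(1 - sm$upper, 1 - sm$lower)
  degenerate <- horizon < min(times) || sm$surv == 1
  if (degenerate && !is.finite(ci[1])) ci <- c(0, NA_real_)
  structure(list(
    horizon = horizon,
    incidence = inc,
    ci = ci,
    degenerate = degenerate,
    at_risk = data.frame(time = fit$time, n_risk = fit$n.risk,
                         n_event = fit$n.event)
  ), class = "km_estimate")
}

#' Cox hazard ratio for exposure with cluster-robust variance
#'
#' Partial-likelihood estimation with Efron tie handling; the variance
#' is the robust sandwich aggregated over `cluster_ids` (hospital by
#' default in the pipeline; matched designs pass the pair id).
#' Stratification covariates can enter as indicator terms (default for
#' quintiles) or as baseline-hazard strata.
#'
#' @param data data.frame containing `followup_days`, `event`, and every
#'   term column.
#' @param terms character vector of model terms; must include
#'   `"exposure"`.
#' @param cluster_ids cluster identifiers aligned with `data` rows; NULL
#'   for independent observations.
#' @param strata optional column name used as baseline-hazard strata.
#' @param adjustment label stored on the estimate.
#' @param model_id label stored on the estimate.
#' @return object of class `hazard_estimate`: `hr`, `ci95`,
#'   `se_log_hr`, `log_hr`, `n`, `events` (each by arm), `adjustment`,
#'   `model_id`.
#' @export
fit_cox <- function(data, terms = "exposure", cluster_ids = NULL,
                    strata = NULL, adjustment = "crude", model_id = "crude") {
  if (!"exposure" %in% terms) stop("terms must include exposure", call. = FALSE)
  for (arm in c(0, 1)) {
    rows <- data$exposure == arm
    if (sum(data$event[rows]) < 1) {
      stop("need at least one event per arm", call. = FALSE)
    }
  }
  rhs <- paste(vapply(terms, function(t) sprintf("`%s`", t), character(1)),
               collapse = " + ")
  if (!is.null(strata)) rhs <- paste0(rhs, " + strata(`", strata, "`)")
  f <- stats::as.formula(paste("survival::Surv(followup_days, event) ~", rhs))
  fit <- tryCatch(
    if (is.null(cluster_ids)) {
      survival::coxph(f, data = data, ties = "efron", robust = TRUE)
    } else {
      survival::coxph(f, data = data, ties = "efron", robust = TRUE,
                      cluster = cluster_ids)
    },
    error = function(e) stop("Cox fit failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  beta <- stats::coef(fit)[["exposure"]]
  if (!is.finite(beta) || abs(beta) > 15) {
    stop("monotone partial likelihood for exposure; consider penalization",
         call. = FALSE)
  }
  se <- sqrt(diag(stats::vcov(fit))[["exposure"]])
  z <- stats::qnorm(0.975)
  structure(list(
    hr = exp(beta),
    log_hr = beta,
    se_log_hr = se,
    ci95 = exp(c(beta - z * se, beta + z * se)),
    n = c(exposed = sum(data$exposure == 1), unexposed = sum(data$exposure == 0)),
    events = c(exposed = sum(data$event[data$exposure == 1]),
               unexposed = sum(data$event[data$exposure == 0])),
    adjustment = adjustment,
    model_id = model_id
  ), class = "hazard_estimate")
}
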