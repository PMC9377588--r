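# Synthetic linked claims + registry cohort generator.
#
# The generative model:
#   conditions C_k ~ Bernoulli(prev_k), independent
#   exposure   A   ~ Bernoulli(expit(a0 + sum_k b_k C_k))
#   death time T   ~ PH model: S(t) = exp(-lambda0 * t^shape * M_i)
#                    M_i = exp(theta*A + sum_k g_k C_k + demographics) * frailty
#   follow-up      = min(T, admin censoring)
# Claims codes fire per (condition x dimension) with the configured
# sensitivity and zero-truncated Poisson counts, plus independent noise
# codes; the registry records conditions subject to capture probability
# and MCAR/MAR missingness.

# demographic layout: marginals held balanced across arms, with modest
# age/sex effects on the log-hazard only
.DEMO <- list(
  age_levels = c("66-69", "70-74", "75-79", "80+"),
  age_probs  = c(0.17, 0.27, 0.30, 0.26),
  age_log_hr = c(0.00, 0.15, 0.30, 0.50),
  p_female   = 0.41,
  female_log_hr = -0.15,
  p_white    = 0.937,
  years      = 2005:2008
)

.dim_prefix <- c(
  inpatient_dx = "IDX", inpatient_px = "IPX", outpatient_dx = "ODX",
  outpatient_px = "OPX", carrier = "CAR", nursing_home = "NH"
)

condition_code <- function(dimension, cond_index) {
  sprintf("%s%04d", .dim_prefix[[dimension]], cond_index)
}

noise_code <- function(dimension, noise_index) {
  sprintf("%s%04d", .dim_prefix[[dimension]], 1000L + noise_index)
}

#' Generate a linked claims + registry cohort
#'
#' Draws a full synthetic cohort from a [scenario_config()]: a patient
#' table with exposure, follow-up and death, a long-format claims-code
#' table organized into six data dimensions, a registry table organized
#' into five clinical dimensions, and a truth record carrying the latent
#' condition indicators, true propensities and the code-to-condition map
#' needed to evaluate covariate-selection recall.
#'
#' Deterministic given `config` (including its seed): the same
#' configuration always yields byte-identical tables.
#'
#' @param config a [scenario_config()].
#' @return list with elements `cohort`, `claims`, `registry`, `truth`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "scenario_config")) {
    stop("config must be a scenario_config", call. = FALSE)
  }
  with_local_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_patients
  conds <- config$confounder_spec
  K <- length(conds)
  cond_names <- vapply(conds, `[[`, character(1), "name")

  patient_id <- sprintf("P%05d", seq_len(n))

  # demographics (balanced across arms by construction)
  age_group <- sample(.DEMO$age_levels, n, replace = TRUE, prob = .DEMO$age_probs)
  female <- rbinom(n, 1L, .DEMO$p_female)
  white <- rbinom(n, 1L, .DEMO$p_white)
  year <- sample(.DEMO$years, n, replace = TRUE)

  # latent conditions
  C <- matrix(0L, n, max(K, 1L), dimnames = list(NULL, if (K) cond_names))
  for (k in seq_len(K)) C[, k] <- rbinom(n, 1L, conds[[k]]$prevalence)

  # treatment assignment (confounding by indication enters here)
  trt_eff <- if (K) vapply(conds, `[[`, numeric(1), "trt_log_odds") else numeric(0)
  lin_trt <- config$treat_intercept + if (K) drop(C[, seq_len(K), drop = FALSE] %*% trt_eff) else 0
  p_treat <- expit(lin_trt)
  exposure <- rbinom(n, 1L, p_treat)

  # clustering: physicians nested in hospitals; lognormal hospital frailty
  hospital <- sample.int(config$n_hospitals, n, replace = TRUE)
  physician_within <- sample.int(config$n_physicians_per_hospital, n, replace = TRUE)
  hospital_id <- sprintf("H%03d", hospital)
  physician_id <- sprintf("H%03dM%02d", hospital, physician_within)
  frailty <- exp(rnorm(config$n_hospitals, 0, config$cluster_frailty_sd))

  # proportional-hazards death time
  haz_eff <- if (K) vapply(conds, `[[`, numeric(1), "log_hr") else numeric(0)
  age_idx <- match(age_group, .DEMO$age_levels)
  log_mult <- config$true_log_hr * exposure +
    (if (K) drop(C[, seq_len(K), drop = FALSE] %*% haz_eff) else 0) +
    .DEMO$age_log_hr[age_idx] + .DEMO$female_log_hr * female +
    log(frailty[hospital])
  rate <- config$baseline_hazard * exp(log_mult)
  p_event_admin <- 1 - exp(-rate * config$admin_censor_time^config$weibull_shape)
  if (all(p_event_admin < 1e-10) || all(p_event_admin > 1 - 1e-10)) {
    stop("degenerate outcome: implied event probability is 0 or 1 for all patients",
         call. = FALSE)
  }
  u <- rexp(n)
  death_time <- (u / rate)^(1 / config$weibull_shape)
  event <- as.integer(death_time <= config$admin_censor_time)
  followup_days <- pmin(death_time, config$admin_censor_time)

  cohort <- data.frame(
    patient_id = patient_id,
    exposure = exposure,
    followup_days = followup_days,
    event = event,
    hospital_id = hospital_id,
    physician_id = physician_id,
    age_group = age_group,
    female = female,
    white = white,
    year = year,
    stringsAsFactors = FALSE
  )

  claims <- rbind(
    generate_condition_claims(patient_id, C, conds),
    generate_noise_claims(patient_id, config)
  )
  claims <- claims[order(claims$patient_id, claims$dimension, claims$code), ,
                   drop = FALSE]
  rownames(claims) <- NULL

  registry <- generate_registry(patient_id, C, conds)
  if (length(config$missingness_rates)) {
    registry <- apply_missingness(
      registry, config$missingness_rates,
      seed = child_seed(config$seed, 101L),
      mechanism = config$missingness_mechanism,
      mar_odds_ratio = config$mar_odds_ratio,
      exposure = stats::setNames(exposure, patient_id)
    )
  }

  code_map <- if (K) {
    data.frame(
      condition = rep(cond_names, each = length(CLAIMS_DIMENSIONS)),
      dimension = rep(CLAIMS_DIMENSIONS, times = K),
      code = unlist(lapply(seq_len(K), function(k)
        vapply(CLAIMS_DIMENSIONS, condition_code, character(1), cond_index = k))),
      sensitivity = unlist(lapply(conds, `[[`, "claims_sensitivity")),
      row.names = NULL, stringsAsFactors = FALSE
    )
  } else {
    data.frame(condition = character(0), dimension = character(0),
               code = character(0), sensitivity = numeric(0))
  }

  hsr <- which(cond_names == "high_surgical_risk")
  hsr_by_arm <- if (length(hsr) == 1L && any(exposure == 1) && any(exposure == 0)) {
    c(exposed = mean(C[exposure == 1, hsr]),
      unexposed = mean(C[exposure == 0, hsr]))
  } else {
    c(exposed = NA_real_, unexposed = NA_real_)
  }

  truth <- list(
    true_log_hr = config$true_log_hr,
    conditions = as.data.frame(cbind(C)),
    patient_id = patient_id,
    true_propensity = pmin(pmax(p_treat, .Machine$double.eps),
                           1 - .Machine$double.eps),
    hsr_prevalence_by_arm = hsr_by_arm,
    code_map = code_map
  )

  list(cohort = cohort, claims = claims, registry = registry, truth = truth)
}

generate_condition_claims <- function(patient_id, C, conds) {
  out <- vector("list", length(conds) * length(CLAIMS_DIMENSIONS))
  i <- 0L
  for (k in seq_along(conds)) {
    affected <- which(C[, k] == 1L)
    for (d in CLAIMS_DIMENSIONS) {
      i <- i + 1L
      sens <- conds[[k]]$claims_sensitivity[[d]]
      if (!length(affected) || sens <= 0) next
      fired <- affected[runif(length(affected)) < sens]
      if (!length(fired)) next
      out[[i]] <- data.frame(
        patient_id = patient_id[fired],
        dimension = d,
        code = condition_code(d, k),
        count = rztpois(length(fired), conds[[k]]$claims_mean_count),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(patient_id = character(0), dimension = character(0),
                      code = character(0), count = integer(0)))
  }
  do.call(rbind, out)
}

generate_noise_claims <- function(patient_id, config) {
  n <- length(patient_id)
  J <- config$n_noise_codes
  if (J < 1L) {
    return(data.frame(patient_id = character(0), dimension = character(0),
                      code = character(0), count = integer(0)))
  }
  rng <- log(config$noise_code_prevalence)
  out <- vector("list", length(CLAIMS_DIMENSIONS))
  for (di in seq_along(CLAIMS_DIMENSIONS)) {
    d <- CLAIMS_DIMENSIONS[di]
    prev <- exp(runif(J, rng[1], rng[2]))
    present <- matrix(runif(n * J), n, J) < rep(prev, each = n)
    idx <- which(present, arr.ind = TRUE)
    if (!nrow(idx)) next
    out[[di]] <- data.frame(
      patient_id = patient_id[idx[, 1]],
      dimension = d,
      code = noise_code(d, idx[, 2]),
      count = rztpois(nrow(idx), 1.5),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(patient_id = character(0), dimension = character(0),
                      code = character(0), count = integer(0)))
  }
  do.call(rbind, out)
}

generate_registry <- function(patient_id, C, conds) {
  n <- length(patient_id)
  out <- vector("list", length(conds))
  for (k in seq_along(conds)) {
    cap <- conds[[k]]$registry_capture
    value <- C[, k]
    if (cap < 1) value <- value * (runif(n) < cap)
    out[[k]] <- data.frame(
      patient_id = patient_id,
      dimension = conds[[k]]$registry_dimension,
      variable = conds[[k]]$name,
      value = as.integer(value),
      missing = FALSE,
      stringsAsFactors = FALSE
    )
  }
  reg <- do.call(rbind, out)
  reg <- reg[order(reg$patient_id, reg$variable), , drop = FALSE]
  rownames(reg) <- NULL
  reg
}

#' Apply missingness to registry values
#'
#' Independently blanks each targeted registry value with the requested
#' rate (MCAR), or with exposure-tilted odds (MAR) for sensitivity runs.
#' Row count and order are unchanged; blanked rows get `missing = TRUE`
#' and `value = NA`.
#'
#' @param registry a registry table (`patient_id`, `dimension`,
#'   `variable`, `value`, `missing`).
#' @param rates named list/vector of missingness probabilities keyed by
#'   registry variable name.
#' @param seed integer seed.
#' @param mechanism `"mcar"` (default) or `"mar"`.
#' @param mar_odds_ratio under `"mar"`, the exposure odds ratio on
#'   missingness.
#' @param exposure named 0/1 vector (names = patient ids); required for
#'   `"mar"`.
#' @return the registry table with missingness applied.
#' @export
apply_missingness <- function(registry, rates, seed,
                              mechanism = c("mcar", "mar"),
                              mar_odds_ratio = 2.0, exposure = NULL) {
  mechanism <- match.arg(mechanism)
  rates <- unlist(rates)
  if (!length(rates)) return(registry)
  stopifnot_prob(rates, "rates")
  known <- unique(registry$variable)
  unknown <- setdiff(names(rates), known)
  if (length(unknown)) {
    stop("unknown registry variable(s) in rates: ",
         paste(unknown, collapse = ", "),
         "; known variables: ", paste(known, collapse = ", "), call. = FALSE)
  }
  with_local_seed(seed, {
    for (v in names(rates)) {
      rows <- which(registry$variable == v)
      p <- rep(rates[[v]], length(rows))
      if (mechanism == "mar") {
        if (is.null(exposure)) stop("MAR missingness needs exposure", call. = FALSE)
        expo <- exposure[registry$patient_id[rows]]
        odds <- p / (1 - p) * ifelse(expo == 1, mar_odds_ratio, 1)
        p <- odds / (1 + odds)
      }
      hit <- runif(length(rows)) < p
      registry$missing[rows[hit]] <- TRUE
      registry$value[rows[hit]] <- NA_integer_
    }
    registry
  })
}
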