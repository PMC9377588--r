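#' Claims data dimensions
#'
#' The six streams of healthcare codes the simulator emits and the hdPS
#' candidate engine scans: inpatient/outpatient diagnoses and procedures,
#' carrier (non-institutional) services, and nursing-home codes.
#'
#' @export
CLAIMS_DIMENSIONS <- c(
  "inpatient_dx", "inpatient_px", "outpatient_dx",
  "outpatient_px", "carrier", "nursing_home"
)

#' Registry data dimensions
#'
#' The five clinical-registry dimensions: medical history, symptomatic
#' status, diagnostic imaging, pre-procedural medications, and the
#' high-surgical-risk composite that drives treatment choice.
#'
#' @export
REGISTRY_DIMENSIONS <- c(
  "medical_history", "symptomatic_status", "imaging",
  "medications", "high_surgical_risk"
)

#' Define a latent clinical condition for the cohort simulator
#'
#' Each condition is a binary patient attribute with a population
#' prevalence, an effect on the treatment log-odds (confounding by
#' indication enters here), an effect on the log-hazard of death, a
#' registry dimension and capture probability, and per-dimension
#' probabilities that a claims code fires for an affected patient.
#'
#' @param name condition name; doubles as the registry variable name.
#' @param prevalence population prevalence in \[0, 1\].
#' @param trt_log_odds effect on the treatment-assignment log-odds.
#' @param log_hr effect on the log-hazard of death.
#' @param registry_dimension one of [REGISTRY_DIMENSIONS].
#' @param registry_capture probability the registry records the condition
#'   when present (1 = perfectly measured).
#' @param claims_sensitivity probability a claims code fires in a data
#'   dimension given the condition; a scalar is recycled to all six
#'   dimensions, or supply a vector named by [CLAIMS_DIMENSIONS].
#' @param claims_mean_count mean occurrence count (zero-truncated Poisson)
#'   of a fired code.
#' @return a one-row list suitable for `confounder_spec`.
#' @export
condition_spec <- function(name, prevalence, trt_log_odds, log_hr,
                           registry_dimension = "medical_history",
                           registry_capture = 1.0,
                           claims_sensitivity = 0.7,
                           claims_mean_count = 2.0) {
  stopifnot_prob(prevalence, "prevalence")
  stopifnot_prob(registry_capture, "registry_capture")
  registry_dimension <- match.arg(registry_dimension, REGISTRY_DIMENSIONS)
  if (is.null(names(claims_sensitivity))) {
    sens <- rep_len(claims_sensitivity, length(CLAIMS_DIMENSIONS))
    names(sens) <- CLAIMS_DIMENSIONS
  } else {
    if (!all(names(claims_sensitivity) %in% CLAIMS_DIMENSIONS)) {
      stop("claims_sensitivity names must be claims dimensions", call. = FALSE)
    }
    sens <- stats::setNames(numeric(length(CLAIMS_DIMENSIONS)), CLAIMS_DIMENSIONS)
    sens[names(claims_sensitivity)] <- claims_sensitivity
  }
  stopifnot_prob(sens, "claims_sensitivity")
  if (claims_mean_count <= 0) stop("claims_mean_count must be > 0", call. = FALSE)
  list(
    name = name, prevalence = prevalence, trt_log_odds = trt_log_odds,
    log_hr = log_hr, registry_dimension = registry_dimension,
    registry_capture = registry_capture, claims_sensitivity = sens,
    claims_mean_count = claims_mean_count
  )
}

#' Construct a simulation scenario
#'
#' Bundles every knob of the linked claims+registry cohort generator:
#' cohort size, the true (benchmark) treatment effect, the latent
#' conditions and their effects, the claims noise-code layer, registry
#' missingness, follow-up/censoring, and the clustering structure.
#'
#' @param n_patients cohort size (>= 2).
#' @param true_log_hr true treatment effect on the log-hazard; 0 encodes
#'   the benchmark hazard ratio of 1.0.
#' @param treat_intercept intercept of the treatment-assignment logistic
#'   model.
#' @param confounder_spec list of [condition_spec()] entries.
#' @param n_noise_codes number of pure-noise codes per claims dimension.
#' @param noise_code_prevalence length-2 range; noise-code prevalences are
#'   drawn log-uniformly inside it.
#' @param missingness_rates named list/vector of MCAR missingness
#'   probabilities keyed by registry variable name.
#' @param missingness_mechanism `"mcar"` or `"mar"`; under `"mar"` the
#'   missingness odds are multiplied by `mar_odds_ratio` for exposed
#'   patients.
#' @param mar_odds_ratio exposure odds ratio for MAR missingness.
#' @param admin_censor_time administrative censoring time in days.
#' @param baseline_hazard baseline hazard (events per day).
#' @param weibull_shape shape of the baseline time distribution; 1 gives
#'   the exponential default.
#' @param n_hospitals,n_physicians_per_hospital clustering structure;
#'   physicians are nested within hospitals.
#' @param cluster_frailty_sd SD of the lognormal hospital frailty.
#' @param seed integer seed making generation deterministic.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(n_patients = 5254L,
                            true_log_hr = 0.0,
                            treat_intercept = -4.0,
                            confounder_spec = list(),
                            n_noise_codes = 40L,
                            noise_code_prevalence = c(0.01, 0.3),
                            missingness_rates = list(),
                            missingness_mechanism = c("mcar", "mar"),
                            mar_odds_ratio = 2.0,
                            admin_censor_time = 1460,
                            baseline_hazard = 6e-5,
                            weibull_shape = 1.0,
                            n_hospitals = 40L,
                            n_physicians_per_hospital = 5L,
                            cluster_frailty_sd = 0.2,
                            seed = 20050101L) {
  if (n_patients < 2) stop("n_patients must be >= 2", call. = FALSE)
  if (admin_censor_time <= 0) stop("admin_censor_time must be > 0", call. = FALSE)
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0", call. = FALSE)
  if (weibull_shape <= 0) stop("weibull_shape must be > 0", call. = FALSE)
  if (cluster_frailty_sd < 0) stop("cluster_frailty_sd must be >= 0", call. = FALSE)
  if (length(noise_code_prevalence) != 2 ||
      any(noise_code_prevalence <= 0) || any(noise_code_prevalence > 1) ||
      noise_code_prevalence[1] > noise_code_prevalence[2]) {
    stop("noise_code_prevalence must be an increasing range within (0, 1]",
         call. = FALSE)
  }
  cond_names <- vapply(confounder_spec, `[[`, character(1), "name")
  if (anyDuplicated(cond_names)) stop("duplicate condition names", call. = FALSE)
  rates <- unlist(missingness_rates)
  if (length(rates)) {
    stopifnot_prob(rates, "missingness_rates")
    unknown <- setdiff(names(rates), cond_names)
    if (length(unknown)) {
      stop("missingness_rates name unknown registry variables: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      true_log_hr = true_log_hr,
      treat_intercept = treat_intercept,
      confounder_spec = confounder_spec,
      n_noise_codes = as.integer(n_noise_codes),
      noise_code_prevalence = noise_code_prevalence,
      missingness_rates = as.list(rates),
      missingness_mechanism = match.arg(missingness_mechanism),
      mar_odds_ratio = mar_odds_ratio,
      admin_censor_time = admin_censor_time,
      baseline_hazard = baseline_hazard,
      weibull_shape = weibull_shape,
      n_hospitals = as.integer(n_hospitals),
      n_physicians_per_hospital = as.integer(n_physicians_per_hospital),
      cluster_frailty_sd = cluster_frailty_sd,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' Read or write a scenario configuration file
#'
#' Scenario files mirror [scenario_config()] field for field; the
#' format is chosen by extension (`.json`, or `.yaml`/`.yml` when the
#' yaml package is installed).
#'
#' @param config a `scenario_config`.
#' @param path file path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_scenario()` returns `path` invisibly;
#'   `read_scenario()` returns a validated `scenario_config`.
#' @export
write_scenario <- function(config, path) {
  x <- unclass(config)
  x$confounder_spec <- lapply(x$confounder_spec, function(cs) {
    cs$claims_sensitivity <- as.list(cs$claims_sensitivity)
    cs
  })
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed for YAML scenario files", call. = FALSE)
    }
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  x <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the yaml package is needed for YAML scenario files", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  conds <- lapply(x$confounder_spec, function(cs) {
    do.call(condition_spec, list(
      name = cs$name, prevalence = cs$prevalence,
      trt_log_odds = cs$trt_log_odds, log_hr = cs$log_hr,
      registry_dimension = cs$registry_dimension,
      registry_capture = cs$registry_capture,
      claims_sensitivity = unlist(cs$claims_sensitivity),
      claims_mean_count = cs$claims_mean_count))
  })
  scenario_config(
    n_patients = x$n_patients, true_log_hr = x$true_log_hr,
    treat_intercept = x$treat_intercept, confounder_spec = conds,
    n_noise_codes = x$n_noise_codes,
    noise_code_prevalence = unlist(x$noise_code_prevalence),
    missingness_rates = x$missingness_rates,
    missingness_mechanism = x$missingness_mechanism,
    mar_odds_ratio = x$mar_odds_ratio,
    admin_censor_time = x$admin_censor_time,
    baseline_hazard = x$baseline_hazard,
    weibull_shape = x$weibull_shape,
    n_hospitals = x$n_hospitals,
    n_physicians_per_hospital = x$n_physicians_per_hospital,
    cluster_frailty_sd = x$cluster_frailty_sd,
    seed = x$seed
  )
}

#' The shipped default scenario
#'
#' A stylized analog of a carotid revascularization cohort (stenting vs
#' endarterectomy) in the era when stenting was indicated only for
#' high-surgical-risk patients.  Treatment assignment is dominated by a
#' registry-measured high-surgical-risk composite that claims codes
#' capture poorly (sensitivity 0.15), so claims-only adjustment leaves
#' residual confounding by indication.  The true treatment effect is the
#' benchmark hazard ratio of 1.0.  Calibrated marginals: ~38% exposed,
#' high-surgical-risk prevalence ~96.7% among exposed and ~44.5% among
#' unexposed, and 3-year mortality per arm in the 15-26% range with a
#' crude hazard ratio well above 1.3.
#'
#' @param n_patients cohort size; default 5254.
#' @param true_log_hr true treatment log-hazard; default 0 (benchmark).
#' @param seed integer seed.
#' @return a `scenario_config`.
#' @export
default_scenario <- function(n_patients = 5254L, true_log_hr = 0.0,
                             seed = 20050101L) {
  conditions <- list(
    condition_spec("high_surgical_risk", 0.643, trt_log_odds = 3.70,
                   log_hr = 0.50, registry_dimension = "high_surgical_risk",
                   claims_sensitivity = 0.15, claims_mean_count = 1.5),
    condition_spec("heart_failure", 0.108, 0.70, 0.65,
                   claims_sensitivity = 0.85, claims_mean_count = 2.5),
    condition_spec("symptomatic", 0.337, 0.35, 0.20,
                   registry_dimension = "symptomatic_status",
                   claims_sensitivity = 0.55, claims_mean_count = 1.8),
    condition_spec("coronary_artery_disease", 0.559, 0.25, 0.30,
                   claims_sensitivity = 0.70, claims_mean_count = 2.0),
    condition_spec("diabetes", 0.302, 0.10, 0.25,
                   claims_sensitivity = 0.75, claims_mean_count = 2.2),
    condition_spec("copd", 0.184, 0.05, 0.35,
                   claims_sensitivity = 0.70, claims_mean_count = 2.0),
    condition_spec("cancer", 0.154, 0.10, 0.45,
                   claims_sensitivity = 0.60, claims_mean_count = 1.8),
    condition_spec("renal_failure", 0.038, 0.20, 0.60,
                   claims_sensitivity = 0.65, claims_mean_count = 2.0),
    condition_spec("contralateral_occlusion", 0.107, 0.45, 0.30,
                   registry_dimension = "imaging",
                   claims_sensitivity = 0.08, claims_mean_count = 1.2),
    condition_spec("antiplatelet_use", 0.50, 0.15, -0.10,
                   registry_dimension = "medications",
                   claims_sensitivity = 0.30, claims_mean_count = 1.5),
    condition_spec("hyperlipidemia", 0.55, 0.10, 0.05,
                   claims_sensitivity = 0.50, claims_mean_count = 1.6)
  )
  scenario_config(
    n_patients = n_patients,
    true_log_hr = true_log_hr,
    treat_intercept = -3.95,
    confounder_spec = conditions,
    n_noise_codes = 40L,
    noise_code_prevalence = c(0.01, 0.3),
    missingness_rates = list(
      heart_failure = 0.176,
      hyperlipidemia = 0.332,
      contralateral_occlusion = 0.054
    ),
    admin_censor_time = 1460,
    baseline_hazard = 6.4e-5,
    n_hospitals = 40L,
    n_physicians_per_hospital = 5L,
    cluster_frailty_sd = 0.2,
    seed = seed
  )
}
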