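# Independent brute-force oracles.  Each is written from the definition
# of the quantity, not from the package's implementation, and is kept
# deliberately naive (loops, enumeration, fine grid search).

oracle_bross <- function(pc1, pc0, rr) {
  rr <- max(rr, 1 / rr)
  num <- pc1 * (rr - 1) + 1
  den <- pc0 * (rr - 1) + 1
  num / den
}

oracle_cstat <- function(scores, exposure) {
  s1 <- scores[exposure == 1]
  s0 <- scores[exposure == 0]
  tot <- 0
  for (a in s1) {
    for (b in s0) {
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  tot / (length(s1) * length(s0))
}

oracle_km <- function(times, events, horizon) {
  s <- 1
  for (t in sort(unique(times[events == 1]))) {
    if (t > horizon) break
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
  }
  1 - s
}

# greedy 1:1 caliper matching on the logit scale, traced literally:
# exposed in descending ps (ties by id), nearest available unexposed,
# distance ties to the smaller unexposed id
oracle_greedy_match <- function(ps, exposure, width, ids) {
  lp <- log(ps / (1 - ps))
  e <- which(exposure == 1)
  u <- which(exposure == 0)
  e <- e[order(-ps[e], ids[e])]
  taken <- rep(FALSE, length(ps))
  pairs <- NULL
  for (i in e) {
    best <- NA; best_d <- Inf
    for (j in u) {
      if (taken[j]) next
      d <- abs(lp[j] - lp[i])
      if (d > width + 1e-12) next
      if (d < best_d - 1e-15 ||
          (abs(d - best_d) <= 1e-15 && !is.na(best) && ids[j] < ids[best])) {
        best <- j; best_d <- d
      }
    }
    if (!is.na(best)) {
      taken[best] <- TRUE
      pairs <- rbind(pairs, data.frame(exposed_id = ids[i],
                                       unexposed_id = ids[best],
                                       stringsAsFactors = FALSE))
    }
  }
  pairs
}

# linear-interpolation percentile from first principles
oracle_pctile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  sapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h)
    hi <- ceiling(h)
    xs[lo] + (h - lo) * (xs[hi] - xs[lo])
  })
}

oracle_rubin <- function(q, v) {
  m <- length(q)
  W <- sum(v) / m
  qbar <- sum(q) / m
  B <- if (m > 1) sum((q - qbar)^2) / (m - 1) else 0
  Tv <- W + (1 + 1 / m) * B
  list(q = qbar, W = W, B = B, T = Tv)
}

# Efron partial log-likelihood for a single binary covariate
oracle_efron_loglik <- function(beta, times, events, x) {
  ll <- 0
  for (t in sort(unique(times[events == 1]))) {
    D <- which(times == t & events == 1)
    R <- which(times >= t)
    rs <- sum(exp(beta * x[R]))
    ds <- sum(exp(beta * x[D]))
    ll <- ll + beta * sum(x[D])
    for (l in seq_along(D) - 1) {
      ll <- ll - log(rs - (l / length(D)) * ds)
    }
  }
  ll
}

# two-stage grid search maximizer of the Efron partial likelihood
oracle_cox_grid <- function(times, events, x, lo = -8, hi = 8) {
  grid <- seq(lo, hi, by = 0.01)
  ll <- vapply(grid, oracle_efron_loglik, numeric(1),
               times = times, events = events, x = x)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.01, b0 + 0.01, by = 1e-5)
  llf <- vapply(fine, oracle_efron_loglik, numeric(1),
                times = times, events = events, x = x)
  fine[which.max(llf)]
}

# ridge-penalized logistic log-likelihood maximized by BFGS with
# analytic gradient (independent of the package's IRLS)
oracle_ridge_logistic <- function(X, y, lambda) {
  X <- cbind(1, X)
  pen <- c(0, rep(lambda, ncol(X) - 1L))
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(eta))) - sum(y * eta) + 0.5 * sum(pen * b^2)
  }
  gr <- function(b) {
    mu <- 1 / (1 + exp(-drop(X %*% b)))
    drop(crossprod(X, mu - y)) + pen * b
  }
  opt <- stats::optim(numeric(ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
  opt$par
}

# a small, fast scenario with moderate confounding and plentiful events,
# used by structural tests that do not need the calibrated default
tiny_scenario <- function(n = 600L, seed = 1L, true_log_hr = 0,
                          n_noise = 6L, missing = TRUE) {
  scenario_config(
    n_patients = n,
    true_log_hr = true_log_hr,
    treat_intercept = -1.2,
    confounder_spec = list(
      condition_spec("risk_composite", 0.5, 1.6, 0.6,
                     registry_dimension = "high_surgical_risk",
                     claims_sensitivity = 0.2),
      condition_spec("cardiac", 0.3, 0.6, 0.5, claims_sensitivity = 0.8),
      condition_spec("sympt", 0.4, 0.3, 0.2,
                     registry_dimension = "symptomatic_status",
                     claims_sensitivity = 0.5)
    ),
    n_noise_codes = n_noise,
    missingness_rates = if (missing) list(cardiac = 0.15) else list(),
    admin_censor_time = 1460,
    baseline_hazard = 4e-4,
    n_hospitals = 8L,
    n_physicians_per_hospital = 3L,
    cluster_frailty_sd = 0.1,
    seed = seed
  )
}
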