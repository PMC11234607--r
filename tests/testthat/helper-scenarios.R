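# One-stratum scenario with an explicit treatment effect and no covariate
# effects: the workhorse for oracle and recovery checks.
one_stratum_scenario <- function(n, hr = 1, lambda = 0.05, censor = 5,
                                 seed = 1, cancer_type = "CC",
                                 prevalence = c(0.5, 0.5)) {
  defs <- stratum_definitions()[[cancer_type]]
  arms <- defs$arms[1:2]
  scenario_config(
    n_per_stratum = stats::setNames(n, cancer_type),
    treatment_prevalence = stats::setNames(
      list(stats::setNames(prevalence, arms)), cancer_type),
    true_log_hr = stats::setNames(
      list(stats::setNames(c(0, log(hr)), arms)), cancer_type),
    baseline_hazard_rate = stats::setNames(lambda, cancer_type),
    covariate_effects = NULL,
    admin_censor_years = censor,
    seed = seed)
}

simulated_tables <- function(config) {
  pop <- simulate_outcomes(generate_population(config), config)
  emit_source_tables(pop)
}

# Minimal survival data.frame for direct Cox checks.
toy_survival <- function(time, status, arm) {
  data.frame(event_time_years = time,
             event_indicator = ifelse(status == 1, "fracture", "censored"),
             treatment_arm = arm, stringsAsFactors = FALSE)
}

# Hand-built 10-person registry/claims pair with aligned identifiers.
toy_pair_tables <- function(n = 10) {
  uid <- sprintf("T%03d", seq_len(n))
  base <- data.frame(
    uid = uid,
    name_key = sprintf("nm%02d", seq_len(n)),
    dob = as.Date("1960-01-01") + seq_len(n) * 37,
    sex = rep(c("F", "M"), length.out = n),
    stringsAsFactors = FALSE)
  registry <- cbind(base, cancer_type = "TC", seer_stage = "localized",
                    diagnosis_date = as.Date("2010-06-01"),
                    stringsAsFactors = FALSE)
  claims <- cbind(rid = uid, base, cancer_type = "TC",
                  age_years = 50L, residence = "urban",
                  insurance = "employee", premium_quantile = 5L,
                  cci_category = "0-1",
                  treatment_arm = rep(c("no-vitamin-D", "vitamin-D"),
                                      length.out = n),
                  index_date = as.Date("2010-07-01"),
                  event_time_years = seq_len(n) / 2,
                  event_indicator = rep(c("fracture", "censored"),
                                        length.out = n),
                  fracture_site = ifelse(seq_len(n) %% 2 == 1, "hip",
                                         NA_character_),
                  stringsAsFactors = FALSE)
  truth <- data.frame(uid = uid, rid = uid, stringsAsFactors = FALSE)
  list(registry = registry, claims = claims, truth = truth)
}

# Brute-force reference linkage: all-pairs key comparison with sequential
# pairing inside each key group. Independent of link_tables internals.
brute_force_link <- function(registry, claims, level) {
  kr <- composite_key(registry, level)
  kc <- composite_key(claims, level)
  pairs <- data.frame(uid = character(), rid = character(),
                      stringsAsFactors = FALSE)
  for (key in unique(stats::na.omit(kr))) {
    ri <- which(!is.na(kr) & kr == key)
    ci <- which(!is.na(kc) & kc == key)
    m <- min(length(ri), length(ci))
    if (m > 0)
      pairs <- rbind(pairs, data.frame(uid = registry$uid[ri[seq_len(m)]],
                                       rid = claims$rid[ci[seq_len(m)]],
                                       stringsAsFactors = FALSE))
  }
  pairs[order(pairs$uid, pairs$rid), , drop = FALSE]
}

# Brute-force exact Poisson interval by tail-probability inversion.
poisson_ci_oracle <- function(k, py, per = 100000, ci_level = 0.95) {
  alpha <- 1 - ci_level
  upper_m <- stats::uniroot(function(m) stats::ppois(k, m) - alpha / 2,
                            c(1e-12, 1000), tol = 1e-11)$root
  lower_m <- if (k == 0) 0 else
    stats::uniroot(function(m) 1 - stats::ppois(k - 1, m) - alpha / 2,
                   c(1e-12, 1000), tol = 1e-11)$root
  c(lo = lower_m / py * per, hi = upper_m / py * per)
}

# Hand-written Cox partial likelihood (no ties) maximized by grid search.
cox_grid_oracle <- function(time, status, x, beta_grid = seq(-3, 3, 1e-4)) {
  logpl <- vapply(beta_grid, function(b) {
    s <- 0
    for (i in which(status == 1)) {
      risk <- which(time >= time[i])
      s <- s + b * x[i] - log(sum(exp(b * x[risk])))
    }
    s
  }, numeric(1))
  beta_grid[which.max(logpl)]
}
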