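#' Generate a synthetic cancer cohort with known ground truth
#'
#' Draws one record per simulated person across the configured cancer
#' strata: an opaque unique identifier (standing in for a resident
#' registration number), quasi-identifiers (name token, date of birth,
#' sex), baseline covariates (age, residence, insurance type, premium
#' quantile, Charlson comorbidity category, SEER summary stage) and a
#' stratum-specific treatment arm. Outcomes are filled in by
#' \code{\link{simulate_outcomes}}.
#'
#' Name tokens come from a finite dictionary, so distinct people can share
#' a (name, date of birth, sex) triple — the natural source of false
#' matches under indirect-identifier linkage. Date of birth is derived
#' from age plus a uniform within-year offset so the two stay coherent.
#' Sex respects the diseases studied: breast and cervical strata are
#' female, prostate male. Premium quantile is 0 exactly for medical-aid
#' beneficiaries.
#'
#' @param config A \code{\link{scenario_config}}.
#' @return A data.frame with one row per person, deterministic given the
#'   config's seed.
#' @examples
#' pop <- generate_population(scenario_config(n_per_stratum = c(TC = 50), seed = 1))
#' nrow(pop)
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  defs <- stratum_definitions()
  with_seed_(config$seed, {
    parts <- lapply(names(config$n_per_stratum), function(ct) {
      n <- config$n_per_stratum[[ct]]
      if (n == 0) return(NULL)
      d <- defs[[ct]]
      prev <- config$treatment_prevalence[[ct]]
      diagnosis_date <- as.Date("2008-01-01") +
        sample.int(as.integer(as.Date("2016-12-31") - as.Date("2008-01-01")) + 1L,
                   n, replace = TRUE) - 1L
      age <- pmax(18L, as.integer(round(rnorm(n, d$age_mean, d$age_sd))))
      dob <- diagnosis_date - round(age * 365.25) - sample(0:364, n, replace = TRUE)
      sex <- sample(names(d$sex), n, replace = TRUE, prob = d$sex)
      insurance <- sample(c("employee", "local", "medical-aid"), n,
                          replace = TRUE, prob = c(0.60, 0.35, 0.05))
      premium <- ifelse(insurance == "medical-aid", 0L,
                        sample(1:10, n, replace = TRUE))
      data.frame(
        cancer_type = ct,
        name_key = sprintf("nk%05d",
                           sample.int(config$name_dictionary_size, n, replace = TRUE)),
        dob = dob,
        sex = sex,
        age_years = age,
        residence = sample(c("urban", "rural"), n, replace = TRUE,
                           prob = c(0.7, 0.3)),
        insurance = insurance,
        premium_quantile = premium,
        cci_category = sample(c("0-1", "2", "3", ">=4"), n, replace = TRUE,
                              prob = c(0.60, 0.20, 0.12, 0.08)),
        seer_stage = sample(c("localized", "regional", "distant", "unknown"),
                            n, replace = TRUE, prob = c(0.60, 0.25, 0.08, 0.07)),
        treatment_arm = sample(names(prev), n, replace = TRUE, prob = prev),
        diagnosis_date = diagnosis_date,
        stringsAsFactors = FALSE
      )
    })
    pop <- do.call(rbind, parts)
    if (is.null(pop)) {
      pop <- data.frame(cancer_type = character(), name_key = character(),
                        dob = as.Date(character()), sex = character(),
                        age_years = integer(), residence = character(),
                        insurance = character(), premium_quantile = integer(),
                        cci_category = character(), seer_stage = character(),
                        treatment_arm = character(),
                        diagnosis_date = as.Date(character()),
                        stringsAsFactors = FALSE)
    }
    pop <- cbind(uid = sprintf("P%07d", seq_len(nrow(pop))), pop,
                 stringsAsFactors = FALSE)
    pop$index_date <- pop$diagnosis_date + config$index_lag_days
    rownames(pop) <- NULL
    pop
  })
}

# (age - 60)/10, CCI category index 0-3, urban indicator, centred premium:
# the encoded covariates that covariate_effects coefficients act on.
encode_covariates <- function(pop) {
  cci_idx <- match(pop$cci_category, c("0-1", "2", "3", ">=4")) - 1L
  cbind(age10 = (pop$age_years - 60) / 10,
        cci = cci_idx,
        urban = as.numeric(pop$residence == "urban"),
        premium = (pop$premium_quantile - 5) / 5)
}

#' Simulate proportional-hazards fracture outcomes
#'
#' Event times are drawn by inverse-CDF simulation from an exponential
#' baseline: T = -log(U) / (lambda * exp(x'beta)), where lambda is the
#' stratum's baseline hazard rate, and beta collects the arm's true log
#' hazard ratio plus any configured covariate effects. Times beyond the
#' administrative censoring horizon are censored at the horizon
#' (competing death/emigration is folded into this censoring). Fracture
#' sites are drawn for events; the cervical stratum's outcome is pelvic
#' insufficiency fracture only.
#'
#' @param population Output of \code{\link{generate_population}}.
#' @param config The same \code{\link{scenario_config}}.
#' @return The population with \code{event_time_years},
#'   \code{event_indicator} ("fracture"/"censored") and
#'   \code{fracture_site} (NA when censored) filled in.
#' @export
simulate_outcomes <- function(population, config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- nrow(population)
  if (n == 0) {
    population$event_time_years <- numeric(0)
    population$event_indicator <- character(0)
    population$fracture_site <- character(0)
    return(population)
  }
  lambda <- config$baseline_hazard_rate[population$cancer_type]
  if (any(is.na(lambda)) || any(lambda <= 0))
    stop("baseline_hazard_rate must be positive for every stratum present")
  beta_arm <- mapply(function(ct, arm) config$true_log_hr[[ct]][[arm]],
                     population$cancer_type, population$treatment_arm)
  lp <- beta_arm
  ce <- config$covariate_effects
  if (length(ce)) {
    X <- encode_covariates(population)
    use <- intersect(names(ce), colnames(X))
    if (length(use)) lp <- lp + as.vector(X[, use, drop = FALSE] %*% ce[use])
  }
  with_seed_(config$seed + 1L, {
    u <- runif(n)
    t_event <- -log(u) / (lambda * exp(lp))
    censored <- t_event > config$admin_censor_years
    population$event_time_years <- ifelse(censored, config$admin_censor_years,
                                          t_event)
    population$event_indicator <- ifelse(censored, "censored", "fracture")
    site <- rep(NA_character_, n)
    for (ct in unique(population$cancer_type)) {
      w <- fracture_site_weights(ct)
      idx <- which(population$cancer_type == ct & !censored)
      if (length(idx))
        site[idx] <- sample(names(w), length(idx), replace = TRUE, prob = w)
    }
    population$fracture_site <- site
  })
  population
}

#' Split a simulated population into registry and claims source tables
#'
#' Mirrors the two agencies' holdings: the cancer registry carries the
#' identifiers plus cancer type, SEER summary stage and diagnosis date;
#' the claims table carries the identifiers plus covariates, treatment and
#' outcome. The truth map records the ground-truth pairing between the
#' registry identifier and a corruption-proof claims row id (equal to the
#' uid at emission), so linkage quality can be audited after identifiers
#' are corrupted.
#'
#' @param population A fully simulated population.
#' @return A list with elements \code{registry}, \code{claims} and
#'   \code{truth} (data.frame of uid/rid pairs).
#' @export
emit_source_tables <- function(population) {
  id_cols <- c("uid", "name_key", "dob", "sex")
  registry <- population[, c(id_cols, "cancer_type", "seer_stage",
                             "diagnosis_date")]
  claims <- cbind(rid = population$uid,
                  population[, c(id_cols, "cancer_type", "age_years",
                                 "residence", "insurance", "premium_quantile",
                                 "cci_category", "treatment_arm", "index_date",
                                 "event_time_years", "event_indicator",
                                 "fracture_site")],
                  stringsAsFactors = FALSE)
  rownames(registry) <- rownames(claims) <- NULL
  truth <- data.frame(uid = population$uid, rid = population$uid,
                      stringsAsFactors = FALSE)
  list(registry = registry, claims = claims, truth = truth)
}

#' Write / read the source tables as CSV with a JSON truth sidecar
#'
#' \code{registry.csv} and \code{claims.csv} are RFC-4180 CSV with
#' ISO-8601 dates; \code{truth.json} lists the ground-truth uid/rid
#' pairs; when a scenario is supplied it is echoed to
#' \code{scenario.yaml}.
#'
#' @param tables List as returned by \code{\link{emit_source_tables}}.
#' @param dir Output directory (created if needed).
#' @param config Optional \code{\link{scenario_config}} to echo.
#' @return \code{dir}, invisibly.
#' @export
write_source_tables <- function(tables, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(format_full_precision(tables$registry),
                   file.path(dir, "registry.csv"), row.names = FALSE)
  utils::write.csv(format_full_precision(tables$claims),
                   file.path(dir, "claims.csv"), row.names = FALSE)
  jsonlite::write_json(tables$truth, file.path(dir, "truth.json"),
                       dataframe = "rows")
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$treatment_prevalence <- lapply(cfg$treatment_prevalence, as.list)
    cfg$true_log_hr <- lapply(cfg$true_log_hr, as.list)
    yaml::write_yaml(cfg, file.path(dir, "scenario.yaml"))
  }
  invisible(dir)
}

#' @rdname write_source_tables
#' @export
read_source_tables <- function(dir) {
  registry <- utils::read.csv(file.path(dir, "registry.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(uid = "character"))
  claims <- utils::read.csv(file.path(dir, "claims.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(rid = "character", uid = "character"))
  for (nm in c("dob", "diagnosis_date")) registry[[nm]] <-
      if (nm %in% names(registry)) as.Date(registry[[nm]]) else NULL
  claims$dob <- as.Date(claims$dob)
  claims$index_date <- as.Date(claims$index_date)
  truth <- as.data.frame(jsonlite::read_json(file.path(dir, "truth.json"),
                                             simplifyVector = TRUE))
  if (nrow(truth) == 0)
    truth <- data.frame(uid = character(), rid = character(),
                        stringsAsFactors = FALSE)
  list(registry = registry, claims = claims, truth = truth)
}
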