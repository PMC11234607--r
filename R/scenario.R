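#' Built-in stratum definitions
#'
#' Five cancer strata, each a study subtopic pairing a cancer type with a
#' stratum-specific treatment contrast for osteoporotic fracture risk:
#' thyroid (TC, postoperative vitamin D vs none), gastric (GC, gastrectomy
#' type vs endoscopic resection), breast (BC, anti-hormone therapy),
#' prostate (PC, androgen deprivation therapy) and cervical (CC, radiation
#' therapy, with pelvic insufficiency fracture as the outcome).
#'
#' @return Named list, one element per cancer type, each holding the arm
#'   labels, the reference arm, default arm prevalences, default true
#'   log hazard ratios, the sex distribution and a typical age model.
#' @export
stratum_definitions <- function() {
  list(
    TC = list(
      arms = c("no-vitamin-D", "vitamin-D"), reference = "no-vitamin-D",
      prevalence = c("no-vitamin-D" = 0.55, "vitamin-D" = 0.45),
      log_hr = c("no-vitamin-D" = 0, "vitamin-D" = log(0.83)),
      sex = c(M = 0.2, F = 0.8), age_mean = 47, age_sd = 12
    ),
    GC = list(
      arms = c("ESD-EMR", "subtotal-gastrectomy", "total-gastrectomy"),
      reference = "ESD-EMR",
      prevalence = c("ESD-EMR" = 0.30, "subtotal-gastrectomy" = 0.50,
                     "total-gastrectomy" = 0.20),
      log_hr = c("ESD-EMR" = 0, "subtotal-gastrectomy" = log(1.26),
                 "total-gastrectomy" = log(1.26)),
      sex = c(M = 0.65, F = 0.35), age_mean = 62, age_sd = 11
    ),
    BC = list(
      arms = c("non-HT", "AI-only", "TAM-only", "AI-TAM"), reference = "non-HT",
      prevalence = c("non-HT" = 0.4689, "AI-only" = 0.2234,
                     "TAM-only" = 0.30, "AI-TAM" = 0.0077),
      log_hr = c("non-HT" = 0, "AI-only" = log(1.03),
                 "TAM-only" = log(0.80), "AI-TAM" = log(0.94)),
      sex = c(M = 0, F = 1), age_mean = 52, age_sd = 11
    ),
    PC = list(
      arms = c("non-ADT", "ADT"), reference = "non-ADT",
      prevalence = c("non-ADT" = 0.6, "ADT" = 0.4),
      log_hr = c("non-ADT" = 0, "ADT" = log(1.96)),
      sex = c(M = 1, F = 0), age_mean = 70, age_sd = 8
    ),
    CC = list(
      arms = c("non-RT", "RT"), reference = "non-RT",
      prevalence = c("non-RT" = 0.7, "RT" = 0.3),
      log_hr = c("non-RT" = 0, "RT" = log(1.80)),
      sex = c(M = 0, F = 1), age_mean = 54, age_sd = 12
    )
  )
}

#' Fracture sites and their sampling weights
#'
#' Non-cervical strata draw among hip, vertebral, distal-radius and
#' proximal-humerus fractures (distal radius most frequent, proximal
#' humerus least); the cervical stratum's outcome is pelvic insufficiency
#' fracture only.
#' @keywords internal
fracture_site_weights <- function(cancer_type) {
  if (cancer_type == "CC") {
    c("pelvic-insufficiency" = 1)
  } else {
    c("distal-radius" = 0.40, "vertebral" = 0.30,
      "hip" = 0.20, "proximal-humerus" = 0.10)
  }
}

#' Build a simulation scenario
#'
#' A scenario fixes the data-generating process for a paired
#' registry/claims cohort: per-stratum sample sizes, treatment-arm
#' prevalences, true log hazard ratios, an exponential baseline hazard per
#' stratum, covariate effects on the log hazard, administrative censoring,
#' the name-key dictionary size (the homonym pool behind false matches)
#' and the seed.
#'
#' @param n_per_stratum Named integer vector of cohort sizes by cancer
#'   type (any subset of TC, GC, BC, PC, CC).
#' @param treatment_prevalence Named list (by cancer type) of named
#'   probability vectors over that stratum's arms; each must sum to 1.
#' @param true_log_hr Named list (by cancer type) of named log hazard
#'   ratios per arm (reference arm 0).
#' @param baseline_hazard_rate Named numeric vector of exponential
#'   baseline event rates per person-year, by cancer type.
#' @param covariate_effects Named numeric vector of log-hazard
#'   coefficients over the encoded covariates \code{age10} ((age - 60)/10),
#'   \code{cci} (category index 0-3), \code{urban} (indicator) and
#'   \code{premium} ((quantile - 5)/5).
#' @param admin_censor_years Administrative censoring horizon in years.
#' @param index_lag_days Days from diagnosis to treatment (index) date.
#' @param name_dictionary_size Number of distinct name tokens; smaller
#'   dictionaries create more natural homonyms.
#' @param seed Integer seed driving every random draw.
#' @return An object of class \code{scenario_config}.
#' @examples
#' sc <- scenario_config(n_per_stratum = c(TC = 100, CC = 10), seed = 7)
#' sc$n_per_stratum
#' @export
scenario_config <- function(n_per_stratum = c(TC = 20000, GC = 14000, BC = 10000,
                                              PC = 6000, CC = 1500),
                            treatment_prevalence = NULL,
                            true_log_hr = NULL,
                            baseline_hazard_rate = c(TC = 0.008, GC = 0.012,
                                                     BC = 0.010, PC = 0.015,
                                                     CC = 0.010),
                            covariate_effects = c(age10 = 0.25, cci = 0.15),
                            admin_censor_years = 5,
                            index_lag_days = 30,
                            name_dictionary_size = 10000,
                            seed = 1L) {
  defs <- stratum_definitions()
  if (is.null(names(n_per_stratum)) || !all(names(n_per_stratum) %in% names(defs)))
    stop("n_per_stratum must be named with cancer types among ",
         paste(names(defs), collapse = ", "))
  if (any(n_per_stratum < 0) || any(n_per_stratum != round(n_per_stratum)))
    stop("n_per_stratum entries must be non-negative integers")
  strata <- names(n_per_stratum)

  if (is.null(treatment_prevalence))
    treatment_prevalence <- lapply(defs[strata], `[[`, "prevalence")
  if (is.null(true_log_hr))
    true_log_hr <- lapply(defs[strata], `[[`, "log_hr")

  for (s in strata) {
    p <- treatment_prevalence[[s]]
    if (is.null(p)) stop("no treatment_prevalence for stratum ", s)
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8)
      stop("treatment_prevalence for ", s,
           " must be probabilities in [0,1] summing to 1")
    if (!setequal(names(p), defs[[s]]$arms))
      stop("treatment_prevalence arms for ", s, " must match ",
           paste(defs[[s]]$arms, collapse = ", "))
    if (is.null(true_log_hr[[s]])) stop("no true_log_hr for stratum ", s)
  }
  lam <- baseline_hazard_rate[strata]
  if (any(is.na(lam)) || any(lam <= 0))
    stop("baseline_hazard_rate must be positive for every stratum")
  if (admin_censor_years <= 0) stop("admin_censor_years must be positive")
  if (name_dictionary_size < 1) stop("name_dictionary_size must be >= 1")

  structure(
    list(n_per_stratum = n_per_stratum,
         treatment_prevalence = treatment_prevalence,
         true_log_hr = true_log_hr,
         baseline_hazard_rate = lam,
         covariate_effects = covariate_effects,
         admin_censor_years = admin_censor_years,
         index_lag_days = index_lag_days,
         name_dictionary_size = name_dictionary_size,
         seed = as.integer(seed)),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat("  strata:", paste(sprintf("%s=%d", names(x$n_per_stratum),
                                 x$n_per_stratum), collapse = ", "), "\n")
  cat("  baseline hazard/yr:",
      paste(sprintf("%s=%.3g", names(x$baseline_hazard_rate),
                    x$baseline_hazard_rate), collapse = ", "), "\n")
  cat("  admin censoring:", x$admin_censor_years, "years; seed:", x$seed, "\n")
  invisible(x)
}
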