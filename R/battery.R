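default_battery_covariates <- function()
  c("age_years", "sex", "residence", "insurance", "cci_category")

default_subgroup_specs <- function()
  list(BC = list(stratifier = "age_group"),
       PC = list(stratifier = "seer_stage",
                 levels = c("localized", "regional")))

reference_arm_for <- function(cancer_type, arms) {
  defs <- stratum_definitions()
  if (cancer_type %in% names(defs) &&
      defs[[cancer_type]]$reference %in% arms)
    return(defs[[cancer_type]]$reference)
  sort(arms)[1]
}

# Rate ratio with a log-normal CI; 0.5 continuity correction when a zero
# event count would make the ratio or its variance degenerate.
rate_ratio <- function(e1, py1, e0, py0, ci_level = 0.95) {
  if (e1 == 0 && e0 == 0) return(NULL)
  cc <- if (e1 == 0 || e0 == 0) 0.5 else 0
  rr <- ((e1 + cc) / py1) / ((e0 + cc) / py0)
  se <- sqrt(1 / (e1 + cc) + 1 / (e0 + cc))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  c(est = rr, lo = rr * exp(-z * se), hi = rr * exp(z * se))
}

#' Run the full analysis battery on a linked cohort
#'
#' Per cancer stratum: descriptive category shares; treatment-group
#' comparisons of the baseline covariates (with rule-based test
#' selection); person-years incidence per arm with exact Poisson
#' intervals and between-arm rate ratios; the adjusted Cox
#' proportional-hazards treatment effect; and, where a subgroup spec
#' applies, stratified (moderation) treatment effects. The battery is
#' linkage-level agnostic: it runs identically on a DII- or III-level
#' cohort.
#'
#' @param cohort A \code{linked_cohort} (or compatible data.frame).
#' @param covariates Adjustment covariates for the Cox models; those
#'   constant within a stratum are dropped automatically.
#' @param subgroup_specs Named list (by cancer type) of
#'   \code{list(stratifier =, levels =)}; the default stratifies the
#'   breast stratum by age below/at-or-above 50 and the prostate stratum
#'   by localized/regional summary stage. \code{age_group} is derived
#'   from \code{age_years}.
#' @param per Incidence reporting scale.
#' @return List with \code{summary} — the exchange data.frame consumed by
#'   \code{\link{concordance_report}} (stratum, method, item, kind, est,
#'   lo, hi) — and \code{details} holding the full per-stratum objects
#'   (descriptives, comparison tests, incidence tables, Cox fits with
#'   pseudo-R-squared, subgroup fits, notes).
#' @export
analyze_cohort <- function(cohort,
                           covariates = default_battery_covariates(),
                           subgroup_specs = default_subgroup_specs(),
                           per = 100000) {
  cohort <- as.data.frame(cohort)
  cohort$age_group <- ifelse(cohort$age_years < 50, "<50", ">=50")
  cat_vars <- c("cci_category", "insurance", "residence", "seer_stage")
  rows <- list(); details <- list()
  add <- function(stratum, method, item, kind, est, lo = NA_real_,
                  hi = NA_real_)
    rows[[length(rows) + 1L]] <<- data.frame(
      stratum = stratum, method = method, item = item, kind = kind,
      est = est, lo = lo, hi = hi, stringsAsFactors = FALSE)

  for (ct in sort(unique(cohort$cancer_type))) {
    d <- cohort[cohort$cancer_type == ct, , drop = FALSE]
    arms <- sort(unique(d$treatment_arm))
    ref <- reference_arm_for(ct, arms)
    det <- list(notes = character())

    # descriptive: marginal category shares
    det$descriptive <- describe_cohort(d, c("age_years", "treatment_arm",
                                            cat_vars), strata = NULL)
    for (v in c("treatment_arm", cat_vars)) {
      tab <- table(d[[v]])
      for (lv in names(tab))
        add(ct, "descriptive", paste0(v, "=", lv), "proportion",
            tab[[lv]] / sum(tab))
    }

    # group comparison: covariate shares within each arm, plus the tests
    det$group_tests <- list()
    for (v in cat_vars) {
      det$group_tests[[v]] <- tryCatch(
        compare_groups(d, v, "treatment_arm"),
        error = function(e) conditionMessage(e))
      for (arm in arms) {
        da <- d[d$treatment_arm == arm, ]
        tab <- table(factor(da[[v]], levels = sort(unique(d[[v]]))))
        if (sum(tab) == 0) next
        for (lv in names(tab))
          add(ct, "group_comparison", paste0(arm, "|", v, "=", lv),
              "proportion", tab[[lv]] / sum(tab))
      }
    }

    # incidence per arm and between-arm rate ratios
    det$incidence <- cohort_incidence(d, per = per)
    inc <- det$incidence
    i0 <- which(inc$group == ref)
    if (length(i0) == 1) {
      for (arm in setdiff(arms, ref)) {
        i1 <- which(inc$group == arm)
        if (length(i1) != 1) next
        rr <- rate_ratio(inc$events[i1], inc$person_years[i1],
                         inc$events[i0], inc$person_years[i0])
        if (!is.null(rr))
          add(ct, "incidence", arm, "rate_ratio", rr["est"], rr["lo"],
              rr["hi"])
      }
    }

    # adjusted Cox treatment effect
    fit <- tryCatch(
      fit_cox(d, covariates = covariates, reference_arm = ref),
      error = function(e) conditionMessage(e))
    if (inherits(fit, "hr_estimates")) {
      det$cox <- fit
      det$cox_f <- cohens_f(cox_r_squared(fit))
      trt <- fit[fit$is_treatment & !fit$reference, , drop = FALSE]
      for (i in seq_len(nrow(trt)))
        add(ct, "cox", trt$term[i], "hr", trt$hr[i], trt$ci_low[i],
            trt$ci_high[i])
    } else det$notes <- c(det$notes, paste("cox:", fit))

    # subgroup (moderation) effects where a spec applies
    spec <- subgroup_specs[[ct]]
    if (!is.null(spec)) {
      sg <- tryCatch(
        suppressMessages(subgroup_effects(d, covariates = covariates,
                                          stratifier = spec$stratifier,
                                          reference_arm = ref)),
        error = function(e) conditionMessage(e))
      if (is.list(sg)) {
        keep <- if (is.null(spec$levels)) names(sg)
                else intersect(spec$levels, names(sg))
        det$subgroup <- sg[keep]
        for (lv in keep) {
          trt <- sg[[lv]][sg[[lv]]$is_treatment & !sg[[lv]]$reference, ,
                          drop = FALSE]
          for (i in seq_len(nrow(trt)))
            add(ct, "subgroup", paste0(lv, "|", trt$term[i]), "hr",
                trt$hr[i], trt$ci_low[i], trt$ci_high[i])
        }
      } else det$notes <- c(det$notes, paste("subgroup:", sg))
    }
    details[[ct]] <- det
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stratum = character(), method = character(),
               item = character(), kind = character(), est = numeric(),
               lo = numeric(), hi = numeric(), stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  list(summary = summary, details = details)
}
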