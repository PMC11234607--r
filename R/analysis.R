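#' Descriptive summaries per stratum
#'
#' Continuous variables are summarised as n, mean, SD, median, minimum
#' and maximum; categorical variables as frequencies and one-decimal
#' percentages — the standard baseline-characteristics table.
#'
#' @param cohort A \code{linked_cohort} or plain data.frame.
#' @param variables Character vector of column names to summarise.
#' @param strata Stratifying column (default \code{"cancer_type"}); use
#'   \code{NULL} for a single overall stratum.
#' @return A long data.frame, one row per (stratum, variable, level).
#' @export
describe_cohort <- function(cohort, variables, strata = "cancer_type") {
  groups <- if (is.null(strata)) list(all = cohort)
            else split(cohort, cohort[[strata]])
  rows <- list()
  for (g in names(groups)) {
    d <- groups[[g]]
    for (v in variables) {
      x <- d[[v]]
      if (is.numeric(x)) {
        rows[[length(rows) + 1L]] <- data.frame(
          stratum = g, variable = v, type = "continuous", level = NA_character_,
          n = sum(!is.na(x)),
          mean = mean(x, na.rm = TRUE), sd = stats::sd(x),
          median = stats::median(x, na.rm = TRUE),
          min = suppressWarnings(min(x, na.rm = TRUE)),
          max = suppressWarnings(max(x, na.rm = TRUE)),
          count = NA_integer_, pct = NA_real_, stringsAsFactors = FALSE)
      } else {
        tab <- table(x)
        for (lv in names(tab)) {
          rows[[length(rows) + 1L]] <- data.frame(
            stratum = g, variable = v, type = "categorical", level = lv,
            n = sum(tab), mean = NA_real_, sd = NA_real_, median = NA_real_,
            min = NA_real_, max = NA_real_,
            count = as.integer(tab[[lv]]),
            pct = pct1(tab[[lv]] / sum(tab)), stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Shapiro-Wilk normality gate at alpha = 0.05, n capped at 5000 per group;
# constant samples are treated as non-normal (the test is undefined there).
group_is_normal <- function(x, cap = 5000) {
  x <- x[!is.na(x)]
  if (length(x) > cap) x <- x[seq_len(cap)]
  if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
  stats::shapiro.test(x)$p.value >= 0.05
}

#' Compare groups with rule-based test selection
#'
#' Implements the conventional selection rules: a continuous variable
#' compared across two groups gets a t-test when every group passes a
#' Shapiro-Wilk normality check, otherwise a Mann-Whitney U test; across
#' three or more groups, one-way ANOVA or Kruskal-Wallis; a categorical
#' variable gets Pearson's chi-square unless more than 20\% of cells have
#' expected frequency below 5, in which case Fisher's exact test. All
#' tests are two-sided at the 5\% level.
#'
#' @param cohort Data.frame holding both columns.
#' @param variable Column to compare.
#' @param group_var Grouping column with at least two non-empty levels.
#' @return An object of class \code{group_comparison}: the per-group
#'   summaries, the test used, its statistic and p-value.
#' @export
compare_groups <- function(cohort, variable, group_var) {
  g <- factor(cohort[[group_var]])
  g <- droplevels(g[!is.na(g)])
  x <- cohort[[variable]][!is.na(cohort[[group_var]])]
  if (nlevels(g) < 2) stop("group_var needs at least 2 non-empty levels")

  if (is.numeric(x)) {
    sizes <- tapply(!is.na(x), g, sum)
    small <- names(sizes)[sizes < 2]
    if (length(small))
      stop("group(s) with fewer than 2 observations: ",
           paste(small, collapse = ", "))
    normal <- all(vapply(split(x, g), group_is_normal, logical(1)))
    summaries <- do.call(rbind, lapply(split(x, g), function(z) data.frame(
      n = sum(!is.na(z)), mean = mean(z, na.rm = TRUE), sd = stats::sd(z),
      median = stats::median(z, na.rm = TRUE), min = min(z, na.rm = TRUE),
      max = max(z, na.rm = TRUE))))
    if (nlevels(g) == 2) {
      if (normal) {
        tt <- stats::t.test(x ~ g)
        res <- list(test_used = "t-test", statistic = unname(tt$statistic),
                    p_value = tt$p.value)
      } else {
        wt <- suppressWarnings(stats::wilcox.test(x ~ g))
        res <- list(test_used = "Mann-Whitney", statistic = unname(wt$statistic),
                    p_value = wt$p.value)
      }
    } else {
      if (normal) {
        av <- summary(stats::aov(x ~ g))[[1]]
        res <- list(test_used = "ANOVA", statistic = av$`F value`[1],
                    p_value = av$`Pr(>F)`[1])
      } else {
        kw <- stats::kruskal.test(x, g)
        res <- list(test_used = "Kruskal-Wallis",
                    statistic = unname(kw$statistic), p_value = kw$p.value)
      }
    }
  } else {
    tab <- table(x, g)
    expected <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$expected
    if (mean(expected < 5) > 0.20) {
      ft <- stats::fisher.test(tab, simulate.p.value = (nrow(tab) * ncol(tab) > 10))
      res <- list(test_used = "Fisher", statistic = NA_real_,
                  p_value = ft$p.value)
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      res <- list(test_used = "chi-square", statistic = unname(ct$statistic),
                  p_value = ct$p.value)
    }
    summaries <- as.data.frame.matrix(tab)
  }
  structure(list(variable = variable, group_var = group_var,
                 groups = levels(g), summaries = summaries,
                 test_used = res$test_used, statistic = res$statistic,
                 p_value = res$p_value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s by %s: %s, statistic = %s, p = %.4g\n", x$variable,
              x$group_var, x$test_used,
              ifelse(is.na(x$statistic), "-", format(x$statistic, digits = 4)),
              x$p_value))
  invisible(x)
}

#' Person-years incidence with an exact Poisson interval
#'
#' Rate = \code{per * events / person_years}; the confidence interval is
#' the exact (Garwood) Poisson interval obtained from chi-square
#' quantiles, lower bound 0 when there are no events.
#'
#' @param events Non-negative event count.
#' @param person_years Positive follow-up total.
#' @param per Reporting scale (default per 100,000 person-years).
#' @param ci_level Confidence level (default 0.95).
#' @return An \code{incidence_estimate}: events, person_years, rate,
#'   ci_low, ci_high, ci_level.
#' @examples
#' incidence_rate(events = 10, person_years = 1e5)
#' @export
incidence_rate <- function(events, person_years, per = 100000,
                           ci_level = 0.95) {
  if (person_years <= 0) stop("person_years must be positive")
  if (events < 0 || events != round(events)) stop("events must be a non-negative integer")
  alpha <- 1 - ci_level
  lower <- if (events == 0) 0 else
    stats::qchisq(alpha / 2, 2 * events) / 2 / person_years * per
  upper <- stats::qchisq(1 - alpha / 2, 2 * events + 2) / 2 / person_years * per
  structure(list(events = as.integer(events), person_years = person_years,
                 rate = per * events / person_years,
                 ci_low = lower, ci_high = upper, per = per,
                 ci_level = ci_level),
            class = "incidence_estimate")
}

#' @export
print.incidence_estimate <- function(x, ...) {
  cat(sprintf("%d events / %.1f PY: %.2f (%.2f-%.2f) per %s PY\n",
              x$events, x$person_years, x$rate, x$ci_low, x$ci_high,
              format(x$per, big.mark = ",")))
  invisible(x)
}

#' Incidence by group within a cohort
#'
#' Events are fractures; person-years are the summed follow-up times.
#'
#' @param cohort Data.frame with \code{event_indicator} and
#'   \code{event_time_years}.
#' @param by Grouping column (default the treatment arm).
#' @inheritParams incidence_rate
#' @return Data.frame with one row per group.
#' @export
cohort_incidence <- function(cohort, by = "treatment_arm", per = 100000,
                             ci_level = 0.95) {
  groups <- split(cohort, cohort[[by]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    est <- incidence_rate(sum(d$event_indicator == "fracture"),
                          sum(d$event_time_years), per = per,
                          ci_level = ci_level)
    data.frame(group = g, events = est$events, person_years = est$person_years,
               rate = est$rate, ci_low = est$ci_low, ci_high = est$ci_high,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cox proportional-hazards fit with Wald intervals
#'
#' Maximizes the Cox partial likelihood (Efron tie handling) for the
#' treatment variable plus any adjustment covariates, and reports hazard
#' ratios with Wald 95\% intervals. The reference arm is reported with
#' HR 1 by convention. Covariates constant within the analysis subset
#' are dropped with a note. An empty covariate list gives the simple
#' (unadjusted) model.
#'
#' @param cohort Data.frame with \code{event_time_years} and
#'   \code{event_indicator}.
#' @param treatment_var Treatment column name.
#' @param covariates Character vector of adjustment columns (the
#'   treatment variable itself is always excluded).
#' @param subset Optional logical vector selecting analysis rows.
#' @param reference_arm Reference level of the treatment variable; default
#'   its first factor level.
#' @param ci_level Confidence level for the Wald intervals.
#' @return An \code{hr_estimates} data.frame: one row per model term plus
#'   the reference-arm row, with columns term, hr, ci_low, ci_high,
#'   p_value, is_treatment, reference, flag. Attributes carry the fitted
#'   model's log-likelihoods and n for pseudo-R-squared computation.
#' @export
fit_cox <- function(cohort, treatment_var = "treatment_arm",
                    covariates = character(), subset = NULL,
                    reference_arm = NULL, ci_level = 0.95) {
  d <- if (is.null(subset)) cohort else cohort[subset, , drop = FALSE]
  if (nrow(d) == 0) stop("empty analysis subset")
  if (any(d$event_time_years <= 0)) stop("event times must be positive")
  status <- as.integer(d$event_indicator == "fracture")
  if (sum(status) == 0) stop("no events in the analysis subset")

  d[[treatment_var]] <- droplevels(factor(d[[treatment_var]]))
  if (!is.null(reference_arm))
    d[[treatment_var]] <- stats::relevel(d[[treatment_var]], ref = reference_arm)
  ref <- levels(d[[treatment_var]])[1]

  covariates <- setdiff(covariates, treatment_var)
  kept <- character(); dropped <- character()
  for (v in covariates) {
    col <- d[[v]]
    if (length(unique(col[!is.na(col)])) > 1) kept <- c(kept, v)
    else dropped <- c(dropped, v)
  }
  rhs <- paste(c(treatment_var, kept), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(event_time_years, status) ~", rhs))
  d$status <- status

  flag <- ""
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "efron"),
    warning = function(w) {
      flag <<- conditionMessage(w)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit, conf.int = ci_level)
  co <- s$coefficients
  ci <- s$conf.int
  terms <- rownames(co)
  is_trt <- startsWith(terms, treatment_var)
  est <- data.frame(
    term = terms,
    hr = unname(co[, "exp(coef)"]),
    ci_low = unname(ci[, 3]),
    ci_high = unname(ci[, 4]),
    p_value = unname(co[, "Pr(>|z|)"]),
    is_treatment = is_trt,
    reference = FALSE,
    flag = flag,
    stringsAsFactors = FALSE)
  est$term[is_trt] <- sub(paste0("^", treatment_var), "", est$term[is_trt])
  ref_row <- data.frame(term = ref, hr = 1, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_,
                        is_treatment = TRUE, reference = TRUE, flag = flag,
                        stringsAsFactors = FALSE)
  out <- rbind(ref_row, est)
  rownames(out) <- NULL
  structure(out, class = c("hr_estimates", "data.frame"),
            adjusted = length(kept) > 0, covariates = kept,
            dropped_covariates = dropped,
            loglik = fit$loglik, n = fit$n, nevent = fit$nevent)
}

#' @export
print.hr_estimates <- function(x, ...) {
  cat(sprintf("Cox PH (%s), %d events / %d subjects\n",
              if (isTRUE(attr(x, "adjusted"))) "adjusted" else "unadjusted",
              attr(x, "nevent"), attr(x, "n")))
  for (i in seq_len(nrow(x))) {
    if (x$reference[i]) cat(sprintf("  %-24s 1 (Reference)\n", x$term[i]))
    else cat(sprintf("  %-24s %.2f (%.2f-%.2f)%s\n", x$term[i], x$hr[i],
                     x$ci_low[i], x$ci_high[i],
                     if (x$is_treatment[i]) "" else "  [covariate]"))
  }
  invisible(x)
}

#' Partial-likelihood pseudo R-squared of a Cox fit
#'
#' \code{1 - exp(2 * (loglik0 - loglik1) / n)}, the likelihood-ratio
#' pseudo R-squared used to feed Cohen's f for survival models.
#'
#' @param fit An \code{hr_estimates} object from \code{\link{fit_cox}}.
#' @return Pseudo R-squared in [0, 1).
#' @export
cox_r_squared <- function(fit) {
  ll <- attr(fit, "loglik")
  n <- attr(fit, "n")
  max(0, 1 - exp(2 * (ll[1] - ll[2]) / n))
}

#' Stratified (moderation) treatment-effect estimates
#'
#' Fits \code{\link{fit_cox}} independently within each level of a
#' stratifying variable, excluding the stratifier from the covariates.
#' Strata without events are skipped and reported in the
#' \code{"skipped"} attribute.
#'
#' @inheritParams fit_cox
#' @param stratifier Column defining the subgroups.
#' @return Named list of \code{hr_estimates}, one per stratum with
#'   events; attribute \code{skipped} lists strata without events.
#' @export
subgroup_effects <- function(cohort, treatment_var = "treatment_arm",
                             covariates = character(), stratifier,
                             reference_arm = NULL) {
  covariates <- setdiff(covariates, stratifier)
  levels_present <- unique(cohort[[stratifier]])
  levels_present <- levels_present[!is.na(levels_present)]
  out <- list(); skipped <- character()
  for (lv in levels_present) {
    sel <- !is.na(cohort[[stratifier]]) & cohort[[stratifier]] == lv
    if (sum(cohort$event_indicator[sel] == "fracture", na.rm = TRUE) == 0 ||
        length(unique(cohort[[treatment_var]][sel])) < 2) {
      skipped <- c(skipped, as.character(lv))
      next
    }
    out[[as.character(lv)]] <- fit_cox(cohort, treatment_var, covariates,
                                       subset = sel,
                                       reference_arm = reference_arm)
  }
  if (length(skipped))
    message("subgroup level(s) skipped (no events or single arm): ",
            paste(skipped, collapse = ", "))
  attr(out, "skipped") <- skipped
  out
}
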