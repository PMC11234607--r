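#' Interpret an effect size on the conventional bins
#'
#' Half-open bins, lower bound inclusive: none below 0.01, very small
#' from 0.01, small from 0.2, medium from 0.5, large from 0.8 upward.
#'
#' @param value Non-negative effect-size value(s).
#' @return Character label(s).
#' @examples
#' interpret_effect_size(c(0.005, 0.216, 0.8))
#' @export
interpret_effect_size <- function(value) {
  if (any(is.na(value)) || any(value < 0)) stop("effect size must be >= 0")
  cut(value, breaks = c(-Inf, 0.01, 0.2, 0.5, 0.8, Inf), right = FALSE,
      labels = c("none", "very small", "small", "medium", "large")) |>
    as.character()
}

new_effect_size <- function(family, value, inputs) {
  structure(list(family = family, value = value, inputs = inputs,
                 interpretation = interpret_effect_size(value)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("%s = %.4f (%s)\n", x$family, x$value, x$interpretation))
  invisible(x)
}

#' Cohen's h for a difference of two proportions
#'
#' The arcsine effect size |2 arcsin sqrt(p1) - 2 arcsin sqrt(p2)|,
#' ranging over [0, pi].
#'
#' @param p1,p2 Proportions in [0, 1].
#' @return An \code{effect_size} with family \code{"cohens_h"}.
#' @examples
#' cohens_h(0.172, 0.099) # a "small" shift in a category share
#' @export
cohens_h <- function(p1, p2) {
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1))
    stop("proportions must lie in [0, 1]")
  h <- abs(2 * asin(sqrt(p1)) - 2 * asin(sqrt(p2)))
  new_effect_size("cohens_h", h, c(p1 = p1, p2 = p2))
}

#' Cohen's f for a model's explanatory power
#'
#' f = sqrt(R^2 / (1 - R^2)).
#'
#' @param r_squared R-squared in [0, 1).
#' @return An \code{effect_size} with family \code{"cohens_f"}.
#' @export
cohens_f <- function(r_squared) {
  if (is.na(r_squared) || r_squared < 0 || r_squared >= 1)
    stop("r_squared must lie in [0, 1)")
  new_effect_size("cohens_f", sqrt(r_squared / (1 - r_squared)),
                  c(r_squared = r_squared))
}

#' Effect size for a pair of hazard (or rate) ratios
#'
#' Package convention for comparing two ratio estimates of the same
#' contrast: each ratio r is mapped to the proportion r / (1 + r) and the
#' two proportions are compared with Cohen's h. Symmetric, and zero
#' exactly when the ratios are equal.
#'
#' @param hr_a,hr_b Positive ratios.
#' @return An \code{effect_size} with family \code{"hr_h"}.
#' @examples
#' hr_effect_size(2.14, 1.96)
#' @export
hr_effect_size <- function(hr_a, hr_b) {
  if (any(c(hr_a, hr_b) <= 0)) stop("ratios must be positive")
  h <- cohens_h(hr_a / (1 + hr_a), hr_b / (1 + hr_b))
  new_effect_size("hr_h", h$value, c(hr_a = hr_a, hr_b = hr_b))
}

#' Classify the agreement of two interval estimates
#'
#' The three-tier rule for judging whether an indirect-linkage result can
#' stand in for the direct-linkage result, evaluated top-down:
#' \enumerate{
#'   \item both estimates fall on opposite sides of the reference value
#'     and both intervals exclude it (significantly opposite directions)
#'     — insufficient;
#'   \item effect size >= 0.8 — insufficient;
#'   \item effect size in [0.5, 0.8) — poor;
#'   \item opposite directions without joint significance — poor;
#'   \item otherwise (effect < 0.5, same direction or similar estimates)
#'     — good.
#' }
#' Symbols: good = \enc{○}{o}, poor = \enc{△}{^}, insufficient = X.
#'
#' @param effect An \code{effect_size} (or bare non-negative number).
#' @param estimate_a,estimate_b Numeric length-3 vectors or lists with
#'   elements est, lo, hi (point estimate and CI bounds).
#' @param direction_reference Neutral value: 1 for ratios, 0 for
#'   differences/proportions.
#' @return A \code{concordance_verdict}: level, symbol, the effect, the
#'   direction/significance flags, the rule that fired and a rationale.
#' @export
classify_study_level <- function(effect, estimate_a, estimate_b,
                                 direction_reference = 1) {
  value <- if (inherits(effect, "effect_size")) effect$value else effect
  if (is.na(value) || value < 0) stop("effect size must be >= 0")
  ea <- as_estimate(estimate_a); eb <- as_estimate(estimate_b)
  ref <- direction_reference

  dir_a <- sign(ea["est"] - ref); dir_b <- sign(eb["est"] - ref)
  opposite <- dir_a != 0 && dir_b != 0 && dir_a != dir_b
  sig_a <- !is.na(ea["lo"]) && !is.na(ea["hi"]) &&
    (ea["lo"] > ref || ea["hi"] < ref)
  sig_b <- !is.na(eb["lo"]) && !is.na(eb["hi"]) &&
    (eb["lo"] > ref || eb["hi"] < ref)
  significant_opposite <- opposite && sig_a && sig_b

  if (significant_opposite) {
    level <- "insufficient"; rule <- 1L
    rationale <- "directions significantly opposite"
  } else if (value >= 0.8) {
    level <- "insufficient"; rule <- 2L
    rationale <- "effect size >= 0.8"
  } else if (value >= 0.5) {
    level <- "poor"; rule <- 3L
    rationale <- "effect size in [0.5, 0.8)"
  } else if (opposite) {
    level <- "poor"; rule <- 4L
    rationale <- "opposite directions, not jointly significant"
  } else {
    level <- "good"; rule <- 5L
    rationale <- "effect size < 0.5, same direction or similar estimates"
  }
  structure(list(level = level, symbol = verdict_symbol(level),
                 effect = value,
                 direction_agrees = !opposite,
                 significant_opposite = significant_opposite,
                 rule = rule, rationale = rationale),
            class = "concordance_verdict")
}

as_estimate <- function(e) {
  if (is.list(e)) e <- c(est = e$est, lo = e$lo, hi = e$hi)
  if (is.null(names(e)) && length(e) == 3) names(e) <- c("est", "lo", "hi")
  e <- e[c("est", "lo", "hi")]
  if (!is.na(e["lo"]) && !is.na(e["hi"]) && e["lo"] > e["hi"])
    stop("malformed interval: lower bound exceeds upper bound")
  e
}

verdict_symbol <- function(level) {
  c(good = "\u25cb", poor = "\u25b3", insufficient = "X")[[level]]
}

#' @export
print.concordance_verdict <- function(x, ...) {
  cat(sprintf("%s %s (effect %.3f; rule %d: %s)\n", x$symbol, x$level,
              x$effect, x$rule, x$rationale))
  invisible(x)
}

#' Pairwise concordance of two linkage levels' analysis results
#'
#' Takes the analysis summaries of the indirect- (III) and direct- (DII)
#' level cohorts — data.frames keyed by (stratum, method, item) with a
#' result kind and interval estimate per row — pairs them, computes the
#' appropriate effect size per pair (Cohen's h for proportions, the
#' ratio arcsine transform for hazard/rate ratios), classifies each pair,
#' and aggregates to a method-by-stratum verdict grid with the
#' good/poor/insufficient symbols. Unpaired keys are reported as missing,
#' never dropped silently.
#'
#' @param results_iii,results_dii Data.frames with columns
#'   \code{stratum}, \code{method}, \code{item}, \code{kind}
#'   (\code{"proportion"}, \code{"rate_ratio"} or \code{"hr"}),
#'   \code{est}, \code{lo}, \code{hi} (bounds may be NA for
#'   proportions).
#' @return A \code{concordance_report}: per-item verdict table
#'   (\code{items}), the cell-level grid (\code{grid}, worst verdict per
#'   method and stratum), and the unpaired keys (\code{missing}).
#' @export
concordance_report <- function(results_iii, results_dii) {
  key <- function(d) paste(d$stratum, d$method, d$item, sep = "\r")
  ka <- key(results_iii); kb <- key(results_dii)
  common <- intersect(ka, kb)
  missing <- data.frame(
    key = c(setdiff(ka, kb), setdiff(kb, ka)),
    present_in = c(rep("III", length(setdiff(ka, kb))),
                   rep("DII", length(setdiff(kb, ka)))),
    stringsAsFactors = FALSE)

  a <- results_iii[match(common, ka), , drop = FALSE]
  b <- results_dii[match(common, kb), , drop = FALSE]
  rows <- lapply(seq_along(common), function(i) {
    kind <- a$kind[i]
    es <- if (kind == "proportion") cohens_h(a$est[i], b$est[i])
          else hr_effect_size(a$est[i], b$est[i])
    ref <- if (kind == "proportion") 0 else 1
    v <- classify_study_level(
      es,
      c(est = a$est[i], lo = a$lo[i], hi = a$hi[i]),
      c(est = b$est[i], lo = b$lo[i], hi = b$hi[i]),
      direction_reference = ref)
    data.frame(stratum = a$stratum[i], method = a$method[i], item = a$item[i],
               kind = kind, est_iii = a$est[i], est_dii = b$est[i],
               effect = v$effect,
               interpretation = interpret_effect_size(v$effect),
               level = v$level, symbol = v$symbol, rule = v$rule,
               stringsAsFactors = FALSE)
  })
  items <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stratum = character(), method = character(), item = character(),
               kind = character(), est_iii = numeric(), est_dii = numeric(),
               effect = numeric(), interpretation = character(),
               level = character(), symbol = character(), rule = integer(),
               stringsAsFactors = FALSE)
  rownames(items) <- NULL

  rank <- c(good = 1, poor = 2, insufficient = 3)
  strata <- unique(c(results_iii$stratum, results_dii$stratum))
  methods <- unique(c(results_iii$method, results_dii$method))
  grid <- matrix("-", nrow = length(methods), ncol = length(strata),
                 dimnames = list(methods, strata))
  for (m in methods) for (s in strata) {
    cell <- items[items$method == m & items$stratum == s, ]
    if (nrow(cell))
      grid[m, s] <- verdict_symbol(names(rank)[max(rank[cell$level])])
  }
  structure(list(items = items, grid = grid, missing = missing),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance of III-level vs DII-level results",
      "(\u25cb good, \u25b3 poor, X insufficient, - not assessed)\n\n")
  print(x$grid, quote = FALSE)
  if (nrow(x$missing)) {
    cat("\nUnpaired results:\n")
    for (i in seq_len(nrow(x$missing)))
      cat("  [missing]", gsub("\r", " / ", x$missing$key[i]),
          "present only in", x$missing$present_in[i], "\n")
  }
  invisible(x)
}
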