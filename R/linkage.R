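#' Specify the identifier error process
#'
#' Two error mechanisms drive indirect-identifier (III) linkage quality:
#' \emph{missed matches}, where a record's name/date-of-birth/sex fields
#' are corrupted in one source so its composite key no longer equals its
#' partner's, and \emph{false matches}, where a record is assigned another
#' individual's III identifiers and so links to the wrong registry record.
#' A third rate models imperfect direct-identifier (DII) linkage by
#' blanking the unique id. Missingness can be made informative: named
#' log-odds shifts keyed by \code{"column=value"} predicates (conjunctions
#' joined with \code{&}) are added to the logit of the miss rate for
#' records satisfying the predicate.
#'
#' @param miss_rate Probability a record's III identifiers are corrupted.
#' @param collision_rate Probability a record receives another
#'   individual's III identifiers (one false match each).
#' @param dii_miss_rate Probability the unique id is blanked.
#' @param informative_coeffs Named numeric vector of log-odds shifts,
#'   names like \code{"event_indicator=fracture&treatment_arm=non-RT"}.
#' @param seed Integer seed for the corruption draws.
#' @return An object of class \code{error_model}.
#' @examples
#' error_model(miss_rate = 0.287, collision_rate = 0.002, dii_miss_rate = 0.003)
#' @export
error_model <- function(miss_rate = 0.287, collision_rate = 0.002,
                        dii_miss_rate = 0.003, informative_coeffs = NULL,
                        seed = 1L) {
  for (p in c(miss_rate, collision_rate, dii_miss_rate))
    if (is.na(p) || p < 0 || p > 1) stop("error rates must lie in [0, 1]")
  if (!is.null(informative_coeffs) &&
      (is.null(names(informative_coeffs)) || any(names(informative_coeffs) == "")))
    stop("informative_coeffs must be a named numeric vector")
  structure(list(miss_rate = miss_rate, collision_rate = collision_rate,
                 dii_miss_rate = dii_miss_rate,
                 informative_coeffs = informative_coeffs,
                 seed = as.integer(seed)),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat("<error_model> miss:", x$miss_rate, " collision:", x$collision_rate,
      " dii miss:", x$dii_miss_rate, "\n")
  if (length(x$informative_coeffs))
    cat("  informative shifts:",
        paste(sprintf("%s (%+.2f)", names(x$informative_coeffs),
                      x$informative_coeffs), collapse = "; "), "\n")
  invisible(x)
}

# Evaluate "col=val&col2=val2" predicates against table rows.
predicate_mask <- function(table, predicate) {
  clauses <- strsplit(predicate, "&", fixed = TRUE)[[1]]
  mask <- rep(TRUE, nrow(table))
  for (cl in clauses) {
    kv <- strsplit(cl, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed predicate: ", cl)
    col <- trimws(kv[1]); val <- trimws(kv[2])
    if (!col %in% names(table)) stop("predicate refers to unknown column: ", col)
    mask <- mask & !is.na(table[[col]]) & as.character(table[[col]]) == val
  }
  mask
}

#' Composite linkage keys
#'
#' Deterministic exact-match keys: the DII key depends only on the unique
#' id; the III key only on the (name token, date of birth, sex) triple.
#' Records missing a required field get \code{NA} — they are unlinkable at
#' that level, not an error.
#'
#' @param table A registry or claims table.
#' @param level \code{"DII"} or \code{"III"}.
#' @return Character vector of keys, \code{NA} where unlinkable.
#' @export
composite_key <- function(table, level = c("DII", "III")) {
  level <- match.arg(level)
  if (level == "DII") {
    key <- ifelse(is.na(table$uid) | table$uid == "", NA_character_,
                  paste0("D|", table$uid))
  } else {
    bad <- is.na(table$name_key) | table$name_key == "" |
      is.na(table$dob) | is.na(table$sex) | table$sex == ""
    key <- ifelse(bad, NA_character_,
                  paste("I", table$name_key, as.character(table$dob),
                        table$sex, sep = "|"))
  }
  key
}

#' Inject linkage errors into a claims table
#'
#' Realizes the configured \code{\link{error_model}} on one source so the
#' subsequent deterministic join exhibits missed and false matches with
#' known ground truth:
#' \itemize{
#'   \item \emph{miss}: with per-record probability
#'     \code{plogis(qlogis(miss_rate) + informative shifts)} the III
#'     fields are perturbed (name token swapped or date of birth edited),
#'     re-drawn until the corrupted key collides with no original key, so
#'     the miss mechanism can never create a false match;
#'   \item \emph{collision}: with probability \code{collision_rate} the
#'     record's III fields are overwritten with the original identifiers
#'     of another individual drawn (without replacement, same cancer
#'     stratum when possible) from the missed set — whose own claims key
#'     is already corrupted — so each collision yields exactly one false
#'     match; collision records are corrupted first if not already missed;
#'   \item \emph{DII miss}: with probability \code{dii_miss_rate} the
#'     unique id is blanked, making the record unlinkable at DII level.
#' }
#' Every change is logged. Deterministic given the model's seed.
#'
#' @param claims Claims table from \code{\link{emit_source_tables}}.
#' @param model An \code{\link{error_model}}.
#' @return List with the corrupted \code{table} and a \code{log}
#'   data.frame (rid, action, detail).
#' @export
corrupt_identifiers <- function(claims, model) {
  stopifnot(inherits(model, "error_model"))
  empty_log <- data.frame(rid = character(), action = character(),
                          detail = character(), stringsAsFactors = FALSE)
  n <- nrow(claims)
  if (n == 0) return(list(table = claims, log = empty_log))

  orig_key <- composite_key(claims, "III")
  key_pool <- unique(orig_key[!is.na(orig_key)])
  name_pool <- unique(claims$name_key)
  logs <- list()

  with_seed_(model$seed, {
    # per-record miss probability, logistic-shifted for predicate hits
    if (model$miss_rate <= 0) {
      p_miss <- rep(0, n)
    } else if (model$miss_rate >= 1) {
      p_miss <- rep(1, n)
    } else {
      eta <- rep(stats::qlogis(model$miss_rate), n)
      for (pred in names(model$informative_coeffs)) {
        hit <- predicate_mask(claims, pred)
        eta[hit] <- eta[hit] + model$informative_coeffs[[pred]]
      }
      p_miss <- stats::plogis(eta)
    }
    missed <- stats::runif(n) < p_miss
    collide <- stats::runif(n) < model$collision_rate
    # collision recipients are corruption targets themselves: their own
    # true pair is broken by taking on someone else's identity
    missed_only <- which(missed & !collide)
    collide_idx <- which(collide)

    # donors: missed records whose own claims key will be perturbed away,
    # so the donor's registry record is free to (falsely) link the
    # collision recipient; same cancer stratum preferred, no donor reuse
    donor_of <- integer(0)
    if (length(collide_idx)) {
      pool <- missed_only
      for (i in collide_idx) {
        same <- pool[claims$cancer_type[pool] == claims$cancer_type[i] &
                       pool != i]
        pick <- if (length(same)) same[1]
                else if (length(setdiff(pool, i))) setdiff(pool, i)[1]
                else NA_integer_
        if (is.na(pick)) {
          # no corrupted donor available: fall back to plain corruption
          missed_only <- c(missed_only, i)
        } else {
          pool <- setdiff(pool, pick)
          donor_of[as.character(i)] <- pick
        }
      }
      collide_idx <- as.integer(names(donor_of))
    }

    # perturb the missed records in vectorized rounds: swap the name
    # token or edit the date of birth, re-drawing until the corrupted key
    # matches no original key
    how <- character(0)
    if (length(missed_only)) {
      idx <- missed_only
      how <- rep(NA_character_, length(idx))
      pending <- seq_along(idx)
      for (round in 1:6) {
        if (!length(pending)) break
        take <- idx[pending]
        swap <- stats::runif(length(take)) < 0.5 & length(name_pool) > 1
        if (any(swap)) {
          cur <- match(claims$name_key[take[swap]], name_pool)
          k <- sample.int(length(name_pool) - 1L, sum(swap), replace = TRUE)
          k <- ifelse(!is.na(cur) & k >= cur, k + 1L, k)
          claims$name_key[take[swap]] <- name_pool[k]
        }
        if (any(!swap))
          claims$dob[take[!swap]] <- claims$dob[take[!swap]] +
            sample(c(-10:-1, 1:10), sum(!swap), replace = TRUE)
        key_new <- composite_key(claims[take, , drop = FALSE], "III")
        ok <- !(key_new %in% key_pool)
        how[pending[ok]] <- ifelse(swap[ok], "name-swap", "dob-edit")
        pending <- pending[!ok]
      }
      if (length(pending)) {
        # guaranteed off-dictionary token: cannot match any original key
        claims$name_key[idx[pending]] <- sprintf("xx%07d", idx[pending])
        how[pending] <- "name-void"
      }
    }

    # apply the engineered collisions from the donors' ORIGINAL
    # identifiers, which still match the donors' registry records
    for (i in collide_idx) {
      donor_orig <- strsplit(orig_key[donor_of[[as.character(i)]]],
                             "|", fixed = TRUE)[[1]]
      claims$name_key[i] <- donor_orig[2]
      claims$dob[i] <- as.Date(donor_orig[3])
      claims$sex[i] <- donor_orig[4]
    }

    blank <- which(stats::runif(n) < model$dii_miss_rate)
    claims$uid[blank] <- NA_character_

    logs <- list(
      if (length(missed_only))
        data.frame(rid = claims$rid[missed_only], action = "miss",
                   detail = how, stringsAsFactors = FALSE),
      if (length(collide_idx))
        data.frame(rid = claims$rid[collide_idx], action = "collision",
                   detail = claims$rid[unname(donor_of)],
                   stringsAsFactors = FALSE),
      if (length(blank))
        data.frame(rid = claims$rid[blank], action = "dii-blank",
                   detail = "", stringsAsFactors = FALSE))
    logs <- Filter(Negate(is.null), logs)
  })
  log <- if (length(logs)) do.call(rbind, logs) else empty_log
  list(table = claims, log = log)
}

#' Deterministically link registry and claims tables
#'
#' Inner join on the composite key of the requested level. Key groups
#' with multiple candidate rows on a side (homonyms, engineered
#' collisions) are resolved by sequential pairing: the k-th registry row
#' of a group is linked with the k-th claims row, in order of appearance;
#' surplus candidates on the longer side are dropped to a collision
#' report (kept as an attribute). Sequential pairing is deterministic,
#' auditable, and guarantees that uncorrupted tables link every record to
#' its true partner even when distinct people share a key. Row provenance
#' (true match / false match) is assigned by comparing each linked
#' uid/rid pair with the ground-truth map.
#'
#' @param registry,claims Source tables.
#' @param level \code{"DII"} or \code{"III"}.
#' @param truth Ground-truth uid/rid pairs from
#'   \code{\link{emit_source_tables}}.
#' @return A \code{linked_cohort} data.frame: registry payload
#'   (\code{uid}, \code{cancer_type}, \code{seer_stage},
#'   \code{diagnosis_date}), claims payload (covariates, treatment,
#'   outcome) and a \code{provenance} column; attributes \code{level} and
#'   \code{collisions}.
#' @export
link_tables <- function(registry, claims, level = c("DII", "III"), truth) {
  level <- match.arg(level)
  kr <- composite_key(registry, level)
  kc <- composite_key(claims, level)
  ir <- which(!is.na(kr)); ic <- which(!is.na(kc))
  # sequential pairing: tag each row with its rank within its key group
  rank_r <- stats::ave(seq_along(ir), kr[ir], FUN = seq_along)
  rank_c <- stats::ave(seq_along(ic), kc[ic], FUN = seq_along)
  kr2 <- paste(kr[ir], rank_r); kc2 <- paste(kc[ic], rank_c)
  shared <- intersect(kr2, kc2)
  reg_first <- ir[match(shared, kr2)]
  clm_first <- ic[match(shared, kc2)]

  # surplus candidates of multi-candidate groups that found no partner
  surplus_r <- ir[rank_r > 1 & !(kr2 %in% kc2) & kr[ir] %in% kc[ic]]
  surplus_c <- ic[rank_c > 1 & !(kc2 %in% kr2) & kc[ic] %in% kr[ir]]
  collisions <- data.frame(
    side = c(rep("registry", length(surplus_r)),
             rep("claims", length(surplus_c))),
    key = c(kr[surplus_r], kc[surplus_c]),
    id = c(registry$uid[surplus_r], claims$rid[surplus_c]),
    stringsAsFactors = FALSE)

  claims_payload <- claims[clm_first,
                           setdiff(names(claims),
                                   c("uid", "name_key", "dob", "sex",
                                     "cancer_type")),
                           drop = FALSE]
  out <- cbind(
    registry[reg_first, c("uid", "cancer_type", "seer_stage",
                          "diagnosis_date"), drop = FALSE],
    claims_payload)
  rownames(out) <- NULL
  true_uid <- truth$uid[match(out$rid, truth$rid)]
  out$provenance <- ifelse(!is.na(true_uid) & true_uid == out$uid,
                           "true-match", "false-match")
  structure(out, level = level, collisions = collisions,
            class = c("linked_cohort", "data.frame"))
}

#' Linkage accounting from raw counts
#'
#' The flow-chart arithmetic of a linkage exercise: given the number of
#' truth pairs, false matches and missed matches, derives the linked
#' total via \code{n_linked = (n_total - n_missed) + n_false}, the
#' one-decimal percentages of false and missed matches relative to the
#' truth pairs, and (optionally) the linkage rate relative to a reference
#' cohort, \code{100 * n_linked / n_reference_linked}, to one decimal.
#'
#' @param n_total Number of ground-truth pairs.
#' @param n_false Number of false-match rows.
#' @param n_missed Number of truth pairs not correctly linked.
#' @param n_linked Linked-row count; derived from the identity if omitted,
#'   validated against it otherwise.
#' @param n_reference_linked Linked-row count of the reference-level
#'   cohort (e.g. the DII-linked cohort), if a relative rate is wanted.
#' @return An object of class \code{linkage_accounting}.
#' @examples
#' # the flow-chart percentages of a III vs DII linkage exercise
#' linkage_accounting(n_total = 916854, n_false = 1730, n_missed = 263080,
#'                    n_reference_linked = 914399)
#' @export
linkage_accounting <- function(n_total, n_false, n_missed, n_linked = NULL,
                               n_reference_linked = NULL) {
  if (any(c(n_total, n_false, n_missed) < 0)) stop("counts must be >= 0")
  if (n_missed > n_total) stop("n_missed cannot exceed n_total")
  derived <- (n_total - n_missed) + n_false
  if (is.null(n_linked)) n_linked <- derived
  if (n_linked != derived)
    stop("inconsistent counts: n_linked must equal (n_total - n_missed) + n_false")
  structure(list(
    n_total = n_total, n_linked = n_linked, n_false = n_false,
    n_missed = n_missed,
    false_pct = pct1(n_false / n_total),
    missed_pct = pct1(n_missed / n_total),
    linked_pct_of_total = pct1(n_linked / n_total),
    linkage_rate_vs_reference =
      if (is.null(n_reference_linked)) NA_real_
      else pct1(n_linked / n_reference_linked)),
    class = "linkage_accounting")
}

#' Linkage rate of one cohort relative to a reference cohort
#'
#' \code{100 * n_linked / n_reference_linked}, reported to one decimal:
#' the conventional summary of how much of the reference-level cohort an
#' indirect-identifier linkage retains.
#'
#' @param n_linked Size of the linked cohort.
#' @param n_reference_linked Size of the reference (gold-standard) cohort.
#' @return One-decimal percentage.
#' @examples
#' linkage_rate(652004, 914399)
#' @export
linkage_rate <- function(n_linked, n_reference_linked) {
  if (n_reference_linked <= 0) stop("reference cohort must be non-empty")
  if (n_linked < 0) stop("counts must be >= 0")
  pct1(n_linked / n_reference_linked)
}

#' Audit a linked cohort against the ground truth
#'
#' @param linked A \code{linked_cohort}.
#' @param truth Ground-truth uid/rid pairs covering every linked row.
#' @param reference Optional reference \code{linked_cohort} (typically the
#'   DII-level cohort) for the relative linkage rate.
#' @return A \code{\link{linkage_accounting}}.
#' @export
account <- function(linked, truth, reference = NULL) {
  if (nrow(linked) && any(!linked$rid %in% truth$rid))
    stop("integrity error: linked rid absent from the truth map")
  n_false <- sum(linked$provenance == "false-match")
  n_true <- sum(linked$provenance == "true-match")
  linkage_accounting(
    n_total = nrow(truth), n_false = n_false,
    n_missed = nrow(truth) - n_true,
    n_reference_linked = if (is.null(reference)) NULL else nrow(reference))
}

#' @export
print.linkage_accounting <- function(x, ...) {
  cat("Linkage flow\n")
  cat(sprintf("  truth pairs            %10d\n", x$n_total))
  cat(sprintf("  linked rows            %10d  (%.1f%% of truth pairs)\n",
              x$n_linked, x$linked_pct_of_total))
  cat(sprintf("  false matches          %10d  (%.1f%%)\n", x$n_false, x$false_pct))
  cat(sprintf("  missed matches         %10d  (%.1f%%)\n", x$n_missed, x$missed_pct))
  if (!is.na(x$linkage_rate_vs_reference))
    cat(sprintf("  linkage rate vs reference  %.1f%%\n",
                x$linkage_rate_vs_reference))
  invisible(x)
}

#' @export
print.linked_cohort <- function(x, ...) {
  cat(sprintf("<linked_cohort level=%s> %d rows (%d false-match)\n",
              attr(x, "level"), nrow(x),
              sum(x$provenance == "false-match")))
  invisible(x)
}
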