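# Questionnaire scoring: instrument totals, Big-5 subscale means, and
# transdiagnostic factor scores from a supplied item-weight matrix.

#' Collapse social-anxiety fear and avoidance answers
#'
#' The social-anxiety instrument asks a fear/anxiety and an avoidance question
#' per situation; the two answer matrices are averaged elementwise.
#'
#' @param fear,avoidance numeric matrices of equal shape, same item order.
#' @return elementwise mean matrix.
#' @export
collapse_lsas <- function(fear, avoidance) {
  fear <- as.matrix(fear); avoidance <- as.matrix(avoidance)
  if (!identical(dim(fear), dim(avoidance))) stop("fear/avoidance shape mismatch")
  (fear + avoidance) / 2
}

#' Assemble the participant x item matrix expected by the weight matrix
#'
#' Pivots a long questionnaire table into a numeric matrix with one column per
#' scored psychiatric item, in the weight matrix's item order. Fear/avoidance
#' sub-answers (`<item>_fear` / `<item>_avoid`) are averaged into their base
#' item; catch and personality items are ignored.
#'
#' @param items long table: participant_id, instrument, item_id, response.
#' @param weights a `factor_weights` object.
#' @return numeric matrix (participants x 209) with participant ids as
#'   rownames.
#' @export
cohort_item_matrix <- function(items, weights) {
  ids <- sort(unique(items$participant_id))
  base <- sub("_(fear|avoid)$", "", items$item_id)
  keep <- base %in% weights$item_ids
  it <- items[keep, , drop = FALSE]
  base <- base[keep]
  # average duplicates (fear/avoid pairs) within participant x base item
  agg <- tapply(it$response,
                list(factor(it$participant_id, levels = ids),
                     factor(base, levels = weights$item_ids)),
                mean)
  m <- matrix(as.numeric(agg), nrow = length(ids),
              dimnames = list(ids, weights$item_ids))
  if (anyNA(m)) {
    bad <- colnames(m)[colSums(is.na(m)) > 0]
    stop("missing responses for item(s): ", paste(utils::head(bad, 5), collapse = ", "))
  }
  m
}

#' Transdiagnostic factor scores from an item-weight matrix
#'
#' Raw item responses are z-scored across participants, multiplied by their
#' factor weights and summed across items within each factor, and the factor
#' sums are z-scored across participants again.
#'
#' @param items numeric matrix (participants x items), columns in the weight
#'   matrix's item order (see [cohort_item_matrix()]).
#' @param weights a `factor_weights` object.
#' @return numeric matrix (participants x 3) of z-scored AD/CIT/SW scores.
#' @export
score_factors <- function(items, weights) {
  items <- as.matrix(items)
  if (nrow(items) < 3L) stop("need at least 3 participants to z-score")
  if (ncol(items) != length(weights$item_ids)) stop("item count does not match weights")
  sds <- apply(items, 2, stats::sd)
  if (any(sds == 0)) stop("zero-variance item column(s): ",
                          paste(utils::head(weights$item_ids[sds == 0], 5), collapse = ", "))
  z <- scale(items)
  sums <- z %*% weights$weights
  out <- scale(sums)
  dimnames(out) <- list(rownames(items), weights$factor_names)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Questionnaire totals, log-totals and Big-5 subscale scores
#'
#' Per-instrument totals follow each instrument's standard summation (with
#' fear/avoidance sub-answers averaged per item first and reverse-keyed items
#' flipped per `reverse_items`). Log-totals are `log(total + offset)`; the
#' offset (default 1) guards instruments whose minimum total is zero.
#' Big-5 scores are subscale means of the personality items.
#'
#' @param items long table: participant_id, instrument, item_id, response.
#' @param config instrument configuration (see [instrument_config()]).
#' @param log_offset offset added inside the log (default 1).
#' @param reverse_items optional character vector of item ids scored in
#'   reverse (flipped within their instrument's range before summing).
#' @return data frame: participant_id, one total and one log-total column per
#'   psychiatric instrument, and big5_* subscale means where personality items
#'   are present.
#' @export
questionnaire_totals <- function(items, config = instrument_config(),
                                 log_offset = 1, reverse_items = NULL) {
  it <- items
  it <- it[it$item_id != "zung_catch", , drop = FALSE]
  if (!is.null(reverse_items)) {
    for (iid in reverse_items) {
      sel <- it$item_id == iid
      if (!any(sel)) next
      ins <- config[config$instrument == it$instrument[sel][1], ]
      it$response[sel] <- ins$max + ins$min - it$response[sel]
    }
  }
  ids <- sort(unique(it$participant_id))
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)

  psych <- .psych_instruments(config)
  for (ins in psych$instrument) {
    sub <- it[it$instrument == ins, , drop = FALSE]
    base <- sub("_(fear|avoid)$", "", sub$item_id)
    n_expected <- psych$n_items[psych$instrument == ins]
    per_item <- tapply(sub$response,
                       list(factor(sub$participant_id, levels = ids), base), mean)
    if (anyNA(per_item) || ncol(per_item) != n_expected) {
      missing_items <- if (ncol(per_item) != n_expected)
        paste(n_expected - ncol(per_item), "item(s) absent") else
        paste("gaps in", paste(utils::head(colnames(per_item)[colSums(is.na(per_item)) > 0], 3),
                               collapse = ", "))
      stop("instrument '", ins, "' incomplete: ", missing_items)
    }
    tot <- rowSums(per_item)
    out[[paste0(ins, "_total")]] <- as.numeric(tot)
    out[[paste0(ins, "_log")]] <- log(as.numeric(tot) + log_offset)
  }

  b5 <- it[it$instrument == "bfi", , drop = FALSE]
  if (nrow(b5)) {
    sub5 <- sub("^bfi_([a-z])_.*$", "\\1", b5$item_id)
    key <- c(e = "extraversion", a = "agreeableness", c = "conscientiousness",
             o = "openness", n = "neuroticism")
    means <- tapply(b5$response,
                    list(factor(b5$participant_id, levels = ids), sub5), mean)
    for (s in colnames(means)) out[[paste0("big5_", key[[s]])]] <- as.numeric(means[, s])
  }
  attr(out, "log_offset") <- log_offset
  out
}

#' Per-participant score table for a cohort
#'
#' Convenience wrapper combining factor scores, questionnaire totals, Big-5
#' scores and demographics into the regression-ready score table.
#'
#' @param cohort a `cohort` (or any list with `items` and `demographics`).
#' @param weights a `factor_weights` object; defaults to the cohort's own.
#' @param ... passed to [questionnaire_totals()].
#' @return data frame keyed by participant_id.
#' @export
participant_scores <- function(cohort, weights = NULL, ...) {
  if (is.null(weights)) weights <- cohort$spec$weights
  m <- cohort_item_matrix(cohort$items, weights)
  fs <- score_factors(m, weights)
  tot <- questionnaire_totals(cohort$items, ...)
  out <- data.frame(participant_id = rownames(fs),
                    AD = fs[, "AD"], CIT = fs[, "CIT"], SW = fs[, "SW"],
                    stringsAsFactors = FALSE)
  out <- merge(out, tot, by = "participant_id")
  merge(out, cohort$demographics, by = "participant_id")
}
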