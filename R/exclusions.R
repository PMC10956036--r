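# Data-quality exclusion rules. Experiment-1 style analyses apply six rules on
# the perception task (missing gender, under 18, near-chance accuracy, failed
# catch item, constant confidence, negative metacognitive efficiency);
# experiment-2 style analyses add four knowledge-task rules (near-chance
# accuracy, constant confidence, negative efficiency, more than four
# non-responses). A participant violating several rules is excluded once but
# counted under every rule violated.

.default_exclusion_config <- function() {
  list(accuracy_min = 0.55, max_nonresponse = 4L,
       catch = list(instrument = "zung", item = "zung_catch", required = 3L))
}

#' Per-participant screening measures
#'
#' Computes, for each participant and task, the quantities the exclusion rules
#' consult: overall accuracy (responded, non-identical-condition trials only),
#' whether a single confidence rating was used on every trial, the number of
#' non-responses, and the (non-hierarchical, maximum-likelihood) Mratio.
#'
#' @param cohort a `cohort` or any list with `trials` in the standard schema.
#' @param fits optional data frame (participant_id, task, m_ratio) of
#'   precomputed single-subject fits; when absent, Mratio is fitted by MLE
#'   from the trial data.
#' @param K confidence-scale points.
#' @return data frame: participant_id, task, accuracy, constant_confidence,
#'   n_nonresponse, m_ratio.
#' @export
participant_measures <- function(cohort, fits = NULL, K = 6L) {
  tr <- cohort$trials
  chunks <- split(tr, list(tr$participant_id, tr$task), drop = TRUE)
  rows <- lapply(chunks, function(t) {
    pid <- t$participant_id[1L]; task <- t$task[1L]
    conf <- t$confidence[t$responded]
    mr <- NA_real_
    if (!is.null(fits)) {
      hit <- fits$participant_id == pid & fits$task == task
      if (any(hit)) mr <- fits$m_ratio[hit][1]
    }
    if (is.na(mr)) {
      mr <- tryCatch(fit_metad(counts_from_trials(t, K = K))$m_ratio,
                     error = function(e) NA_real_)
    }
    data.frame(participant_id = pid, task = task,
               accuracy = trial_accuracy(t),
               constant_confidence = length(unique(conf)) == 1L,
               n_nonresponse = sum(!t$responded),
               m_ratio = mr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$task, out$participant_id), ]
}

.catch_failures <- function(items, catch) {
  sel <- items$instrument == catch$instrument & items$item_id == catch$item
  resp <- items[sel, , drop = FALSE]
  resp$participant_id[resp$response != catch$required]
}

#' Apply the per-experiment exclusion rules
#'
#' @param cohort a `cohort` (needs `trials`, `demographics`, `items`).
#' @param experiment "exp1" (perception-task rules only) or "exp2"
#'   (perception plus knowledge-task rules).
#' @param fits optional precomputed fits, see [participant_measures()].
#' @param measures optional precomputed output of [participant_measures()]
#'   (skips fitting entirely).
#' @param config thresholds: `accuracy_min` (strict `<` comparison),
#'   `max_nonresponse`, and the `catch` item definition.
#' @return list with `retained` (the cohort filtered to surviving
#'   participants) and `report`, an `exclusion_report` with `n_input`,
#'   `n_excluded`, `n_retained`, `per_rule` counts (a multi-rule violator is
#'   counted under each rule) and `per_participant` violations.
#' @export
apply_exclusions <- function(cohort, experiment = c("exp1", "exp2"),
                             fits = NULL, measures = NULL,
                             config = .default_exclusion_config()) {
  experiment <- match.arg(experiment)
  config <- utils::modifyList(.default_exclusion_config(), config)
  dem <- cohort$demographics
  ids <- dem$participant_id
  if (is.null(measures)) measures <- participant_measures(cohort, fits = fits)

  task_rules <- function(task) {
    m <- measures[measures$task == task, , drop = FALSE]
    if (length(ids) == 0L)
      return(stats::setNames(list(character(0), character(0), character(0)),
                             paste0(c("accuracy_", "constant_confidence_",
                                      "negative_efficiency_"), task)))
    if (nrow(m) == 0L) stop("no fits/measures available for task '", task, "'")
    missing_ids <- setdiff(ids, m$participant_id)
    if (length(missing_ids)) stop("missing required fit for participant(s): ",
                                  paste(utils::head(missing_ids, 5), collapse = ", "))
    m <- m[match(ids, m$participant_id), ]
    out <- list()
    out[[paste0("accuracy_", task)]] <- ids[!is.na(m$accuracy) & m$accuracy < config$accuracy_min]
    out[[paste0("constant_confidence_", task)]] <- ids[m$constant_confidence]
    out[[paste0("negative_efficiency_", task)]] <- ids[!is.na(m$m_ratio) & m$m_ratio < 0]
    out
  }

  viol <- list(
    missing_gender = ids[is.na(dem$gender)],
    under_18 = ids[!is.na(dem$age) & dem$age < 18],
    catch_fail = intersect(ids, .catch_failures(cohort$items, config$catch)))
  viol <- c(viol, task_rules("perception"))
  if (experiment == "exp2") {
    viol <- c(viol, task_rules("knowledge"))
    m <- measures[measures$task == "knowledge", , drop = FALSE]
    m <- m[match(ids, m$participant_id), ]
    viol$nonresponse_knowledge <- ids[m$n_nonresponse > config$max_nonresponse]
  }

  excluded <- unique(unlist(viol))
  retained_ids <- setdiff(ids, excluded)
  per_participant <- lapply(stats::setNames(excluded, excluded), function(p)
    names(viol)[vapply(viol, function(v) p %in% v, logical(1))])

  report <- structure(list(
    n_input = length(ids), n_excluded = length(excluded),
    n_retained = length(retained_ids),
    per_rule = vapply(viol, length, integer(1)),
    per_participant = per_participant,
    experiment = experiment), class = "exclusion_report")

  keep <- function(df) df[df$participant_id %in% retained_ids, , drop = FALSE]
  retained <- cohort
  for (f in intersect(c("trials", "items", "demographics", "truth"), names(cohort)))
    retained[[f]] <- keep(cohort[[f]])

  list(retained = retained, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("Exclusion report (%s): %d of %d excluded (%.1f%%), %d retained\n",
              x$experiment, x$n_excluded, x$n_input,
              100 * x$n_excluded / max(x$n_input, 1), x$n_retained))
  for (r in names(x$per_rule))
    cat(sprintf("  %-32s %d\n", r, x$per_rule[[r]]))
  invisible(x)
}
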