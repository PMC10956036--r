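# Tabular I/O (CSV, RFC-4180 via base R), JSON configuration, and the
# end-to-end pipeline: fits -> exclusion -> scoring -> regressions.

.trial_schema <- c("participant_id", "task", "block", "evidence_level",
                   "stimulus_side", "response_side", "confidence", "responded")

#' Read a trial-level CSV
#'
#' One row per trial; header required; missing confidence encoded as an empty
#' field. Validates sides, the confidence range and the responded/confidence
#' invariant, naming the offending row and column.
#'
#' @param path CSV file path.
#' @param K confidence-scale points.
#' @return validated trial data frame.
#' @export
read_trials <- function(path, K = 6L) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(setdiff(.trial_schema, c("block", "responded")), names(tr))
  if (length(miss)) stop("trial CSV lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(tr) == 0L) {
    warning("empty trial file (header only): ", path)
    return(tr)
  }
  for (col in c("response_side", "stimulus_side"))
    tr[[col]][!is.na(tr[[col]]) & tr[[col]] == ""] <- NA_character_
  tr$confidence <- as.integer(tr$confidence)
  if (!"responded" %in% names(tr)) tr$responded <- !is.na(tr$response_side)
  tr$responded <- as.logical(tr$responded)
  bad <- which(tr$responded & (is.na(tr$confidence) | tr$confidence < 1 | tr$confidence > K))
  if (length(bad)) stop("invalid confidence at row ", bad[1],
                        " (column 'confidence': must be 1..", K, " when responded)")
  bad <- which(tr$responded & !tr$response_side %in% c("left", "right"))
  if (length(bad)) stop("invalid response_side at row ", bad[1])
  bad <- which(!tr$stimulus_side %in% c("left", "right"))
  if (length(bad)) stop("invalid stimulus_side at row ", bad[1])
  tr
}

#' Write a trial table as CSV
#' @param trials trial data frame.
#' @param path output path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a long-format questionnaire CSV
#'
#' Columns participant_id, instrument, item_id, response.
#' @param path CSV file path.
#' @return validated item data frame.
#' @export
read_questionnaires <- function(path) {
  it <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "instrument", "item_id", "response")
  miss <- setdiff(need, names(it))
  if (length(miss)) stop("questionnaire CSV lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(it) && anyNA(it$response)) {
    stop("missing response at row ", which(is.na(it$response))[1])
  }
  it
}

#' Read a factor item-weight CSV (item_id, AD, CIT, SW)
#' @param path CSV file path.
#' @return a `factor_weights` object.
#' @export
read_factor_weights <- function(path) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "AD", "CIT", "SW")
  miss <- setdiff(need, names(w))
  if (length(miss)) stop("weights CSV lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(w$item_id)) stop("duplicate item ids in weights")
  if (anyNA(w[, c("AD", "CIT", "SW")])) stop("missing weights")
  m <- as.matrix(w[, c("AD", "CIT", "SW")])
  rownames(m) <- w$item_id
  structure(list(item_ids = w$item_id, weights = m,
                 factor_names = c("AD", "CIT", "SW")),
            class = "factor_weights")
}

#' Write per-participant fit measures (tidy CSV + JSON sidecar)
#'
#' The CSV holds one row per participant x task x measure; the JSON sidecar
#' keeps the full criteria vectors and any MCMC convergence diagnostics.
#'
#' @param fits named list of `metad_fit` objects (names "participant.task" or
#'   use `meta` to supply labels).
#' @param csv_path,json_path output paths (`NULL` skips the sidecar).
#' @param meta optional data frame (participant_id, task) aligned with `fits`.
#' @return invisible csv_path.
#' @export
write_metad_fits <- function(fits, csv_path, json_path = NULL, meta = NULL) {
  if (is.null(meta)) {
    parts <- strsplit(names(fits), ".", fixed = TRUE)
    meta <- data.frame(participant_id = vapply(parts, `[`, "", 1),
                       task = vapply(parts, `[`, "", 2))
  }
  tidy <- do.call(rbind, lapply(seq_along(fits), function(i)
    metad_measures(fits[[i]], meta$participant_id[i], meta$task[i])))
  utils::write.csv(tidy, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    side <- lapply(seq_along(fits), function(i) {
      f <- fits[[i]]
      out <- list(participant_id = meta$participant_id[i], task = meta$task[i],
                  method = f$method, degenerate = f$degenerate,
                  t2c_left = f$t2c_left, t2c_right = f$t2c_right,
                  meta_c = f$meta_c, loglik = f$loglik)
      if (!is.null(f$posterior)) out$diagnostics <- f$posterior$diagnostics
      out
    })
    jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Pipeline configuration
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param cohort a `cohort_spec` to simulate, or `NULL` to read CSV inputs.
#' @param trials_csv,questionnaires_csv,demographics_csv,weights_csv input
#'   paths (used when `cohort` is `NULL`; weights fall back to the synthetic
#'   matrix).
#' @param experiment exclusion rule set, "exp1" or "exp2".
#' @param exclusions_enabled set `FALSE` to skip the exclusion stage.
#' @param measures behavioural outcome measures to regress.
#' @param out_dir output directory (created if needed).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, cohort = cohort_spec(seed = seed),
                            trials_csv = NULL, questionnaires_csv = NULL,
                            demographics_csv = NULL, weights_csv = NULL,
                            experiment = "exp2", exclusions_enabled = TRUE,
                            measures = c("d_prime", "meta_d", "log_efficiency",
                                         "confidence_criterion"),
                            out_dir = tempfile("metacogr_run_")) {
  structure(list(seed = as.integer(seed), cohort = cohort,
                 trials_csv = trials_csv, questionnaires_csv = questionnaires_csv,
                 demographics_csv = demographics_csv, weights_csv = weights_csv,
                 experiment = experiment,
                 exclusions_enabled = isTRUE(exclusions_enabled),
                 measures = measures, out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON
#' @param path JSON file with any subset of the [pipeline_config()] fields
#'   (`cohort` given as a list of [cohort_spec()] arguments).
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(j$cohort)) j$cohort <- do.call(cohort_spec, as.list(j$cohort))
  do.call(pipeline_config, j)
}

#' Run the full analysis pipeline
#'
#' Stages, in the order of the source workflow: obtain behaviour and
#' questionnaires (simulated or read from CSV), fit the meta-d' model per
#' participant and task (MLE), apply exclusions, score questionnaires and
#' factors, and run the three-symptom-dimension regression family for each
#' behavioural measure. Writes fits, scores, the exclusion report, regression
#' results and a run log into `config$out_dir`; outputs are deterministic
#' given the seed and each CSV carries the seed in a comment-free sidecar log.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) list with `fits_tidy`, `scores`, `exclusion_report`,
#'   `regressions`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run_log.txt")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%OS2"), " ", sprintf(...),
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("pipeline start; seed=%d; experiment=%s", config$seed, config$experiment)

  if (!is.null(config$cohort)) {
    cohort <- simulate_cohort(config$cohort)
    logf("simulated cohort: n=%d", config$cohort$n)
  } else {
    trials <- read_trials(config$trials_csv)
    items <- read_questionnaires(config$questionnaires_csv)
    dem <- utils::read.csv(config$demographics_csv, stringsAsFactors = FALSE)
    weights <- if (!is.null(config$weights_csv)) read_factor_weights(config$weights_csv)
               else synthetic_factor_weights()
    cohort <- structure(list(trials = trials, items = items, demographics = dem,
                             truth = NULL, spec = list(weights = weights,
                                                       tasks = unique(trials$task))),
                        class = "cohort")
    logf("loaded cohort: %d trials, %d item rows", nrow(trials), nrow(items))
  }

  tasks <- unique(cohort$trials$task)
  cf <- fit_cohort_metad(cohort$trials)
  fits <- cf$fits; combos <- cf$meta
  logf("fitted %d participant x task meta-d' models (MLE)", length(fits))
  fits_csv <- file.path(config$out_dir, "fits.csv")
  write_metad_fits(fits, fits_csv, file.path(config$out_dir, "fits.json"),
                   meta = combos)

  measures_df <- participant_measures(cohort, fits = data.frame(
    participant_id = combos$participant_id, task = combos$task,
    m_ratio = vapply(fits, `[[`, numeric(1), "m_ratio")))
  if (config$exclusions_enabled) {
    ex <- apply_exclusions(cohort, experiment = config$experiment,
                           measures = measures_df)
    logf("exclusions: %d of %d excluded", ex$report$n_excluded, ex$report$n_input)
  } else {
    ex <- list(retained = cohort,
               report = structure(list(n_input = length(unique(cohort$demographics$participant_id)),
                                       n_excluded = 0L,
                                       n_retained = length(unique(cohort$demographics$participant_id)),
                                       per_rule = integer(0), per_participant = list(),
                                       experiment = config$experiment),
                                  class = "exclusion_report"))
    logf("exclusions disabled")
  }
  jsonlite::write_json(ex$report[c("n_input", "n_excluded", "n_retained", "per_rule")],
                       file.path(config$out_dir, "exclusion_report.json"),
                       auto_unbox = TRUE, digits = NA)

  scores <- participant_scores(ex$retained)
  utils::write.csv(scores, file.path(config$out_dir, "scores.csv"), row.names = FALSE)
  logf("scored %d retained participants", nrow(scores))

  tidy <- cf$measures
  regressions <- list()
  for (task in tasks) {
    for (meas in config$measures) {
      sub <- tidy[tidy$task == task & tidy$measure == meas, ]
      dat <- merge(scores, sub[, c("participant_id", "value")], by = "participant_id")
      dat <- dat[stats::complete.cases(dat[, c("value", "AD", "CIT", "SW", "age", "gender")]), ]
      res <- standardized_ols(dat, "value", c("AD", "CIT", "SW", "age", "gender"),
                              model_id = paste(task, meas, sep = "."))
      res$outcome <- meas
      regressions[[paste(task, meas, sep = ".")]] <- res
    }
  }
  reg_df <- do.call(rbind, regressions)
  reg_df$alpha_corrected <- bonferroni_alpha(0.05, length(config$measures))
  reg_df$significant <- reg_df$p < reg_df$alpha_corrected
  utils::write.csv(reg_df, file.path(config$out_dir, "regressions.csv"),
                   row.names = FALSE)
  logf("regressions: %d models; done in %.1fs", length(regressions),
       as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(list(fits_tidy = tidy, scores = scores, exclusion_report = ex$report,
                 regressions = reg_df, out_dir = config$out_dir))
}
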