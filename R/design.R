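# Experimental designs: 2-AFC numerosity discrimination (perception) and
# national-population comparison (knowledge), both with 6-point confidence
# ratings.

#' Generate an experimental design and ordered trial list
#'
#' The default perception design is the dot-numerosity task: a reference box
#' of 272 dots against a comparison differing by -64..+64 dots in steps of 8
#' (17 conditions including the identical condition), 8 trials per condition,
#' 136 trials over 2 blocks. The default knowledge design bins country pairs
#' by population log10 ratio into 8 bins of width 0.225 (edges 0 to 1.8);
#' with both response sides that is 16 signed conditions, 9 trials each,
#' 144 trials over 2 blocks.
#'
#' The reference side (perception) is counterbalanced within each condition
#' (requires an even number of trials per condition); for knowledge the two
#' sides are themselves conditions, so counterbalancing holds by construction.
#' Trial order is pseudo-random given `seed`.
#'
#' @param task "perception" or "knowledge".
#' @param conditions,trials_per_condition,blocks,reference_magnitude,bin_edges
#'   overrides of the default design.
#' @param seed integer seed for the trial order.
#' @return object of class `design_spec`: list with the design fields and
#'   `trials`, a data frame with one row per trial (`trial`, `block`,
#'   `condition`, `reference_side` (perception), `evidence_level` (signed
#'   dots difference or signed log-ratio bin), `stimulus_side`).
#' @export
generate_design <- function(task = c("perception", "knowledge"),
                            conditions = NULL, trials_per_condition = NULL,
                            blocks = 2L, reference_magnitude = 272L,
                            bin_edges = seq(0, 1.8, by = 0.225), seed = 1L) {
  task <- match.arg(task)
  if (task == "perception") {
    if (is.null(conditions)) conditions <- seq(-64L, 64L, by = 8L)
    if (is.null(trials_per_condition)) trials_per_condition <- 8L
    if (trials_per_condition %% 2L != 0L)
      stop("odd trials_per_condition: reference side cannot be counterbalanced")
    rows <- do.call(rbind, lapply(conditions, function(d) {
      ref <- rep(c("left", "right"), each = trials_per_condition / 2L)
      # evidence = dots right minus dots left; comparison sits opposite the reference
      ev <- ifelse(ref == "left", d, -d)
      data.frame(condition = d, reference_side = ref, evidence_level = ev)
    }))
  } else {
    if (is.null(conditions)) conditions <- setdiff(-8:8, 0L)
    if (is.null(trials_per_condition)) trials_per_condition <- 9L
    rows <- do.call(rbind, lapply(conditions, function(b) {
      data.frame(condition = b, reference_side = NA_character_,
                 evidence_level = rep(b, trials_per_condition))
    }))
  }
  n <- nrow(rows)
  if (n %% blocks != 0L) stop("trial total ", n, " not divisible by ", blocks, " blocks")
  set.seed(seed)
  rows <- rows[sample.int(n), , drop = FALSE]
  rows$trial <- seq_len(n)
  rows$block <- rep(seq_len(blocks), each = n %/% blocks)
  # stimulus side: side with the stronger evidence; the identical condition
  # carries its (counterbalanced) reference side as the label
  rows$stimulus_side <- ifelse(rows$evidence_level > 0, "right",
                        ifelse(rows$evidence_level < 0, "left",
                               rows$reference_side))
  rownames(rows) <- NULL
  structure(list(task = task, conditions = conditions,
                 trials_per_condition = as.integer(trials_per_condition),
                 blocks = as.integer(blocks),
                 reference_magnitude = as.integer(reference_magnitude),
                 bin_edges = if (task == "knowledge") bin_edges else NULL,
                 n_trials = n, seed = as.integer(seed),
                 trials = rows[, c("trial", "block", "condition", "reference_side",
                                   "evidence_level", "stimulus_side")]),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("%s design: %d trials (%d conditions x %d, %d blocks)\n",
              x$task, x$n_trials, length(x$conditions),
              x$trials_per_condition, x$blocks))
  invisible(x)
}

#' Abstract stimulus description for one perception trial
#'
#' @param design a perception `design_spec`.
#' @param trial trial index.
#' @return list with `reference_count` (272 by default), `comparison_count`
#'   (reference + dots difference), `reference_side`, `comparison_side`.
#' @export
generate_stimulus_spec <- function(design, trial) {
  if (design$task != "perception") stop("stimulus specs exist for the perception task only")
  row <- design$trials[design$trials$trial == trial, ]
  if (nrow(row) != 1L) stop("no such trial: ", trial)
  d <- row$condition
  if (!d %in% design$conditions) stop("dots difference outside the condition set")
  list(reference_count = design$reference_magnitude,
       comparison_count = design$reference_magnitude + d,
       reference_side = row$reference_side,
       comparison_side = if (row$reference_side == "left") "right" else "left")
}
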