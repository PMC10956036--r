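#' Tabulate confidence-rating counts from a trial table
#'
#' Collapses a trial-level table of 2-AFC decisions with confidence ratings
#' into the 2 (stimulus side) x 2 (response side) x K (confidence) count table
#' that is the sufficient statistic for all type-1 and type-2 signal-detection
#' fitting. Counts are collapsed across evidence levels, as in analyses that
#' compute a single sensitivity estimate per participant and task.
#'
#' Trials without a response (e.g. knowledge-task time-outs) are dropped and
#' their number recorded. Zero-evidence trials (the "identical" condition,
#' where no response is objectively correct) are tabulated under their labelled
#' stimulus side and their count is recorded so that accuracy computations can
#' ignore them.
#'
#' @param trials data frame with columns `stimulus_side`, `response_side`,
#'   `confidence`, and optionally `responded` (logical) and `evidence_level`.
#' @param K number of confidence-scale points (default 6).
#' @return an object of class `rating_counts`: a list with `counts`
#'   (2 x 2 x K integer array, dimnames stimulus/response/confidence),
#'   `K`, `n_trials`, `n_dropped` (non-responded), and `n_zero_evidence`.
#' @export
counts_from_trials <- function(trials, K = 6L) {
  stopifnot(is.data.frame(trials), K >= 2)
  need <- c("stimulus_side", "response_side", "confidence")
  miss <- setdiff(need, names(trials))
  if (length(miss)) stop("trial table lacks columns: ", paste(miss, collapse = ", "))

  responded <- if ("responded" %in% names(trials)) {
    as.logical(trials$responded)
  } else {
    !is.na(trials$response_side) & !is.na(trials$confidence)
  }
  responded[is.na(responded)] <- FALSE
  n_dropped <- sum(!responded)
  t <- trials[responded, , drop = FALSE]
  if (nrow(t) == 0L) stop("no responded trials")

  conf <- as.integer(t$confidence)
  if (anyNA(conf)) stop("responded trials with missing confidence")
  if (any(conf < 1L | conf > K)) {
    stop("confidence out of range 1..", K, " at row(s) ",
         paste(utils::head(which(conf < 1L | conf > K), 5), collapse = ", "))
  }
  side <- function(x, what) {
    x <- as.character(x)
    if (!all(x %in% c("left", "right"))) stop("invalid ", what, " labels")
    factor(x, levels = c("left", "right"))
  }
  stim <- side(t$stimulus_side, "stimulus_side")
  resp <- side(t$response_side, "response_side")

  counts <- table(stimulus = stim, response = resp,
                  confidence = factor(conf, levels = seq_len(K)))
  counts <- array(as.integer(counts), dim = c(2L, 2L, K),
                  dimnames = list(stimulus = c("left", "right"),
                                  response = c("left", "right"),
                                  confidence = as.character(seq_len(K))))
  n_zero <- if ("evidence_level" %in% names(t)) sum(t$evidence_level == 0, na.rm = TRUE) else 0L

  structure(list(counts = counts, K = as.integer(K),
                 n_trials = nrow(t), n_dropped = n_dropped,
                 n_zero_evidence = as.integer(n_zero)),
            class = "rating_counts")
}

#' @export
print.rating_counts <- function(x, ...) {
  cat("Rating counts: 2 x 2 x", x$K, "table,", x$n_trials, "responded trials")
  if (x$n_dropped > 0) cat(" (", x$n_dropped, " non-responded dropped)", sep = "")
  cat("\n")
  print(x$counts)
  invisible(x)
}

validate_rating_counts <- function(counts) {
  if (!inherits(counts, "rating_counts")) stop("expected a 'rating_counts' object")
  if (!is.array(counts$counts) || !identical(dim(counts$counts), c(2L, 2L, counts$K)))
    stop("malformed rating_counts")
  if (any(counts$counts < 0)) stop("negative counts")
  invisible(counts)
}

# standard-normal quantile with probability clipping for extreme observers
z_clip <- function(p, eps = 1e-6) stats::qnorm(pmin(pmax(p, eps), 1 - eps))

#' Closed-form type-1 signal-detection estimates
#'
#' Computes d', criterion c and the relative criterion c' = c/d' from a rating
#' count table, collapsing confidence ratings to response marginals. Every
#' rating cell receives `padding` pseudo-counts before rates are formed (with
#' the default 1/(2K) this is the classic +0.5 correction on the collapsed
#' response counts), so estimates stay finite for extreme observers.
#'
#' Coordinate convention: stimulus "right" is the signal (S2) and response
#' "right" is "yes", so a hit is a "right" response to a "right" stimulus and
#' a bias toward "left" responses appears as c > 0.
#'
#' @param counts a `rating_counts` object.
#' @param padding pseudo-count added to each of the 2 x 2 x K cells
#'   (default `1/(2 * K)`).
#' @return object of class `type1_estimates`: list with `d_prime`, `c`,
#'   `c_rel` (c/d', `NA` when d' = 0), `hit_rate`, `fa_rate`, `n`.
#' @export
type1_fit <- function(counts, padding = 1 / (2 * counts$K)) {
  validate_rating_counts(counts)
  stopifnot(padding >= 0)
  K <- counts$K
  n <- counts$counts + padding
  # collapse confidence: response marginals per stimulus
  resp <- apply(n, c(1, 2), sum)
  if (any(rowSums(resp) <= 0)) stop("a stimulus row has zero total; cannot form rates")
  hit <- resp["right", "right"] / sum(resp["right", ])
  fa  <- resp["left", "right"] / sum(resp["left", ])
  zh <- z_clip(hit); zf <- z_clip(fa)
  d <- zh - zf
  c_ <- -0.5 * (zh + zf)
  structure(list(d_prime = d, c = c_,
                 c_rel = if (d != 0) c_ / d else NA_real_,
                 hit_rate = hit, fa_rate = fa, n = counts$n_trials),
            class = "type1_estimates")
}

#' @export
print.type1_estimates <- function(x, ...) {
  cat(sprintf("Type-1 SDT estimates (n = %d trials)\n", x$n))
  cat(sprintf("  d' = %.3f   c = %.3f   c' = %s   hit = %.3f   fa = %.3f\n",
              x$d_prime, x$c,
              if (is.na(x$c_rel)) "NA" else sprintf("%.3f", x$c_rel),
              x$hit_rate, x$fa_rate))
  invisible(x)
}

#' Overall accuracy from a trial table
#'
#' Proportion correct over responded trials with non-zero evidence
#' (correctness is undefined in the identical condition, which is excluded
#' from the denominator).
#'
#' @param trials trial data frame (needs `stimulus_side`, `response_side`,
#'   `evidence_level`; `responded` honoured when present).
#' @return proportion correct in [0, 1], or `NA` if no eligible trials.
#' @export
trial_accuracy <- function(trials) {
  responded <- if ("responded" %in% names(trials)) {
    as.logical(trials$responded)
  } else {
    !is.na(trials$response_side)
  }
  responded[is.na(responded)] <- FALSE
  ok <- responded & !is.na(trials$evidence_level) & trials$evidence_level != 0
  if (!any(ok)) return(NA_real_)
  mean(trials$response_side[ok] == trials$stimulus_side[ok])
}
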