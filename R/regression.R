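# Standardized multiple regression families linking symptom/personality
# scores to behavioural measures, with collinearity diagnostics, Bonferroni
# correction and between-task comparisons.

.z <- function(x) {
  s <- stats::sd(x)
  if (is.na(s) || s == 0) stop("zero-variance variable cannot be z-scored")
  (x - mean(x)) / s
}

# gender (or any two-level label) as a binary contrast, then z-scored like the
# continuous predictors so coefficients stay comparable
.encode_predictor <- function(x, name) {
  if (is.character(x) || is.factor(x) || is.logical(x)) {
    lev <- sort(unique(as.character(x)))
    if (length(lev) > 2L) stop("predictor '", name, "' has more than two levels")
    x <- as.numeric(as.character(x) == lev[length(lev)])
  }
  .z(as.numeric(x))
}

#' Standardized ordinary least squares
#'
#' All variables (outcome and predictors, including the binary gender
#' contrast) are z-scored before an OLS fit, so each coefficient is the change
#' in the outcome in standard deviations per standard deviation of the
#' predictor. Two-sided p-values use the t distribution with n - p - 1
#' degrees of freedom; 95% confidence intervals are t-based and symmetric
#' around the coefficient; a variance inflation factor is reported per
#' predictor (when there are at least two).
#'
#' @param data data frame holding outcome and predictors, no missing values.
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor columns.
#' @param model_id label stored with the result.
#' @param conf_level confidence level for the intervals (default 0.95).
#' @return data frame of class `regression_result`: one row per predictor
#'   with beta, se, ci_low, ci_high, p, vif; attributes `n`, `outcome`,
#'   `model_id`, `r_squared`.
#' @export
standardized_ols <- function(data, outcome, predictors, model_id = outcome,
                             conf_level = 0.95) {
  stopifnot(outcome %in% names(data), all(predictors %in% names(data)))
  if (anyNA(data[c(outcome, predictors)])) stop("missing values in model variables")
  n <- nrow(data)
  if (n <= length(predictors) + 1L) stop("n must exceed number of predictors + 1")
  y <- .z(as.numeric(data[[outcome]]))
  X <- vapply(predictors, function(p) .encode_predictor(data[[p]], p), numeric(n))
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) stop("singular design matrix")

  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  co <- sm$coefficients[-1L, , drop = FALSE]
  df <- n - length(predictors) - 1L
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df)
  vifs <- if (length(predictors) >= 2L) vif(X) else rep(NA_real_, length(predictors))

  out <- data.frame(model_id = model_id, outcome = outcome, term = predictors,
                    beta = co[, 1L], se = co[, 2L],
                    ci_low = co[, 1L] - tcrit * co[, 2L],
                    ci_high = co[, 1L] + tcrit * co[, 2L],
                    p = co[, 4L], vif = vifs,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n") <- n
  attr(out, "r_squared") <- sm$r.squared
  class(out) <- c("regression_result", "data.frame")
  out
}

#' Bonferroni-corrected alpha level
#'
#' `alpha / m`, where m is the number of dependent variables tested in the
#' analysis family. The exact value is returned; round to four decimals for
#' display (e.g. 0.05 over 36 tests displays as 0.0014).
#'
#' @param alpha nominal alpha (default 0.05).
#' @param m number of tests in the family (>= 1).
#' @return corrected alpha (exact).
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  if (m < 1) stop("family size m must be >= 1")
  alpha / m
}

#' Variance inflation factors
#'
#' For each predictor k, 1 / (1 - R^2_k) with R^2_k from regressing predictor
#' k on all the others.
#'
#' @param predictors numeric matrix with at least two columns, full rank.
#' @return numeric vector of VIFs (all >= 1).
#' @export
vif <- function(predictors) {
  X <- as.matrix(predictors)
  if (ncol(X) < 2L) stop("need at least two predictors")
  if (qr(cbind(1, X))$rank < ncol(X) + 1L) stop("rank-deficient predictor matrix")
  vapply(seq_len(ncol(X)), function(k) {
    r2 <- summary(stats::lm(X[, k] ~ X[, -k, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
}

#' Paired t-test and Pearson correlation between two tasks' measures
#'
#' @param x,y per-participant measures for the two tasks, aligned by
#'   participant (equal length, n >= 3).
#' @return list with `t`, `df`, `p_t` (paired t, two-sided; `t` is `NA` with
#'   `degenerate = TRUE` when every difference is zero), `r`, `p_r`
#'   (Pearson, df = n - 2), `n`.
#' @export
compare_measures <- function(x, y) {
  if (length(x) != length(y)) stop("measure vectors must be aligned by participant")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  d <- x - y
  if (stats::sd(d) == 0) {
    tt <- list(statistic = NA_real_, p.value = NA_real_, degenerate = TRUE)
  } else {
    ht <- stats::t.test(x, y, paired = TRUE)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value,
               degenerate = FALSE)
  }
  r <- stats::cor(x, y)
  p_r <- if (abs(r) >= 1) 0 else {
    tr <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tr), n - 2)
  }
  list(t = tt$statistic, df = n - 1L, p_t = tt$p.value,
       degenerate = tt$degenerate, r = r, p_r = p_r, n = n)
}
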