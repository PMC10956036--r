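# Generative confidence-rating observer. The observer sees evidence
# x ~ normal(mu, 1) with mu = sensitivity_scale * evidence_level / 2 (so the
# task-level d' at evidence Delta is sensitivity_scale * |Delta|), answers
# "right" when x exceeds the type-1 criterion, and rates confidence by cutting
# a noisy copy of the same evidence (x + normal(0, meta_noise_sd)) with
# equal-width type-2 criteria offset from the type-1 criterion by
# confidence_shift. With zero metacognitive noise and zero confidence shift
# this is the metacognitively ideal observer (Mratio = 1).

.default_sensitivity <- c(perception = 0.060, knowledge = 0.315)

#' Generative observer parameters
#'
#' @param sensitivity_scale slope k mapping |evidence| to d' (d' = k|Delta|).
#'   `NULL` picks a task-appropriate default calibrated so the default designs
#'   land near the reported task-average sensitivities (collapsed d' of about
#'   1.7 for perception, about 1.3 for knowledge).
#' @param criterion type-1 criterion on the evidence axis; positive values
#'   bias responses toward "left".
#' @param meta_noise_sd SD of noise added to the confidence copy of the
#'   evidence; 0 gives ideal metacognition, larger values reduce Mratio
#'   (approximately Mratio = 1/sqrt(1 + meta_noise_sd^2)).
#' @param confidence_shift additive shift of all type-2 criteria away from
#'   (positive) or toward (negative) the type-1 criterion; the generative
#'   counterpart of the confidence-criterion statistic (metacognitive bias).
#' @param conf_width spacing of the equal-width type-2 criteria.
#' @param K confidence-scale points.
#' @param nonresponse_prob per-trial probability of a time-out (knowledge task).
#' @return list of class `observer_params`.
#' @export
observer_params <- function(sensitivity_scale = NULL, criterion = 0,
                            meta_noise_sd = 0, confidence_shift = 0,
                            conf_width = 0.25, K = 6L, nonresponse_prob = 0) {
  stopifnot(meta_noise_sd >= 0, conf_width > 0, K >= 2,
            nonresponse_prob >= 0, nonresponse_prob < 1)
  structure(list(sensitivity_scale = sensitivity_scale, criterion = criterion,
                 meta_noise_sd = meta_noise_sd, confidence_shift = confidence_shift,
                 conf_width = conf_width, K = as.integer(K),
                 nonresponse_prob = nonresponse_prob),
            class = "observer_params")
}

# vectorised simulator for n observers over one design; par: data.frame with
# one row per observer (columns as observer_params plus participant_id)
.simulate_trials_multi <- function(design, par, seed) {
  set.seed(seed)
  tr <- design$trials
  Tn <- nrow(tr)
  n <- nrow(par)
  K <- par$K[1L]
  e <- tr$evidence_level

  mu <- 0.5 * outer(par$sensitivity_scale, e)
  x <- mu + matrix(stats::rnorm(n * Tn), n, Tn)
  resp_right <- x > par$criterion
  xm <- x + matrix(stats::rnorm(n * Tn), n, Tn) * par$meta_noise_sd
  # confidence evidence measured from the criterion on the chosen side
  v <- ifelse(resp_right, xm - par$criterion, par$criterion - xm)
  conf <- matrix(1L, n, Tn)
  for (y in seq_len(K - 1L)) {
    off <- pmax(par$conf_width * y + par$confidence_shift, 1e-3 * y)
    conf <- conf + (v > off)
  }
  responded <- matrix(TRUE, n, Tn)
  if (any(par$nonresponse_prob > 0)) {
    responded <- matrix(stats::runif(n * Tn), n, Tn) >= par$nonresponse_prob
  }

  out <- data.frame(
    participant_id = rep(par$participant_id, each = Tn),
    task = design$task,
    block = rep(tr$block, n),
    trial = rep(tr$trial, n),
    condition = rep(tr$condition, n),
    evidence_level = rep(e, n),
    stimulus_side = rep(tr$stimulus_side, n),
    response_side = ifelse(t(resp_right), "right", "left")[seq_len(Tn * n)],
    confidence = as.integer(t(conf)),
    responded = as.logical(t(responded)),
    stringsAsFactors = FALSE)
  out$response_side[!out$responded] <- NA_character_
  out$confidence[!out$responded] <- NA_integer_
  out
}

#' Simulate one observer's session on a design
#'
#' @param design a `design_spec` from [generate_design()].
#' @param params an `observer_params` object.
#' @param seed integer seed; the output is deterministic given (design, params,
#'   seed).
#' @param participant_id label for the participant column.
#' @return trial table (one row per trial) in the standard schema:
#'   participant_id, task, block, trial, condition, evidence_level,
#'   stimulus_side, response_side, confidence, responded.
#' @export
simulate_observer <- function(design, params = observer_params(), seed = 1L,
                              participant_id = "sim01") {
  if (!inherits(params, "observer_params")) stop("params must be observer_params()")
  k <- params$sensitivity_scale
  if (is.null(k)) k <- unname(.default_sensitivity[design$task])
  par <- data.frame(participant_id = participant_id, sensitivity_scale = k,
                    criterion = params$criterion,
                    meta_noise_sd = params$meta_noise_sd,
                    confidence_shift = params$confidence_shift,
                    conf_width = params$conf_width, K = params$K,
                    nonresponse_prob = params$nonresponse_prob,
                    stringsAsFactors = FALSE)
  .simulate_trials_multi(design, par, seed)
}
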