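# Synthetic cohorts: three correlated latent symptom dimensions (AD, CIT, SW)
# expressed through 209 questionnaire items across nine instruments, Big-5
# personality items, demographics, and per-participant observer parameters
# carrying planted symptom -> behaviour effects. Every planted quantity is
# recorded in a ground-truth table.

#' Instrument configuration for the questionnaire battery
#'
#' The nine psychiatric instruments with their item counts and response
#' ranges (209 scored items in total: depression 20, OCD 18, trait anxiety 20,
#' alcohol use 10, apathy 18, eating attitudes 26, impulsivity 30, schizotypy
#' 43, social anxiety 24 with fear/avoidance sub-answers averaged), plus the
#' 44-item Big-5 inventory. `factor` names the symptom dimension each
#' instrument loads on most strongly.
#'
#' @return data frame with columns instrument, n_items, min, max, factor, big5.
#' @export
instrument_config <- function() {
  data.frame(
    instrument = c("zung", "stai", "aes", "bis", "oci", "eat", "audit", "sss",
                   "lsas", "bfi"),
    n_items = c(20L, 20L, 18L, 30L, 18L, 26L, 10L, 43L, 24L, 44L),
    min = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 1L),
    max = c(4L, 4L, 4L, 4L, 4L, 3L, 4L, 1L, 3L, 5L),
    factor = c("AD", "AD", "AD", "AD", "CIT", "CIT", "CIT", "CIT", "SW", NA),
    big5 = c(rep(FALSE, 9), TRUE),
    stringsAsFactors = FALSE)
}

.psych_instruments <- function(cfg = instrument_config()) cfg[!cfg$big5, ]

.item_ids <- function(cfg = instrument_config()) {
  ins <- .psych_instruments(cfg)
  unlist(mapply(function(i, n) sprintf("%s_%02d", i, seq_len(n)),
                ins$instrument, ins$n_items, SIMPLIFY = FALSE), use.names = FALSE)
}

#' Synthetic factor item-weight matrix
#'
#' A stand-in for a published 209-item x 3-factor weight matrix (which is
#' user-supplied in real analyses): each item loads mainly on its instrument's
#' dominant dimension with small cross-loadings.
#'
#' @param seed integer seed.
#' @return object of class `factor_weights`: list with `item_ids` (209),
#'   `weights` (209 x 3 matrix), `factor_names` c("AD", "CIT", "SW").
#' @export
synthetic_factor_weights <- function(seed = 20L) {
  set.seed(seed)
  cfg <- .psych_instruments()
  ids <- .item_ids()
  fac <- rep(cfg$factor, cfg$n_items)
  n <- length(ids)
  # cross-loadings centred on zero with mixed signs, as in oblique-rotation
  # solutions; uniformly positive cross-loadings would induce a spurious
  # general factor and near-collinear scores
  w <- matrix(stats::rnorm(n * 3, 0, 0.06), n, 3,
              dimnames = list(ids, c("AD", "CIT", "SW")))
  for (f in c("AD", "CIT", "SW")) w[fac == f, f] <- stats::runif(sum(fac == f), 0.45, 0.8)
  structure(list(item_ids = ids, weights = w, factor_names = c("AD", "CIT", "SW")),
            class = "factor_weights")
}

#' Specification of a synthetic cohort
#'
#' Defaults state the world the generator emulates: three symptom dimensions
#' correlated as in large transdiagnostic samples; planted standardized
#' effects of +0.33 (AD) and -0.17 (CIT) on the confidence criterion and
#' -0.16 (CIT) on d'; population Mratio centred on 0.8; task-level
#' sensitivity landing near the reported task averages.
#'
#' @param n cohort size.
#' @param tasks tasks each participant completes.
#' @param weights a `factor_weights` object (defaults to the synthetic matrix).
#' @param factor_cov 3 x 3 correlation matrix of the AD/CIT/SW latents.
#' @param effect_map named list of planted standardized effects: each element
#'   (names "confidence_criterion", "d_prime") is a named vector of
#'   standardized betas over c(AD, CIT, SW).
#' @param item_noise_sd SD of item-level noise around the factor model.
#' @param violators named counts of planted rule violators: `under_18`,
#'   `missing_gender`, `chance_performer`, `constant_confidence`,
#'   `catch_fail`, `knowledge_nonresponse`.
#' @param demographics list: `age_mean`, `age_sd`, `age_min`, `age_max`,
#'   `p_female`.
#' @param mratio_mean,mratio_sd population distribution of the generative
#'   Mratio (clipped to [0.3, 1]; values at 1 mean zero metacognitive noise).
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 100L,
                        tasks = c("perception", "knowledge"),
                        weights = synthetic_factor_weights(),
                        factor_cov = matrix(c(1, 0.45, 0.58,
                                              0.45, 1, 0.42,
                                              0.58, 0.42, 1), 3, 3,
                                            dimnames = list(c("AD", "CIT", "SW"),
                                                            c("AD", "CIT", "SW"))),
                        effect_map = list(
                          confidence_criterion = c(AD = 0.33, CIT = -0.17, SW = 0),
                          d_prime = c(AD = 0, CIT = -0.16, SW = 0)),
                        item_noise_sd = 1,
                        violators = list(),
                        demographics = list(age_mean = 25, age_sd = 9,
                                            age_min = 18, age_max = 70,
                                            p_female = 0.5),
                        mratio_mean = 0.8, mratio_sd = 0.2,
                        seed = 1L) {
  tasks <- match.arg(tasks, c("perception", "knowledge"), several.ok = TRUE)
  if (length(weights$item_ids) != 209L) stop("weight matrix must cover 209 items")
  ev <- eigen(factor_cov, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("factor_cov must be positive-definite")
  violators <- utils::modifyList(
    list(under_18 = 0L, missing_gender = 0L, chance_performer = 0L,
         constant_confidence = 0L, catch_fail = 0L, knowledge_nonresponse = 0L),
    violators)
  if (sum(unlist(violators)) > n) stop("more planted violators than participants")
  structure(list(n = as.integer(n), tasks = tasks, weights = weights,
                 factor_cov = factor_cov, effect_map = effect_map,
                 item_noise_sd = item_noise_sd, violators = violators,
                 demographics = demographics,
                 mratio_mean = mratio_mean, mratio_sd = mratio_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# standardized latent outcome: planted linear effect of the factors plus just
# enough residual (shared across tasks + task-specific) for unit variance
.planted_latent <- function(F, beta, R, share = 0.5, n_tasks = 1L) {
  lin <- drop(F %*% beta)
  var_lin <- drop(t(beta) %*% R %*% beta)
  resid_var <- max(1 - var_lin, 0.02)
  shared <- stats::rnorm(nrow(F), 0, sqrt(share * resid_var))
  lapply(seq_len(n_tasks), function(t)
    lin + shared + stats::rnorm(nrow(F), 0, sqrt((1 - share) * resid_var)))
}

#' Simulate a full synthetic cohort
#'
#' Draws factor scores from a multivariate normal, expresses them through
#' ordinal questionnaire items (plus Big-5 items and a catch item), assigns
#' each participant observer parameters carrying the planted effects, runs the
#' observer over the default task designs, and injects the requested rule
#' violators (taken from the end of the cohort, one rule each, no overlaps).
#'
#' @param spec a `cohort_spec`.
#' @return list of class `cohort`: `trials` (all tasks stacked, standard
#'   schema), `items` (long questionnaire table: participant_id, instrument,
#'   item_id, response), `demographics`, `truth` (ground-truth table with
#'   every planted parameter), `spec`.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  ids <- sprintf("p%04d", seq_len(n))
  R <- spec$factor_cov

  F <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(R)
  colnames(F) <- colnames(R)

  dg <- spec$demographics
  age <- round(pmin(pmax(stats::rnorm(n, dg$age_mean, dg$age_sd),
                         dg$age_min), dg$age_max))
  gender <- ifelse(stats::runif(n) < dg$p_female, "female", "male")

  # ---- planted behavioural latents (standardized scale) ----
  # The effect_map targets are standardized effects on the *measured*
  # confidence criterion, which carries trial-level measurement noise into
  # its SD; the measurement chain at the default designs passes the latent
  # effect with gain ~0.71 (criteria-spacing recovery x outcome z-scoring),
  # so the latent plant is scaled by its inverse. Calibrated once against
  # the default world; see the methods vignette.
  cc_gain <- c(AD = 0.83, CIT = 0.74, SW = 0.78)
  nt <- length(spec$tasks)
  u_cc <- .planted_latent(F, spec$effect_map$confidence_criterion[colnames(R)] /
                               cc_gain[colnames(R)],
                          R, share = 0.6, n_tasks = nt)
  u_d <- .planted_latent(F, spec$effect_map$d_prime[colnames(R)],
                         R, share = 0.2, n_tasks = nt)
  names(u_cc) <- names(u_d) <- spec$tasks

  mr <- pmin(pmax(stats::rnorm(n, spec$mratio_mean, spec$mratio_sd), 0.3), 1)
  meta_noise <- sqrt(1 / mr^2 - 1)
  criterion <- stats::rnorm(n, 0.1, 0.15)  # mild leftward bias (c > 0)

  # ---- violators ----
  v <- spec$violators
  vc <- unlist(v)
  vidx <- split(rev(seq_len(n))[seq_len(sum(vc))],
                rep(names(vc), vc))
  flag <- function(rule) seq_len(n) %in% vidx[[rule]]
  is_under18 <- flag("under_18"); is_nogender <- flag("missing_gender")
  is_chance <- flag("chance_performer"); is_constconf <- flag("constant_confidence")
  is_catch <- flag("catch_fail"); is_nonresp <- flag("knowledge_nonresponse")
  age[is_under18] <- sample(16:17, sum(is_under18), replace = TRUE)
  gender[is_nogender] <- NA_character_

  # ---- behaviour ----
  trials <- list()
  truth_rows <- data.frame(participant_id = ids, AD = F[, "AD"], CIT = F[, "CIT"],
                           SW = F[, "SW"], age = age, gender = gender,
                           mratio_target = mr, criterion = criterion,
                           under_18 = is_under18, missing_gender = is_nogender,
                           chance_performer = is_chance,
                           constant_confidence = is_constconf,
                           catch_fail = is_catch,
                           knowledge_nonresponse = is_nonresp,
                           stringsAsFactors = FALSE)
  for (task in spec$tasks) {
    k0 <- unname(.default_sensitivity[task])
    # d' proportional to sensitivity; cv 0.3, clamped so a non-violator cannot
    # drift into the near-chance exclusion band
    k <- k0 * pmax(1 + 0.3 * u_d[[task]], 0.35)
    k[is_chance] <- 0.02 * k0
    nonresp <- rep(0, n)
    if (task == "knowledge") nonresp[is_nonresp] <- 0.08  # E[nonresponses] ~ 11 > 4
    # Confidence bias is multiplicative on the criterion spacing (log-normal
    # across subjects): always-positive offsets with realistic right skew and
    # no floor truncation. Offsets live on the meta axis, which metacognitive
    # noise rescales by 1/sqrt(1 + sd^2), hence the per-subject conversion;
    # the 0.42 log-scale spread realises the planted standardized effects on
    # the *measured* confidence criterion at the default designs.
    atten <- 1 / sqrt(1 + meta_noise^2)
    par <- data.frame(participant_id = ids, sensitivity_scale = k,
                      criterion = criterion, meta_noise_sd = meta_noise,
                      confidence_shift = 0,
                      conf_width = 0.25 * exp(0.42 * u_cc[[task]]) / atten,
                      K = 6L,
                      nonresponse_prob = nonresp, stringsAsFactors = FALSE)
    design <- generate_design(task, seed = spec$seed + match(task, spec$tasks))
    tt <- .simulate_trials_multi(design, par, seed = spec$seed + 100L + match(task, spec$tasks))
    if (any(is_constconf)) {
      sel <- tt$participant_id %in% ids[is_constconf] & tt$responded
      tt$confidence[sel] <- 4L
    }
    trials[[task]] <- tt
    truth_rows[[paste0("sensitivity_", task)]] <- k
    truth_rows[[paste0("conf_width_", task)]] <- par$conf_width
    truth_rows[[paste0("latent_cc_", task)]] <- u_cc[[task]]
    truth_rows[[paste0("latent_d_", task)]] <- u_d[[task]]
  }

  items <- .simulate_items(F, spec, ids, is_catch)

  structure(list(trials = do.call(rbind, trials),
                 items = items,
                 demographics = data.frame(participant_id = ids, age = age,
                                           gender = gender, stringsAsFactors = FALSE),
                 truth = truth_rows, spec = spec),
            class = "cohort")
}

# ordinal mapping: probability-integral transform of the unit-variance latent
# onto the instrument's response range, then rounding
.to_ordinal <- function(latent, latent_sd, mn, mx) {
  as.integer(mn + round((mx - mn) * stats::pnorm(latent / latent_sd)))
}

.simulate_items <- function(F, spec, ids, is_catch) {
  n <- nrow(F)
  cfg <- instrument_config()
  ins <- .psych_instruments(cfg)
  W <- spec$weights$weights
  R <- spec$factor_cov
  sig <- spec$item_noise_sd
  lat <- F %*% t(W) + matrix(stats::rnorm(n * nrow(W)), n) * sig  # n x 209
  lat_sd <- sqrt(rowSums((W %*% R) * W) + sig^2)                  # per item
  inst_of <- rep(ins$instrument, ins$n_items)

  rows <- vector("list", 0L)
  for (j in seq_len(nrow(W))) {
    i <- inst_of[j]
    mn <- ins$min[ins$instrument == i]; mx <- ins$max[ins$instrument == i]
    if (i == "lsas") {
      # fear and avoidance sub-answers around the shared item latent
      for (sub in c("fear", "avoid")) {
        lj <- lat[, j] + stats::rnorm(n, 0, 0.5)
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = ids, instrument = "lsas",
          item_id = paste0(rownames(W)[j], "_", sub),
          response = .to_ordinal(lj, sqrt(lat_sd[j]^2 + 0.25), mn, mx),
          stringsAsFactors = FALSE)
      }
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = ids, instrument = i, item_id = rownames(W)[j],
        response = .to_ordinal(lat[, j], lat_sd[j], mn, mx),
        stringsAsFactors = FALSE)
    }
  }

  # catch item embedded in the depression scale: attentive answer is option 3
  catch_resp <- rep(3L, n)
  catch_resp[is_catch] <- sample(c(1L, 2L, 4L), sum(is_catch), replace = TRUE)
  rows[[length(rows) + 1L]] <- data.frame(
    participant_id = ids, instrument = "zung", item_id = "zung_catch",
    response = catch_resp, stringsAsFactors = FALSE)

  # Big-5 latents tied to the symptom factors (signs as observed in large
  # questionnaire studies), expressed through 44 items on a 1-5 scale
  B <- rbind(extraversion = c(-0.24, 0.28, -0.62),
             agreeableness = c(-0.31, 0, 0),
             conscientiousness = c(-0.66, 0, 0.17),
             openness = c(-0.15, 0.17, 0),
             neuroticism = c(0.45, 0.24, 0.24))
  n_items_b5 <- c(extraversion = 8L, agreeableness = 9L, conscientiousness = 9L,
                  openness = 10L, neuroticism = 8L)
  for (tr in rownames(B)) {
    b <- B[tr, ]
    var_lin <- drop(t(b) %*% R %*% b)
    latb <- drop(F %*% b) + stats::rnorm(n, 0, sqrt(max(1 - var_lin, 0.05)))
    for (jj in seq_len(n_items_b5[[tr]])) {
      lj <- latb + stats::rnorm(n, 0, 1)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = ids, instrument = "bfi",
        item_id = sprintf("bfi_%s_%02d", substr(tr, 1, 1), jj),
        response = .to_ordinal(lj, sqrt(2), 1L, 5L),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, tasks: %s\n",
              x$spec$n, paste(x$spec$tasks, collapse = ", ")))
  cat(sprintf("  %d trials, %d item responses\n", nrow(x$trials), nrow(x$items)))
  nv <- sum(unlist(x$spec$violators))
  if (nv > 0) cat("  planted rule violators:", nv, "\n")
  invisible(x)
}
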