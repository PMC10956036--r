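# Meta-d' observer model: type-2 response probabilities, maximum-likelihood and
# MCMC single-subject fitting, metacognitive efficiency and the confidence-
# criterion (metacognitive bias) statistic.
#
# The meta-level evidence axis carries unit-variance normals at +/- meta_d/2
# (equal-variance model). The meta-level type-1 criterion meta_c is pinned to
# c_rel * meta_d, i.e. the observer's relative criterion c/d' transplanted onto
# the meta axis, as in the standard meta-d' framework.

# ---- internal vectorised machinery (shared with the hierarchical module) ----

# Conditional type-2 probabilities for n observers at once.
# meta_d, meta_c: length-n; tL, tR: n x (K-1) criteria matrices.
# Returns list of n x K matrices P[[stim]][[resp]] ordered LL, RL, LR, RR
# (stimulus left/right x response left/right).
.t2_cond_probs <- function(meta_d, meta_c, tL, tR) {
  n <- length(meta_d)
  K <- ncol(tL) + 1L
  muL <- -meta_d / 2
  muR <- meta_d / 2
  # response "right": boundaries meta_c = b0 < b1 <= ... < bK = +Inf
  BR <- cbind(meta_c, tR, Inf, deparse.level = 0)
  # response "left": meta_c = a0 > a1 >= ... > aK = -Inf
  BL <- cbind(meta_c, tL, -Inf, deparse.level = 0)
  probs_for <- function(mu) {
    cdfR <- stats::pnorm(BR - mu)
    cdfL <- stats::pnorm(BL - mu)
    pR <- cdfR[, -1L, drop = FALSE] - cdfR[, -(K + 1L), drop = FALSE]
    pL <- cdfL[, -(K + 1L), drop = FALSE] - cdfL[, -1L, drop = FALSE]
    dR <- pmax(1 - cdfR[, 1L], 1e-12)
    dL <- pmax(cdfL[, 1L], 1e-12)
    list(left = pL / dL, right = pR / dR)
  }
  list(stimL = probs_for(muL), stimR = probs_for(muR))
}

# Multinomial log-likelihood of confidence counts conditional on
# (stimulus, response). cnt: list of n x K count matrices LL, RL, LR, RR.
.t2_loglik <- function(meta_d, meta_c, tL, tR, cnt) {
  p <- .t2_cond_probs(meta_d, meta_c, tL, tR)
  lg <- function(x) log(pmax(x, 1e-12))
  rowSums(cnt$LL * lg(p$stimL$left) + cnt$LR * lg(p$stimL$right) +
          cnt$RL * lg(p$stimR$left) + cnt$RR * lg(p$stimR$right))
}

# split a (padded) 2 x 2 x K count array into the four 1 x K matrices
.count_mats <- function(counts_arr) {
  K <- dim(counts_arr)[3]
  list(LL = matrix(counts_arr["left", "left", ], 1, K),
       LR = matrix(counts_arr["left", "right", ], 1, K),
       RL = matrix(counts_arr["right", "left", ], 1, K),
       RR = matrix(counts_arr["right", "right", ], 1, K))
}

# criteria from unconstrained log-increment parameters (monotone by design)
.crit_from_increments <- function(meta_c, aL, aR) {
  list(tL = meta_c - cumsum(exp(aL)), tR = meta_c + cumsum(exp(aR)))
}

#' Predicted confidence-rating probabilities under the meta-d' model
#'
#' Conditional probabilities P(confidence = y | stimulus, response) for an
#' equal-variance meta-level observer with sensitivity `meta_d`, meta-level
#' type-1 criterion `meta_c`, and response-conditional type-2 criteria.
#' For "right" responses the rating regions are bounded below by `meta_c` and
#' by the increasing criteria `t2c_right`; "left" responses mirror this with
#' the decreasing `t2c_left`. Each conditional distribution sums to one.
#'
#' @param meta_d meta-level sensitivity (>= 0).
#' @param meta_c meta-level type-1 criterion.
#' @param t2c_left decreasing vector of K-1 criteria, all <= `meta_c`.
#' @param t2c_right increasing vector of K-1 criteria, all >= `meta_c`.
#' @param K number of confidence levels.
#' @return 2 x 2 x K array of probabilities with dimnames
#'   stimulus/response/confidence.
#' @export
predict_type2_probs <- function(meta_d, meta_c, t2c_left, t2c_right, K) {
  if (meta_d < 0) stop("meta_d must be non-negative")
  stopifnot(length(t2c_left) == K - 1, length(t2c_right) == K - 1)
  if (any(t2c_right < meta_c) || is.unsorted(t2c_right))
    stop("t2c_right must be non-decreasing and >= meta_c")
  if (any(t2c_left > meta_c) || is.unsorted(rev(t2c_left)))
    stop("t2c_left must be non-increasing and <= meta_c")
  p <- .t2_cond_probs(meta_d, meta_c,
                      matrix(t2c_left, 1), matrix(t2c_right, 1))
  out <- array(NA_real_, dim = c(2L, 2L, K),
               dimnames = list(stimulus = c("left", "right"),
                               response = c("left", "right"),
                               confidence = as.character(seq_len(K))))
  out["left", "left", ] <- p$stimL$left
  out["left", "right", ] <- p$stimL$right
  out["right", "left", ] <- p$stimR$left
  out["right", "right", ] <- p$stimR$right
  out
}

#' Simulate rating counts directly from the meta-d' observer model
#'
#' Type-1 responses follow the equal-variance SDT observer (d', criterion
#' c = c_rel * d'); confidence ratings are then drawn from the model's own
#' conditional distributions P(y | stimulus, response) at the stated meta-d'.
#' Unlike the process observer in [simulate_observer()], the generative
#' Mratio here is exactly `meta_d / d_prime`, which makes the counts suitable
#' for parameter-recovery studies.
#'
#' @param n_trials total trials (half per stimulus side).
#' @param d_prime,c_rel type-1 sensitivity and relative criterion.
#' @param meta_d meta-level sensitivity (>= 0).
#' @param t2c_offsets positive increasing offsets of the K-1 type-2 criteria
#'   from the meta-level criterion (mirrored across sides).
#' @param seed integer seed.
#' @return a `rating_counts` object.
#' @export
simulate_metad_counts <- function(n_trials, d_prime, c_rel = 0, meta_d = d_prime,
                                  t2c_offsets = 0.5 * seq_len(5), seed = 1L) {
  set.seed(seed)
  K <- length(t2c_offsets) + 1L
  meta_c <- c_rel * meta_d
  p2 <- predict_type2_probs(meta_d, meta_c, meta_c - t2c_offsets,
                            meta_c + t2c_offsets, K)
  c1 <- c_rel * d_prime
  n_s <- c(left = n_trials %/% 2L, right = n_trials - n_trials %/% 2L)
  counts <- array(0L, dim = c(2L, 2L, K),
                  dimnames = list(stimulus = c("left", "right"),
                                  response = c("left", "right"),
                                  confidence = as.character(seq_len(K))))
  for (s in c("left", "right")) {
    mu <- if (s == "right") d_prime / 2 else -d_prime / 2
    n_right <- stats::rbinom(1L, n_s[[s]], stats::pnorm(c1 - mu, lower.tail = FALSE))
    for (r in c("left", "right")) {
      nr <- if (r == "right") n_right else n_s[[s]] - n_right
      counts[s, r, ] <- as.integer(stats::rmultinom(1L, nr, p2[s, r, ]))
    }
  }
  structure(list(counts = counts, K = K, n_trials = n_trials,
                 n_dropped = 0L, n_zero_evidence = 0L),
            class = "rating_counts")
}

# ---- fitting -----------------------------------------------------------------

# analytic gradient of the negative conditional log-likelihood in the
# (meta_d, log-increment) parameterisation; keeps BFGS off the numeric-
# differencing path, which dominates fitting cost in large cohorts
.metad_negll_grad <- function(theta, K, c_rel, cnt) {
  meta_d <- theta[1L]
  aL <- theta[2:K]; aR <- theta[(K + 1):(2 * K - 1)]
  eL <- exp(aL); eR <- exp(aR)
  meta_c <- c_rel * meta_d
  bR <- meta_c + cumsum(eR)   # right-side boundaries beyond meta_c
  bL <- meta_c - cumsum(eL)
  g <- numeric(2 * K - 1)
  for (stim in c("L", "R")) {
    mu <- if (stim == "R") meta_d / 2 else -meta_d / 2
    dmu <- if (stim == "R") 0.5 else -0.5
    # response "right"
    n <- as.numeric(if (stim == "R") cnt$RR else cnt$LR)
    b <- c(meta_c, bR)
    PHI <- c(stats::pnorm(b - mu), 1)
    phi <- stats::dnorm(b - mu)
    P <- pmax(PHI[-1L] - PHI[-(K + 1L)], 1e-12)
    D <- pmax(1 - PHI[1L], 1e-12)
    w <- n / P
    coef <- c(0, w[-K]) - w
    coef[1L] <- coef[1L] + sum(n) / D
    gj <- coef * phi
    g[1L] <- g[1L] + sum(gj) * (c_rel - dmu)
    tailg <- rev(cumsum(rev(gj)))          # sum_{j >= i}
    g[(K + 1):(2 * K - 1)] <- g[(K + 1):(2 * K - 1)] +
      eR * c(tailg[-1L], 0)[seq_len(K - 1L)]
    # response "left"
    n <- as.numeric(if (stim == "R") cnt$RL else cnt$LL)
    b <- c(meta_c, bL)
    PHI <- c(stats::pnorm(b - mu), 0)
    phi <- stats::dnorm(b - mu)
    P <- pmax(PHI[-(K + 1L)] - PHI[-1L], 1e-12)
    D <- pmax(PHI[1L], 1e-12)
    w <- n / P
    coef <- w - c(0, w[-K])
    coef[1L] <- coef[1L] - sum(n) / D
    gj <- coef * phi
    g[1L] <- g[1L] + sum(gj) * (c_rel - dmu)
    tailg <- rev(cumsum(rev(gj)))
    g[2:K] <- g[2:K] - eL * c(tailg[-1L], 0)[seq_len(K - 1L)]
  }
  -g
}

.metad_negll <- function(theta, K, c_rel, cnt) {
  meta_d <- theta[1L]
  meta_c <- c_rel * meta_d
  cr <- .crit_from_increments(meta_c, theta[2:K], theta[(K + 1):(2 * K - 1)])
  -.t2_loglik(meta_d, meta_c, matrix(cr$tL, 1), matrix(cr$tR, 1), cnt)
}

#' Fit the meta-d' model to a rating count table
#'
#' Type-1 parameters (d', c, c' = c/d') are fixed from [type1_fit()]; the
#' meta-level criterion is pinned at c' * meta-d' throughout. Meta-d' and the
#' two response-conditional criteria vectors are then chosen to maximise the
#' multinomial log-likelihood of the confidence counts conditional on
#' (stimulus, response), with every rating cell padded. Criterion ordering is
#' guaranteed by fitting positive increments on a log scale away from the
#' meta-level criterion.
#'
#' `method = "mle"` returns the constrained maximum-likelihood point estimate
#' (meta-d' may come out negative, which flags the participant for exclusion
#' screening). `method = "mcmc"` draws posterior samples by adaptive
#' random-walk Metropolis under weakly informative priors
#' (log Mratio ~ normal(0, 1); log criteria increments ~ normal(0, 2)) and
#' reports posterior means, with convergence diagnostics.
#'
#' @param counts a `rating_counts` object.
#' @param method "mle" (default) or "mcmc".
#' @param mcmc sampler settings from [mcmc_params()].
#' @param padding per-cell pseudo-count, default `1/(2K)` as in [type1_fit()].
#' @return object of class `metad_fit` with elements `type1`, `meta_d`,
#'   `meta_c`, `t2c_left`, `t2c_right`, `m_ratio`, `log_efficiency`
#'   (`NA` when m_ratio <= 0), `confidence_criterion`, `loglik`, `method`,
#'   `degenerate`, and for MCMC fits a `posterior` list with draws and
#'   diagnostics (R-hat, effective sample size).
#' @export
fit_metad <- function(counts, method = c("mle", "mcmc"), mcmc = mcmc_params(),
                      padding = 1 / (2 * counts$K)) {
  method <- match.arg(method)
  validate_rating_counts(counts)
  K <- counts$K
  t1 <- type1_fit(counts, padding = padding)
  if (is.na(t1$c_rel)) stop("d' is exactly zero; relative criterion undefined")
  cnt <- .count_mats(counts$counts + padding)

  # all confidence mass in one rating level leaves the criteria unidentified
  conf_marg <- apply(counts$counts, 3, sum)
  degenerate <- sum(conf_marg > 0) <= 1L

  if (method == "mle") {
    fit <- .fit_metad_mle(K, t1, cnt)
  } else {
    fit <- .fit_metad_mcmc(K, t1, cnt, mcmc)
  }

  out <- structure(c(list(type1 = t1), fit,
                     list(m_ratio = fit$meta_d / t1$d_prime,
                          method = method, degenerate = degenerate,
                          K = K, padding = padding)),
                   class = "metad_fit")
  out$log_efficiency <- if (out$m_ratio > 0) log(out$m_ratio) else NA_real_
  out$confidence_criterion <- confidence_criterion(out)
  out
}

.metad_start <- function(K, t1) {
  # modest spread of criteria around the meta criterion; two spacings tried
  list(c(t1$d_prime, rep(log(0.4), 2 * (K - 1))),
       c(t1$d_prime * 0.5, rep(log(0.9), 2 * (K - 1))))
}

.fit_metad_mle <- function(K, t1, cnt) {
  starts <- .metad_start(K, t1)
  best <- NULL
  for (s in seq_along(starts)) {
    o <- tryCatch(
      stats::optim(starts[[s]], .metad_negll, gr = .metad_negll_grad,
                   K = K, c_rel = t1$c_rel, cnt = cnt,
                   method = "BFGS", control = list(maxit = 500, reltol = 1e-11)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value - 1e-9)) best <- o
    # the second start is a safety net, only consulted when the first failed
    # or clearly did not converge
    if (s == 1L && !is.null(o) && o$convergence == 0L) break
  }
  if (is.null(best)) stop("meta-d' optimisation failed to evaluate; counts may be malformed")
  theta <- best$par
  meta_d <- theta[1L]
  meta_c <- t1$c_rel * meta_d
  cr <- .crit_from_increments(meta_c, theta[2:K], theta[(K + 1):(2 * K - 1)])
  list(meta_d = meta_d, meta_c = meta_c,
       t2c_left = cr$tL, t2c_right = cr$tR,
       loglik = -best$value, convergence = best$convergence)
}

#' MCMC sampler settings
#'
#' Defaults follow the settings used for individual participant fits in the
#' source workflow: 3 chains, 1000 burn-in iterations, 10000 retained samples
#' per chain, no thinning.
#'
#' @param nchains,nburnin,nsamples,nthin sampler settings.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @return list of class `mcmc_params`.
#' @export
mcmc_params <- function(nchains = 3L, nburnin = 1000L, nsamples = 10000L,
                        nthin = 1L, seed = 1L) {
  stopifnot(nchains >= 1, nburnin >= 0, nsamples >= 1, nthin >= 1)
  structure(list(nchains = as.integer(nchains), nburnin = as.integer(nburnin),
                 nsamples = as.integer(nsamples), nthin = as.integer(nthin),
                 seed = as.integer(seed)),
            class = "mcmc_params")
}

.fit_metad_mcmc <- function(K, t1, cnt, mcmc,
                            prior_logm_sd = 1, prior_inc_mean = 0, prior_inc_sd = 2) {
  if (t1$d_prime <= 0) stop("MCMC fit requires d' > 0 (log Mratio parameterisation)")
  npar <- 2 * K - 1
  logpost <- function(theta) {
    logm <- theta[1L]
    meta_d <- exp(logm) * t1$d_prime
    meta_c <- t1$c_rel * meta_d
    cr <- .crit_from_increments(meta_c, theta[2:K], theta[(K + 1):npar])
    ll <- .t2_loglik(meta_d, meta_c, matrix(cr$tL, 1), matrix(cr$tR, 1), cnt)
    ll + stats::dnorm(logm, 0, prior_logm_sd, log = TRUE) +
      sum(stats::dnorm(theta[-1L], prior_inc_mean, prior_inc_sd, log = TRUE))
  }
  blocks <- list(1L, 2:K, (K + 1):npar)
  chains <- vector("list", mcmc$nchains)
  for (ch in seq_len(mcmc$nchains)) {
    set.seed(mcmc$seed + ch - 1L)
    theta <- c(0, rep(log(0.4), npar - 1L))
    lp <- logpost(theta)
    scales <- c(0.15, 0.25, 0.25)
    keep <- matrix(NA_real_, mcmc$nsamples, npar)
    total <- mcmc$nburnin + mcmc$nsamples * mcmc$nthin
    acc <- numeric(3)
    for (it in seq_len(total)) {
      for (b in seq_along(blocks)) {
        idx <- blocks[[b]]
        prop <- theta
        prop[idx] <- prop[idx] + stats::rnorm(length(idx), 0, scales[b])
        lp_prop <- logpost(prop)
        if (log(stats::runif(1)) < lp_prop - lp) {
          theta <- prop; lp <- lp_prop; acc[b] <- acc[b] + 1
        }
      }
      if (it <= mcmc$nburnin && it %% 50L == 0L) {
        rate <- acc / 50
        scales <- scales * exp((rate - 0.3))
        acc[] <- 0
      }
      if (it > mcmc$nburnin) {
        j <- it - mcmc$nburnin
        if (j %% mcmc$nthin == 0L) keep[j %/% mcmc$nthin, ] <- theta
      }
    }
    chains[[ch]] <- keep
  }
  draws <- do.call(rbind, chains)
  logm_chains <- lapply(chains, function(m) m[, 1L])
  theta_mean <- colMeans(draws)
  meta_d <- mean(exp(draws[, 1L])) * t1$d_prime
  meta_c <- t1$c_rel * meta_d
  cr <- .crit_from_increments(meta_c, theta_mean[2:K], theta_mean[(K + 1):npar])
  ll <- .t2_loglik(meta_d, meta_c, matrix(cr$tL, 1), matrix(cr$tR, 1), cnt)
  list(meta_d = meta_d, meta_c = meta_c,
       t2c_left = cr$tL, t2c_right = cr$tR, loglik = ll, convergence = 0L,
       posterior = list(
         log_mratio = draws[, 1L],
         meta_d = exp(draws[, 1L]) * t1$d_prime,
         increments = draws[, -1L, drop = FALSE],
         diagnostics = data.frame(
           parameter = "log_mratio",
           rhat = rhat(logm_chains),
           ess = ess(unlist(logm_chains)))))
}

#' Fit the meta-d' model to every participant x task in a trial table
#'
#' @param trials trial table in the standard schema (or a `cohort`, whose
#'   `$trials` are used).
#' @param method,mcmc,K passed to [fit_metad()].
#' @return list with `fits` (named `participant.task` list of `metad_fit`),
#'   `meta` (participant_id/task data frame aligned with `fits`) and
#'   `measures` (tidy one-row-per-measure data frame).
#' @export
fit_cohort_metad <- function(trials, method = "mle", mcmc = mcmc_params(), K = 6L) {
  if (inherits(trials, "cohort")) trials <- trials$trials
  chunks <- split(trials, list(trials$participant_id, trials$task), drop = TRUE)
  fits <- lapply(chunks, function(t)
    tryCatch(fit_metad(counts_from_trials(t, K = K), method = method, mcmc = mcmc),
             error = function(e) stop("fit failed for participant ",
                                      t$participant_id[1L], " (", t$task[1L], "): ",
                                      conditionMessage(e))))
  meta <- data.frame(
    participant_id = vapply(chunks, function(t) t$participant_id[1L], ""),
    task = vapply(chunks, function(t) t$task[1L], ""),
    stringsAsFactors = FALSE, row.names = NULL)
  measures <- do.call(rbind, lapply(seq_along(fits), function(i)
    metad_measures(fits[[i]], meta$participant_id[i], meta$task[i])))
  list(fits = fits, meta = meta, measures = measures)
}

#' Confidence-criterion statistic (metacognitive bias)
#'
#' Mean absolute distance between the type-2 criteria and the type-1 reference
#' criterion, averaged first over the K-1 rating levels within each response
#' side and then over the two side means. Lower values indicate a bias toward
#' high absolute confidence; the statistic is inversely related to mean raw
#' confidence.
#'
#' @param fit a `metad_fit` object.
#' @param reference "meta_c" (default: the model's own type-1 criterion on the
#'   meta axis) or "c" (the raw type-1 criterion).
#' @return non-negative scalar.
#' @export
confidence_criterion <- function(fit, reference = c("meta_c", "c")) {
  reference <- match.arg(reference)
  ref <- if (reference == "meta_c") fit$meta_c else fit$type1$c
  mean(c(mean(abs(fit$t2c_left - ref)), mean(abs(fit$t2c_right - ref))))
}

#' Metacognitive efficiency log(meta-d'/d')
#'
#' @param fit a `metad_fit` object.
#' @return `log(m_ratio)`. Raw m_ratio below zero is representable in the fit
#'   (for exclusion screening) but the log transform is refused for it.
#' @export
efficiency <- function(fit) {
  if (!inherits(fit, "metad_fit")) stop("expected a 'metad_fit' object")
  if (is.na(fit$m_ratio) || fit$m_ratio <= 0)
    stop("efficiency undefined; participant subject to exclusion rule (m_ratio <= 0)")
  log(fit$m_ratio)
}

#' @export
print.metad_fit <- function(x, ...) {
  cat(sprintf("meta-d' fit (%s%s)\n", x$method,
              if (isTRUE(x$degenerate)) ", DEGENERATE: single rating level" else ""))
  cat(sprintf("  d' = %.3f  c = %.3f  meta-d' = %.3f  Mratio = %.3f\n",
              x$type1$d_prime, x$type1$c, x$meta_d, x$m_ratio))
  cat(sprintf("  confidence criterion = %.3f  loglik = %.2f\n",
              x$confidence_criterion, x$loglik))
  invisible(x)
}

#' Tidy one-row-per-measure summary of a meta-d' fit
#'
#' @param fit a `metad_fit`.
#' @param participant_id,task optional labels attached to every row.
#' @return data frame with columns participant_id, task, measure, value.
#' @export
metad_measures <- function(fit, participant_id = NA_character_, task = NA_character_) {
  data.frame(
    participant_id = participant_id, task = task,
    measure = c("d_prime", "c", "c_rel", "meta_d", "m_ratio",
                "log_efficiency", "confidence_criterion"),
    value = c(fit$type1$d_prime, fit$type1$c, fit$type1$c_rel, fit$meta_d,
              fit$m_ratio, fit$log_efficiency, fit$confidence_criterion),
    stringsAsFactors = FALSE)
}
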