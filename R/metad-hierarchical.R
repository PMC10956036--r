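# Hierarchical Bayesian estimation of metacognitive efficiency (Mratio).
#
# Model: for subject s with type-1 parameters (d'_s, c'_s) fixed from the
# closed-form fit, log Mratio_s ~ normal(mu + X_s beta, sigma); meta-d'_s =
# exp(log Mratio_s) d'_s; the confidence counts follow the response-conditional
# multinomial type-2 likelihood of the meta-d' model, with subject-specific
# type-2 criteria (log-increment parameterisation). Priors: mu ~ normal(0, 1),
# beta_k ~ normal(0, 1), sigma ~ half-normal(1), log criteria increments ~
# normal(0, 2). Sampling is adaptive Metropolis-within-Gibbs: vectorised
# random-walk updates across subjects, conjugate Gibbs draws for (mu, beta).

# row-wise cumulative sum across columns
.row_cumsum <- function(m) {
  k <- ncol(m)
  if (k == 1L) return(m)
  m %*% upper.tri(diag(k), diag = TRUE)
}

.hier_loglik <- function(z, aL, aR, d, c_rel, cnt) {
  meta_d <- exp(z) * d
  meta_c <- c_rel * meta_d
  tL <- meta_c - .row_cumsum(exp(aL))
  tR <- meta_c + .row_cumsum(exp(aR))
  .t2_loglik(meta_d, meta_c, tL, tR, cnt)
}

.stack_counts <- function(counts_list, padding) {
  K <- counts_list[[1]]$K
  n <- length(counts_list)
  get <- function(s, r) t(vapply(counts_list,
                                 function(x) x$counts[s, r, ] + padding,
                                 numeric(K)))
  list(LL = get("left", "left"), LR = get("left", "right"),
       RL = get("right", "left"), RR = get("right", "right"))
}

.fit_hier <- function(counts_list, covariates = NULL, mcmc = mcmc_params(),
                      padding = NULL, prior = list()) {
  stopifnot(length(counts_list) >= 2L)
  for (x in counts_list) validate_rating_counts(x)
  K <- counts_list[[1]]$K
  if (!all(vapply(counts_list, function(x) x$K, integer(1)) == K))
    stop("all subjects must share the confidence scale K")
  if (is.null(padding)) padding <- 1 / (2 * K)
  n <- length(counts_list)

  t1 <- lapply(counts_list, type1_fit, padding = padding)
  d <- vapply(t1, `[[`, numeric(1), "d_prime")
  c_rel <- vapply(t1, `[[`, numeric(1), "c_rel")
  if (any(d <= 0)) stop("all subjects must have d' > 0 for the hierarchical model; offending subject(s): ",
                        paste(which(d <= 0), collapse = ", "))
  cnt <- .stack_counts(counts_list, padding)

  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariate rows must match number of subjects")
    if (anyNA(covariates)) stop("missing values in covariates")
    sds <- apply(covariates, 2, stats::sd)
    if (any(sds == 0)) stop("zero-variance covariate column(s): ",
                            paste(which(sds == 0), collapse = ", "))
    X <- cbind(X, covariates)
    if (qr(X)$rank < ncol(X)) stop("rank-deficient covariate matrix")
  }
  p <- ncol(X)
  prior <- utils::modifyList(list(mu_sd = 1, beta_sd = 1, sigma_sd = 1,
                                  inc_mean = 0, inc_sd = 2), prior)
  prior_theta_sd <- c(prior$mu_sd, rep(prior$beta_sd, p - 1L))
  XtX <- crossprod(X)

  nkeep <- mcmc$nsamples
  total <- mcmc$nburnin + nkeep * mcmc$nthin
  chains <- vector("list", mcmc$nchains)

  for (ch in seq_len(mcmc$nchains)) {
    set.seed(mcmc$seed + ch - 1L)
    z <- stats::rnorm(n, 0, 0.1)
    aL <- matrix(log(0.4), n, K - 1L)
    aR <- matrix(log(0.4), n, K - 1L)
    theta <- rep(0, p)
    sigma <- 0.5
    ll <- .hier_loglik(z, aL, aR, d, c_rel, cnt)

    step_z <- rep(0.3, n); step_aL <- rep(0.25, n); step_aR <- rep(0.25, n)
    step_sig <- 0.3
    acc_z <- acc_aL <- acc_aR <- rep(0, n); acc_sig <- 0

    keep_theta <- matrix(NA_real_, nkeep, p)
    keep_sigma <- numeric(nkeep)
    keep_z <- matrix(NA_real_, nkeep, n)

    for (it in seq_len(total)) {
      mu_s <- drop(X %*% theta)

      # subject log Mratio (vectorised independent accept/reject)
      zp <- z + stats::rnorm(n, 0, step_z)
      llp <- .hier_loglik(zp, aL, aR, d, c_rel, cnt)
      la <- llp - ll +
        stats::dnorm(zp, mu_s, sigma, log = TRUE) -
        stats::dnorm(z, mu_s, sigma, log = TRUE)
      ok <- log(stats::runif(n)) < la
      z[ok] <- zp[ok]; ll[ok] <- llp[ok]; acc_z <- acc_z + ok

      # left-side criteria increments (joint per subject)
      ap <- aL + matrix(stats::rnorm(n * (K - 1L), 0, rep(step_aL, K - 1L)), n)
      llp <- .hier_loglik(z, ap, aR, d, c_rel, cnt)
      la <- llp - ll + rowSums(stats::dnorm(ap, prior$inc_mean, prior$inc_sd, log = TRUE) -
                               stats::dnorm(aL, prior$inc_mean, prior$inc_sd, log = TRUE))
      ok <- log(stats::runif(n)) < la
      aL[ok, ] <- ap[ok, ]; ll[ok] <- llp[ok]; acc_aL <- acc_aL + ok

      # right-side criteria increments
      ap <- aR + matrix(stats::rnorm(n * (K - 1L), 0, rep(step_aR, K - 1L)), n)
      llp <- .hier_loglik(z, aL, ap, d, c_rel, cnt)
      la <- llp - ll + rowSums(stats::dnorm(ap, prior$inc_mean, prior$inc_sd, log = TRUE) -
                               stats::dnorm(aR, prior$inc_mean, prior$inc_sd, log = TRUE))
      ok <- log(stats::runif(n)) < la
      aR[ok, ] <- ap[ok, ]; ll[ok] <- llp[ok]; acc_aR <- acc_aR + ok

      # conjugate draw for (mu, beta) given z and sigma
      prec <- XtX / sigma^2 + diag(1 / prior_theta_sd^2, p)
      ch_u <- chol(prec)
      mean_theta <- backsolve(ch_u, forwardsolve(t(ch_u), crossprod(X, z) / sigma^2))
      theta <- drop(mean_theta + backsolve(ch_u, stats::rnorm(p)))

      # sigma: random walk on log scale, half-normal(sigma_sd) prior
      mu_s <- drop(X %*% theta)
      lsp <- log(sigma) + stats::rnorm(1, 0, step_sig)
      sp <- exp(lsp)
      la <- sum(stats::dnorm(z, mu_s, sp, log = TRUE)) -
        sum(stats::dnorm(z, mu_s, sigma, log = TRUE)) -
        (sp^2 - sigma^2) / (2 * prior$sigma_sd^2) + (lsp - log(sigma))
      if (log(stats::runif(1)) < la) { sigma <- sp; acc_sig <- acc_sig + 1 }

      if (it <= mcmc$nburnin && it %% 50L == 0L) {
        adj <- function(step, acc) pmin(pmax(step * exp(acc / 50 - 0.3), 1e-3), 5)
        step_z <- adj(step_z, acc_z); step_aL <- adj(step_aL, acc_aL)
        step_aR <- adj(step_aR, acc_aR); step_sig <- adj(step_sig, acc_sig)
        acc_z[] <- 0; acc_aL[] <- 0; acc_aR[] <- 0; acc_sig <- 0
      }
      if (it > mcmc$nburnin) {
        j <- it - mcmc$nburnin
        if (j %% mcmc$nthin == 0L) {
          j <- j %/% mcmc$nthin
          keep_theta[j, ] <- theta; keep_sigma[j] <- sigma; keep_z[j, ] <- z
        }
      }
    }
    chains[[ch]] <- list(theta = keep_theta, sigma = keep_sigma, z = keep_z)
  }

  theta_all <- do.call(rbind, lapply(chains, `[[`, "theta"))
  sigma_all <- unlist(lapply(chains, `[[`, "sigma"))
  z_all <- do.call(rbind, lapply(chains, `[[`, "z"))

  par_chains <- function(extract) lapply(chains, extract)
  diag_rows <- list(
    data.frame(parameter = "group_mu_logMratio",
               rhat = rhat(par_chains(function(c) c$theta[, 1L])),
               ess = ess(theta_all[, 1L])),
    data.frame(parameter = "group_sigma",
               rhat = rhat(par_chains(function(c) c$sigma)),
               ess = ess(sigma_all)))
  if (p > 1L) {
    for (k in 2:p) {
      diag_rows[[length(diag_rows) + 1L]] <- data.frame(
        parameter = paste0("beta_", colnames(X)[k]),
        rhat = rhat(par_chains(function(c) c$theta[, k])),
        ess = ess(theta_all[, k]))
    }
  }
  diagnostics <- do.call(rbind, diag_rows)
  if (any(diagnostics$rhat > 1.1, na.rm = TRUE))
    warning("R-hat > 1.1 for: ",
            paste(diagnostics$parameter[diagnostics$rhat > 1.1], collapse = ", "),
            "; consider longer chains")

  structure(list(
    group_mu_logMratio = theta_all[, 1L],
    group_sigma = sigma_all,
    betas = if (p > 1L) {
      b <- theta_all[, -1L, drop = FALSE]; colnames(b) <- colnames(X)[-1L]; b
    } else NULL,
    subject_logMratio = z_all,
    diagnostics = diagnostics,
    d_prime = d, n_subjects = n, mcmc = mcmc,
    subject_mle = NULL), class = "hier_fit")
}

#' Hierarchical group-level fit of metacognitive efficiency
#'
#' Fits the hierarchical meta-d' model to a list of subjects' rating counts:
#' subject-level log Mratio values are drawn from a group-level normal
#' distribution whose mean and spread are estimated jointly with the
#' subject-level type-2 criteria. Returns posterior samples for all group
#' parameters with R-hat and effective-sample-size diagnostics (an R-hat above
#' 1.1 raises a warning recorded in the diagnostics, never a silent pass).
#'
#' @param counts_list list of `rating_counts`, one per subject (>= 2), each
#'   with d' > 0.
#' @param mcmc sampler settings from [mcmc_params()].
#' @param padding per-cell pseudo-count (default 1/(2K)).
#' @param prior optional list overriding `mu_sd`, `beta_sd`, `sigma_sd`,
#'   `inc_mean`, `inc_sd`.
#' @return object of class `hier_fit` with posterior sample vectors
#'   `group_mu_logMratio`, `group_sigma`, matrix `subject_logMratio`
#'   (draws x subjects), and a `diagnostics` data frame.
#' @export
fit_metad_group <- function(counts_list, mcmc = mcmc_params(), padding = NULL,
                            prior = list()) {
  .fit_hier(counts_list, covariates = NULL, mcmc = mcmc, padding = padding,
            prior = prior)
}

#' Hierarchical regression of covariates on metacognitive efficiency
#'
#' Embeds a linear model in the hierarchical meta-d' fit: subject-level
#' log Mratio means are `mu + X beta`, so each regression coefficient
#' expresses the change in log metacognitive efficiency per unit of the
#' (standardized) covariate. Significance of each coefficient is judged by
#' whether its 95% highest-density interval excludes zero.
#'
#' @param counts_list list of `rating_counts`, one per subject.
#' @param covariates n x p numeric matrix, standardized, no missing values.
#' @param mcmc,padding,prior see [fit_metad_group()].
#' @return `hier_fit` with a `betas` posterior sample matrix.
#' @export
fit_metad_regression <- function(counts_list, covariates, mcmc = mcmc_params(),
                                 padding = NULL, prior = list()) {
  if (is.null(covariates)) stop("covariates required; use fit_metad_group() otherwise")
  .fit_hier(counts_list, covariates = covariates, mcmc = mcmc,
            padding = padding, prior = prior)
}

#' @export
print.hier_fit <- function(x, ...) {
  mu <- x$group_mu_logMratio
  cat(sprintf("Hierarchical Mratio fit: %d subjects, %d posterior draws\n",
              x$n_subjects, length(mu)))
  cat(sprintf("  group Mratio (posterior mean of exp(mu)): %.3f\n", mean(exp(mu))))
  h <- hdi(mu)
  cat(sprintf("  group mu (log Mratio): %.3f, 95%% HDI [%.3f, %.3f]\n",
              mean(mu), h$lower, h$upper))
  if (!is.null(x$betas)) {
    for (k in colnames(x$betas)) {
      h <- hdi(x$betas[, k])
      cat(sprintf("  beta[%s] = %.3f, 95%% HDI [%.3f, %.3f]%s\n", k,
                  mean(x$betas[, k]), h$lower, h$upper,
                  if (h$lower > 0 || h$upper < 0) " *" else ""))
    }
  }
  cat("  max R-hat:", sprintf("%.3f", max(x$diagnostics$rhat, na.rm = TRUE)), "\n")
  invisible(x)
}

#' Median split into high and low scoring groups
#'
#' Splits a symptom-dimension score vector at its median; subjects exactly at
#' the median are assigned to the low group.
#'
#' @param scores numeric vector.
#' @return factor with levels "low", "high".
#' @export
median_split <- function(scores) {
  med <- stats::median(scores)
  factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
}

#' Posterior group difference in metacognitive efficiency
#'
#' Pairs posterior draws of the group-level mean log Mratio from two fits
#' (high minus low), and judges the difference significant when the
#' highest-density interval of the paired difference excludes zero.
#'
#' @param fit_high,fit_low `hier_fit` objects sampled with identical settings.
#' @param mass posterior mass of the HDI (default 0.95).
#' @return list with `hdi` (an `hdi_interval`), `significant` (logical),
#'   `mean_diff` and the difference `samples`.
#' @export
compare_groups <- function(fit_high, fit_low, mass = 0.95) {
  a <- fit_high$group_mu_logMratio
  b <- fit_low$group_mu_logMratio
  if (length(a) != length(b)) stop("mismatched posterior sample counts")
  diff <- a - b
  h <- hdi(diff, mass)
  list(hdi = h, significant = (h$lower > 0 || h$upper < 0),
       mean_diff = mean(diff), samples = diff)
}

#' Highest-density interval
#'
#' Narrowest contiguous interval containing `ceiling(mass * n)` of the sorted
#' samples; ties between equally narrow windows are broken leftmost.
#'
#' @param samples numeric vector of at least 100 posterior draws.
#' @param mass probability mass in (0, 1) (default 0.95).
#' @return object of class `hdi_interval`: list with `lower`, `upper`, `mass`.
#' @export
hdi <- function(samples, mass = 0.95) {
  stopifnot(mass > 0, mass < 1)
  n <- length(samples)
  if (n < 100L) stop("at least 100 samples required for an HDI")
  s <- sort(samples)
  m <- ceiling(mass * n)
  if (m >= n) return(structure(list(lower = s[1L], upper = s[n], mass = mass),
                               class = "hdi_interval"))
  widths <- s[m:n] - s[1:(n - m + 1L)]
  i <- which.min(widths)  # which.min returns the leftmost minimum
  structure(list(lower = s[i], upper = s[i + m - 1L], mass = mass),
            class = "hdi_interval")
}

#' @export
print.hdi_interval <- function(x, ...) {
  cat(sprintf("%.0f%% HDI: [%.4f, %.4f]\n", 100 * x$mass, x$lower, x$upper))
  invisible(x)
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' @param chains list of numeric vectors (one per chain) or a single vector.
#' @return scalar R-hat; `NA` if fewer than 4 split-half draws are available.
#' @export
rhat <- function(chains) {
  if (!is.list(chains)) chains <- list(chains)
  # split each chain in half
  halves <- unlist(lapply(chains, function(x) {
    h <- length(x) %/% 2L
    if (h < 2L) return(list(x))
    list(x[1:h], x[(h + 1L):(2L * h)])
  }), recursive = FALSE)
  m <- length(halves)
  n <- min(lengths(halves))
  if (m < 2L || n < 2L) return(NA_real_)
  halves <- lapply(halves, function(x) x[1:n])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size (initial positive sequence estimator)
#'
#' @param x numeric vector of (pooled) posterior draws.
#' @return estimated number of independent draws.
#' @export
ess <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1L, 500L), plot = FALSE)$acf[-1L]
  s <- 0
  k <- 1L
  while (k <= length(ac) - 1L) {
    pair <- ac[k] + ac[k + 1L]
    if (pair < 0) break
    s <- s + pair
    k <- k + 2L
  }
  min(n, n / (1 + 2 * s))
}
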