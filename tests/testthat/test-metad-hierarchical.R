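test_that("HDI follows the leftmost-narrowest-window rule", {
  expect_equal(unclass(hdi(1:100, 0.95))[c("lower", "upper")],
               list(lower = 1, upper = 95))
  set.seed(1)
  h <- hdi(rnorm(200000), 0.95)
  expect_equal(h$lower, -1.96, tolerance = 0.02)
  expect_equal(h$upper, 1.96, tolerance = 0.02)
  hp <- hdi(rep(2.5, 150), 0.5)
  expect_equal(c(hp$lower, hp$upper), c(2.5, 2.5))
  expect_error(hdi(rnorm(50)), "at least 100")
  # width non-decreasing in mass
  set.seed(2)
  x <- rgamma(5000, 2)
  widths <- sapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(m) {
    h <- hdi(x, m); h$upper - h$lower
  })
  expect_true(all(diff(widths) > 0))
})

test_that("convergence diagnostics behave sensibly", {
  set.seed(3)
  same <- lapply(1:3, function(i) rnorm(1000))
  expect_lt(abs(rhat(same) - 1), 0.02)
  shifted <- list(rnorm(1000), rnorm(1000) + 3)
  expect_gt(rhat(shifted), 1.5)
  expect_equal(ess(rnorm(1000)), 1000, tolerance = 0.35)
  ar <- as.numeric(arima.sim(list(ar = 0.9), 2000))
  expect_lt(ess(ar), 600)
})

test_that("group fit recovers a shared generative Mratio", {
  cl <- lapply(1:12, function(i)
    simulate_metad_counts(400, d_prime = 1.5, c_rel = 0.05, meta_d = 0.8 * 1.5,
                          seed = 100 + i))
  hf <- fit_metad_group(cl, mcmc = mcmc_params(nchains = 2, nburnin = 400,
                                               nsamples = 800, seed = 7))
  expect_lt(abs(mean(exp(hf$group_mu_logMratio)) - 0.8), 0.15)
  expect_true(all(c("group_mu_logMratio", "group_sigma") %in%
                  hf$diagnostics$parameter))
  expect_true(all(hf$group_sigma > 0))
})

test_that("duplicated subjects concentrate the group spread near zero", {
  one <- simulate_metad_counts(600, 1.5, 0.05, 1.2, seed = 11)
  cl <- rep(list(one), 10)
  hf <- suppressWarnings(
    fit_metad_group(cl, mcmc = mcmc_params(nchains = 1, nburnin = 400,
                                           nsamples = 800, seed = 13)))
  expect_lt(median(hf$group_sigma), 0.3)
})

test_that("group comparison is paired, signed and null for self-comparison", {
  cl <- lapply(1:8, function(i) simulate_metad_counts(300, 1.4, 0, 1.1,
                                                      seed = 40 + i))
  hf <- suppressWarnings(
    fit_metad_group(cl, mcmc = mcmc_params(nchains = 1, nburnin = 300,
                                           nsamples = 600, seed = 3)))
  self <- compare_groups(hf, hf)
  expect_false(self$significant)
  expect_equal(self$mean_diff, 0)

  cl2 <- lapply(1:8, function(i) simulate_metad_counts(300, 1.4, 0, 1.1,
                                                       seed = 140 + i))
  hf2 <- suppressWarnings(
    fit_metad_group(cl2, mcmc = mcmc_params(nchains = 1, nburnin = 300,
                                            nsamples = 600, seed = 4)))
  ab <- compare_groups(hf, hf2); ba <- compare_groups(hf2, hf)
  expect_equal(ab$hdi$lower, -ba$hdi$upper, tolerance = 1e-12)
  expect_equal(ab$hdi$upper, -ba$hdi$lower, tolerance = 1e-12)
})

test_that("median splits send exact-median subjects to the low group", {
  s <- c(1, 2, 3, 4, 5)
  g <- median_split(s)
  expect_equal(as.character(g), c("low", "low", "low", "high", "high"))
  expect_equal(levels(g), c("low", "high"))
  expect_true(all(median_split(rep(2, 4)) == "low"))
})

test_that("hierarchical regression validates its design matrix", {
  cl <- lapply(1:6, function(i) simulate_metad_counts(200, 1.4, 0, 1.1,
                                                      seed = 70 + i))
  zeros <- cbind(x = rnorm(6), z = rep(0, 6))
  expect_error(fit_metad_regression(cl, zeros,
                                    mcmc = mcmc_params(nchains = 1, nburnin = 50,
                                                       nsamples = 100)),
               "zero-variance")
  dup <- cbind(x = scale(rnorm(6))[, 1])
  dup <- cbind(dup, dup)
  expect_error(fit_metad_regression(cl, dup,
                                    mcmc = mcmc_params(nchains = 1, nburnin = 50,
                                                       nsamples = 100)),
               "rank-deficient")
})

test_that("hierarchical subject estimates shrink toward the group mean", {
  set.seed(21)
  true_mr <- exp(rnorm(15, log(0.8), 0.3))
  cl <- lapply(seq_along(true_mr), function(i)
    simulate_metad_counts(150, 1.5, 0.05, true_mr[i] * 1.5, seed = 300 + i))
  hf <- fit_metad_group(cl, mcmc = mcmc_params(nchains = 1, nburnin = 400,
                                               nsamples = 800, seed = 5))
  post <- colMeans(hf$subject_logMratio)
  mle <- sapply(cl, function(c) log(max(fit_metad(c)$m_ratio, 1e-3)))
  expect_lt(mean(abs(post - mean(post))), mean(abs(mle - mean(mle))))
})
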