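test_that("type-2 probability tables follow the truncated-normal construction", {
  # zero sensitivity: ratings carry no stimulus information
  p0 <- predict_type2_probs(0, 0, c(-0.5, -1), c(0.5, 1), K = 3)
  expect_equal(p0["left", "right", ], p0["right", "right", ], tolerance = 1e-12)
  expect_equal(p0["left", "left", ], p0["right", "left", ], tolerance = 1e-12)

  # K = 2 closed form: P(conf 2 | S2, right) = (1 - Phi(1-1)) / (1 - Phi(0-1))
  p <- predict_type2_probs(2, 0, -1, 1, K = 2)
  expect_equal(p["right", "right", "2"], 0.5 / pnorm(1), tolerance = 1e-10)
  expect_equal(p["right", "right", "2"], 0.5943, tolerance = 1e-4)

  # distant criteria: all mass on confidence 1
  pfar <- predict_type2_probs(1.5, 0, c(-20, -21), c(20, 21), K = 3)
  expect_equal(unname(pfar[, , "1"]), matrix(1, 2, 2), tolerance = 1e-9)

  # conditional distributions sum to one for every (stimulus, response)
  pr <- predict_type2_probs(1.2, 0.2, c(-0.1, -0.6, -1.4), c(0.5, 0.7, 2.1), K = 4)
  expect_equal(unname(apply(pr, c(1, 2), sum)), matrix(1, 2, 2), tolerance = 1e-9)

  expect_error(predict_type2_probs(-0.5, 0, -1, 1, K = 2), "non-negative")
  expect_error(predict_type2_probs(1, 0, c(-1, -2), c(1, 0.5), K = 3),
               "non-decreasing")
  expect_error(predict_type2_probs(1, 0, c(-1, -0.5), c(0.5, 1), K = 3),
               "non-increasing")
})

test_that("meta-d' MLE recovers generative parameters from model counts", {
  cnt <- simulate_metad_counts(50000, d_prime = 1.5, c_rel = 0.1, meta_d = 1.2,
                               seed = 2)
  f <- fit_metad(cnt)
  expect_lt(abs(f$meta_d - 1.2), 0.05)
  expect_equal(f$m_ratio, f$meta_d / f$type1$d_prime, tolerance = 1e-12)

  # ideal observer (confidence cut from the decision evidence): Mratio ~ 1
  des <- generate_design("perception", conditions = c(-32L, 32L),
                         trials_per_condition = 25000, blocks = 1L)
  tt <- simulate_observer(des, observer_params(sensitivity_scale = 1.5 / 32),
                          seed = 5)
  fi <- fit_metad(counts_from_trials(tt))
  expect_lt(abs(fi$m_ratio - 1), 0.05)
})

test_that("MLE matches an independent grid-search oracle on small tables", {
  for (s in 1:4) {
    cnt <- simulate_metad_counts(40, d_prime = 1.2, c_rel = 0.05 * s,
                                 meta_d = 0.9, t2c_offsets = 0.8, seed = 30 + s)
    f <- fit_metad(cnt)
    oracle <- grid_oracle_loglik(cnt)
    expect_lt(abs(f$loglik - oracle), 1e-3)
  }
})

test_that("fitted meta-d' is invariant to count scaling (unpadded)", {
  set.seed(9)
  arr <- array(rpois(16, 15) + 2L, dim = c(2, 2, 4))
  f1 <- fit_metad(make_counts(arr), padding = 0)
  f3 <- fit_metad(make_counts(arr * 3L), padding = 0)
  expect_equal(f1$meta_d, f3$meta_d, tolerance = 1e-4)
})

test_that("single-rating-level tables are flagged degenerate", {
  arr <- array(0L, dim = c(2, 2, 4))
  arr[, , 2] <- matrix(c(30L, 10L, 8L, 32L), 2, 2)
  f <- fit_metad(make_counts(arr))
  expect_true(f$degenerate)
})

test_that("confidence criterion averages per-side criterion distances", {
  fit <- structure(list(meta_c = 0.2,
                        t2c_right = 0.2 + c(0.2, 0.4, 0.6, 0.8, 1.0),
                        t2c_left = 0.2 - c(0.2, 0.4, 0.6, 0.8, 1.0),
                        type1 = list(c = 0.3)), class = "metad_fit")
  expect_equal(confidence_criterion(fit), 0.6)
  fit$t2c_right <- rep(0.2, 5); fit$t2c_left <- rep(0.2, 5)
  expect_equal(confidence_criterion(fit), 0)
  # alternative reference axis
  expect_equal(confidence_criterion(fit, reference = "c"), 0.1)
})

test_that("confidence criterion is inversely related to mean confidence", {
  des <- generate_design("perception", conditions = c(-32L, 32L),
                         trials_per_condition = 1000, blocks = 1L)
  shifts <- seq(-0.15, 0.9, length.out = 40)
  res <- t(sapply(seq_along(shifts), function(i) {
    tt <- simulate_observer(des, observer_params(sensitivity_scale = 1.5 / 32,
                                                 confidence_shift = shifts[i]),
                            seed = 500 + i)
    f <- fit_metad(counts_from_trials(tt))
    c(cc = f$confidence_criterion, mean_conf = mean(tt$confidence))
  }))
  expect_lt(cor(res[, "cc"], res[, "mean_conf"]), -0.8)
})

test_that("efficiency is log(Mratio) and refuses non-positive ratios", {
  f <- fit_metad(simulate_metad_counts(2000, 1.5, 0, 1.5, seed = 3))
  expect_equal(efficiency(f), log(f$m_ratio))
  f$m_ratio <- -0.2
  expect_error(efficiency(f), "exclusion rule")
  f$m_ratio <- 1
  expect_equal(efficiency(f), 0)
  f$m_ratio <- 0.5
  expect_equal(efficiency(f), log(0.5), tolerance = 1e-12)
})

test_that("MCMC and MLE point estimates agree on moderate data", {
  diffs <- sapply(1:6, function(s) {
    cnt <- simulate_metad_counts(1000, 1.5, 0.05, 1.2, seed = 600 + s)
    fm <- fit_metad(cnt, method = "mcmc",
                    mcmc = mcmc_params(nchains = 2, nburnin = 300,
                                       nsamples = 600, seed = 700 + s))
    abs(fm$meta_d - fit_metad(cnt)$meta_d)
  })
  expect_lt(mean(diffs), 0.1)
})

test_that("more metacognitive noise means lower fitted Mratio", {
  des <- generate_design("perception", conditions = c(-32L, 32L),
                         trials_per_condition = 2000, blocks = 1L)
  mr <- sapply(c(0, 0.5, 1, 2), function(noise) {
    mean(sapply(1:3, function(s) {
      tt <- simulate_observer(des, observer_params(sensitivity_scale = 1.5 / 32,
                                                   meta_noise_sd = noise),
                              seed = 40 + s)
      fit_metad(counts_from_trials(tt))$m_ratio
    }))
  })
  expect_true(all(diff(mr) < 0))
})
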