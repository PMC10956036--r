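test_that("default designs match the experiment-2 trial structure", {
  d <- generate_design("perception")
  expect_equal(d$n_trials, 136)
  expect_equal(length(d$conditions), 17)
  expect_equal(sort(unique(d$trials$block)), 1:2)
  # counterbalancing: reference side split evenly within every condition
  tab <- table(d$trials$condition, d$trials$reference_side)
  expect_true(all(tab == 4))

  k <- generate_design("knowledge")
  expect_equal(k$n_trials, 144)
  expect_equal(length(k$conditions), 16)
  expect_equal(k$bin_edges, seq(0, 1.8, by = 0.225))
  expect_true(all(table(k$trials$condition) == 9))

  expect_error(generate_design("perception", trials_per_condition = 7),
               "counterbalanced")
  expect_error(generate_design("perception", trials_per_condition = 6,
                               blocks = 5), "not divisible")
})

test_that("designs and simulations are deterministic given the seed", {
  expect_identical(generate_design("perception", seed = 9),
                   generate_design("perception", seed = 9))
  d <- generate_design("knowledge", seed = 2)
  expect_identical(simulate_observer(d, seed = 3), simulate_observer(d, seed = 3))
  sp <- cohort_spec(n = 8, seed = 5)
  expect_identical(simulate_cohort(sp), simulate_cohort(sp))
})

test_that("stimulus specs carry the 272-dot reference", {
  d <- generate_design("perception", seed = 1)
  row <- d$trials[d$trials$condition == 64, ][1, ]
  s <- generate_stimulus_spec(d, row$trial)
  expect_equal(s$reference_count, 272)
  expect_equal(s$comparison_count, 336)
  expect_true(s$comparison_side != s$reference_side)
  z <- generate_stimulus_spec(d, d$trials$trial[d$trials$condition == 0][1])
  expect_equal(z$comparison_count, 272)
  # reference constant across arbitrary trials
  expect_true(all(sapply(c(1, 50, 136), function(t)
    generate_stimulus_spec(d, t)$reference_count) == 272))
})

test_that("a zero-sensitivity observer performs at chance", {
  d <- generate_design("perception", trials_per_condition = 100, blocks = 1)
  tt <- simulate_observer(d, observer_params(sensitivity_scale = 0), seed = 8)
  expect_lt(abs(trial_accuracy(tt) - 0.5), 0.04)
})

test_that("cohorts carry 209 scored psychiatric items plus Big-5 items", {
  co <- simulate_cohort(cohort_spec(n = 10, tasks = "perception", seed = 3))
  per_p <- co$items[co$items$participant_id == "p0001", ]
  psych <- per_p[per_p$instrument != "bfi" & per_p$item_id != "zung_catch", ]
  base <- unique(sub("_(fear|avoid)$", "", psych$item_id))
  expect_equal(length(base), 209)
  expect_equal(sum(per_p$instrument == "bfi"), 44)
  expect_equal(sum(per_p$item_id == "zung_catch"), 1)
  # responses respect instrument ranges
  cfg <- instrument_config()
  for (i in seq_len(nrow(cfg))) {
    r <- per_p$response[per_p$instrument == cfg$instrument[i]]
    expect_true(all(r >= cfg$min[i] & r <= cfg$max[i]))
  }
})

test_that("factor scores recovered from items track the planted factors", {
  co <- simulate_cohort(cohort_spec(n = 400, tasks = "perception", seed = 6))
  m <- cohort_item_matrix(co$items, co$spec$weights)
  fs <- score_factors(m, co$spec$weights)
  for (f in c("AD", "CIT")) expect_gt(cor(co$truth[[f]], fs[, f]), 0.9)
  expect_gt(cor(co$truth$SW, fs[, "SW"]), 0.8)  # 24-item dimension is noisier
})

test_that("the ground-truth table records every planted quantity", {
  sp <- cohort_spec(n = 12, seed = 4,
                    violators = list(under_18 = 1, chance_performer = 2))
  co <- simulate_cohort(sp)
  need <- c("AD", "CIT", "SW", "mratio_target", "criterion",
            "sensitivity_perception", "conf_width_perception",
            "latent_cc_perception", "under_18", "chance_performer")
  expect_true(all(need %in% names(co$truth)))
  expect_equal(sum(co$truth$under_18), 1)
  expect_equal(sum(co$truth$chance_performer), 2)
  expect_true(all(co$demographics$age[co$truth$under_18] < 18))
  # chance performers actually perform near chance
  acc <- sapply(co$truth$participant_id[co$truth$chance_performer], function(p)
    trial_accuracy(co$trials[co$trials$participant_id == p, ]))
  expect_true(all(acc < 0.55))
})

test_that("planted knowledge non-responders exceed the time-out threshold", {
  co <- simulate_cohort(cohort_spec(n = 10, seed = 9,
                                    violators = list(knowledge_nonresponse = 2)))
  nr <- tapply(!co$trials$responded[co$trials$task == "knowledge"],
               co$trials$participant_id[co$trials$task == "knowledge"], sum)
  planted <- co$truth$participant_id[co$truth$knowledge_nonresponse]
  expect_true(all(nr[planted] > 4))
  expect_true(all(nr[setdiff(names(nr), planted)] == 0))
})
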