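# rule engine tests use precomputed measures so no model fitting is involved

clean_measures <- function(ids, tasks = c("perception", "knowledge")) {
  expand <- expand.grid(participant_id = ids, task = tasks,
                        stringsAsFactors = FALSE)
  data.frame(expand, accuracy = 0.75, constant_confidence = FALSE,
             n_nonresponse = 0L, m_ratio = 0.8, stringsAsFactors = FALSE)
}

make_cohort <- function(n, age = rep(25, n), gender = rep("female", n),
                        catch = rep(3L, n)) {
  ids <- sprintf("p%02d", seq_len(n))
  structure(list(
    trials = data.frame(),  # unused when measures are supplied
    items = data.frame(participant_id = ids, instrument = "zung",
                       item_id = "zung_catch", response = catch,
                       stringsAsFactors = FALSE),
    demographics = data.frame(participant_id = ids, age = age, gender = gender,
                              stringsAsFactors = FALSE)), class = "cohort")
}

test_that("a clean cohort passes every rule", {
  co <- make_cohort(8)
  m <- clean_measures(co$demographics$participant_id)
  for (exp_id in c("exp1", "exp2")) {
    res <- apply_exclusions(co, exp_id, measures = m)
    expect_equal(res$report$n_excluded, 0)
    expect_equal(res$report$n_retained, 8)
    expect_true(all(res$report$per_rule == 0))
  }
})

test_that("planted violators produce exactly the planted per-rule counts", {
  co <- make_cohort(12)
  co$demographics$age[1:2] <- 17                       # 2 under-18
  m <- clean_measures(co$demographics$participant_id)
  m$accuracy[m$participant_id %in% c("p03", "p04", "p05") &
             m$task == "perception"] <- 0.50           # 3 chance performers
  m$constant_confidence[m$participant_id == "p06" &
                        m$task == "perception"] <- TRUE # 1 constant rater
  res <- apply_exclusions(co, "exp1", measures = m)
  expect_equal(res$report$n_excluded, 6)
  expect_equal(unname(res$report$per_rule["under_18"]), 2L)
  expect_equal(unname(res$report$per_rule["accuracy_perception"]), 3L)
  expect_equal(unname(res$report$per_rule["constant_confidence_perception"]), 1L)
  expect_equal(res$report$n_retained, 6)
  expect_false(any(c("p01", "p06") %in% res$retained$demographics$participant_id))
})

test_that("multi-rule violators are excluded once but counted per rule", {
  co <- make_cohort(5)
  co$demographics$age[1] <- 16
  m <- clean_measures(co$demographics$participant_id)
  m$accuracy[m$participant_id == "p01" & m$task == "perception"] <- 0.4
  res <- apply_exclusions(co, "exp1", measures = m)
  expect_equal(res$report$n_excluded, 1)
  expect_equal(unname(res$report$per_rule["under_18"]), 1L)
  expect_equal(unname(res$report$per_rule["accuracy_perception"]), 1L)
  expect_equal(sort(res$report$per_participant$p01),
               c("accuracy_perception", "under_18"))
})

test_that("thresholds are strict: 55% accuracy and 4 non-responses survive", {
  co <- make_cohort(4)
  m <- clean_measures(co$demographics$participant_id)
  m$accuracy[m$participant_id == "p01"] <- 0.55       # boundary: retained
  m$accuracy[m$participant_id == "p02"] <- 0.5499     # below: excluded
  m$n_nonresponse[m$participant_id == "p03" & m$task == "knowledge"] <- 4L
  m$n_nonresponse[m$participant_id == "p04" & m$task == "knowledge"] <- 5L
  res <- apply_exclusions(co, "exp2", measures = m)
  expect_setequal(names(res$report$per_participant), c("p02", "p04"))
  # negative efficiency boundary: exactly zero is retained
  m2 <- clean_measures(co$demographics$participant_id)
  m2$m_ratio[m2$participant_id == "p01" & m2$task == "perception"] <- 0
  m2$m_ratio[m2$participant_id == "p02" & m2$task == "perception"] <- -0.01
  res2 <- apply_exclusions(co, "exp1", measures = m2)
  expect_setequal(names(res2$report$per_participant), "p02")
})

test_that("experiment 1 ignores knowledge-task violations", {
  co <- make_cohort(3)
  m <- clean_measures(co$demographics$participant_id)
  m$accuracy[m$task == "knowledge"] <- 0.4
  m$n_nonresponse[m$task == "knowledge"] <- 20L
  expect_equal(apply_exclusions(co, "exp1", measures = m)$report$n_excluded, 0)
  expect_equal(apply_exclusions(co, "exp2", measures = m)$report$n_excluded, 3)
})

test_that("exclusion is idempotent and order-independent on random cohorts", {
  set.seed(99)
  for (i in 1:100) {
    n <- sample(5:15, 1)
    co <- make_cohort(n,
                      age = sample(15:60, n, TRUE),
                      gender = ifelse(runif(n) < 0.1, NA, "male"),
                      catch = sample(c(3L, 3L, 3L, 2L), n, TRUE))
    m <- clean_measures(co$demographics$participant_id)
    m$accuracy <- round(runif(nrow(m), 0.45, 0.95), 2)
    m$m_ratio <- round(rnorm(nrow(m), 0.6, 0.4), 2)
    m$constant_confidence <- runif(nrow(m)) < 0.1
    m$n_nonresponse <- rpois(nrow(m), 2)
    res <- apply_exclusions(co, "exp2", measures = m)
    # idempotence: rerun on the retained cohort excludes no one
    kept <- res$retained$demographics$participant_id
    res2 <- apply_exclusions(res$retained, "exp2",
                             measures = m[m$participant_id %in% kept, ])
    expect_equal(res2$report$n_excluded, 0)
    # order-independence: permuting participants leaves the retained set fixed
    perm <- sample(n)
    cop <- co
    cop$demographics <- co$demographics[perm, ]
    cop$items <- co$items[perm, ]
    resp <- apply_exclusions(cop, "exp2", measures = m[sample(nrow(m)), ])
    expect_setequal(resp$retained$demographics$participant_id, kept)
  }
})

test_that("missing fits are reported by participant", {
  co <- make_cohort(3)
  m <- clean_measures(co$demographics$participant_id)
  m <- m[m$participant_id != "p02" | m$task != "perception", ]
  expect_error(apply_exclusions(co, "exp1", measures = m), "p02")
})

test_that("catch failures are detected end-to-end from items", {
  co <- make_cohort(4, catch = c(3L, 1L, 3L, 4L))
  m <- clean_measures(co$demographics$participant_id)
  res <- apply_exclusions(co, "exp1", measures = m)
  expect_equal(unname(res$report$per_rule["catch_fail"]), 2L)
  expect_setequal(names(res$report$per_participant), c("p02", "p04"))
})
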