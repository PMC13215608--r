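make_records <- function(...) {
  assessment_records(do.call(rbind, list(...)))
}
rec <- function(id, days, states, age = 70, sex = "male", death = NA,
                censor = 2000) {
  data.frame(patient_id = id, day = days, state = states, age = age,
             sex = sex, death_day = death, censor_day = censor)
}

test_that("exclusion rules remove and audit the right patients", {
  rs <- make_records(
    rec("a", c(0, 10, 20), c(0, 16, 16)),
    rec("b", c(0, 10), c(0, 0)),                      # too few visits
    rec("c", c(0, 10, 20), c(0, 0, 16), death = 5),   # death before last visit
    rec("d", c(0, 30, 60), c(52, 52, 52)),
    rec("e", c(0, 10, 20), c(0, 0, 0))
  )
  out <- apply_exclusions(rs)
  expect_setequal(unique(out$records$patient_id), c("a", "d", "e"))
  expect_identical(out$audit[["min_visits"]], 1L)
  expect_identical(out$audit[["death_order"]], 1L)
  expect_identical(sum(out$audit), 2L)

  expect_identical(apply_exclusions(rs[rs$patient_id %in% c("a", "d"), ])$audit,
                   c(invalid_age = 0L, death_order = 0L, min_visits = 0L))

  bad_age <- make_records(rec("z", c(0, 10, 20), c(0, 0, 0), age = 0))
  expect_identical(apply_exclusions(bad_age)$audit[["invalid_age"]], 1L)
  expect_identical(nrow(apply_exclusions(bad_age)$records), 0L)

  expect_error(apply_exclusions(rs[0, ]), "empty")
})

test_that("duplicate same-day assessments keep the last record", {
  rs <- make_records(rec("a", c(0, 10, 10, 20), c(0, 16, 20, 20)))
  expect_warning(out <- apply_exclusions(rs), "duplicate")
  expect_identical(out$records$state[out$records$day == 10], 20L)
})

test_that("spells are maximal runs with persistence between visits", {
  s <- build_spells(c(0, 30, 60), c(1, 1, 2))
  # final one-visit run gets the minimum duration of 1 day
  expect_equal(s$spells$state, c(1, 2))
  expect_equal(s$spells$begin, c(0, 60))
  expect_equal(s$spells$end, c(60, 61))

  s <- build_spells(c(0, 10, 20), c(1, 2, 1))
  expect_equal(nrow(s$spells), 3)
  st <- traj_stats(s)
  expect_equal(st[["n_states"]], 2)
  expect_equal(st[["recurrence"]], 1.5)

  s <- build_spells(c(0, 5, 9, 14), c(7, 7, 7, 7))
  expect_equal(nrow(s$spells), 1)
  expect_equal(traj_stats(s)[["recurrence"]], 1)
  expect_equal(s$spells$visits, 4)

  expect_error(build_spells(c(0, 10, 5), c(1, 2, 3)), "increasing")
})

test_that("recurrence degree is 1 exactly when no state is revisited", {
  set.seed(11)
  for (i in 1:25) {
    states <- sample.int(4, sample(3:8, 1), replace = TRUE)
    s <- make_traj(states)
    st <- traj_stats(s)
    revisited <- anyDuplicated(s$spells$state) > 0
    expect_identical(unname(st["recurrence"] > 1), revisited)
    expect_gte(st[["recurrence"]], 1)
  }
})

test_that("identical trajectories merge with preserved total weight", {
  t1 <- make_traj(c(1, 1, 2), id = "p1")
  t2 <- make_traj(c(1, 1, 2), id = "p2")
  t3 <- make_traj(c(1, 1, 2), id = "p3")
  t4 <- make_traj(c(2, 1, 2), id = "p4")
  pool <- merge_identical(list(t1, t2, t3, t4))
  expect_identical(pool_size(pool), 2L)
  expect_identical(sort(pool$weights), c(1L, 3L))
  expect_identical(sum(pool$weights), 4L)
  expect_setequal(pool$members[[1]], c("p1", "p2", "p3"))

  # same states, different durations: distinct patterns
  t5 <- make_traj(c(1, 1, 2), days = c(0, 40, 80), id = "p5")
  pool2 <- merge_identical(list(t1, t5))
  expect_identical(pool_size(pool2), 2L)

  all_distinct <- merge_identical(list(t1, t4, t5))
  expect_true(all(all_distinct$weights == 1L))
})

test_that("top-K restriction drops or recodes rare states, keeping ties", {
  # frequencies: state 1 x10, state 2 x5, state 3 x1
  seqs <- c(replicate(2, make_traj(c(1, 1, 1, 1, 1), id = "a"),
                      simplify = FALSE),
            list(make_traj(c(2, 2, 2, 2, 2), id = "b"),
                 make_traj(c(1, 1, 1, 2, 2), id = "c"),
                 make_traj(c(1, 1, 3, 2, 2), id = "d")))
  dropped <- restrict_states(seqs, K = 2, strategy = "drop")
  expect_false(any(unlist(lapply(dropped, `[[`, "states")) == 3))
  expect_length(dropped, 5)

  other <- restrict_states(seqs, K = 2, strategy = "other")
  expect_true(any(unlist(lapply(other, `[[`, "states")) == OTHER_STATE))

  # tie at rank K keeps all tied states
  tied <- list(make_traj(c(1, 1, 2, 3), id = "a"),
               make_traj(c(1, 2, 3, 1), id = "b"))
  expect_message(kept <- restrict_states(tied, K = 2, strategy = "drop"),
                 "tie")
  expect_setequal(unique(unlist(lapply(kept, `[[`, "states"))), c(1, 2, 3))

  expect_warning(restrict_states(seqs, K = 10), "unchanged")
})

test_that("dropping states re-applies the minimum-visit rule", {
  seqs <- list(make_traj(c(1, 1, 1, 1), id = "a"),
               make_traj(c(1, 1, 1, 1), id = "a2"),
               make_traj(c(2, 2, 1, 1), id = "b"),
               make_traj(c(2, 2, 2, 1), id = "c"))  # only 1 visit survives
  out <- restrict_states(seqs, K = 1, strategy = "drop", min_visits = 3)
  expect_setequal(vapply(out, `[[`, character(1), "patient_id"), c("a", "a2"))
})

test_that("pool weights stay consistent through restrict/merge combinations", {
  set.seed(7)
  seqs <- lapply(1:30, function(i) {
    make_traj(sample.int(5, sample(3:6, 1), replace = TRUE),
              id = sprintf("p%02d", i))
  })
  pool <- merge_identical(seqs)
  expect_identical(sum(pool$weights), 30L)
  pool2 <- restrict_states(pool, K = 3, strategy = "other")
  expect_identical(sum(pool2$weights), 30L)
})

test_that("state distribution conditions on sequences under observation", {
  t_a <- make_spell_traj(1, 100, id = "a")          # state 1 over [0,100]
  t_b <- make_spell_traj(2, 100, id = "b")
  t_short <- make_spell_traj(1, 10, id = "c")       # ends at day 10
  pool <- merge_identical(list(t_a, t_b))
  d <- state_distribution(pool, 50)
  expect_equal(d$proportion, c(0.5, 0.5))

  pool1 <- merge_identical(list(t_a, make_spell_traj(1, 100, id = "a2")))
  d1 <- state_distribution(pool1, 50)
  expect_equal(d1$proportion, 1.0)

  pool2 <- merge_identical(list(t_a, t_short))
  d2 <- state_distribution(pool2, 50)
  expect_equal(d2$n_covered, 1)   # the short sequence has left observation
  expect_equal(sum(d2$proportion), 1)
  expect_error(state_distribution(pool2, numeric(0)), "empty")
})

test_that("binary domain columns round-trip through the CSV schema", {
  sim <- simulate_cohort(sim_preset("tiny"), seed = 3)
  path <- tempfile(fileext = ".csv")
  write_assessments(sim$records, path)
  back <- read_assessments(path)
  expect_equal(back$state, sim$records$state)
  expect_equal(back$day, sim$records$day)
  expect_equal(back$death_day, sim$records$death_day)
})
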