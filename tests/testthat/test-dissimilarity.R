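test_that("substitution schemes give the documented costs", {
  states <- c(0L, 16L, 20L, 48L, 52L)   # O, B, GB, BW, GBW
  sev <- build_cost_model(states, scheme = "severity")
  expect_true(all(diag(sev$sub) == 0))
  expect_true(isSymmetric(sev$sub))
  expect_lte(max(sev$sub), 2)
  # distinct equal-severity states get the floor
  expect_equal(sev$sub["20", "48"], 0.1)
  expect_equal(sev$sub["0", "52"], 2 * 3 / 9)

  ham <- build_cost_model(states, scheme = "hamming")
  expect_equal(ham$sub["52", "20"], 2 * 1 / 9)   # GBW vs GB differ in W
  expect_equal(ham$sub["0", "52"], 2 * 3 / 9)
  expect_true(isSymmetric(ham$sub))

  expect_error(build_cost_model(states, indel = 0), "positive")
  expect_error(build_cost_model(c(0L, OTHER_STATE)), "OTHER")
})

test_that("single-spell distances follow the edit-operation formulas", {
  cost <- build_cost_model(c(0L, 16L, 52L), scheme = "severity")
  a <- make_spell_traj(16, 5)
  b <- make_spell_traj(16, 3)
  # same state, duration gap 2, phi identity, e = 0.5
  expect_equal(omspell_distance(a, b, cost), 1.0)
  expect_equal(omspell_distance(a, a, cost), 0)

  # different states, equal duration: min(substitution, two indels)
  x <- make_spell_traj(0, 4)
  y <- make_spell_traj(52, 4)
  sub <- cost$sub["0", "52"]
  two_indel <- 2 * (cost$indel + cost$expansion * 3)
  expect_equal(omspell_distance(x, y, cost), min(sub, two_indel))
})

test_that("the DP matches a memoized brute-force recursion on random pairs", {
  set.seed(101)
  states <- 1:4
  sub <- matrix(runif(16, 0.2, 2), 4, 4)
  sub <- (sub + t(sub)) / 2
  diag(sub) <- 0
  for (tf in c("identity", "sqrt")) {
    cost <- make_cost(states, sub, indel = 0.8, expansion = 0.4,
                      transform = tf)
    for (i in 1:100) {
      a <- random_spell_traj()
      b <- random_spell_traj()
      expect_equal(omspell_distance(a, b, cost), bf_omspell(a, b, cost),
                   tolerance = 1e-12)
    }
  }
})

test_that("with zero expansion and unit durations OMspell reduces to OM", {
  set.seed(202)
  states <- 1:4
  sub <- matrix(runif(16, 0.5, 2), 4, 4)
  sub <- (sub + t(sub)) / 2
  diag(sub) <- 0
  cost <- make_cost(states, sub, indel = 0.9, expansion = 0)
  for (i in 1:50) {
    sa <- random_spell_traj(max_spells = 5, max_dur = 1)
    sb <- random_spell_traj(max_spells = 5, max_dur = 1)
    expect_equal(omspell_distance(sa, sb, cost),
                 naive_om(sa$spells$state, sb$spells$state, sub, 0.9),
                 tolerance = 1e-12)
  }
})

test_that("flat substitution 2 with unit INDEL equals generalized edit distance", {
  # with S = 2 and indel = 1 the optimum is the classic edit distance with
  # substitution weight 2; utils::adist is the independent reference
  set.seed(303)
  sub <- matrix(2, 4, 4)
  diag(sub) <- 0
  cost <- make_cost(1:4, sub, indel = 1, expansion = 0)
  letters4 <- c("a", "b", "c", "d")
  for (i in 1:50) {
    sa <- random_spell_traj(max_spells = 5, max_dur = 1)
    sb <- random_spell_traj(max_spells = 5, max_dur = 1)
    ref <- utils::adist(paste(letters4[sa$spells$state], collapse = ""),
                        paste(letters4[sb$spells$state], collapse = ""),
                        costs = list(ins = 1, del = 1, sub = 2))
    expect_equal(omspell_distance(sa, sb, cost), as.numeric(ref))
  }
})

test_that("distance is a semimetric; triangle holds for hamming costs", {
  set.seed(404)
  states <- c(0L, 1L, 3L, 16L, 48L, 52L)
  cost <- build_cost_model(states, scheme = "hamming", indel = 1,
                           expansion = 0.5)
  trajs <- replicate(60, {
    idx <- sample(seq_along(states), sample(1:4, 1), replace = TRUE)
    # avoid adjacent repeats
    keep <- c(TRUE, diff(idx) != 0)
    make_spell_traj(states[idx[keep]], sample.int(6, sum(keep), replace = TRUE))
  }, simplify = FALSE)
  pool <- merge_identical(trajs)
  D <- distance_matrix(pool, cost)
  expect_true(all(D >= 0))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  n <- nrow(D)
  for (t in 1:1000) {
    ijk <- sample.int(n, 3)
    expect_lte(D[ijk[1], ijk[3]],
               D[ijk[1], ijk[2]] + D[ijk[2], ijk[3]] + 1e-9)
  }
})

test_that("merging adjacent same-state spells never changes the distance", {
  cost <- build_cost_model(c(0L, 16L, 52L), scheme = "severity")
  canonical <- make_spell_traj(c(16, 0, 16), c(5, 2, 3))
  split_up <- canonical
  split_up$spells <- data.frame(state = c(16, 16, 0, 16),
                                begin = c(0, 2, 5, 7), end = c(2, 5, 7, 10),
                                duration = c(2, 3, 2, 3),
                                visits = c(1, 1, 1, 1))
  other <- make_spell_traj(c(0, 52), c(4, 4))
  expect_equal(omspell_distance(split_up, other, cost),
               omspell_distance(canonical, other, cost))
  expect_equal(omspell_distance(split_up, canonical, cost), 0)
})

test_that("rectangular distance blocks agree with the square matrix", {
  set.seed(505)
  trajs <- replicate(15, random_spell_traj(id = paste0("p", runif(1))),
                     simplify = FALSE)
  pool <- merge_identical(trajs)
  cost <- build_cost_model(pool$alphabet, scheme = "hamming")
  D <- distance_matrix(pool, cost)
  cols <- c(2L, 5L, 9L)
  R <- distance_matrix(pool, cost, columns = cols)
  expect_equal(unname(R), unname(D[, cols]), ignore_attr = TRUE)
  expect_identical(dim(R), c(pool_size(pool), 3L))
  one <- merge_identical(trajs[1])
  expect_equal(unname(distance_matrix(one, cost)), matrix(0, 1, 1),
               ignore_attr = TRUE)
})

test_that("distances error on states missing from the cost model", {
  cost <- build_cost_model(c(0L, 16L))
  expect_error(omspell_distance(make_spell_traj(52, 3),
                                make_spell_traj(0, 3), cost), "absent")
})

test_that("distance matrices round-trip through CSV", {
  set.seed(606)
  trajs <- replicate(8, random_spell_traj(), simplify = FALSE)
  pool <- merge_identical(trajs)
  cost <- build_cost_model(pool$alphabet, scheme = "hamming")
  D <- distance_matrix(pool, cost)
  p <- tempfile(fileext = ".csv")
  write_distance_matrix(D, p)
  back <- read_distance_matrix(p)
  expect_equal(unname(back), unname(D), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(attr(back, "weights"), attr(D, "weights"))
})
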