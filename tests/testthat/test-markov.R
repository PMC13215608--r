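# random pool of assessment-level sequences over a small alphabet
random_markov_pool <- function(n = 25, n_states = 4, len = 3:8) {
  trajs <- lapply(seq_len(n), function(i) {
    make_traj(sample.int(n_states, sample(len, 1), replace = TRUE),
              id = sprintf("p%03d", i))
  })
  merge_identical(trajs)
}

test_that("sequence log-likelihood is the log product of transitions", {
  pool <- merge_identical(list(make_traj(c(1, 2, 1), id = "a"),
                               make_traj(c(2, 1, 2), id = "b")))
  model <- fit_markov_mixture(pool, k = 1, seed = 1, alpha = 0)
  P <- model$trans[[1]]
  states <- c(1, 2, 1)
  manual <- log(P["START", "1"]) + log(P["1", "2"]) + log(P["2", "1"])
  expect_equal(sequence_loglik(model, states, 1), manual)

  # deterministic chain: every transition probability 1 -> loglik 0
  det <- model
  det$trans[[1]][] <- 0
  det$trans[[1]]["START", "1"] <- 1
  det$trans[[1]]["1", "2"] <- 1
  det$trans[[1]]["2", "1"] <- 1
  expect_equal(sequence_loglik(det, c(1, 2, 1), 1), 0)

  # two transitions of probability 0.5 each
  half <- det
  half$trans[[1]]["1", ] <- 0.5
  half$trans[[1]]["2", ] <- 0.5
  expect_equal(sequence_loglik(half, c(1, 1, 2), 1), log(0.25))

  # hand-built 2-state chain, 3-step sequence
  hb <- det
  hb$trans[[1]]["START", ] <- c(0.6, 0.4)
  hb$trans[[1]]["1", ] <- c(0.7, 0.3)
  hb$trans[[1]]["2", ] <- c(0.2, 0.8)
  expect_equal(sequence_loglik(hb, c(2, 2, 1), 1),
               log(0.4) + log(0.8) + log(0.2))

  # zero-probability transition at alpha = 0 gives -Inf
  expect_identical(sequence_loglik(det, c(1, 1), 1), -Inf)
})

test_that("k = 1 recovers pooled smoothed empirical transition frequencies", {
  pool <- merge_identical(list(make_traj(c(1, 2, 2), id = "a"),
                               make_traj(c(1, 2, 2), id = "a2"),
                               make_traj(c(2, 2, 1), id = "b")))
  alpha <- 0.5
  model <- fit_markov_mixture(pool, k = 1, seed = 1, alpha = alpha)
  # weighted counts from row 1->2: "a" twice (weight 2); 2->2: a x2, b x1...
  counts <- matrix(0, 3, 2, dimnames = list(c("START", "1", "2"), c("1", "2")))
  for (i in seq_along(pool$seqs)) {
    st <- pool$seqs[[i]]$states
    w <- pool$weights[i]
    from <- c("START", as.character(st[-length(st)]))
    to <- as.character(st)
    for (j in seq_along(to)) counts[from[j], to[j]] <- counts[from[j], to[j]] + w
  }
  expected <- (counts + alpha) / rowSums(counts + alpha)
  expect_equal(model$trans[[1]], expected, tolerance = 1e-12)
})

test_that("transition matrices are row-stochastic after fitting", {
  set.seed(21)
  pool <- random_markov_pool(40)
  model <- fit_markov_mixture(pool, k = 3, seed = 5)
  for (P in model$trans) {
    expect_equal(unname(rowSums(P)), rep(1, nrow(P)), tolerance = 1e-12)
  }
  expect_length(model$assignment, pool_size(pool))
})

test_that("the hard-EM objective is non-decreasing across iterations", {
  set.seed(31)
  for (i in 1:10) {
    pool <- random_markov_pool(n = 30)
    model <- fit_markov_mixture(pool, k = 2, seed = i)
    if (model$reseeds == 0) {
      expect_true(all(diff(model$loglik_trace) >= -1e-8))
    }
  }
})

test_that("disjoint state alphabets are recovered perfectly from any seed", {
  set.seed(99)
  trajs <- c(
    lapply(1:15, function(i) make_traj(sample(1:2, 12, replace = TRUE),
                                       id = paste0("a", i))),
    lapply(1:15, function(i) make_traj(sample(3:4, 12, replace = TRUE),
                                       id = paste0("b", i)))
  )
  pool <- merge_identical(trajs)
  truth <- vapply(pool$seqs, function(s) as.integer(all(s$states <= 2)),
                  integer(1))
  for (seed in c(1, 7, 42)) {
    model <- fit_markov_mixture(pool, k = 2, seed = seed)
    expect_equal(adjusted_rand_index(model$assignment, truth, pool$weights), 1)
  }
})

test_that("assignment is the E-step and handles edge cases", {
  set.seed(51)
  pool <- random_markov_pool(30)
  model <- fit_markov_mixture(pool, k = 2, seed = 3)
  expect_identical(assign_components(model, pool), model$assignment)

  # unseen sequence over the known alphabet gets a finite score (alpha > 0)
  unseen <- merge_identical(list(make_traj(rep(c(4, 1), 4), id = "u")))
  expect_true(is.finite(sequence_loglik(model, unseen$seqs[[1]]$states, 1)))

  # a single-assessment sequence is scored by the START row alone
  single <- make_traj(2, days = 0, id = "s")
  expect_equal(sequence_loglik(model, single$states, 1),
               log(model$trans[[1]]["START", "2"]))
})

test_that("well-separated chains are recovered (median ARI over seeds)", {
  # 3 diagonal-dominant chains over a shared alphabet, 150 sequences
  set.seed(61)
  gen_chain <- function(stay, states) {
    function(len) {
      x <- integer(len)
      x[1] <- sample(states, 1)
      for (j in 2:len) {
        other <- setdiff(states, x[j - 1])
        x[j] <- if (runif(1) < stay) x[j - 1] else other[sample.int(length(other), 1)]
      }
      x
    }
  }
  chains <- list(gen_chain(0.9, 1:2), gen_chain(0.9, 3:4), gen_chain(0.9, 5:6))
  trajs <- unlist(lapply(1:3, function(g) {
    lapply(1:50, function(i) {
      make_traj(chains[[g]](sample(8:14, 1)), id = sprintf("g%d_%d", g, i))
    })
  }), recursive = FALSE)
  pool <- merge_identical(trajs)
  truth <- vapply(pool$seqs, function(s) (min(s$states) + 1) %/% 2, numeric(1))
  aris <- vapply(1:7, function(seed) {
    m <- fit_markov_mixture(pool, k = 3, seed = seed)
    adjusted_rand_index(m$assignment, truth, pool$weights)
  }, numeric(1))
  expect_gte(median(aris), 0.9)
})

test_that("fitted models round-trip through JSON", {
  set.seed(71)
  pool <- random_markov_pool(25)
  model <- fit_markov_mixture(pool, k = 2, seed = 4)
  p <- tempfile(fileext = ".json")
  write_markov_model(model, p)
  back <- read_markov_model(p)
  expect_equal(back$trans, model$trans, tolerance = 1e-12)
  expect_identical(back$assignment, model$assignment)
  expect_equal(back$loglik, model$loglik)
  expect_equal(sequence_loglik(back, pool$seqs[[1]]$states, 1),
               sequence_loglik(model, pool$seqs[[1]]$states, 1))
})
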