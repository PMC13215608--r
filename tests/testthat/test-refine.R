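# small pool with two clear shape groups for reassignment tests
two_group_pool <- function(n_per = 6, seed = 7) {
  set.seed(seed)
  trajs <- c(
    lapply(seq_len(n_per), function(i) {
      make_spell_traj(c(0, 16), c(100 + i, 50 + 2 * i), id = paste0("a", i))
    }),
    lapply(seq_len(n_per), function(i) {
      make_spell_traj(c(511, 510), c(100 + i, 50 + 2 * i), id = paste0("b", i))
    })
  )
  merge_identical(trajs)
}

test_that("global reassignment is argmin over pooled medoids", {
  pool <- two_group_pool()
  cost <- build_cost_model(pool$alphabet, transform = "sqrt",
                           expansion = 0.05)
  sol <- global_reassign(pool, c(1L, 7L), cost)
  D <- distance_matrix(pool, cost)
  for (i in seq_len(pool_size(pool))) {
    expect_equal(D[i, sol$medoids[sol$labels[i]]],
                 min(D[i, sol$medoids]), tolerance = 1e-12)
  }
  # a sequence identical to a medoid lands there with distance 0
  expect_identical(sol$labels[1], 1L)
  expect_identical(sol$labels[7], 2L)

  # duplicate medoid patterns are deduplicated with a warning
  dup_pool <- merge_identical(list(
    make_spell_traj(0, 10, id = "x1"), make_spell_traj(16, 10, id = "x2"),
    make_spell_traj(52, 10, id = "x3")))
  dup_cost <- build_cost_model(dup_pool$alphabet, transform = "sqrt",
                               expansion = 0.05)
  expect_warning(
    sol2 <- global_reassign(dup_pool, c(1L, 2L, 2L), dup_cost),
    "duplicate")
  expect_identical(sol2$k, 2L)
  expect_error(suppressWarnings(global_reassign(dup_pool, c(2L, 2L), dup_cost)),
               "two distinct")
})

test_that("ties in reassignment go to the lowest medoid index", {
  pool <- merge_identical(list(
    make_spell_traj(0, 10, id = "m1"), make_spell_traj(16, 10, id = "m2"),
    make_spell_traj(20, 10, id = "q")))
  cost <- build_cost_model(pool$alphabet, scheme = "hamming")
  # pattern q (GB) is equidistant from... verify and assert the tie rule
  D <- distance_matrix(pool, cost)
  sol <- global_reassign(pool, c(1L, 2L), cost)
  if (abs(D[3, 1] - D[3, 2]) < 1e-12) {
    expect_identical(sol$labels[3], 1L)
  } else {
    expect_identical(sol$labels[3], which.min(c(D[3, 1], D[3, 2])))
  }
})

test_that("a merge step removes the weakest cluster and keeps optimality", {
  set.seed(123)
  bm <- block_matrix(c(6, 6, 5), within = 0.05, between = 1, jitter = 0.03)
  w <- sample(1:3, 17, replace = TRUE)
  med <- cluster_medoids(bm$D, w, bm$labels)
  sol <- cluster_solution(bm$labels, med)
  # split block 3 artificially into two weak half-clusters
  labels4 <- bm$labels
  labels4[which(bm$labels == 3)[1:2]] <- 4L
  med4 <- cluster_medoids(bm$D, w, labels4)
  sol4 <- cluster_solution(labels4, med4)
  st <- merge_step(sol4, bm$D, w)
  expect_identical(st$solution$k, 3L)
  expect_setequal(sort(st$merged_pair), 3:4)   # the split halves remerge
  expect_equal(adjusted_rand_index(st$solution$labels, bm$labels), 1)
  # merged medoid minimizes weighted within-union load (exhaustive check)
  merged_cl <- st$solution$labels[which(labels4 %in% 3:4)[1]]
  u <- which(st$solution$labels == merged_cl)
  loads <- vapply(u, function(m) sum(w[u] * bm$D[m, u]), numeric(1))
  expect_equal(sum(w[u] * bm$D[st$solution$medoids[merged_cl], u]),
               min(loads))
  expect_error(merge_step(cluster_solution(rep(1:2, 8), c(1L, 2L)),
                          bm$D[1:16, 1:16], w[1:16]), "three")
})

test_that("merging runs to the floor with consistent traces", {
  # four homogeneous point clouds on a line, shattered into 8 half-clusters:
  # sibling halves merge first and the multi-metric rule lands on 4 blocks
  set.seed(124)
  x <- as.vector(vapply(0:3, function(b) 10 * b + runif(6, 0, 0.05),
                        numeric(6)))
  D <- as.matrix(dist(x))
  n <- 24
  blocks <- rep(1:4, each = 6)
  labels8 <- rep(1:8, each = 3)
  w <- sample(1:3, n, replace = TRUE)
  sol <- cluster_solution(labels8, cluster_medoids(D, w, labels8))
  trace <- run_merging(sol, D, w, down_to_k = 2)
  rep <- trace$report
  expect_identical(rep$k, seq(max(rep$k), 2L))
  # R2 non-increasing as k drops (up to tiny reassignment wiggle within a
  # homogeneous cloud)
  expect_true(all(diff(rep$R2sq) <= 1e-4))
  sel <- select_optimal_k(trace)
  expect_identical(sel$k, 4L)
  sol4 <- trace$solutions[["4"]]
  expect_equal(adjusted_rand_index(sol4$labels, blocks), 1)
})

test_that("composite selection prefers dominating k and breaks ties low", {
  mk <- function(k, ASWw, HGSD, HC, CHsq, R2sq) {
    data.frame(k = k, ASWw = ASWw, HGSD = HGSD, HC = HC, CH = CHsq,
               CHsq = CHsq, R2 = R2sq, R2sq = R2sq)
  }
  tr <- structure(list(report = rbind(
    mk(5, 0.2, 0.5, 0.30, 100, 0.5),
    mk(4, 0.9, 0.9, 0.05, 500, 0.9),   # dominates everywhere
    mk(3, 0.3, 0.4, 0.25, 200, 0.4),
    mk(2, 0.1, 0.2, 0.40, 150, 0.2))), class = "merge_trace")
  expect_identical(select_optimal_k(tr)$k, 4)

  tied <- structure(list(report = rbind(
    mk(4, 0.5, 0.5, 0.2, 100, 0.5),
    mk(3, 0.5, 0.5, 0.2, 100, 0.5))), class = "merge_trace")
  expect_identical(select_optimal_k(tied)$k, 3)

  expect_identical(select_optimal_k(tr, max_k = 3)$k, 3)
})
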