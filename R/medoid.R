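#' Weighted average-linkage hierarchical clustering
#'
#' Agglomerative clustering of a precomputed dissimilarity matrix under the
#' average-linkage criterion with frequency weights: a weight-`w` pattern
#' acts as `w` coincident points, so the inter-cluster distance is the
#' weighted mean of cross-pair distances and cluster mass is the summed
#' member weight. Implemented through the Lance-Williams recurrence of
#' [stats::hclust()] with `members = weights`.
#'
#' @param D square dissimilarity matrix.
#' @param weights positive pattern weights.
#' @param k number of clusters to cut the tree at.
#' @return integer cluster labels `1..k`.
#' @export
weighted_average_linkage <- function(D, weights, k) {
  n <- nrow(D)
  if (k > n) stop("k exceeds the number of patterns")
  if (n == 1L) return(1L)
  hc <- stats::hclust(stats::as.dist(D), method = "average",
                      members = weights)
  unname(stats::cutree(hc, k = k))
}

#' Weighted cluster medoids
#'
#' Per cluster, the member minimizing the weighted sum of distances to all
#' cluster members; ties break to the lowest pattern index.
#'
#' @param D square dissimilarity matrix.
#' @param weights positive pattern weights.
#' @param labels integer cluster labels.
#' @return integer medoid indices, one per cluster (ordered by cluster id).
#' @export
cluster_medoids <- function(D, weights, labels) {
  vapply(sort(unique(labels)), function(cl) {
    i <- which(labels == cl)
    load <- as.numeric(D[i, i, drop = FALSE] %*% weights[i])
    i[which.min(load)]
  }, integer(1))
}

#' Weighted partitioning around medoids (PAM)
#'
#' Assigns every pattern to its nearest medoid, then repeatedly applies the
#' single best-improvement medoid/non-medoid swap (steepest descent on the
#' weighted objective `sum_i w_i d(i, medoid(i))`) until no swap lowers it.
#' Deterministic: swap candidates are scanned in index order and assignment
#' ties go to the lowest medoid position.
#'
#' @param D square dissimilarity matrix.
#' @param weights positive pattern weights.
#' @param init_medoids distinct initial medoid indices.
#' @param max_iter swap cap.
#' @return object of class `cluster_solution`: `labels` (cluster ids `1..k`
#'   aligned with `medoids`), `medoids` (pattern indices), `objective`, `k`.
#' @export
weighted_pam <- function(D, weights, init_medoids, max_iter = 200L) {
  init_medoids <- as.integer(init_medoids)
  if (anyDuplicated(init_medoids)) stop("initial medoids must be distinct")
  fit <- pam_cpp(D, as.numeric(weights), init_medoids, as.integer(max_iter))
  cluster_solution(labels = fit$labels, medoids = fit$medoids,
                   objective = fit$objective)
}

#' Construct a cluster solution object
#'
#' @param labels integer cluster ids aligned with positions in `medoids`.
#' @param medoids pattern indices, one per cluster.
#' @param objective weighted sum of distances to assigned medoids.
#' @return object of class `cluster_solution`.
#' @export
cluster_solution <- function(labels, medoids, objective = NA_real_) {
  structure(list(labels = as.integer(labels), medoids = as.integer(medoids),
                 objective = objective, k = length(medoids)),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("<cluster_solution> k=", x$k, " objective=", format(x$objective),
      "\n", sep = "")
  invisible(x)
}

#' Silhouette-driven choice of the number of sub-clusters
#'
#' For each `k` in `k_range`: cut the weighted average-linkage tree at `k`,
#' take the cluster medoids as PAM initialization, run weighted PAM, and
#' score the solution with the weighted average silhouette width (ASWw). The
#' `k` with the highest ASWw wins; ties go to the smaller `k`.
#'
#' @param D square dissimilarity matrix.
#' @param weights positive pattern weights.
#' @param k_range candidate cluster counts (values above `n - 1` are
#'   dropped).
#' @return list: `best_k`, `solution` (the winning `cluster_solution`),
#'   `solutions` (per k), `report` (data.frame `k`, `ASWw`, `objective`).
#' @export
select_k_by_asww <- function(D, weights, k_range = 2:20) {
  n <- nrow(D)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (n < 3L || length(k_range) == 0L) {
    sol <- cluster_solution(rep(1L, n), cluster_medoids(D, weights, rep(1L, n)))
    sol$objective <- sum(weights * D[, sol$medoids[1]])
    return(list(best_k = 1L, solution = sol, solutions = list(`1` = sol),
                report = data.frame(k = 1L, ASWw = NA_real_,
                                    objective = sol$objective)))
  }
  if (all(D == 0)) {
    warning("degenerate all-zero dissimilarity matrix; returning k = 2")
    labels <- c(1L, rep(2L, n - 1L))
    sol <- cluster_solution(labels, c(1L, 2L), 0)
    return(list(best_k = 2L, solution = sol, solutions = list(`2` = sol),
                report = data.frame(k = 2L, ASWw = 0, objective = 0)))
  }
  sols <- list()
  rep_rows <- list()
  for (k in k_range) {
    hl <- weighted_average_linkage(D, weights, k)
    med <- cluster_medoids(D, weights, hl)
    sol <- weighted_pam(D, weights, med)
    sols[[as.character(k)]] <- sol
    a <- if (length(unique(sol$labels)) >= 2L) {
      asww(D, weights, sol$labels)
    } else NA_real_
    rep_rows[[as.character(k)]] <- data.frame(k = k, ASWw = a,
                                              objective = sol$objective)
  }
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  ok <- which(!is.na(report$ASWw))
  best <- ok[which.max(report$ASWw[ok])]   # which.max: first max -> smaller k
  list(best_k = report$k[best], solution = sols[[as.character(report$k[best])]],
       solutions = sols, report = report)
}
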