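#' Global reassignment to pooled medoids (Step 3.1)
#'
#' Pools the sub-cluster medoids from all primary clusters and reassigns
#' every pattern to its nearest medoid, regardless of its Phase-1 cluster of
#' origin. Only the rectangular pattern-by-medoid distance block is needed,
#' shrinking the computation from `n x n` to `n x m`. Duplicate medoid
#' patterns (identical spell lists) are deduplicated with a warning;
#' assignment ties go to the lowest medoid index.
#'
#' @param pool a `traj_pool`.
#' @param medoids integer pattern indices of the candidate medoids.
#' @param cost a [build_cost_model()] object.
#' @return `cluster_solution` over the pool.
#' @export
global_reassign <- function(pool, medoids, cost) {
  medoids <- as.integer(medoids)
  keys <- vapply(pool$seqs[medoids], function(s) {
    paste(s$spells$state, s$spells$begin, s$spells$end, collapse = ";")
  }, character(1))
  if (anyDuplicated(keys)) {
    warning("duplicate medoid patterns removed")
    medoids <- medoids[!duplicated(keys)]
  }
  if (length(medoids) < 2L) stop("need at least two distinct medoid patterns")
  R <- distance_matrix(pool, cost, columns = medoids)
  labels <- apply(R, 1L, which.min)   # first minimum -> lowest medoid index
  cluster_solution(labels, medoids,
                   objective = sum(pool$weights * R[cbind(seq_len(nrow(R)), labels)]))
}

# nearest-medoid labels from a square matrix (columns restricted to medoids)
.assign_to_medoids <- function(D, medoids) {
  sub <- D[, medoids, drop = FALSE]
  apply(sub, 1L, which.min)
}

#' One quality-driven merge step (Step 3.2)
#'
#' Identifies the weakest cluster (lowest weighted mean silhouette width
#' among its members), merges it into the cluster whose medoid is nearest to
#' its own medoid, recomputes the merged cluster's weighted medoid, and
#' reassigns every pattern to the updated medoid set. `k` decreases by
#' exactly one.
#'
#' @param solution a `cluster_solution` with `k >= 3`.
#' @param D square dissimilarity matrix over the pool.
#' @param weights pattern weights.
#' @return list: `solution` (the merged `cluster_solution`) and
#'   `merged_pair` (cluster ids `c(weak, neighbor)` in the input labelling).
#' @export
merge_step <- function(solution, D, weights) {
  if (solution$k < 3L) stop("merging requires at least three clusters")
  labels <- solution$labels
  med <- solution$medoids
  s <- silhouette_widths(D, weights, labels)
  per_cl <- vapply(seq_len(solution$k), function(cl) {
    i <- labels == cl
    if (!any(i)) return(-Inf)
    sum(weights[i] * s[i]) / sum(weights[i])
  }, numeric(1))
  weak <- which.min(per_cl)
  dmed <- D[med[weak], med]
  dmed[weak] <- Inf
  neighbor <- which.min(dmed)
  keep <- sort(c(weak, neighbor))[1]
  drop <- sort(c(weak, neighbor))[2]
  union_i <- which(labels %in% c(weak, neighbor))
  load <- as.numeric(D[union_i, union_i, drop = FALSE] %*% weights[union_i])
  new_med <- union_i[which.min(load)]
  med_new <- med
  med_new[keep] <- new_med
  med_new <- med_new[-drop]
  labels_new <- .assign_to_medoids(D, med_new)
  obj <- sum(weights * D[cbind(seq_along(labels_new), med_new[labels_new])])
  list(solution = cluster_solution(labels_new, med_new, obj),
       merged_pair = c(weak = weak, neighbor = neighbor))
}

#' Iterative merging with full quality trace (Steps 3.2-3.3)
#'
#' Applies [merge_step()] from the initial solution down to `down_to_k`
#' clusters, recording the five-metric [quality_report()] at every `k`
#' (including the initial solution).
#'
#' @param solution initial `cluster_solution` (`k >= 3`).
#' @param D square dissimilarity matrix.
#' @param weights pattern weights.
#' @param down_to_k smallest cluster count to reach (`>= 2`).
#' @return object of class `merge_trace`: list with `report` (data.frame of
#'   metrics per k plus the merged pair), `solutions` (named by k).
#' @export
run_merging <- function(solution, D, weights, down_to_k = 2L) {
  stopifnot(down_to_k >= 2L, solution$k >= 3L)
  solutions <- list()
  rows <- list()
  cur <- solution
  pair <- c(NA_integer_, NA_integer_)
  repeat {
    rep_row <- quality_report(D, weights, cur$labels)
    rep_row$merged_from <- pair[1]
    rep_row$merged_into <- pair[2]
    rows[[as.character(cur$k)]] <- rep_row
    solutions[[as.character(cur$k)]] <- cur
    if (cur$k <= down_to_k) break
    st <- merge_step(cur, D, weights)
    cur <- st$solution
    pair <- st$merged_pair
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, solutions = solutions),
            class = "merge_trace")
}

#' @export
print.merge_trace <- function(x, ...) {
  cat("<merge_trace> k:", max(x$report$k), "->", min(x$report$k), "\n")
  print(x$report[c("k", "ASWw", "HGSD", "HC", "CHsq", "R2sq")], row.names = FALSE)
  invisible(x)
}

#' Multi-metric selection of the optimal cluster count (Step 3.3)
#'
#' Min-max normalizes ASWw, CH (squared variant), HGSD, pseudo-R2 (squared
#' variant) and HC across the merge trace and maximizes the composite
#' `mean(ASWw', CH', HGSD', R2', 1 - HC')`; ties go to the smaller `k`. A
#' metric constant across the trace contributes 0.5 everywhere. `max_k`
#' optionally caps the admissible `k` for interpretability.
#'
#' @param trace a [run_merging()] trace.
#' @param max_k optional hard cap on `k`.
#' @return list: `k` (chosen count), `composite` (data.frame `k`, `composite`).
#' @export
select_optimal_k <- function(trace, max_k = Inf) {
  rep <- trace$report
  rep <- rep[rep$k <= max_k, , drop = FALSE]
  if (nrow(rep) < 1L) stop("empty trace after applying max_k")
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) return(rep(0.5, length(x)))
    (x - r[1]) / diff(r)
  }
  comp <- rowMeans(cbind(norm01(rep$ASWw), norm01(rep$CHsq), norm01(rep$HGSD),
                         norm01(rep$R2sq), 1 - norm01(rep$HC)))
  o <- order(-comp, rep$k)
  list(k = rep$k[o[1]],
       composite = data.frame(k = rep$k, composite = comp))
}
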