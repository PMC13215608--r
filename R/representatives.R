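#' Extract representative trajectories for one cluster
#'
#' Greedy coverage-based selection of a small set of patterns that stand for
#' a cluster. Candidates are scored under one of four criteria, sorted
#' descending, and admitted unless they lie within the neighborhood radius
#' (`pradius` times the maximum within-cluster distance) of an already chosen
#' representative; selection stops once the weighted coverage (share of
#' cluster weight within `r` of some representative) reaches `trep` or
#' `nrep_max` representatives have been chosen.
#'
#' Criteria:
#' * `frequency` — the pattern's frequency weight;
#' * `centrality` — negative weighted sum of distances to all members (the
#'   weighted medoid scores highest);
#' * `density` — weighted number of members within `r`;
#' * `likelihood` — log-probability under a smoothed first-order Markov
#'   chain fitted to the cluster (the Phase-1 machinery with one component).
#'
#' The gain compares the mean distance to the nearest representative against
#' the single-medoid baseline:
#' `gain = 1 - sum_i w_i d(i, nearest rep) / sum_i w_i d(i, medoid)` (0 when
#' the baseline is already perfect).
#'
#' @param D square dissimilarity matrix of the cluster members.
#' @param weights member weights.
#' @param criterion one of `"frequency"`, `"centrality"`, `"density"`,
#'   `"likelihood"`.
#' @param seqs list of the cluster's `traj` patterns (required for the
#'   likelihood criterion).
#' @param trep coverage threshold in `[0, 1]`.
#' @param nrep_max maximum number of representatives.
#' @param pradius neighborhood radius as a fraction of the maximum
#'   within-cluster distance.
#' @param alpha smoothing pseudo-count for the likelihood criterion.
#' @return object of class `rep_set`: `criterion`, `reps` (member indices in
#'   selection order), `n_reps`, `coverage`, `gain`, `radius`.
#' @export
extract_representatives <- function(D, weights, criterion = c("centrality",
                                    "likelihood", "frequency", "density"),
                                    seqs = NULL, trep = 0.75, nrep_max = 10L,
                                    pradius = 0.10, alpha = 0.5) {
  criterion <- match.arg(criterion)
  n <- nrow(D)
  if (n == 0L) stop("empty cluster")
  w <- as.numeric(weights)
  W <- sum(w)
  r <- pradius * max(D)
  score <- switch(criterion,
    frequency = w,
    centrality = -as.numeric(D %*% w),
    density = as.numeric((D <= r) %*% w),
    likelihood = {
      if (is.null(seqs)) stop("likelihood criterion needs the cluster's sequences")
      sub <- structure(list(seqs = seqs, weights = w,
                            members = vector("list", n),
                            alphabet = sort(unique(unlist(lapply(seqs,
                              function(s) unique(s$states)))))),
                       class = "traj_pool")
      chain <- fit_markov_mixture(sub, k = 1L, seed = 1L, alpha = alpha,
                                  max_iter = 2L)
      vapply(seqs, function(s) sequence_loglik(chain, s$states, 1L), numeric(1))
    })
  ord <- order(-score, seq_len(n))
  reps <- integer(0)
  coverage <- 0
  for (cand in ord) {
    if (length(reps) > 0L && any(D[cand, reps] <= r)) next
    reps <- c(reps, cand)
    covered <- apply(D[, reps, drop = FALSE], 1L, min) <= r
    coverage <- sum(w[covered]) / W
    if (coverage >= trep || length(reps) >= nrep_max) break
  }
  medoid <- which.min(as.numeric(D %*% w))
  base <- sum(w * D[, medoid])
  repd <- sum(w * apply(D[, reps, drop = FALSE], 1L, min))
  gain <- if (base == 0) 0 else 1 - repd / base
  structure(list(criterion = criterion, reps = reps,
                 n_reps = length(reps), coverage = coverage, gain = gain,
                 radius = r),
            class = "rep_set")
}

#' @export
print.rep_set <- function(x, ...) {
  cat("<rep_set> criterion=", x$criterion, " n_reps=", x$n_reps,
      " coverage=", round(x$coverage, 3), " gain=", round(x$gain, 3),
      "\n", sep = "")
  invisible(x)
}

#' Choose the best representative set across criteria
#'
#' Filters to sets meeting the coverage threshold within the size cap (if
#' none qualifies, all sets stay in play), then ranks by gain (descending),
#' number of representatives (ascending), coverage (descending) and finally
#' the fixed criterion priority centrality > likelihood > frequency >
#' density.
#'
#' @param sets list of `rep_set` objects (one per criterion).
#' @param trep coverage threshold.
#' @param nrep_max size cap.
#' @return the winning `rep_set`.
#' @export
select_best_criterion <- function(sets, trep = 0.75, nrep_max = 10L) {
  stopifnot(length(sets) >= 1L)
  prio <- c(centrality = 1L, likelihood = 2L, frequency = 3L, density = 4L)
  ok <- vapply(sets, function(s) {
    s$coverage >= trep && s$n_reps <= nrep_max
  }, logical(1))
  pool <- if (any(ok)) sets[ok] else sets
  key <- vapply(pool, function(s) s$gain, numeric(1))
  o <- order(-key,
             vapply(pool, `[[`, integer(1), "n_reps"),
             -vapply(pool, `[[`, numeric(1), "coverage"),
             prio[vapply(pool, `[[`, character(1), "criterion")])
  pool[[o[1]]]
}

#' Representatives for every cluster of a solution
#'
#' Runs [extract_representatives()] under all four criteria within each
#' cluster and keeps the [select_best_criterion()] winner.
#'
#' @param pool a `traj_pool`.
#' @param D square dissimilarity matrix over the pool.
#' @param labels final cluster labels.
#' @param trep,nrep_max,pradius,alpha see [extract_representatives()].
#' @return named list (by cluster id) of lists: `best` (`rep_set` with
#'   `reps` as pool indices), `all` (per criterion), `patterns`
#'   (data.frame of the winning representatives' spell lists).
#' @export
cluster_representatives <- function(pool, D, labels, trep = 0.75,
                                    nrep_max = 10L, pradius = 0.10,
                                    alpha = 0.5) {
  w <- pool$weights
  out <- lapply(sort(unique(labels)), function(cl) {
    i <- which(labels == cl)
    Dc <- D[i, i, drop = FALSE]
    sets <- lapply(c("centrality", "likelihood", "frequency", "density"),
                   function(cr) {
      extract_representatives(Dc, w[i], cr, seqs = pool$seqs[i], trep = trep,
                              nrep_max = nrep_max, pradius = pradius,
                              alpha = alpha)
    })
    best <- select_best_criterion(sets, trep = trep, nrep_max = nrep_max)
    best$reps <- i[best$reps]
    pats <- do.call(rbind, lapply(seq_along(best$reps), function(j) {
      sp <- pool$seqs[[best$reps[j]]]$spells
      data.frame(cluster = cl, rep = j, pattern = best$reps[j],
                 state = sp$state, duration = sp$duration)
    }))
    list(best = best, all = sets, patterns = pats)
  })
  names(out) <- sort(unique(labels))
  out
}
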