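#' Weighted cluster-quality indices
#'
#' Five complementary indices evaluate a weighted partition of a
#' dissimilarity matrix. All are defined so that a weight-`w` pattern behaves
#' exactly like `w` coincident unit-weight copies (zero distance apart):
#' the weighted index on the compact pool equals the unweighted index on the
#' weight-expanded instance.
#'
#' * `asww()` — weighted average silhouette width, in `[-1, 1]`, higher
#'   better. Within-cluster mean distance uses the own-weight-inclusive
#'   denominator `W_C - 1`.
#' * `hubert_somers_d()` — rank agreement between the dissimilarities and the
#'   binary within/between-pair partition, in `[-1, 1]`, higher better.
#' * `hubert_c()` — gap between the within-pair distance sum and the best
#'   achievable sum over equally many (weighted) pairs, in `[0, 1]`, lower
#'   better.
#' * `calinski_harabasz()` — ANOVA-like compactness/separation ratio and the
#'   accompanying pseudo-R2 (share of pairwise dissimilarity explained),
#'   computed from squared distances by default.
#'
#' @param D square dissimilarity matrix over patterns.
#' @param weights positive pattern weights.
#' @param labels integer cluster labels (at least two clusters).
#' @name quality_metrics
NULL

#' @rdname quality_metrics
#' @return `asww()`: scalar weighted average silhouette width.
#' @export
asww <- function(D, weights, labels) {
  sum(weights * silhouette_widths(D, weights, labels)) / sum(weights)
}

#' @rdname quality_metrics
#' @return `silhouette_widths()`: per-pattern weighted silhouette `s(i)`.
#' @export
silhouette_widths <- function(D, weights, labels) {
  labels <- as.integer(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2L) stop("silhouette requires at least two clusters")
  n <- nrow(D)
  W <- vapply(cls, function(cl) sum(weights[labels == cl]), numeric(1))
  G <- vapply(cls, function(cl) {
    as.numeric(D[, labels == cl, drop = FALSE] %*% weights[labels == cl])
  }, numeric(n))
  own <- match(labels, cls)
  a <- G[cbind(seq_len(n), own)] / (W[own] - 1)
  Gb <- sweep(G, 2L, W, "/")
  Gb[cbind(seq_len(n), own)] <- Inf
  b <- apply(Gb, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[!is.finite(a) | W[own] <= 1 | pmax(a, b) == 0] <- 0
  s[is.nan(s)] <- 0
  s
}

# weighted multisets of within-pair and between-pair distances; a weight-w
# pattern contributes choose(w, 2) zero-distance within pairs.
.pair_sets <- function(D, weights, labels) {
  n <- nrow(D)
  ut <- upper.tri(D)
  same <- outer(labels, labels, "==")[ut]
  pw <- outer(weights, weights)[ut]
  d <- D[ut]
  self_w <- weights * (weights - 1) / 2
  list(
    within = list(d = c(d[same], rep(0, sum(self_w > 0))),
                  w = c(pw[same], self_w[self_w > 0])),
    between = list(d = d[!same], w = pw[!same])
  )
}

#' @rdname quality_metrics
#' @return `hubert_somers_d()`: scalar in `[-1, 1]` —
#'   `(C - D) / (C + D + T)` where `C`/`D`/`T` count weighted
#'   (within-pair, between-pair) comparisons in which the between distance
#'   exceeds / falls below / ties the within distance.
#' @export
hubert_somers_d <- function(D, weights, labels) {
  ps <- .pair_sets(D, weights, labels)
  if (length(ps$within$d) == 0L || length(ps$between$d) == 0L) {
    stop("Somers' D undefined: all pairs fall in one class")
  }
  o <- order(ps$within$d)
  wd <- ps$within$d[o]
  ww <- ps$within$w[o]
  cum <- cumsum(ww)
  tot <- cum[length(cum)]
  # weight of within distances strictly below / above each between distance
  lo <- findInterval(ps$between$d, wd, left.open = TRUE)   # wd <  d
  hi <- findInterval(ps$between$d, wd)                     # wd <= d
  w_lt <- ifelse(lo > 0, cum[pmax(lo, 1L)], 0) * (lo > 0)
  w_le <- ifelse(hi > 0, cum[pmax(hi, 1L)], 0) * (hi > 0)
  conc <- sum(ps$between$w * w_lt)
  ties <- sum(ps$between$w * (w_le - w_lt))
  disc <- sum(ps$between$w * (tot - w_le))
  (conc - disc) / (conc + disc + ties)
}

#' @rdname quality_metrics
#' @return `hubert_c()`: scalar in `[0, 1]`, `(S - S_min) / (S_max - S_min)`
#'   with `S` the weighted within-pair distance sum and `S_min`/`S_max` the
#'   sums of the same total pair weight taken over the smallest/largest
#'   distances of the whole matrix (fractional take at the boundary).
#' @export
hubert_c <- function(D, weights, labels) {
  ps <- .pair_sets(D, weights, labels)
  S <- sum(ps$within$d * ps$within$w)
  n_w <- sum(ps$within$w)
  alld <- c(ps$within$d, ps$between$d)
  allw <- c(ps$within$w, ps$between$w)
  o <- order(alld)
  smin <- .head_weighted_sum(alld[o], allw[o], n_w)
  o2 <- order(alld, decreasing = TRUE)
  smax <- .head_weighted_sum(alld[o2], allw[o2], n_w)
  if (smax == smin) return(0)
  (S - smin) / (smax - smin)
}

# weighted sum of the first `target` units of pair weight along sorted values
.head_weighted_sum <- function(d, w, target) {
  cum <- cumsum(w)
  k <- findInterval(target, cum, left.open = TRUE) + 1L
  if (k > length(d)) k <- length(d)
  full <- if (k > 1L) sum(d[seq_len(k - 1L)] * w[seq_len(k - 1L)]) else 0
  used <- if (k > 1L) cum[k - 1L] else 0
  full + d[k] * (target - used)
}

#' @rdname quality_metrics
#' @param squared use squared distances (default) or raw distances.
#' @return `calinski_harabasz()`: list with `CH` and `R2`.
#' @export
calinski_harabasz <- function(D, weights, labels, squared = TRUE) {
  labels <- as.integer(labels)
  cls <- sort(unique(labels))
  k <- length(cls)
  if (k < 2L) stop("requires at least two clusters")
  n <- sum(weights)
  if (n <= k) stop("effective size must exceed the number of clusters")
  delta <- if (squared) D^2 else D
  total <- as.numeric(weights %*% delta %*% weights) / 2 / n
  if (total == 0) stop("all dissimilarities are zero: CH undefined (R2 = 1)")
  wss <- sum(vapply(cls, function(cl) {
    i <- labels == cl
    wi <- weights[i]
    as.numeric(wi %*% delta[i, i, drop = FALSE] %*% wi) / 2 / sum(wi)
  }, numeric(1)))
  if (wss == 0) {
    stop("zero within-cluster dissimilarity: CH infinite (R2 = 1)")
  }
  list(CH = ((total - wss) / (k - 1)) / (wss / (n - k)),
       R2 = 1 - wss / total)
}

#' Full quality report for one partition
#'
#' @param D,weights,labels as in [asww()].
#' @return one-row data.frame: `k`, `n_effective`, `ASWw`, `HGSD`, `HC`,
#'   `CH`, `CHsq`, `R2`, `R2sq`.
#' @export
quality_report <- function(D, weights, labels) {
  ch1 <- calinski_harabasz(D, weights, labels, squared = FALSE)
  ch2 <- calinski_harabasz(D, weights, labels, squared = TRUE)
  data.frame(k = length(unique(labels)), n_effective = sum(weights),
             ASWw = asww(D, weights, labels),
             HGSD = hubert_somers_d(D, weights, labels),
             HC = hubert_c(D, weights, labels),
             CH = ch1$CH, CHsq = ch2$CH, R2 = ch1$R2, R2sq = ch2$R2)
}
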