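# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately written as naive/brute-force implementations,
# independent of the package's computational paths.

# --- sequence fixtures ----------------------------------------------------

# traj from explicit visit days and state codes
make_traj <- function(states, days = seq(0, by = 30, length.out = length(states)),
                      id = "X") {
  build_spells(days, states, patient_id = id)
}

# a traj with given (state, duration-in-days) spells, visits 1 per spell
make_spell_traj <- function(states, durs, id = "X") {
  days <- cumsum(c(0, durs))[seq_along(states)]
  # one visit per spell start plus a terminal visit fixes the durations
  build_spells(c(days, sum(durs)), c(states, states[length(states)]), id)
}

# random spell sequence over a small alphabet (durations in whole days)
random_spell_traj <- function(max_spells = 5, n_states = 4, max_dur = 6,
                              id = "X") {
  n <- sample.int(max_spells, 1)
  st <- integer(n)
  st[1] <- sample.int(n_states, 1)
  if (n > 1) {
    for (i in 2:n) {
      st[i] <- sample(setdiff(seq_len(n_states), st[i - 1]), 1)
    }
  }
  make_spell_traj(st, sample.int(max_dur, n, replace = TRUE), id)
}

# pool of raw trajs (possibly with duplicates for weighting)
make_pool <- function(trajs) merge_identical(trajs)

# hand-built cost model with an arbitrary substitution matrix
make_cost <- function(states, sub, indel = 1, expansion = 0.5,
                      transform = "identity", units = "days") {
  structure(list(states = as.integer(states), sub = sub, indel = indel,
                 expansion = expansion, transform = transform, units = units,
                 scheme = "custom"),
            class = "cost_model")
}

# --- OMspell oracles ------------------------------------------------------

# memoized brute-force recursion over the same operation set as the DP
bf_omspell <- function(a, b, cost) {
  tf <- function(t) if (cost$transform == "sqrt") sqrt(t) else t
  sidx <- function(s) match(s$spells$state, cost$states)
  dur <- function(s) if (cost$units == "visits") s$spells$visits else s$spells$duration
  sa <- sidx(a); da <- dur(a); sb <- sidx(b); db <- dur(b)
  indel <- function(i, from_a) {
    t <- if (from_a) da[i] else db[i]
    cost$indel + cost$expansion * (tf(t) - tf(1))
  }
  subc <- function(i, j) {
    cost$sub[sa[i], sb[j]] + cost$expansion * abs(tf(da[i]) - tf(db[j]))
  }
  memo <- new.env()
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == 0 && j == 0) 0
    else if (i == 0) rec(0, j - 1) + indel(j, FALSE)
    else if (j == 0) rec(i - 1, 0) + indel(i, TRUE)
    else min(rec(i - 1, j - 1) + subc(i, j),
             rec(i - 1, j) + indel(i, TRUE),
             rec(i, j - 1) + indel(j, FALSE))
    memo[[key]] <- val
    val
  }
  rec(length(sa), length(sb))
}

# classical optimal matching on state strings (unit elements, no durations)
naive_om <- function(x, y, sub, indel) {
  n <- length(x); m <- length(y)
  Dp <- matrix(0, n + 1, m + 1)
  Dp[, 1] <- (0:n) * indel
  Dp[1, ] <- (0:m) * indel
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Dp[i + 1, j + 1] <- min(Dp[i, j] + sub[x[i], y[j]],
                              Dp[i, j + 1] + indel,
                              Dp[i + 1, j] + indel)
    }
  }
  Dp[n + 1, m + 1]
}

# --- clustering oracles ---------------------------------------------------

# naive O(n^3) weighted average-linkage agglomeration
naive_average_linkage <- function(D, w, k) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  dist_cl <- function(a, b) {
    wa <- w[a]; wb <- w[b]
    sum(outer(wa, wb) * D[a, b, drop = FALSE]) / (sum(wa) * sum(wb))
  }
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- dist_cl(clusters[[i]], clusters[[j]])
        if (d < best[1] - 1e-12) best <- c(d, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  labels <- integer(n)
  for (c in seq_along(clusters)) labels[clusters[[c]]] <- c
  labels
}

# expand a weighted instance into unit-weight rows (for metric oracles)
expand_instance <- function(D, w, labels) {
  idx <- rep(seq_along(w), times = w)
  list(D = D[idx, idx, drop = FALSE], labels = labels[idx], idx = idx)
}

# unweighted silhouette via the cluster package (independent implementation)
oracle_asw <- function(D, labels) {
  s <- cluster::silhouette(labels, dmatrix = D)
  mean(s[, "sil_width"])
}

# direct double-loop Somers' D over expanded unit pairs
oracle_somers_d <- function(D, labels) {
  n <- nrow(D)
  pairs <- t(utils::combn(n, 2))
  within <- labels[pairs[, 1]] == labels[pairs[, 2]]
  d <- D[pairs]
  conc <- disc <- ties <- 0
  for (p in which(!within)) {
    for (q in which(within)) {
      if (d[p] > d[q]) conc <- conc + 1
      else if (d[p] < d[q]) disc <- disc + 1
      else ties <- ties + 1
    }
  }
  (conc - disc) / (conc + disc + ties)
}

# direct Hubert C over expanded unit pairs
oracle_hubert_c <- function(D, labels) {
  n <- nrow(D)
  pairs <- t(utils::combn(n, 2))
  within <- labels[pairs[, 1]] == labels[pairs[, 2]]
  d <- D[pairs]
  S <- sum(d[within])
  nw <- sum(within)
  smin <- sum(sort(d)[seq_len(nw)])
  smax <- sum(sort(d, decreasing = TRUE)[seq_len(nw)])
  if (smax == smin) return(0)
  (S - smin) / (smax - smin)
}

# classical Calinski-Harabasz / R2 from Euclidean coordinates
oracle_ch_r2 <- function(X, labels) {
  n <- nrow(X)
  k <- length(unique(labels))
  grand <- colMeans(X)
  tss <- sum(sweep(X, 2, grand)^2)
  wss <- sum(vapply(unique(labels), function(cl) {
    Xi <- X[labels == cl, , drop = FALSE]
    sum(sweep(Xi, 2, colMeans(Xi))^2)
  }, numeric(1)))
  list(CH = ((tss - wss) / (k - 1)) / (wss / (n - k)), R2 = 1 - wss / tss)
}

# hand-coded Cox partial likelihood (Breslow, no ties in the fixtures used)
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# block-structured distance matrix with given within/between levels
block_matrix <- function(sizes, within = 0, between = 1, jitter = 0) {
  labels <- rep(seq_along(sizes), sizes)
  n <- length(labels)
  D <- matrix(between, n, n)
  for (cl in seq_along(sizes)) {
    i <- labels == cl
    D[i, i] <- within
  }
  if (jitter > 0) {
    J <- matrix(stats::runif(n * n, 0, jitter), n, n)
    J <- (J + t(J)) / 2
    D <- D + J
  }
  diag(D) <- 0
  list(D = D, labels = labels)
}
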