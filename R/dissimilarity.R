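#' Substitution and INDEL cost model for OMspell distances
#'
#' Builds the cost structure for optimal matching on spells: a symmetric
#' substitution matrix over the state alphabet, a constant insertion/deletion
#' (INDEL) cost, and an expansion cost per duration unit that prices
#' differences in spell durations.
#'
#' Two substitution schemes are provided, both bounded by 2:
#' * `"severity"` (default): `S(x, y) = 2 * |sev(x) - sev(y)| / 9`, where
#'   `sev` is the number of impaired domains; distinct states of equal
#'   severity get a configurable floor (default 0.1) so that no two distinct
#'   states are cost-free to exchange.
#' * `"hamming"`: `S(x, y) = 2 * H(x, y) / 9`, with `H` the number of domains
#'   on which the two states differ.
#'
#' @param states integer state codes forming the alphabet.
#' @param scheme `"severity"` or `"hamming"`.
#' @param indel constant INDEL cost (must be positive).
#' @param expansion cost `e` per transformed duration unit; a spell of
#'   duration `t` costs `indel + e * (phi(t) - phi(1))` to insert or delete,
#'   and substituting spells of durations `t`, `u` adds `e * |phi(t) - phi(u)|`.
#' @param transform duration transform `phi`: `"identity"` or `"sqrt"`.
#' @param units whether spell durations are measured in `"days"` or in
#'   `"visits"` (number of assessments in the run).
#' @param sev_floor substitution floor for distinct equal-severity states
#'   under the severity scheme (set to 0 to disable).
#' @return object of class `cost_model`.
#' @export
build_cost_model <- function(states, scheme = c("severity", "hamming"),
                             indel = 1.0, expansion = 0.5,
                             transform = c("identity", "sqrt"),
                             units = c("days", "visits"), sev_floor = 0.1) {
  scheme <- match.arg(scheme)
  transform <- match.arg(transform)
  units <- match.arg(units)
  states <- sort(unique(as.integer(states)))
  if (length(states) == 0L) stop("empty state alphabet")
  if (indel <= 0) stop("INDEL cost must be positive")
  if (expansion < 0) stop("expansion cost must be non-negative")
  if (any(states > 511L)) {
    stop("synthetic OTHER states have no domain attributes; use the 'drop' ",
         "restriction strategy before building a cost model")
  }
  n <- length(states)
  sub <- matrix(0, n, n, dimnames = list(states, states))
  if (scheme == "severity") {
    sev <- state_severity(states)
    sub <- 2 * abs(outer(sev, sev, "-")) / 9
    eq <- sub == 0 & !diag(n)
    sub[eq] <- sev_floor
  } else {
    ham <- outer(states, states, function(a, b) {
      mapply(function(x, y) sum(bitwAnd(bitwXor(x, y), .adl_bits) > 0L), a, b)
    })
    sub <- 2 * ham / 9
  }
  dimnames(sub) <- list(states, states)
  structure(list(states = states, sub = sub, indel = indel,
                 expansion = expansion, transform = transform, units = units,
                 scheme = scheme),
            class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat("<cost_model> scheme=", x$scheme, " indel=", x$indel,
      " expansion=", x$expansion, " transform=", x$transform,
      " units=", x$units, " |alphabet|=", length(x$states), "\n", sep = "")
  invisible(x)
}

# spell states as 0-based alphabet indices + durations in the model's units,
# after canonicalization (merge adjacent equal-state spells).
.spell_encode <- function(s, cost) {
  sp <- s$spells
  st <- sp$state
  dur <- if (cost$units == "visits") sp$visits else sp$duration
  if (length(st) > 1L) {
    same <- c(FALSE, st[-1] == st[-length(st)])
    if (any(same)) {
      grp <- cumsum(!same)
      dur <- as.numeric(tapply(dur, grp, sum))
      st <- st[!same]
    }
  }
  idx <- match(st, cost$states)
  if (anyNA(idx)) {
    stop("state(s) absent from cost model: ",
         paste(unique(st[is.na(idx)]), collapse = ", "))
  }
  list(states = as.integer(idx - 1L), durs = as.numeric(dur))
}

#' OMspell distance between two spell sequences
#'
#' Edit distance over spells via dynamic programming: a spell `(x, t)` can be
#' inserted or deleted at cost `indel + e * (phi(t) - phi(1))`, or substituted
#' for `(y, u)` at cost `S(x, y) + e * |phi(t) - phi(u)|`. Adjacent
#' same-state spells are merged before the computation, so the distance is
#' invariant to non-canonical input.
#'
#' @param a,b `traj` objects.
#' @param cost a [build_cost_model()] object covering all states in `a`, `b`.
#' @return non-negative distance; `0` for identical sequences; symmetric.
#' @export
omspell_distance <- function(a, b, cost) {
  ea <- .spell_encode(a, cost)
  eb <- .spell_encode(b, cost)
  omspell_pair_cpp(ea$states, ea$durs, eb$states, eb$durs, cost$sub,
                   cost$indel, cost$expansion,
                   as.integer(cost$transform == "sqrt"))
}

#' Pairwise OMspell distance matrix over a weighted pool
#'
#' Computes the square matrix of pairwise distances among the unique patterns
#' of a pool, or — when `columns` is given — the rectangular matrix of
#' distances from every pattern to the selected column patterns (used for
#' global reassignment to pooled medoids, which shrinks the computation from
#' `n x n` to `n x m`).
#'
#' @param pool a `traj_pool`.
#' @param cost a [build_cost_model()] object.
#' @param columns optional integer indices (into the pool) of column patterns.
#' @param subset optional integer indices restricting the rows (and, for the
#'   square form, columns) to a sub-pool.
#' @return numeric matrix with `weights` attribute aligned to its rows.
#' @export
distance_matrix <- function(pool, cost, columns = NULL, subset = NULL) {
  idx <- if (is.null(subset)) seq_along(pool$seqs) else as.integer(subset)
  enc <- lapply(pool$seqs[idx], .spell_encode, cost = cost)
  states <- lapply(enc, `[[`, "states")
  durs <- lapply(enc, `[[`, "durs")
  tf <- as.integer(cost$transform == "sqrt")
  if (is.null(columns)) {
    D <- omspell_matrix_cpp(states, durs, cost$sub, cost$indel,
                            cost$expansion, tf, integer(0))
    dimnames(D) <- list(idx, idx)
  } else {
    cols <- match(as.integer(columns), idx)
    if (anyNA(cols)) stop("'columns' must index patterns within the subset")
    D <- omspell_matrix_cpp(states, durs, cost$sub, cost$indel,
                            cost$expansion, tf, as.integer(cols))
    dimnames(D) <- list(idx, columns)
  }
  attr(D, "weights") <- pool$weights[idx]
  D
}

#' Serialize a distance matrix to CSV and back
#'
#' Row and column pattern ids travel in the header/first column, and row
#' weights in a leading `weight` column, so a written matrix reconstructs
#' exactly.
#'
#' @param D matrix from [distance_matrix()].
#' @param path CSV file.
#' @export
write_distance_matrix <- function(D, path) {
  df <- data.frame(id = rownames(D), weight = attr(D, "weights"), D,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  D <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(D) <- df$id
  storage.mode(D) <- "double"
  attr(D, "weights") <- df$weight
  D
}
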