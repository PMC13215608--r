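#' Hard-EM mixture of first-order Markov chains (Phase 1)
#'
#' Fits `k` first-order Markov chains to the per-assessment state sequences of
#' a weighted pool by classification (hard) EM. Each trajectory's probability
#' under component `c` is the product of transition probabilities
#' `P(x_i | x_{i-1}; c)`, with the first state drawn from a virtual START
#' row. The E-step assigns every unique pattern (carrying its frequency
#' weight) to the component with the highest log-likelihood (ties to the
#' lowest component index); the M-step re-estimates each component's
#' transition matrix from the weighted transition counts of its members plus
#' `alpha` pseudo-counts, row-normalized.
#'
#' With `alpha > 0` the monotone objective of this classification EM is the
#' penalized classification log-likelihood (log-likelihood plus the
#' Dirichlet smoothing term); `loglik_trace` records it per iteration and it
#' coincides with the plain classification log-likelihood at `alpha = 0`.
#'
#' @param pool a `traj_pool`.
#' @param k number of components (`>= 1`).
#' @param seed integer seed for the random initialization.
#' @param alpha pseudo-count added to every transition cell (`>= 0`).
#' @param tol_assign stop when the weighted fraction of patterns changing
#'   component falls below this.
#' @param tol_matrix stop when the largest pointwise change of any transition
#'   matrix falls below this.
#' @param max_iter iteration cap.
#' @param init `"sequences"` seeds each component's transition matrix from
#'   the smoothed counts of a randomly drawn pattern (weighted by
#'   frequency), which places the starting chains on observed dynamics;
#'   `"dirichlet"` draws fully random row-stochastic matrices.
#' @param n_init number of random restarts (default 10); the fit with the
#'   highest final objective is kept (classification EM is greedy and can stall in mixed
#'   local optima from a single start).
#' @return object of class `markov_mix`: `k`, `alphabet`, `trans` (list of
#'   `(S+1) x S` row-stochastic matrices, first row START), `assignment`,
#'   `loglik` (weighted classification log-likelihood of the final state),
#'   `loglik_trace`, `iterations`, `converged`, `reseeds`, `alpha`, `seed`.
#' @export
fit_markov_mixture <- function(pool, k, seed = 1L, alpha = 0.5,
                               tol_assign = 1e-3, tol_matrix = 1e-4,
                               max_iter = 100L,
                               init = c("sequences", "dirichlet"),
                               n_init = 10L) {
  stopifnot(k >= 1L, alpha >= 0, all(pool$weights > 0))
  init <- match.arg(init)
  alphabet <- pool$alphabet
  S <- length(alphabet)
  X <- .transition_counts(pool$seqs, alphabet)   # n x (S+1)S
  w <- pool$weights
  n <- length(w)

  # seeded initialization without disturbing the caller's RNG stream
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  best <- NULL
  for (restart in seq_len(max(1L, as.integer(n_init)))) {
    trans0 <- if (init == "sequences" && n >= k) {
      picks <- sample.int(n, k, prob = w)
      lapply(picks, function(i) {
        .smoothed_rows(matrix(X[i, ], S + 1L, S, byrow = TRUE),
                       max(alpha, 0.5))
      })
    } else {
      replicate(k, .random_stochastic(S), simplify = FALSE)
    }
    fit <- .cem_run(X, w, trans0, k, S, alpha, tol_assign, tol_matrix,
                    max_iter)
    if (is.null(best) || fit$objective > best$objective) best <- fit
    if (k == 1L) break   # deterministic given the assignment
  }
  trans <- best$trans
  L <- .loglik_matrix(X, trans)
  lab <- max.col(L, ties.method = "first")
  for (cl in seq_len(k)) {
    dimnames(trans[[cl]]) <- list(c("START", alphabet), alphabet)
  }
  structure(list(k = k, alphabet = alphabet, trans = trans, assignment = lab,
                 loglik = sum(w * L[cbind(seq_len(n), lab)]),
                 loglik_trace = best$trace, iterations = best$iterations,
                 converged = best$converged, reseeds = best$reseeds,
                 reseed_iters = best$reseed_iters,
                 alpha = alpha, seed = seed),
            class = "markov_mix")
}

# one classification-EM run from a given set of starting matrices
.cem_run <- function(X, w, trans, k, S, alpha, tol_assign, tol_matrix,
                     max_iter) {
  n <- length(w)
  assign_old <- rep(0L, n)
  trace <- numeric(0)
  reseeds <- 0L
  reseed_iters <- integer(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    L <- .loglik_matrix(X, trans)               # n x k
    lab <- max.col(L, ties.method = "first")
    # re-seed empty components from the worst-fitting sequence
    empty <- setdiff(seq_len(k), unique(lab))
    if (length(empty) > 0L) {
      fit <- L[cbind(seq_len(n), lab)]
      worst <- order(fit)[seq_along(empty)]
      for (j in seq_along(empty)) {
        trans[[empty[j]]] <- .smoothed_rows(matrix(X[worst[j], ], S + 1L, S,
                                                   byrow = TRUE), alpha)
      }
      reseeds <- reseeds + length(empty)
      reseed_iters <- c(reseed_iters, it)
      message("re-seeded ", length(empty), " empty component(s)")
      L <- .loglik_matrix(X, trans)
      lab <- max.col(L, ties.method = "first")
    }
    obj <- sum(w * L[cbind(seq_len(n), lab)]) +
      alpha * sum(vapply(trans, function(P) sum(log(P)), numeric(1)))
    trace <- c(trace, obj)
    changed <- sum(w[lab != assign_old]) / sum(w)
    assign_old <- lab
    # M-step
    trans_new <- lapply(seq_len(k), function(cl) {
      rows <- lab == cl
      counts <- colSums(X[rows, , drop = FALSE] * w[rows])
      .smoothed_rows(matrix(counts, S + 1L, S, byrow = TRUE), alpha)
    })
    dmat <- max(vapply(seq_len(k), function(cl) {
      max(abs(trans_new[[cl]] - trans[[cl]]))
    }, numeric(1)))
    trans <- trans_new
    if (it > 1L && (changed < tol_assign || dmat < tol_matrix)) {
      converged <- TRUE
      break
    }
  }
  L <- .loglik_matrix(X, trans)
  lab <- max.col(L, ties.method = "first")
  objective <- sum(w * L[cbind(seq_len(n), lab)]) +
    alpha * sum(vapply(trans, function(P) sum(log(P)), numeric(1)))
  list(trans = trans, objective = objective, trace = trace, iterations = it,
       converged = converged, reseeds = reseeds, reseed_iters = reseed_iters)
}

#' @export
print.markov_mix <- function(x, ...) {
  cat("<markov_mix> k=", x$k, " |alphabet|=", length(x$alphabet),
      " iterations=", x$iterations, " converged=", x$converged,
      " loglik=", format(x$loglik), "\n", sep = "")
  invisible(x)
}

#' Log-likelihood of one state sequence under one component
#'
#' `log P(x_1 | START) + sum_i log P(x_i | x_{i-1})` in log space. A
#' zero-probability transition (possible at `alpha = 0`) yields `-Inf`.
#'
#' @param model a [fit_markov_mixture()] fit.
#' @param states integer state codes of the per-assessment sequence.
#' @param component component index.
#' @return scalar log-likelihood.
#' @export
sequence_loglik <- function(model, states, component = 1L) {
  idx <- match(as.integer(states), model$alphabet)
  if (anyNA(idx)) stop("sequence contains states outside the model alphabet")
  P <- model$trans[[component]]
  from <- c(1L, idx[-length(idx)] + 1L)   # row 1 is START
  sum(log(P[cbind(from, idx)]))
}

#' Assign pool patterns to mixture components
#'
#' Argmax component log-likelihood per pattern, ties to the lowest component
#' index; identical to the E-step on the training pool.
#'
#' @param model a [fit_markov_mixture()] fit.
#' @param pool a `traj_pool` over the model alphabet.
#' @return integer component labels, one per pattern.
#' @export
assign_components <- function(model, pool) {
  X <- .transition_counts(pool$seqs, model$alphabet)
  L <- .loglik_matrix(X, lapply(model$trans, unname))
  max.col(L, ties.method = "first")
}

# --- internals ------------------------------------------------------------

# n x (S+1)*S matrix of transition counts; row-major flattening of the
# (S+1) x S transition table, row 1 = START.
.transition_counts <- function(seqs, alphabet) {
  S <- length(alphabet)
  ncell <- (S + 1L) * S
  X <- matrix(0, length(seqs), ncell)
  for (i in seq_along(seqs)) {
    idx <- match(seqs[[i]]$states, alphabet)
    if (anyNA(idx)) stop("sequence contains states outside the alphabet")
    from <- c(0L, idx[-length(idx)])          # 0 = START
    cells <- from * S + idx                   # 1-based into row-major flat
    tab <- tabulate(cells, nbins = ncell)
    X[i, ] <- tab
  }
  X
}

.smoothed_rows <- function(counts, alpha) {
  counts <- counts + alpha
  rs <- rowSums(counts)
  zero <- rs == 0
  if (any(zero)) {                            # alpha = 0 and no data: uniform
    counts[zero, ] <- 1
    rs[zero] <- ncol(counts)
  }
  counts / rs
}

.random_stochastic <- function(S) {
  m <- matrix(stats::rgamma((S + 1L) * S, shape = 1), S + 1L, S)
  m / rowSums(m)
}

# clamp log(0) to a large finite negative so 0-count cells (0 * -Inf) do not
# produce NaN in the inner product; argmax behaviour is unchanged.
.loglik_matrix <- function(X, trans) {
  k <- length(trans)
  out <- matrix(0, nrow(X), k)
  for (cl in seq_len(k)) {
    lp <- as.numeric(t(trans[[cl]]))
    lp <- log(pmax(lp, 1e-300))
    out[, cl] <- X %*% lp
  }
  out
}

#' Serialize a fitted Markov mixture to JSON and back
#'
#' Stores the alphabet, per-component transition matrices, assignments,
#' objective trace, smoothing and seed, so a fit can be reloaded and used
#' for scoring without refitting.
#'
#' @param model a [fit_markov_mixture()] fit.
#' @param path JSON file.
#' @export
write_markov_model <- function(model, path) {
  payload <- list(k = model$k, alphabet = model$alphabet,
                  trans = lapply(model$trans, unname),
                  assignment = model$assignment, loglik = model$loglik,
                  loglik_trace = model$loglik_trace,
                  iterations = model$iterations, converged = model$converged,
                  reseeds = model$reseeds, alpha = model$alpha,
                  seed = model$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_markov_model
#' @export
read_markov_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  trans <- lapply(seq_len(x$k), function(cl) {
    P <- x$trans[cl, , ]
    if (is.null(dim(P))) P <- matrix(P, length(x$alphabet) + 1L)
    dimnames(P) <- list(c("START", x$alphabet), x$alphabet)
    P
  })
  structure(list(k = x$k, alphabet = x$alphabet, trans = trans,
                 assignment = x$assignment, loglik = x$loglik,
                 loglik_trace = x$loglik_trace, iterations = x$iterations,
                 converged = x$converged, reseeds = x$reseeds,
                 alpha = x$alpha, seed = x$seed),
            class = "markov_mix")
}
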