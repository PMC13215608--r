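#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same objects;
#' 1 for identical partitions (up to renaming), ~0 for independent ones.
#' Used to score recovery of simulated phenotype structure.
#'
#' @param a,b integer label vectors of equal length.
#' @param weights optional object weights (frequency expansion).
#' @return scalar ARI.
#' @export
adjusted_rand_index <- function(a, b, weights = NULL) {
  stopifnot(length(a) == length(b))
  if (is.null(weights)) weights <- rep(1, length(a))
  tab <- tapply(weights, list(factor(a), factor(b)), sum, default = 0)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  ai <- sum(ch2(rowSums(tab)))
  bj <- sum(ch2(colSums(tab)))
  n <- sum(tab)
  expected <- ai * bj / ch2(n)
  denom <- (ai + bj) / 2 - expected
  if (denom == 0) return(1)
  (sum_ij - expected) / denom
}

# derive a per-stage seed from the pipeline seed (kept below 2^31)
.stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, phase1 = 23L, phase2 = 37L, refine = 53L,
               represent = 71L, survive = 89L)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483629)
}
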