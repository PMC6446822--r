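# Shared numerical helpers.

#' Multivariate hypergeometric draw
#'
#' Draw `k` individuals uniformly without replacement from a population with
#' the given category counts, by sequential univariate hypergeometric
#' sampling. Used for egg allocation, density regulation and dispersal, all
#' of which must conserve counts exactly and preserve category proportions
#' in expectation.
#'
#' @param counts Non-negative integer vector of category counts.
#' @param k Number to draw; must not exceed `sum(counts)`.
#' @return Integer vector of drawn counts per category, summing to `k`.
#' @export
rmvhyper <- function(counts, k) {
  counts <- as.numeric(counts)
  stopifnot(all(counts >= 0), k >= 0, k <= sum(counts))
  out <- numeric(length(counts))
  rem <- sum(counts)
  for (i in seq_along(counts)) {
    if (k <= 0) break
    if (counts[i] > 0) {
      x <- stats::rhyper(1, counts[i], rem - counts[i], k)
      out[i] <- x
      k <- k - x
    }
    rem <- rem - counts[i]
  }
  out
}

# Hypergeometric subsample of a cohort matrix down to exactly k individuals.
cohort_subsample <- function(x, k) {
  flat <- as.vector(unclass(x))
  cohort(matrix(rmvhyper(flat, k), N_GENO, 2))
}

#' Derive reproducible sub-stream seeds from a master seed
#'
#' A fixed splitting scheme: the master seed seeds R's RNG once and `n`
#' integer seeds are drawn. Each simulation unit (replicate, repetition)
#' is then seeded independently, so any unit can be reproduced in isolation.
#'
#' @param master_seed Integer master seed.
#' @param n Number of sub-seeds.
#' @return Integer vector of length `n`.
#' @export
derive_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1, n >= 0)
  if (n == 0) return(integer(0))
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(master_seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
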