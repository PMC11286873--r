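#' Exhaustive enumeration of the inheritance distribution
#'
#' Lists all `2^N` source vectors together with their exact chain
#' probabilities. Intended as an independent oracle for small `N`: the
#' closed-form marginals, the PCV dynamic program, and the ECV closed forms
#' can all be checked against sums over this table.
#'
#' @param params an [inheritance_params()]; `N` must be at most 20.
#' @return list with `vectors` (a `2^N x N` 0/1 matrix) and `prob`
#'   (numeric vector summing to 1).
#' @export
enumerate_inheritance <- function(params) {
  N <- params$n
  if (N > 20L) stop("enumeration is limited to N <= 20")
  vecs <- as.matrix(expand.grid(rep(list(0:1), N)))
  dimnames(vecs) <- NULL
  prob <- ifelse(vecs[, 1L] == 0L, params$alpha0, 1 - params$alpha0)
  if (N > 1L) {
    for (i in 2:N) {
      r <- params$r[i - 1L]
      prob <- prob * ifelse(vecs[, i] == vecs[, i - 1L], 1 - r, r)
    }
  }
  list(vectors = vecs, prob = prob)
}

#' Marginal source probabilities by enumeration
#'
#' Brute-force counterpart of [marginal_prob_zero()]: sums the probability
#' mass of all source vectors with `J_i = 0`, locus by locus.
#'
#' @inheritParams enumerate_inheritance
#' @return numeric vector of length `N`.
#' @export
marginal_prob_zero_enum <- function(params) {
  enum <- enumerate_inheritance(params)
  as.numeric(crossprod(enum$vectors == 0L, enum$prob))
}

#' Exact gamete distribution summaries by triple enumeration
#'
#' Enumerates all `2^(3N)` joint realizations of the three independent
#' inheritance vectors behind the grandchild gamete `g3` and returns the
#' exact expected desirable-allele count (the ECV) and the exact probability
#' that every allele is desirable (the PCV). Exponential work; the oracle for
#' the closed forms at small `N`.
#'
#' @param L1,L2 binary `N x 2` genotype matrices of the parents.
#' @param params an [inheritance_params()]; `N` must be at most 6.
#' @return list with numeric scalars `ecv` and `pcv`.
#' @export
cross_moments_bruteforce <- function(L1, L2, params) {
  L1 <- as.matrix(L1); L2 <- as.matrix(L2)
  N <- params$n
  if (N > 6L) stop("triple enumeration is limited to N <= 6")
  stopifnot(nrow(L1) == N, nrow(L2) == N)
  enum <- enumerate_inheritance(params)
  m <- nrow(enum$vectors)
  ecv <- 0
  pall <- 0
  for (a in seq_len(m)) {
    g1 <- gam(L1, enum$vectors[a, ])
    for (b in seq_len(m)) {
      g2 <- gam(L2, enum$vectors[b, ])
      child <- cbind(g1, g2)
      for (cc in seq_len(m)) {
        g3 <- gam(child, enum$vectors[cc, ])
        w <- enum$prob[a] * enum$prob[b] * enum$prob[cc]
        s <- sum(g3)
        ecv <- ecv + w * s
        if (s == N) pall <- pall + w
      }
    }
  }
  list(ecv = ecv, pcv = pall)
}

#' Monte-Carlo estimate of the ECV
#'
#' Averages the desirable-allele count of repeated draws of
#' [recombinant_gamete()]. Verification oracle for the closed forms; uses the
#' global RNG.
#'
#' @inheritParams recombinant_gamete
#' @param n_draws number of simulated gametes.
#' @return list with `estimate` and its standard error `se`.
#' @export
ecv_monte_carlo <- function(L1, L2, params, n_draws = 10000L) {
  counts <- vapply(seq_len(n_draws), function(i) {
    sum(recombinant_gamete(L1, L2, params))
  }, numeric(1))
  list(estimate = mean(counts), se = stats::sd(counts) / sqrt(n_draws))
}
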