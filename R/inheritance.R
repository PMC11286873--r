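#' Parameters of the meiotic inheritance distribution
#'
#' During meiosis, which of the two parental gametes contributes the allele at
#' each locus is modelled as a binary Markov chain `J` along the map: the
#' first locus comes from gamete 1 with probability `alpha0`, and adjacent
#' loci switch source with the local recombination frequency. Under Mendelian
#' segregation `alpha0 = 0.5`.
#'
#' @param r numeric vector of adjacent-locus recombination frequencies,
#'   length `N - 1`, each in \[0, 0.5\].
#' @param alpha0 probability that the first locus is copied from the first
#'   gamete column, in \[0, 1\]. Default 0.5 (Mendel's second law).
#' @return An object of class `inheritance_params`.
#' @export
inheritance_params <- function(r, alpha0 = 0.5) {
  r <- as.numeric(r)
  check_recomb(r)
  alpha0 <- as.numeric(alpha0)
  if (is.na(alpha0) || alpha0 < 0 || alpha0 > 1) stop("alpha0 must be in [0, 1]")
  structure(list(r = r, alpha0 = alpha0, n = length(r) + 1L),
            class = "inheritance_params")
}

#' Recursion underlying the marginal source probabilities
#'
#' `phi_i` is the probability that an even number of source switches occurred
#' between locus 1 and locus i, reflected into \[0, 0.5\]:
#' `phi_1 = 0`, `phi_2 = r_1`, and
#' `phi_i = r_{i-1} + (1 - 2 r_{i-1}) phi_{i-1}` for `i >= 3`.
#'
#' @param params an [inheritance_params()].
#' @return numeric vector of length `N`, all entries in \[0, 0.5\].
#' @export
phi <- function(params) {
  stopifnot(inherits(params, "inheritance_params"))
  n <- params$n
  out <- numeric(n)
  if (n >= 2L) {
    out[2L] <- params$r[1L]
    for (i in seq_len(n)[-(1:2)]) {
      out[i] <- params$r[i - 1L] + (1 - 2 * params$r[i - 1L]) * out[i - 1L]
    }
  }
  out
}

#' Marginal probability that each locus is copied from gamete 1
#'
#' Closed form `Pr(J_i = 0) = alpha0 + (1 - 2 alpha0) * phi_i(r)`. With
#' `alpha0 = 0.5` this is 0.5 at every locus regardless of `r`.
#'
#' @param params an [inheritance_params()].
#' @return numeric vector of length `N` of probabilities.
#' @export
marginal_prob_zero <- function(params) {
  params$alpha0 + (1 - 2 * params$alpha0) * phi(params)
}

#' Sample inheritance vectors from the Markov chain
#'
#' Draws `n` independent realizations of the source-indicator chain `J`:
#' `J_1 = 0` with probability `alpha0`, and each subsequent indicator flips
#' with the local recombination frequency. Uses R's global RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @param params an [inheritance_params()].
#' @param n number of vectors to draw.
#' @return an `n x N` integer matrix of 0/1 source indicators.
#' @export
sample_inheritance <- function(params, n = 1L) {
  N <- params$n
  J <- matrix(0L, n, N)
  J[, 1L] <- as.integer(stats::runif(n) >= params$alpha0)
  if (N > 1L) {
    for (i in 2:N) {
      flip <- as.integer(stats::runif(n) < params$r[i - 1L])
      J[, i] <- (J[, i - 1L] + flip) %% 2L
    }
  }
  J
}

#' Gamete function: read alleles off a genotype matrix along a source vector
#'
#' `g_i = L[i, 1]` where `J_i = 0` and `L[i, 2]` where `J_i = 1`.
#'
#' @param L binary matrix with `N` rows and 2 columns (a genotype or
#'   desirability matrix).
#' @param J binary vector of length `N` of source indicators.
#' @return integer gamete vector of length `N`.
#' @export
gam <- function(L, J) {
  L <- as.matrix(L)
  J <- as.integer(J)
  if (nrow(L) != length(J)) {
    stop(sprintf("gamete function: L has %d rows but J has length %d",
                 nrow(L), length(J)))
  }
  as.integer(L[, 1L] * (1L - J) + L[, 2L] * J)
}

#' Simulate the gamete a random grandchild would transmit
#'
#' Draws three independent inheritance vectors: `g1 = gam(L1, J1)` and
#' `g2 = gam(L2, J2)` are the gametes the two parents contribute to a child,
#' and the returned `g3 = gam([g1, g2], J3)` is the gamete that child
#' produces. The distribution of `g3` is what the ECV and PCV criteria
#' summarize.
#'
#' @param L1,L2 binary `N x 2` genotype (or desirability) matrices of the two
#'   parents.
#' @param params an [inheritance_params()] with `N` loci.
#' @return integer gamete vector of length `N`.
#' @export
recombinant_gamete <- function(L1, L2, params) {
  L1 <- as.matrix(L1); L2 <- as.matrix(L2)
  if (nrow(L1) != nrow(L2) || nrow(L1) != params$n) {
    stop("recombinant_gamete: parents and params must agree on the locus count")
  }
  J <- sample_inheritance(params, 3L)
  g1 <- gam(L1, J[1L, ])
  g2 <- gam(L2, J[2L, ])
  gam(cbind(g1, g2), J[3L, ])
}

#' Count undesirable alleles in a gamete
#'
#' The loss of a gamete is `N - sum(g)`: 0 iff every allele is desirable,
#' `N` iff none is. The ECV equals `N - E(loss)`.
#'
#' @param g3 binary gamete vector.
#' @return integer in \[0, length(g3)\].
#' @export
loss_count <- function(g3) length(g3) - as.integer(sum(g3))

#' Predicted cross value (PCV) by exact dynamic programming
#'
#' Probability that the gamete `g3` produced by a random child of the two
#' parents carries the desirable allele at every locus. Computed exactly by a
#' forward pass over the 8-state joint chain `(J1_i, J2_i, J3_i)` — the three
#' inheritance chains are independent, so their joint is Markov with
#' locus-wise transition probabilities built from the recombination vector.
#' Work is linear in `N`.
#'
#' If any locus carries no desirable allele in either parent, the PCV is 0
#' regardless of the rest of the genome — the property that makes PCV
#' unsuitable for polygenic, non-introgression targets.
#'
#' @inheritParams recombinant_gamete
#' @return probability in \[0, 1\].
#' @export
pcv <- function(L1, L2, params) {
  L1 <- as.matrix(L1); L2 <- as.matrix(L2)
  if (nrow(L1) != nrow(L2) || nrow(L1) != params$n) {
    stop("pcv: parents and params must agree on the locus count")
  }
  N <- params$n
  a0 <- params$alpha0
  # state s = 1..8 encodes (j1, j2, j3) with j1 the least significant bit
  states <- as.matrix(expand.grid(j1 = 0:1, j2 = 0:1, j3 = 0:1))
  start <- apply(states, 1L, function(s) {
    prod(ifelse(s == 0L, a0, 1 - a0))
  })
  # admissibility of a state at locus i: the resulting g3 allele is desirable
  g3_of_state <- function(i) {
    g1 <- ifelse(states[, "j1"] == 0L, L1[i, 1L], L1[i, 2L])
    g2 <- ifelse(states[, "j2"] == 0L, L2[i, 1L], L2[i, 2L])
    ifelse(states[, "j3"] == 0L, g1, g2)
  }
  # Hamming distance between joint states: d chains flip, 3 - d stay
  ham <- outer(seq_len(8L), seq_len(8L), Vectorize(function(s, t) {
    sum(states[s, ] != states[t, ])
  }))
  p <- start * (g3_of_state(1L) == 1L)
  if (N > 1L) {
    for (i in 2:N) {
      r <- params$r[i - 1L]
      trans <- r^ham * (1 - r)^(3L - ham)
      p <- as.numeric(p %*% trans) * (g3_of_state(i) == 1L)
    }
  }
  sum(p)
}
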