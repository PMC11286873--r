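#' Expected cross value under Mendelian segregation
#'
#' The ECV of a parent pair is the expected number of desirable alleles in
#' the gamete `g3` that a random child of the pair would transmit. Under
#' Mendel's second law (`alpha0 = 0.5`) it has the closed form
#' `0.25 * sum_i (L1[i,1] + L1[i,2] + L2[i,1] + L2[i,2])` — one quarter of
#' the total desirable-allele count of the two parents, independent of the
#' recombination frequencies. The value is computed as an integer scaled once
#' by 0.25, so it is an exact quarter-integer.
#'
#' @param view1,view2 binary `N x 2` desirability matrices of the two
#'   parents, e.g. from [trait_view()].
#' @return numeric ECV in \[0, N\].
#' @export
ecv_mendel <- function(view1, view2) {
  view1 <- as.matrix(view1); view2 <- as.matrix(view2)
  if (nrow(view1) != nrow(view2)) {
    stop(sprintf("ecv_mendel: parents disagree on locus count (%d vs %d)",
                 nrow(view1), nrow(view2)))
  }
  0.25 * (as.integer(sum(view1)) + as.integer(sum(view2)))
}

#' Expected cross value without Mendel's second law
#'
#' General closed form of the ECV for an arbitrary start probability
#' `alpha0`: with `beta_i = 1 - alpha0 + (2 alpha0 - 1) phi_i(r)` (the
#' marginal probability that locus i is copied from the second gamete
#' column),
#' `ECV = sum_i ( L1[i,1] + beta_i (L1[i,2] - 2 L1[i,1] + L2[i,1])
#'   + beta_i^2 (L2[i,2] + L1[i,1] - L1[i,2] - L2[i,1]) )`.
#' At `alpha0 = 0.5` this reduces exactly to [ecv_mendel()].
#'
#' @inheritParams ecv_mendel
#' @param params an [inheritance_params()] matching the locus count.
#' @return numeric ECV in \[0, N\].
#' @export
ecv_general <- function(view1, view2, params) {
  view1 <- as.matrix(view1); view2 <- as.matrix(view2)
  if (nrow(view1) != nrow(view2) || nrow(view1) != params$n) {
    stop("ecv_general: parents and params must agree on the locus count")
  }
  beta <- 1 - params$alpha0 + (2 * params$alpha0 - 1) * phi(params)
  sum(view1[, 1L] +
        beta * (view1[, 2L] - 2 * view1[, 1L] + view2[, 1L]) +
        beta^2 * (view2[, 2L] + view1[, 1L] - view1[, 2L] - view2[, 1L]))
}

#' Per-trait ECV of a candidate parent pair
#'
#' Applies the Mendelian closed form trait by trait, using each trait's
#' desirability orientation. Trait `l`'s value is bounded by its locus count
#' `N_l`.
#'
#' @param pop a [haplotype_population()].
#' @param arch a [trait_architecture()].
#' @param k1,k2 individual indices or ids of the two parents.
#' @param allow_self_cross permit `k1 == k2` (off by default).
#' @return named numeric vector of ECV values, one per trait.
#' @export
ecv_all_traits <- function(pop, arch, k1, k2, allow_self_cross = FALSE) {
  i1 <- resolve_individuals(pop, k1)
  i2 <- resolve_individuals(pop, k2)
  if (i1 == i2 && !allow_self_cross) {
    stop("self-cross requested but allow_self_cross is FALSE")
  }
  out <- vapply(arch$trait_ids, function(tr) {
    ecv_mendel(trait_view(pop, arch, i1, tr), trait_view(pop, arch, i2, tr))
  }, numeric(1))
  names(out) <- arch$trait_ids
  out
}
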