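`%||%` <- function(x, y) if (is.null(x)) y else x

# Shared generators for randomized tests. All callers seed the global RNG
# themselves so every test is reproducible in isolation.

# A single-chromosome map with the given locus classes and uniform random
# adjacent recombination frequencies in [0, 0.5].
make_test_map <- function(N, classes = rep("qtl", N), r = NULL) {
  if (is.null(r)) r <- stats::runif(max(N - 1L, 0L), 0, 0.5)
  genetic_map(paste0("L", seq_len(N)), rep(1L, N), classes, r)
}

# A population of K individuals with i.i.d. fair-coin alleles.
make_test_pop <- function(K, map) {
  N <- n_loci(map)
  haplotype_population(
    matrix(stats::rbinom(K * N, 1L, 0.5), K, N),
    matrix(stats::rbinom(K * N, 1L, 0.5), K, N),
    sprintf("ind%03d", seq_len(K)), map
  )
}

# An architecture assigning every qtl locus of the map to each of n_traits
# traits, with random desirable-allele orientation and unit effects.
make_test_arch <- function(map, n_traits = 1L) {
  qtl <- which(map$locus_class == "qtl")
  df <- do.call(rbind, lapply(seq_len(n_traits), function(l) {
    data.frame(trait_id = paste0("trait", l), locus_id = map$locus_id[qtl],
               desirable_allele = stats::rbinom(length(qtl), 1L, 0.5),
               effect_size = 1, stringsAsFactors = FALSE)
  }))
  trait_architecture(df, map)
}

# A random binary N x 2 desirability/genotype matrix.
make_test_view <- function(N) {
  matrix(stats::rbinom(2L * N, 1L, 0.5), N, 2L)
}
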