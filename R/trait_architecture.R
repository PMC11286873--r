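#' Trait architecture: loci, desirable-allele orientation, effect sizes
#'
#' Defines, for each target trait, which loci of the map affect it, which
#' physical allele state (0 or 1) counts as desirable, and the additive effect
#' per desirable-allele copy. A locus may belong to several traits
#' (pleiotropy); antagonistic pleiotropy is expressed by giving the same
#' physical locus opposite desirable-allele orientations in two traits.
#'
#' @param df data frame with columns `trait_id`, `locus_id`,
#'   `desirable_allele` (0/1) and `effect_size` (phenotype units per
#'   desirable-allele copy).
#' @param map the [genetic_map()] the locus ids refer to; only loci of class
#'   `"qtl"` may appear in an architecture.
#'
#' @return An object of class `trait_architecture`: per trait, integer locus
#'   indices into the map, the desirable-allele orientation and effects.
#' @export
trait_architecture <- function(df, map) {
  need <- c("trait_id", "locus_id", "desirable_allele", "effect_size")
  if (!all(need %in% names(df))) {
    stop(sprintf("trait architecture needs columns: %s", paste(need, collapse = ", ")))
  }
  if (!all(df$desirable_allele %in% c(0, 1))) stop("desirable_allele must be 0 or 1")
  idx <- match(as.character(df$locus_id), map$locus_id)
  if (anyNA(idx)) {
    stop(sprintf("unknown locus id in trait architecture: %s",
                 df$locus_id[is.na(idx)][1L]))
  }
  if (any(map$locus_class[idx] != "qtl")) {
    stop("trait loci must have locus_class 'qtl' in the map")
  }
  trait_ids <- unique(as.character(df$trait_id))
  traits <- lapply(trait_ids, function(tr) {
    rows <- which(df$trait_id == tr)
    if (anyDuplicated(idx[rows])) {
      stop(sprintf("trait %s lists a locus more than once", tr))
    }
    o <- order(idx[rows])  # keep trait loci in map order
    list(loci = idx[rows][o],
         desirable = as.integer(df$desirable_allele[rows][o]),
         effect = as.numeric(df$effect_size[rows][o]))
  })
  names(traits) <- trait_ids
  structure(list(traits = traits, trait_ids = trait_ids),
            class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  sizes <- vapply(x$traits, function(t) length(t$loci), integer(1))
  cat(sprintf("<trait_architecture> %d trait(s): %s\n", length(x$traits),
              paste(sprintf("%s (%d loci)", x$trait_ids, sizes), collapse = ", ")))
  invisible(x)
}

#' Number of traits in an architecture
#' @param arch a [trait_architecture()].
#' @return integer count.
#' @export
n_traits <- function(arch) length(arch$traits)

resolve_trait <- function(arch, trait) {
  if (is.character(trait)) {
    if (!trait %in% arch$trait_ids) stop(sprintf("unknown trait id: %s", trait))
    trait
  } else {
    trait <- as.integer(trait)
    if (is.na(trait) || trait < 1L || trait > n_traits(arch)) {
      stop("trait index out of range")
    }
    arch$trait_ids[trait]
  }
}

#' Per-trait genotype matrix of one individual
#'
#' The trait genotype matrix recodes an individual's physical alleles at the
#' trait loci into desirability: entry (i, j) is 1 iff gamete j carries the
#' desirable allele at the i-th trait locus. This is the matrix the ECV and
#' PCV criteria operate on.
#'
#' @param pop a [haplotype_population()].
#' @param arch a [trait_architecture()] on the same map.
#' @param k individual index or id.
#' @param trait trait index or id.
#' @return An `N_l x 2` binary integer matrix (N_l = number of trait loci).
#' @export
trait_view <- function(pop, arch, k, trait) {
  k <- resolve_individuals(pop, k)
  tr <- arch$traits[[resolve_trait(arch, trait)]]
  cbind(as.integer(pop$h1[k, tr$loci] == tr$desirable),
        as.integer(pop$h2[k, tr$loci] == tr$desirable))
}

#' Count desirable alleles in a trait genotype matrix
#'
#' Sum of all entries of the desirability matrix: the number of desirable
#' allele copies the individual carries at the trait loci, in \[0, 2 N_l\].
#'
#' @param view a binary `N_l x 2` matrix, e.g. from [trait_view()].
#' @return integer count.
#' @export
allele_count <- function(view) as.integer(sum(view))

#' Desirable-allele dosage for all individuals at one trait
#'
#' Vectorized companion of [trait_view()]: for each individual the number of
#' desirable allele copies summed over the trait's loci (0..2 N_l). The ECV of
#' a pair under Mendelian segregation is 0.25 times the sum of the two mates'
#' dosages, which is what makes pair selection separable.
#'
#' @inheritParams trait_view
#' @return integer vector of length `n_individuals(pop)`.
#' @export
desirable_count <- function(pop, arch, trait) {
  tr <- arch$traits[[resolve_trait(arch, trait)]]
  des <- matrix(tr$desirable, nrow = n_individuals(pop), ncol = length(tr$loci),
                byrow = TRUE)
  as.integer(rowSums(pop$h1[, tr$loci, drop = FALSE] == des) +
             rowSums(pop$h2[, tr$loci, drop = FALSE] == des))
}

#' Per-locus desirable-allele frequency for one trait
#'
#' @inheritParams trait_view
#' @return numeric vector over the trait's loci: the fraction of all `2K`
#'   allele copies that are desirable.
#' @export
desirable_frequency <- function(pop, arch, trait) {
  tr <- arch$traits[[resolve_trait(arch, trait)]]
  des <- matrix(tr$desirable, nrow = n_individuals(pop), ncol = length(tr$loci),
                byrow = TRUE)
  (colSums(pop$h1[, tr$loci, drop = FALSE] == des) +
   colSums(pop$h2[, tr$loci, drop = FALSE] == des)) / (2 * n_individuals(pop))
}

#' Read a trait architecture from TSV
#'
#' Header: `trait_id  locus_id  desirable_allele  effect_size`.
#'
#' @param path path to the TSV file.
#' @param map the [genetic_map()] the locus ids refer to.
#' @return A [trait_architecture()].
#' @export
read_trait_architecture <- function(path, map) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  trait_architecture(df, map)
}

#' Write a trait architecture to TSV
#' @param arch a [trait_architecture()].
#' @param map the [genetic_map()] used to resolve locus ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trait_architecture <- function(arch, map, path) {
  rows <- do.call(rbind, lapply(arch$trait_ids, function(id) {
    tr <- arch$traits[[id]]
    data.frame(trait_id = id, locus_id = map$locus_id[tr$loci],
               desirable_allele = tr$desirable, effect_size = tr$effect,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
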