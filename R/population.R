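#' Haplotype-resolved population
#'
#' Stores phased biallelic genotypes for `K` individuals over the loci of a
#' genetic map. Alleles are kept once, in physical 0/1 coding; which physical
#' state counts as "desirable" is a per-trait orientation layer supplied by a
#' [trait_architecture()]. The two haplotypes of an individual correspond to
#' the two parental gametes that formed it.
#'
#' @param h1,h2 integer matrices, `K x N` with entries in \{0, 1\}; row `k`
#'   of `h1` (`h2`) is the first (second) gamete of individual `k`.
#' @param individual_id character vector of unique ids, length `K`.
#' @param map a [genetic_map()] with `N` loci, defining locus order.
#'
#' @return An object of class `haplotype_population`.
#' @export
haplotype_population <- function(h1, h2, individual_id, map) {
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  if (!identical(dim(h1), dim(h2))) stop("h1 and h2 must have identical dimensions")
  if (ncol(h1) != n_loci(map)) {
    stop(sprintf("haplotypes have %d loci but the map has %d", ncol(h1), n_loci(map)))
  }
  if (anyNA(h1) || anyNA(h2) || !all(h1 %in% c(0L, 1L)) || !all(h2 %in% c(0L, 1L))) {
    stop("allele values must be 0 or 1")
  }
  individual_id <- as.character(individual_id)
  if (length(individual_id) != nrow(h1)) stop("one individual_id per row required")
  if (anyDuplicated(individual_id)) stop("duplicated individual_id")
  dimnames(h1) <- dimnames(h2) <- NULL
  structure(
    list(h1 = h1, h2 = h2, individual_id = individual_id, map = map),
    class = "haplotype_population"
  )
}

#' @export
print.haplotype_population <- function(x, ...) {
  cat(sprintf("<haplotype_population> %d individuals x %d loci\n",
              nrow(x$h1), ncol(x$h1)))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop a [haplotype_population()].
#' @return integer count.
#' @export
n_individuals <- function(pop) nrow(pop$h1)

#' Subset a population by individual
#' @param pop a [haplotype_population()].
#' @param idx integer indices or character ids of individuals to keep.
#' @return A [haplotype_population()] restricted to the chosen individuals.
#' @export
subset_population <- function(pop, idx) {
  idx <- resolve_individuals(pop, idx)
  haplotype_population(pop$h1[idx, , drop = FALSE], pop$h2[idx, , drop = FALSE],
                       pop$individual_id[idx], pop$map)
}

resolve_individuals <- function(pop, ids) {
  if (is.character(ids)) {
    idx <- match(ids, pop$individual_id)
    if (anyNA(idx)) stop(sprintf("unknown individual id: %s", ids[is.na(idx)][1L]))
    idx
  } else {
    idx <- as.integer(ids)
    if (anyNA(idx) || any(idx < 1L) || any(idx > n_individuals(pop))) {
      stop("individual index out of range")
    }
    idx
  }
}

#' Read a haplotype population from TSV files
#'
#' The haplotype file has header
#' `individual_id  haplotype  <locus_id_1> ... <locus_id_N>` with two rows per
#' individual (`haplotype` 1 and 2) and cells in \{0, 1\}. Locus order is
#' taken from the map file; the haplotype file must list loci in map order.
#'
#' @param haplotype_file path to the haplotype TSV.
#' @param map_file path to the genetic-map TSV (see [read_genetic_map()]).
#' @return A [haplotype_population()].
#' @export
read_population <- function(haplotype_file, map_file) {
  map <- read_genetic_map(map_file)
  df <- utils::read.delim(haplotype_file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("individual_id", "haplotype") %in% names(df))) {
    stop(sprintf("%s must start with columns individual_id, haplotype", haplotype_file))
  }
  loci <- setdiff(names(df), c("individual_id", "haplotype"))
  if (!identical(loci, map$locus_id)) {
    stop(sprintf("%s: locus columns do not match the map (same loci, map order, required)",
                 haplotype_file))
  }
  alle <- as.matrix(df[, loci, drop = FALSE])
  bad <- which(!(alle %in% c(0, 1)))
  if (length(bad)) {
    stop(sprintf("%s line %d: non-binary allele value '%s'",
                 haplotype_file, ((bad[1L] - 1L) %% nrow(df)) + 2L, alle[bad[1L]]))
  }
  ids <- unique(df$individual_id)
  h1 <- matrix(0L, length(ids), length(loci))
  h2 <- matrix(0L, length(ids), length(loci))
  for (k in seq_along(ids)) {
    rows <- which(df$individual_id == ids[k])
    if (length(rows) != 2L || !setequal(df$haplotype[rows], c(1, 2))) {
      stop(sprintf("%s: individual %s must have exactly haplotype rows 1 and 2",
                   haplotype_file, ids[k]))
    }
    h1[k, ] <- as.integer(alle[rows[df$haplotype[rows] == 1], ])
    h2[k, ] <- as.integer(alle[rows[df$haplotype[rows] == 2], ])
  }
  haplotype_population(h1, h2, ids, map)
}

#' Write a haplotype population to TSV
#'
#' Inverse of [read_population()]; `read_population(write_population(...))`
#' round-trips bit-exactly.
#'
#' @param pop a [haplotype_population()].
#' @param haplotype_file output path for the haplotype table.
#' @param map_file optional output path for the map (omit to skip).
#' @return `haplotype_file`, invisibly.
#' @export
write_population <- function(pop, haplotype_file, map_file = NULL) {
  K <- n_individuals(pop)
  out <- data.frame(
    individual_id = rep(pop$individual_id, each = 2L),
    haplotype = rep(c(1L, 2L), times = K),
    stringsAsFactors = FALSE
  )
  alle <- matrix(0L, 2L * K, ncol(pop$h1))
  alle[seq(1L, 2L * K, by = 2L), ] <- pop$h1
  alle[seq(2L, 2L * K, by = 2L), ] <- pop$h2
  colnames(alle) <- pop$map$locus_id
  utils::write.table(cbind(out, alle), haplotype_file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(map_file)) write_genetic_map(pop$map, map_file)
  invisible(haplotype_file)
}
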