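#' Genetic map with adjacent-locus recombination frequencies
#'
#' A genetic map fixes the total order of loci, their chromosome assignment,
#' their class (trait locus vs. neutral marker), and the recombination
#' frequency between each pair of adjacent loci. Recombination frequencies
#' live in \[0, 0.5\]; a value of 0.5 corresponds to independent assortment,
#' which is how chromosome boundaries are encoded (the `r` entry spanning two
#' chromosomes must be exactly 0.5).
#'
#' @param locus_id character vector of unique locus identifiers, in map order.
#' @param chromosome integer vector, one entry per locus, non-decreasing
#'   blocks (all loci of a chromosome are contiguous in map order).
#' @param locus_class character vector with entries `"qtl"` or `"marker"`.
#' @param r_adjacent numeric vector of length `length(locus_id) - 1` with
#'   recombination frequencies between consecutive loci, each in \[0, 0.5\].
#'   May be length 0 for a single-locus map.
#'
#' @return An object of class `genetic_map`: a list with the validated fields.
#' @export
genetic_map <- function(locus_id, chromosome, locus_class, r_adjacent) {
  locus_id <- as.character(locus_id)
  n <- length(locus_id)
  if (n < 1L) stop("a genetic map needs at least one locus")
  if (anyDuplicated(locus_id)) stop("duplicated locus_id in genetic map")
  chromosome <- as.integer(chromosome)
  if (length(chromosome) != n) stop("chromosome must have one entry per locus")
  locus_class <- as.character(locus_class)
  if (length(locus_class) != n || !all(locus_class %in% c("qtl", "marker"))) {
    stop("locus_class must be 'qtl' or 'marker' for every locus")
  }
  r_adjacent <- as.numeric(r_adjacent)
  if (length(r_adjacent) != n - 1L) {
    stop("r_adjacent must have length(locus_id) - 1 entries")
  }
  check_recomb(r_adjacent)
  # a chromosome change forces independent assortment
  if (n > 1L) {
    brk <- which(diff(chromosome) != 0L)
    if (any(r_adjacent[brk] != 0.5)) {
      stop("r_adjacent across a chromosome boundary must equal 0.5")
    }
  }
  structure(
    list(locus_id = locus_id, chromosome = chromosome,
         locus_class = locus_class, r_adjacent = r_adjacent),
    class = "genetic_map"
  )
}

check_recomb <- function(r) {
  if (length(r) && (anyNA(r) || any(r < 0) || any(r > 0.5))) {
    bad <- which(is.na(r) | r < 0 | r > 0.5)[1L]
    stop(sprintf("recombination frequency out of [0, 0.5] at position %d (r = %s)",
                 bad, format(r[bad])))
  }
  invisible(r)
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %d loci (%d qtl, %d marker) on %d chromosome(s)\n",
              length(x$locus_id), sum(x$locus_class == "qtl"),
              sum(x$locus_class == "marker"), length(unique(x$chromosome))))
  invisible(x)
}

#' Number of loci in a genetic map
#' @param map a [genetic_map()] object.
#' @return integer count of loci.
#' @export
n_loci <- function(map) length(map$locus_id)

#' Read a genetic map from TSV
#'
#' Expects a header `locus_id  chromosome  locus_class  r_to_next`. The
#' `r_to_next` column holds the recombination frequency between each locus and
#' the next one in file order; the entry on the final line is ignored (by
#' convention it is written as 0.5).
#'
#' @param path path to the TSV file.
#' @return A [genetic_map()] object.
#' @export
read_genetic_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("locus_id", "chromosome", "locus_class", "r_to_next")
  if (!all(need %in% names(df))) {
    stop(sprintf("genetic map file %s must have columns: %s",
                 path, paste(need, collapse = ", ")))
  }
  n <- nrow(df)
  r <- as.numeric(df$r_to_next)
  if (n > 1L && (anyNA(r[-n]) || any(r[-n] < 0) || any(r[-n] > 0.5))) {
    bad <- which(is.na(r[-n]) | r[-n] < 0 | r[-n] > 0.5)[1L]
    stop(sprintf("%s line %d: r_to_next out of [0, 0.5]", path, bad + 1L))
  }
  genetic_map(df$locus_id, df$chromosome, df$locus_class,
              if (n > 1L) r[-n] else numeric(0))
}

#' Write a genetic map to TSV
#' @param map a [genetic_map()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genetic_map <- function(map, path) {
  df <- data.frame(locus_id = map$locus_id, chromosome = map$chromosome,
                   locus_class = map$locus_class,
                   r_to_next = c(map$r_adjacent, 0.5),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
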