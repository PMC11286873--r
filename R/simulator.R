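#' Pair counts for the benchmark selection-intensity scenarios
#'
#' Number of parental pairs selected in each of the four selection rounds
#' (from the initial population and from generations one, two and three).
#' Scenario A is high selection intensity (50, 10, 3, 3), scenario B
#' intermediate (50, 10, 5, 5), scenario C reduced (50, 25, 5, 5). With 100
#' progeny per cross, scenario B yields population sizes 5000, 1000, 500 and
#' 500 over generations one to four.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @return integer vector of pairs per selection round.
#' @export
scenario_pairs <- function(scenario = c("B", "A", "C")) {
  switch(match.arg(scenario),
         A = c(50L, 10L, 3L, 3L),
         B = c(50L, 10L, 5L, 5L),
         C = c(50L, 25L, 5L, 5L))
}

#' Simulation configuration for the breeding-program benchmark
#'
#' Defaults reproduce the benchmark conditions: an initial population of
#' 10,000 individuals with allele frequency 0.5 at every locus, 200 trait
#' loci plus 100 neutral markers, trait architectures of 40/10/70 loci with
#' 20 antagonistic pleiotropic loci shared between Traits 1 and 3, 100
#' progeny per cross, and four rounds of selection.
#'
#' @param scenario selection-intensity scenario, see [scenario_pairs()].
#' @param mode `"multi"` for lexicographic multi-trait selection over all
#'   three traits, `"single"` for selection on Trait 1 only.
#' @param K0 initial population size.
#' @param n_qtl,n_markers number of trait loci and neutral markers.
#' @param trait_sizes loci per trait (Trait 1, 2, 3).
#' @param n_antagonistic loci shared by Traits 1 and 3 with opposite
#'   desirable-allele orientation.
#' @param progeny_per_cross progeny simulated per selected pair.
#' @param pairs_per_generation pairs selected per round (defaults to the
#'   scenario's counts); its length sets the number of generations.
#' @param heritability narrow-sense heritability per trait (recycled).
#' @param chromosomes number of chromosomes in the generated map.
#' @param r_within recombination frequency between adjacent loci within a
#'   chromosome (0.5 is placed across chromosome boundaries).
#' @param epsilon genomic-relationship cap for ECV selection.
#' @param trait_priority trait ids in decreasing order of importance for
#'   lexicographic multi-trait selection. The default puts the polygenic
#'   yield-like Trait 3 first, Trait 1 second and the oligogenic Trait 2
#'   last: the primary breeding objective is optimized first and the
#'   tolerance schedule trades a little of it for the later objectives.
#' @param tolerances `M x T` matrix of lexicographic degradation tolerances
#'   (priority position by selection round). The default uses 0.17 for the
#'   first objective in the first round then 0.05, and 0 for the second
#'   objective except 0.05 in the last round; the last objective always 0.
#' @param replications number of independent simulation replications.
#' @param prescreen_per_trait candidate prescreen size per trait for large
#'   populations (see the methods vignette); `Inf` disables prescreening.
#' @param g_reference allele frequencies used to center the VanRaden
#'   relationship matrix during selection: `"current"` (default) recomputes
#'   observed frequencies in each generation, `"base"` fixes them at the
#'   initial generation so relatedness is measured against the founder
#'   population.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(scenario = "B", mode = c("multi", "single"),
                       K0 = 10000L, n_qtl = 200L, n_markers = 100L,
                       trait_sizes = c(40L, 10L, 70L), n_antagonistic = 20L,
                       progeny_per_cross = 100L,
                       pairs_per_generation = scenario_pairs(scenario),
                       heritability = 0.5, chromosomes = 10L, r_within = 0.1,
                       epsilon = 0.20,
                       trait_priority = c("trait3", "trait1", "trait2"),
                       tolerances = NULL,
                       replications = 30L, prescreen_per_trait = 250L,
                       g_reference = c("current", "base")) {
  mode <- match.arg(mode)
  g_reference <- match.arg(g_reference)
  n_traits <- length(trait_sizes)
  if (trait_sizes[1] < n_antagonistic) {
    stop("n_antagonistic cannot exceed the Trait 1 locus count")
  }
  if (sum(trait_sizes) - n_antagonistic > n_qtl) {
    stop("trait architectures do not fit into n_qtl loci")
  }
  T_gen <- length(pairs_per_generation)
  if (is.null(tolerances)) {
    tolerances <- matrix(0, n_traits, T_gen)
    tolerances[1, ] <- c(0.17, rep(0.05, T_gen - 1L))
    if (n_traits >= 2L && T_gen >= 1L) tolerances[2, T_gen] <- 0.05
  }
  if (!all(dim(tolerances) == c(n_traits, T_gen))) {
    stop("tolerances must be an n_traits x n_generations matrix")
  }
  heritability <- rep_len(heritability, n_traits)
  if (any(heritability <= 0) || any(heritability > 1)) {
    stop("heritability must lie in (0, 1]")
  }
  structure(list(scenario = scenario, mode = mode, K0 = as.integer(K0),
                 n_qtl = as.integer(n_qtl), n_markers = as.integer(n_markers),
                 trait_sizes = as.integer(trait_sizes),
                 n_antagonistic = as.integer(n_antagonistic),
                 progeny_per_cross = as.integer(progeny_per_cross),
                 pairs_per_generation = as.integer(pairs_per_generation),
                 heritability = heritability,
                 chromosomes = as.integer(chromosomes), r_within = r_within,
                 epsilon = epsilon, trait_priority = trait_priority,
                 tolerances = tolerances,
                 replications = as.integer(replications),
                 prescreen_per_trait = prescreen_per_trait,
                 g_reference = g_reference),
            class = "sim_config")
}

# Genome layout: loci split as evenly as possible over chromosomes, class
# pattern (qtl, qtl, marker) repeated so markers interleave with trait loci
# and stay linked to them.
build_sim_map <- function(config) {
  total <- config$n_qtl + config$n_markers
  cls <- rep(c("qtl", "qtl", "marker"), length.out = total)
  # correct the quotas if the 2:1 pattern does not divide the counts
  nq <- sum(cls == "qtl")
  if (nq > config$n_qtl) {
    cls[utils::tail(which(cls == "qtl"), nq - config$n_qtl)] <- "marker"
  } else if (nq < config$n_qtl) {
    cls[utils::tail(which(cls == "marker"), config$n_qtl - nq)] <- "qtl"
  }
  sizes <- rep(total %/% config$chromosomes, config$chromosomes)
  extra <- total - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  chrom <- rep(seq_len(config$chromosomes), times = sizes)
  r <- rep(config$r_within, total - 1L)
  r[which(diff(chrom) != 0L)] <- 0.5
  genetic_map(sprintf("c%02d_p%03d", chrom, sequence(sizes)),
              chrom, cls, r)
}

build_sim_architecture <- function(config, map) {
  qtl <- which(map$locus_class == "qtl")
  s <- config$trait_sizes
  t1 <- qtl[seq_len(s[1])]
  t2 <- qtl[s[1] + seq_len(s[2])]
  antag <- sort(sample(t1, config$n_antagonistic))
  t3_private <- qtl[s[1] + s[2] + seq_len(s[3] - config$n_antagonistic)]
  t3 <- sort(c(t3_private, antag))
  df <- rbind(
    data.frame(trait_id = "trait1", locus_id = map$locus_id[t1],
               desirable_allele = 1L, effect_size = 1),
    data.frame(trait_id = "trait2", locus_id = map$locus_id[t2],
               desirable_allele = 1L, effect_size = 1),
    data.frame(trait_id = "trait3", locus_id = map$locus_id[t3],
               desirable_allele = ifelse(t3 %in% antag, 0L, 1L),
               effect_size = 1)
  )
  trait_architecture(df, map)
}

#' Generate the initial breeding population
#'
#' Every allele copy is an independent fair coin, so each locus has allele
#' frequency 0.5 up to binomial noise, and linkage disequilibrium is absent
#' at the start. The trait architecture is built alongside: Trait 1 takes
#' the first block of trait loci, Trait 2 the next, and Trait 3 combines its
#' private loci with `n_antagonistic` loci drawn at random from Trait 1's
#' set, oriented oppositely (the allele that raises Trait 1 lowers Trait 3).
#' Uses the global RNG; seed with [set.seed()].
#'
#' @param config a [sim_config()].
#' @return list with `pop` (a [haplotype_population()]) and `arch`
#'   (a [trait_architecture()]).
#' @export
generate_initial_population <- function(config = sim_config()) {
  map <- build_sim_map(config)
  arch <- build_sim_architecture(config, map)
  N <- n_loci(map)
  K <- config$K0
  h1 <- matrix(stats::rbinom(K * N, 1L, 0.5), K, N)
  h2 <- matrix(stats::rbinom(K * N, 1L, 0.5), K, N)
  pop <- haplotype_population(h1, h2, sprintf("g0_%05d", seq_len(K)), map)
  list(pop = pop, arch = arch)
}

#' Additive phenotypes with environmental noise
#'
#' Phenotype of trait `l` is the sum over its loci of effect times
#' desirable-allele dosage plus Gaussian noise. The noise standard deviation
#' is fixed from the initial-population genetic variance (allele frequency
#' 0.5 at every locus, so the variance of a locus dosage is 0.5):
#' `sigma_e^2 = 0.5 sum(effect^2) (1 - h2) / h2`, which makes the realized
#' heritability in the base generation equal the configured one and keeps
#' the environment consistent across generations. `h2 = 1` gives phenotypes
#' identical to genetic values.
#'
#' @param pop a [haplotype_population()].
#' @param arch a [trait_architecture()].
#' @param heritability per-trait heritability in (0, 1] (recycled).
#' @return numeric `K x M` phenotype matrix with the genetic-value matrix
#'   attached as attribute `"genetic_value"`.
#' @export
simulate_phenotypes <- function(pop, arch, heritability = 0.5) {
  M <- n_traits(arch)
  h2 <- rep_len(heritability, M)
  K <- n_individuals(pop)
  geno <- matrix(0, K, M, dimnames = list(NULL, arch$trait_ids))
  pheno <- geno
  for (l in seq_len(M)) {
    tr <- arch$traits[[l]]
    des <- matrix(tr$desirable, K, length(tr$loci), byrow = TRUE)
    dos <- (pop$h1[, tr$loci, drop = FALSE] == des) +
      (pop$h2[, tr$loci, drop = FALSE] == des)
    geno[, l] <- as.numeric(dos %*% tr$effect)
    var_g0 <- 0.5 * sum(tr$effect^2)
    sigma_e <- sqrt(var_g0 * (1 - h2[l]) / h2[l])
    pheno[, l] <- geno[, l] + stats::rnorm(K, 0, sigma_e)
  }
  attr(pheno, "genetic_value") <- geno
  pheno
}

# One round of meiosis for a vector of parent indices: returns the gametes
# (one per parent entry) as an n x N matrix. The source chain runs over the
# whole map with alpha0 = 0.5.
meiosis_batch <- function(pop, parents) {
  params <- inheritance_params(pop$map$r_adjacent, 0.5)
  J <- sample_inheritance(params, length(parents))
  pop$h1[parents, , drop = FALSE] * (1L - J) +
    pop$h2[parents, , drop = FALSE] * J
}

#' Advance a population by one generation of crossing
#'
#' Each pair in the plan produces `progeny_per_cross` offspring; each
#' offspring receives one independently recombined gamete from each parent,
#' drawn from the inheritance chain over the full map with `alpha0 = 0.5`.
#'
#' @param pop a [haplotype_population()].
#' @param plan a crossing plan with `parent1` and `parent2` index columns
#'   referring to `pop`.
#' @param config a [sim_config()] (for `progeny_per_cross`).
#' @param generation integer label used in the offspring ids.
#' @return the offspring [haplotype_population()], of size
#'   `nrow(plan) * progeny_per_cross`.
#' @export
advance_generation <- function(pop, plan, config, generation = 1L) {
  if (!NROW(plan)) stop("empty crossing plan")
  n_off <- config$progeny_per_cross
  p1 <- rep(plan$parent1, each = n_off)
  p2 <- rep(plan$parent2, each = n_off)
  h1 <- meiosis_batch(pop, p1)
  h2 <- meiosis_batch(pop, p2)
  haplotype_population(h1, h2,
                       sprintf("g%d_%05d", generation, seq_along(p1)), pop$map)
}

# Candidate prescreen for large populations: the ECV objective is additive
# in the mates' desirable-allele counts, so optimal pairs are drawn from the
# top-count individuals; the union of per-trait top lists (with generous
# margin over the number of pairs needed) is kept and the relationship
# matrix computed on it only.
prescreen_candidates <- function(pop, arch, per_trait) {
  K <- n_individuals(pop)
  if (!is.finite(per_trait) || K <= 3 * per_trait) return(seq_len(K))
  sort(unique(unlist(lapply(arch$trait_ids, function(tr) {
    utils::head(order(-desirable_count(pop, arch, tr), seq_len(K)), per_trait)
  }))))
}

select_plan_ecv <- function(pop, arch, config, round_idx, base_freqs = NULL) {
  cand <- prescreen_candidates(pop, arch, config$prescreen_per_trait)
  sub <- subset_population(pop, cand)
  G <- vanraden_G(pop, rows = cand, allele_freqs = base_freqs)
  n_pairs <- config$pairs_per_generation[round_idx]
  if (config$mode == "single") {
    cfg <- selection_config(epsilon = config$epsilon, n_pairs = n_pairs)
    plan <- select_pairs_iterative(sub, arch, "trait1", G, cfg)
  } else {
    tol <- config$tolerances[, round_idx]
    tol[length(tol)] <- 0
    cfg <- selection_config(epsilon = config$epsilon, n_pairs = n_pairs,
                            tolerances = tol,
                            trait_priority = config$trait_priority)
    plan <- select_pairs_lexicographic(sub, arch, G, cfg)
  }
  plan$parent1 <- cand[plan$parent1]
  plan$parent2 <- cand[plan$parent2]
  plan
}

select_plan_score <- function(pop, arch, config, round_idx, scores,
                              base_freqs = NULL) {
  n_pairs <- config$pairs_per_generation[round_idx]
  if (config$mode == "single") {
    s <- scores[, 1L]
  } else {
    s <- rowSums(apply(scores, 2L, function(x) {
      if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x
    }))
  }
  plan <- select_pairs_by_score(s, selection_config(n_pairs = n_pairs))
  g <- vanraden_G(pop, rows = sort(unique(c(plan$parent1, plan$parent2))),
                  allele_freqs = base_freqs)
  ids <- pop$individual_id
  plan$g_value <- g$G[cbind(match(ids[plan$parent1], rownames(g$G)),
                            match(ids[plan$parent2], rownames(g$G)))]
  plan
}

gebv_scores <- function(pop, pheno, heritability) {
  X <- marker_dosage(pop)
  vapply(seq_len(ncol(pheno)), function(l) {
    model <- fit_rrblup(X, pheno[, l], h2_fallback = heritability[l])
    predict_gebv(model, X)
  }, numeric(nrow(X)))
}

metric_rows <- function(rep, gen, method, pop, arch, pheno, mean_rel) {
  data.frame(
    replication = rep, generation = gen, method = method,
    trait = arch$trait_ids,
    allele_freq = vapply(arch$trait_ids, function(tr) {
      mean(desirable_frequency(pop, arch, tr))
    }, numeric(1)),
    phenotype_mean = colMeans(pheno),
    mean_relatedness = mean_rel,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Run a benchmark scenario for one selection method
#'
#' Simulates `replications` independent breeding programs: generate the
#' initial population, then for each selection round compute phenotypes
#' (and GEBVs or the relationship matrix as the method requires), select a
#' crossing block, and advance the population. Per generation and trait the
#' desirable-allele frequency, mean phenotype, and mean VanRaden
#' relationship of the selected mate pairs are recorded.
#'
#' Replication seeds are derived from the master seed by a counter scheme
#' (`seed + 100000 * replication`), so individual replications can be re-run
#' independently; identical config and seed give identical results.
#'
#' @param method `"ecv"` (optimized selection), `"phenotypic"` or `"gebv"`
#'   (baselines ranked by summed scores, no relatedness constraint).
#' @param config a [sim_config()].
#' @param seed master seed.
#' @param replications number of replications (defaults to the config's).
#' @return data frame of per-replication, per-generation, per-trait metrics
#'   (class `scenario_result`), with the config attached as an attribute.
#' @export
run_scenario <- function(method = c("ecv", "phenotypic", "gebv"),
                         config = sim_config(), seed = 1L,
                         replications = config$replications) {
  method <- match.arg(method)
  out <- vector("list", replications)
  for (rep_i in seq_len(replications)) {
    set.seed(seed + 100000L * rep_i)
    init <- generate_initial_population(config)
    pop <- init$pop; arch <- init$arch
    # with g_reference = "base" the relationship matrix is referenced to the
    # founder generation, so relatedness accumulates as selection narrows
    # the genetic base; the default recomputes frequencies each generation
    base_freqs <- if (identical(config$g_reference, "base")) {
      colMeans(marker_dosage(pop)) / 2
    } else NULL
    pheno <- simulate_phenotypes(pop, arch, config$heritability)
    rows <- list(metric_rows(rep_i, 0L, method, pop, arch, pheno, NA_real_))
    for (g in seq_along(config$pairs_per_generation)) {
      plan <- switch(method,
        ecv = select_plan_ecv(pop, arch, config, g, base_freqs),
        phenotypic = select_plan_score(pop, arch, config, g, pheno, base_freqs),
        gebv = select_plan_score(pop, arch, config, g,
                                 gebv_scores(pop, pheno, config$heritability),
                                 base_freqs))
      pop <- advance_generation(pop, plan, config, generation = g)
      pheno <- simulate_phenotypes(pop, arch, config$heritability)
      rows[[g + 1L]] <- metric_rows(rep_i, g, method, pop, arch, pheno,
                                    mean(plan$g_value))
    }
    out[[rep_i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  attr(res, "config") <- config
  class(res) <- c("scenario_result", "data.frame")
  res
}

#' Summarize a scenario result across replications
#'
#' @param result a [run_scenario()] result (rows may be pooled across
#'   methods).
#' @return data frame of mean and standard deviation of each metric per
#'   generation, method and trait.
#' @export
summarize_scenario <- function(result) {
  agg <- function(x) c(mean = mean(x), sd = stats::sd(x))
  sp <- split(result, list(result$method, result$generation, result$trait),
              drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(method = d$method[1], generation = d$generation[1],
               trait = d$trait[1],
               allele_freq_mean = mean(d$allele_freq),
               allele_freq_sd = stats::sd(d$allele_freq),
               phenotype_mean = mean(d$phenotype_mean),
               phenotype_sd = stats::sd(d$phenotype_mean),
               relatedness_mean = mean(d$mean_relatedness),
               relatedness_sd = stats::sd(d$mean_relatedness),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$method, out$generation, out$trait), ]
}
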