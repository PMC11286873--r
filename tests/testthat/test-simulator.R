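# A deliberately small configuration so end-to-end runs stay fast.
tiny_config <- function(K0 = 120L, ...) {
  sim_config(K0 = K0, n_qtl = 20L, n_markers = 10L,
             trait_sizes = c(6L, 2L, 7L), n_antagonistic = 3L,
             progeny_per_cross = 15L, pairs_per_generation = c(6L, 3L),
             chromosomes = 3L, replications = 2L,
             prescreen_per_trait = Inf, ...)
}

test_that("scenario pair counts match the three selection intensities", {
  expect_equal(scenario_pairs("A"), c(50L, 10L, 3L, 3L))
  expect_equal(scenario_pairs("B"), c(50L, 10L, 5L, 5L))
  expect_equal(scenario_pairs("C"), c(50L, 25L, 5L, 5L))
  expect_error(scenario_pairs("D"))
})

test_that("sim_config validates and defaults the tolerance schedule", {
  cfg <- sim_config()
  expect_equal(cfg$trait_sizes, c(40L, 10L, 70L))
  expect_equal(dim(cfg$tolerances), c(3L, 4L))
  expect_equal(cfg$tolerances[1L, ], c(0.17, 0.05, 0.05, 0.05))
  expect_equal(cfg$tolerances[2L, ], c(0, 0, 0, 0.05))
  expect_equal(cfg$tolerances[3L, ], rep(0, 4L))
  expect_equal(cfg$g_reference, "current")

  expect_error(sim_config(n_antagonistic = 50L, trait_sizes = c(40, 10, 70)),
               "n_antagonistic")
  expect_error(sim_config(heritability = 0), "heritability")
  expect_error(sim_config(scenario = "Z"))
})

test_that("the generated genome matches the configured layout", {
  set.seed(91)
  cfg <- sim_config(K0 = 50L)
  init <- generate_initial_population(cfg)
  map <- init$pop$map
  expect_equal(n_loci(map), 300L)
  expect_equal(sum(map$locus_class == "qtl"), 200L)
  expect_equal(sum(map$locus_class == "marker"), 100L)
  expect_equal(length(unique(map$chromosome)), 10L)
  # within-chromosome linkage at r_within, independent assortment across
  brk <- which(diff(map$chromosome) != 0L)
  expect_equal(map$r_adjacent[brk], rep(0.5, 9L))
  expect_equal(unique(map$r_adjacent[-brk]), 0.1)
})

test_that("the trait architecture has the configured antagonistic overlap", {
  set.seed(92)
  init <- generate_initial_population(sim_config(K0 = 20L))
  tr <- init$arch$traits
  expect_equal(vapply(tr, function(t) length(t$loci), integer(1)),
               c(trait1 = 40L, trait2 = 10L, trait3 = 70L))
  shared <- intersect(tr$trait1$loci, tr$trait3$loci)
  expect_equal(length(shared), 20L)
  expect_equal(length(intersect(tr$trait2$loci, tr$trait3$loci)), 0L)
  # opposite desirable orientation at every shared locus
  o1 <- tr$trait1$desirable[match(shared, tr$trait1$loci)]
  o3 <- tr$trait3$desirable[match(shared, tr$trait3$loci)]
  expect_equal(o1 + o3, rep(1L, 20L))
})

test_that("phenotypes decompose into genetic value plus calibrated noise", {
  set.seed(93)
  init <- generate_initial_population(tiny_config(K0 = 3000L))
  ph1 <- simulate_phenotypes(init$pop, init$arch, heritability = 1)
  gv <- attr(ph1, "genetic_value")
  expect_equal(unclass(ph1), gv, ignore_attr = TRUE)
  # hand-check one genetic value
  t1 <- init$arch$traits$trait1
  v <- trait_view(init$pop, init$arch, 7L, "trait1")
  expect_equal(unname(gv[7L, "trait1"]), sum(rowSums(v) * t1$effect))
  # realized base-generation heritability close to the configured 0.5
  ph <- simulate_phenotypes(init$pop, init$arch, heritability = 0.5)
  g <- attr(ph, "genetic_value")
  h2_hat <- apply(g, 2L, stats::var) / apply(ph, 2L, stats::var)
  expect_true(all(abs(h2_hat - 0.5) < 0.08))
})

test_that("meiosis produces valid recombinant progeny of the right size", {
  set.seed(94)
  cfg <- tiny_config()
  init <- generate_initial_population(cfg)
  plan <- data.frame(parent1 = c(1L, 2L), parent2 = c(3L, 4L))
  off <- advance_generation(init$pop, plan, cfg, generation = 1L)
  expect_equal(n_individuals(off), 2L * cfg$progeny_per_cross)
  expect_true(all(off$h1 %in% c(0L, 1L)))
  expect_true(grepl("^g1_", off$individual_id[1L]))
  # every offspring allele is carried by the corresponding parent
  for (k in c(1L, cfg$progeny_per_cross)) {
    p1 <- plan$parent1[1L]
    carried <- off$h1[k, ] == init$pop$h1[p1, ] |
               off$h1[k, ] == init$pop$h2[p1, ]
    expect_true(all(carried))
  }
  expect_error(advance_generation(init$pop, plan[0, ], cfg), "empty")
})

test_that("fully linked chromosomes transmit parental haplotypes intact", {
  set.seed(95)
  cfg <- tiny_config(r_within = 0)
  init <- generate_initial_population(cfg)
  plan <- data.frame(parent1 = 1L, parent2 = 2L)
  off <- advance_generation(init$pop, plan, cfg)
  # with r = 0 inside chromosomes, each offspring gamete equals one parental
  # haplotype per chromosome block
  for (chr in unique(init$pop$map$chromosome)) {
    loci <- which(init$pop$map$chromosome == chr)
    for (k in 1:5) {
      g <- off$h1[k, loci]
      expect_true(identical(g, init$pop$h1[1L, loci]) ||
                  identical(g, init$pop$h2[1L, loci]))
    }
  }
})

test_that("the candidate prescreen contains the top-dosage individuals", {
  set.seed(96)
  init <- generate_initial_population(tiny_config(K0 = 200L))
  cand <- ecvmate:::prescreen_candidates(init$pop, init$arch, 30L)
  for (tr in init$arch$trait_ids) {
    cts <- desirable_count(init$pop, init$arch, tr)
    top <- order(-cts, seq_along(cts))[1:30]
    expect_true(all(top %in% cand))
  }
  # small populations are passed through unchanged
  expect_equal(ecvmate:::prescreen_candidates(init$pop, init$arch, Inf),
               seq_len(200L))
})

test_that("scenario runs produce complete, well-formed metric tables", {
  cfg <- tiny_config()
  for (m in c("ecv", "phenotypic", "gebv")) {
    res <- run_scenario(m, cfg, seed = 7L)
    expect_s3_class(res, "scenario_result")
    expect_setequal(names(res), c("replication", "generation", "method",
                                  "trait", "allele_freq", "phenotype_mean",
                                  "mean_relatedness"))
    # 2 replications x 3 generations (0..2) x 3 traits
    expect_equal(nrow(res), 2L * 3L * 3L)
    expect_true(all(res$method == m))
    expect_true(all(res$allele_freq >= 0 & res$allele_freq <= 1))
    expect_true(all(is.na(res$mean_relatedness[res$generation == 0L])))
    expect_true(all(!is.na(res$mean_relatedness[res$generation > 0L])))
  }
})

test_that("scenario runs are reproducible and replications differ", {
  cfg <- tiny_config()
  a <- run_scenario("ecv", cfg, seed = 11L)
  b <- run_scenario("ecv", cfg, seed = 11L)
  expect_equal(a, b)
  r1 <- a[a$replication == 1L, "allele_freq"]
  r2 <- a[a$replication == 2L, "allele_freq"]
  expect_false(identical(r1, r2))
})

test_that("single-trait mode improves the selected trait", {
  cfg <- tiny_config(mode = "single")
  res <- run_scenario("ecv", cfg, seed = 3L)
  t1 <- res[res$trait == "trait1", ]
  first <- tapply(t1$allele_freq[t1$generation == 0L],
                  t1$replication[t1$generation == 0L], mean)
  last <- tapply(t1$allele_freq[t1$generation == 2L],
                 t1$replication[t1$generation == 2L], mean)
  expect_true(all(last > first))
})

test_that("scenario summaries aggregate over replications", {
  cfg <- tiny_config()
  res <- run_scenario("ecv", cfg, seed = 5L)
  s <- summarize_scenario(res)
  expect_equal(nrow(s), 3L * 3L)  # 3 generations x 3 traits
  expect_setequal(names(s), c("method", "generation", "trait",
                              "allele_freq_mean", "allele_freq_sd",
                              "phenotype_mean", "phenotype_sd",
                              "relatedness_mean", "relatedness_sd"))
  row <- s[s$generation == 2L & s$trait == "trait1", ]
  d <- res[res$generation == 2L & res$trait == "trait1", ]
  expect_equal(row$allele_freq_mean, mean(d$allele_freq))
  expect_equal(row$allele_freq_sd, stats::sd(d$allele_freq))
})
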