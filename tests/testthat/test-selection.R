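random_instance <- function(K, N = 8L, n_traits = 1L) {
  map <- make_test_map(N)
  pop <- make_test_pop(K, map)
  arch <- make_test_arch(map, n_traits = n_traits)
  G <- matrix(stats::runif(K * K, -0.3, 0.6), K, K)
  G <- (G + t(G)) / 2
  diag(G) <- 1
  list(pop = pop, arch = arch, G = G)
}

# Independent reference: rank all admissible pairs by (-ecv, p1, p2).
reference_best_pair <- function(inst, trait, epsilon, forbidden = NULL) {
  K <- n_individuals(inst$pop)
  cts <- desirable_count(inst$pop, inst$arch, trait)
  best <- NULL
  for (a in seq_len(K - 1L)) for (b in (a + 1L):K) {
    if (inst$G[a, b] > epsilon + 1e-12) next
    if (!is.null(forbidden) &&
        any(forbidden[, 1L] == a & forbidden[, 2L] == b)) next
    e <- 0.25 * (cts[a] + cts[b])
    if (is.null(best) || e > best$objective + 1e-9) {
      best <- list(pair = c(a, b), objective = e)
    }
  }
  best
}

test_that("selection_config validates its arguments", {
  expect_error(selection_config(epsilon = -0.1), "epsilon")
  expect_error(selection_config(n_pairs = 0L), "positive integer")
  expect_error(selection_config(tolerances = c(0.1, 0.1),
                                trait_priority = c("a", "b")),
               "last")
  expect_error(selection_config(tolerances = c(1.5, 0)), "\\[0, 1\\]")
  expect_error(selection_config(tolerances = c(0.1, 0),
                                trait_priority = "a"),
               "equal length")
  expect_error(selection_config(trait_priority = c("a", "a")),
               "exactly once")
})

test_that("both backends match a hand-rankable reference with constraints", {
  set.seed(81)
  for (trial in 1:40) {
    inst <- random_instance(K = sample(4:14, 1))
    eps <- stats::runif(1, 0.05, 0.5)
    ref <- reference_best_pair(inst, "trait1", eps)
    for (backend in c("exhaustive", "bnb")) {
      cfg <- selection_config(epsilon = eps, backend = backend)
      if (is.null(ref)) {
        expect_error(
          select_best_pair_ilp(inst$pop, inst$arch, "trait1", inst$G, cfg),
          class = "ecvmate_infeasible"
        )
      } else {
        got <- if (backend == "bnb") {
          select_best_pair_ilp(inst$pop, inst$arch, "trait1", inst$G, cfg)
        } else {
          select_best_pair_exhaustive(inst$pop, inst$arch, "trait1", inst$G, cfg)
        }
        expect_equal(got$pair, ref$pair)
        expect_equal(got$objective, ref$objective)
        expect_lte(got$g_value, eps + 1e-12)
      }
    }
  }
})

test_that("ties break toward the lexicographically smallest pair", {
  # all individuals identical: every pair has the same ECV
  map <- make_test_map(4, r = rep(0.2, 3))
  h <- matrix(1L, 5L, 4L)
  pop <- haplotype_population(h, h, paste0("i", 1:5), map)
  arch <- trait_architecture(
    data.frame(trait_id = "t", locus_id = map$locus_id,
               desirable_allele = 1L, effect_size = 1), map)
  G <- matrix(0, 5, 5); diag(G) <- 1
  for (backend in c("exhaustive", "bnb")) {
    got <- select_best_pair_ilp(pop, arch, "t", G,
                                selection_config(backend = backend))
    expect_equal(got$pair, c(1L, 2L))
  }
  # forbid (1,2): the next lexicographic pair wins
  got <- select_best_pair_ilp(pop, arch, "t", G, selection_config(),
                              forbidden = rbind(c(1L, 2L)))
  expect_equal(got$pair, c(1L, 3L))
})

test_that("conflict constraints walk down the ranking without repeats", {
  set.seed(82)
  inst <- random_instance(K = 10)
  for (backend in c("exhaustive", "bnb")) {
    cfg <- selection_config(epsilon = 0.4, n_pairs = 6L, backend = backend)
    plan <- select_pairs_iterative(inst$pop, inst$arch, "trait1", inst$G, cfg)
    expect_equal(nrow(plan), 6L)
    # objectives non-increasing, no pair repeated, all admissible
    expect_true(all(diff(plan$ecv_trait1) <= 1e-12))
    expect_false(anyDuplicated(plan[, c("parent1", "parent2")]) > 0)
    expect_true(all(plan$g_value <= 0.4 + 1e-12))
    # each slot equals the reference with all earlier pairs forbidden
    for (s in seq_len(6L)) {
      forb <- if (s == 1L) NULL else
        cbind(plan$parent1[seq_len(s - 1L)], plan$parent2[seq_len(s - 1L)])
      ref <- reference_best_pair(inst, "trait1", 0.4, forb)
      expect_equal(c(plan$parent1[s], plan$parent2[s]), ref$pair)
    }
  }
})

test_that("disallowing repeated parents yields disjoint pairs", {
  set.seed(83)
  inst <- random_instance(K = 12)
  cfg <- selection_config(epsilon = 1, n_pairs = 4L,
                          allow_repeated_parent = FALSE)
  plan <- select_pairs_iterative(inst$pop, inst$arch, "trait1", inst$G, cfg)
  parents <- c(plan$parent1, plan$parent2)
  expect_equal(anyDuplicated(parents), 0L)
})

test_that("infeasible selection raises a classed condition with partial plan", {
  set.seed(84)
  inst <- random_instance(K = 5)
  G <- matrix(1, 5, 5)  # everything inadmissible at epsilon = 0.2
  err <- tryCatch(
    select_best_pair_ilp(inst$pop, inst$arch, "trait1", G, selection_config()),
    error = identity
  )
  expect_s3_class(err, "ecvmate_infeasible")

  # only one admissible pair but two requested: partial plan attached
  G2 <- matrix(1, 5, 5); G2[1, 2] <- G2[2, 1] <- 0
  err2 <- tryCatch(
    select_pairs_iterative(inst$pop, inst$arch, "trait1", G2,
                           selection_config(n_pairs = 2L)),
    error = identity
  )
  expect_s3_class(err2, "ecvmate_partial_plan")
  expect_equal(nrow(err2$pairs), 1L)
  expect_equal(c(err2$pairs$parent1, err2$pairs$parent2), c(1L, 2L))
})

test_that("lexicographic stages respect the tolerance contract", {
  set.seed(85)
  for (trial in 1:20) {
    inst <- random_instance(K = sample(5:12, 1), n_traits = 3L)
    tau <- c(stats::runif(2, 0, 0.3), 0)
    cfg <- selection_config(epsilon = 0.45, n_pairs = 2L, tolerances = tau,
                            trait_priority = c("trait2", "trait3", "trait1"))
    plan <- try(select_pairs_lexicographic(inst$pop, inst$arch, inst$G, cfg),
                silent = TRUE)
    if (inherits(plan, "try-error")) next  # infeasible random instance
    opts <- attr(plan, "stage_opts")
    for (s in seq_len(nrow(plan))) {
      e <- c(plan$ecv_trait2[s], plan$ecv_trait3[s], plan$ecv_trait1[s])
      expect_true(all(e >= (1 - tau) * unname(opts[s, ]) - 1e-9))
      # the last stage is optimized outright
      expect_equal(e[3L], unname(opts[s, 3L]))
    }
  }
})

test_that("lexicographic selection is backend independent", {
  set.seed(86)
  for (trial in 1:15) {
    inst <- random_instance(K = sample(5:10, 1), n_traits = 2L)
    plans <- lapply(c("exhaustive", "bnb"), function(bk) {
      cfg <- selection_config(epsilon = 0.5, n_pairs = 2L,
                              tolerances = c(0.2, 0),
                              trait_priority = c("trait1", "trait2"),
                              backend = bk)
      try(select_pairs_lexicographic(inst$pop, inst$arch, inst$G, cfg),
          silent = TRUE)
    })
    if (inherits(plans[[1]], "try-error")) {
      expect_true(inherits(plans[[2]], "try-error"))
    } else {
      expect_equal(plans[[2]][, names(plans[[1]])], plans[[1]],
                   ignore_attr = TRUE)
    }
  }
})

test_that("zero-tolerance lexicographic selection optimizes each stage exactly", {
  set.seed(87)
  inst <- random_instance(K = 8, n_traits = 2L)
  cfg <- selection_config(epsilon = 1, tolerances = c(0, 0),
                          trait_priority = c("trait1", "trait2"))
  plan <- select_pairs_lexicographic(inst$pop, inst$arch, inst$G, cfg)
  ref <- reference_best_pair(inst, "trait1", 1)
  expect_equal(plan$ecv_trait1[1L], ref$objective)
})

test_that("score-based pairing matches a full ranking of all pairs", {
  set.seed(88)
  for (trial in 1:20) {
    K <- sample(6:25, 1)
    s <- stats::rnorm(K)
    n_pairs <- sample(1:8, 1)
    plan <- select_pairs_by_score(s, selection_config(n_pairs = n_pairs))
    # reference: enumerate every unordered pair
    pairs <- t(utils::combn(K, 2L))
    o <- order(-(s[pairs[, 1]] + s[pairs[, 2]]), pairs[, 1], pairs[, 2])
    ref <- pairs[o[seq_len(n_pairs)], , drop = FALSE]
    expect_equal(cbind(plan$parent1, plan$parent2), ref, ignore_attr = TRUE)
    expect_true(all(plan$parent1 < plan$parent2))  # never a self-cross
  }
  expect_error(select_pairs_by_score(stats::rnorm(3),
                                     selection_config(n_pairs = 10L)),
               "only 3 distinct pairs")
  expect_error(select_pairs_by_score(c(1, NA, 2)), "finite")
})

test_that("matrix scores are summed across traits and ties go by index", {
  sc <- cbind(c(1, 1, 0), c(1, 1, 2))  # summed scores (2, 2, 2): full tie
  plan <- select_pairs_by_score(sc, selection_config(n_pairs = 2L))
  expect_equal(cbind(plan$parent1, plan$parent2),
               rbind(c(1L, 2L), c(1L, 3L)), ignore_attr = TRUE)
})

test_that("distinct_parents pairs the ranked individuals consecutively", {
  s <- c(5, 9, 1, 7, 3, 8)
  plan <- select_pairs_by_score(s, selection_config(n_pairs = 3L),
                                distinct_parents = TRUE)
  # ranking: 2 (9), 6 (8), 4 (7), 1 (5), 5 (3), 3 (1)
  expect_equal(cbind(plan$parent1, plan$parent2),
               rbind(c(2L, 6L), c(1L, 4L), c(3L, 5L)), ignore_attr = TRUE)
  expect_equal(anyDuplicated(c(plan$parent1, plan$parent2)), 0L)
  expect_error(select_pairs_by_score(s, selection_config(n_pairs = 4L),
                                     distinct_parents = TRUE),
               "needs 8 individuals")
})

test_that("crossing plans serialize with generation and method labels", {
  set.seed(89)
  inst <- random_instance(K = 6)
  plan <- select_pairs_iterative(inst$pop, inst$arch, "trait1", inst$G,
                                 selection_config(epsilon = 1, n_pairs = 2L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_crossing_plan(plan, path, generation = 2L, method = "ecv")
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$generation, c(2L, 2L))
  expect_equal(back$method, c("ecv", "ecv"))
  expect_equal(back$parent1, plan$parent1)
})
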