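#' Configuration for mate selection
#'
#' @param epsilon maximum admissible VanRaden relationship between mates
#'   (inbreeding cap). Default 0.20, between unrelated (about 0) and
#'   full sibs (about 0.5). Pairs with `G > epsilon` are removed from the
#'   model.
#' @param n_pairs number of parent pairs to select (the crossing block size).
#' @param tolerances numeric vector of lexicographic degradation tolerances,
#'   one per prioritized trait, each in \[0, 1\]; the last entry must be 0
#'   (the final objective is optimized outright).
#' @param trait_priority trait ids in decreasing order of importance.
#' @param allow_self_cross permit selecting an individual with itself
#'   (default off).
#' @param allow_repeated_parent permit the same individual to appear in
#'   several selected pairs (default on).
#' @param backend `"exhaustive"` (vectorized scan over admissible pairs) or
#'   `"bnb"` (integer program solved by branch and bound); both are exact and
#'   share the tie rule, so results are backend-independent.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(epsilon = 0.20, n_pairs = 1L, tolerances = NULL,
                             trait_priority = NULL, allow_self_cross = FALSE,
                             allow_repeated_parent = TRUE,
                             backend = c("exhaustive", "bnb")) {
  backend <- match.arg(backend)
  if (epsilon < 0) stop("epsilon must be >= 0")
  n_pairs <- as.integer(n_pairs)
  if (n_pairs < 1L) stop("n_pairs must be a positive integer")
  if (!is.null(tolerances)) {
    if (any(tolerances < 0) || any(tolerances > 1)) {
      stop("tolerances must lie in [0, 1]")
    }
    if (utils::tail(tolerances, 1L) != 0) {
      stop("the tolerance of the last (least important) trait must be 0")
    }
    if (!is.null(trait_priority) &&
        length(tolerances) != length(trait_priority)) {
      stop("tolerances and trait_priority must have equal length")
    }
  }
  if (!is.null(trait_priority) && anyDuplicated(trait_priority)) {
    stop("trait_priority must list each trait exactly once")
  }
  structure(list(epsilon = epsilon, n_pairs = n_pairs,
                 tolerances = tolerances, trait_priority = trait_priority,
                 allow_self_cross = allow_self_cross,
                 allow_repeated_parent = allow_repeated_parent,
                 backend = backend),
            class = "selection_config")
}

as_G_matrix <- function(G) {
  if (inherits(G, "relationship_matrix")) G$G else as.matrix(G)
}

# All candidate pairs in lexicographic (k, k') order with per-trait ECVs and
# G values. The lexicographic order of generation is what the tie rule keys
# on everywhere downstream.
pair_table <- function(pop, arch, G, config) {
  K <- n_individuals(pop)
  if (K < 2L && !config$allow_self_cross) {
    stop("selection requires at least two individuals")
  }
  G <- as_G_matrix(G)
  if (!all(dim(G) == K)) stop("G must be K x K for the population")
  if (config$allow_self_cross) {
    cnt <- K:1L
    p1 <- rep(seq_len(K), cnt)
    p2 <- sequence(cnt, from = seq_len(K))
  } else {
    cnt <- (K - 1L):1L
    p1 <- rep(seq_len(K - 1L), cnt)
    p2 <- sequence(cnt, from = seq_len(K - 1L) + 1L)
  }
  g <- G[cbind(p1, p2)]
  ecv <- vapply(arch$trait_ids, function(tr) {
    cts <- desirable_count(pop, arch, tr)
    0.25 * (cts[p1] + cts[p2])
  }, numeric(length(p1)))
  ecv <- matrix(ecv, ncol = n_traits(arch),
                dimnames = list(NULL, arch$trait_ids))
  list(p1 = p1, p2 = p2, g = g, ecv = ecv, K = K,
       admissible = g <= config$epsilon + 1e-12)
}

pair_keys <- function(p1, p2, K) (pmin(p1, p2) - 1) * K + pmax(p1, p2)

forbidden_mask <- function(tab, forbidden) {
  if (is.null(forbidden) || NROW(forbidden) == 0L) {
    return(rep(FALSE, length(tab$p1)))
  }
  forbidden <- matrix(as.integer(forbidden), ncol = 2L)
  pair_keys(tab$p1, tab$p2, tab$K) %in%
    pair_keys(forbidden[, 1L], forbidden[, 2L], tab$K)
}

infeasible_stop <- function(message, pairs_so_far = NULL) {
  cond <- structure(
    class = c(if (!is.null(pairs_so_far)) "ecvmate_partial_plan",
              "ecvmate_infeasible", "error", "condition"),
    list(message = message, call = sys.call(-1L), pairs = pairs_so_far)
  )
  stop(cond)
}

# Single-stage maximization over the pair table under a feasibility mask.
# Returns the lexicographically smallest optimal pair.
solve_stage_exhaustive <- function(tab, objective, mask) {
  if (!any(mask)) return(NULL)
  opt <- max(objective[mask])
  idx <- which(mask & objective >= opt - 1e-9)[1L]
  list(index = idx, objective = objective[idx])
}

# Same contract through the integer program: one binary per admissible pair,
# one per participating individual, select-one plus linking plus cardinality
# constraints, optional extra rows (lexicographic stage floors).
solve_stage_bnb <- function(tab, objective, mask, extra = NULL) {
  vars <- which(mask)
  if (!length(vars)) return(NULL)
  P <- length(vars)
  ind <- sort(unique(c(tab$p1[vars], tab$p2[vars])))
  Ti <- length(ind)
  t_of <- match(seq_len(tab$K), ind)
  nvar <- P + Ti
  obj <- c(objective[vars], rep(0, Ti))

  rows <- list(); cols <- list(); vals <- list(); dir <- c(); rhs <- c()
  add_row <- function(cc, vv, d, b) {
    i <- length(dir) + 1L
    rows[[i]] <<- rep(i - 1L, length(cc)); cols[[i]] <<- cc - 1L
    vals[[i]] <<- vv; dir[i] <<- d; rhs[i] <<- b
  }
  add_row(seq_len(P), rep(1, P), 2L, 1)                       # sum x == 1
  for (p in seq_len(P)) {                                     # linking
    add_row(c(p, P + t_of[tab$p1[vars[p]]]), c(1, -1), 0L, 0)
    add_row(c(p, P + t_of[tab$p2[vars[p]]]), c(1, -1), 0L, 0)
  }
  add_row(P + seq_len(Ti), rep(1, Ti), 0L, 2)                 # sum t <= 2
  if (!is.null(extra)) {
    for (e in extra) add_row(seq_len(P), e$coef[vars], 1L, e$rhs)
  }
  sol <- bnb_solve(obj, unlist(rows), unlist(cols), unlist(vals),
                   as.integer(dir), as.numeric(rhs))
  if (!isTRUE(sol$feasible)) return(NULL)
  chosen <- vars[which(sol$solution[seq_len(P)] == 1L)[1L]]
  list(index = chosen, objective = objective[chosen])
}

#' Best parent pair for one trait by integer programming
#'
#' Maximizes the trait's ECV over all unordered candidate pairs subject to
#' the genomic-relationship cap `G(k, k') <= epsilon` and an optional set of
#' forbidden (conflict) pairs, formulated as a 0/1 integer program (pair
#' indicators linked to individual indicators) and solved exactly by branch
#' and bound. Ties are broken toward the lexicographically smallest index
#' pair.
#'
#' @param pop a [haplotype_population()].
#' @param arch a [trait_architecture()].
#' @param trait trait id or index to optimize.
#' @param G `K x K` relationship matrix (or a [vanraden_G()] result).
#' @param config a [selection_config()].
#' @param forbidden optional 2-column integer matrix of excluded pairs.
#' @return list with `pair` (sorted index pair), `objective` (the exact ECV,
#'   a quarter-integer), and `g_value`.
#' @export
select_best_pair_ilp <- function(pop, arch, trait, G, config = selection_config(),
                                 forbidden = NULL) {
  tab <- pair_table(pop, arch, G, config)
  tr <- resolve_trait(arch, trait)
  mask <- tab$admissible & !forbidden_mask(tab, forbidden)
  sol <- solve_stage_bnb(tab, tab$ecv[, tr], mask)
  if (is.null(sol)) {
    infeasible_stop(paste0("no admissible pair: every candidate pair is ",
                           "either above epsilon = ", config$epsilon,
                           " or in the forbidden set"))
  }
  list(pair = c(tab$p1[sol$index], tab$p2[sol$index]),
       objective = sol$objective, g_value = tab$g[sol$index])
}

#' Best parent pair for one trait by exhaustive scan
#'
#' Independent oracle for [select_best_pair_ilp()]: scans every admissible
#' unordered pair directly, with the identical constraint set and tie rule.
#' Guarded to populations small enough to enumerate.
#'
#' @inheritParams select_best_pair_ilp
#' @param max_K guard on the population size (default 2000).
#' @return same structure as [select_best_pair_ilp()].
#' @export
select_best_pair_exhaustive <- function(pop, arch, trait, G,
                                        config = selection_config(),
                                        forbidden = NULL, max_K = 2000L) {
  if (n_individuals(pop) > max_K) {
    stop(sprintf("exhaustive pair scan guarded at K <= %d", max_K))
  }
  tab <- pair_table(pop, arch, G, config)
  tr <- resolve_trait(arch, trait)
  mask <- tab$admissible & !forbidden_mask(tab, forbidden)
  sol <- solve_stage_exhaustive(tab, tab$ecv[, tr], mask)
  if (is.null(sol)) {
    infeasible_stop(paste0("no admissible pair: every candidate pair is ",
                           "either above epsilon = ", config$epsilon,
                           " or in the forbidden set"))
  }
  list(pair = c(tab$p1[sol$index], tab$p2[sol$index]),
       objective = sol$objective, g_value = tab$g[sol$index])
}

new_crossing_plan <- function(pop, arch, tab, indices) {
  df <- data.frame(
    slot = seq_along(indices),
    parent1 = tab$p1[indices], parent2 = tab$p2[indices],
    parent1_id = pop$individual_id[tab$p1[indices]],
    parent2_id = pop$individual_id[tab$p2[indices]],
    stringsAsFactors = FALSE
  )
  ecv <- tab$ecv[indices, , drop = FALSE]
  colnames(ecv) <- paste0("ecv_", arch$trait_ids)
  df <- cbind(df, as.data.frame(ecv))
  df$g_value <- tab$g[indices]
  class(df) <- c("crossing_plan", "data.frame")
  df
}

#' Iterative crossing-block design for a single trait
#'
#' Solves the single-pair selection problem `n_pairs` times, adding a
#' conflict constraint that excludes exactly the winning pair after each
#' solve, so successive solves return the next-best admissible pairs.
#' Objective values are non-increasing across slots. The same individual may
#' recur across pairs unless `allow_repeated_parent` is off.
#'
#' @inheritParams select_best_pair_ilp
#' @return a `crossing_plan` data frame: one row per selected pair with
#'   parent ids, per-trait ECV values, and the pair's G value.
#' @export
select_pairs_iterative <- function(pop, arch, trait, G, config = selection_config()) {
  tab <- pair_table(pop, arch, G, config)
  tr <- resolve_trait(arch, trait)
  objective <- tab$ecv[, tr]
  mask <- tab$admissible
  chosen <- integer(0)
  for (s in seq_len(config$n_pairs)) {
    sol <- if (config$backend == "bnb") {
      solve_stage_bnb(tab, objective, mask)
    } else {
      solve_stage_exhaustive(tab, objective, mask)
    }
    if (is.null(sol)) {
      infeasible_stop(
        sprintf("infeasible after %d of %d pairs (epsilon and conflict constraints)",
                length(chosen), config$n_pairs),
        pairs_so_far = new_crossing_plan(pop, arch, tab, chosen)
      )
    }
    chosen <- c(chosen, sol$index)
    mask[sol$index] <- FALSE  # conflict constraint: exclude just this pair
    if (!config$allow_repeated_parent) {
      used <- c(tab$p1[sol$index], tab$p2[sol$index])
      mask <- mask & !(tab$p1 %in% used | tab$p2 %in% used)
    }
  }
  new_crossing_plan(pop, arch, tab, chosen)
}

#' Lexicographic multi-trait crossing-block design
#'
#' For each pair slot, optimizes the prioritized traits in sequence: stage 1
#' maximizes the most important trait's ECV over admissible pairs; each later
#' stage maximizes its trait's ECV among pairs retaining at least a
#' `(1 - tau_i)` fraction of every earlier stage's optimum. The final-stage
#' winner fills the slot, a conflict constraint removes it, and the process
#' repeats (stage optima are recomputed under the updated conflict set).
#' With a single prioritized trait this reduces to
#' [select_pairs_iterative()].
#'
#' @inheritParams select_best_pair_ilp
#' @return a `crossing_plan` data frame (see [select_pairs_iterative()]),
#'   with an attribute `stage_opts`: the per-slot stage optima against which
#'   the tolerance floors were set.
#' @export
select_pairs_lexicographic <- function(pop, arch, G, config) {
  priority <- config$trait_priority
  if (is.null(priority)) priority <- arch$trait_ids
  priority <- vapply(priority, function(tr) resolve_trait(arch, tr), character(1))
  tau <- config$tolerances
  if (is.null(tau)) tau <- rep(0, length(priority))
  M <- length(priority)
  stopifnot(length(tau) == M)

  tab <- pair_table(pop, arch, G, config)
  base_mask <- tab$admissible
  chosen <- integer(0)
  stage_opts <- matrix(NA_real_, nrow = config$n_pairs, ncol = M,
                       dimnames = list(NULL, priority))
  for (s in seq_len(config$n_pairs)) {
    mask <- base_mask
    floors <- list()
    sol <- NULL
    for (l in seq_len(M)) {
      objective <- tab$ecv[, priority[l]]
      sol <- if (config$backend == "bnb") {
        solve_stage_bnb(tab, objective, base_mask, extra = floors)
      } else {
        solve_stage_exhaustive(tab, objective, mask)
      }
      if (is.null(sol)) {
        infeasible_stop(
          sprintf("infeasible at slot %d, stage %d (trait %s)", s, l, priority[l]),
          pairs_so_far = new_crossing_plan(pop, arch, tab, chosen)
        )
      }
      stage_opts[s, l] <- sol$objective
      if (l < M) {
        floor_l <- (1 - tau[l]) * sol$objective
        mask <- mask & tab$ecv[, priority[l]] >= floor_l - 1e-9
        floors[[l]] <- list(coef = tab$ecv[, priority[l]], rhs = floor_l - 1e-9)
      }
    }
    chosen <- c(chosen, sol$index)
    base_mask[sol$index] <- FALSE
    if (!config$allow_repeated_parent) {
      used <- c(tab$p1[sol$index], tab$p2[sol$index])
      base_mask <- base_mask & !(tab$p1 %in% used | tab$p2 %in% used)
    }
  }
  plan <- new_crossing_plan(pop, arch, tab, chosen)
  attr(plan, "stage_opts") <- stage_opts
  plan
}

#' Baseline pairing by summed individual scores
#'
#' Ranks all unordered pairs of distinct individuals by the sum of the two
#' mates' scores (summed over traits for a score matrix) and returns the top
#' `n_pairs`. This is the phenotypic / GEBV baseline: no
#' genomic-relationship constraint is applied, self-crossing is never
#' allowed, and ties go to the smallest index pair.
#'
#' With `distinct_parents = TRUE` each individual is used in at most one
#' pair: pairs are still taken greedily by score sum, but every selected
#' pair removes its two parents from the pool, which is equivalent to
#' pairing the top `2 * n_pairs` ranked individuals consecutively
#' (first with second, third with fourth, and so on).
#'
#' @param scores numeric vector of length `K`, or a `K x M` matrix of
#'   per-trait scores (summed across columns).
#' @param config a [selection_config()] (only `n_pairs` is used).
#' @param distinct_parents if `TRUE`, no individual appears in more than
#'   one pair.
#' @return data frame with columns `slot`, `parent1`, `parent2`,
#'   `score_sum`.
#' @export
select_pairs_by_score <- function(scores, config = selection_config(),
                                  distinct_parents = FALSE) {
  s <- if (is.matrix(scores)) rowSums(scores) else as.numeric(scores)
  if (anyNA(s) || any(!is.finite(s))) stop("scores must be finite")
  K <- length(s)
  n_pairs <- config$n_pairs
  if (distinct_parents) {
    if (2L * n_pairs > K) {
      stop(sprintf("distinct pairing needs %d individuals but only %d exist",
                   2L * n_pairs, K))
    }
    top <- order(-s, seq_len(K))[seq_len(2L * n_pairs)]
    a <- top[seq(1L, 2L * n_pairs, by = 2L)]
    b <- top[seq(2L, 2L * n_pairs, by = 2L)]
    return(data.frame(slot = seq_len(n_pairs),
                      parent1 = pmin(a, b), parent2 = pmax(a, b),
                      score_sum = s[a] + s[b]))
  }
  if (K * (K - 1) / 2 < n_pairs) {
    stop(sprintf("only %d distinct pairs exist but %d were requested",
                 K * (K - 1L) %/% 2L, n_pairs))
  }
  # the j-th best pair sum only involves individuals of score rank <= j + 1,
  # so ranking within the top n_pairs + 2 individuals is exact
  top <- order(-s, seq_len(K))[seq_len(min(K, n_pairs + 2L))]
  cnt <- (length(top) - 1L):1L
  a <- rep(seq_along(top)[-length(top)], cnt)
  b <- sequence(cnt, from = seq_along(top)[-length(top)] + 1L)
  p1 <- pmin(top[a], top[b]); p2 <- pmax(top[a], top[b])
  ord <- order(-(s[p1] + s[p2]), p1, p2)[seq_len(n_pairs)]
  data.frame(slot = seq_len(n_pairs), parent1 = p1[ord], parent2 = p2[ord],
             score_sum = (s[p1] + s[p2])[ord])
}

#' Write a crossing plan as CSV
#'
#' @param plan a `crossing_plan` (or baseline plan) data frame.
#' @param path output path.
#' @param generation generation label to record.
#' @param method method label (`"ecv"`, `"phenotypic"`, `"gebv"`).
#' @return `path`, invisibly.
#' @export
write_crossing_plan <- function(plan, path, generation = 0L, method = "ecv") {
  out <- cbind(generation = generation, as.data.frame(plan), method = method)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
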