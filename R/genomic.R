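#' Marker dosage matrix of a population
#'
#' Dosage of physical allele 1 (0/1/2) at every locus of class `"marker"`.
#'
#' @param pop a [haplotype_population()].
#' @return integer `K x M` matrix with marker locus ids as column names.
#' @export
marker_dosage <- function(pop) {
  m <- which(pop$map$locus_class == "marker")
  if (!length(m)) stop("the map contains no marker loci")
  X <- pop$h1[, m, drop = FALSE] + pop$h2[, m, drop = FALSE]
  colnames(X) <- pop$map$locus_id[m]
  X
}

#' VanRaden genomic relationship matrix
#'
#' Method-1 VanRaden matrix from marker dosages: with `Z = X - 2p` (columns
#' centered at twice the allele frequency), `G = Z Z' / (2 sum p (1 - p))`.
#' Markers that are monomorphic in the observed data carry no relationship
#' information and are excluded from both numerator and denominator.
#' Frequencies are the observed current-population frequencies unless
#' supplied, and are clipped to \[0.01, 0.99\] so the denominator cannot
#' collapse as selection drives markers toward fixation.
#'
#' @param pop a [haplotype_population()] with marker loci.
#' @param rows optional individual indices/ids: return G among these rows
#'   only (frequencies still computed from the whole population).
#' @param allele_freqs optional numeric vector of allele-1 frequencies per
#'   marker (in map marker order) overriding the observed ones.
#' @return object of class `relationship_matrix`: list with the symmetric
#'   matrix `G`, the `marker_ids` used, and the `allele_freqs` applied.
#' @export
vanraden_G <- function(pop, rows = NULL, allele_freqs = NULL) {
  X <- marker_dosage(pop)
  if (is.null(allele_freqs)) {
    p <- colMeans(X) / 2
    keep <- p > 0 & p < 1
    if (!any(keep)) stop("all markers are monomorphic; G is undefined")
  } else {
    if (length(allele_freqs) != ncol(X)) {
      stop("allele_freqs must have one entry per marker")
    }
    p <- as.numeric(allele_freqs)
    keep <- rep(TRUE, ncol(X))
  }
  p <- pmin(pmax(p, 0.01), 0.99)
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  idx <- if (is.null(rows)) seq_len(nrow(X)) else resolve_individuals(pop, rows)
  Z <- sweep(X[idx, , drop = FALSE], 2L, 2 * p)
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(pop$individual_id[idx], pop$individual_id[idx])
  structure(list(G = G, marker_ids = colnames(X), allele_freqs = p),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix> %d x %d from %d markers\n",
              nrow(x$G), ncol(x$G), length(x$marker_ids)))
  invisible(x)
}

#' Write a relationship matrix as TSV
#' @param rel a `relationship_matrix` from [vanraden_G()].
#' @param path output path; individual ids form the header row and column.
#' @return `path`, invisibly.
#' @export
write_relationship_matrix <- function(rel, path) {
  df <- data.frame(individual_id = rownames(rel$G), rel$G,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Ridge-regression BLUP of marker effects
#'
#' Fits the additive genomic model `y = mu + X u + e` with
#' `u ~ N(0, sigma_u^2 I)` by ridge regression, the shrinkage ratio
#' `lambda = sigma_e^2 / sigma_u^2` estimated by restricted maximum
#' likelihood. The restricted likelihood is profiled analytically after an
#' SVD rotation of the column-centered dosage matrix, leaving a
#' one-dimensional optimization in `log(lambda)`; the fit is deterministic
#' given the inputs. If the likelihood optimization does not yield a finite
#' optimum, `lambda` falls back to `M (1 - h2) / h2` with the configured
#' heritability.
#'
#' @param markers numeric `n x M` dosage matrix (0/1/2).
#' @param phenotypes numeric vector of length `n`.
#' @param h2_fallback heritability used for the fallback shrinkage
#'   (default 0.5).
#' @return object of class `gebv_model`: marker effects, intercept, the
#'   shrinkage `lambda`, and the training column means used for centering.
#' @export
fit_rrblup <- function(markers, phenotypes, h2_fallback = 0.5) {
  X <- as.matrix(markers)
  y <- as.numeric(phenotypes)
  n <- nrow(X)
  if (length(y) != n) stop("phenotype length must match marker rows")
  M <- ncol(X)
  center <- colMeans(X)
  if (stats::sd(y) == 0) {
    warning("constant phenotypes: all marker effects set to zero")
    return(structure(list(marker_effects = rep(0, M), intercept = y[1L],
                          shrinkage = Inf, center = center,
                          marker_ids = colnames(X)),
                     class = "gebv_model"))
  }
  Xc <- sweep(X, 2L, center)
  yc <- y - mean(y)
  sv <- svd(Xc, nu = min(n, M), nv = min(n, M))
  tol <- max(dim(Xc)) * max(sv$d) * .Machine$double.eps
  q <- sum(sv$d > tol)
  d2 <- sv$d[seq_len(q)]^2
  z <- as.numeric(crossprod(sv$u[, seq_len(q), drop = FALSE], yc))
  w2 <- max(sum(yc^2) - sum(z^2), 0)
  df <- n - 1L            # REML degrees of freedom after the intercept
  resid_dim <- df - q     # dimension of the marker-orthogonal complement
  neg_restricted_ll <- function(loglam) {
    lam <- exp(loglam)
    quad <- sum(z^2 / (d2 + lam)) + if (resid_dim > 0) w2 / lam else 0
    su2 <- quad / df
    0.5 * (df * log(su2) + sum(log(d2 + lam)) + resid_dim * log(lam))
  }
  opt <- try(stats::optimize(neg_restricted_ll, c(-12, 12)), silent = TRUE)
  if (inherits(opt, "try-error") || !is.finite(opt$objective)) {
    lambda <- M * (1 - h2_fallback) / h2_fallback
  } else {
    lambda <- exp(opt$minimum)
  }
  # BLUP of effects: u = V diag(d / (d^2 + lambda)) U' yc
  u <- sv$v[, seq_len(q), drop = FALSE] %*% (sv$d[seq_len(q)] / (d2 + lambda) * z)
  structure(list(marker_effects = as.numeric(u), intercept = mean(y),
                 shrinkage = lambda, center = center,
                 marker_ids = colnames(X)),
            class = "gebv_model")
}

#' @export
print.gebv_model <- function(x, ...) {
  cat(sprintf("<gebv_model> %d markers, shrinkage lambda = %.4g\n",
              length(x$marker_effects), x$shrinkage))
  invisible(x)
}

#' Genomic estimated breeding values from a fitted model
#'
#' `intercept + (X - training column means) %*% effects` per individual.
#'
#' @param model a [fit_rrblup()] model.
#' @param markers numeric dosage matrix with the training columns.
#' @return numeric vector of GEBVs.
#' @export
predict_gebv <- function(model, markers) {
  X <- as.matrix(markers)
  if (ncol(X) != length(model$marker_effects)) {
    stop(sprintf("marker columns (%d) do not match the trained model (%d)",
                 ncol(X), length(model$marker_effects)))
  }
  as.numeric(model$intercept + sweep(X, 2L, model$center) %*% model$marker_effects)
}
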