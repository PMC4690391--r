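#' Genomic relationship matrix
#'
#' First-method GRM: `G = W W' / (2 sum p_j q_j)` with `W` the allele-count
#' matrix column-centered by `2 p_j`. Frequencies default to the combined set
#' of individuals in the panel (reference plus candidates), so that reference
#' and candidate rows live on one scale. Monomorphic markers contribute zero
#' to both numerator and denominator.
#'
#' @param panel a `genotype_panel` (or allele-count matrix) over reference and
#'   candidate individuals.
#' @param marker_ids marker columns to use (candidate QTL are excluded
#'   upstream); default all columns.
#' @param allele_frequencies optional per-marker frequency of the counted
#'   allele; default computed from the panel.
#' @return object of class `grm`: `G` (symmetric, with individual ids),
#'   `allele_frequencies`, `scale` (`2 sum p q`), `ids`.
#' @export
compute_grm <- function(panel, marker_ids = NULL, allele_frequencies = NULL) {
  W <- marker_matrix(panel, marker_ids)
  if (nrow(W) < 2L) stop("at least 2 individuals required", call. = FALSE)
  p <- if (is.null(allele_frequencies)) colMeans(W) / 2 else allele_frequencies
  stopifnot(length(p) == ncol(W))
  scale <- 2 * sum(p * (1 - p))
  if (scale <= 0) stop("all markers are monomorphic", call. = FALSE)
  Wc <- sweep(W, 2, 2 * p)
  G <- tcrossprod(Wc) / scale
  ids <- if (inherits(panel, "genotype_panel")) panel$individual_ids
         else rownames(W)
  if (!is.null(ids)) dimnames(G) <- list(ids, ids)
  structure(list(G = G, allele_frequencies = p, scale = scale, ids = ids),
            class = "grm")
}

# internal: REML pieces at given variances. Returns restricted log-likelihood,
# P matrix, Py, and the fixed-effect GLS solution.
reml_parts <- function(y, X, G, s2a, s2e) {
  n <- length(y)
  V <- s2a * G + diag(s2e, n)
  cV <- chol(V)
  Vinv <- chol2inv(cV)
  XtVinvX <- crossprod(X, Vinv %*% X)
  cX <- chol(XtVinvX)
  b <- backsolve(cX, forwardsolve(t(cX), crossprod(X, Vinv %*% y)))
  P <- Vinv - Vinv %*% X %*% chol2inv(cX) %*% crossprod(X, Vinv)
  Py <- P %*% y
  ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cX))) +
                  sum(y * Py))
  list(ll = as.numeric(ll), P = P, Py = as.numeric(Py), b = as.numeric(b))
}

#' REML variance components for the GBLUP model
#'
#' Fits `y = X b + g + e` with `g ~ N(0, G sigma2_a)` and
#' `e ~ N(0, I sigma2_e)` by maximizing the restricted likelihood with
#' average-information (AI) updates and expectation-maximization fallback
#' steps whenever an AI step does not improve the restricted log-likelihood
#' or leaves the parameter space. Variances are floored at `1e-8` times the
#' phenotypic variance rather than allowed to go negative. Convergence is
#' declared when the relative change in restricted log-likelihood falls below
#' `tolerance`; non-convergence is flagged, not thrown.
#'
#' @param phenotypes numeric vector over the reference individuals.
#' @param X fixed-effect design matrix (breed effects; full column rank).
#' @param G genomic relationship matrix over the reference individuals; a
#'   ridge of `1e-6` is added to its diagonal.
#' @param tolerance relative log-likelihood convergence threshold.
#' @param max_iterations iteration cap.
#' @return object of class `greml_result`: `sigma2_a`, `sigma2_e`, `h2`,
#'   `fixed_effects`, `converged`, `iterations`, `loglik_trace`.
#' @export
fit_greml <- function(phenotypes, X, G, tolerance = 1e-8,
                      max_iterations = 100L) {
  y <- as.numeric(phenotypes)
  n <- length(y)
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient",
                                 call. = FALSE)
  G <- as.matrix(G)
  stopifnot(nrow(G) == n, ncol(G) == n)
  G <- G + diag(1e-6, n)

  vy <- stats::var(y)
  floor_v <- 1e-8 * vy
  s2a <- 0.5 * vy
  s2e <- 0.5 * vy
  trace <- numeric(0)
  parts <- reml_parts(y, X, G, s2a, s2e)
  converged <- FALSE
  it <- 0L

  em_step <- function(s2a, s2e, parts) {
    Py <- parts$Py
    GPy <- G %*% Py
    s2a_new <- s2a + s2a^2 / n * (sum(Py * GPy) - sum(parts$P * G))
    s2e_new <- s2e + s2e^2 / n * (sum(Py * Py) - sum(diag(parts$P)))
    c(max(s2a_new, floor_v), max(s2e_new, floor_v))
  }

  for (it in seq_len(max_iterations)) {
    trace <- c(trace, parts$ll)
    Py <- parts$Py
    GPy <- as.numeric(G %*% Py)
    PGPy <- as.numeric(parts$P %*% GPy)
    PPy <- as.numeric(parts$P %*% Py)
    # scores (trace terms use symmetry: tr(PG) = sum(P * G))
    sc <- c(-0.5 * (sum(parts$P * G) - sum(Py * GPy)),
            -0.5 * (sum(diag(parts$P)) - sum(Py * Py)))
    # average information matrix
    AI <- 0.5 * rbind(
      c(sum(GPy * PGPy), sum(GPy * PPy)),
      c(sum(Py * PGPy), sum(Py * PPy)))
    step <- tryCatch(solve(AI, sc), error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(step) && it > 1L) { # first step always EM, for stability
      prop <- pmax(c(s2a, s2e) + step, floor_v)
      new_parts <- tryCatch(reml_parts(y, X, G, prop[1], prop[2]),
                            error = function(e) NULL)
      if (!is.null(new_parts) && is.finite(new_parts$ll) &&
          new_parts$ll >= parts$ll - 1e-12) {
        accepted <- TRUE
      }
    }
    if (!accepted) { # EM fallback: monotone, always valid
      prop <- em_step(s2a, s2e, parts)
      new_parts <- reml_parts(y, X, G, prop[1], prop[2])
    }
    delta_ll <- abs(new_parts$ll - parts$ll) / max(1, abs(parts$ll))
    s2a <- prop[1]; s2e <- prop[2]; parts <- new_parts
    if (delta_ll < tolerance) { converged <- TRUE; break }
  }
  trace <- c(trace, parts$ll)

  structure(list(sigma2_a = s2a, sigma2_e = s2e,
                 h2 = s2a / (s2a + s2e),
                 fixed_effects = parts$b,
                 converged = converged, iterations = it,
                 loglik_trace = trace),
            class = "greml_result")
}

#' BLUP genomic breeding values at estimated variance components
#'
#' Solves the mixed model `y = X b + g + e` at the fitted variance ratio: `b`
#' by generalized least squares and `g` for every individual (reference and
#' candidates) by propagating reference information through the genomic
#' relationships, `g_hat = sigma2_a G[. , ref] V^{-1} (y - X b_hat)`. This is
#' the joint solution of the dense mixed-model equations; candidates carry no
#' phenotype, so their GEBVs come entirely from their genomic relationship
#' with the reference. A candidate genomically unrelated to every reference
#' individual gets GEBV 0.
#'
#' @param fit a `greml_result` (or list with `sigma2_a`, `sigma2_e`).
#' @param phenotypes reference phenotypes.
#' @param X fixed-effect design over the reference individuals.
#' @param G relationship matrix over reference and candidate individuals.
#' @param reference_index positions of the reference individuals in `G`.
#' @return list: `gebv` (named by `G` row names; all individuals),
#'   `fixed_effects`.
#' @export
solve_blup <- function(fit, phenotypes, X, G, reference_index) {
  if (inherits(G, "grm")) G <- G$G
  y <- as.numeric(phenotypes)
  X <- as.matrix(X)
  Gr <- G[reference_index, reference_index, drop = FALSE]
  V <- fit$sigma2_a * Gr + diag(fit$sigma2_e, length(reference_index))
  Vinv <- tryCatch(chol2inv(chol(V)), error = function(e) {
    warning("singular coefficient matrix; ridge-stabilized")
    chol2inv(chol(V + diag(1e-8 * mean(diag(V)), nrow(V))))
  })
  b <- solve(crossprod(X, Vinv %*% X), crossprod(X, Vinv %*% y))
  resid <- y - X %*% b
  gebv <- as.numeric(fit$sigma2_a * G[, reference_index, drop = FALSE] %*%
                       (Vinv %*% resid))
  names(gebv) <- rownames(G)
  list(gebv = gebv, fixed_effects = as.numeric(b))
}

#' Fixed-effect design matrix for breed means
#'
#' One indicator column per population label; for a single-population
#' reference this reduces to an intercept.
#'
#' @param population label per individual.
#' @return incidence matrix, individuals x populations.
#' @export
breed_design <- function(population) {
  lv <- unique(population)
  X <- vapply(lv, function(p) as.numeric(population == p),
              numeric(length(population)))
  colnames(X) <- lv
  X
}

#' One-call GBLUP prediction
#'
#' Convenience wrapper: builds the breed design, fits REML on the reference,
#' and returns candidate GEBVs.
#'
#' @param phenotypes reference phenotypes.
#' @param reference,candidates `genotype_panel`s sharing marker columns.
#' @param marker_ids marker columns to use.
#' @param tolerance REML convergence tolerance.
#' @return list: `gebv` (candidates), `fit` (the `greml_result`), `grm`.
#' @export
run_gblup <- function(phenotypes, reference, candidates,
                      marker_ids = NULL, tolerance = 1e-8) {
  stopifnot(inherits(reference, "genotype_panel"),
            inherits(candidates, "genotype_panel"))
  all_geno <- rbind(marker_matrix(reference, marker_ids),
                    marker_matrix(candidates,
                                  colnames(marker_matrix(reference, marker_ids))))
  rownames(all_geno) <- c(reference$individual_ids, candidates$individual_ids)
  grm <- compute_grm(all_geno)
  n_ref <- nrow(reference$genotypes)
  ref_idx <- seq_len(n_ref)
  X <- breed_design(reference$population)
  fit <- fit_greml(phenotypes, X, grm$G[ref_idx, ref_idx], tolerance)
  blup <- solve_blup(fit, phenotypes, X, grm$G, ref_idx)
  list(gebv = blup$gebv[-ref_idx], fit = fit, grm = grm)
}
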