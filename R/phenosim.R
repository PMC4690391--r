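#' Partition panel SNPs into candidate QTL and markers
#'
#' A uniform random sample of SNPs (without replacement, regardless of
#' chromosome or allele frequency) becomes the candidate QTL set; every
#' remaining SNP is a marker. Markers are what the prediction models see;
#' candidate QTL (whether active in a given replicate or not) are never passed
#' to a predictor.
#'
#' @param snp_ids character vector of panel SNP ids, or a `genotype_panel`.
#' @param n_candidates number of candidate QTL (default 5000).
#' @param seed RNG seed.
#' @return object of class `qtl_architecture`: `candidate_qtl_ids`,
#'   `marker_ids`, `active_qtl_ids` (empty until [draw_active_qtl()]), `m`.
#' @export
partition_candidate_qtl <- function(snp_ids, n_candidates = 5000, seed = 1L) {
  if (inherits(snp_ids, "genotype_panel")) snp_ids <- snp_ids$snp_map$snp_id
  if (n_candidates >= length(snp_ids)) {
    stop("n_candidates must be smaller than the number of SNPs", call. = FALSE)
  }
  set.seed(derive_seed(seed, "qtl-partition"))
  cand <- if (n_candidates > 0) sort(sample(snp_ids, n_candidates)) else character(0)
  structure(list(candidate_qtl_ids = cand,
                 marker_ids = setdiff(snp_ids, cand),
                 active_qtl_ids = character(0),
                 m = 0L),
            class = "qtl_architecture")
}

#' Draw the active QTL for one replicate
#'
#' Uniform draw of `m` QTL from the candidate set, redrawn independently per
#' replicate.
#'
#' @param arch a `qtl_architecture` from [partition_candidate_qtl()].
#' @param m number of active QTL (typically 3, 30, 300 or 3000).
#' @param seed RNG seed (vary per replicate).
#' @return the architecture with `active_qtl_ids` and `m` filled in.
#' @export
draw_active_qtl <- function(arch, m, seed = 1L) {
  stopifnot(inherits(arch, "qtl_architecture"))
  if (m > length(arch$candidate_qtl_ids)) {
    stop("m exceeds the number of candidate QTL", call. = FALSE)
  }
  set.seed(derive_seed(seed, "active-qtl"))
  arch$active_qtl_ids <- sort(sample(arch$candidate_qtl_ids, m))
  arch$m <- as.integer(m)
  arch
}

#' Sample allele substitution effects correlated across populations
#'
#' Each QTL's effects in the P populations are drawn independently from a
#' zero-mean multivariate normal with unit variances and the target
#' correlation matrix (genetic correlation r_g between populations). With a
#' target correlation of 1 every population column is identical; with finite
#' numbers of QTL the realized sample correlation scatters around (and, for
#' targets in (0,1), is on average below) the target.
#'
#' @param m number of QTL.
#' @param target_correlation P x P correlation matrix, or a single off-diagonal
#'   value applied to all population pairs.
#' @param n_populations number of populations when `target_correlation` is a
#'   scalar (default 2).
#' @param seed RNG seed; with `z` given, ignored.
#' @param z optional m x P matrix of standard-normal draws to be given the
#'   target correlation structure — used to pair conditions (same underlying
#'   draws, different r_g) for variance reduction.
#' @return object of class `effect_matrix`: `alpha` (m x P matrix),
#'   `target_correlation`.
#' @export
sample_correlated_effects <- function(m, target_correlation, n_populations = 2L,
                                      seed = 1L, z = NULL) {
  if (length(target_correlation) == 1L) {
    R <- matrix(target_correlation, n_populations, n_populations)
    diag(R) <- 1
  } else {
    R <- as.matrix(target_correlation)
  }
  if (!isSymmetric(unname(R)) || any(diag(R) != 1)) {
    stop("target correlation must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop(sprintf("target correlation is not positive semi-definite (eigenvalue %.4g)",
                 min(ev)), call. = FALSE)
  }
  P <- ncol(R)
  if (is.null(z)) {
    set.seed(derive_seed(seed, "effects"))
    z <- matrix(stats::rnorm(m * P), nrow = m)
  } else {
    stopifnot(nrow(z) == m, ncol(z) == P)
  }
  # Triangular factor so the first population's column equals z[, 1] exactly:
  # with a shared z across correlation settings, conditions are paired (the
  # reference population's effects do not change, only the others rotate).
  U <- tryCatch(chol(R), error = function(e) NULL)
  if (is.null(U)) { # singular target (e.g. r_g = 1): pivoted PSD factorization
    Up <- suppressWarnings(chol(R, pivot = TRUE))
    piv <- attr(Up, "pivot")
    rank <- attr(Up, "rank")
    if (rank < P) Up[(rank + 1):P, ] <- 0 # rows beyond the rank are junk
    U <- matrix(0, P, P)
    U[, piv] <- Up[, ]
  }
  alpha <- z %*% U
  colnames(alpha) <- colnames(R)
  structure(list(alpha = alpha, target_correlation = R),
            class = "effect_matrix")
}

#' Realized genetic correlation between population effect columns
#'
#' Plain Pearson correlation between the columns of the effect matrix. With a
#' single QTL the correlation is undefined (returned as `NA` with a warning);
#' with two QTL it is always plus or minus 1 (flagged with a warning).
#'
#' @param effects an `effect_matrix` (or bare m x P matrix).
#' @return P x P matrix of sample correlations.
#' @export
realized_genetic_correlation <- function(effects) {
  a <- if (inherits(effects, "effect_matrix")) effects$alpha else as.matrix(effects)
  if (nrow(a) < 2L) {
    warning("sample correlation undefined for a single QTL")
    out <- matrix(NA_real_, ncol(a), ncol(a))
    diag(out) <- 1
    return(out)
  }
  if (nrow(a) == 2L) warning("with 2 QTL the sample correlation is always +/-1")
  zero_var <- apply(a, 2, stats::sd) == 0
  if (any(zero_var)) warning("zero-variance effect column; correlations undefined")
  suppressWarnings(stats::cor(a))
}

#' True breeding values from QTL genotypes and effects
#'
#' TBV of an individual is the sum over active QTL of its allele count times
#' the allele substitution effect of that QTL in the individual's own
#' population (raw 0/1/2 coding, additive model).
#'
#' @param panel a `genotype_panel` containing the active QTL columns.
#' @param arch a `qtl_architecture` with a non-empty active set.
#' @param effects an `effect_matrix` with rows aligned to
#'   `arch$active_qtl_ids` and one column per population label.
#' @return named numeric vector of TBVs, one per individual.
#' @export
compute_tbv <- function(panel, arch, effects) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(arch, "qtl_architecture"))
  if (length(arch$active_qtl_ids) == 0L) stop("active QTL set is empty", call. = FALSE)
  a <- if (inherits(effects, "effect_matrix")) effects$alpha else effects
  stopifnot(nrow(a) == length(arch$active_qtl_ids))
  if (is.null(colnames(a))) {
    colnames(a) <- unique(panel$population)[seq_len(ncol(a))]
  }
  pop_col <- match(panel$population, colnames(a))
  if (anyNA(pop_col)) {
    stop("individuals with unknown population label: ",
         paste(unique(panel$population[is.na(pop_col)]), collapse = ", "),
         call. = FALSE)
  }
  X <- panel$genotypes[, arch$active_qtl_ids, drop = FALSE]
  # X %*% alpha, then each individual picks its own population column
  prod <- X %*% a
  tbv <- prod[cbind(seq_len(nrow(prod)), pop_col)]
  names(tbv) <- panel$individual_ids
  tbv
}

#' Simulate phenotypes from true breeding values
#'
#' Adds an environmental effect drawn per individual from a zero-mean normal
#' whose variance is `(1/h2 - 1)` times the within-population variance of the
#' TBV (TBV mean-corrected within that population), so that the
#' within-population heritability equals `h2` in expectation.
#'
#' @param tbv named numeric vector of true breeding values.
#' @param h2 heritability in `(0, 1]` (default 0.95).
#' @param population population label per individual.
#' @param seed RNG seed.
#' @param replicate replicate index stored with the result.
#' @return object of class `trait_replicate`: `tbv`, `phenotype`, `h2`,
#'   `replicate`, `seed`.
#' @export
simulate_phenotypes <- function(tbv, h2 = 0.95, population, seed = 1L,
                                replicate = 1L) {
  check_scalar(h2, 0, 1, "h2", open_lo = TRUE)
  stopifnot(length(tbv) == length(population))
  set.seed(derive_seed(seed, "phenotypes"))
  env <- numeric(length(tbv))
  for (pop in unique(population)) {
    idx <- population == pop
    v <- stats::var(tbv[idx]) # mean-corrected within population
    if (!is.finite(v) || v == 0) {
      if (h2 < 1) warning(sprintf(
        "within-population TBV variance is 0 in '%s'; environmental variance set to 0",
        pop))
      v <- 0
    }
    env[idx] <- stats::rnorm(sum(idx), 0, sqrt((1 / h2 - 1) * v))
  }
  structure(list(tbv = tbv, phenotype = tbv + env, h2 = h2,
                 replicate = as.integer(replicate), seed = as.integer(seed)),
            class = "trait_replicate")
}
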