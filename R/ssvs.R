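#' Configuration for the SSVS Gibbs sampler
#'
#' @param pi_large prior probability that a SNP carries a large effect
#'   (the study's `1 - pi`; default 0.01).
#' @param variance_ratio ratio between the large and small prior effect
#'   variances (default 100: the small component is `sigma2_beta / 100`).
#' @param n_iterations Gibbs chain length (default 5000).
#' @param burn_in iterations discarded before accumulation (default 1000).
#' @param prior_df degrees of freedom of the scaled inverse chi-square prior
#'   on `sigma2_beta` (default 4.2).
#' @param prior_scale scale of that prior; `NULL` auto-calibrates it so the
#'   prior expected total marker variance, `sum_j 2 p_j q_j * (pi_large *
#'   sigma2_beta + (1 - pi_large) * sigma2_beta / variance_ratio)`, matches
#'   the sample phenotypic variance times an assumed heritability of 0.95.
#' @param include_population_intercepts fit one intercept per population in
#'   the reference; `NULL` (default) enables it when the reference spans more
#'   than one population, mirroring the fixed breed effect of GBLUP. `FALSE`
#'   gives the literal single-mean model.
#' @param random_order randomize the marker update order each iteration
#'   (default `FALSE`: fixed panel order).
#' @param fix_sigma2_beta,fix_sigma2_e optionally hold a variance fixed at
#'   the given value instead of sampling it (used e.g. to exercise the
#'   ridge-regression limit of the sampler); `NULL` samples normally.
#' @param debug_every if > 0, every that many iterations the incrementally
#'   updated residual is checked against a full recomputation.
#' @param seed RNG seed for the chain.
#' @return an object of class `ssvs_config`.
#' @export
ssvs_config <- function(pi_large = 0.01, variance_ratio = 100,
                        n_iterations = 5000, burn_in = 1000,
                        prior_df = 4.2, prior_scale = NULL,
                        include_population_intercepts = NULL,
                        random_order = FALSE,
                        fix_sigma2_beta = NULL, fix_sigma2_e = NULL,
                        debug_every = 0L, seed = 1L) {
  check_scalar(pi_large, 0, 1, "pi_large", open_lo = TRUE, open_hi = TRUE)
  if (variance_ratio <= 1) stop("variance_ratio must exceed 1", call. = FALSE)
  if (burn_in >= n_iterations) stop("burn_in must be below n_iterations",
                                    call. = FALSE)
  structure(list(pi_large = pi_large, variance_ratio = variance_ratio,
                 n_iterations = as.integer(n_iterations),
                 burn_in = as.integer(burn_in),
                 prior_df = prior_df, prior_scale = prior_scale,
                 include_population_intercepts = include_population_intercepts,
                 random_order = isTRUE(random_order),
                 fix_sigma2_beta = fix_sigma2_beta,
                 fix_sigma2_e = fix_sigma2_e,
                 debug_every = as.integer(debug_every),
                 seed = as.integer(seed)),
            class = "ssvs_config")
}

# internal: extract a marker matrix (individuals x markers) from a panel or
# matrix, verifying marker ids
marker_matrix <- function(x, marker_ids = NULL) {
  g <- if (inherits(x, "genotype_panel")) x$genotypes else as.matrix(x)
  if (!is.null(marker_ids)) {
    missing_ids <- setdiff(marker_ids, colnames(g))
    if (length(missing_ids) > 0) {
      stop("markers absent from panel: ",
           paste(utils::head(missing_ids, 5), collapse = ", "),
           if (length(missing_ids) > 5) ", ..." else "", call. = FALSE)
    }
    g <- g[, marker_ids, drop = FALSE]
  }
  g
}

#' Run the SSVS Gibbs sampler and predict GEBVs
#'
#' Fits `y = intercept + sum_j X_j beta_j + e` on the reference individuals by
#' Gibbs sampling with right-hand-side updating: per iteration the
#' intercept(s) are updated from their normal full conditionals; each marker's
#' indicator is sampled from its Bernoulli posterior (see
#' [indicator_posterior()]) and its effect from the corresponding normal full
#' conditional, with the residual updated incrementally; then `sigma2_beta`
#' and `sigma2_e` are drawn from their inverse chi-square full conditionals.
#' Post burn-in samples of the selection candidates' genetic values
#' (candidate marker matrix times the current effects) are averaged into
#' GEBVs. Marker columns are centered by the combined reference + candidate
#' mean allele count.
#'
#' @param phenotypes numeric vector for the reference individuals.
#' @param reference a `genotype_panel` (or matrix) of reference individuals.
#' @param candidates a `genotype_panel` (or matrix) of selection candidates
#'   with the same marker columns; may be `NULL`.
#' @param config an [ssvs_config()].
#' @param marker_ids columns to use (default: all shared columns, in
#'   reference order); reference and candidate columns are matched by id.
#' @return object of class `ssvs_result`: `beta` (posterior mean per marker),
#'   `inclusion_prob`, `intercepts`, `sigma2_beta`, `sigma2_e`, `gebv` (named,
#'   per candidate), `marker_ids`, `center` (column means used), and
#'   `max_resid_drift` when `debug_every > 0`.
#' @export
run_ssvs <- function(phenotypes, reference, candidates = NULL,
                     config = ssvs_config(), marker_ids = NULL) {
  stopifnot(inherits(config, "ssvs_config"))
  if (anyNA(phenotypes) || any(!is.finite(phenotypes))) {
    stop("phenotypes must be finite", call. = FALSE)
  }
  Xr <- marker_matrix(reference, marker_ids)
  if (length(phenotypes) != nrow(Xr)) {
    stop("one phenotype per reference individual required", call. = FALSE)
  }
  if (!is.null(candidates)) {
    Xc <- marker_matrix(candidates, colnames(Xr))
  } else {
    Xc <- matrix(0, nrow = 0, ncol = ncol(Xr))
  }

  # center by combined mean allele count
  ctr <- colMeans(rbind(Xr, Xc))
  Xr_c <- sweep(Xr, 2, ctr)
  Xc_c <- if (nrow(Xc) > 0) sweep(Xc, 2, ctr) else Xc

  # intercept groups
  pops <- if (inherits(reference, "genotype_panel")) reference$population
          else rep("all", nrow(Xr))
  use_pop <- config$include_population_intercepts
  if (is.null(use_pop)) use_pop <- length(unique(pops)) > 1L
  groups <- if (use_pop) factor(pops) else factor(rep("all", nrow(Xr)))

  # auto-calibrated prior scale for sigma2_beta
  S0 <- config$prior_scale
  if (is.null(S0)) {
    p <- ctr / 2
    sum2pq <- sum(2 * p * (1 - p))
    mix <- config$pi_large + (1 - config$pi_large) / config$variance_ratio
    S0 <- 0.95 * stats::var(phenotypes) / max(sum2pq * mix, .Machine$double.eps)
    S0 <- max(S0, 1e-8) # constant phenotypes: keep the prior proper
  }

  set.seed(derive_seed(config$seed, "ssvs-chain"))
  fit <- ssvs_gibbs_cpp(Xr_c, as.numeric(phenotypes),
                        as.integer(groups) - 1L, nlevels(groups),
                        Xc_c, config$n_iterations, config$burn_in,
                        config$pi_large, config$variance_ratio,
                        config$prior_df, S0, config$random_order,
                        config$debug_every,
                        if (is.null(config$fix_sigma2_beta)) -1 else config$fix_sigma2_beta,
                        if (is.null(config$fix_sigma2_e)) -1 else config$fix_sigma2_e)
  gebv <- as.numeric(fit$gebv)
  if (!is.null(candidates) && inherits(candidates, "genotype_panel")) {
    names(gebv) <- candidates$individual_ids
  }
  structure(list(beta = stats::setNames(as.numeric(fit$beta_mean), colnames(Xr)),
                 inclusion_prob = stats::setNames(as.numeric(fit$inclusion_prob),
                                                  colnames(Xr)),
                 intercepts = stats::setNames(as.numeric(fit$mu_mean),
                                              levels(groups)),
                 sigma2_beta = fit$sigma2_beta_mean,
                 sigma2_e = fit$sigma2_e_mean,
                 gebv = gebv,
                 marker_ids = colnames(Xr),
                 center = ctr,
                 prior_scale = S0,
                 max_resid_drift = fit$max_resid_drift,
                 config = config),
            class = "ssvs_result")
}

#' Posterior probability of the large-effect indicator
#'
#' Returns `pd1 * (1 - pi) / (pd1 * (1 - pi) + pd0 * pi)` where `pd1`/`pd0`
#' are the marginal densities of the marker's right-hand side under the large
#' and small prior effect variances, `1 - pi = pi_large`. Computed in log
#' space so simultaneous underflow of both densities never yields 0/0. The
#' right-hand side `r = X_j'e + X_j'X_j beta_j` is marginally
#' `N(0, X_j'X_j sigma2_e + (X_j'X_j)^2 v)` under prior variance `v`.
#'
#' @param rhs right-hand side statistic for the marker.
#' @param xtx the marker's sum of squares `X_j'X_j` (centered coding).
#' @param sigma2_beta large-component prior variance.
#' @param sigma2_e residual variance.
#' @param pi_large prior probability of a large effect.
#' @param variance_ratio large-to-small prior variance ratio.
#' @return probability that the indicator equals 1 (vectorized over `rhs`).
#' @export
indicator_posterior <- function(rhs, xtx, sigma2_beta, sigma2_e,
                                pi_large = 0.01, variance_ratio = 100) {
  stopifnot(sigma2_beta > 0, sigma2_e > 0)
  v1 <- xtx * sigma2_e + xtx^2 * sigma2_beta
  v0 <- xtx * sigma2_e + xtx^2 * sigma2_beta / variance_ratio
  log_pd1 <- -0.5 * log(v1) - 0.5 * rhs^2 / v1
  log_pd0 <- -0.5 * log(v0) - 0.5 * rhs^2 / v0
  indicator_prob_from_log_pd(log_pd1, log_pd0, pi_large)
}

#' Indicator probability from log component densities
#'
#' Log-sum-exp form of the Bernoulli posterior of the indicator; usable with
#' log densities from any source. `log_pd0 = -Inf` gives probability 1.
#'
#' @param log_pd1,log_pd0 log marginal densities under the large and small
#'   components.
#' @param pi_large prior probability of a large effect.
#' @return probability in `[0, 1]`.
#' @export
indicator_prob_from_log_pd <- function(log_pd1, log_pd0, pi_large = 0.01) {
  a <- log_pd1 + log(pi_large)
  b <- log_pd0 + log1p(-pi_large)
  1 / (1 + exp(b - a))
}

#' Sample the prior variances from their full conditionals
#'
#' `sigma2_beta` is drawn from a scaled inverse chi-square with
#' `prior_df + m` degrees of freedom and scale `(prior_df * prior_scale +
#' sum_j beta_j^2 c_j) / (prior_df + m)`, where `c_j = 1` for included markers
#' and `c_j = variance_ratio` otherwise (both mixture components share
#' `sigma2_beta` up to the fixed ratio). `sigma2_e` is drawn as
#' `e'e / chisq(n)` (scale-invariant prior), so that for fixed `e` with
#' `e'e = n` the draw has expectation `n / (n - 2)`.
#'
#' @param state list with `beta`, `gamma` (0/1 per marker) and `residuals`.
#' @param config an [ssvs_config()] with an explicit `prior_scale`.
#' @return list with `sigma2_beta` and `sigma2_e`.
#' @export
sample_prior_variances <- function(state, config) {
  stopifnot(is.numeric(state$beta), length(state$gamma) == length(state$beta))
  if (is.null(config$prior_scale)) {
    stop("config$prior_scale must be explicit here", call. = FALSE)
  }
  m <- length(state$beta)
  cj <- ifelse(state$gamma == 1, 1, config$variance_ratio)
  df_b <- config$prior_df + m
  scale_b <- (config$prior_df * config$prior_scale + sum(state$beta^2 * cj)) / df_b
  n <- length(state$residuals)
  list(sigma2_beta = rinvchisq(1, df_b, scale_b),
       sigma2_e = sum(state$residuals^2) / stats::rchisq(1, n))
}

#' Predict GEBVs from posterior mean marker effects
#'
#' Because accumulation over the chain is linear in the effects, the average
#' over per-iteration candidate predictions equals the candidate marker matrix
#' times the posterior mean effects; this function applies that identity to
#' new candidates. Columns are centered with the means stored in the result,
#' so GEBVs are on the same scale as the chain's accumulated predictions
#' (centering shifts all candidates by a constant and leaves
#' correlation-based accuracy unchanged).
#'
#' @param result an `ssvs_result`.
#' @param candidates a `genotype_panel` or matrix with the result's marker
#'   columns (matched by id; a mismatch is an error listing offending ids).
#' @return named numeric vector of GEBVs.
#' @export
predict_gebv <- function(result, candidates) {
  stopifnot(inherits(result, "ssvs_result"))
  Xc <- marker_matrix(candidates, result$marker_ids)
  Xc_c <- sweep(Xc, 2, result$center)
  gebv <- as.numeric(Xc_c %*% result$beta)
  if (inherits(candidates, "genotype_panel")) {
    names(gebv) <- candidates$individual_ids
  }
  gebv
}
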