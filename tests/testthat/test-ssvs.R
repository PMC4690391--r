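test_that("indicator posterior follows the mixture-density odds", {
  # equal densities cancel to the prior
  expect_equal(indicator_prob_from_log_pd(0, 0, 0.01), 0.01)
  # pd1 = 2 pd0
  expect_equal(indicator_prob_from_log_pd(log(2), 0, 0.01), 0.02 / 1.01,
               tolerance = 1e-12)
  # small-component density zero: certainty
  expect_equal(indicator_prob_from_log_pd(-1000, -Inf, 0.01), 1)
  # simultaneous underflow resolved in log space, never 0/0
  expect_equal(indicator_prob_from_log_pd(-5000, -5000, 0.3), 0.3)

  # full-statistic form: a null right-hand side favours the small component
  p0 <- indicator_posterior(0, xtx = 50, sigma2_beta = 1, sigma2_e = 1,
                            pi_large = 0.01, variance_ratio = 100)
  expect_lt(p0, 0.01)
  # an extreme right-hand side favours the large component
  p_big <- indicator_posterior(500, xtx = 50, sigma2_beta = 1, sigma2_e = 1)
  expect_gt(p_big, 0.99)
  expect_error(indicator_posterior(1, 1, -1, 1), "sigma2_beta")
})

test_that("prior variance draws match their scaled inverse chi-square law", {
  cfg <- ssvs_config(prior_df = 4, prior_scale = 2, variance_ratio = 100)
  state <- list(beta = c(0.3, -0.2, 0.05), gamma = c(1, 1, 0),
                residuals = rep(1, 50)) # e'e = n = 50
  set.seed(1)
  draws <- replicate(4000, sample_prior_variances(state, cfg))
  s2b <- unlist(draws["sigma2_beta", ])
  s2e <- unlist(draws["sigma2_e", ])

  m <- length(state$beta)
  ss <- sum(state$beta^2 * c(1, 1, 100))
  df_b <- 4 + m
  scale_b <- (4 * 2 + ss) / df_b
  an_mean <- df_b * scale_b / (df_b - 2)
  expect_lt(abs(mean(s2b) - an_mean), 3 * sd(s2b) / sqrt(length(s2b)))

  # flat-prior residual draw: E = e'e/(n-2) = 50/48
  expect_lt(abs(mean(s2e) - 50 / 48), 3 * sd(s2e) / sqrt(length(s2e)))
})

test_that("null phenotypes give null effects and GEBVs", {
  set.seed(3)
  X <- matrix(rbinom(100 * 150, 2, 0.4), 100, 150)
  colnames(X) <- paste0("m", 1:150)
  res <- run_ssvs(rep(0, 100), X, X[1:10, ],
                  ssvs_config(n_iterations = 800, burn_in = 200, seed = 1))
  expect_lt(max(abs(res$beta)), 1e-2)
  expect_lt(max(abs(res$gebv)), 1e-2)
})

test_that("a single causal marker attains the top inclusion probability", {
  set.seed(4)
  n <- 200; m <- 500
  X <- matrix(rbinom(n * m, 2, 0.5), n, m)
  colnames(X) <- paste0("m", 1:m)
  y <- X[, 250] * 1.0 # h2 = 1, all variance from marker 250
  res <- run_ssvs(y, X, NULL,
                  ssvs_config(n_iterations = 1500, burn_in = 300, seed = 2))
  expect_equal(unname(which.max(res$inclusion_prob)), 250)
})

test_that("pure-noise phenotypes keep inclusion near the prior", {
  set.seed(5)
  X <- matrix(rbinom(120 * 400, 2, 0.5), 120, 400)
  colnames(X) <- paste0("m", 1:400)
  y <- rnorm(120)
  res <- run_ssvs(y, X, NULL,
                  ssvs_config(n_iterations = 3000, burn_in = 500, seed = 3))
  mean_incl <- mean(res$inclusion_prob)
  expect_gt(mean_incl, 0.005); expect_lt(mean_incl, 0.015)
})

test_that("incremental residuals equal full recomputation", {
  set.seed(6)
  X <- matrix(rbinom(80 * 200, 2, 0.3), 80, 200)
  colnames(X) <- paste0("m", 1:200)
  y <- rnorm(80) + X[, 5] * 0.5
  res <- run_ssvs(y, X, NULL,
                  ssvs_config(n_iterations = 2000, burn_in = 100,
                              debug_every = 500, seed = 4))
  expect_lt(res$max_resid_drift, 1e-8)
})

test_that("with all indicators on and fixed variances the sampler is ridge", {
  set.seed(9)
  n <- 150; m <- 300
  X <- matrix(rbinom(n * m, 2, 0.3), n, m)
  colnames(X) <- paste0("m", 1:m)
  y <- as.numeric(X[, 1] * 0.5 - X[, 2] * 0.3 + rnorm(n))
  s2b <- 0.1; s2e <- 1
  res <- run_ssvs(y, X, NULL,
                  ssvs_config(pi_large = 1 - 1e-12, n_iterations = 6000,
                              burn_in = 1000, fix_sigma2_beta = s2b,
                              fix_sigma2_e = s2e, seed = 2))
  Xc <- sweep(X, 2, colMeans(X))
  ridge <- solve(crossprod(Xc) + diag(s2e / s2b, m),
                 crossprod(Xc, y - mean(y)))
  expect_gt(cor(res$beta, as.numeric(ridge)), 0.98)
  expect_lt(max(abs(res$beta - ridge)), 0.06) # ~3 MC SE at this chain length
})

test_that("marker update order does not change GEBVs beyond MC error", {
  dat <- get_mini_data()
  pop <- dat$panel$population
  mp <- subset_panel(dat$panel, snps = dat$arch$marker_ids)
  arch <- draw_active_qtl(dat$arch, 20, seed = 31)
  eff <- sample_correlated_effects(20, 1, n_populations = 3, seed = 31)
  colnames(eff$alpha) <- unique(pop)
  tbv <- compute_tbv(dat$panel, arch, eff)
  y <- simulate_phenotypes(tbv, 0.95, pop, seed = 31)$phenotype
  ref <- which(pop == "HF")[1:200]
  cand <- which(pop == "HF")[201:260]
  rp <- subset_panel(mp, individuals = ref)
  cp <- subset_panel(mp, individuals = cand)

  run1 <- function(seed, ro) run_ssvs(
    y[ref], rp, cp, ssvs_config(n_iterations = 1500, burn_in = 300,
                                random_order = ro, seed = seed))$gebv
  fixed <- sapply(1:3, run1, ro = FALSE)
  rand <- sapply(4:6, run1, ro = TRUE)
  mc_se <- mean(apply(cbind(fixed, rand), 1, sd)) / sqrt(3)
  expect_lt(mean(abs(rowMeans(fixed) - rowMeans(rand))), 3 * mc_se)
  expect_gt(cor(rowMeans(fixed), rowMeans(rand)), 0.98)
})

test_that("GEBV prediction is linear in the posterior mean effects", {
  dat <- get_mini_data()
  pop <- dat$panel$population
  mp <- subset_panel(dat$panel, snps = dat$arch$marker_ids)
  ref <- which(pop == "HF")[1:150]
  cand <- which(pop == "GWH")
  rp <- subset_panel(mp, individuals = ref)
  cp <- subset_panel(mp, individuals = cand)
  arch <- draw_active_qtl(dat$arch, 10, seed = 8)
  eff <- sample_correlated_effects(10, 1, n_populations = 3, seed = 8)
  colnames(eff$alpha) <- unique(pop)
  y <- simulate_phenotypes(compute_tbv(dat$panel, arch, eff), 0.95, pop,
                           seed = 8)$phenotype
  res <- run_ssvs(y[ref], rp, cp,
                  ssvs_config(n_iterations = 600, burn_in = 100, seed = 5))
  # chain-accumulated GEBVs equal candidate matrix x posterior mean effects
  expect_equal(res$gebv, predict_gebv(res, cp), tolerance = 1e-8)

  # hand-computable single-marker prediction
  one <- structure(list(beta = c(m1 = 0.5), marker_ids = "m1",
                        center = c(m1 = 0)), class = "ssvs_result")
  counts <- matrix(0:2, 3, 1, dimnames = list(NULL, "m1"))
  expect_equal(unname(predict_gebv(one, counts)), c(0, 0.5, 1.0))

  # identical genotypes give identical GEBVs
  same <- matrix(1, 4, 1, dimnames = list(NULL, "m1"))
  expect_length(unique(predict_gebv(one, same)), 1L)

  # marker mismatch names the offending ids
  expect_error(predict_gebv(one, matrix(1, 2, 1, dimnames = list(NULL, "zz"))),
               "m1")
})

test_that("non-finite phenotypes are rejected", {
  X <- matrix(rbinom(30, 2, 0.5), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_error(run_ssvs(c(rnorm(9), NA), X, NULL), "finite")
  expect_error(run_ssvs(c(rnorm(9), Inf), X, NULL), "finite")
})
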