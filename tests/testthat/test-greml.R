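test_that("GRM matches a brute-force double loop", {
  g <- matrix(c(0, 1, 2, 2, 1, 0, 1, 1, 2, 0, 0, 1), 3, 4,
              dimnames = list(c("a", "b", "c"), paste0("m", 1:4)))
  grm <- compute_grm(g)
  p <- colMeans(g) / 2
  denom <- 2 * sum(p * (1 - p))
  G_brute <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    s <- 0
    for (k in 1:4) s <- s + (g[i, k] - 2 * p[k]) * (g[j, k] - 2 * p[k])
    G_brute[i, j] <- s / denom
  }
  expect_equal(unname(grm$G), G_brute, tolerance = 1e-12)
  expect_equal(grm$scale, denom)
})

test_that("identical genotypes give identical relationships", {
  g <- rbind(c(0, 2, 1, 1), c(0, 2, 1, 1), c(2, 0, 1, 2))
  colnames(g) <- paste0("m", 1:4)
  G <- compute_grm(g)$G
  expect_equal(G[1, 2], G[1, 1])
  expect_equal(G[1, 2], G[2, 2])
})

test_that("Hardy-Weinberg genotypes give near-zero mean off-diagonal", {
  set.seed(11)
  n <- 500
  g <- matrix(rbinom(n * 400, 2, rep(runif(400, 0.1, 0.9), each = n)), n, 400)
  colnames(g) <- paste0("m", 1:400)
  G <- compute_grm(g)$G
  expect_lt(abs(mean(G[upper.tri(G)])), 0.01)
  expect_lt(abs(mean(diag(G)) - 1), 0.2)
  expect_error(compute_grm(matrix(2, 5, 3,
                                  dimnames = list(NULL, c("a", "b", "c")))),
               "monomorphic")
})

test_that("REML recovers the simulated heritability", {
  dat <- get_mini_data()
  hf <- which(dat$panel$population == "HF")
  G <- compute_grm(subset_panel(dat$panel, individuals = hf,
                                snps = dat$arch$marker_ids))$G
  n <- length(hf)
  L <- chol(G + diag(1e-4, n))
  X <- matrix(1, n, 1)
  h2_hat <- vapply(1:12, function(i) {
    set.seed(100 + i)
    g_true <- drop(crossprod(L, rnorm(n))) * sqrt(0.95)
    y <- 5 + g_true + rnorm(n, 0, sqrt(0.05))
    fit_greml(y, X, G, tolerance = 1e-8)$h2
  }, numeric(1))
  expect_lt(abs(median(h2_hat) - 0.95), 0.05)

  # null phenotypes: heritability estimate collapses
  h2_null <- vapply(1:12, function(i) {
    set.seed(200 + i)
    fit_greml(rnorm(n), X, G)$h2
  }, numeric(1))
  expect_lte(median(h2_null), 0.1)
})

test_that("restricted likelihood never decreases along the iterations", {
  dat <- get_mini_data()
  hf <- which(dat$panel$population == "HF")[1:150]
  panel <- subset_panel(dat$panel, individuals = hf,
                        snps = dat$arch$marker_ids)
  G <- compute_grm(panel)$G
  set.seed(21)
  y <- drop(chol(G + diag(0.01, 150)) %*% rnorm(150)) + rnorm(150, 0, 0.5)
  fit <- fit_greml(y, matrix(1, 150, 1), G)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_gte(fit$sigma2_a, 0); expect_gte(fit$sigma2_e, 0)
})

test_that("REML is invariant to phenotype location shifts", {
  dat <- get_mini_data()
  hf <- which(dat$panel$population == "HF")[1:120]
  G <- compute_grm(subset_panel(dat$panel, individuals = hf,
                                snps = dat$arch$marker_ids))$G
  set.seed(31)
  y <- drop(chol(G + diag(0.01, 120)) %*% rnorm(120)) + rnorm(120, 0, 0.3)
  X <- matrix(1, 120, 1)
  f1 <- fit_greml(y, X, G)
  f2 <- fit_greml(y + 100, X, G)
  expect_equal(f1$sigma2_a, f2$sigma2_a, tolerance = 1e-4)
  expect_equal(f1$sigma2_e, f2$sigma2_e, tolerance = 1e-4)
  expect_equal(f2$fixed_effects - f1$fixed_effects, 100, tolerance = 1e-4)
  expect_error(fit_greml(y, cbind(1, 1), G), "rank deficient")
})

test_that("BLUP solutions equal a dense mixed-model-equation solve", {
  set.seed(41)
  n <- 5; n_ref <- 3
  g <- matrix(rbinom(n * 12, 2, 0.5), n, 12,
              dimnames = list(paste0("i", 1:n), paste0("m", 1:12)))
  G <- compute_grm(g)$G + diag(0.05, n) # keep G invertible for the MME oracle
  y <- c(1.2, -0.3, 0.8)
  X <- matrix(1, n_ref, 1)
  fit <- list(sigma2_a = 0.7, sigma2_e = 0.4)
  blup <- solve_blup(fit, y, X, G, 1:n_ref)

  # dense MME with G^{-1}: [X'X  X'Z; Z'X  Z'Z + lambda G^-1] [b; g] = [X'y; Z'y]
  Z <- cbind(diag(n_ref), matrix(0, n_ref, n - n_ref))
  lambda <- fit$sigma2_e / fit$sigma2_a
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + lambda * solve(G)))
  sol <- solve(C, c(crossprod(X, y), crossprod(Z, y)))
  expect_equal(blup$fixed_effects, unname(sol[1]), tolerance = 1e-10)
  expect_equal(unname(blup$gebv), unname(sol[-1]), tolerance = 1e-10)
})

test_that("a candidate unrelated to the reference gets GEBV zero", {
  G <- diag(4)
  rownames(G) <- colnames(G) <- paste0("i", 1:4)
  blup <- solve_blup(list(sigma2_a = 1, sigma2_e = 0.5),
                     c(1, 2, 3), matrix(1, 3, 1), G, 1:3)
  expect_equal(unname(blup$gebv["i4"]), 0)
})

test_that("in the h2 -> 1 limit reference GEBVs interpolate the phenotypes", {
  set.seed(51)
  g <- matrix(rbinom(8 * 40, 2, 0.5), 8, 40,
              dimnames = list(paste0("i", 1:8), paste0("m", 1:40)))
  G <- compute_grm(g)$G + diag(0.01, 8)
  y <- rnorm(6)
  X <- matrix(1, 6, 1)
  blup <- solve_blup(list(sigma2_a = 1, sigma2_e = 0), y, X, G, 1:6)
  expect_equal(unname(blup$gebv[1:6]), as.numeric(y - blup$fixed_effects),
               tolerance = 1e-6)
})

test_that("G-based BLUP equals SNP-BLUP ridge prediction", {
  dat <- get_mini_data()
  pop <- dat$panel$population
  idx <- c(which(pop == "HF")[1:100], which(pop == "GWH")[1:30])
  panel <- subset_panel(dat$panel, individuals = idx,
                        snps = dat$arch$marker_ids)
  grm <- compute_grm(panel)
  n_ref <- 100
  set.seed(61)
  y <- rnorm(n_ref)
  X <- matrix(1, n_ref, 1)
  fit <- list(sigma2_a = 0.6, sigma2_e = 0.4)
  blup <- solve_blup(fit, y, X, grm$G, 1:n_ref)

  W <- sweep(panel$genotypes, 2, 2 * grm$allele_frequencies)
  Wr <- W[1:n_ref, ]; Wc <- W[-(1:n_ref), ]
  lambda <- fit$sigma2_e / (fit$sigma2_a / grm$scale)
  a_hat <- solve(crossprod(Wr) + diag(lambda, ncol(Wr)),
                 crossprod(Wr, y - blup$fixed_effects))
  expect_equal(unname(blup$gebv[-(1:n_ref)]), as.numeric(Wc %*% a_hat),
               tolerance = 1e-8)
})
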