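test_that("candidate/marker partition is a disjoint cover", {
  ids <- sprintf("s%03d", 1:100)
  arch <- partition_candidate_qtl(ids, 10, seed = 4)
  expect_length(arch$candidate_qtl_ids, 10)
  expect_length(arch$marker_ids, 90)
  expect_length(intersect(arch$candidate_qtl_ids, arch$marker_ids), 0)
  expect_setequal(c(arch$candidate_qtl_ids, arch$marker_ids), ids)

  expect_equal(partition_candidate_qtl(ids, 0)$marker_ids, ids)
  expect_error(partition_candidate_qtl(ids, 100), "smaller")
})

test_that("active QTL are drawn uniformly from the candidates", {
  arch <- partition_candidate_qtl(sprintf("s%02d", 1:20), 5, seed = 1)
  full <- draw_active_qtl(arch, 5, seed = 2)
  expect_setequal(full$active_qtl_ids, full$candidate_qtl_ids)
  expect_error(draw_active_qtl(arch, 6), "exceeds")

  a3 <- draw_active_qtl(arch, 3, seed = 9)
  expect_length(a3$active_qtl_ids, 3)
  expect_true(all(a3$active_qtl_ids %in% arch$candidate_qtl_ids))
  expect_false(anyDuplicated(a3$active_qtl_ids) > 0)

  # m = 1 from 5 candidates, 1000 draws: each candidate at frequency 0.2
  draws <- vapply(1:1000, function(i) {
    draw_active_qtl(arch, 1, seed = i)$active_qtl_ids
  }, character(1))
  freq <- table(factor(draws, levels = arch$candidate_qtl_ids)) / 1000
  expect_true(all(abs(freq - 0.2) < 0.04))
})

test_that("correlated effects match their target correlation", {
  perfect <- sample_correlated_effects(50, 1.0, n_populations = 3, seed = 1)
  expect_equal(perfect$alpha[, 1], perfect$alpha[, 2], tolerance = 1e-12)
  expect_equal(perfect$alpha[, 1], perfect$alpha[, 3], tolerance = 1e-12)

  big <- sample_correlated_effects(10000, 0.8, seed = 2)
  r <- cor(big$alpha[, 1], big$alpha[, 2])
  expect_gte(r, 0.78); expect_lte(r, 0.82)

  expect_error(
    sample_correlated_effects(5, matrix(c(1, 2, 2, 1), 2), seed = 1),
    "positive semi-definite")
})

test_that("shared Gaussian draws pair conditions across correlation targets", {
  z <- matrix(rnorm(60), 30, 2)
  e1 <- sample_correlated_effects(30, 1.0, z = z)
  e2 <- sample_correlated_effects(30, 0.8, z = z)
  expect_equal(e1$alpha[, 1], e2$alpha[, 1], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(e1$alpha[, 2], e2$alpha[, 2])))
})

test_that("TBV is the dot product of own-population effects with QTL dosages", {
  map <- data.frame(snp_id = c("q1", "q2"), chromosome = "1",
                    position = c(1L, 2L), genetic_position = c(0, 0.1))
  panel <- genotype_panel(matrix(c(0L, 1L, 2L, 1L), 2, 2), c("i1", "i2"),
                          c("A", "A"), map)
  arch <- structure(list(candidate_qtl_ids = c("q1", "q2"),
                         active_qtl_ids = c("q1", "q2"),
                         marker_ids = character(0), m = 2L),
                    class = "qtl_architecture")
  alpha <- matrix(c(0.5, -1), 2, 1, dimnames = list(NULL, "A"))
  expect_equal(unname(compute_tbv(panel, arch, alpha)), c(-2.0, -0.5))

  zero <- genotype_panel(matrix(0L, 2, 2), c("i1", "i2"), c("A", "A"), map)
  expect_equal(unname(compute_tbv(zero, arch, alpha)), c(0, 0))

  # scaling: doubling effects doubles TBVs exactly
  expect_equal(compute_tbv(panel, arch, 2 * alpha),
               2 * compute_tbv(panel, arch, alpha))

  # r_g = 1: invariant to which population column is used
  a2 <- matrix(c(0.5, -1, 0.5, -1), 2, 2, dimnames = list(NULL, c("A", "B")))
  pb <- genotype_panel(panel$genotypes, panel$individual_ids, c("B", "B"), map)
  expect_equal(unname(compute_tbv(pb, arch, a2)),
               unname(compute_tbv(panel, arch, a2)))

  bad <- genotype_panel(panel$genotypes, panel$individual_ids, c("A", "Z"), map)
  expect_error(compute_tbv(bad, arch, alpha), "unknown population")
})

test_that("phenotypes realize the requested heritability", {
  tbv <- rnorm(10000)
  pop <- rep("P", 10000)
  exact <- simulate_phenotypes(tbv, 1.0, pop, seed = 1)
  expect_identical(exact$phenotype, tbv)

  half <- simulate_phenotypes(tbv, 0.5, pop, seed = 2)
  h2_real <- var(tbv) / var(half$phenotype)
  expect_gte(h2_real, 0.48); expect_lte(h2_real, 0.52)

  # the environmental-variance multiplier at h2 = 0.95
  expect_equal(1 / 0.95 - 1, 0.05263, tolerance = 1e-3)
  env_var <- vapply(1:30, function(i) {
    tr <- simulate_phenotypes(tbv, 0.95, pop, seed = i)
    var(tr$phenotype - tbv)
  }, numeric(1))
  expect_equal(mean(env_var), (1 / 0.95 - 1) * var(tbv), tolerance = 0.02)

  expect_error(simulate_phenotypes(tbv, 0, pop), "h2")
  expect_error(simulate_phenotypes(tbv, 1.2, pop), "h2")
  expect_warning(simulate_phenotypes(rep(1, 5), 0.5, rep("P", 5)),
                 "variance is 0")
})

test_that("median realized heritability tracks h2 across replicates", {
  dat <- get_mini_data()
  pop <- dat$panel$population
  ratios <- vapply(1:15, function(i) {
    arch <- draw_active_qtl(dat$arch, 100, seed = i)
    eff <- sample_correlated_effects(100, 0.8, n_populations = 3, seed = i)
    colnames(eff$alpha) <- unique(pop)
    tbv <- compute_tbv(dat$panel, arch, eff)
    tr <- simulate_phenotypes(tbv, 0.9, pop, seed = i)
    hf <- pop == "HF"
    var(tbv[hf]) / var(tr$phenotype[hf])
  }, numeric(1))
  expect_lt(abs(median(ratios) - 0.9), 0.03)
})

test_that("realized genetic correlation is a plain Pearson correlation", {
  expect_equal(realized_genetic_correlation(cbind(1:3, 1:3))[1, 2], 1.0)
  expect_equal(realized_genetic_correlation(cbind(c(1, 2, 3), c(3, 2, 1)))[1, 2],
               -1.0)
  expect_warning(r1 <- realized_genetic_correlation(matrix(1, 1, 2)),
                 "undefined")
  expect_true(is.na(r1[1, 2]))
  expect_warning(realized_genetic_correlation(matrix(c(1, 2, 5, 3), 2, 2)),
                 "2 QTL")
  expect_warning(r0 <- realized_genetic_correlation(cbind(c(1, 1, 1), 1:3)),
                 "zero-variance")
  expect_true(is.na(r0[1, 2]))
})

test_that("sample correlation is biased downward for few QTL", {
  r <- vapply(1:1000, function(i) {
    e <- sample_correlated_effects(3, 0.8, seed = i)
    realized_genetic_correlation(e)[1, 2]
  }, numeric(1))
  se <- sd(r) / sqrt(length(r))
  expect_lt(mean(r) + 3 * se, 0.8)
})
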