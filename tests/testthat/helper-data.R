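# Shared simulated datasets, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Desk-scale study dataset: 400/100/120 individuals, ~2,600 SNPs,
# 600 candidate QTL. Used by the scenario-level and acceptance tests.
get_desk_data <- function(seed = 3) {
  memo(paste0("desk", seed), simulate_study_data("desk", seed = seed))
}

# Small three-population dataset for module-level tests.
get_mini_data <- function(seed = 7) {
  memo(paste0("mini", seed), {
    config <- pop_sim_config(
      n_individuals = c(HF = 300, GWH = 80, MRY = 100),
      n_snps_per_chromosome = 300,
      within_pop_ne = c(250L, 160L, 200L),
      half_sib_family_size = 20,
      seed = seed)
    sim <- simulate_genotypes(config)
    arch <- partition_candidate_qtl(sim$panel, 250, seed = seed)
    c(sim, list(arch = arch, config = config))
  })
}

# Deterministic toy panel: two populations, independent SNPs.
toy_panel <- function(n = 20, s = 30, seed = 5, pops = c("A", "B")) {
  set.seed(seed)
  g <- matrix(rbinom(n * s, 2, runif(s, 0.2, 0.8)[rep(seq_len(s), each = n)]),
              n, s)
  map <- data.frame(snp_id = sprintf("t%03d", seq_len(s)), chromosome = "1",
                    position = seq_len(s) * 10L,
                    genetic_position = (seq_len(s) - 1) / s)
  genotype_panel(g, sprintf("i%02d", seq_len(n)),
                 rep(pops, length.out = n), map)
}
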