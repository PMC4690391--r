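#' Configuration for the multi-population genotype simulator
#'
#' Defines the structure of the simulated genotype data: three cattle-like
#' populations (by default sized 1033, 105 and 147, labelled HF, GWH and MRY),
#' SNPs on three chromosomes (labelled "13", "23", "28"), founder-mosaic
#' linkage disequilibrium, Wright-Fisher divergence after a population split,
#' and paternal half-sib family structure in the final generation of the
#' largest population.
#'
#' @param n_individuals named integer vector: genotyped individuals per
#'   population. Names are the population labels.
#' @param chromosomes character vector of chromosome labels.
#' @param n_snps_per_chromosome SNPs simulated per chromosome before the
#'   minor-allele-frequency filter.
#' @param chromosome_length_morgans genetic length of each chromosome.
#' @param n_founder_haplotypes number of founder sequences in the base
#'   haplotype mosaic (>= 2). This is the depth of ancestral segment sharing
#'   and sets the LD that is common to all populations (expected ancestral
#'   r-squared is roughly `1 / (n_founder_haplotypes - 1)`); the default of
#'   10 gives the short-range across-population LD persistence reported for
#'   dense cattle genotypes, which across-population prediction relies on.
#' @param founder_switch_rate expected founder switches per morgan along a
#'   mosaic haplotype; 0 gives exact founder copies.
#' @param divergence_generations Wright-Fisher generations of random mating
#'   after the population split.
#' @param within_pop_ne effective size of each population during divergence;
#'   defaults to `pmin(n_individuals, 200)`, which after 50 generations of
#'   drift gives allele-frequency divergence in the range reported between
#'   dairy cattle breeds (Fst roughly 0.1-0.2).
#' @param half_sib_family_size daughters per sire in the final generation of
#'   the largest population.
#' @param maf_threshold combined-data minor allele frequency at or below which
#'   a SNP is deleted; in `[0, 0.5)`.
#' @param seed master seed; expanded into independent per-stage streams.
#' @return an object of class `pop_sim_config`.
#' @export
pop_sim_config <- function(n_individuals = c(HF = 1033, GWH = 105, MRY = 147),
                           chromosomes = c("13", "23", "28"),
                           n_snps_per_chromosome = 10500,
                           chromosome_length_morgans = 1.0,
                           n_founder_haplotypes = 10,
                           founder_switch_rate = 20,
                           divergence_generations = 50,
                           within_pop_ne = NULL,
                           half_sib_family_size = 20,
                           maf_threshold = 0.005,
                           seed = 1L) {
  if (is.null(names(n_individuals))) {
    names(n_individuals) <- paste0("POP", seq_along(n_individuals))
  }
  if (anyDuplicated(names(n_individuals)) > 0L) {
    stop("population labels must be unique", call. = FALSE)
  }
  if (any(n_individuals < 1L)) stop("population sizes must be positive", call. = FALSE)
  if (n_founder_haplotypes < 2L) {
    stop("n_founder_haplotypes must be at least 2", call. = FALSE)
  }
  check_scalar(maf_threshold, 0, 0.5, "maf_threshold", open_hi = TRUE)
  check_scalar(n_snps_per_chromosome, 1, Inf, "n_snps_per_chromosome")
  check_scalar(divergence_generations, 0, Inf, "divergence_generations")
  check_scalar(founder_switch_rate, 0, Inf, "founder_switch_rate")
  if (is.null(within_pop_ne)) within_pop_ne <- pmin(unname(n_individuals), 200L)
  if (length(within_pop_ne) == 1L) {
    within_pop_ne <- rep(within_pop_ne, length(n_individuals))
  }
  if (any(within_pop_ne < 2L)) stop("within_pop_ne must be at least 2", call. = FALSE)
  if (length(chromosome_length_morgans) == 1L) {
    chromosome_length_morgans <- rep(chromosome_length_morgans, length(chromosomes))
  }
  structure(list(
    n_individuals = n_individuals,
    chromosomes = as.character(chromosomes),
    n_snps_per_chromosome = as.integer(n_snps_per_chromosome),
    chromosome_length_morgans = chromosome_length_morgans,
    n_founder_haplotypes = as.integer(n_founder_haplotypes),
    founder_switch_rate = founder_switch_rate,
    divergence_generations = as.integer(divergence_generations),
    within_pop_ne = as.integer(within_pop_ne),
    half_sib_family_size = as.integer(half_sib_family_size),
    maf_threshold = maf_threshold,
    seed = as.integer(seed)
  ), class = "pop_sim_config")
}

# internal: SNP map for one config; 1-based bp positions, genetic positions
# spread uniformly over each chromosome
make_snp_map <- function(config) {
  maps <- lapply(seq_along(config$chromosomes), function(ci) {
    s <- config$n_snps_per_chromosome
    L <- config$chromosome_length_morgans[ci]
    data.frame(
      snp_id = sprintf("snp%s_%05d", config$chromosomes[ci], seq_len(s)),
      chromosome = config$chromosomes[ci],
      position = as.integer(seq_len(s) * 1000L),
      genetic_position = L * (seq_len(s) - 1) / max(1L, s - 1L),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, maps)
}

#' Simulate a base pool of mosaic haplotypes
#'
#' Each pool haplotype is a first-order mosaic of `n_founder_haplotypes`
#' founder sequences: along a chromosome the copied founder switches between
#' adjacent SNPs with probability proportional to their genetic distance
#' (`founder_switch_rate` per morgan). Shared founder segments among pool
#' haplotypes create linkage disequilibrium that decays with genetic distance.
#' Per-SNP allele frequencies are drawn from a symmetric U-shaped Beta(0.5,
#' 0.5) distribution truncated to `[0.1, 0.9]` to keep loci away from fixation.
#'
#' @param config a [pop_sim_config()].
#' @param n_haplotypes pool size; defaults to `2 * sum(within_pop_ne)` so the
#'   populations can be founded from disjoint draws.
#' @return list with `haplotypes` (binary matrix, haplotypes x SNPs) and
#'   `snp_map` (data frame: snp_id, chromosome, position, genetic_position).
#' @export
simulate_base_haplotypes <- function(config, n_haplotypes = NULL) {
  stopifnot(inherits(config, "pop_sim_config"))
  if (is.null(n_haplotypes)) n_haplotypes <- 2L * sum(config$within_pop_ne)
  set.seed(derive_seed(config$seed, "base-haplotypes"))
  snp_map <- make_snp_map(config)
  S <- nrow(snp_map)
  nf <- config$n_founder_haplotypes

  # U-shaped frequencies truncated away from fixation
  p <- 0.1 + 0.8 * stats::rbeta(S, 0.5, 0.5)
  founders <- matrix(stats::rbinom(nf * S, 1L, rep(p, each = nf)), nrow = nf)

  # per-adjacent-pair switch probability, clipped at 1; forced switch (prob 1)
  # at chromosome boundaries so chromosomes are independent
  d <- diff(snp_map$genetic_position)
  new_chrom <- snp_map$chromosome[-1] != snp_map$chromosome[-S]
  p_switch <- pmin(1, config$founder_switch_rate * pmax(d, 0))
  p_switch[new_chrom] <- 1

  haps <- matrix(0L, nrow = n_haplotypes, ncol = S)
  for (h in seq_len(n_haplotypes)) {
    switches <- stats::rbinom(S - 1L, 1L, p_switch)
    seg <- cumsum(c(1L, switches))
    f <- sample.int(nf, max(seg), replace = TRUE)[seg]
    haps[h, ] <- founders[cbind(f, seq_len(S))]
  }
  list(haplotypes = haps, snp_map = snp_map)
}

# internal: one gamete from a diploid parent (two haplotype rows).
# Crossovers per chromosome: Poisson with mean = genetic length (Haldane, no
# interference), positions uniform in genetic distance.
meiosis <- function(hap1, hap2, gpos, chrom_index, chrom_lengths) {
  gamete <- integer(length(hap1))
  for (ci in seq_along(chrom_lengths)) {
    idx <- chrom_index[[ci]]
    L <- chrom_lengths[ci]
    n_xo <- stats::rpois(1L, L)
    phase0 <- sample.int(2L, 1L)
    if (n_xo == 0L) {
      gamete[idx] <- if (phase0 == 1L) hap1[idx] else hap2[idx]
    } else {
      xo <- sort(stats::runif(n_xo, 0, L))
      phase <- (phase0 + findInterval(gpos[idx], xo)) %% 2L
      gamete[idx] <- ifelse(phase == 1L, hap1[idx], hap2[idx])
    }
  }
  gamete
}

# internal: advance one Wright-Fisher generation of random mating.
# haps: matrix with rows 2i-1, 2i = the two haplotypes of individual i.
wf_generation <- function(haps, n_offspring, gpos, chrom_index, chrom_lengths) {
  n_parents <- nrow(haps) / 2L
  out <- matrix(0L, nrow = 2L * n_offspring, ncol = ncol(haps))
  sires <- sample.int(n_parents, n_offspring, replace = TRUE)
  dams <- sample.int(n_parents, n_offspring, replace = TRUE)
  for (i in seq_len(n_offspring)) {
    out[2L * i - 1L, ] <- meiosis(haps[2L * sires[i] - 1L, ], haps[2L * sires[i], ],
                                  gpos, chrom_index, chrom_lengths)
    out[2L * i, ] <- meiosis(haps[2L * dams[i] - 1L, ], haps[2L * dams[i], ],
                             gpos, chrom_index, chrom_lengths)
  }
  list(haps = out, sire = sires, dam = dams)
}

#' Evolve populations from a base haplotype pool
#'
#' Founds each population from a disjoint random draw of base haplotypes, then
#' evolves `divergence_generations` of Wright-Fisher random mating with
#' recombination (pure drift: no selection, no mutation), so that allele
#' frequencies and LD phase diverge between populations. The final genotyped
#' generation of the largest population is produced from a limited set of
#' sires (each with `half_sib_family_size` daughters) to create paternal
#' half-sib family structure. The pedigree of the final two generations is
#' recorded; the parent generation are base animals with unknown parents.
#'
#' @param base output of [simulate_base_haplotypes()].
#' @param config the same [pop_sim_config()].
#' @return list with `panel` (a `genotype_panel`: `genotypes` individuals x
#'   SNPs allele-count matrix with entries 0/1/2, `individual_ids`,
#'   `population`, `snp_map`) and `pedigree` (data frame: id, sire, dam,
#'   population, generation; unknown parents are `NA`).
#' @export
evolve_populations <- function(base, config) {
  stopifnot(inherits(config, "pop_sim_config"))
  if (any(config$n_individuals < 2L)) {
    stop("each population must have at least 2 individuals", call. = FALSE)
  }
  snp_map <- base$snp_map
  gpos <- snp_map$genetic_position
  chrom_index <- split(seq_len(nrow(snp_map)), factor(snp_map$chromosome,
                                                      levels = config$chromosomes))
  chrom_lengths <- config$chromosome_length_morgans
  labels <- names(config$n_individuals)
  largest <- which.max(config$n_individuals)

  set.seed(derive_seed(config$seed, "drift"))
  # disjoint founder draws
  need <- 2L * config$within_pop_ne
  if (sum(need) > nrow(base$haplotypes)) {
    stop("base pool too small for disjoint founder draws", call. = FALSE)
  }
  draw_order <- sample.int(nrow(base$haplotypes))
  offsets <- cumsum(c(0L, need))

  geno_list <- vector("list", length(labels))
  ped_list <- vector("list", length(labels))

  for (p in seq_along(labels)) {
    ne <- config$within_pop_ne[p]
    rows <- draw_order[(offsets[p] + 1L):offsets[p + 1L]]
    haps <- base$haplotypes[rows, , drop = FALSE]
    for (g in seq_len(config$divergence_generations)) {
      haps <- wf_generation(haps, ne, gpos, chrom_index, chrom_lengths)$haps
    }
    # parent generation (recorded as base animals), then the genotyped
    # final generation
    n_final <- config$n_individuals[p]
    parent_ids <- sprintf("%s_P%04d", labels[p], seq_len(ne))
    final_ids <- sprintf("%s_%04d", labels[p], seq_len(n_final))

    if (p == largest && config$half_sib_family_size > 1L) {
      fam <- config$half_sib_family_size
      n_sires <- ceiling(n_final / fam)
      if (n_sires > ne) n_sires <- ne
      sire_pool <- sample.int(ne, n_sires)
      sires <- rep(sire_pool, each = fam, length.out = n_final)
      dams <- vapply(sires, function(s) sample(setdiff(seq_len(ne), s), 1L), 1L)
    } else {
      sires <- sample.int(ne, n_final, replace = TRUE)
      dams <- vapply(sires, function(s) sample(setdiff(seq_len(ne), s), 1L), 1L)
    }
    geno <- matrix(0L, nrow = n_final, ncol = nrow(snp_map))
    for (i in seq_len(n_final)) {
      g1 <- meiosis(haps[2L * sires[i] - 1L, ], haps[2L * sires[i], ],
                    gpos, chrom_index, chrom_lengths)
      g2 <- meiosis(haps[2L * dams[i] - 1L, ], haps[2L * dams[i], ],
                    gpos, chrom_index, chrom_lengths)
      geno[i, ] <- g1 + g2
    }
    geno_list[[p]] <- geno
    ped_list[[p]] <- rbind(
      data.frame(id = parent_ids, sire = NA_character_, dam = NA_character_,
                 population = labels[p], generation = 0L,
                 stringsAsFactors = FALSE),
      data.frame(id = final_ids, sire = parent_ids[sires],
                 dam = parent_ids[dams], population = labels[p],
                 generation = 1L, stringsAsFactors = FALSE)
    )
  }

  genotypes <- do.call(rbind, geno_list)
  population <- rep(labels, config$n_individuals)
  individual_ids <- unlist(lapply(seq_along(labels), function(p) {
    sprintf("%s_%04d", labels[p], seq_len(config$n_individuals[p]))
  }), use.names = FALSE)
  panel <- genotype_panel(genotypes, individual_ids, population, snp_map)
  list(panel = panel, pedigree = do.call(rbind, ped_list))
}

#' Construct a genotype panel
#'
#' @param genotypes individuals x SNPs matrix of allele counts in `{0, 1, 2}`.
#' @param individual_ids character vector, one per row.
#' @param population population label per individual.
#' @param snp_map data frame with columns snp_id, chromosome, position,
#'   genetic_position; one row per SNP column.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(genotypes, individual_ids, population, snp_map) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (anyNA(genotypes) || !all(genotypes %in% 0:2)) {
    stop("allele counts must be 0, 1 or 2 with no missing values", call. = FALSE)
  }
  stopifnot(nrow(genotypes) == length(individual_ids),
            length(individual_ids) == length(population),
            ncol(genotypes) == nrow(snp_map))
  for (chr in unique(snp_map$chromosome)) {
    pos <- snp_map$position[snp_map$chromosome == chr]
    if (any(diff(pos) <= 0)) {
      stop("positions must be strictly increasing within a chromosome",
           call. = FALSE)
    }
  }
  rownames(genotypes) <- individual_ids
  colnames(genotypes) <- snp_map$snp_id
  structure(list(genotypes = genotypes,
                 individual_ids = as.character(individual_ids),
                 population = as.character(population),
                 snp_map = snp_map),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d SNPs\n",
              nrow(x$genotypes), ncol(x$genotypes)))
  cat("populations:", paste(sprintf("%s (%d)", names(table(x$population)),
                                    table(x$population)), collapse = ", "), "\n")
  cat("chromosomes:", paste(unique(x$snp_map$chromosome), collapse = ", "), "\n")
  invisible(x)
}

#' Combined-data minor allele frequencies of a panel
#'
#' @param panel a `genotype_panel` or an allele-count matrix.
#' @return per-SNP minor allele frequency over all individuals.
#' @export
panel_maf <- function(panel) {
  g <- if (inherits(panel, "genotype_panel")) panel$genotypes else panel
  p <- colMeans(g) / 2
  pmin(p, 1 - p)
}

#' Delete SNPs at or below a minor-allele-frequency threshold
#'
#' Frequencies are computed on the combined data over all populations. A SNP
#' whose combined minor allele frequency is equal to or lower than `threshold`
#' is deleted; monomorphic SNPs are always deleted. The individual set is
#' unchanged and the operation is idempotent.
#'
#' @param panel a `genotype_panel`.
#' @param threshold MAF threshold in `[0, 0.5)`; default 0.005 (0.5 %).
#' @return the filtered `genotype_panel`.
#' @export
apply_maf_filter <- function(panel, threshold = 0.005) {
  stopifnot(inherits(panel, "genotype_panel"))
  check_scalar(threshold, 0, 0.5, "threshold", open_hi = TRUE)
  keep <- panel_maf(panel) > threshold
  genotype_panel(panel$genotypes[, keep, drop = FALSE], panel$individual_ids,
                 panel$population, panel$snp_map[keep, , drop = FALSE])
}

#' Subset a panel by individuals and/or SNPs
#'
#' @param panel a `genotype_panel`.
#' @param individuals individual ids or logical/integer row index (optional).
#' @param snps snp ids or logical/integer column index (optional).
#' @return the subset `genotype_panel`.
#' @export
subset_panel <- function(panel, individuals = NULL, snps = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  ri <- seq_along(panel$individual_ids)
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) {
      match(individuals, panel$individual_ids)
    } else ri[individuals]
    if (anyNA(ri)) stop("unknown individual ids", call. = FALSE)
  }
  ci <- seq_len(nrow(panel$snp_map))
  if (!is.null(snps)) {
    ci <- if (is.character(snps)) match(snps, panel$snp_map$snp_id) else ci[snps]
    if (anyNA(ci)) stop("unknown snp ids", call. = FALSE)
  }
  genotype_panel(panel$genotypes[ri, ci, drop = FALSE],
                 panel$individual_ids[ri], panel$population[ri],
                 panel$snp_map[ci, , drop = FALSE])
}

#' Simulate a complete multi-population genotype dataset
#'
#' Convenience wrapper: base haplotypes, population divergence, and the
#' combined-data MAF filter in one call.
#'
#' @param config a [pop_sim_config()].
#' @return list with `panel` (MAF-filtered `genotype_panel`) and `pedigree`.
#' @export
simulate_genotypes <- function(config = pop_sim_config()) {
  base <- simulate_base_haplotypes(config)
  out <- evolve_populations(base, config)
  out$panel <- apply_maf_filter(out$panel, config$maf_threshold)
  out
}

#' Mean r-squared linkage disequilibrium by genetic-distance bin
#'
#' Utility used to check that simulated LD decays with distance. Samples SNP
#' pairs within chromosomes, computes squared genotype correlation, and
#' averages per distance bin.
#'
#' @param panel a `genotype_panel` (or haplotype matrix with `snp_map`).
#' @param snp_map required when `panel` is a bare matrix.
#' @param breaks genetic-distance bin edges in morgans.
#' @param max_pairs number of random SNP pairs sampled.
#' @param seed RNG seed for pair sampling.
#' @return data frame: bin midpoint, mean r2, number of pairs.
#' @export
ld_decay <- function(panel, snp_map = NULL,
                     breaks = seq(0, 1, by = 0.05), max_pairs = 20000,
                     seed = 1L) {
  if (inherits(panel, "genotype_panel")) {
    g <- panel$genotypes
    snp_map <- panel$snp_map
  } else {
    g <- panel
    if (is.null(snp_map)) stop("snp_map required for a bare matrix", call. = FALSE)
  }
  set.seed(seed)
  i <- sample.int(ncol(g), max_pairs, replace = TRUE)
  j <- sample.int(ncol(g), max_pairs, replace = TRUE)
  same <- snp_map$chromosome[i] == snp_map$chromosome[j] & i != j
  i <- i[same]; j <- j[same]
  d <- abs(snp_map$genetic_position[i] - snp_map$genetic_position[j])
  keep <- d <= max(breaks)
  i <- i[keep]; j <- j[keep]; d <- d[keep]
  r2 <- vapply(seq_along(i), function(k) {
    suppressWarnings(stats::cor(g[, i[k]], g[, j[k]]))^2
  }, numeric(1))
  bin <- cut(d, breaks, include.lowest = TRUE)
  ok <- !is.na(r2)
  agg <- tapply(r2[ok], bin[ok], mean)
  data.frame(distance = (breaks[-length(breaks)] + breaks[-1]) / 2,
             mean_r2 = as.numeric(agg),
             n_pairs = as.numeric(tapply(rep(1, sum(ok)), bin[ok], sum)))
}
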