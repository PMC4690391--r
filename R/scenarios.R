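#' Specification of one prediction scenario
#'
#' The study design compares within-population prediction (the base scenario:
#' reference and candidates drawn from the same population via k-fold
#' cross-validation) with four across-population scenarios in which one or two
#' populations form the reference and a different population supplies the
#' selection candidates.
#'
#' @param reference character vector of reference population labels.
#' @param candidate single candidate population label. Must not be among the
#'   reference populations unless it is the only reference population (the
#'   cross-validated base scenario).
#' @param n_qtl number of active QTL per replicate (typically 3, 30, 300,
#'   3000).
#' @param r_g genetic correlation between populations (typically 1.0, 0.8,
#'   0.4).
#' @param n_replicates trait replicates (default 100).
#' @param models subset of `c("ssvs", "gblup")`.
#' @param h2 heritability of the simulated trait (default 0.95).
#' @param n_folds folds for the base scenario's cross-validation (default 20).
#' @param id scenario label carried into the output table.
#' @param seed master seed; replicates derive their own streams from it.
#' @return object of class `scenario_spec`.
#' @export
scenario_spec <- function(reference, candidate, n_qtl, r_g = 1.0,
                          n_replicates = 100L, models = c("ssvs", "gblup"),
                          h2 = 0.95, n_folds = 20L, id = NULL, seed = 1L) {
  models <- match.arg(models, several.ok = TRUE)
  is_base <- identical(sort(unique(reference)), sort(candidate))
  if (!is_base && candidate %in% reference) {
    stop("candidate population must not be in the reference (except base CV)",
         call. = FALSE)
  }
  if (is.null(id)) {
    id <- if (is_base) "base" else paste0(paste(reference, collapse = "+"),
                                          "->", candidate)
  }
  structure(list(reference = reference, candidate = candidate,
                 is_base = is_base, n_qtl = as.integer(n_qtl), r_g = r_g,
                 n_replicates = as.integer(n_replicates), models = models,
                 h2 = h2, n_folds = as.integer(n_folds), id = id,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' The study's five standard scenarios for a three-population panel
#'
#' Base: within the largest population by cross-validation. Scenarios 1-4:
#' candidates from one small population, reference either the large
#' population alone or the large population plus the other small one (the
#' large population is always in the reference).
#'
#' @param labels population labels ordered large, small1, small2.
#' @param ... passed to [scenario_spec()] (n_qtl, r_g, seed, ...).
#' @return named list of `scenario_spec`s (`base`, `1`, `2`, `3`, `4`).
#' @export
standard_scenarios <- function(labels = c("HF", "GWH", "MRY"), ...) {
  stopifnot(length(labels) == 3L)
  list(
    base = scenario_spec(labels[1], labels[1], id = "base", ...),
    `1` = scenario_spec(labels[1], labels[2], id = "1", ...),
    `2` = scenario_spec(labels[c(1, 3)], labels[2], id = "2", ...),
    `3` = scenario_spec(labels[1], labels[3], id = "3", ...),
    `4` = scenario_spec(labels[c(1, 2)], labels[3], id = "4", ...)
  )
}

#' Random k-fold partition
#'
#' Randomly divides `n` individuals into `k` groups whose sizes differ by at
#' most one (e.g. 1033 individuals into 20 groups of 51 or 52); each
#' individual falls in exactly one group.
#'
#' @param n number of individuals.
#' @param k number of folds (`k <= n`).
#' @param seed RNG seed.
#' @return list of `k` integer index vectors.
#' @export
make_cv_folds <- function(n, k, seed = 1L) {
  if (k > n) stop("more folds than individuals", call. = FALSE)
  set.seed(derive_seed(seed, "cv-folds"))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(sample.int(n), rep(seq_len(k), sizes))
}

#' Prediction accuracy: correlation between GEBV and TBV
#'
#' Pearson correlation over the selection candidates of one replicate. A
#' zero-variance input is flagged with a warning and yields `NA`.
#'
#' @param gebv,tbv numeric vectors (at least 3 candidates, finite).
#' @return single correlation in `[-1, 1]`, or `NA`.
#' @export
accuracy <- function(gebv, tbv) {
  stopifnot(length(gebv) == length(tbv))
  if (length(gebv) < 3L) stop("at least 3 candidates required", call. = FALSE)
  if (any(!is.finite(gebv)) || any(!is.finite(tbv))) {
    stop("accuracy requires finite GEBV and TBV", call. = FALSE)
  }
  if (stats::sd(gebv) == 0 || stats::sd(tbv) == 0) {
    warning("zero variance; accuracy undefined")
    return(NA_real_)
  }
  stats::cor(gebv, tbv)
}

# internal: GEBVs of the candidate individuals for one model
predict_one_model <- function(model, y_ref, ref_panel, cand_panel,
                              ssvs_cfg, reml_tolerance) {
  if (model == "ssvs") {
    run_ssvs(y_ref, ref_panel, cand_panel, ssvs_cfg)$gebv
  } else {
    run_gblup(y_ref, ref_panel, cand_panel, tolerance = reml_tolerance)$gebv
  }
}

#' Run one scenario over replicates
#'
#' For each replicate: draw the active QTL from the fixed candidate set,
#' sample allele substitution effects with the target genetic correlation
#' (pairing: the underlying Gaussian draws depend on the replicate seed only,
#' so runs that differ in `r_g` or in the model share QTL sets and noise),
#' compute TBVs and phenotypes, train every requested model on the reference
#' phenotypes and markers only, and correlate candidate GEBVs with candidate
#' TBVs. The base scenario trains on k-1 folds and predicts the left-out
#' fold, pooling the GEBVs of all folds into a single accuracy per replicate.
#' A model failure excludes the replicate from every model (paired
#' comparison) and is counted.
#'
#' @param spec a [scenario_spec()].
#' @param panel the MAF-filtered `genotype_panel` of all populations.
#' @param arch a `qtl_architecture` from [partition_candidate_qtl()].
#' @param ssvs an [ssvs_config()] template; its seed is re-derived per
#'   replicate.
#' @param reml_tolerance REML convergence tolerance for the GBLUP model.
#' @return object of class `accuracy_table`: `table` (one row per model:
#'   scenario, model, n_qtl, r_g, mean_accuracy, se_accuracy,
#'   mean_reliability, n_replicates, n_failed) and `replicates` (long data
#'   frame of per-replicate accuracies).
#' @export
run_scenario <- function(spec, panel, arch, ssvs = ssvs_config(),
                         reml_tolerance = 1e-6) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(panel, "genotype_panel"),
            inherits(arch, "qtl_architecture"))
  pops <- unique(panel$population)
  stopifnot(all(c(spec$reference, spec$candidate) %in% pops))
  marker_panel <- subset_panel(panel, snps = arch$marker_ids)

  R <- matrix(spec$r_g, length(pops), length(pops))
  diag(R) <- 1
  dimnames(R) <- list(pops, pops)

  acc <- matrix(NA_real_, nrow = spec$n_replicates, ncol = length(spec$models),
                dimnames = list(NULL, spec$models))
  n_failed <- 0L

  for (rep in seq_len(spec$n_replicates)) {
    rep_seed <- derive_seed(spec$seed, 1000L + rep)
    arch_r <- draw_active_qtl(arch, spec$n_qtl, rep_seed)
    effects <- sample_correlated_effects(arch_r$m, R, seed = rep_seed)
    tbv <- compute_tbv(panel, arch_r, effects)
    trait <- simulate_phenotypes(tbv, spec$h2, panel$population,
                                 seed = rep_seed, replicate = rep)
    y <- trait$phenotype
    names(y) <- panel$individual_ids

    rep_acc <- tryCatch({
      vapply(spec$models, function(model) {
        cfg <- ssvs
        cfg$seed <- derive_seed(rep_seed, model)
        if (spec$is_base) {
          idx <- which(panel$population == spec$candidate)
          folds <- make_cv_folds(length(idx), spec$n_folds, rep_seed)
          gebv <- rep(NA_real_, length(idx))
          for (f in folds) {
            ref_panel <- subset_panel(marker_panel, individuals = idx[-f])
            cand_panel <- subset_panel(marker_panel, individuals = idx[f])
            gebv[f] <- predict_one_model(model, y[idx[-f]], ref_panel,
                                         cand_panel, cfg, reml_tolerance)
          }
          accuracy(gebv, tbv[idx])
        } else {
          ref_idx <- which(panel$population %in% spec$reference)
          cand_idx <- which(panel$population == spec$candidate)
          ref_panel <- subset_panel(marker_panel, individuals = ref_idx)
          cand_panel <- subset_panel(marker_panel, individuals = cand_idx)
          gebv <- predict_one_model(model, y[ref_idx], ref_panel, cand_panel,
                                    cfg, reml_tolerance)
          accuracy(gebv, tbv[cand_idx])
        }
      }, numeric(1))
    }, error = function(e) {
      warning(sprintf("replicate %d failed (%s); excluded from all models",
                      rep, conditionMessage(e)))
      NULL
    })
    if (is.null(rep_acc)) n_failed <- n_failed + 1L else acc[rep, ] <- rep_acc
  }

  ok <- stats::complete.cases(acc)
  tab <- do.call(rbind, lapply(spec$models, function(model) {
    a <- acc[ok, model]
    data.frame(scenario = spec$id, model = model, n_qtl = spec$n_qtl,
               r_g = spec$r_g,
               mean_accuracy = mean(a),
               se_accuracy = stats::sd(a) / sqrt(length(a)),
               mean_reliability = mean(a^2),
               n_replicates = length(a), n_failed = n_failed,
               stringsAsFactors = FALSE)
  }))
  reps <- data.frame(replicate = rep(which(ok), length(spec$models)),
                     model = rep(spec$models, each = sum(ok)),
                     accuracy = as.numeric(acc[ok, spec$models]),
                     stringsAsFactors = FALSE)
  structure(list(table = tab, replicates = reps, spec = spec),
            class = "accuracy_table")
}

#' @export
print.accuracy_table <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Regression of reliability on the log number of QTL
#'
#' The relationship between reliability (squared accuracy) and the number of
#' QTL is approximately linear in `ln(n_qtl)`; this fits that line by
#' ordinary least squares through the per-level mean reliabilities.
#'
#' @param table data frame with columns `n_qtl` and `mean_reliability` for
#'   one scenario and model (e.g. rows of an `accuracy_table$table`).
#' @return object of class `reliability_fit`: `slope`, `intercept`.
#' @export
fit_reliability_regression <- function(table) {
  stopifnot(all(c("n_qtl", "mean_reliability") %in% names(table)))
  if (length(unique(table$n_qtl)) < 2L) {
    stop("at least 2 distinct n_qtl levels required", call. = FALSE)
  }
  fit <- stats::lm(mean_reliability ~ log(n_qtl), data = table)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1])),
            class = "reliability_fit")
}

#' Crossing point of two reliability lines
#'
#' Solves `intercept1 + slope1 x = intercept2 + slope2 x` for the point (on
#' the `ln(n_qtl)` axis) where the two models' reliabilities become
#' equivalent, and compares it with `ln(M_e)` when an estimate of the number
#' of independent chromosome segments is supplied. Parallel lines give an
#' absent crossing, not an error.
#'
#' @param fit1,fit2 `reliability_fit`s (e.g. SSVS and GBLUP).
#' @param me optional M_e estimate (number or `me_estimate`).
#' @return object of class `crossing_point`: `absent`, `ln_n_qtl`, `n_qtl`,
#'   and `ln_n_qtl_minus_ln_me` when `me` is given.
#' @export
find_crossing_point <- function(fit1, fit2, me = NULL) {
  ds <- fit1$slope - fit2$slope
  if (abs(ds) < 1e-12) {
    return(structure(list(absent = TRUE, ln_n_qtl = NA_real_,
                          n_qtl = NA_real_),
                     class = "crossing_point"))
  }
  x <- (fit2$intercept - fit1$intercept) / ds
  out <- list(absent = FALSE, ln_n_qtl = x, n_qtl = exp(x))
  if (!is.null(me)) {
    if (inherits(me, "me_estimate")) me <- me$me
    out$ln_n_qtl_minus_ln_me <- x - log(me)
  }
  structure(out, class = "crossing_point")
}

#' Desk-scale simulation profile
#'
#' A reduced configuration with the same structure as the full study design
#' (three diverged populations with a half-sib large population, three
#' chromosomes, combined-data MAF filter) at sizes suited to interactive
#' work and testing: populations 400/100/120, about 2,600 retained SNPs.
#'
#' @param seed master seed.
#' @param ... overrides passed to [pop_sim_config()].
#' @return a `pop_sim_config`.
#' @export
desk_profile_config <- function(seed = 1L, ...) {
  args <- list(n_individuals = c(HF = 400, GWH = 100, MRY = 120),
               n_snps_per_chromosome = 900,
               within_pop_ne = c(300L, 200L, 240L),
               half_sib_family_size = 20,
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(pop_sim_config, args)
}

#' Simulate a complete study dataset
#'
#' Genotypes (simulated, MAF-filtered) plus the fixed candidate-QTL /
#' marker partition shared by every replicate.
#'
#' @param profile `"desk"` (default) or `"full"` (full-size panel:
#'   1033/105/147 individuals, ~31,500 SNPs, 5,000 candidate QTL).
#' @param seed master seed.
#' @param n_candidates candidate QTL count; defaults to 600 (desk) or 5000
#'   (full).
#' @return list: `panel`, `pedigree`, `arch`, `config`.
#' @export
simulate_study_data <- function(profile = c("desk", "full"), seed = 1L,
                                n_candidates = NULL) {
  profile <- match.arg(profile)
  config <- if (profile == "desk") desk_profile_config(seed)
            else pop_sim_config(seed = seed)
  if (is.null(n_candidates)) {
    n_candidates <- if (profile == "desk") 600L else 5000L
  }
  sim <- simulate_genotypes(config)
  arch <- partition_candidate_qtl(sim$panel, n_candidates, seed = seed)
  list(panel = sim$panel, pedigree = sim$pedigree, arch = arch,
       config = config)
}
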