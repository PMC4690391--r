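---
title: "Methods: multi-population genomic prediction with crossgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-population genomic prediction with crossgp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`crossgp` studies how the accuracy of across-population genomic prediction
depends on the number of QTL underlying a trait, on the genetic correlation
between populations, and on the number of independent chromosome segments
(M_e). Everything runs on simulated data, so every stage is testable without
external downloads. This vignette documents the models, the tunable
parameters, the calibration of the simulator, and the numerical choices —
i.e. the things a reviewer or maintainer would want to know that the
reference pages do not say.

## The genotype simulator

The analysis needs genotype data with four structural properties: linkage
disequilibrium that decays with genetic distance; several populations with
diverged allele frequencies and LD phase but a shared ancestral LD backbone;
paternal half-sib family structure in the large population; and a
minor-allele-frequency filter applied to the combined data. `popsim`
produces exactly these properties and nothing more — it is not a coalescent
simulator and carries no mutation model.

**Founder mosaic.** A base pool of haplotypes is built by copying segments
from `n_founder_haplotypes` founder sequences; the copied founder switches
between adjacent SNPs with probability `founder_switch_rate` (default 20 per
morgan) times the genetic distance, so segments average 0.05 M. Per-SNP
allele frequencies come from a U-shaped Beta(0.5, 0.5) truncated to
[0.1, 0.9] to keep loci polymorphic.

**Why 10 founders.** The mosaic depth is the single knob that controls the
LD *shared by all populations*: because founder alleles are independent
across loci, the expected r² between nearby SNPs in the pool is roughly
1/(n_founders − 1). Across-population prediction is only possible through
this shared ancestral LD — each population's subsequent drift LD is private
to it. Ten founders give ancestral r² ≈ 0.11, in the range reported for
short-range across-breed LD persistence on dense bovine genotypes. A much
deeper mosaic (say 60 founders, ancestral r² ≈ 0.017) still looks fine
within a population — drift and family structure supply plenty of LD there —
but silently removes the across-population signal entirely, which would make
the whole design pointless. This is the most consequential calibration in
the package.

**Divergence.** Each population is founded from a disjoint draw of base
haplotypes and evolves `divergence_generations` (default 50) of
Wright–Fisher random mating at effective size `within_pop_ne` — pure drift,
no selection or mutation. Crossovers per chromosome are Poisson with mean
equal to the map length (Haldane, no interference), positions uniform on the
genetic map, and genetic positions are spread uniformly over the SNPs of
each 1-morgan chromosome. The default `within_pop_ne` of `pmin(n, 200)`
(desk profile: 300/200/240) yields a mean absolute allele-frequency
difference around 0.15 after 50 generations — Fst of roughly 0.1, the order
reported between dairy cattle breeds. Stronger drift makes the populations
essentially unpredictable from one another; weaker drift makes the
"across-population" label cosmetic.

**Families and pedigree.** The final, genotyped generation of the largest
population is sired by a limited set of males (default 20 daughters per
sire), creating paternal half-sib families like a progeny-testing scheme.
Only the final two generations are recorded in the pedigree; everything
older is a base animal with unknown parents. This mirrors real, shallow
pedigrees and gives the A matrix its conventional structure: diagonal 1,
0.25 half-sib blocks, parent–offspring 0.5, and exact zeros between breeds.

**MAF filter.** SNPs whose combined-data minor allele frequency is *equal to
or lower than* the threshold (default 0.5 %) are deleted — the boundary case
is removed, not kept. The filter is idempotent and never touches
individuals.

**Seeding.** One master seed expands into independent per-stage streams
(haplotype pool, drift, families, per-replicate traits, sampler chains) via
`derive_seed()`, so any stage can be reproduced in isolation and paired
designs can share exactly the streams they should share.

## Trait architecture

A fixed set of candidate QTL (default 5,000 at full scale, 600 at desk
scale) is drawn uniformly from all SNPs once per dataset; all remaining SNPs
are the markers that predictors see. Candidate QTL — active or not — are
never passed to a predictor, so the models must act through marker–QTL LD.
Per replicate, `m` active QTL are redrawn from the candidates and their
allele substitution effects are sampled from a zero-mean multivariate normal
with unit variances and the target correlation r_g between populations. Unit
effect variance is harmless: accuracy is scale-free.

Pairing across conditions deserves a note: the sampler factorizes the
correlation matrix by its Cholesky triangle, so when conditions share the
underlying Gaussian draws (same replicate seed), the first population's
effects are *identical* across r_g settings and only the other populations'
effects rotate. Reference data then stay fixed and the comparison of r_g
levels is a true paired design. With r_g = 1 the factorization is rank one
and every population gets the same effects.

TBV is the raw dosage sum Σₖ Xₖ αₖ using the individual's own population
column; phenotypes add N(0, (1/h² − 1) · var(TBV)) noise, variance computed
within population around the population's TBV mean. The default h² = 0.95
mimics deregressed bull proofs. With 3 QTL the realized per-replicate sample
correlation of effects is biased down (mean ≈ 0.69–0.74 at target 0.8 —
the correlation can rise only to 1 but fall to −1); this is a property of
the sample correlation at n = 3, reproduced deliberately, not a bug.

## The SSVS sampler

The model is y = 1μ + Σⱼ Xⱼβⱼ + e with a two-component mixture prior:
βⱼ ~ N(0, σ²_β) with prior probability 1 − π = 0.01 (indicator γⱼ = 1) and
βⱼ ~ N(0, σ²_β/100) otherwise. Both components share the *same* sampled
σ²_β up to the fixed ratio. The Gibbs sweep uses right-hand-side updating:
for each marker, r = Xⱼ′e + Xⱼ′Xⱼβⱼ is formed from the running residual,
the indicator is drawn from Bernoulli(pd₁(1 − π)/(pd₁(1 − π) + pd₀π)) with
pd the marginal density of r under each component (computed in log space —
simultaneous underflow can never produce 0/0), the effect from its normal
full conditional, and the residual is updated incrementally. A debug mode
verifies the incremental residual against full recomputation to 1e-8.

Numerical and prior choices:

* Marker dosages are centered by the combined reference + candidate mean.
  Centering stabilizes mixing and shifts GEBVs by a constant, which
  correlation-based accuracy ignores.
* σ²_β has a scaled inverse chi-square prior with 4.2 degrees of freedom.
  Its scale is auto-calibrated so the prior expected total marker variance,
  Σⱼ 2pⱼqⱼ · [(1 − π)σ²_β + πσ²_β/100], matches the phenotypic variance
  times an assumed heritability of 0.95.
* σ²_e is drawn as e′e/χ²(n) (scale-invariant prior), giving expectation
  n/(n − 2) for fixed e′e = n.
* When the reference spans more than one population, one intercept per
  population is fitted by default, mirroring GBLUP's fixed breed effect; a
  flag restores the literal single-μ model.
* Markers are updated in panel order; a randomized order is available and
  changes GEBVs only within Monte Carlo error.
* Chains run 5,000 iterations with 1,000 burn-in by default; the desk
  profile uses 2,000/400. No thinning — all post-burn-in samples are
  accumulated. GEBV accumulation is linear, so the average per-iteration
  candidate prediction equals the candidate matrix times the posterior mean
  effects (asserted in tests).
* With all indicators forced on and fixed variances the sampler reduces to
  ridge regression with λ = σ²_e/σ²_β; this limit is exercised in the test
  suite against the closed-form solution.

## GBLUP / REML

G is the first-method cross-product G = WW′/2Σpⱼqⱼ with W centered by 2pⱼ
and frequencies from the combined reference + candidate individuals. This
choice makes G-BLUP algebraically identical to SNP-BLUP ridge prediction
(checked to 1e-8) and puts reference and candidates on one scale, which the
M_e computation presumes. Variance components of y = Xb + g + e,
g ~ N(0, Gσ²_a), are estimated by average-information REML with a fixed
breed effect; the first step and any AI step that fails to improve the
restricted likelihood fall back to EM, variances are floored at 1e-8 of the
phenotypic variance instead of going negative, G gets a 1e-6 ridge, and
convergence is a relative log-likelihood change below 1e-8 (non-convergence
is flagged, not thrown). BLUP solutions propagate reference information
through G; candidates carry no phenotype, and a candidate genomically
unrelated to every reference individual gets GEBV 0.

## M_e

M_e = 1/Var(G_ij − A_ij), with the variance over all (reference, candidate)
cross pairs for across-population scenarios — a combined two-breed reference
is pooled into one pair set, as is the cross-validation pair set of the base
scenario — or over all unordered distinct pairs within one population. The
variance uses divisor N; at tens of thousands of pairs the distinction from
N − 1 is far below every other source of noise. A is built by the tabular
method, with zeros between breeds by the base-animal convention. On default
simulated data M_e is several-fold larger across populations than within,
and the package asserts only this ordering — the simulator is not calibrated
to any particular M_e value.

## Scenarios, accuracy, and the crossing point

The five standard scenarios use the largest population (HF) within
(20-fold cross-validation, pooled fold predictions giving one accuracy per
replicate) or as (part of) an across-population reference for the two small
populations. Accuracy is the Pearson correlation between GEBV and TBV over
the selection candidates of a replicate; reliability is its square, averaged
per replicate; the standard error is sd/√n over replicates. Replicates share
the genotype panel — only QTL, effects and noise are redrawn. A model
failure drops the replicate for *all* models, keeping comparisons paired.
Reliability is regressed on ln(nQTL) through the per-level means, and the
intersection of the SSVS and GBLUP lines approximates ln(M_e); parallel
lines yield an absent crossing, not an error.

## Problem sizes

The desk profile — populations 400/100/120, drift Ne 300/200/240, about
2,600 retained SNPs on three 1-morgan chromosomes, 600 candidate QTL, about
2,000 markers, 20 replicates, 2,000-iteration chains — is the package's
standard working scale: it shows every qualitative phenomenon (SSVS > GBLUP
at few QTL, convergence at many, proportionality to r_g, M_e ordering)
while a full scenario sweep stays in the minutes. The full-scale profile
(`simulate_study_data("full")`: 1033/105/147 individuals, ~31,500 SNPs,
5,000 candidate QTL) is available behind the same interface.

## What passing tests do and do not show

The simulator emulates the *structure* the analysis needs, not cattle
history: no mutation, no selection, no variable recombination, uniform SNP
spacing, three equal-length chromosomes, and founder-mosaic ancestral LD
instead of a demographic ancestral population. Consequently, passing the
suite shows the estimators and the model-comparison logic are correct under
the stated assumptions; it does not certify numeric accuracy values for any
real breed. Known limitations: single trait, additive effects only (no
dominance or epistasis, no population-specific QTL sets), π is fixed rather
than estimated, single-trait REML only, and the base-scenario M_e pair set
follows the cross-validation convention rather than all within-population
pairs.
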