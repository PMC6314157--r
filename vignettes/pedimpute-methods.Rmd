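---
title: "Evaluating imputation study designs in pedigrees: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating imputation study designs in pedigrees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pedimpute is a simulation framework for a study-design question that
comes up whenever an extended-pedigree cohort is sequenced in part and
imputed in the rest: which subjects should be sequenced, how should the
remaining genotypes be imputed (from identity by descent, from linkage
disequilibrium, or both), and how should the result be scored so that the
score predicts downstream association power? The package simulates the
whole experiment end to end — founder haplotypes, gene dropping,
reference-panel selection, baseline imputation, accuracy metrics, and
mixed-model association — so that every design choice can be compared on
data whose truth is known.

This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions behind the implementation.

## The simulated world

### Founder haplotype pool

`generate_founder_pool()` creates an `H x S` binary matrix of founder
haplotypes over a chromosomal region. Two properties of real panels are
emulated and controllable:

* **MAF spectrum.** Each site receives a target minor-allele frequency
  drawn from a binned histogram over (0, 0.5] (`maf_spectrum()`); inside
  the rarest bin the draw is log-uniform, which gives the rare-variant
  excess characteristic of sequence data. The `"eur_like"` and
  `"afr_like"` presets (8954 and 11,891 sites over ~5.6 Mb) use bin
  weights matching the per-bin site proportions of the European- and
  African-ancestry scenarios the package emulates; the African-like
  preset has more sites and a heavier rare tail.
* **Linkage disequilibrium.** Each haplotype is generated from a latent
  standard-normal AR(1) process along the chromosome with inter-site
  correlation `exp(-d_bp / ld_strength)`; the allele is minor when the
  latent value falls below the site's frequency quantile. Marginal
  frequencies therefore match the target spectrum exactly in expectation,
  while pairwise r² decays geometrically with distance and is monotone in
  `ld_strength`; `ld_strength = 0` yields independent sites whose mean
  window r² equals the sampling floor `1/(H-1)`.

We considered the obvious alternative, a haplotype-copying (mosaic)
scheme. With a fixed set of K independent template haplotypes, the
attainable window LD is capped near `1/(K-1)` while the attainable minor
allele frequencies are floored near `1/K`, so no K reproduces both a
rare-heavy spectrum and window LD of ~0.03; with sequential copying from
a growing pool, the spectrum becomes emergent and uncontrollable. The
latent-Gaussian threshold model achieves both stated goals with one
interpretable knob, which is why it is the implementation.

The preset `ld_strength` values (15,000 bp EUR-like, 6,000 bp AFR-like)
are calibrated so the mean pairwise r² within non-overlapping 100-SNP
windows (`mean_window_ld()`) lands near 0.032 and 0.020 respectively —
the regime in which population-based imputation has visibly more to work
with in the European-like than the African-like scenario.

What the generator does **not** emulate: recombination-hotspot structure,
mutation-age-dependent haplotype backgrounds of rare variants (a latent-
Gaussian rare variant can be better tagged by its neighbours than a
recent real mutation would be), multi-allelic sites, and genotyping
error. Conclusions drawn from these simulations about absolute accuracy
levels therefore do not transfer to real data; the package's purpose is
the *relative* comparison of designs under a controlled truth.

### Pedigrees

`generate_pedigree_set()` builds random extended pedigrees top-down: a
founding couple, a spine of descendants guaranteeing the requested
generation depth, then growth by adding children to existing couples or
marrying in founder spouses (who immediately have a child, so no couple
stays childless and the Lander–Green complexity `bits = 2n − f` stays
nonnegative). Both-or-neither parenthood and acyclicity hold by
construction. Defaults mirror the demography the package emulates: 20
pedigrees, sizes 10–174, 3–9 generations, sibships 1–11 with most
sibships small. Sex is recorded but plays no role in transmission: the
model is autosomal with a single uniform map.

### Gene dropping

`drop_haplotypes()` assigns each founder two pool haplotypes, sampled
without replacement *across all pedigrees of a replicate*, and transmits
them in parent-first order. A gamete starts on a random parental
haplotype and switches between the parent's two haplotypes between
adjacent sites with probability `min(0.5, 0.01 × d_cM)` under a uniform
1 cM = 1000 kb map — a linear 1%-per-cM convention, chosen deliberately
over a Haldane map function: it matches the stated rate exactly at short
distances, and no crossover interference is modelled. Replicate datasets
(`make_replicates()`) redraw pool, drop and GWAS panel per replicate from
deterministic seed streams (`derive_seeds()`), so any replicate is
reproducible in isolation.

The GWAS panel (`mask_gwas_panel()`, default 500 sites, ~5% of an
EUR-like region) is the sparse marker set observed on every subject;
reference subjects are additionally observed at every site.

## Reference-panel selection

All four strategies select the same per-pedigree counts, computed by
`selection_quotas()`: `floor(fraction × size)` per pedigree plus a
largest-remainder correction so the global total is exactly
`round(fraction × N)` — with the default 20% on 20 pedigrees of 1200
subjects, exactly 240 reference and 960 study subjects. The strategies:

* `select_random()` — uniform within pedigree.
* `select_max_unrelated()` — greedy insertion in order of increasing
  total relatedness, accepting a subject only if its pairwise
  relationship with everyone selected stays at or below a threshold
  (default 0), then topping up with the least-related remainder. A
  surrogate for tools that force a maximally unrelated set.
* `select_generation_units()` — parent couples ranked oldest generation
  first, larger sibships first; whole units selected until the quota. A
  surrogate for tools that pick family units from the oldest generations.
* `select_founder_coverage()` — greedy forward selection maximizing the
  expected fraction of founder genome copies present in at least one
  selected subject, estimated by Monte-Carlo single-locus label drops. A
  simplified surrogate for inheritance-vector-based pickers; the
  published algorithms' exact objectives are not reproduced, so
  benchmark claims about the original tools do not transfer verbatim.

Ties are always broken lexicographically by subject id, making every
strategy deterministic (given its seed, where randomness exists).

## Imputation

The package's primary mode for real studies is `import_external_result()`
— any tool that writes VCF with `GP` or `DS` FORMAT fields can be plugged
in, with allele polarization harmonized against the simulation's minor
allele. For self-contained experiments, three deliberately transparent
baselines are built in, all producing genotype posterior triples and
dosages on the minor-allele-count scale [0, 2]:

* `impute_allele_frequency()` — Hardy–Weinberg posteriors from the
  reference-panel frequency; the no-information floor. Its dosage is
  constant per SNP, so its dosage R² is *undefined*, not zero.
* `impute_population_ld()` — per target SNP, a least-squares predictor
  from the `k_flank` nearest panel SNPs, fit on reference subjects;
  the LD-only route of population-based tools.
* `impute_family_kinship()` — per SNP, the dosage vector is modelled
  with mean `2p` and covariance proportional to the additive
  relationship matrix; study dosages are the Gaussian conditional
  expectation given reference dosages,
  `2p + A_so A_oo^{-1} (d_obs − 2p)`. Information flows only along
  relatedness: with `A = I` this reduces *exactly* to the
  allele-frequency baseline.
* `combine_ped_pop()` — per cell, the family call is kept when its
  largest posterior reaches `tau` (default 0.8), otherwise the
  population call. The published combiner's exact rule lives in
  supplementary material we do not restate; this thresholded-confidence
  rule is the documented, configurable surrogate, with the limit
  identities `tau = 0` (family) and `tau > 1` (population).

When only a dosage `d` is available, posteriors come from the
moment-matching map `((1−d/2)², 2(d/2)(1−d/2), (d/2)²)`
(`dosage_to_posterior()`), needed because the imputation quality score
operates on genotype-class probabilities.

The internal dosage scale is the minor-allele *count* (0–2). Some
authors phrase dosage as the minor-allele *fraction* (count/2); Pearson
R² is invariant to this affine rescaling, so accuracy numbers are
unaffected — a property the test suite verifies numerically.

## Accuracy metrics

`dosage_r2()` is the squared Pearson correlation between true and
imputed dosages over the non-reference subjects; undefined when either
vector is constant. `iqs()` is a kappa-type chance-corrected agreement
built from a *fractional* 3×3 contingency table (each subject
contributes its posterior triple to the column of its true genotype);
its upper bound is 1, it can be negative, and with hard calls it equals
Cohen's kappa. The probability-weighted table is the default because the
score is defined on imputation probabilities; a best-guess mode exists.
`concordance_rate()` is provided for completeness but excluded from
headline summaries, since always calling the major homozygote is almost
always "correct" for rare variants.

Scoring (`snp_accuracy()`) excludes the GWAS panel always, and by
default also an edge buffer of 500 SNPs at each end of the region, where
LD-based imputation lacks flanking markers (8954 → 7954 scored sites;
11,891 → 10,891). Both exclusion modes are available (`n_buffer = 0`
disables the buffer). Undefined metrics are reported as missing and
counted per bin (`summarize_by_bin()`), never coerced to zero. The
default MAF bins are (0,0.01), [0.01,0.05), [0.05,0.1), [0.1,0.2),
[0.2,0.3), [0.3,0.4), [0.4,0.5].

## Quantitative traits and association

Traits are simulated (`simulate_traits()`) under
`Y = ε` (null) or `Y = β_j X_j + ε` (alternative), with
`ε ~ N(0, σ_g² A + σ_e² I)` and `A` the matrix of twice the kinship
coefficients from the tabular recursion (`relationship_matrix()`).
The defaults `σ_g² = σ_e² = 1` set the total variance of a non-inbred
subject to 2 and the heritability to 0.5 — one consistent
parameterization of the "heritability one half, polygenic variance one,
total variance two" convention. Effect sizes follow
`β_j = sqrt(v_a / (2 MAF_j (1 − MAF_j)))` with `v_a = 0.01` by default,
so each tested SNP contributes additive variance `v_a` under
Hardy–Weinberg. β uses the true simulated frequency by default (a
reference-estimated frequency can be passed instead). Under the
alternative, traits are generated from *true* genotypes even when
imputed dosages are tested, so imputation error degrades only the test,
not the phenotype.

`lmm_test()` is an exact two-variance-component maximum-likelihood fit:
`A` is eigendecomposed once per subject set, the profile log-likelihood
is maximized over `log(δ)` with `δ = σ_e²/σ_g²` on [−10, 10] by 1-D
optimization (with the residual-only boundary checked explicitly, so
unstructured data reduce to ordinary least squares exactly), and `β`
gets a Wald test against the standard-normal reference. Wald-normal
p-values with per-fit ML components mirror the per-model mixed-model
fits used in pedigree association practice; intercept included;
continuous dosages enter directly, with no imputation-quality filtering
and no multiple-testing correction — rates are evaluated at fixed
nominal α.

`estimate_rates()` computes, per SNP, the proportion of trait replicates
with `p < α` (strict inequality, following the definition "smaller than
a given α"), then averages SNP rates per MAF bin, per α, per genotype
source: type-I error under the null, power under the alternative.
`exclude_buffer()` drops the first and last 500 SNPs from testing.

One analytic anchor ties accuracy to power: testing an imputed SNP with
dosage R² = r² is equivalent to testing a perfectly genotyped SNP on r²
times the sample, so matching the power of perfect genotypes requires a
`1/r²`-fold larger sample (`effective_sample_factor()`; 1.25 at
r² = 0.8).

## Orchestration and reproducibility

`run_pipeline()` drives the full experiment from one YAML configuration:
pedigree generation, replicate simulation, selection, imputation,
scoring, optional association, and TSV/JSON reporting. A single
`base_seed` fans out into named per-stage, per-replicate streams, so
identical configurations reproduce identical outputs; every report file
is stamped with an MD5 hash of the scientific configuration (the output
directory is excluded from the hash). `export_for_external_tools()`
writes the file set an external imputation tool consumes: reference
full-sites VCF, study panel-sites VCF, LINKAGE/PED pedigrees, SNP map,
and panel list.

## Numerical choices and degenerate inputs

* Pool columns that come out monomorphic are redrawn from a
  polymorphism-conditioned binomial; all sites are polarized so the
  coded allele has frequency in (0, 0.5].
* Reference-sample allele frequencies of ~0.5-MAF sites can exceed 0.5;
  imputers accept any frequency in [0, 1] rather than re-polarizing
  mid-experiment.
* Imputed dosages are clipped to [0, 2] before posterior conversion.
* A singular observed relationship block is ridge-regularized
  (ε = 1e−8, logged); a singular LD design falls back to the
  allele-frequency baseline for that SNP (counted, logged).
* A constant genotype vector yields `p = 1` with a warning in
  `lmm_test()`; a Cholesky failure in trait simulation falls back to an
  eigenvalue-clipped factorization with a warning.
* Ties in best-guess genotype calls go to the smaller genotype index;
  selection ties go to the lexicographically smaller subject id.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run the full machinery at
reduced, self-calibrated sizes chosen to keep every check sharp:
window-LD preset checks use density-preserving sub-regions (1500–1600
sites, 2000 haplotypes) of the full presets; recombination recovery uses
10⁵ meioses; kinship oracles use 10⁵ Monte-Carlo label drops; type-I
calibration uses 5 pedigrees × 60 subjects and 50 SNPs × 20 traits
(1000 tests); the rare-variant design comparison uses 10 replicates of
10 nuclear families at EUR-like density with a 5% panel. The full-scale
presets (20,000 haplotypes × ~9,000–12,000 SNPs, 100 replicates) run in
minutes to hours and are exercised through the same code paths.

## Known limitations

* The built-in imputers are transparent linear/Gaussian baselines, not
  reimplementations of Lander–Green, MCMC IBD, or Li–Stephens HMM
  engines; absolute accuracies are below state-of-the-art tools, which
  should be plugged in via VCF for real comparisons.
* The selection surrogates capture the stated *goals* of the published
  pickers, not their algorithms.
* Binary or ascertained phenotypes, dominance/epistasis, covariates,
  sex-specific maps, crossover interference, de novo mutation and
  genotyping error are out of scope.
* Pedigree splitting into bit-bounded subpedigrees is not automated;
  `pedigree_bits()` computes the complexity, the splitting policy is the
  user's.
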