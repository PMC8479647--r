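---
title: "Gene-set burden analysis of ultra-rare variants: model, simulator and design choices"
author: "urvburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-set burden analysis of ultra-rare variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the statistical method it
implements, the synthetic cohorts it validates itself on, and the design
decisions that were genuinely open.

## 1. The model

### Qualifying variants

The unit of analysis is the *qualifying variant* (QV): an alternate
allele that passes three rarity filters and belongs to a functional
class. The rarity filters are

* **internal MAC ≤ 3** — the minor allele count summed over the samples
  of the *current* analysis (one phenotype's cases plus all controls).
  MACs are deliberately recomputed per analysis: pooling all phenotypes
  would let an allele common in one case group leak into another
  analysis as "rare", inflating the burden. A consequence is that the
  same variant can qualify in one per-phenotype analysis and not in
  another.
* **absent from DiscovEHR** (frequency 0), and
* **gnomAD frequency ≤ 2 × 10⁻⁵**. Complete absence from gnomAD is not
  required because control cohorts of this design typically overlap
  gnomAD.

All three thresholds are configurable (`urv_filter_config()`). A missing
external frequency is treated as 0 — absence from the reference database
is exactly what the filter is probing. A missing constraint score, by
contrast, *fails* every threshold predicate: we never impute constraint.

### The thirteen classes

`class_rules()` ships the class roster: synonymous (a negative-control
class, presumed neutral), benign and damaging missense (PolyPhen-2 and
SIFT in conjunction), PTV (stop-gained, start-lost, frameshift,
splice-donor, splice-acceptor), "all functional" (PTV ∪ in-frame indels
∪ damaging missense), two MPC tiers (≥ 1, ≥ 2), two MTR tiers (≤ 0.825
and ≤ 0.565 — the median MTR of ClinVar non-de-novo and de-novo
pathogenic missense variants respectively), CCR 80 (CCR percentile ≥ 80
*and* MPC ≥ 1 *and* MTR ≤ 0.825), and three paralog-conservation tiers
(para-Z ≤ 0, > 0, ≥ 1). The classes overlap by construction, and the
predicates imply a nesting that the test suite asserts on every
simulated cohort: MPC 2 ⊆ MPC 1, MTR De Novo ⊆ MTR ClinVar,
CCR 80 ⊆ MPC 1 ∩ MTR ClinVar, paralog highly conserved ⊆
paralog-conserved.

Two readings of "damaging as predicted by PolyPhen-2 and SIFT" exist;
the package defaults to the conjunction (both predictors must agree;
discordant or missing predictions put the variant in neither the benign
nor the damaging class) with `damaging_rule = "either"` as the
configurable alternative. In-frame indels enter only "all functional":
MPC, MTR and CCR are missense metrics and are undefined there.

### Burden test

Per sample, QVs are collapsed to a binary indicator per (gene, class);
the burden score of a gene-set is the count of its genes with indicator
1 (equal weights, one direction). Case status is regressed on the score
with a logistic model adjusting for sex (female = 1), the top ten
principal components, the exome-wide URV count and the exome-wide
singleton (MAC = 1) count. Whether the "exome-wide variant count"
covariate should count all variants or URVs only is ambiguous; the
package counts URVs (the variants the analysis actually uses), and the
covariate is recomputed per analysis along with the MACs.

The p value is a 1-df chi-square likelihood-ratio test against the
covariates-only null; the reported effect is the burden coefficient
(log-odds per additional burdened gene) with a Wald 95% interval. The
pairing of an LRT p value with a Wald interval is a deliberate,
conventional choice — profile-likelihood intervals were considered out
of scope, and the interval construction is recorded here as a reporting
caveat rather than hidden.

Numerical contract of the fitter (`fit_logistic()`, an IRLS wrapper):
convergence when the deviance change falls below 1e-8 within 100
iterations; any |coefficient| > 15 flags the fit as unconverged
(quasi-separation guard — no Firth or penalized fallback is attempted,
the cell is reported with its diagnostic flags instead). Constant
covariate columns (e.g. sex in a single-sex stratum) are dropped with a
warning; rank deficiency after pruning is an error naming the collinear
columns. A burden score that is constant across samples (typically all
zero) is a *degenerate* cell: log-odds 0, LRT statistic 0, p = 1. Such
cells stay in the grid and count toward the Benjamini–Hochberg `m`, so
the size of the printed grid does not depend on data sparsity.

### Multiplicity

All (gene-set × phenotype × non-synonymous class) cells are adjusted
jointly by Benjamini–Hochberg (via `stats::p.adjust`; the test suite
checks it against an independent hand-written step-up oracle). The
synonymous class is excluded from the adjustment by design: it is the
calibration track, and its rejection rate at raw p < 0.05 is the
pipeline's empirical type-I error. Stars annotate adjusted p values
(raw for synonymous) with strict inequalities at 0.05, 0.005, 0.0005,
0.00005; boundary values take the weaker annotation.

## 2. What the simulator emulates — and what it does not

`generate_cohort()` produces cohorts with the structure the analysis
assumes, so that every downstream stage is testable without
access-controlled data:

* **Carrier model.** Per sample, gene and generation archetype, a
  Bernoulli draw; for case samples in a spiked (set, class) cell the
  log-odds are shifted by `log(spiked_or)`. Because carriage is rare per
  gene, the burden score is approximately Poisson and the logistic
  burden coefficient recovers `log(spiked_or)` — the recovery experiment
  below confirms this to within 0.05.
* **Archetypes and rates.** The thirteen classes nest, so independent
  per-class draws cannot hit per-class rates exactly. The simulator
  instead draws from disjoint *archetypes* (one per most-specific class
  profile) and solves the archetype intensities from the configured
  per-class marginal rates; a configuration that violates the nesting
  (e.g. rate("MPC 1") < rate("MPC 2") + rate("CCR 80")) is rejected with
  an error naming the constraint. Score values are drawn uniformly
  within the archetype's admissible region, so every class has both
  positives and negatives and each variant satisfies its intended
  class's predicate (asserted in the tests).
* **Spiking and leakage.** Spiking a class shifts *every* archetype
  contributing to it, so the spiked class's carrier odds scale exactly
  by the configured odds ratio. Super-classes that contain the spiked
  class (e.g. MPC 1 when CCR 80 is spiked) inherit a diluted enrichment;
  the truth table records 0 for them. Recovery experiments therefore
  spike leaf classes.
* **Allele-count spectrum.** Each carrier event creates its own variant
  site with probability 0.9 (singleton) and otherwise pairs with another
  event at a shared site (doubleton); 0.5% of carriers are homozygous.
  About 20% of events add a second site in the same gene, so the
  gene-level collapsing is genuinely exercised. Planted decoys carry
  damaging-like scores but fail exactly one rarity filter each (gnomAD
  frequency above threshold, DiscovEHR presence, or MAC > 3 — the
  high-MAC decoys live in controls so that they exceed the MAC cap in
  every per-phenotype analysis); class-less filler variants exercise the
  "no class" path. Decoy and filler carriers are spread over the whole
  cohort: concentrating them in one stratum would make the exome-wide
  count covariates differ systematically between cases and controls and
  distort the null (this is visible immediately as type-I inflation if
  done wrong).
* **Confounders.** Sex is drawn at 53.6% female in cases vs 19.4% in
  controls — the strong imbalance of the motivating study design —
  with an optional sex-coupled carrier-rate shift (default off, so the
  imbalance is a pure confounder test). Controls are split into
  sub-cohorts (default relative sizes 1673/1082/924/283) standing in for
  capture-kit batches, with mild batch offsets on the leading principal
  components. Covariates (URV and singleton counts) are *computed from
  the generated data*, not simulated independently.

Default per-class rates (`default_qv_rates()`, QVs per sample per 1,000
genes: synonymous 10 down to CCR 80 at 1) describe a compact synthetic
exome; they are chosen so that a 1,000-gene universe yields per-sample
QV counts in the tens, comparable in order of magnitude to ultra-rare
exome profiles while keeping simulation tractable.

**Not emulated:** linkage disequilibrium and haplotype structure, a
realistic site-frequency spectrum beyond the singleton-dominated regime,
joint correlation of the constraint scores (archetypal score profiles
are deliberately minimal), read-level artefacts, and real capture-kit
coverage differences. Passing tests on these cohorts therefore
demonstrate the *statistical machinery* — calibration, recovery,
invariances — not robustness to annotation error or sequencing
artefacts in real exomes.

## 3. Validation experiments the package runs on itself

The test suite (`tests/testthat/test-acceptance.R`) executes these at
the sizes stated; the figures quoted are what those tests compute and
assert.

* **Grid arithmetic.** 92 sets × 3 phenotypes × 12 non-synonymous
  classes = 3,312 jointly adjusted tests, plus 276 synonymous control
  tests; the 15 non-neuronal control sets contribute 540 of the adjusted
  tests. `calibration_summary()` reports such tracks with one-decimal
  percentages (15/276 → 5.4%, 18/540 → 3.3%).
* **Null calibration.** Four all-null cohorts (2,000 vs 2,000 samples,
  1,000 genes, 20 sets × 13 classes) give > 1,000 tests whose raw
  p < 0.05 rate is required to sit inside the binomial 99% interval
  around 5%, with a global uniformity (Kolmogorov–Smirnov) check.
  `scripts/acceptance.R` repeats this with five cohorts and writes the
  observed percentage.
* **Recovery.** 100 replicates at 2,000 vs 2,000 with odds ratio 1.5
  spiked into the CCR 80 class of a 100-gene set (CCR 80 rate 5/1,000 so
  the cell is informative; all other classes switched off to keep each
  replicate to ~1 s): the Wald CI must cover ln 1.5 in ≥ 90 replicates
  and the mean estimate must lie within 0.05 of ln 1.5.
* **Oracles.** The logistic slope against the 2×2 closed form
  ln(ad/bc) on 50 random tables (|Δ| < 1e-6); BH against a hand step-up
  oracle on 100 random vectors; the class-nesting invariants on every
  simulated cohort.
* **Contracts.** `group_contrast(A, B)` negates `group_contrast(B, A)`
  within 1e-6; identical configuration + seed reproduces byte-identical
  cohort files.

## 4. Secondary analyses

* `exclude_chromosome()` removes every gene whose variants lie on the
  named chromosome (gene-to-chromosome taken from the variant table;
  conflicts are errors) — the sex-imbalance sensitivity analysis.
* `group_contrast()` reruns the machinery on an arbitrary disjoint pair
  of groups with MACs computed inside the union — the controls-only
  capture-kit contrast and the direct case-vs-case comparison.
* `permutation_subsample()` redraws sub-cohorts without replacement and
  reruns one cell, summarising mean log-odds, 2.5/97.5 centiles
  (linear-interpolation quantiles, type 7) and mean raw p. "Average
  odds" is ambiguous between averaging odds and averaging log-odds; the
  summary reports the mean log-odds, its exponential, *and* the mean of
  per-permutation odds ratios. The mean of raw p values is reported
  (rather than mean −log p), with the full per-permutation draws kept
  for any other summary.
* `leave_genes_out()` recomputes one cell before and after dropping
  named genes — the driver-gene sensitivity report for control
  pathways that contain known disease genes.

## 5. Known limitations

* No Firth/penalized fallback under separation: very sparse cells are
  flagged, not rescued.
* Wald intervals can be poor in cells with few carriers even when the
  LRT p is reasonable; compare `p` with the interval before quoting
  either.
* Gene symbols are matched by exact (case-insensitive) string equality;
  synonym resolution is upstream's job.
* One gene per variant row: multi-gene annotations must be exploded to
  one row per gene before input.
* The simulator's truth table records 0 for super-classes of a spiked
  class even though they inherit diluted enrichment (see §2); interpret
  truth as "directly spiked log-odds", not "expected marginal effect".
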