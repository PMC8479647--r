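# urvburden

Collapsing gene-set burden analysis of **ultra-rare coding variants
(URVs)** for case-control exome studies, with a synthetic-cohort
simulator for end-to-end validation.

Rare-variant association studies of severe phenotypes (the package's
motivating use case is epilepsy, with the DEE / GGE / NAFE case
phenotypes against a shared control pool) rarely have power at the level
of single variants. The standard remedy is *collapsing*: qualify
variants by rarity and predicted function, collapse them to a binary
indicator per sample and gene, sum the indicators over a gene-set, and
test whether cases carry a heavier burden than controls.

## The method

1. **Qualifying variants.** A variant is *ultra-rare* when its internal
   minor allele count — recomputed within each case-control analysis — is
   at most 3, it is absent from DiscovEHR, and its gnomAD frequency is at
   most 2 × 10⁻⁵. Qualifying URVs are assigned to thirteen partially
   overlapping classes: synonymous (negative-control class), benign and
   damaging missense (PolyPhen-2 + SIFT), protein-truncating variants
   (PTV), all functional variants, missense constraint classes
   (MPC ≥ 1, MPC ≥ 2; MTR ≤ 0.825, MTR ≤ 0.565; CCR ≥ 80 with MPC ≥ 1
   and MTR ≤ 0.825), and paralog-conservation classes
   (para-Z ≤ 0, > 0, ≥ 1).
2. **Burden score.** For sample *i* and gene-set *S* with class *c*,
   the score is the number of genes in *S* in which *i* carries at least
   one qualifying variant of class *c* (equal weights).
3. **Test.** Logistic regression of case status on the burden score,
   adjusting for sex, ten principal components, the exome-wide URV count
   and the exome-wide singleton count; a 1-df likelihood-ratio test
   against the covariates-only model gives the p value, and the burden
   coefficient (log-odds per burdened gene) with its Wald 95% CI gives
   the effect.
4. **Multiplicity.** Benjamini–Hochberg adjustment over the full grid of
   (gene-set × phenotype × non-synonymous class) tests; the synonymous
   class is computed as an unadjusted calibration track. Stars:
   `*` < 0.05, `**` < 0.005, `***` < 0.0005, `****` < 0.00005.
5. **Bias controls.** Chromosome-X exclusion (sex-imbalance check),
   controls-only capture-kit contrast, permutation subsampling of a
   single cell, and driver-gene leave-out sensitivity.

## Worked example

Simulate a cohort with a known enrichment (odds ratio 3 for the
highly-constrained "MTR De Novo" missense class in an ion-channel set),
then run the grid:

```r
library(urvburden)
library(dplyr)

cfg <- sim_config(
  n_cases = c(GGE = 1000), n_controls = 1000, n_genes = 500,
  genes_per_set = c(ion_channels = 40, synaptic = 60),
  spiked_or = tibble::tibble(set = "ion_channels",
                             class = "MTR De Novo", or = 3),
  seed = 42)
cohort <- generate_cohort(cfg)
grid <- run_grid(cohort, phenotypes = "GGE")

grid |>
  filter(class %in% c("MTR De Novo", "PTV", "Synonymous")) |>
  select(set, class, log_odds, ci_lo, ci_hi, p, p_fdr, stars)
#> # A tibble: 12 × 8
#>    set                 class    log_odds   ci_lo  ci_hi        p     p_fdr stars
#>    <chr>               <chr>       <dbl>   <dbl>  <dbl>    <dbl>     <dbl> <chr>
#>  1 all_genes           Synonym…  0.0375  -0.0123 0.0872 1.40e- 1 NA        ""
#>  2 all_genes           PTV      -0.0338  -0.131  0.0637 4.97e- 1  9.93e- 1 ""
#>  3 all_genes           MTR De …  0.0817  -0.0153 0.179  9.82e- 2  6.15e- 1 ""
#>  4 ion_channels        Synonym… -0.0628  -0.218  0.0921 4.27e- 1 NA        ""
#>  5 ion_channels        PTV       0.139   -0.214  0.492  4.41e- 1  9.93e- 1 ""
#>  6 ion_channels        MTR De …  1.06     0.779  1.34   5.45e-15  2.61e-13 "****"
#>  ...
```

The spiked cell is recovered: the estimated log-odds 1.06 (CI
0.78–1.34) brackets the simulated ln 3 ≈ 1.10, survives FDR adjustment
(`****`), while the synonymous track, PTV class and the never-spiked
control set stay null. `glance(grid)` summarises the grid,
`calibration_summary(grid)` reports the negative-control tracks, and
`autoplot(grid)` draws the forest plot. Secondary analyses:
`exclude_chromosome()`, `group_contrast()`, `permutation_subsample()`,
`leave_genes_out()`.

Real data enter through the same tabular interfaces: `read_samples_tsv()`,
`read_variants_tsv()` + `read_carriers_tsv()` (or `read_vcf_cohort()`),
`read_gmt()` (an example catalogue ships in
`inst/extdata/example_gene_sets.gmt`), and `run_pipeline()` drives the
whole analysis from a `run_config()` or YAML file.

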