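# Shared fixtures: a small simulated cohort and a hand-built micro cohort
# whose expected values can be derived by hand.

tiny_cohort <- function(seed = 42, n_case = 80, n_ctrl = 80,
                        n_genes = 120,
                        sets = c(setA = 15, setB = 15),
                        spiked = NULL, phenotype = "GGE") {
  cfg <- sim_config(n_cases = stats::setNames(n_case, phenotype),
                    n_controls = n_ctrl, n_genes = n_genes,
                    genes_per_set = sets, spiked_or = spiked,
                    seed = seed)
  generate_cohort(cfg)
}

# minimal samples table: phenotype + the covariate columns the model uses
micro_samples <- function(case_ids, control_ids, phenotype = "GGE") {
  n <- length(case_ids) + length(control_ids)
  tibble::tibble(
    sample_id = c(case_ids, control_ids),
    phenotype = c(rep(phenotype, length(case_ids)),
                  rep("control", length(control_ids))),
    sex = rep_len(c(0L, 1L), n),
    batch = "b1") |>
    dplyr::bind_cols(tibble::as_tibble(
      matrix(0, nrow = n, ncol = 10,
             dimnames = list(NULL, paste0("PC", 1:10)))))
}

# one fully-specified missense annotation row; override fields as needed
micro_variant <- function(chrom = "1", pos = 100L, ref = "A", alt = "T",
                          gene = "GENE1", consequence = "missense",
                          pph2 = NA_character_, sift = NA_character_,
                          mpc = NA_real_, mtr = NA_real_, ccr = NA_real_,
                          para_z = NA_real_, gnomad_af = 0,
                          discovehr_af = 0) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                 alt = alt, gene = gene, consequence = consequence,
                 pph2 = pph2, sift = sift, mpc = mpc, mtr = mtr,
                 ccr = ccr, para_z = para_z, gnomad_af = gnomad_af,
                 discovehr_af = discovehr_af)
}

micro_carrier <- function(variant, sample_id, allele_count = 1L) {
  tibble::tibble(chrom = variant$chrom, pos = variant$pos,
                 ref = variant$ref, alt = variant$alt,
                 sample_id = sample_id,
                 allele_count = as.integer(allele_count))
}

# independent step-up oracle for Benjamini-Hochberg adjustment
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i, 1)
    q[o[i]] <- running
  }
  q
}

# brute-force 2x2 logistic data: a/b cases, c/d controls by exposure
two_by_two_data <- function(a, b, c, d) {
  list(y = c(rep(1, a + b), rep(0, c + d)),
       x = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)))
}
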