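#' Exclude all genes on one chromosome
#'
#' Sensitivity analysis for the case-control sex imbalance: removes every
#' gene whose variants lie on the named chromosome (default X) from the
#' variant, carrier and gene-set views, leaving the rest of the pipeline
#' unchanged. A gene's chromosome is taken from the variant table; a gene
#' annotated on more than one chromosome is an error.
#'
#' @param cohort A cohort list with `variants`, `carriers`, `gene_sets`.
#' @param chrom Chromosome name (a `"chr"` prefix is ignored).
#' @return The cohort with the chromosome's genes removed.
#' @export
exclude_chromosome <- function(cohort, chrom = "X") {
  chrom <- normalize_chrom(chrom)
  gmap <- cohort$variants |>
    dplyr::distinct(.data$gene, chrom = normalize_chrom(.data$chrom))
  multi <- gmap |> dplyr::count(.data$gene) |> dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0)
    stop("conflicting gene-to-chromosome mapping for: ",
         paste(head(multi$gene, 5), collapse = ", "), call. = FALSE)
  drop_genes <- gmap$gene[gmap$chrom == chrom]
  if (length(drop_genes) == 0) return(cohort)
  keep_var <- !(cohort$variants$gene %in% drop_genes)
  kept <- cohort$variants[keep_var, , drop = FALSE]
  cohort$variants <- kept
  cohort$carriers <- cohort$carriers |>
    dplyr::semi_join(kept, by = c("chrom", "pos", "ref", "alt"))
  cohort$gene_sets <- cohort$gene_sets |>
    dplyr::filter(!(.data$gene %in% drop_genes))
  cohort
}

#' Direct contrast between two sample groups
#'
#' Runs the identical burden machinery with an arbitrary pair of sample
#' groups as pseudo-cases (`group_a`) and pseudo-controls (`group_b`):
#' internal MACs are recomputed within `group_a` + `group_b`. This covers
#' the controls-only capture-kit contrast (e.g. one control sub-cohort
#' against the others) and the direct case-vs-case comparison between
#' phenotypes.
#'
#' @param cohort Cohort list.
#' @param group_a,group_b Disjoint, non-empty character vectors of sample
#'   ids.
#' @param gene_sets Catalogue to test (default the cohort's).
#' @param classes Class roster to test.
#' @param cfg A [urv_filter_config()].
#' @param rules A [class_rules()] roster.
#' @param label Analysis label stored in the `phenotype` column.
#' @return A `burden_grid` tibble (BH adjustment within this grid).
#' @export
group_contrast <- function(cohort, group_a, group_b,
                           gene_sets = NULL,
                           classes = qv_class_names(rules),
                           cfg = urv_filter_config(),
                           rules = class_rules(),
                           label = "group_a_vs_group_b") {
  if (length(group_a) == 0 || length(group_b) == 0)
    stop("both contrast groups must be non-empty", call. = FALSE)
  if (length(intersect(group_a, group_b)) > 0)
    stop("contrast groups overlap: ",
         paste(head(intersect(group_a, group_b), 5), collapse = ", "),
         call. = FALSE)
  gene_sets <- gene_sets %||% cohort$gene_sets
  qv <- build_qv_core(cohort$variants, cohort$carriers, group_a, group_b,
                      cfg, rules, analysis = label,
                      known_samples = cohort$samples$sample_id)
  res <- run_grid_core(qv, cohort$samples, gene_sets, classes,
                       label = label)
  finalize_grid(res)
}

#' Permutation subsampling of one burden test
#'
#' Repeatedly draws random sub-cohorts without replacement (cases of one
#' phenotype and controls, at the requested sizes), reruns the burden test
#' for a single (gene-set, class) cell — internal MACs recomputed within
#' each subsample — and summarises the permutation distribution: mean
#' log-odds (and its exponential), the mean of per-permutation odds, the
#' 2.5th/97.5th centiles (linear-interpolation quantiles) and the mean raw
#' p value.
#'
#' @param cohort Cohort list.
#' @param phenotype Case phenotype to subsample.
#' @param set Gene-set name (or character vector of genes).
#' @param class Variant class of the tested cell.
#' @param n_case_sub,n_ctrl_sub Subsample sizes (must not exceed the
#'   available strata).
#' @param n_perm Number of permutations (the reference analysis uses 500).
#' @param seed Integer seed; identical seed reproduces the summary.
#' @param cfg,rules Filter and class configuration.
#' @return A `permutation_summary` object; per-permutation draws are kept
#'   in `$draws`.
#' @export
permutation_subsample <- function(cohort, phenotype, set, class,
                                  n_case_sub, n_ctrl_sub, n_perm = 500,
                                  seed = 1, cfg = urv_filter_config(),
                                  rules = class_rules()) {
  samples <- cohort$samples
  case_pool <- samples$sample_id[samples$phenotype == phenotype]
  ctrl_pool <- samples$sample_id[samples$phenotype == "control"]
  if (n_case_sub > length(case_pool))
    stop("requested ", n_case_sub, " cases but only ", length(case_pool),
         " available", call. = FALSE)
  if (n_ctrl_sub > length(ctrl_pool))
    stop("requested ", n_ctrl_sub, " controls but only ",
         length(ctrl_pool), " available", call. = FALSE)
  genes <- resolve_set_genes(cohort$gene_sets, set)
  class_map <- assign_classes(cohort$variants, rules)

  set.seed(seed)
  draws <- purrr::map(seq_len(n_perm), function(i) {
    a <- sample(case_pool, n_case_sub)
    b <- sample(ctrl_pool, n_ctrl_sub)
    qv <- build_qv_core(cohort$variants, cohort$carriers, a, b, cfg,
                        rules, class_map = class_map,
                        analysis = paste0("perm", i))
    covars <- analysis_covariates(samples, qv)
    scores <- burden_score(qv, genes, class)$score
    res <- lrt_burden_test(qv$y, scores, covars)
    dplyr::mutate(res, perm = i, .before = 1)
  }) |> dplyr::bind_rows()

  lo <- draws$log_odds
  structure(
    list(n_perm = n_perm,
         mean_log_odds = mean(lo),
         mean_or = exp(mean(lo)),
         mean_odds_ratio = mean(exp(lo)),
         centile_2_5 = unname(quantile(lo, 0.025, type = 7)),
         centile_97_5 = unname(quantile(lo, 0.975, type = 7)),
         mean_p = mean(draws$p),
         quantile_method = "linear interpolation (type 7)",
         draws = draws),
    class = "permutation_summary")
}

#' @export
print.permutation_summary <- function(x, ...) {
  cat("<permutation_summary>", x$n_perm, "permutations\n",
      sprintf(" mean log-odds %.4f (odds %.3f; mean per-perm odds %.3f)\n",
              x$mean_log_odds, x$mean_or, x$mean_odds_ratio),
      sprintf(" log-odds 2.5/97.5 centiles: [%.4f, %.4f]\n",
              x$centile_2_5, x$centile_97_5),
      sprintf(" mean p value %.4f\n", x$mean_p))
  invisible(x)
}

#' Driver-gene sensitivity of one burden cell
#'
#' Recomputes a single (phenotype, gene-set, class) burden test before and
#' after removing named genes from the set, to show whether an enrichment
#' is driven by a few genes (e.g. known disease genes inside an otherwise
#' unrelated pathway).
#'
#' @param cohort Cohort list.
#' @param phenotype Case phenotype.
#' @param set Gene-set name (or character vector of genes).
#' @param class Variant class.
#' @param genes_to_drop Genes to remove; must be members of the set.
#' @param cfg,rules Filter and class configuration.
#' @return Two-row tibble (`which` = `"full"` / `"reduced"`) with the cell
#'   results and the dropped genes recorded.
#' @export
leave_genes_out <- function(cohort, phenotype, set, class, genes_to_drop,
                            cfg = urv_filter_config(),
                            rules = class_rules()) {
  genes <- resolve_set_genes(cohort$gene_sets, set)
  bad <- setdiff(genes_to_drop, genes)
  if (length(bad) > 0)
    stop("genes not in the set: ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  qv <- build_qv_table(cohort$variants, cohort$carriers, cohort$samples,
                       phenotype, cfg, rules)
  covars <- analysis_covariates(cohort$samples, qv)
  cell <- function(gs, which) {
    scores <- burden_score(qv, gs, class)$score
    dplyr::bind_cols(
      tibble::tibble(which = which, phenotype = phenotype,
                     class = class, n_genes_set = length(gs),
                     genes_removed = paste(genes_to_drop, collapse = ",")),
      carrier_summary(qv, gs, class),
      lrt_burden_test(qv$y, scores, covars))
  }
  dplyr::bind_rows(cell(genes, "full"),
                   cell(setdiff(genes, genes_to_drop), "reduced"))
}
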