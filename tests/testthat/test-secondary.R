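test_that("chromosome exclusion removes exactly the chromosome's genes", {
  co <- tiny_cohort(seed = 25, n_case = 50, n_ctrl = 50, n_genes = 200)
  n_genes_before <- length(unique(co$variants$gene))
  chrx_genes <- unique(co$variants$gene[co$variants$chrom == "X"])
  filtered <- exclude_chromosome(co, "X")
  expect_length(intersect(unique(filtered$variants$gene), chrx_genes), 0)
  expect_equal(length(unique(filtered$variants$gene)),
               n_genes_before - length(chrx_genes))
  # roughly the configured fraction of genes sits on X
  expect_lt(abs(length(chrx_genes) / n_genes_before - 0.05), 0.05)
  # carriers and gene-sets follow the variant view
  expect_equal(
    dplyr::anti_join(filtered$carriers, filtered$variants,
                     by = c("chrom", "pos", "ref", "alt")) |> nrow(), 0)
  expect_length(intersect(filtered$gene_sets$gene, chrx_genes), 0)
  # excluding an absent chromosome is the identity
  same <- exclude_chromosome(co, "chr21_nonexistent")
  expect_identical(same$variants, co$variants)
  # "chr" prefixes are normalized away
  expect_identical(exclude_chromosome(co, "chrX")$variants,
                   filtered$variants)
})

test_that("conflicting gene-to-chromosome annotation is an error", {
  co <- tiny_cohort(seed = 25, n_case = 20, n_ctrl = 20, n_genes = 50)
  v <- co$variants
  v$chrom[which(v$gene == v$gene[1])[1]] <- "ZZ"
  v2 <- dplyr::bind_rows(v, dplyr::mutate(v[1, ], chrom = "YY", pos = 1L))
  co$variants <- v2
  expect_error(exclude_chromosome(co, "X"), "conflicting")
})

test_that("group contrast is antisymmetric under label swap", {
  co <- tiny_cohort(seed = 26, n_case = 80, n_ctrl = 80, n_genes = 120,
                    sets = c(setA = 20))
  ctrls <- co$samples$sample_id[co$samples$phenotype == "control"]
  a <- ctrls[1:40]
  b <- ctrls[41:80]
  sets <- co$gene_sets |> dplyr::filter(set == "setA")
  g_ab <- group_contrast(co, a, b, gene_sets = sets)
  g_ba <- group_contrast(co, b, a, gene_sets = sets)
  ok <- !g_ab$degenerate & g_ab$converged & g_ba$converged
  expect_true(any(ok))
  expect_true(all(abs(g_ab$log_odds[ok] + g_ba$log_odds[ok]) < 1e-6))
  expect_equal(g_ab$lrt_stat[ok], g_ba$lrt_stat[ok], tolerance = 1e-6)

  expect_error(group_contrast(co, a, a[1:5]), "overlap")
  expect_error(group_contrast(co, a, character(0)), "non-empty")
})

test_that("exchangeable control halves show no systematic enrichment", {
  co <- tiny_cohort(seed = 27, n_case = 40, n_ctrl = 300, n_genes = 150)
  ctrls <- co$samples$sample_id[co$samples$phenotype == "control"]
  g <- group_contrast(co, ctrls[1:150], ctrls[151:300])
  live <- g[!g$degenerate & g$converged, ]
  expect_lt(mean(live$p < 0.05), 0.3)
  # inverse-variance weighted mean effect compatible with zero
  w <- 1 / live$se^2
  wmean <- sum(w * live$log_odds) / sum(w)
  # cells are correlated (nested classes, shared genes): allow twice the
  # independent-cell standard error
  expect_lt(abs(wmean), 2 * 3 * sqrt(1 / sum(w)) + 0.05)
})

test_that("permutation subsampling is reproducible and sane", {
  co <- tiny_cohort(seed = 28, n_case = 60, n_ctrl = 80, n_genes = 100,
                    sets = c(setA = 25))
  ps1 <- permutation_subsample(co, "GGE", "setA", "All functional",
                               n_case_sub = 40, n_ctrl_sub = 50,
                               n_perm = 5, seed = 7)
  ps2 <- permutation_subsample(co, "GGE", "setA", "All functional",
                               n_case_sub = 40, n_ctrl_sub = 50,
                               n_perm = 5, seed = 7)
  expect_identical(glance(ps1), glance(ps2))
  expect_equal(ps1$n_perm, 5)
  expect_true(ps1$centile_2_5 <= ps1$mean_log_odds &
                ps1$mean_log_odds <= ps1$centile_97_5)

  # a single permutation summarises to that run
  one <- permutation_subsample(co, "GGE", "setA", "All functional",
                               n_case_sub = 40, n_ctrl_sub = 50,
                               n_perm = 1, seed = 3)
  expect_equal(one$mean_log_odds, one$draws$log_odds)
  expect_equal(one$mean_p, one$draws$p)
  expect_equal(one$centile_2_5, one$draws$log_odds)

  expect_error(
    permutation_subsample(co, "GGE", "setA", "PTV", n_case_sub = 1000,
                          n_ctrl_sub = 10, n_perm = 1), "available")
})

test_that("null permutation log-odds centre on zero and MC error shrinks", {
  co <- tiny_cohort(seed = 29, n_case = 150, n_ctrl = 150, n_genes = 120,
                    sets = c(setA = 40))
  ps <- permutation_subsample(co, "GGE", "setA", "All functional",
                              n_case_sub = 100, n_ctrl_sub = 100,
                              n_perm = 60, seed = 11)
  # permutation draws centre on the (noisy) cohort-level effect, whose
  # scale is the per-draw estimator SE, not the Monte-Carlo SE
  expect_lt(abs(ps$mean_log_odds), 3 * mean(ps$draws$se))
  se <- sd(ps$draws$log_odds) / sqrt(ps$n_perm)
  # Monte-Carlo SE of the mean scales ~ 1/sqrt(n_perm)
  se15 <- sd(ps$draws$log_odds[1:15]) / sqrt(15)
  ratio <- se15 / se
  expect_gt(ratio, 1)
  expect_lt(ratio, 4)
})

test_that("leave-genes-out isolates driver genes", {
  co <- tiny_cohort(seed = 30, n_case = 60, n_ctrl = 60, n_genes = 100,
                    sets = c(setA = 15))
  qv <- build_qv_table(co$variants, co$carriers, co$samples, "GGE")
  set_genes <- co$gene_sets$gene[co$gene_sets$set == "setA"]
  hit_genes <- unique(qv$qv$gene[qv$qv$class == "All functional" &
                                   qv$qv$gene %in% set_genes])
  quiet <- setdiff(set_genes, hit_genes)

  # dropping genes without QVs changes nothing
  if (length(quiet) > 0) {
    res <- leave_genes_out(co, "GGE", "setA", "All functional",
                           genes_to_drop = quiet[1])
    expect_equal(res$log_odds[1], res$log_odds[2], tolerance = 1e-12)
    expect_equal(res$p[1], res$p[2], tolerance = 1e-12)
  }
  # dropping every gene leaves a degenerate cell with p = 1
  res_all <- leave_genes_out(co, "GGE", "setA", "All functional",
                             genes_to_drop = set_genes)
  expect_true(res_all$degenerate[2])
  expect_equal(res_all$p[2], 1)

  expect_error(leave_genes_out(co, "GGE", "setA", "PTV",
                               genes_to_drop = "NOT_IN_SET"),
               "not in the set")
})
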