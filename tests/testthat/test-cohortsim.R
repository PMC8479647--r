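test_that("identical config and seed reproduce the cohort exactly", {
  co1 <- tiny_cohort(seed = 21, n_case = 50, n_ctrl = 50, n_genes = 100)
  co2 <- tiny_cohort(seed = 21, n_case = 50, n_ctrl = 50, n_genes = 100)
  co3 <- tiny_cohort(seed = 22, n_case = 50, n_ctrl = 50, n_genes = 100)
  expect_identical(co1$samples, co2$samples)
  expect_identical(co1$variants, co2$variants)
  expect_identical(co1$carriers, co2$carriers)
  expect_identical(co1$gene_sets, co2$gene_sets)
  expect_false(identical(co1$carriers, co3$carriers))
})

test_that("truth table records spiked log-odds and zero elsewhere", {
  null_co <- tiny_cohort(seed = 3)
  expect_true(all(null_co$truth$log_odds == 0))

  sp <- tibble::tibble(set = "setA", class = "CCR 80", or = 1.5)
  co <- tiny_cohort(seed = 3, spiked = sp)
  spiked_rows <- co$truth[co$truth$set == "setA" &
                            co$truth$class == "CCR 80", ]
  expect_true(all(abs(spiked_rows$log_odds - log(1.5)) < 1e-12))
  other <- co$truth[!(co$truth$set == "setA" &
                        co$truth$class == "CCR 80"), ]
  expect_true(all(other$log_odds == 0))
})

test_that("gene-set catalogue has declared sets plus reference sets", {
  cfg <- sim_config(n_cases = c(GGE = 10), n_controls = 10,
                    n_genes = 100, genes_per_set = c(setA = 10),
                    seed = 2)
  gs <- generate_gene_sets(cfg)
  sizes <- gs |> dplyr::count(set)
  expect_equal(sizes$n[sizes$set == "setA"], 10)
  expect_equal(sizes$n[sizes$set == "all_genes"], 100)
  ctrl <- gs |> dplyr::filter(category == "control")
  expect_true(nrow(ctrl) > 0)
  # catalogue identical to the one embedded in the generated cohort
  co <- generate_cohort(cfg)
  expect_identical(gs, co$gene_sets)
})

test_that("declared set overlap is honoured", {
  base <- list(n_cases = c(GGE = 10), n_controls = 10, n_genes = 100,
               genes_per_set = c(s1 = 10, s2 = 10))
  gs0 <- generate_gene_sets(do.call(sim_config, c(base, set_overlap = 0,
                                                  seed = 4)))
  g1 <- gs0$gene[gs0$set == "s1"]
  g2 <- gs0$gene[gs0$set == "s2"]
  expect_length(intersect(g1, g2), 0)

  gs5 <- generate_gene_sets(do.call(sim_config, c(base, set_overlap = 0.5,
                                                  seed = 4)))
  expect_length(intersect(gs5$gene[gs5$set == "s1"],
                          gs5$gene[gs5$set == "s2"]), 5)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(female_frac_cases = 1.2), "female_frac_cases")
  expect_error(sim_config(n_genes = 50, genes_per_set = c(setA = 60)),
               "genes_per_set")
  expect_error(sim_config(spiked_or = tibble::tibble(
    set = "nope", class = "CCR 80", or = 1.5)), "spiked_or")
  expect_error(sim_config(spiked_or = tibble::tibble(
    set = "setA", class = "not a class", or = 1.5)), "spiked_or")
  # rates violating the class nesting are infeasible
  bad <- default_qv_rates()
  bad["MPC 1"] <- 0.5
  expect_error(sim_config(baseline_qv_rate = bad), "baseline_qv_rate")
})

test_that("variant scores are consistent with their generation intent", {
  co <- tiny_cohort(seed = 13, n_case = 60, n_ctrl = 60, n_genes = 150)
  v <- co$variants
  m <- urvburden:::class_membership(v, class_rules())
  real <- v$origin %in% qv_class_names()
  intent <- v$origin[real]
  hit <- m[cbind(which(real), match(intent, colnames(m)))]
  expect_true(all(hit))
  # fillers satisfy no class at all
  expect_true(all(rowSums(m[v$origin == "filler", , drop = FALSE]) == 0))
})

test_that("per-class QV rates match the configured baseline", {
  n_case <- 120; n_ctrl <- 120; n_genes <- 500
  co <- tiny_cohort(seed = 31, n_case = n_case, n_ctrl = n_ctrl,
                    n_genes = n_genes)
  qv <- build_qv_table(co$variants, co$carriers, co$samples, "GGE")
  counts <- qv$qv |> dplyr::count(class)
  n <- n_case + n_ctrl
  rates <- default_qv_rates()
  for (cl in qv_class_names()) {
    expected <- rates[[cl]] * n_genes / 1000
    k <- counts$n[counts$class == cl]
    observed <- (if (length(k) == 0) 0L else k) / n
    se <- sqrt(expected / n)  # Poisson-scale standard error of the mean
    expect_lt(abs(observed - expected), 3 * se + 1e-9,
              label = paste("rate for", cl))
  }
})

test_that("allele-count spectrum is singleton-dominated with planted decoys", {
  co <- tiny_cohort(seed = 17, n_case = 100, n_ctrl = 100, n_genes = 200)
  mac <- compute_internal_mac(co$carriers, co$samples$sample_id,
                              variants = co$variants)
  expect_gt(mean(mac$mac == 1), 0.7)
  v <- co$variants |>
    dplyr::left_join(mac, by = c("chrom", "pos", "ref", "alt"))
  # each decoy mode is present: gnomAD-frequent, DiscovEHR-seen, high MAC
  expect_gt(sum(v$gnomad_af > 2e-5), 0)
  expect_gt(sum(v$discovehr_af > 0), 0)
  expect_gt(sum(v$mac > 3), 0)
  # and none of them survives the ultra-rare filter
  pass <- filter_urv(v, v$mac, urv_filter_config())
  expect_true(all(v$origin[pass] != "decoy"))
})

test_that("cohort structure follows the configured confounders", {
  cfg <- sim_config(n_cases = c(DEE = 200, GGE = 300), n_controls = 500,
                    n_genes = 50, genes_per_set = c(setA = 10), seed = 8)
  co <- generate_cohort(cfg)
  s <- co$samples
  expect_equal(sum(s$phenotype == "DEE"), 200)
  expect_equal(sum(s$phenotype == "control"), 500)
  # sex imbalance: cases mostly female-enriched relative to controls
  f_case <- mean(s$sex[s$phenotype != "control"])
  f_ctrl <- mean(s$sex[s$phenotype == "control"])
  expect_gt(f_case, f_ctrl)
  expect_lt(abs(f_case - 0.536), 0.1)
  expect_lt(abs(f_ctrl - 0.194), 0.1)
  # control batches present in declared proportions
  expect_setequal(unique(s$batch[s$phenotype == "control"]),
                  c("ATVB", "Leicester", "Ottawa", "Epi25_Italian"))
})
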