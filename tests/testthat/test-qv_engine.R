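test_that("internal MAC sums allele counts within the analysis cohort", {
  v <- micro_variant()
  carr <- dplyr::bind_rows(
    micro_carrier(v, "S1"), micro_carrier(v, "S2"), micro_carrier(v, "S3"))
  mac <- compute_internal_mac(carr, c("S1", "S2", "S3"))
  expect_equal(mac$mac, 3L)

  # one homozygous + one het in cohort, one het outside
  carr2 <- dplyr::bind_rows(
    micro_carrier(v, "S1", allele_count = 2L), micro_carrier(v, "S2"),
    micro_carrier(v, "S9"))
  mac2 <- compute_internal_mac(carr2, c("S1", "S2"))
  expect_equal(mac2$mac, 3L)

  # carried only by samples outside the analysis -> 0 via variant completion
  mac3 <- compute_internal_mac(carr2, c("S5", "S6"), variants = v)
  expect_equal(mac3$mac, 0L)

  expect_error(
    compute_internal_mac(carr, c("S1"), known_samples = c("S1", "S2")),
    "unknown sample")
})

test_that("ultra-rare filter applies MAC and external frequency bounds", {
  cfg <- urv_filter_config()
  v <- dplyr::bind_rows(
    micro_variant(pos = 1, gnomad_af = 0, discovehr_af = 0),
    micro_variant(pos = 2, gnomad_af = 0, discovehr_af = 0),
    micro_variant(pos = 3, gnomad_af = 3e-5),
    micro_variant(pos = 4, gnomad_af = NA, discovehr_af = NA),
    micro_variant(pos = 5, discovehr_af = 1e-6))
  pass <- filter_urv(v, mac = c(3L, 4L, 1L, 1L, 1L), cfg)
  expect_equal(pass, c(TRUE, FALSE, FALSE, TRUE, FALSE))
})

test_that("tightening the gnomAD bound never admits more variants", {
  set.seed(7)
  v <- purrr::map(1:200, function(i)
    micro_variant(pos = i, gnomad_af = sample(c(0, 1e-5, 2e-5, 1e-4), 1)))
  v <- dplyr::bind_rows(v)
  mac <- rep(1L, nrow(v))
  thresholds <- sort(c(0, 1e-5, 2e-5, 5e-5, 1e-3), decreasing = TRUE)
  n_pass <- vapply(thresholds, function(t)
    sum(filter_urv(v, mac, urv_filter_config(gnomad_af_max = t))),
    numeric(1))
  expect_true(all(diff(n_pass) <= 0))
})

test_that("class assignment reproduces hand-derived memberships", {
  rules <- class_rules()
  classes_of <- function(v) sort(assign_classes(v, rules)$class)

  expect_equal(classes_of(micro_variant(consequence = "stop_gained")),
               sort(c("PTV", "All functional")))
  expect_equal(classes_of(micro_variant(consequence = "synonymous")),
               "Synonymous")
  expect_equal(classes_of(micro_variant(consequence = "inframe_indel")),
               "All functional")

  # fully constrained damaging missense variant hits nine classes
  v <- micro_variant(pph2 = "probably_damaging", sift = "deleterious",
                     mpc = 2.5, mtr = 0.5, ccr = 85, para_z = 1.2)
  expect_equal(
    classes_of(v),
    sort(c("Damaging missense", "All functional", "MPC 1", "MPC 2",
           "MTR ClinVar", "MTR De Novo", "CCR 80", "paralog-conserved",
           "paralog highly conserved")))

  # high CCR alone is not enough: the MPC condition gates CCR 80
  v2 <- micro_variant(ccr = 85, mpc = 0.5, mtr = 0.5)
  expect_false("CCR 80" %in% classes_of(v2))
  expect_true("MTR De Novo" %in% classes_of(v2))

  # discordant PPh2/SIFT is neither benign nor damaging under "both"
  v3 <- micro_variant(pph2 = "benign", sift = "deleterious")
  expect_false(any(c("Benign missense", "Damaging missense") %in%
                     classes_of(v3)))
  expect_true("Damaging missense" %in%
                sort(assign_classes(v3, class_rules(
                  damaging_rule = "either"))$class))

  expect_message(out <- assign_classes(
    micro_variant(consequence = "weird_csq")), "unrecognized consequence")
  expect_equal(nrow(out), 0)
})

test_that("class nesting and paralog partition hold on simulated cohorts", {
  co <- tiny_cohort(seed = 5, n_case = 60, n_ctrl = 60, n_genes = 150)
  m <- urvburden:::class_membership(co$variants, class_rules())
  expect_true(all(m[, "MPC 2"] <= m[, "MPC 1"]))
  expect_true(all(m[, "MTR De Novo"] <= m[, "MTR ClinVar"]))
  expect_true(all(m[, "CCR 80"] <= (m[, "MPC 1"] & m[, "MTR ClinVar"])))
  expect_true(all(m[, "paralog highly conserved"] <=
                    m[, "paralog-conserved"]))
  # synonymous never co-occurs with a non-synonymous class
  expect_true(all(rowSums(m[m[, "Synonymous"], -1, drop = FALSE]) == 0))
  # paralog tiers partition missense variants with a para-Z value
  mis <- co$variants$consequence == "missense" &
    !is.na(co$variants$para_z)
  expect_true(all(xor(m[mis, "paralog-conserved"],
                      m[mis, "paralog-non-conserved"])))
})

test_that("gene collapsing yields one indicator per (sample, gene, class)", {
  samples <- micro_samples("S1", c("C1", "C2"))
  v1 <- micro_variant(pos = 101, pph2 = "probably_damaging",
                      sift = "deleterious")
  v2 <- micro_variant(pos = 102, pph2 = "probably_damaging",
                      sift = "deleterious")
  carr <- dplyr::bind_rows(micro_carrier(v1, "S1"), micro_carrier(v2, "S1"))
  qv <- build_qv_table(dplyr::bind_rows(v1, v2), carr, samples, "GGE")
  dm <- qv$qv[qv$qv$class == "Damaging missense", ]
  expect_equal(nrow(dm), 1)
  expect_equal(dm$sample_id, "S1")
  # both carried variants count toward the exome-wide covariates
  expect_equal(
    qv$covariates$urv_count[qv$covariates$sample_id == "S1"], 2L)
  expect_equal(
    qv$covariates$singleton_count[qv$covariates$sample_id == "S1"], 2L)
})

test_that("per-phenotype MACs can change qualifying status", {
  samples <- dplyr::bind_rows(
    micro_samples(c("G1", "G2"), c("C1", "C2"), phenotype = "GGE"),
    micro_samples(c("N1", "N2", "N3"), character(0), phenotype = "NAFE"))
  v <- micro_variant(pph2 = "probably_damaging", sift = "deleterious")
  carr <- dplyr::bind_rows(
    micro_carrier(v, "N1"), micro_carrier(v, "N2"), micro_carrier(v, "N3"),
    micro_carrier(v, "C1"))
  qv_gge <- build_qv_table(v, carr, samples, "GGE")   # MAC 1 -> passes
  qv_nafe <- build_qv_table(v, carr, samples, "NAFE") # MAC 4 -> fails
  expect_true("C1" %in% qv_gge$qv$sample_id)
  expect_equal(nrow(qv_nafe$qv), 0)
})

test_that("QV construction is idempotent and fails on empty strata", {
  co <- tiny_cohort(seed = 9, n_case = 40, n_ctrl = 40, n_genes = 80)
  a <- build_qv_table(co$variants, co$carriers, co$samples, "GGE")
  b <- build_qv_table(co$variants, co$carriers, co$samples, "GGE")
  expect_identical(a$qv, b$qv)
  expect_identical(a$covariates, b$covariates)
  expect_error(build_qv_table(co$variants, co$carriers, co$samples, "DEE"),
               "no samples")
  no_ctrl <- co$samples[co$samples$phenotype != "control", ]
  expect_error(build_qv_table(co$variants, co$carriers, no_ctrl, "GGE"),
               "non-empty")
})
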