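#' Default per-class qualifying-variant rates
#'
#' Expected qualifying variants per sample per 1,000 genes for each of the
#' thirteen classes. The values form a plausible ultra-rare exome profile
#' for a compact simulated gene universe: synonymous variants are the most
#' abundant, protein-truncating the rarest, and the nested constraint
#' classes (MPC 2 within MPC 1, MTR De Novo within MTR ClinVar, CCR 80
#' within both, paralog tiers) obey the rate ordering that the nesting
#' imposes.
#'
#' @return Named numeric vector over [qv_class_names()].
#' @export
default_qv_rates <- function() {
  c("Synonymous" = 10, "Benign missense" = 6, "Damaging missense" = 5,
    "PTV" = 2, "All functional" = 8, "MPC 1" = 5, "MPC 2" = 1.5,
    "MTR ClinVar" = 5, "MTR De Novo" = 2, "CCR 80" = 1,
    "paralog-non-conserved" = 4, "paralog-conserved" = 4,
    "paralog highly conserved" = 1.5)
}

# Generation archetypes: disjoint variant-producing processes whose realized
# class memberships respect the class nesting. Each archetype's score
# profile satisfies exactly the listed classes under the default rules.
archetype_membership <- function() {
  list(
    syn = "Synonymous",
    benign = "Benign missense",
    damaging = c("Damaging missense", "All functional"),
    ptv = c("PTV", "All functional"),
    inframe = "All functional",
    mpc1 = "MPC 1",
    mpc2 = c("MPC 1", "MPC 2"),
    mtr_cv = "MTR ClinVar",
    mtr_dn = c("MTR ClinVar", "MTR De Novo"),
    ccr80 = c("CCR 80", "MPC 1", "MTR ClinVar"),
    para_nc = "paralog-non-conserved",
    para_c = "paralog-conserved",
    para_hc = c("paralog-conserved", "paralog highly conserved")
  )
}

# Solve archetype intensities (per sample per 1,000 genes) so that the
# realized marginal rate of every class equals the configured rate.
archetype_intensities <- function(rates) {
  need <- qv_class_names()
  missing <- setdiff(need, names(rates))
  if (length(missing) > 0)
    abort_config("baseline_qv_rate",
                 paste("is missing class(es):",
                       paste(missing, collapse = ", ")))
  r <- rates[need]
  lam <- c(
    syn = unname(r["Synonymous"]),
    benign = unname(r["Benign missense"]),
    damaging = unname(r["Damaging missense"]),
    ptv = unname(r["PTV"]),
    inframe = unname(r["All functional"] - r["PTV"] -
                       r["Damaging missense"]),
    mpc1 = unname(r["MPC 1"] - r["MPC 2"] - r["CCR 80"]),
    mpc2 = unname(r["MPC 2"]),
    mtr_cv = unname(r["MTR ClinVar"] - r["MTR De Novo"] - r["CCR 80"]),
    mtr_dn = unname(r["MTR De Novo"]),
    ccr80 = unname(r["CCR 80"]),
    para_nc = unname(r["paralog-non-conserved"]),
    para_c = unname(r["paralog-conserved"] -
                      r["paralog highly conserved"]),
    para_hc = unname(r["paralog highly conserved"])
  )
  if (any(lam < -1e-12)) {
    bad <- names(lam)[lam < -1e-12]
    abort_config("baseline_qv_rate",
                 paste0("is infeasible under class nesting (negative ",
                        "implied intensity for archetype(s): ",
                        paste(bad, collapse = ", "),
                        "); e.g. rate('MPC 1') must be >= rate('MPC 2') ",
                        "+ rate('CCR 80')"))
  }
  pmax(lam, 0)
}

#' Simulation configuration
#'
#' Parameters of the synthetic case-control exome cohort. The defaults
#' reproduce the structure of the study cohort: three case phenotypes
#' (DEE, GGE, NAFE) against a shared control pool with a strong sex
#' imbalance (53.6% female cases vs 19.4% female controls) and controls
#' drawn from several sub-cohorts of different sizes (capture-kit
#' batches). Gene-set enrichment is spiked through `spiked_or`: for case
#' samples, the per-gene carrier odds of the named class in the named set
#' are multiplied by the odds ratio.
#'
#' @param n_cases Named integer vector, cases per phenotype.
#' @param n_controls Number of controls.
#' @param n_genes Size of the simulated gene universe.
#' @param genes_per_set Named integer vector: declared gene-set sizes. A
#'   set of all genes (`all_genes`) and a never-spiked control set
#'   (`non_brain_expressed`, category `"control"`) are always added.
#' @param set_categories Optional named character vector giving the
#'   category of each declared set (default `"functional"`).
#' @param set_overlap Fraction of each declared set shared with the
#'   previously declared set (0 = declared sets are disjoint).
#' @param spiked_or Data frame with columns `set`, `class`, `or` (odds
#'   ratio >= 0 applied to case carrier odds), or `NULL` for the all-null
#'   cohort.
#' @param baseline_qv_rate Named vector over [qv_class_names()]: expected
#'   qualifying variants per sample per 1,000 genes, per class. See
#'   [default_qv_rates()].
#' @param female_frac_cases,female_frac_controls Female proportions.
#' @param batch_labels Named numeric vector of control sub-cohort relative
#'   sizes.
#' @param pc_noise_sd Spread of the simulated principal components.
#' @param chrx_gene_frac Fraction of genes placed on chromosome X.
#' @param sex_effect Optional log-odds shift of carrier rates in females
#'   (default 0, i.e. no sex-linked carrier effect).
#' @param decoy_frac Fraction of additional decoy variant sites that carry
#'   damaging-like scores but fail exactly one ultra-rare filter (gnomAD
#'   frequency, DiscovEHR frequency, or internal MAC), planted to exercise
#'   the filters.
#' @param filler_frac Fraction of additional passing variants with an
#'   uninformative consequence (`"other"`) that belong to no class.
#' @param seed Integer seed; identical configuration + seed reproduces
#'   byte-identical output.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_cases = c(DEE = 1003, GGE = 3064, NAFE = 3522),
                       n_controls = 3962,
                       n_genes = 1000,
                       genes_per_set = c(setA = 50, setB = 50),
                       set_categories = NULL,
                       set_overlap = 0,
                       spiked_or = NULL,
                       baseline_qv_rate = default_qv_rates(),
                       female_frac_cases = 0.536,
                       female_frac_controls = 0.194,
                       batch_labels = c(ATVB = 1673, Leicester = 1082,
                                        Ottawa = 924, Epi25_Italian = 283),
                       pc_noise_sd = 1,
                       chrx_gene_frac = 0.05,
                       sex_effect = 0,
                       decoy_frac = 0.05,
                       filler_frac = 0.05,
                       seed = 1L) {
  cfg <- structure(
    list(n_cases = n_cases, n_controls = n_controls, n_genes = n_genes,
         genes_per_set = genes_per_set, set_categories = set_categories,
         set_overlap = set_overlap, spiked_or = spiked_or,
         baseline_qv_rate = baseline_qv_rate,
         female_frac_cases = female_frac_cases,
         female_frac_controls = female_frac_controls,
         batch_labels = batch_labels, pc_noise_sd = pc_noise_sd,
         chrx_gene_frac = chrx_gene_frac, sex_effect = sex_effect,
         decoy_frac = decoy_frac, filler_frac = filler_frac,
         seed = as.integer(seed)),
    class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (is.null(names(cfg$n_cases)) || any(!nzchar(names(cfg$n_cases))))
    abort_config("n_cases", "must be a named vector (one count per phenotype)")
  if (any(cfg$n_cases <= 0)) abort_config("n_cases", "counts must be > 0")
  if (cfg$n_controls <= 0) abort_config("n_controls", "must be > 0")
  if (cfg$n_genes <= 0) abort_config("n_genes", "must be > 0")
  if (cfg$n_genes > 20000)
    abort_config("n_genes",
                 paste("must be <= 20,000 (each simulated gene occupies",
                       "a fixed 100-kb position window)"))
  if (is.null(names(cfg$genes_per_set)))
    abort_config("genes_per_set", "must be a named vector of set sizes")
  if (any(cfg$genes_per_set > cfg$n_genes))
    abort_config("genes_per_set",
                 "requests a set larger than the gene universe")
  if (cfg$set_overlap < 0 || cfg$set_overlap > 1)
    abort_config("set_overlap", "must be a proportion in [0, 1]")
  for (f in c("female_frac_cases", "female_frac_controls",
              "chrx_gene_frac")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      abort_config(f, "must be a proportion in [0, 1]")
  }
  if (any(cfg$baseline_qv_rate < 0))
    abort_config("baseline_qv_rate", "rates must be >= 0")
  archetype_intensities(cfg$baseline_qv_rate)  # feasibility under nesting
  if (!is.null(cfg$spiked_or)) {
    sp <- cfg$spiked_or
    if (!all(c("set", "class", "or") %in% names(sp)))
      abort_config("spiked_or", "needs columns set, class, or")
    if (any(!sp$set %in% names(cfg$genes_per_set)))
      abort_config("spiked_or", "references an undeclared gene-set")
    if (any(!sp$class %in% qv_class_names()))
      abort_config("spiked_or", "references an unknown class")
    if (any(sp$or < 0)) abort_config("spiked_or", "odds ratios must be >= 0")
  }
  if (length(cfg$seed) != 1 || is.na(cfg$seed))
    abort_config("seed", "must be a single integer")
  invisible(cfg)
}

sim_genes <- function(cfg) {
  n <- cfg$n_genes
  chrom <- as.character(sample(1:22, n, replace = TRUE))
  n_x <- round(cfg$chrx_gene_frac * n)
  if (n_x > 0) chrom[sample.int(n, n_x)] <- "X"
  tibble::tibble(gene = sprintf("G%05d", seq_len(n)),
                 chrom = chrom,
                 pos_base = 100000 * seq_len(n))
}

sim_sets <- function(cfg, genes) {
  sizes <- cfg$genes_per_set
  cats <- cfg$set_categories %||%
    setNames(rep("functional", length(sizes)), names(sizes))
  pool <- genes$gene
  available <- pool
  out <- list()
  prev <- character(0)
  for (i in seq_along(sizes)) {
    nm <- names(sizes)[i]
    sz <- sizes[[i]]
    k <- if (i > 1) round(cfg$set_overlap * sz) else 0
    k <- min(k, length(prev))
    shared <- if (k > 0) sample(prev, k) else character(0)
    fresh_pool <- setdiff(available, shared)
    if (sz - k > length(fresh_pool))
      abort_config("genes_per_set",
                   paste("cannot allocate disjoint genes; reduce set",
                         "sizes or increase overlap"))
    fresh <- sample(fresh_pool, sz - k)
    members <- c(shared, fresh)
    available <- setdiff(available, fresh)
    out[[nm]] <- tibble::tibble(set = nm,
                                category = unname(cats[nm] %||% "functional"),
                                gene = members)
    prev <- members
  }
  ctrl_sz <- min(50, cfg$n_genes)
  dplyr::bind_rows(
    dplyr::bind_rows(out),
    tibble::tibble(set = "all_genes", category = "all", gene = pool),
    tibble::tibble(set = "non_brain_expressed", category = "control",
                   gene = sample(pool, ctrl_sz))
  )
}

sim_samples <- function(cfg) {
  phenos <- rep(names(cfg$n_cases), times = cfg$n_cases)
  n_case <- length(phenos)
  n <- n_case + cfg$n_controls
  ids <- sprintf("S%06d", seq_len(n))
  phenotype <- c(phenos, rep("control", cfg$n_controls))
  sex <- c(rbinom(n_case, 1, cfg$female_frac_cases),
           rbinom(cfg$n_controls, 1, cfg$female_frac_controls))
  # control sub-cohorts in proportion to their declared relative sizes
  bl <- cfg$batch_labels
  ctrl_batch <- sample(rep(names(bl),
                           diff(round(cumsum(c(0, bl)) / sum(bl) *
                                        cfg$n_controls))))
  batch <- c(rep("case_cohort", n_case), ctrl_batch)
  pcs <- matrix(rnorm(n * 10, sd = cfg$pc_noise_sd), nrow = n)
  # mild batch structure on the leading components (capture-kit proxy)
  offsets <- matrix(rnorm(length(unique(batch)) * 2,
                          sd = 0.3 * cfg$pc_noise_sd), ncol = 2)
  rownames(offsets) <- unique(batch)
  pcs[, 1:2] <- pcs[, 1:2] + offsets[batch, ]
  colnames(pcs) <- paste0("PC", 1:10)
  dplyr::bind_cols(
    tibble::tibble(sample_id = ids, phenotype = phenotype,
                   sex = as.integer(sex), batch = batch),
    tibble::as_tibble(pcs))
}

# archetype score profiles; n rows each, satisfying exactly the intended
# classes under the default rules
archetype_scores <- function(arch, n) {
  na <- rep(NA_real_, n)
  nac <- rep(NA_character_, n)
  base <- tibble::tibble(consequence = rep("missense", n),
                         pph2 = nac, sift = nac,
                         mpc = na, mtr = na, ccr = na, para_z = na)
  fail_mis <- function(t) {  # missense scores failing every threshold class
    t$mpc <- runif(n, 0, 0.9); t$mtr <- runif(n, 0.85, 1)
    t$ccr <- runif(n, 0, 70); t
  }
  discordant <- function(t) {  # PPh2/SIFT disagree -> neither benign nor damaging
    t$pph2 <- rep("benign", n); t$sift <- rep("deleterious", n); t
  }
  switch(arch,
    syn = { b <- base; b$consequence <- rep("synonymous", n)
            b$pph2 <- nac; b },
    benign = { b <- fail_mis(base)
               b$pph2 <- rep("benign", n); b$sift <- rep("tolerated", n); b },
    damaging = { b <- fail_mis(base)
                 b$pph2 <- sample(c("possibly_damaging",
                                    "probably_damaging"), n, replace = TRUE)
                 b$sift <- rep("deleterious", n); b },
    ptv = { b <- base
            b$consequence <- sample(ptv_consequences(), n, replace = TRUE)
            b },
    inframe = { b <- base; b$consequence <- rep("inframe_indel", n); b },
    mpc1 = { b <- discordant(fail_mis(base)); b$mpc <- runif(n, 1, 1.9); b },
    mpc2 = { b <- discordant(fail_mis(base)); b$mpc <- runif(n, 2, 4); b },
    mtr_cv = { b <- discordant(fail_mis(base))
               b$mtr <- runif(n, 0.5655, 0.825); b },
    mtr_dn = { b <- discordant(fail_mis(base))
               b$mtr <- runif(n, 0.01, 0.565); b },
    ccr80 = { b <- discordant(base)
              b$mpc <- runif(n, 1, 1.9); b$mtr <- runif(n, 0.5655, 0.825)
              b$ccr <- runif(n, 80, 100); b },
    para_nc = { b <- discordant(fail_mis(base))
                b$para_z <- runif(n, -3, 0); b },
    para_c = { b <- discordant(fail_mis(base))
               b$para_z <- runif(n, 0.001, 0.99); b },
    para_hc = { b <- discordant(fail_mis(base))
                b$para_z <- runif(n, 1, 3); b },
    stop("unknown archetype: ", arch)
  )
}

archetype_origin <- function() {
  c(syn = "Synonymous", benign = "Benign missense",
    damaging = "Damaging missense", ptv = "PTV", inframe = "All functional",
    mpc1 = "MPC 1", mpc2 = "MPC 2", mtr_cv = "MTR ClinVar",
    mtr_dn = "MTR De Novo", ccr80 = "CCR 80",
    para_nc = "paralog-non-conserved", para_c = "paralog-conserved",
    para_hc = "paralog highly conserved")
}

# Bernoulli carrier events for one sample group over one gene subset
draw_events <- function(sample_idx, gene_idx, p, arch) {
  n_s <- length(sample_idx)
  g <- length(gene_idx)
  if (n_s == 0 || g == 0 || p <= 0) return(NULL)
  k <- rbinom(n_s, g, p)
  tot <- sum(k)
  if (tot == 0) return(NULL)
  gidx <- unlist(lapply(k, function(m)
    if (m > 0) gene_idx[sample.int(g, m)] else integer(0)))
  tibble::tibble(sample_idx = rep(sample_idx, k), gene_idx = gidx,
                 archetype = arch)
}

#' Generate the gene-set catalogue of a simulation
#'
#' Builds the declared gene-sets (honouring `set_overlap`) plus a set of
#' all simulated genes (`all_genes`) and a never-spiked control set
#' (`non_brain_expressed`). Deterministic given the configuration seed and
#' identical to the catalogue embedded in [generate_cohort()] output for
#' the same configuration.
#'
#' @param config A [sim_config()].
#' @return Long tibble with `set`, `category`, `gene`.
#' @export
generate_gene_sets <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  genes <- sim_genes(config)
  sim_sets(config, genes)
}

#' Generate a synthetic case-control cohort
#'
#' Simulates samples, variant sites, carriers, gene-sets and an enrichment
#' truth table with the statistical structure the burden analysis assumes:
#' per (sample, gene, class) carrier indicators drawn as Bernoulli events
#' whose log-odds are shifted by `log(spiked_or)` for cases in spiked
#' (set, class) cells; score profiles drawn consistently with each
#' variant's intended class; a singleton-dominated allele-count spectrum
#' (a minority of sites are shared by two carriers, and occasional
#' homozygous carriers contribute two allele copies); and planted decoy
#' variants that fail exactly one ultra-rare filter.
#'
#' @param config A [sim_config()].
#' @return A `synthetic_cohort`: list with tibbles `samples`, `variants`
#'   (annotation columns plus a simulation-only `origin` column naming the
#'   intended class), `carriers`, `gene_sets`, `truth` (per set, class and
#'   phenotype: the simulated log-odds, 0 when unspiked), and the `config`.
#' @examples
#' cfg <- sim_config(n_cases = c(GGE = 60), n_controls = 60, n_genes = 80,
#'                   genes_per_set = c(setA = 10), seed = 7)
#' cohort <- generate_cohort(cfg)
#' cohort$truth
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  genes <- sim_genes(config)
  gene_sets <- sim_sets(config, genes)
  samples <- sim_samples(config)

  lam <- archetype_intensities(config$baseline_qv_rate)
  membership <- archetype_membership()
  spiked <- config$spiked_or %||%
    tibble::tibble(set = character(), class = character(), or = numeric())
  spiked <- spiked[spiked$or != 1, , drop = FALSE]

  case_idx <- which(samples$phenotype != "control")
  ctrl_idx <- which(samples$phenotype == "control")
  female <- samples$sex == 1

  events <- list()
  for (arch in names(lam)) {
    if (lam[[arch]] <= 0) next
    p <- lam[[arch]] / 1000
    sp <- spiked[spiked$class %in% membership[[arch]], , drop = FALSE]
    spiked_genes <- integer(0)
    or_by_gene <- numeric(0)
    if (nrow(sp) > 0) {
      gmap <- gene_sets |>
        dplyr::filter(.data$set %in% sp$set) |>
        dplyr::left_join(sp, by = "set") |>
        dplyr::group_by(.data$gene) |>
        dplyr::summarise(or = max(.data$or), .groups = "drop")
      spiked_genes <- match(gmap$gene, genes$gene)
      or_by_gene <- gmap$or
    }
    draw_group <- function(sidx, shift) {
      base_p <- plogis(qlogis(p) + shift)
      if (length(spiked_genes) == 0) {
        return(draw_events(sidx, seq_len(config$n_genes), base_p, arch))
      }
      plain <- setdiff(seq_len(config$n_genes), spiked_genes)
      parts <- list(draw_events(sidx, plain, base_p, arch))
      for (or_val in unique(or_by_gene)) {
        gsub <- spiked_genes[or_by_gene == or_val]
        parts <- c(parts, list(
          draw_events(sidx, gsub, plogis(qlogis(base_p) + log(or_val)),
                      arch)))
      }
      dplyr::bind_rows(parts)
    }
    if (config$sex_effect != 0) {
      events <- c(events, list(
        draw_group(intersect(case_idx, which(!female)), 0),
        draw_group(intersect(case_idx, which(female)), config$sex_effect),
        draw_events(intersect(ctrl_idx, which(!female)),
                    seq_len(config$n_genes), p, arch),
        draw_events(intersect(ctrl_idx, which(female)),
                    seq_len(config$n_genes),
                    plogis(qlogis(p) + config$sex_effect), arch)))
    } else {
      events <- c(events, list(
        draw_group(case_idx, 0),
        draw_events(ctrl_idx, seq_len(config$n_genes), p, arch)))
    }
  }
  events <- dplyr::bind_rows(events)

  cohort_tables <- materialize_variants(events, genes, samples, config)

  phenos <- names(config$n_cases)
  truth <- tidyr::expand_grid(set = unique(gene_sets$set),
                              class = qv_class_names(),
                              phenotype = phenos) |>
    dplyr::left_join(
      config$spiked_or %||% tibble::tibble(set = character(),
                                           class = character(),
                                           or = numeric()),
      by = c("set", "class")) |>
    dplyr::mutate(log_odds = ifelse(is.na(.data$or), 0, log(.data$or))) |>
    dplyr::select("set", "class", "phenotype", "log_odds")

  structure(
    list(samples = samples, variants = cohort_tables$variants,
         carriers = cohort_tables$carriers, gene_sets = gene_sets,
         truth = truth, config = config),
    class = "synthetic_cohort")
}

# Turn carrier events into variant sites, annotations and carrier records.
materialize_variants <- function(events, genes, samples, config) {
  if (is.null(events) || nrow(events) == 0) {
    events <- tibble::tibble(sample_idx = integer(), gene_idx = integer(),
                             archetype = character())
  }
  n_e <- nrow(events)
  shared <- runif(n_e) < 0.10
  second <- runif(n_e) < 0.20

  ev <- events |>
    dplyr::mutate(eid = dplyr::row_number(), shared = shared,
                  second = second)
  sh <- ev |>
    dplyr::filter(.data$shared) |>
    dplyr::group_by(.data$gene_idx, .data$archetype) |>
    dplyr::mutate(site_key = paste0("p", .data$gene_idx, ":",
                                    .data$archetype, ":",
                                    ceiling(dplyr::row_number() / 2))) |>
    dplyr::ungroup()
  un <- ev |>
    dplyr::filter(!.data$shared) |>
    dplyr::mutate(site_key = paste0("u", .data$eid))
  sec <- ev |>
    dplyr::filter(.data$second) |>
    dplyr::mutate(site_key = paste0("s", .data$eid))
  carr_ev <- dplyr::bind_rows(sh, un, sec)

  sites <- carr_ev |>
    dplyr::distinct(.data$site_key, .data$gene_idx, .data$archetype)

  # decoys: damaging-like scores, each failing exactly one URV filter
  n_decoy <- if (nrow(sites) > 0)
    max(6, round(config$decoy_frac * nrow(sites))) else 6
  decoy_type <- rep(c("gnomad", "discovehr", "highmac"),
                    length.out = n_decoy)
  decoys <- tibble::tibble(
    site_key = paste0("d", seq_len(n_decoy)),
    gene_idx = sample.int(config$n_genes, n_decoy, replace = TRUE),
    archetype = "decoy", decoy_type = decoy_type)
  n_fill <- round(config$filler_frac * max(nrow(sites), 1))
  fillers <- tibble::tibble(
    site_key = paste0("f", seq_len(n_fill)),
    gene_idx = sample.int(config$n_genes, max(n_fill, 0), replace = TRUE),
    archetype = "filler")
  all_sites <- dplyr::bind_rows(sites, decoys |>
                                  dplyr::select(-"decoy_type"), fillers)

  # positions: consecutive offsets within each gene's window
  all_sites <- all_sites |>
    dplyr::group_by(.data$gene_idx) |>
    dplyr::mutate(offset = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::mutate(chrom = genes$chrom[.data$gene_idx],
                  pos = as.integer(genes$pos_base[.data$gene_idx] +
                                     .data$offset),
                  gene = genes$gene[.data$gene_idx])
  bases <- c("A", "C", "G", "T")
  n_s <- nrow(all_sites)
  ref_i <- sample.int(4, n_s, replace = TRUE)
  alt_i <- ((ref_i - 1 + sample.int(3, n_s, replace = TRUE)) %% 4) + 1
  all_sites$ref <- bases[ref_i]
  all_sites$alt <- bases[alt_i]

  # score profiles per archetype
  score_rows <- all_sites |>
    dplyr::group_by(.data$archetype) |>
    dplyr::group_modify(function(d, key) {
      arch <- key$archetype
      sc <- if (arch == "decoy") archetype_scores("damaging", nrow(d))
        else if (arch == "filler")
          tibble::tibble(consequence = rep("other", nrow(d)),
                         pph2 = NA_character_, sift = NA_character_,
                         mpc = NA_real_, mtr = NA_real_, ccr = NA_real_,
                         para_z = NA_real_)
        else archetype_scores(arch, nrow(d))
      dplyr::bind_cols(d, sc)
    }) |>
    dplyr::ungroup()

  # external frequencies: 0 except for the planted decoys
  score_rows$gnomad_af <- 0
  score_rows$discovehr_af <- 0
  dk <- match(decoys$site_key, score_rows$site_key)
  g_d <- dk[decoys$decoy_type == "gnomad"]
  d_d <- dk[decoys$decoy_type == "discovehr"]
  score_rows$gnomad_af[g_d] <- runif(length(g_d), 2.5e-5, 1e-3)
  score_rows$discovehr_af[d_d] <- runif(length(d_d), 1e-5, 1e-3)

  origin <- archetype_origin()
  score_rows$origin <- dplyr::case_when(
    score_rows$archetype == "decoy" ~ "decoy",
    score_rows$archetype == "filler" ~ "filler",
    TRUE ~ unname(origin[score_rows$archetype]))

  variants <- score_rows |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::select("chrom", "pos", "ref", "alt", "gene", "consequence",
                  "pph2", "sift", "mpc", "mtr", "ccr", "para_z",
                  "gnomad_af", "discovehr_af", "origin", "site_key")

  # carriers: cohort events + decoy/filler carriers
  carr <- carr_ev |>
    dplyr::transmute(site_key = .data$site_key,
                     sample_id = samples$sample_id[.data$sample_idx],
                     allele_count = 1L + rbinom(dplyr::n(), 1, 0.005))
  # decoy carriers: high-MAC decoys live in controls (present in every
  # per-phenotype analysis, so their MAC always exceeds the cap); the
  # frequency-failing decoys and the class-less fillers are spread over the
  # whole cohort so that covariate counts stay case-control exchangeable
  ctrl_ids <- samples$sample_id[samples$phenotype == "control"]
  all_ids <- samples$sample_id
  draw_carriers <- function(site_keys, n_per_site, pool) {
    if (length(site_keys) == 0)
      return(tibble::tibble(site_key = character(),
                            sample_id = character(),
                            allele_count = integer()))
    tibble::tibble(site_key = rep(site_keys, n_per_site),
                   sample_id = sample(pool, sum(n_per_site),
                                      replace = TRUE),
                   allele_count = 1L) |>
      dplyr::distinct(.data$site_key, .data$sample_id,
                      .keep_all = TRUE)
  }
  hm <- decoys$decoy_type == "highmac"
  decoy_carr <- dplyr::bind_rows(
    draw_carriers(decoys$site_key[hm],
                  sample(5:7, sum(hm), replace = TRUE), ctrl_ids),
    draw_carriers(decoys$site_key[!hm],
                  sample(1:2, sum(!hm), replace = TRUE), all_ids))
  fill_carr <- draw_carriers(fillers$site_key,
                             sample(1:2, nrow(fillers), replace = TRUE),
                             all_ids)

  carriers <- dplyr::bind_rows(carr, decoy_carr, fill_carr) |>
    dplyr::inner_join(variants |>
                        dplyr::select("site_key", "chrom", "pos", "ref",
                                      "alt"),
                      by = "site_key") |>
    dplyr::select("chrom", "pos", "ref", "alt", "sample_id",
                  "allele_count") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt,
                   .data$sample_id)

  variants$site_key <- NULL
  list(variants = variants, carriers = carriers)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>\n",
      " samples: ", nrow(x$samples), " (",
      sum(x$samples$phenotype != "control"), " cases / ",
      sum(x$samples$phenotype == "control"), " controls)\n",
      " variants:", nrow(x$variants), "  carriers:", nrow(x$carriers), "\n",
      " gene sets:", length(unique(x$gene_sets$set)),
      "  spiked cells:", sum(x$truth$log_odds != 0), "\n")
  invisible(x)
}
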