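# TSV dialect: tab-separated, UTF-8, header row, empty string = missing.

variants_schema <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
                     "pph2", "sift", "mpc", "mtr", "ccr", "para_z",
                     "gnomad_af", "discovehr_af")

#' Read / write the pipeline's tabular inputs
#'
#' Strict TSV readers and writers for the three input tables. Columns and
#' their order are fixed; the empty string marks a missing value. The
#' carrier TSV stores the sample column as `sample` on disk and
#' `sample_id` in memory.
#'
#' @param path File path.
#' @return A tibble with the table's schema.
#' @name io_tables
NULL

#' @rdname io_tables
#' @export
read_variants_tsv <- function(path) {
  v <- readr::read_tsv(
    path, na = "", progress = FALSE,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character(),
      gene = readr::col_character(), consequence = readr::col_character(),
      pph2 = readr::col_character(), sift = readr::col_character(),
      mpc = readr::col_double(), mtr = readr::col_double(),
      ccr = readr::col_double(), para_z = readr::col_double(),
      gnomad_af = readr::col_double(),
      discovehr_af = readr::col_double()))
  missing_cols <- setdiff(variants_schema, names(v))
  if (length(missing_cols) > 0)
    stop("variants TSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  v |> dplyr::mutate(chrom = normalize_chrom(.data$chrom))
}

#' @rdname io_tables
#' @param x Table to write.
#' @export
write_variants_tsv <- function(x, path) {
  readr::write_tsv(x[, variants_schema], path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_carriers_tsv <- function(path) {
  readr::read_tsv(
    path, na = "", progress = FALSE,
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_integer(),
      ref = readr::col_character(), alt = readr::col_character(),
      sample = readr::col_character(),
      allele_count = readr::col_integer())) |>
    dplyr::rename(sample_id = "sample") |>
    dplyr::mutate(chrom = normalize_chrom(.data$chrom))
}

#' @rdname io_tables
#' @export
write_carriers_tsv <- function(x, path) {
  x |>
    dplyr::select("chrom", "pos", "ref", "alt", sample = "sample_id",
                  "allele_count") |>
    readr::write_tsv(path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_samples_tsv <- function(path) {
  readr::read_tsv(path, na = "", progress = FALSE,
                  col_types = readr::cols(
                    sample_id = readr::col_character(),
                    phenotype = readr::col_character(),
                    sex = readr::col_integer(),
                    batch = readr::col_character(),
                    .default = readr::col_double()))
}

#' @rdname io_tables
#' @export
write_samples_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set catalogue
#'
#' Standard GMT: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' used as the set category. Duplicate set names are an error; duplicate
#' genes within a set are deduplicated with a warning.
#'
#' @param path GMT file path.
#' @return Long tibble with `set`, `category`, `gene`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path))
    stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0)
    stop("malformed GMT line ", short[1], ": fewer than 3 fields",
         call. = FALSE)
  names_ <- vapply(parts, `[[`, character(1), 1)
  dup <- unique(names_[duplicated(names_)])
  if (length(dup) > 0)
    stop("duplicate gene-set name(s) in GMT: ",
         paste(dup, collapse = ", "), call. = FALSE)
  purrr::map2(parts, names_, function(p, nm) {
    genes <- p[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicated gene(s) in set '", nm, "' deduplicated",
              call. = FALSE)
      genes <- unique(genes)
    }
    tibble::tibble(set = nm, category = p[2], gene = genes)
  }) |> dplyr::bind_rows()
}

#' Write a GMT gene-set catalogue
#'
#' @param gene_sets Long tibble with `set`, `category`, `gene`.
#' @param path Output path.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- gene_sets |>
    dplyr::group_by(.data$set, .data$category) |>
    dplyr::summarise(line = paste(c(.data$set[1], .data$category[1],
                                    unique(.data$gene)), collapse = "\t"),
                     .groups = "drop")
  writeLines(lines$line, path)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Emits `samples.tsv`, `variants.tsv`, `carriers.tsv`, `gene_sets.gmt`
#' and `truth.tsv` in the documented schemas (the in-memory `origin`
#' column of the variants is simulation metadata and is not written).
#' Optionally also emits a minimal multi-sample VCF 4.2.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @param vcf Also write `cohort.vcf`? Default `FALSE`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, vcf = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_samples_tsv(cohort$samples, file.path(dir, "samples.tsv"))
  write_variants_tsv(cohort$variants, file.path(dir, "variants.tsv"))
  write_carriers_tsv(cohort$carriers, file.path(dir, "carriers.tsv"))
  write_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"), na = "",
                   progress = FALSE)
  if (vcf)
    write_vcf(cohort$variants, cohort$carriers, cohort$samples,
              file.path(dir, "cohort.vcf"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing the cohort TSV/GMT files.
#' @return A cohort list (`samples`, `variants`, `carriers`, `gene_sets`,
#'   and `truth` when present).
#' @export
read_cohort <- function(dir) {
  out <- list(
    samples = read_samples_tsv(file.path(dir, "samples.tsv")),
    variants = read_variants_tsv(file.path(dir, "variants.tsv")),
    carriers = read_carriers_tsv(file.path(dir, "carriers.tsv")),
    gene_sets = read_gmt(file.path(dir, "gene_sets.gmt")))
  tf <- file.path(dir, "truth.tsv")
  if (file.exists(tf))
    out$truth <- readr::read_tsv(tf, na = "", progress = FALSE,
                                 col_types = readr::cols())
  out
}

default_info_keys <- function() {
  c(gene = "GENE", consequence = "CSQ", pph2 = "PPH2", sift = "SIFT",
    mpc = "MPC", mtr = "MTR", ccr = "CCR", para_z = "PARAZ",
    gnomad_af = "GNOMAD_AF", discovehr_af = "DISCOVEHR_AF")
}

#' Write a minimal multi-sample VCF 4.2
#'
#' One record per alternate allele with the annotation scores as INFO
#' key-value pairs (keys per [default_info_keys()]) and GT genotypes
#' (`0/1` heterozygous, `1/1` homozygous alternate).
#'
#' @param variants,carriers,samples Cohort tables.
#' @param path Output path.
#' @export
write_vcf <- function(variants, carriers, samples, path) {
  keys <- default_info_keys()
  ids <- samples$sample_id
  info <- vapply(seq_len(nrow(variants)), function(i) {
    vals <- vapply(names(keys), function(f) {
      v <- variants[[f]][i]
      if (is.na(v)) NA_character_ else as.character(v)
    }, character(1))
    ok <- !is.na(vals)
    paste(paste0(keys[ok], "=", vals[ok]), collapse = ";")
  }, character(1))
  info[!nzchar(info)] <- "."

  carr <- carriers |>
    dplyr::mutate(key = variant_key(.data$chrom, .data$pos, .data$ref,
                                    .data$alt))
  vkeys <- variant_key(variants$chrom, variants$pos, variants$ref,
                       variants$alt)
  gt <- matrix("0/0", nrow = nrow(variants), ncol = length(ids),
               dimnames = list(NULL, ids))
  ri <- match(carr$key, vkeys)
  ci <- match(carr$sample_id, ids)
  gt[cbind(ri, ci)] <- ifelse(carr$allele_count == 2, "1/1", "0/1")

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
            keys,
            ifelse(names(keys) %in% c("gene", "consequence", "pph2",
                                      "sift"), "String", "Float"),
            names(keys)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", ids), collapse = "\t"))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", info, "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a multi-sample VCF into variant and carrier tables
#'
#' Parses a VCF with GT genotypes, splitting multi-allelic records into
#' one annotation row per alternate allele (positions are taken as-is; no
#' left-normalization is attempted). Carrier allele counts are the number
#' of matching alternate alleles in the genotype. INFO keys are mapped to
#' annotation fields via `info_key_map`; a missing mapped key becomes a
#' missing score and is counted in a summary warning.
#'
#' @param path VCF path.
#' @param info_key_map Named character vector mapping annotation fields to
#'   INFO keys; see [default_info_keys()].
#' @return List with `variants` and `carriers` tibbles.
#' @export
read_vcf_cohort <- function(path, info_key_map = default_info_keys()) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  sample_ids <- colnames(gt_raw)

  numeric_fields <- c("mpc", "mtr", "ccr", "para_z", "gnomad_af",
                      "discovehr_af")
  info_vals <- lapply(names(info_key_map), function(f) {
    unname(vcfR::extract.info(vcf, element = info_key_map[[f]]))
  })
  names(info_vals) <- names(info_key_map)
  n_missing <- sum(vapply(info_vals, function(v) all(is.na(v)), logical(1)))
  if (n_missing > 0)
    warning(n_missing, " mapped INFO key(s) absent from the VCF; the ",
            "corresponding fields are missing", call. = FALSE)

  rows <- list()
  carr <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    gts <- gt_raw[i, ]
    alleles <- strsplit(ifelse(is.na(gts), ".", gts), "[/|]")
    for (k in seq_along(alts)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = normalize_chrom(fix[i, "CHROM"]),
        pos = as.integer(fix[i, "POS"]),
        ref = fix[i, "REF"], alt = alts[k],
        gene = info_vals$gene[i], consequence = info_vals$consequence[i],
        pph2 = info_vals$pph2[i], sift = info_vals$sift[i],
        mpc = suppressWarnings(as.numeric(info_vals$mpc[i])),
        mtr = suppressWarnings(as.numeric(info_vals$mtr[i])),
        ccr = suppressWarnings(as.numeric(info_vals$ccr[i])),
        para_z = suppressWarnings(as.numeric(info_vals$para_z[i])),
        gnomad_af = suppressWarnings(
          as.numeric(dplyr::coalesce(info_vals$gnomad_af[i], "0"))),
        discovehr_af = suppressWarnings(
          as.numeric(dplyr::coalesce(info_vals$discovehr_af[i], "0"))))
      ac <- vapply(alleles, function(a) sum(a == as.character(k)),
                   numeric(1))
      hit <- which(ac > 0)
      if (length(hit) > 0) {
        carr[[length(carr) + 1]] <- tibble::tibble(
          chrom = normalize_chrom(fix[i, "CHROM"]),
          pos = as.integer(fix[i, "POS"]),
          ref = fix[i, "REF"], alt = alts[k],
          sample_id = sample_ids[hit],
          allele_count = as.integer(ac[hit]))
      }
    }
  }
  list(variants = dplyr::bind_rows(rows),
       carriers = dplyr::bind_rows(carr))
}

#' Pipeline run configuration
#'
#' Bundles the file paths and analysis parameters of one end-to-end run.
#' Either the three TSV paths or a VCF (plus a samples TSV) must be
#' given.
#'
#' @param samples,variants,carriers,gmt Input paths.
#' @param vcf Optional VCF path replacing `variants` + `carriers`.
#' @param out_dir Output directory.
#' @param phenotypes Case phenotypes to analyse (default: all
#'   non-control phenotypes found in the samples table).
#' @param urv_filter A [urv_filter_config()].
#' @param rules A [class_rules()] roster.
#' @param alpha Significance level. Default 0.05.
#' @param seed Seed recorded in the manifest (the primary analysis is
#'   deterministic).
#' @return A `run_config` object.
#' @export
run_config <- function(samples, gmt, out_dir, variants = NULL,
                       carriers = NULL, vcf = NULL, phenotypes = NULL,
                       urv_filter = urv_filter_config(),
                       rules = class_rules(), alpha = 0.05, seed = 1L) {
  cfg <- structure(
    list(samples = samples, variants = variants, carriers = carriers,
         vcf = vcf, gmt = gmt, out_dir = out_dir, phenotypes = phenotypes,
         urv_filter = urv_filter, rules = rules, alpha = alpha,
         seed = as.integer(seed)),
    class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  need <- c("samples", "gmt")
  if (is.null(cfg$vcf)) need <- c(need, "variants", "carriers")
  for (f in need) {
    if (is.null(cfg[[f]]))
      abort_config(f, "is required")
    if (!file.exists(cfg[[f]]))
      abort_config(f, paste0("file does not exist: ", cfg[[f]]))
  }
  if (!is.null(cfg$vcf) && !file.exists(cfg$vcf))
    abort_config("vcf", paste0("file does not exist: ", cfg$vcf))
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    abort_config("alpha", "must lie in (0, 1)")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the [run_config()] arguments; `urv_filter` may
#' be a mapping with `mac_max`, `gnomad_af_max`, `discovehr_af_max`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  uf <- do.call(urv_filter_config, y$urv_filter %||% list())
  run_config(samples = y$samples, gmt = y$gmt, out_dir = y$out_dir,
             variants = y$variants, carriers = y$carriers, vcf = y$vcf,
             phenotypes = y$phenotypes, urv_filter = uf,
             alpha = y$alpha %||% 0.05, seed = y$seed %||% 1L)
}

#' Run the end-to-end burden pipeline
#'
#' Reads the inputs, runs the per-phenotype burden grid with joint BH
#' adjustment, and writes `results.tsv` (full grid including the
#' synonymous calibration track), `forest.tsv` (effect/CI/stars export),
#' `calibration.tsv`, and `manifest.json` (configuration echo, filter
#' thresholds, per-stage counts and seed). Reruns with an identical
#' configuration produce byte-identical outputs.
#'
#' @param config A [run_config()] or path to a YAML file.
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  message("reading inputs")
  samples <- read_samples_tsv(config$samples)
  if (!is.null(config$vcf)) {
    vc <- read_vcf_cohort(config$vcf)
    variants <- vc$variants
    carriers <- vc$carriers
  } else {
    variants <- read_variants_tsv(config$variants)
    carriers <- read_carriers_tsv(config$carriers)
  }
  gene_sets <- read_gmt(config$gmt)
  cohort <- list(samples = samples, variants = variants,
                 carriers = carriers, gene_sets = gene_sets)
  phenotypes <- config$phenotypes %||%
    setdiff(unique(samples$phenotype), "control")

  plan <- grid_plan(gene_sets, phenotypes)
  message("running grid: ", plan$n_adjusted_tests,
          " jointly adjusted tests + ", plan$n_synonymous_tests,
          " synonymous control tests")
  grid <- run_grid(cohort, phenotypes = phenotypes,
                   gene_sets = gene_sets, cfg = config$urv_filter,
                   rules = config$rules, alpha = config$alpha)

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results_tsv(grid, file.path(config$out_dir, "results.tsv"))
  grid |>
    dplyr::select("set", "class", "phenotype", "log_odds", "ci_lo",
                  "ci_hi", "stars") |>
    format_numeric_cols() |>
    readr::write_tsv(file.path(config$out_dir, "forest.tsv"), na = "",
                     progress = FALSE)
  readr::write_tsv(calibration_summary(grid, config$alpha),
                   file.path(config$out_dir, "calibration.tsv"),
                   na = "", progress = FALSE)

  manifest <- list(
    package = "urvburden",
    version = as.character(utils::packageVersion("urvburden")),
    seed = config$seed,
    alpha = config$alpha,
    urv_filter = unclass(config$urv_filter),
    class_rules = unclass(config$rules),
    phenotypes = phenotypes,
    counts = list(
      n_samples = nrow(samples),
      n_variants = nrow(variants),
      n_carrier_records = nrow(carriers),
      n_gene_sets = length(unique(gene_sets$set)),
      n_tests_adjusted = sum(grid$class != "Synonymous"),
      n_tests_synonymous = sum(grid$class == "Synonymous")))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message("wrote ", config$out_dir)
  invisible(config$out_dir)
}

format_numeric_cols <- function(x) {
  dplyr::mutate(x, dplyr::across(dplyr::where(is.numeric),
                                 function(v) signif(v, 6)))
}

#' Write a burden results grid as TSV
#'
#' Floating-point values are written at 6 significant digits.
#'
#' @param grid A `burden_grid`.
#' @param path Output path.
#' @export
write_results_tsv <- function(grid, path) {
  grid |>
    format_numeric_cols() |>
    readr::write_tsv(path, na = "", progress = FALSE)
  invisible(path)
}
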