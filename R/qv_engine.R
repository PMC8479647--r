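#' Ultra-rare-variant filter configuration
#'
#' Thresholds that qualify a variant as ultra-rare: internal minor allele
#' count (MAC) within the analysis cohort, absence from DiscovEHR and a
#' near-absence from gnomAD.
#'
#' @param mac_max Maximum internal MAC (alternate-allele copies summed over
#'   the cases and controls of the current analysis). Default 3.
#' @param gnomad_af_max Maximum gnomAD allele frequency. Default 2e-5.
#' @param discovehr_af_max Maximum DiscovEHR allele frequency. Default 0
#'   (complete absence).
#' @return A `urv_filter_config` object.
#' @export
urv_filter_config <- function(mac_max = 3, gnomad_af_max = 2e-5,
                              discovehr_af_max = 0) {
  if (!is.numeric(mac_max) || length(mac_max) != 1 || mac_max < 1)
    abort_config("mac_max", "must be a single integer >= 1")
  for (f in c("gnomad_af_max", "discovehr_af_max")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      abort_config(f, "must be a frequency in [0, 1]")
  }
  structure(list(mac_max = as.integer(mac_max),
                 gnomad_af_max = gnomad_af_max,
                 discovehr_af_max = discovehr_af_max),
            class = "urv_filter_config")
}

#' Internal minor allele counts for one analysis
#'
#' MACs are computed independently within each case-control analysis (the
#' cases of one phenotype plus all controls), so the same variant can have
#' different MACs — and hence different ultra-rare status — across the
#' per-phenotype analyses.
#'
#' @param carriers Carrier table (`chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`, `allele_count`).
#' @param analysis_samples Character vector of sample ids forming the
#'   current analysis cohort.
#' @param variants Optional variant table; when supplied, variants with no
#'   in-cohort carrier are returned with MAC 0.
#' @param known_samples Optional vector of all valid sample ids; carriers
#'   referencing a sample outside it raise a validation error.
#' @return A tibble with `chrom`, `pos`, `ref`, `alt`, `mac`.
#' @export
compute_internal_mac <- function(carriers, analysis_samples,
                                 variants = NULL, known_samples = NULL) {
  if (!is.null(known_samples)) {
    bad <- setdiff(unique(carriers$sample_id), known_samples)
    if (length(bad) > 0)
      stop("carrier table references unknown sample(s): ",
           paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  macs <- carriers |>
    dplyr::filter(.data$sample_id %in% analysis_samples) |>
    dplyr::group_by(.data$chrom, .data$pos, .data$ref, .data$alt) |>
    dplyr::summarise(mac = sum(.data$allele_count), .groups = "drop")
  if (!is.null(variants)) {
    macs <- variants |>
      dplyr::distinct(.data$chrom, .data$pos, .data$ref, .data$alt) |>
      dplyr::left_join(macs, by = c("chrom", "pos", "ref", "alt")) |>
      dplyr::mutate(mac = dplyr::coalesce(.data$mac, 0L))
  }
  macs |> dplyr::mutate(mac = as.integer(.data$mac))
}

#' Ultra-rare-variant filter
#'
#' A variant qualifies as ultra-rare when its internal MAC does not exceed
#' `mac_max`, it is absent from DiscovEHR (frequency at or below
#' `discovehr_af_max`) and its gnomAD frequency is at or below
#' `gnomad_af_max`. Missing external frequencies are treated as 0: absence
#' from the reference database is what the filter is probing.
#'
#' @param variants Variant annotation table.
#' @param mac Integer vector of internal MACs aligned with `variants`.
#' @param cfg A [urv_filter_config()].
#' @return Logical vector, `TRUE` for passing variants.
#' @export
filter_urv <- function(variants, mac, cfg = urv_filter_config()) {
  stopifnot(length(mac) == nrow(variants))
  gaf <- dplyr::coalesce(variants$gnomad_af, 0)
  daf <- dplyr::coalesce(variants$discovehr_af, 0)
  mac <= cfg$mac_max & gaf <= cfg$gnomad_af_max & daf <= cfg$discovehr_af_max
}

#' Assign functional classes to variants
#'
#' Evaluates every class predicate on every variant and returns the
#' class memberships in long form. Classes overlap by design (the nesting
#' MPC 2 within MPC 1, MTR De Novo within MTR ClinVar, CCR 80 within both,
#' and the paralog tiers are consequences of the predicates). Variants with
#' an unrecognized consequence fall into no class and are reported via a
#' message.
#'
#' @param variants Variant annotation table.
#' @param rules A [class_rules()] roster.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `gene`, `class` — one
#'   row per (variant, class) membership.
#' @export
assign_classes <- function(variants, rules = class_rules()) {
  unknown <- !is.na(variants$consequence) &
    !(variants$consequence %in% known_consequences())
  if (any(unknown)) {
    message(sum(unknown), " variant(s) with unrecognized consequence ",
            "assigned to no class")
  }
  m <- class_membership(variants, rules)
  idx <- which(m, arr.ind = TRUE)
  tibble::tibble(
    chrom = variants$chrom[idx[, 1]],
    pos = variants$pos[idx[, 1]],
    ref = variants$ref[idx[, 1]],
    alt = variants$alt[idx[, 1]],
    gene = variants$gene[idx[, 1]],
    class = colnames(m)[idx[, 2]]
  ) |>
    dplyr::arrange(.data$chrom, .data$pos, .data$ref, .data$alt, .data$class)
}

# Core QV construction for an arbitrary case/control split.
# Returns the per-(sample, gene, class) indicator table plus the exome-wide
# URV and singleton covariate counts, with internal MACs computed over
# case_ids + control_ids only.
build_qv_core <- function(variants, carriers, case_ids, control_ids,
                          cfg = urv_filter_config(), rules = class_rules(),
                          class_map = NULL, analysis = "analysis",
                          known_samples = NULL) {
  if (length(case_ids) == 0 || length(control_ids) == 0)
    stop("analysis requires non-empty case and control strata",
         call. = FALSE)
  ids <- c(case_ids, control_ids)
  macs <- compute_internal_mac(carriers, ids, variants = variants,
                               known_samples = known_samples)
  v <- variants |>
    dplyr::left_join(macs, by = c("chrom", "pos", "ref", "alt"))
  pass <- filter_urv(v, v$mac, cfg)
  urv <- v[pass, , drop = FALSE]

  if (is.null(class_map)) class_map <- assign_classes(variants, rules)
  urv_keys <- variant_key(urv$chrom, urv$pos, urv$ref, urv$alt)
  cls <- class_map[variant_key(class_map$chrom, class_map$pos,
                               class_map$ref, class_map$alt) %in% urv_keys,
                   , drop = FALSE]

  carr <- carriers |>
    dplyr::filter(.data$sample_id %in% ids) |>
    dplyr::semi_join(urv, by = c("chrom", "pos", "ref", "alt"))

  qv <- carr |>
    dplyr::inner_join(cls, by = c("chrom", "pos", "ref", "alt"),
                      relationship = "many-to-many") |>
    dplyr::distinct(.data$sample_id, .data$gene, .data$class)

  carr_mac <- carr |>
    dplyr::left_join(macs, by = c("chrom", "pos", "ref", "alt"))
  cov <- carr_mac |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(urv_count = dplyr::n(),
                     singleton_count = sum(.data$mac == 1L),
                     .groups = "drop")
  covariates <- tibble::tibble(sample_id = ids) |>
    dplyr::left_join(cov, by = "sample_id") |>
    dplyr::mutate(urv_count = dplyr::coalesce(.data$urv_count, 0L),
                  singleton_count = dplyr::coalesce(.data$singleton_count,
                                                    0L))

  structure(
    list(analysis = analysis,
         sample_ids = ids,
         y = as.integer(ids %in% case_ids),
         qv = qv,
         covariates = covariates,
         n_urv = nrow(urv),
         n_variants = nrow(variants)),
    class = "qv_table")
}

#' Build the qualifying-variant table for one phenotype analysis
#'
#' Selects the cases of `phenotype` plus all controls, computes internal
#' MACs within that cohort, applies the ultra-rare filters, assigns
#' functional classes and collapses to a binary indicator per
#' (sample, gene, class): 1 when the sample carries at least one qualifying
#' variant of that class in that gene. Also returns the per-sample
#' exome-wide URV count and singleton (MAC = 1) count used as model
#' covariates.
#'
#' @param variants Variant annotation table.
#' @param carriers Carrier table.
#' @param samples Sample metadata table with `sample_id` and `phenotype`
#'   (`"control"` marks controls).
#' @param phenotype Case phenotype label, e.g. `"GGE"`.
#' @param cfg A [urv_filter_config()].
#' @param rules A [class_rules()] roster.
#' @param class_map Optional precomputed [assign_classes()] result (the
#'   class assignment does not depend on the analysis cohort, so it can be
#'   shared across analyses).
#' @return A `qv_table` object: the indicator tibble (`qv`), covariate
#'   counts, the analysis cohort and its case indicator.
#' @export
build_qv_table <- function(variants, carriers, samples, phenotype,
                           cfg = urv_filter_config(), rules = class_rules(),
                           class_map = NULL) {
  case_ids <- samples$sample_id[samples$phenotype == phenotype]
  control_ids <- samples$sample_id[samples$phenotype == "control"]
  if (length(case_ids) == 0)
    stop("no samples with phenotype '", phenotype, "'", call. = FALSE)
  build_qv_core(variants, carriers, case_ids, control_ids, cfg, rules,
                class_map = class_map, analysis = phenotype,
                known_samples = samples$sample_id)
}

#' @export
print.qv_table <- function(x, ...) {
  cat("<qv_table> analysis:", x$analysis, "\n",
      " samples:", length(x$sample_ids),
      "(", sum(x$y), "cases /", sum(1 - x$y), "controls )\n",
      " qualifying URVs:", x$n_urv, "of", x$n_variants, "variants\n",
      " (sample, gene, class) indicators:", nrow(x$qv), "\n")
  invisible(x)
}
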