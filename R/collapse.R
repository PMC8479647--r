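resolve_set_genes <- function(gene_sets, set) {
  if (is.character(set) && length(set) == 1 && !is.null(gene_sets) &&
      set %in% gene_sets$set) {
    gene_sets$gene[gene_sets$set == set]
  } else if (is.character(set)) {
    set
  } else {
    stop("gene set must be a set name or a character vector of genes",
         call. = FALSE)
  }
}

#' Per-sample gene-set burden score
#'
#' The burden score of a sample is the number of genes in the target
#' gene-set in which the sample carries at least one qualifying variant of
#' the given class (equal weights, one direction of effect). Gene symbols
#' are matched case-insensitively; set members absent from the data
#' contribute 0.
#'
#' @param qv A `qv_table` from [build_qv_table()].
#' @param genes Character vector of gene symbols forming the set.
#' @param class Class name, one of [qv_class_names()].
#' @return Tibble with `sample_id` and integer `score` for every sample of
#'   the analysis cohort (zeros included).
#' @export
burden_score <- function(qv, genes, class) {
  stopifnot(inherits(qv, "qv_table"))
  genes <- toupper(unique(genes))
  hits <- qv$qv |>
    dplyr::filter(.data$class == !!class,
                  toupper(.data$gene) %in% genes) |>
    dplyr::distinct(.data$sample_id, .data$gene) |>
    dplyr::count(.data$sample_id, name = "score")
  tibble::tibble(sample_id = qv$sample_ids) |>
    dplyr::left_join(hits, by = "sample_id") |>
    dplyr::mutate(score = as.integer(dplyr::coalesce(.data$score, 0L)))
}

#' Carrier summary for one gene-set and class
#'
#' Descriptive counts backing a burden result: genes of the set with at
#' least one observed qualifying variant, case/control carrier counts
#' (samples with score >= 1), total QV-gene hits by group, and carrier
#' fractions.
#'
#' @inheritParams burden_score
#' @return One-row tibble of summary counts.
#' @export
carrier_summary <- function(qv, genes, class) {
  stopifnot(inherits(qv, "qv_table"))
  scores <- burden_score(qv, genes, class)$score
  genes_u <- toupper(unique(genes))
  n_genes_with_qv <- qv$qv |>
    dplyr::filter(.data$class == !!class,
                  toupper(.data$gene) %in% genes_u) |>
    dplyr::distinct(.data$gene) |>
    nrow()
  scores_summary(scores, qv$y, n_genes_with_qv)
}

scores_summary <- function(scores, y, n_genes_with_qv) {
  tibble::tibble(
    n_genes_with_qv = n_genes_with_qv,
    n_case_carriers = sum(scores >= 1 & y == 1),
    n_control_carriers = sum(scores >= 1 & y == 0),
    case_hits = sum(scores[y == 1]),
    control_hits = sum(scores[y == 0]),
    frac_case_carriers = mean(scores[y == 1] >= 1),
    frac_control_carriers = mean(scores[y == 0] >= 1)
  )
}
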