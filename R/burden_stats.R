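#' Maximum-likelihood logistic regression fit
#'
#' Thin wrapper around the iteratively-reweighted-least-squares engine
#' (`stats::glm.fit`) returning exactly what the burden test needs:
#' coefficients, the inverse observed information, the binomial
#' log-likelihood and a convergence flag. Convergence is declared when the
#' deviance change falls below 1e-8 within 100 iterations; fits with any
#' coefficient beyond +/-15 in absolute value are flagged unconverged
#' (quasi-separation guard). Constant non-intercept columns are dropped
#' with a warning; a rank-deficient design after pruning is an error that
#' names the collinear columns.
#'
#' @param y Binary response vector (0/1).
#' @param X Design matrix including an intercept column.
#' @return List with `coefficients`, `vcov`, `loglik`, `converged`,
#'   `kept` (names of retained columns).
#' @export
fit_logistic <- function(y, X) {
  X <- as.matrix(X)
  stopifnot(length(y) == nrow(X))
  if (length(unique(y)) < 2)
    stop("outcome has no variation: cannot fit a logistic model",
         call. = FALSE)
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))

  keep <- apply(X, 2, function(col) length(unique(col)) > 1)
  keep[1] <- TRUE
  if (!all(keep)) {
    warning("dropping constant covariate column(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 100)))
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  vcov <- tryCatch(solve(crossprod(X * sqrt(w))),
                   error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  eps <- .Machine$double.eps
  loglik <- sum(y * log(pmax(mu, eps)) + (1 - y) * log(pmax(1 - mu, eps)))
  converged <- isTRUE(fit$converged) &&
    all(is.finite(fit$coefficients)) &&
    all(abs(fit$coefficients) <= 15)
  list(coefficients = setNames(fit$coefficients, colnames(X)),
       vcov = vcov, loglik = loglik, converged = converged,
       kept = colnames(X))
}

z_975 <- 1.959964

#' Covariate-adjusted burden likelihood-ratio test
#'
#' Regresses case-control status on the gene-set burden score plus
#' covariates and compares against the covariates-only null model with a
#' 1-df chi-square likelihood-ratio test. The reported effect is the
#' log-odds per additional burdened gene, with a Wald 95% confidence
#' interval; the p value comes from the LRT. A burden score that is
#' constant across samples yields a degenerate result (log-odds 0,
#' LRT statistic 0, p = 1) rather than an error, so sparse grid cells stay
#' in the multiple-testing accounting.
#'
#' @param y Binary phenotype vector (1 = case).
#' @param scores Integer burden scores aligned with `y`.
#' @param covariates Optional data frame / matrix of covariates (sex,
#'   principal components, exome-wide URV and singleton counts).
#' @param null_fit Optional precomputed [fit_logistic()] of the null model
#'   (shared across the cells of one analysis for speed); must have been
#'   fit on the identical covariate design.
#' @return One-row tibble: `log_odds`, `se`, `ci_lo`, `ci_hi`, `lrt_stat`,
#'   `p`, `converged`, `degenerate`.
#' @export
lrt_burden_test <- function(y, scores, covariates = NULL, null_fit = NULL) {
  stopifnot(length(scores) == length(y))
  if (length(unique(scores)) < 2) {
    return(tibble::tibble(log_odds = 0, se = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_, lrt_stat = 0, p = 1,
                          converged = TRUE, degenerate = TRUE))
  }
  X0 <- null_design(y, covariates)
  if (is.null(null_fit)) null_fit <- fit_logistic(y, X0)
  X1 <- cbind(X0[, null_fit$kept, drop = FALSE], burden = scores)
  full <- fit_logistic(y, X1)
  b <- full$coefficients["burden"]
  se <- sqrt(full$vcov["burden", "burden"])
  lrt <- max(0, 2 * (full$loglik - null_fit$loglik))
  tibble::tibble(
    log_odds = unname(b), se = unname(se),
    ci_lo = unname(b - z_975 * se), ci_hi = unname(b + z_975 * se),
    lrt_stat = lrt, p = pchisq(lrt, df = 1, lower.tail = FALSE),
    converged = full$converged && null_fit$converged,
    degenerate = FALSE)
}

# intercept + covariates, constant columns pruned with a warning
null_design <- function(y, covariates) {
  X0 <- matrix(1, nrow = length(y), ncol = 1,
               dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cm <- as.matrix(covariates)
    storage.mode(cm) <- "double"
    X0 <- cbind(X0, cm)
  }
  X0
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment over the full grid of burden tests, returned in
#' input order. Input p values outside `[0, 1]` raise a validation error.
#'
#' @param pvalues Numeric vector of raw p values.
#' @return Adjusted p values.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Significance stars
#'
#' Star annotation for (FDR-adjusted) p values with strict thresholds:
#' `"****"` below 0.00005, `"***"` below 0.0005, `"**"` below 0.005,
#' `"*"` below 0.05, otherwise the empty string. Boundary values receive
#' the weaker annotation.
#'
#' @param p_adj Numeric vector of p values.
#' @return Character vector of star strings.
#' @export
star_annotation <- function(p_adj) {
  stopifnot(all(is.na(p_adj) | (p_adj >= 0 & p_adj <= 1)))
  dplyr::case_when(
    is.na(p_adj) ~ NA_character_,
    p_adj < 5e-5 ~ "****",
    p_adj < 5e-4 ~ "***",
    p_adj < 5e-3 ~ "**",
    p_adj < 5e-2 ~ "*",
    TRUE ~ ""
  )
}

#' Size of the burden test grid
#'
#' Arithmetic of the analysis grid: the jointly FDR-adjusted track covers
#' every (gene-set, phenotype, non-synonymous class) cell; the synonymous
#' class runs as an unadjusted calibration track; gene-sets of category
#' `"control"` (non-neuronal sets) form an additional diagnostic sub-count
#' of the adjusted track.
#'
#' @param gene_sets Gene-set catalogue (tibble `set`, `category`, `gene`).
#' @param phenotypes Character vector of case phenotypes.
#' @param classes Class roster (defaults to the shipped thirteen).
#' @return One-row tibble: `n_sets`, `n_phenotypes`, `n_classes`,
#'   `n_adjusted_tests`, `n_synonymous_tests`, `n_control_set_tests`.
#' @export
grid_plan <- function(gene_sets, phenotypes, classes = qv_class_names()) {
  sets <- unique(gene_sets$set)
  n_ctrl_sets <- gene_sets |>
    dplyr::distinct(.data$set, .data$category) |>
    dplyr::filter(.data$category == "control") |>
    nrow()
  nonsyn <- setdiff(classes, "Synonymous")
  tibble::tibble(
    n_sets = length(sets),
    n_phenotypes = length(phenotypes),
    n_classes = length(classes),
    n_adjusted_tests = length(sets) * length(phenotypes) * length(nonsyn),
    n_synonymous_tests = if ("Synonymous" %in% classes)
      length(sets) * length(phenotypes) else 0L,
    n_control_set_tests = n_ctrl_sets * length(phenotypes) * length(nonsyn)
  )
}

# covariate matrix for one analysis: sex, PCs, exome-wide counts
analysis_covariates <- function(samples, qv) {
  pc_cols <- grep("^PC[0-9]+$", names(samples), value = TRUE)
  samples |>
    dplyr::filter(.data$sample_id %in% qv$sample_ids) |>
    dplyr::select(dplyr::all_of(c("sample_id", "sex", pc_cols))) |>
    dplyr::left_join(qv$covariates, by = "sample_id") |>
    dplyr::slice(match(qv$sample_ids, .data$sample_id)) |>
    dplyr::select(-"sample_id")
}

# run every (set, class) cell of one prepared analysis; no adjustment here
run_grid_core <- function(qv, samples, gene_sets, classes, label) {
  covars <- analysis_covariates(samples, qv)
  X0 <- null_design(qv$y, covars)
  null_fit <- fit_logistic(qv$y, X0)
  n <- length(qv$sample_ids)
  y <- qv$y

  set_map <- gene_sets |>
    dplyr::mutate(gene_u = toupper(.data$gene)) |>
    dplyr::distinct(.data$set, .data$category, .data$gene_u)
  set_info <- set_map |>
    dplyr::count(.data$set, .data$category, name = "n_genes_set")

  # all per-sample burden scores of the whole grid in one join
  hits <- qv$qv |>
    dplyr::filter(.data$class %in% classes) |>
    dplyr::mutate(gene_u = toupper(.data$gene)) |>
    dplyr::inner_join(set_map |> dplyr::select("set", "gene_u"),
                      by = "gene_u", relationship = "many-to-many") |>
    dplyr::distinct(.data$set, .data$class, .data$sample_id, .data$gene_u)
  counts <- hits |>
    dplyr::count(.data$set, .data$class, .data$sample_id, name = "score")
  genes_hit <- hits |>
    dplyr::distinct(.data$set, .data$class, .data$gene_u) |>
    dplyr::count(.data$set, .data$class, name = "n_genes_with_qv")

  cell_key <- function(s, cl) paste(s, cl, sep = "\r")
  count_rows <- split(seq_len(nrow(counts)),
                      cell_key(counts$set, counts$class))

  cells <- tidyr::expand_grid(set = set_info$set, class = classes) |>
    dplyr::left_join(set_info, by = "set") |>
    dplyr::left_join(genes_hit, by = c("set", "class")) |>
    dplyr::mutate(n_genes_with_qv = dplyr::coalesce(.data$n_genes_with_qv,
                                                    0L))

  rows <- purrr::pmap(cells, function(set, class, category, n_genes_set,
                                      n_genes_with_qv) {
    scores <- integer(n)
    idx <- count_rows[[cell_key(set, class)]]
    if (!is.null(idx))
      scores[match(counts$sample_id[idx], qv$sample_ids)] <-
        counts$score[idx]
    res <- lrt_burden_test(y, scores, covars, null_fit = null_fit)
    dplyr::bind_cols(
      tibble::tibble(phenotype = label, set = set, category = category,
                     class = class, n_genes_set = n_genes_set),
      scores_summary(scores, y, n_genes_with_qv), res)
  })
  dplyr::bind_rows(rows)
}

finalize_grid <- function(results, alpha = 0.05) {
  nonsyn <- results$class != "Synonymous"
  results$p_fdr <- NA_real_
  results$p_fdr[nonsyn] <- bh_adjust(results$p[nonsyn])
  results$stars <- ifelse(nonsyn, star_annotation(results$p_fdr),
                          star_annotation(results$p))
  structure(results, class = c("burden_grid", class(results)),
            alpha = alpha)
}

#' Run the full burden test grid
#'
#' Executes one case-control burden analysis per phenotype (internal MACs
#' recomputed within each analysis), tests every (gene-set, class) cell
#' with the covariate-adjusted logistic LRT and applies a joint
#' Benjamini-Hochberg adjustment across all non-synonymous cells of the
#' grid. Synonymous cells are computed as the calibration track but
#' excluded from the adjustment (their `p_fdr` is `NA` and their stars are
#' based on the raw p value). Degenerate cells (constant burden) are kept
#' in the grid and count toward the number of adjusted tests.
#'
#' @param cohort A `synthetic_cohort` (or any list with `samples`,
#'   `variants`, `carriers`, `gene_sets` tibbles).
#' @param phenotypes Case phenotypes to analyse; defaults to every
#'   non-control phenotype present.
#' @param gene_sets Gene-set catalogue; defaults to `cohort$gene_sets`.
#' @param classes Class roster; defaults to the shipped thirteen.
#' @param cfg A [urv_filter_config()].
#' @param rules A [class_rules()] roster.
#' @param alpha Significance level recorded on the result. Default 0.05.
#' @return A `burden_grid` tibble, one row per (phenotype, set, class)
#'   with effect estimates, LRT p, FDR-adjusted p, stars, carrier
#'   summaries and diagnostic flags.
#' @export
run_grid <- function(cohort, phenotypes = NULL, gene_sets = NULL,
                     classes = qv_class_names(rules),
                     cfg = urv_filter_config(), rules = class_rules(),
                     alpha = 0.05) {
  samples <- cohort$samples
  gene_sets <- gene_sets %||% cohort$gene_sets
  phenotypes <- phenotypes %||%
    setdiff(unique(samples$phenotype), "control")
  class_map <- assign_classes(cohort$variants, rules)
  results <- purrr::map(phenotypes, function(ph) {
    qv <- build_qv_table(cohort$variants, cohort$carriers, samples, ph,
                         cfg, rules, class_map = class_map)
    run_grid_core(qv, samples, gene_sets, classes, label = ph)
  }) |>
    dplyr::bind_rows()
  finalize_grid(results, alpha = alpha)
}

#' Calibration summary of a burden grid
#'
#' Summarises the negative-control tracks of a results grid: the
#' synonymous class (unadjusted p values, by construction excluded from
#' FDR), the benign-missense class, and the non-neuronal control gene-sets
#' (FDR-adjusted p values). Percentages are reported to one decimal.
#'
#' @param grid A `burden_grid`.
#' @param alpha Nominal significance level. Default 0.05.
#' @return Tibble with `track`, `n_tests`, `n_significant`, `percent`.
#' @export
calibration_summary <- function(grid, alpha = 0.05) {
  syn <- grid |> dplyr::filter(.data$class == "Synonymous")
  ben <- grid |> dplyr::filter(.data$class == "Benign missense")
  ctl <- grid |> dplyr::filter(.data$category == "control",
                               .data$class != "Synonymous")
  row <- function(track, n, k) {
    tibble::tibble(track = track, n_tests = n, n_significant = k,
                   percent = round(100 * k / n, 1))
  }
  dplyr::bind_rows(
    row("synonymous (raw p)", nrow(syn), sum(syn$p < alpha)),
    row("benign missense (raw p)", nrow(ben), sum(ben$p < alpha)),
    row("control gene-sets (FDR p)", nrow(ctl),
        sum(ctl$p_fdr < alpha, na.rm = TRUE))
  )
}
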