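#' Tidy a burden results grid
#'
#' A `burden_grid` already is a tibble; `tidy()` returns the inferential
#' columns in a compact, broom-like layout.
#'
#' @param x A `burden_grid`.
#' @param ... Unused.
#' @return A tibble with one row per test.
#' @method tidy burden_grid
#' @export
tidy.burden_grid <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    dplyr::select("phenotype", "set", "class",
                  estimate = "log_odds", std.error = "se",
                  conf.low = "ci_lo", conf.high = "ci_hi",
                  statistic = "lrt_stat", p.value = "p",
                  p.adjusted = "p_fdr", "stars", "converged", "degenerate")
}

#' Glance at a burden results grid
#'
#' @param x A `burden_grid`.
#' @param ... Unused.
#' @return One-row tibble with the grid dimensions, the number of
#'   FDR-significant cells and the calibration-track rejection rates.
#' @method glance burden_grid
#' @export
glance.burden_grid <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.05
  nonsyn <- x$class != "Synonymous"
  syn <- x[!nonsyn, , drop = FALSE]
  tibble::tibble(
    n_tests_adjusted = sum(nonsyn),
    n_tests_synonymous = sum(!nonsyn),
    n_significant_fdr = sum(x$p_fdr[nonsyn] < alpha, na.rm = TRUE),
    n_degenerate = sum(x$degenerate),
    synonymous_pct_raw_sig = if (nrow(syn) > 0)
      round(100 * mean(syn$p < alpha), 1) else NA_real_,
    alpha = alpha)
}

#' @method tidy permutation_summary
#' @export
tidy.permutation_summary <- function(x, ...) {
  tibble::as_tibble(x$draws)
}

#' @method glance permutation_summary
#' @export
glance.permutation_summary <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm, mean_log_odds = x$mean_log_odds,
                 mean_or = x$mean_or,
                 mean_odds_ratio = x$mean_odds_ratio,
                 centile_2_5 = x$centile_2_5,
                 centile_97_5 = x$centile_97_5, mean_p = x$mean_p)
}

#' Forest plot of a burden results grid
#'
#' Log-odds with Wald 95% confidence intervals per gene-set, faceted by
#' variant class, coloured by phenotype, stars appended to significant
#' sets.
#'
#' @param object A `burden_grid`.
#' @param classes Classes to show (default: all non-synonymous classes in
#'   the grid).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot burden_grid
#' @export
autoplot.burden_grid <- function(object,
                                 classes = NULL, ...) {
  classes <- classes %||% setdiff(unique(object$class), "Synonymous")
  d <- object |>
    tibble::as_tibble() |>
    dplyr::filter(.data$class %in% classes, !.data$degenerate) |>
    dplyr::mutate(label = paste0(.data$set, " ", .data$stars))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_odds, y = .data$set,
                                  colour = .data$phenotype)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo,
                                          xmax = .data$ci_hi),
                             position = ggplot2::position_dodge(0.5),
                             size = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$class)) +
    ggplot2::labs(x = "log-odds (burden per gene with QV)", y = NULL,
                  colour = "phenotype") +
    ggplot2::theme_bw()
}

#' Permutation distribution plot
#'
#' Histogram of per-permutation log-odds with the mean and 2.5/97.5
#' centiles marked.
#'
#' @param object A `permutation_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot permutation_summary
#' @export
autoplot.permutation_summary <- function(object, ...) {
  d <- tibble::as_tibble(object$draws)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_odds)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70",
                            colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$mean_log_odds,
                        colour = "firebrick") +
    ggplot2::geom_vline(xintercept = c(object$centile_2_5,
                                       object$centile_97_5),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "per-permutation log-odds", y = "permutations") +
    ggplot2::theme_bw()
}
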