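# ggplot2 views of the main result types.

#' Plot a sliding-window Ka/Ks profile
#'
#' Ka/Ks ratio against window midpoint (codon coordinate), with
#' low-support windows hollow and an optional region boundary line.
#' Undefined ratios are dropped from the line; `cap` (plotting only)
#' truncates extreme ratios.
#'
#' @param object A `kaks_profile` from [sliding_window_kaks()].
#' @param boundary_codon Optional vertical boundary line.
#' @param cap Optional upper cap applied to plotted ratios only.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot kaks_profile
#' @export
autoplot.kaks_profile <- function(object, boundary_codon = NULL, cap = NULL,
                                  ...) {
  df <- dplyr::filter(object, !is.na(.data$ratio))
  if (!is.null(cap)) df$ratio <- pmin(df$ratio, cap)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid_codon, y = .data$ratio)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$low_support)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::labs(x = "Codon (window midpoint)", y = "Ka/Ks") +
    ggplot2::theme_minimal()
  if (!is.null(boundary_codon))
    p <- p + ggplot2::geom_vline(xintercept = boundary_codon,
                                 linetype = "dashed", colour = "red3")
  p
}

#' Plot a branch-site scan
#'
#' Bonferroni-corrected p-values per tested branch on a -log10 scale, with
#' the significance level marked.
#'
#' @param object A `branch_site_scan` from [scan_all_branches()].
#' @param alpha Significance level to mark.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot branch_site_scan
#' @export
autoplot.branch_site_scan <- function(object, alpha = 0.05, ...) {
  df <- dplyr::filter(object, !is.na(.data$p_bonferroni))
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$branch, -.data$p_bonferroni),
    y = -log10(pmax(.data$p_bonferroni, 1e-16)))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "red3") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "Branch", y = expression(-log[10]~p[Bonferroni])) +
    ggplot2::theme_minimal()
}

#' Plot per-site posterior probabilities of positive selection
#'
#' @param fit A `branch_site_fit` (alternative model).
#' @param method Posterior estimator, see [site_posteriors()].
#' @return A ggplot with the 0.8 and 0.9 thresholds marked.
#' @export
plot_site_posteriors <- function(fit, method = "NEB") {
  pp <- site_posteriors(fit, method = method)
  ggplot2::ggplot(pp, ggplot2::aes(x = .data$site, y = .data$pp_positive)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$site, yend = 0),
                          colour = "grey55") +
    ggplot2::geom_hline(yintercept = c(0.8, 0.9), linetype = "dashed",
                        colour = c("orange", "red3")) +
    ggplot2::labs(x = "Codon site",
                  y = "Posterior P(positive selection)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
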