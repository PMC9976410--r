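# ggplot2 conveniences for the main result types.

#' Plot a conservation profile
#'
#' Position-wise mean upstream conservation per divergence group with the
#' loess smoother and its 95% band.
#'
#' @param object A `crossmac_profile` from [conservation_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossmac_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position,
                                       colour = .data$group,
                                       fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$smooth)) +
    ggplot2::labs(x = "position relative to TSS (bp)",
                  y = "mean conservation score",
                  colour = "divergence", fill = "divergence") +
    ggplot2::theme_minimal()
}

#' Plot a cumulative DEG-coverage curve
#'
#' @param object A `crossmac_coverage` from [cumulative_deg_coverage()].
#' @param ... Unused.
#' @return A ggplot object with the 80% coverage level marked.
#' @export
autoplot.crossmac_coverage <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$k, y = .data$coverage)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = "dashed") +
    ggplot2::labs(x = "top k TFs by selectivity",
                  y = "fraction of DEGs covered") +
    ggplot2::theme_minimal()
}

#' DM versus mean expression scatter plot
#'
#' @param dm_records Output of [dm_statistic()].
#' @param divergence Optional divergence tibble (`gene`, `group`) to colour
#'   points by group.
#' @return A ggplot object.
#' @export
plot_dm <- function(dm_records, divergence = NULL) {
  d <- dm_records
  if (!is.null(divergence)) {
    d <- dplyr::inner_join(d, divergence[, c("gene", "group")], by = "gene")
    p <- ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$mean_expression),
                                         y = .data$dm, colour = .data$group))
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$mean_expression),
                                         y = .data$dm))
  }
  p + ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "log10 mean expression", y = "DM") +
    ggplot2::theme_minimal()
}

#' Volcano-style DE plot
#'
#' @param de DE tibble from [find_markers()].
#' @param fdr_alpha Significance threshold on the adjusted p-value.
#' @return A ggplot object.
#' @export
plot_de <- function(de, fdr_alpha = 0.05) {
  d <- dplyr::mutate(de, significant = .data$p_adjusted < fdr_alpha)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log_fc,
                                  y = -log10(.data$p_adjusted),
                                  colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "log fold change (resident vs infiltrated)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Divergence distribution by group
#'
#' @param records Divergence tibble (`gene`, `divergence`, `group`).
#' @return A ggplot object.
#' @export
plot_divergence <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(x = .data$group, y = .data$divergence,
                                        fill = .data$group)) +
    ggplot2::geom_boxplot(alpha = 0.7) +
    ggplot2::labs(x = "divergence group", y = "divergence (log scale)") +
    ggplot2::theme_minimal()
}
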