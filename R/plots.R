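# ggplot2 views of the main result types. Each returns a ggplot object
# the caller can theme further.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a principal-coordinates ordination
#'
#' @param object A `tp_pcoa` object.
#' @param metadata Optional metadata tibble with `sample_id` and `group`
#'   for colouring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tp_pcoa <- function(object, metadata = NULL, ...) {
  pts <- object$points
  lab <- function(i) sprintf("Axis %d (%.1f%%)", i, 100 * object$explained[i])
  if (!is.null(metadata)) {
    pts <- dplyr::left_join(pts, metadata, by = "sample_id")
    p <- ggplot2::ggplot(pts, ggplot2::aes(.data$Axis1, .data$Axis2,
                                           colour = .data$group))
  } else {
    p <- ggplot2::ggplot(pts, ggplot2::aes(.data$Axis1, .data$Axis2))
  }
  p + ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$sample_id),
                       vjust = -0.8, show.legend = FALSE, size = 3) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' Plot rarefaction curves
#'
#' @param rarefaction Output of [rarefy_observed_species()].
#' @return A ggplot object (one curve per sample).
#' @export
plot_rarefaction <- function(rarefaction) {
  ggplot2::ggplot(dplyr::filter(rarefaction, !is.na(.data$observed_species)),
                  ggplot2::aes(.data$depth, .data$observed_species,
                               colour = .data$sample_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Rarefaction depth (sequences)",
                  y = "Observed species (mean over iterations)",
                  colour = "Sample") +
    ggplot2::theme_minimal()
}

#' Diverging bar chart of pathway log odds
#'
#' Positive bars are pathways associated with the first group, negative
#' with the second, with significant pathways highlighted.
#'
#' @param pathway_enrichment Output of [pathway_fisher()].
#' @param alpha FDR significance level used for highlighting.
#' @return A ggplot object.
#' @export
plot_pathway_log_odds <- function(pathway_enrichment, alpha = 0.05) {
  df <- dplyr::mutate(pathway_enrichment,
                      significant = .data$fdr_p <= alpha,
                      pathway_id = stats::reorder(.data$pathway_id, .data$log_odds))
  ggplot2::ggplot(df, ggplot2::aes(.data$pathway_id, .data$log_odds,
                                   fill = .data$log_odds > 0,
                                   alpha = .data$significant)) +
    ggplot2::geom_col(show.legend = c(fill = FALSE, alpha = TRUE)) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.35)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "log odds ratio", alpha = "FDR significant") +
    ggplot2::theme_minimal()
}

#' Plot the temperature-correlation screen
#'
#' Rho against FDR-adjusted p with the pass region marked.
#'
#' @param screen Output of [spearman_screen()].
#' @param rho_min,fdr_alpha Thresholds to draw.
#' @return A ggplot object.
#' @export
plot_correlation_screen <- function(screen, rho_min = 0.7, fdr_alpha = 0.05) {
  df <- dplyr::filter(screen, .data$assessable)
  ggplot2::ggplot(df, ggplot2::aes(.data$rho, -log10(.data$fdr_p),
                                   colour = .data$passes)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = c(-rho_min, rho_min), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(fdr_alpha), linetype = 2) +
    ggplot2::labs(x = "Spearman rho vs temperature",
                  y = expression(-log[10]~"FDR-adjusted p"),
                  colour = "Passes screen") +
    ggplot2::theme_minimal()
}
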