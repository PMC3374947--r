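# ggplot2 displays for the result types.

#' Plot the ORF-scale log2 ratio track of a gene
#'
#' Windows are drawn as horizontal segments, exon-overlapping windows in
#' red, intron-only windows in black — the upper panel of the standard
#' deletion plot.
#'
#' @param projection A `ps_orf_projection` from [project_orf()].
#' @return A ggplot.
#' @export
plot_orf_track <- function(projection) {
  orf <- projection$orf
  ggplot2::ggplot(orf, ggplot2::aes(x = .data$start, xend = .data$end,
                                    y = .data$M, yend = .data$M,
                                    colour = .data$exonic)) +
    ggplot2::geom_segment(linewidth = 1.2) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "red", `FALSE` = "black"),
      labels = c(`TRUE` = "exon overlap", `FALSE` = "no overlap"),
      name = NULL
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "genomic position (bp)", y = "M (log2 ratio)",
      title = paste0(projection$gene, " - ORF scale")
    ) +
    ggplot2::theme_minimal()
}

#' Plot the exon-scale summary of a gene
#'
#' Per-exon mean M with 25th/75th percentile bars — the lower panel of the
#' standard deletion plot.
#'
#' @param summaries Exon summaries from [aggregate_exons()], or a
#'   `ps_orf_projection`.
#' @return A ggplot.
#' @export
plot_exon_summary <- function(summaries) {
  if (inherits(summaries, "ps_orf_projection")) summaries <- summaries$exon
  ggplot2::ggplot(summaries, ggplot2::aes(x = .data$exon, y = .data$mean_M)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$q25_M, ymax = .data$q75_M),
      width = 0.4, colour = "grey40"
    ) +
    ggplot2::geom_point(colour = "red", size = 2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "exon", y = "mean M (log2 ratio)",
      title = unique(summaries$gene)[1]
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot an ORF/exon projection (both scales stacked)
#'
#' @param object A `ps_orf_projection`.
#' @param ... Unused.
#' @return A patchwork of the ORF-scale and exon-scale panels.
#' @export
autoplot.ps_orf_projection <- function(object, ...) {
  patchwork::wrap_plots(
    plot_orf_track(object), plot_exon_summary(object), ncol = 1
  )
}

#' Autoplot a filtering funnel
#'
#' @param object A `ps_cascade`.
#' @param ... Unused.
#' @return A ggplot bar chart of the stage counts.
#' @export
autoplot.ps_cascade <- function(object, ...) {
  d <- object$stages
  d$label <- factor(d$label, levels = d$label)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "variants") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
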