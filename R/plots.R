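#' Gene parity plot
#'
#' Scatter of homologous genes' ordinal positions in the two genomes;
#' diagonal runs indicate collinear gene order.
#'
#' @param object A `parity_data` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.parity_data <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$index_a, y = .data$index_b)) +
    ggplot2::geom_point(size = 1.2, colour = "#2c5f8a") +
    ggplot2::coord_fixed(ratio = object$n_genes_a / object$n_genes_b) +
    ggplot2::labs(
      x = "gene position, genome A",
      y = "gene position, genome B",
      title = sprintf("Gene parity (collinearity %.2f%s)",
                      object$collinearity,
                      if (object$reflection_used) ", reflected" else "")
    ) +
    ggplot2::theme_minimal()
}

#' Promoter hit map
#'
#' One row per ORF, with element hits at their position upstream of the
#' start codon (0 = the A of ATG).
#'
#' @param hits Output of [scan_promoters()].
#' @return A ggplot.
#' @export
plot_promoter_map <- function(hits) {
  ggplot2::ggplot(hits, ggplot2::aes(x = .data$rel_start, y = .data$orf_id,
                                     colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::labs(x = "position relative to start codon (nt)", y = NULL,
                  colour = "element class") +
    ggplot2::theme_minimal()
}

#' Repeat-region map along the genome
#'
#' @param repeats A repeat-region tibble ([find_hrs()] and/or
#'   [find_tandem_repeats()] output, possibly row-bound).
#' @param genome_length Genome length in bp, for the x scale.
#' @return A ggplot.
#' @export
plot_repeat_map <- function(repeats, genome_length = NULL) {
  p <- ggplot2::ggplot(repeats) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = .data$region_id, yend = .data$region_id,
                   colour = .data$kind),
      linewidth = 4
    ) +
    ggplot2::labs(x = "genome position (bp)", y = NULL, colour = "kind") +
    ggplot2::theme_minimal()
  if (!is.null(genome_length)) {
    p <- p + ggplot2::xlim(0, genome_length)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
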