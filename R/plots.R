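# ggplot2 displays for the main result types.

#' @importFrom ggplot2 ggplot aes geom_col geom_hline facet_grid labs
#'   theme_minimal scale_fill_brewer
NULL

#' Bar chart of relative synonymous codon usage by family
#'
#' Mirrors the conventional RSCU panel of mitogenome descriptions: one bar
#' per codon, grouped by synonymous family.
#'
#' @param object A `codon_usage` table from [codon_usage()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot codon_usage
#' @export
autoplot.codon_usage <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$rscu), ]
  ggplot(df, aes(x = .data$codon, y = .data$rscu)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = 1, linetype = 2, linewidth = 0.3) +
    facet_grid(. ~ family, scales = "free_x", space = "free_x") +
    labs(x = NULL, y = "RSCU") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6),
                   strip.text = ggplot2::element_text(size = 7))
}

#' Bar chart of AT content per genome region
#'
#' @param report Output of [region_composition_report()].
#' @return A ggplot.
#' @export
plot_region_at <- function(report) {
  ggplot(report, aes(x = .data$region, y = .data$at_content)) +
    geom_col(fill = "darkorange") +
    labs(x = NULL, y = "AT content (%)") +
    theme_minimal()
}

#' Junction gap profile around the circular genome
#'
#' Spacers above the axis, overlaps below.
#'
#' @param ledger Output of [junction_ledger()].
#' @return A ggplot.
#' @export
plot_junctions <- function(ledger) {
  df <- mutate(ledger, junction = factor(paste0(.data$upstream, "|", .data$downstream),
                                         levels = paste0(.data$upstream, "|",
                                                         .data$downstream)))
  ggplot(df, aes(x = .data$junction, y = .data$gap, fill = .data$class)) +
    geom_col() +
    scale_fill_brewer(palette = "Set2") +
    labs(x = NULL, y = "gap (bp)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       size = 6))
}
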