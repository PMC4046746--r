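#' Plot a tag copy-number distribution
#'
#' Side-by-side bars of distinct and total tag counts per copy-number bin,
#' the standard library-quality display for tag sequencing.
#'
#' @param lib A `tag_library` (or a distribution tibble from
#'   [abundance_distribution()]).
#' @param bin_edges Passed to [abundance_distribution()] when `lib` is a
#'   library.
#' @return A ggplot object.
#' @export
plot_abundance_distribution <- function(lib, bin_edges = c(1, 2, 6, 11, 21, 51, 101)) {
  dist <- if (inherits(lib, "tag_library")) {
    abundance_distribution(lib, bin_edges)
  } else {
    lib
  }
  long <- tidyr::pivot_longer(
    dist, c("n_distinct", "n_total"),
    names_to = "measure", values_to = "n_tags"
  )
  long$measure <- ifelse(long$measure == "n_distinct", "distinct tags", "total tags")
  long$bin <- factor(long$bin, levels = dist$bin)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$n_tags,
                                     fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "tag copy number", y = "number of tags", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tag_library <- function(object, ...) {
  plot_abundance_distribution(object, ...)
}

#' Plot a gene-detection saturation curve
#'
#' @param curve A `saturation_curve` from [saturation_curve()].
#' @return A ggplot object.
#' @export
plot_saturation <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$subsample_size,
                                      y = .data$n_detected)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "clean tags sampled", y = "genes detected") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.saturation_curve <- function(object, ...) plot_saturation(object)

#' Volcano plot of a differential-expression result
#'
#' @param dge A `dge_result` from [dge_test()].
#' @return A ggplot object (genes with undefined ratios are omitted).
#' @export
plot_dge <- function(dge) {
  tab <- dge$table[!is.na(dge$table$log2_ratio), , drop = FALSE]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log2_ratio,
                                    y = -log10(pmax(.data$fdr, 1e-300)),
                                    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(up = "#c0392b", down = "#2980b9",
                                            none = "grey60")) +
    ggplot2::geom_hline(yintercept = -log10(dge$fdr_max), linetype = 2) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * dge$min_abs_log2, linetype = 2) +
    ggplot2::labs(x = "log2 ratio (treatment / control)", y = "-log10 FDR",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dge_result <- function(object, ...) plot_dge(object)

#' Dot plot of enriched terms
#'
#' @param rows Enrichment tibble from [enrich_terms()].
#' @param max_terms Show at most this many terms (most significant first).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(rows, max_terms = 20) {
  rows <- head(rows, max_terms)
  rows$term_name <- factor(rows$term_name, levels = rev(rows$term_name))
  ggplot2::ggplot(rows, ggplot2::aes(x = -log10(pmax(.data$q_value, 1e-300)),
                                     y = .data$term_name,
                                     size = .data$k,
                                     colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b", `FALSE` = "grey50")) +
    ggplot2::labs(x = "-log10 q-value", y = NULL, size = "DEGs in term",
                  colour = "q <= 0.05") +
    ggplot2::theme_minimal()
}
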