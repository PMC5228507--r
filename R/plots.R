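#' Plot spacer counts across edit-distance budgets
#'
#' The synthetic analogue of the study's detection-sensitivity figure:
#' non-redundant spacer (and optionally recruited-read) counts against the
#' allowed edit distance.
#'
#' @param counts a tibble with columns `d_max` and `n_spacers`, optionally
#'   `n_recruited` (e.g., built by row-binding `glance()` of several
#'   [detect_spacers()] runs).
#' @return A ggplot object.
#' @export
plot_spacer_counts <- function(counts) {
  stopifnot(all(c("d_max", "n_spacers") %in% names(counts)))
  long <- tidyr::pivot_longer(
    counts[, intersect(c("d_max", "n_spacers", "n_recruited"),
                       names(counts))],
    -"d_max", names_to = "quantity", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(.data$d_max, .data$count,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "allowed edit distance",
                  y = "count after deduplication", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a bipartite virus-host network
#'
#' Spacer nodes (coloured by host taxon) on one side, virus nodes on the
#' other, one segment per edge - a quick textual-layout rendition of the
#' interaction network; for publication-grade layouts export with
#' [write_network()] and use a dedicated network tool.
#'
#' @param object a `crisprscout_network` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.crisprscout_network <- function(object, ...) {
  edges <- object
  sp <- sort(unique(edges$spacer_id))
  vi <- sort(unique(edges$virus_id))
  lay <- dplyr::bind_rows(
    tibble::tibble(node = sp, x = 0,
                   y = seq(0, 1, length.out = max(length(sp), 2))[seq_along(sp)]),
    tibble::tibble(node = vi, x = 1,
                   y = seq(0, 1, length.out = max(length(vi), 2))[seq_along(vi)]))
  seg <- edges |>
    dplyr::left_join(lay, by = c(spacer_id = "node")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(lay, by = c(virus_id = "node"))
  taxa <- edges |> dplyr::distinct(.data$spacer_id, .data$host_taxon)
  sp_lay <- dplyr::left_join(lay[lay$x == 0, ], taxa,
                             by = c(node = "spacer_id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y),
                          colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_point(data = sp_lay,
                        ggplot2::aes(.data$x, .data$y,
                                     colour = .data$host_taxon), size = 2) +
    ggplot2::geom_point(data = lay[lay$x == 1, ],
                        ggplot2::aes(.data$x, .data$y), shape = 15,
                        size = 2) +
    ggplot2::scale_x_continuous(breaks = c(0, 1),
                                labels = c("spacers", "viruses")) +
    ggplot2::labs(x = NULL, y = NULL, colour = "host taxon") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot group summaries of k-mer usage distances
#'
#' Mean squared-difference usage distance per group with `mean +/- 2*SE`
#' error bars, one panel per word length.
#'
#' @param summary a tibble from [summarize_pairs()].
#' @return A ggplot object.
#' @export
plot_group_summary <- function(summary) {
  stopifnot(all(c("group", "k", "mean", "lower", "upper") %in%
                  names(summary)))
  summary$k_label <- paste0(ifelse(summary$k == 2, "dimer", "trimer"),
                            " usage")
  ggplot2::ggplot(summary, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.2) +
    ggplot2::facet_wrap(~k_label, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "squared usage difference") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
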