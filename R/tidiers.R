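#' Tidy a detected spacer set into its provenance table
#'
#' @param x a `crisprscout_spacers` tibble.
#' @param ... unused.
#' @return The provenance tibble (one row per detection event).
#' @export
tidy.crisprscout_spacers <- function(x, ...) spacer_provenance(x)

#' One-row summary of a detection run
#'
#' @param x a `crisprscout_spacers` tibble.
#' @param ... unused.
#' @return A tibble with `n_reads`, `n_recruited`, `n_detections`,
#'   `n_spacers`, `d_max`.
#' @export
glance.crisprscout_spacers <- function(x, ...) {
  tibble::tibble(n_reads = attr(x, "n_reads"),
                 n_recruited = attr(x, "n_recruited"),
                 n_detections = nrow(spacer_provenance(x)),
                 n_spacers = nrow(x),
                 d_max = attr(x, "params")$d_max)
}

#' One-row summary of a clustering
#'
#' @param x a `crisprscout_clusters` tibble.
#' @param ... unused.
#' @return A tibble with `n_sequences`, `n_clusters`, `threshold`,
#'   `largest_cluster`.
#' @export
glance.crisprscout_clusters <- function(x, ...) {
  tibble::tibble(n_sequences = nrow(x),
                 n_clusters = sum(x$is_representative),
                 threshold = attr(x, "params")$threshold,
                 largest_cluster = max(table(x$cluster_id)))
}

#' One-row summary of a virus-host network
#'
#' @param x a `crisprscout_network` tibble.
#' @param ... unused.
#' @return A tibble with `n_edges`, `n_spacers`, `n_viruses`,
#'   `n_host_taxa`.
#' @export
glance.crisprscout_network <- function(x, ...) {
  tibble::tibble(n_edges = nrow(x),
                 n_spacers = length(unique(x$spacer_id)),
                 n_viruses = length(unique(x$virus_id)),
                 n_host_taxa = length(unique(x$host_taxon)))
}
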