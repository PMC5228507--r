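read_sequences_auto <- function(path) {
  if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) read_fastq(path)
  else read_fasta(path)
}

config_echo <- function(out_dir, subcommand, config) {
  path <- file.path(out_dir, paste0(subcommand, ".config.json"))
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  path
}

log_count <- function(...) message(sprintf(...))

#' Run reference-guided spacer detection on files
#'
#' File-level composition of [detect_spacers()]: reads a metagenome
#' (FASTA/FASTQ) and a query DR file, writes the non-redundant spacer
#' FASTA, the provenance TSV and a machine-readable config echo, and logs
#' the counts at every filtering step.
#'
#' @param reads_path metagenome FASTA or FASTQ.
#' @param drs_path DR query FASTA or TSV (see [read_dr_queries()]).
#' @param out_dir output directory (created if needed).
#' @param params a [detection_params()] object; defaults are the study
#'   settings (d_max 3, spacer gap 26-60 bp, both strands).
#' @return The detected `crisprscout_spacers` tibble, invisibly.
#' @export
run_detect <- function(reads_path, drs_path, out_dir,
                       params = detection_params()) {
  if (!file.exists(reads_path)) stop("reads file not found: ", reads_path,
                                     call. = FALSE)
  if (!file.exists(drs_path)) stop("DR query file not found: ", drs_path,
                                   call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reads <- read_sequences_auto(reads_path)
  queries <- read_dr_queries(drs_path)
  log_count("detect: %d reads, %d query DRs, d_max=%d", nrow(reads),
            nrow(queries), params$d_max)
  spacers <- detect_spacers(reads, queries, params)
  prov <- spacer_provenance(spacers)
  log_count("detect: %d reads recruited, %d spacers called, %d non-redundant",
            attr(spacers, "n_recruited"), nrow(prov), nrow(spacers))
  write_spacers(spacers, file.path(out_dir, "spacers.fasta"),
                file.path(out_dir, "spacers.provenance.tsv"))
  config_echo(out_dir, "detect",
              c(list(reads = reads_path, drs = drs_path), unclass(params)))
  invisible(spacers)
}

#' Run greedy spacer clustering on a FASTA file
#'
#' @param spacers_path spacer FASTA (e.g., output of [run_detect()]).
#' @param out_dir output directory.
#' @param params a [cluster_params()] object (default threshold 0.9).
#' @return The `crisprscout_clusters` tibble, invisibly.
#' @export
run_cluster <- function(spacers_path, out_dir, params = cluster_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spacers <- read_fasta(spacers_path)
  clusters <- greedy_cluster(spacers, params)
  log_count("cluster: %d sequences -> %d clusters at threshold %.2f",
            nrow(clusters), sum(clusters$is_representative),
            params$threshold)
  write_clusters(clusters,
                 representatives_fasta = file.path(out_dir,
                                                   "representatives.fasta"),
                 clstr_path = file.path(out_dir, "clusters.clstr"),
                 tsv_path = file.path(out_dir, "clusters.tsv"))
  config_echo(out_dir, "cluster",
              c(list(spacers = spacers_path), unclass(params)))
  invisible(clusters)
}

#' Run spacer-to-virus mapping and network export
#'
#' Aligns spacers (cluster representatives or raw detections) against a
#' viral library, or ingests a precomputed 12-column alignment table, and
#' writes the bipartite network (SIF plus node/edge attribute TSVs).
#'
#' @param spacers_path spacer FASTA.
#' @param viruses_path viral library FASTA.
#' @param out_dir output directory.
#' @param provenance_path optional provenance TSV from [run_detect()]
#'   supplying host-taxon labels via the detecting query; without it all
#'   labels are `"unknown"`.
#' @param queries_path optional DR query file (with `host_taxon`) used
#'   with `provenance_path` to label spacers.
#' @param hits_path optional precomputed 12-column alignment TSV; when
#'   given, the built-in aligner is skipped.
#' @param params an [align_params()] object.
#' @return The `crisprscout_network` edge tibble, invisibly.
#' @export
run_map <- function(spacers_path, viruses_path, out_dir,
                    provenance_path = NULL, queries_path = NULL,
                    hits_path = NULL, params = align_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  spacers <- read_fasta(spacers_path)
  names(spacers)[names(spacers) == "id"] <- "spacer_id"
  if (is.null(hits_path)) {
    viruses <- read_fasta(viruses_path)
    hits <- align_spacers(spacers, viruses, params)
  } else {
    hits <- read_tabular_hits(hits_path, params$evalue_cutoff)
  }
  log_count("map: %d hits retained at E <= %g", nrow(hits),
            params$evalue_cutoff)
  spacers$host_taxon <- "unknown"
  if (!is.null(provenance_path) && !is.null(queries_path)) {
    prov <- readr::read_tsv(provenance_path, show_col_types = FALSE,
                            progress = FALSE)
    queries <- read_dr_queries(queries_path)
    lab <- prov |>
      dplyr::distinct(.data$spacer_id, .data$query_id) |>
      dplyr::left_join(queries[, c("id", "host_taxon")],
                       by = c(query_id = "id")) |>
      dplyr::distinct(.data$spacer_id, .keep_all = TRUE)
    idx <- match(spacers$spacer_id, lab$spacer_id)
    spacers$host_taxon <- ifelse(is.na(idx), "unknown",
                                 lab$host_taxon[idx])
  }
  edges <- build_network(hits, spacers)
  log_count("map: %d virus-host edges (%d spacers, %d viruses)",
            nrow(edges), length(unique(edges$spacer_id)),
            length(unique(edges$virus_id)))
  write_network(edges, file.path(out_dir, "network"))
  config_echo(out_dir, "map",
              c(list(spacers = spacers_path, viruses = viruses_path,
                     hits = hits_path), unclass(params)))
  invisible(edges)
}

#' Run virus-host k-mer usage comparison
#'
#' @param pairs_path TSV with columns `virus_id`, `host_id` and optional
#'   grouping columns (e.g., `host`, `metagenome`).
#' @param genomes_path FASTA containing every referenced genome.
#' @param out_dir output directory; writes the per-pair distance TSV and
#'   one summary TSV per grouping column present.
#' @return The per-pair distance tibble, invisibly.
#' @export
run_kmerdist <- function(pairs_path, genomes_path, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pairs <- readr::read_tsv(pairs_path, show_col_types = FALSE,
                           progress = FALSE)
  genomes <- read_fasta(genomes_path)
  dists <- usage_distance_pairs(pairs, genomes)
  readr::write_tsv(dists, file.path(out_dir, "pair_distances.tsv"),
                   progress = FALSE)
  for (g in intersect(c("host", "metagenome"), names(pairs))) {
    readr::write_tsv(summarize_pairs(dists, g),
                     file.path(out_dir, paste0("summary_by_", g, ".tsv")),
                     progress = FALSE)
  }
  log_count("kmerdist: %d pairs", nrow(dists))
  config_echo(out_dir, "kmerdist",
              list(pairs = pairs_path, genomes = genomes_path))
  invisible(dists)
}

#' Run the synthetic metagenome generator
#'
#' @param out_dir output directory.
#' @param params a [sim_params()] object.
#' @param fastq write reads as FASTQ?
#' @return The `crisprscout_sim` object, invisibly.
#' @export
run_simulate <- function(out_dir, params = sim_params(), fastq = FALSE) {
  sim <- simulate_metagenome(params)
  write_simulation(sim, out_dir, fastq = fastq)
  log_count("simulate: %d reads (%d planted arrays), %d viruses, seed %d",
            nrow(sim$reads), params$n_array_reads, params$n_viruses,
            params$seed)
  invisible(sim)
}
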