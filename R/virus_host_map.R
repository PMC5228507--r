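#' Solve for the Karlin-Altschul lambda of an ungapped scoring system
#'
#' Solves `sum_ij p_i p_j exp(lambda * s_ij) = 1` for the unique positive
#' root, assuming uniform base frequencies: with a match reward `r` and
#' mismatch penalty `q` this is `exp(lambda*r)/4 + 3*exp(lambda*q)/4 = 1`.
#'
#' @param match_reward positive match score.
#' @param mismatch_penalty negative mismatch score.
#' @return lambda (numeric scalar).
#' @export
karlin_lambda <- function(match_reward = 1, mismatch_penalty = -2) {
  stopifnot(match_reward > 0, mismatch_penalty < 0)
  f <- function(l) {
    exp(l * match_reward) / 4 + 3 * exp(l * mismatch_penalty) / 4 - 1
  }
  stats::uniroot(f, c(1e-6, 10), tol = 1e-12)$root
}

#' Alignment parameters for spacer-to-virus mapping
#'
#' The study fixed only the aligner (blastn) and the E-value cutoff of
#' 1e-03; scoring details were unrecorded. The built-in aligner is an
#' ungapped seed-and-extend search with reward +1 / penalty -2 and seed
#' length 11 - adequate for 26-60 bp spacers - with Karlin-Altschul
#' E-value statistics. Bit-for-bit parity with NCBI BLAST is a non-goal;
#' [read_tabular_hits()] accepts genuine BLAST tabular output for strict
#' replication.
#'
#' @param match_reward,mismatch_penalty ungapped scoring pair.
#' @param seed_length exact seed length nominating diagonals.
#' @param lambda,kappa Karlin-Altschul parameters; `lambda = NULL` solves
#'   Karlin's equation for the scoring pair, `kappa` defaults to 0.621,
#'   the standard ungapped value for +1/-2.
#' @param evalue_cutoff retain hits with `E <= evalue_cutoff` (default
#'   1e-03).
#' @return An object of class `align_params`.
#' @export
align_params <- function(match_reward = 1, mismatch_penalty = -2,
                         seed_length = 11, lambda = NULL, kappa = 0.621,
                         evalue_cutoff = 1e-3) {
  stopifnot(match_reward > 0, mismatch_penalty < 0, seed_length >= 4,
            evalue_cutoff > 0, kappa > 0)
  if (is.null(lambda)) lambda <- karlin_lambda(match_reward, mismatch_penalty)
  stopifnot(lambda > 0)
  structure(list(match_reward = match_reward,
                 mismatch_penalty = mismatch_penalty,
                 seed_length = as.integer(seed_length),
                 lambda = lambda, kappa = kappa,
                 evalue_cutoff = evalue_cutoff),
            class = "align_params")
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of chance
#' ungapped local alignments scoring at least `S` between a query of
#' length `m` and a search space of total length `n`. Here `n` is the
#' summed library length (database-style search space), not a per-subject
#' length.
#'
#' @param score raw alignment score(s).
#' @param m query (spacer) length.
#' @param n total subject (library) length.
#' @param params an [align_params()] object supplying lambda and K.
#' @return Numeric vector of E-values.
#' @export
evalue <- function(score, m, n, params = align_params()) {
  stopifnot(inherits(params, "align_params"))
  if (any(m <= 0) || any(n <= 0)) {
    stop("sequence and search-space lengths must be positive", call. = FALSE)
  }
  params$kappa * m * n * exp(-params$lambda * score)
}

#' Align spacers against a viral genome library
#'
#' Ungapped seed-and-extend local alignment on both strands: every exact
#' seed of `seed_length` shared between a spacer and a subject nominates a
#' diagonal, and per (spacer, subject, strand, diagonal) the
#' maximal-scoring ungapped segment is kept. E-values use the summed
#' library length as search space; hits above the cutoff are dropped.
#'
#' @param spacers a data frame with sequence ids and residues (a
#'   `crisprscout_spacers` tibble, cluster representatives, or any
#'   sequence tibble), or a character vector.
#' @param viruses a sequence tibble of viral genomes/contigs.
#' @param params an [align_params()] object.
#' @return A tibble of retained hits sorted by `(spacer_id, evalue)`:
#'   `spacer_id`, `subject_id`, `spacer_start`, `spacer_end`,
#'   `subject_start`, `subject_end` (0-based half-open), `strand`,
#'   `identities`, `mismatches`, `score`, `evalue`.
#' @export
align_spacers <- function(spacers, viruses, params = align_params()) {
  if (is.character(spacers)) {
    spacers <- tibble::tibble(id = sprintf("seq_%03d", seq_along(spacers)),
                              residues = spacers)
  }
  stopifnot(is.data.frame(spacers), nrow(spacers) > 0, "residues" %in% names(spacers))
  id_col <- if ("spacer_id" %in% names(spacers)) "spacer_id" else "id"
  viruses <- validate_seq_tbl(viruses, "virus library")
  n_space <- sum(nchar(viruses$residues))
  short <- nchar(spacers$residues) < params$seed_length
  if (any(short)) {
    warning(sum(short), " spacer(s) shorter than the seed length yield no hits",
            call. = FALSE)
  }
  acc <- list()
  for (i in which(!short)) {
    m_len <- nchar(spacers$residues[i])
    for (v in seq_len(nrow(viruses))) {
      seg <- cpp_ungapped_hits(spacers$residues[i], viruses$residues[v],
                               params$seed_length, params$match_reward,
                               params$mismatch_penalty)
      if (nrow(seg) == 0) next
      seg <- tibble::as_tibble(as.data.frame(seg))
      acc[[length(acc) + 1]] <- tibble::tibble(
        spacer_id = as.character(spacers[[id_col]][i]),
        subject_id = viruses$id[v],
        spacer_start = as.integer(seg$qstart),
        spacer_end = as.integer(seg$qend),
        subject_start = as.integer(seg$sstart),
        subject_end = as.integer(seg$send),
        strand = ifelse(seg$strand > 0, "+", "-"),
        identities = as.integer(seg$identities),
        mismatches = as.integer(seg$mismatches),
        score = seg$score,
        evalue = evalue(seg$score, m_len, n_space, params))
    }
  }
  out <- dplyr::bind_rows(acc)
  if (nrow(out) == 0) {
    return(tibble::tibble(spacer_id = character(), subject_id = character(),
                          spacer_start = integer(), spacer_end = integer(),
                          subject_start = integer(), subject_end = integer(),
                          strand = character(), identities = integer(),
                          mismatches = integer(), score = numeric(),
                          evalue = numeric()))
  }
  out <- out[out$evalue <= params$evalue_cutoff, , drop = FALSE]
  out[order(out$spacer_id, out$evalue, out$subject_id), , drop = FALSE]
}

#' Read a 12-column tabular alignment file
#'
#' Accepts the standard 12-column tab-separated alignment dialect (query,
#' subject, percent identity, alignment length, mismatches, gap opens,
#' qstart, qend, sstart, send, evalue, bitscore) so genuine BLAST output
#' can stand in for the built-in aligner. 1-based inclusive coordinates
#' are converted to 0-based half-open; `sstart > send` encodes the minus
#' strand. Rows above the E-value cutoff are dropped and counted
#' (attribute `"n_dropped"`, also reported via `message()`).
#'
#' @param path input path.
#' @param evalue_cutoff retain rows with `evalue <= evalue_cutoff`.
#' @return A hit tibble in the layout of [align_spacers()] (`score` holds
#'   the bit score).
#' @export
read_tabular_hits <- function(path, evalue_cutoff = 1e-3) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 12)
  if (length(bad) > 0) {
    stop("malformed alignment row at line ", bad[1], " of ", path,
         " (expected 12 tab-separated columns)", call. = FALSE)
  }
  if (length(parts) == 0) {
    m <- matrix(character(0), ncol = 12)
  } else {
    m <- do.call(rbind, parts)
  }
  num <- function(j) suppressWarnings(as.numeric(m[, j]))
  qs <- num(7); qe <- num(8); ss <- num(9); se <- num(10)
  if (any(is.na(c(qs, qe, ss, se, num(11))))) {
    stop("non-numeric coordinate or E-value in ", path, call. = FALSE)
  }
  minus <- ss > se
  out <- tibble::tibble(
    spacer_id = m[, 1], subject_id = m[, 2],
    spacer_start = as.integer(qs - 1), spacer_end = as.integer(qe),
    subject_start = as.integer(ifelse(minus, se, ss) - 1),
    subject_end = as.integer(ifelse(minus, ss, se)),
    strand = ifelse(minus, "-", "+"),
    identities = as.integer(round(num(4) - num(5))),
    mismatches = as.integer(num(5)),
    score = num(12), evalue = num(11))
  keep <- out$evalue <= evalue_cutoff
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " hit(s) dropped above E-value cutoff ", evalue_cutoff)
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$spacer_id, out$evalue, out$subject_id), , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Build the bipartite virus-host interaction network
#'
#' One edge per (spacer, virus) pair with at least one retained hit. The
#' host label on an edge comes exclusively from the annotation of the DR
#' query that detected the spacer - never from the virus side - and is
#' `"unknown"` when the query was unannotated.
#'
#' @param hits a hit tibble from [align_spacers()] or
#'   [read_tabular_hits()].
#' @param spacers a data frame mapping `spacer_id` to `host_taxon` (e.g.,
#'   a `crisprscout_spacers` tibble); every `spacer_id` in `hits` must be
#'   present.
#' @return A tibble of class `crisprscout_network`: `spacer_id`,
#'   `virus_id`, `host_taxon`, `best_evalue` (minimum over the pair's
#'   hits), `n_hits`; deterministic ordering.
#' @export
build_network <- function(hits, spacers) {
  stopifnot(is.data.frame(hits), is.data.frame(spacers),
            "spacer_id" %in% names(spacers))
  if (!"host_taxon" %in% names(spacers)) spacers$host_taxon <- "unknown"
  unknown <- setdiff(hits$spacer_id, spacers$spacer_id)
  if (length(unknown) > 0) {
    stop("hit(s) reference unknown spacer id(s): ",
         paste(head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  edges <- hits |>
    dplyr::group_by(.data$spacer_id, virus_id = .data$subject_id) |>
    dplyr::summarise(best_evalue = min(.data$evalue),
                     n_hits = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(
      dplyr::distinct(spacers[, c("spacer_id", "host_taxon")],
                      .data$spacer_id, .keep_all = TRUE),
      by = "spacer_id") |>
    dplyr::select("spacer_id", "virus_id", "host_taxon", "best_evalue",
                  "n_hits") |>
    dplyr::arrange(.data$spacer_id, .data$virus_id)
  structure(edges, class = c("crisprscout_network", class(edges)))
}

#' Write a virus-host network for Cytoscape-style ingestion
#'
#' Writes `<basename>.sif` (lines `spacer_id  spacer_to_virus  virus_id`),
#' `<basename>.edges.tsv` (`spacer_id`, `virus_id`, `host_taxon`,
#' `best_evalue`, `n_hits`) and `<basename>.nodes.tsv` (`node`, `type`
#' spacer|virus, `label`; spacer labels are `"taxon (id)"`). An empty
#' network yields an empty SIF and headers-only TSVs.
#'
#' @param edges a `crisprscout_network` tibble (possibly empty).
#' @param basename output path prefix.
#' @return Invisibly, the three paths written.
#' @export
write_network <- function(edges, basename) {
  stopifnot(is.data.frame(edges))
  sif <- paste0(basename, ".sif")
  etsv <- paste0(basename, ".edges.tsv")
  ntsv <- paste0(basename, ".nodes.tsv")
  writeLines(sprintf("%s\tspacer_to_virus\t%s", edges$spacer_id,
                     edges$virus_id), sif)
  readr::write_tsv(edges[, c("spacer_id", "virus_id", "host_taxon",
                             "best_evalue", "n_hits")], etsv,
                   progress = FALSE)
  sp <- unique(edges[, c("spacer_id", "host_taxon")])
  nodes <- dplyr::bind_rows(
    tibble::tibble(node = sp$spacer_id, type = "spacer",
                   label = sprintf("%s (%s)", sp$host_taxon, sp$spacer_id)),
    tibble::tibble(node = unique(edges$virus_id), type = "virus",
                   label = unique(edges$virus_id)))
  readr::write_tsv(nodes, ntsv, progress = FALSE)
  invisible(c(sif, etsv, ntsv))
}
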