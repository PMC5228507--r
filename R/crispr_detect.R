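#' Recruit reads containing at least one query DR occurrence
#'
#' Step one of the reference-guided pipeline: every read carrying one or
#' more approximate DR occurrences (within the edit budget) is retained for
#' repeat-spacer geometry checks; all other reads are dropped.
#'
#' @inheritParams find_occurrences
#' @return The recruited subset of `reads` (input order preserved) with a
#'   list-column `matches` holding each read's match tibble.
#' @export
recruit_reads <- function(reads, queries, params = detection_params()) {
  reads <- validate_seq_tbl(reads, "read set")
  hits <- find_occurrences(reads, queries, params)
  keep <- reads$id %in% hits$read_id
  out <- reads[keep, , drop = FALSE]
  out$matches <- lapply(out$id, function(rid) {
    hits[hits$read_id == rid, , drop = FALSE]
  })
  tibble::as_tibble(out)
}

#' Call spacers from chained DR matches in one or more reads
#'
#' Step two and three: consecutive non-overlapping occurrences of the *same*
#' query on the *same* strand whose gap lies within the admissible spacer
#' length range delimit a spacer; the intervening read substring is emitted.
#' Minus-strand spacers are reverse-complemented so emitted residues follow
#' the query DR's orientation. Only adjacent matches in the chained order
#' pair up, so a repeat triplet yields two spacers. Flanks from different
#' queries are never paired: a query set mixes repeats from many taxa and a
#' chimeric repeat pair has no biological reading.
#'
#' @param reads a sequence tibble containing every read referenced by
#'   `matches`.
#' @param matches a match tibble, already chained with
#'   [chain_nonoverlapping()].
#' @inheritParams find_occurrences
#' @return A tibble with one row per called spacer: `read_id`, `query_id`,
#'   `strand`, `start`, `end` (spacer read coordinates, 0-based half-open),
#'   `residues` (query-oriented), `edits_left`, `edits_right`.
#' @export
call_spacers <- function(reads, matches, params = detection_params()) {
  reads <- validate_seq_tbl(reads, "read set")
  empty <- tibble::tibble(read_id = character(), query_id = character(),
                          strand = character(), start = integer(),
                          end = integer(), residues = character(),
                          edits_left = integer(), edits_right = integer())
  if (nrow(matches) == 0) return(empty)
  res <- setNames(reads$residues, reads$id)
  out <- lapply(split(seq_len(nrow(matches)), matches$read_id), function(idx) {
    m <- matches[idx, , drop = FALSE]
    m <- m[order(m$start, m$end), , drop = FALSE]
    if (nrow(m) < 2) return(NULL)
    i <- seq_len(nrow(m) - 1)
    gap <- m$start[i + 1] - m$end[i]
    ok <- m$query_id[i] == m$query_id[i + 1] &
      m$strand[i] == m$strand[i + 1] &
      gap >= params$min_spacer & gap <= params$max_spacer
    if (!any(ok)) return(NULL)
    i <- i[ok]
    sp <- stringi::stri_sub(res[[m$read_id[1]]], m$end[i] + 1,
                            m$start[i + 1])
    minus <- m$strand[i] == "-"
    sp[minus] <- revcomp(sp[minus])
    tibble::tibble(read_id = m$read_id[1], query_id = m$query_id[i],
                   strand = m$strand[i], start = m$end[i],
                   end = m$start[i + 1], residues = sp,
                   edits_left = m$edits[i], edits_right = m$edits[i + 1])
  })
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) return(empty)
  # restore read input order
  out[order(match(out$read_id, reads$id), out$start), , drop = FALSE]
}

#' Detect a non-redundant spacer set in a read collection
#'
#' The full reference-guided detection pipeline: recruit DR-containing
#' reads, chain overlapping matches, call spacers from admissible repeat
#' pairs, and collapse exact duplicate spacer sequences (first occurrence
#' wins; provenance of every duplicate is retained). Similarity-based
#' clustering is deliberately deferred to [greedy_cluster()], mirroring the
#' hash-then-cluster order of the original protocol.
#'
#' @inheritParams find_occurrences
#' @return A tibble of class `crisprscout_spacers` with one row per unique
#'   spacer sequence: `spacer_id` (content-derived hash), `residues`,
#'   `length`, `query_id` and `host_taxon` of the first detection, and
#'   `n_occurrences`. The full per-detection record is attached as
#'   attribute `"provenance"` (see [spacer_provenance()]).
#' @export
detect_spacers <- function(reads, queries, params = detection_params()) {
  recruited <- recruit_reads(reads, queries, params)
  matches <- dplyr::bind_rows(recruited$matches)
  chained <- chain_nonoverlapping(matches)
  called <- call_spacers(reads, chained, params)
  taxon <- if ("host_taxon" %in% names(queries)) {
    setNames(queries$host_taxon, queries$id)
  } else {
    setNames(rep("unknown", nrow(queries)), queries$id)
  }
  called$spacer_id <- if (nrow(called) > 0) {
    paste0("sp_", cpp_fnv1a64(called$residues))
  } else character(0)
  uniq <- called[!duplicated(called$residues), , drop = FALSE]
  out <- tibble::tibble(
    spacer_id = uniq$spacer_id,
    residues = uniq$residues,
    length = nchar(uniq$residues),
    query_id = uniq$query_id,
    host_taxon = unname(taxon[uniq$query_id]),
    n_occurrences = as.integer(table(called$residues)[uniq$residues])
  )
  if (nrow(out) == 0) out$n_occurrences <- integer(0)
  prov <- called[, c("spacer_id", "read_id", "query_id", "strand", "start",
                     "end", "edits_left", "edits_right")]
  structure(out,
            provenance = tibble::as_tibble(prov),
            params = params,
            n_reads = nrow(reads),
            n_recruited = nrow(recruited),
            class = c("crisprscout_spacers", class(out)))
}

#' Per-detection provenance of a spacer set
#'
#' @param x a `crisprscout_spacers` tibble from [detect_spacers()].
#' @return A tibble with one row per detection event: `spacer_id`,
#'   `read_id`, `query_id`, `strand`, `start`, `end`, `edits_left`,
#'   `edits_right`.
#' @export
spacer_provenance <- function(x) {
  stopifnot(inherits(x, "crisprscout_spacers"))
  attr(x, "provenance")
}

#' Spacers shared between two collections
#'
#' Exact sequence identity between two spacer sets, as used to compare
#' detections across sampling sites. With `strand_insensitive` (default) a
#' sequence and its reverse complement count as identical; each sequence is
#' reduced to its canonical form, the lexicographic minimum of the two
#' orientations.
#'
#' @param set_a,set_b spacer collections: character vectors of residues, or
#'   data frames with a `residues` column.
#' @param strand_insensitive treat a sequence and its reverse complement as
#'   the same spacer?
#' @return A tibble with one row per shared canonical sequence (column
#'   `residues`); the shared count is its row count.
#' @export
shared_spacers <- function(set_a, set_b, strand_insensitive = TRUE) {
  get_res <- function(x) {
    if (is.data.frame(x)) x$residues else as.character(x)
  }
  canon <- function(r) {
    if (length(r) == 0) return(character(0))
    r <- toupper(r)
    if (strand_insensitive) pmin(r, revcomp(r)) else r
  }
  a <- unique(canon(get_res(set_a)))
  b <- unique(canon(get_res(set_b)))
  tibble::tibble(residues = sort(intersect(a, b)))
}

#' Spacers per million reads
#'
#' Normalizes spacer counts by sequencing depth so detection rates can be
#' compared across metagenomes of different sizes.
#'
#' @param n_spacers numeric vector of spacer counts.
#' @param n_reads numeric vector of read counts (must be positive).
#' @return `n_spacers / n_reads * 1e6`.
#' @examples
#' spacer_rate(9, 1.5e6) # 6
#' @export
spacer_rate <- function(n_spacers, n_reads) {
  if (any(n_reads <= 0)) stop("n_reads must be positive", call. = FALSE)
  n_spacers / n_reads * 1e6
}

#' Write a spacer set to FASTA plus a provenance TSV
#'
#' @param spacers a `crisprscout_spacers` tibble.
#' @param fasta_path output FASTA (id = content digest; description carries
#'   the first detection's read, query, strand and coordinates).
#' @param provenance_path output TSV of the full provenance table (optional).
#' @return `fasta_path`, invisibly.
#' @export
write_spacers <- function(spacers, fasta_path, provenance_path = NULL) {
  stopifnot(inherits(spacers, "crisprscout_spacers"))
  prov <- spacer_provenance(spacers)
  first <- prov[!duplicated(prov$spacer_id), , drop = FALSE]
  first <- first[match(spacers$spacer_id, first$spacer_id), , drop = FALSE]
  desc <- sprintf("read=%s query=%s strand=%s interval=[%d,%d)",
                  first$read_id, first$query_id, first$strand,
                  first$start, first$end)
  if (nrow(spacers) > 0) {
    write_fasta(tibble::tibble(id = spacers$spacer_id, description = desc,
                               residues = spacers$residues), fasta_path)
  } else {
    writeLines(character(0), fasta_path)
  }
  if (!is.null(provenance_path)) {
    readr::write_tsv(prov, provenance_path, progress = FALSE)
  }
  invisible(fasta_path)
}
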