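#' Detection parameters
#'
#' Bundles the tunable knobs of reference-guided repeat detection. Defaults
#' follow the study design this package reproduces: up to 3 edits between a
#' query repeat and its occurrence in a read, spacers between 26 and 60 bp
#' (60 bp being the maximum allowed distance between two detected repeats),
#' and search on both strands.
#'
#' @param d_max maximum Levenshtein edit distance between a query DR and its
#'   occurrence in a read; the study varied this from 0 to 3.
#' @param min_spacer,max_spacer admissible gap (bp) between two consecutive
#'   DR occurrences for the gap to be called a spacer.
#' @param both_strands search queries as their reverse complements too
#'   (strand `"-"`)?
#' @param dr_len_range advisory empirical DR length range (bp), used only for
#'   warnings on query ingest.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(d_max = 3, min_spacer = 26, max_spacer = 60,
                             both_strands = TRUE, dr_len_range = c(23, 47)) {
  stopifnot(d_max >= 0, min_spacer > 0, max_spacer > 0,
            min_spacer <= max_spacer, length(dr_len_range) == 2)
  structure(list(d_max = as.integer(d_max),
                 min_spacer = as.integer(min_spacer),
                 max_spacer = as.integer(max_spacer),
                 both_strands = isTRUE(both_strands),
                 dr_len_range = as.integer(dr_len_range)),
            class = "detection_params")
}

#' Levenshtein edit distance
#'
#' Unit-cost edit distance (insertions, deletions, substitutions) with the
#' convention that `N` never matches any base, itself included: an `N` in
#' either sequence always costs an edit at its aligned position.
#'
#' @param a,b character vectors over `{A,C,G,T,N}`, recycled to a common
#'   length.
#' @return Integer vector of distances.
#' @examples
#' levenshtein("ACGT", "AGGT") # 1
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- toupper(rep_len(a, n)); b <- toupper(rep_len(b, n))
  mapply(cpp_levenshtein, a, b, USE.NAMES = FALSE)
}

# Collapse candidate end positions: cluster candidates (one query, one
# strand, one read) whose [start, end) intervals overlap transitively; keep
# per cluster the candidate with minimum edits, then shortest span, then
# leftmost start. Prevents a single degenerate repeat from spawning shadow
# matches at neighbouring end positions.
collapse_candidates <- function(cand) {
  if (nrow(cand) <= 1) return(cand)
  cand <- cand[order(cand$start, cand$end), , drop = FALSE]
  cluster <- cumsum(c(TRUE, cand$start[-1] >= cummax(cand$end)[-nrow(cand)]))
  keep <- vapply(split(seq_len(nrow(cand)), cluster), function(idx) {
    sub <- cand[idx, , drop = FALSE]
    o <- order(sub$edits, sub$end - sub$start, sub$start)
    idx[o[1]]
  }, integer(1))
  cand[sort(keep), , drop = FALSE]
}

#' Find approximate occurrences of query DRs in reads
#'
#' Semi-global search: for every query and read position where some read
#' substring lies within `d_max` edits of the query, a match is reported;
#' overlapping candidate end positions for the same query and strand are
#' collapsed to the single best candidate (minimum edits, then shortest
#' span, then leftmost start). With `both_strands`, queries are also
#' searched as reverse complements and reported with strand `"-"`.
#'
#' @param reads a sequence tibble of reads (see [seq_tbl()]).
#' @param queries a DR query tibble (see [as_dr_queries()]), or any data
#'   frame with `id` and `residues`.
#' @param params a [detection_params()] object.
#' @return A tibble with columns `read_id`, `query_id`, `start`, `end`
#'   (0-based half-open read coordinates), `strand`, `edits`, sorted by
#'   read (input order) then `(start, end)`.
#' @export
find_occurrences <- function(reads, queries, params = detection_params()) {
  reads <- validate_seq_tbl(reads, "read set")
  stopifnot(is.data.frame(queries), nrow(queries) > 0,
            inherits(params, "detection_params"))
  strands <- if (params$both_strands) c("+", "-") else "+"
  per_read <- lapply(seq_len(nrow(reads)), function(i) {
    read <- reads$residues[i]
    acc <- list()
    for (q in seq_len(nrow(queries))) {
      for (strand in strands) {
        pat <- if (strand == "+") queries$residues[q] else
          revcomp(queries$residues[q])
        cand <- cpp_semiglobal_candidates(read, pat, params$d_max)
        if (nrow(cand) == 0) next
        cand <- collapse_candidates(as.data.frame(cand))
        acc[[length(acc) + 1]] <- tibble::tibble(
          read_id = reads$id[i], query_id = queries$id[q],
          start = cand$start, end = cand$end, strand = strand,
          edits = cand$edits)
      }
    }
    if (length(acc) == 0) return(NULL)
    dplyr::arrange(dplyr::bind_rows(acc), .data$start, .data$end)
  })
  out <- dplyr::bind_rows(per_read)
  if (nrow(out) == 0) {
    out <- tibble::tibble(read_id = character(), query_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), edits = integer())
  }
  out
}

#' Select a non-overlapping subset of DR matches
#'
#' Overlapping matches within a read are resolved greedily by quality:
#' matches are considered best-first under the ordering (fewer edits, then
#' longer span, then leftmost start, then query id, then strand), and a
#' match is kept when it overlaps no already-kept match. This yields the
#' unique quality-lexicographic optimum over all non-overlapping subsets.
#'
#' @param matches a match tibble as returned by [find_occurrences()]
#'   (possibly spanning several reads; chaining is per read).
#' @return The retained matches, sorted by read then `start`.
#' @export
chain_nonoverlapping <- function(matches) {
  stopifnot(is.data.frame(matches))
  if (nrow(matches) == 0) return(matches)
  chain_one <- function(m) {
    o <- order(m$edits, -(m$end - m$start), m$start, m$query_id, m$strand)
    m <- m[o, , drop = FALSE]
    kept_start <- integer(0); kept_end <- integer(0); keep <- integer(0)
    for (i in seq_len(nrow(m))) {
      if (all(m$end[i] <= kept_start | m$start[i] >= kept_end)) {
        keep <- c(keep, i)
        kept_start <- c(kept_start, m$start[i])
        kept_end <- c(kept_end, m$end[i])
      }
    }
    m <- m[keep, , drop = FALSE]
    m[order(m$start, m$end), , drop = FALSE]
  }
  split_idx <- split(seq_len(nrow(matches)), matches$read_id)
  # preserve read input order
  first_seen <- vapply(split_idx, min, integer(1))
  out <- lapply(split_idx[order(first_seen)],
                function(idx) chain_one(matches[idx, , drop = FALSE]))
  dplyr::bind_rows(out)
}
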