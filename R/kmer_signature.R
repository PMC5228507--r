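all_kmers <- function(k) {
  do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                  stringsAsFactors = FALSE)))
}

#' Overlapping k-mer frequency profile
#'
#' Counts every overlapping window of length `k` (positions `0 ... L-k` in
#' 0-based coordinates) on the forward strand, skips windows containing
#' `N`, and normalizes by the number of counted windows, so frequencies
#' over the `4^k` words (fixed lexicographic order) sum to 1 whenever at
#' least one valid window exists. Strand-naive by design; set
#' `both_strands = TRUE` to add the reverse-complement windows.
#'
#' @param seqs a sequence tibble, or a single character string (given an id
#'   of `"seq"`).
#' @param k word length, 2 (dinucleotides) or 3 (trinucleotides).
#' @param both_strands also count windows of the reverse complement?
#' @return A tibble with columns `sequence_id`, `k`, `word`, `frequency`
#'   (`4^k` rows per sequence).
#' @examples
#' kmer_frequencies("ACGT", k = 2) # AC, CG, GT each 1/3
#' @export
kmer_frequencies <- function(seqs, k, both_strands = FALSE) {
  stopifnot(k %in% c(2, 3))
  if (is.character(seqs) && length(seqs) == 1 && !is.data.frame(seqs)) {
    seqs <- tibble::tibble(id = "seq", residues = seqs)
  }
  seqs <- validate_seq_tbl(seqs)
  words <- all_kmers(k)
  profiles <- lapply(seq_len(nrow(seqs)), function(i) {
    s <- seqs$residues[i]
    L <- nchar(s)
    if (L < k) stop("sequence '", seqs$id[i], "' is shorter than k = ", k,
                    call. = FALSE)
    win <- stringi::stri_sub(s, 1:(L - k + 1), length = k)
    if (both_strands) win <- c(win, stringi::stri_sub(revcomp(s),
                                                      1:(L - k + 1),
                                                      length = k))
    win <- win[!stringr::str_detect(win, "N")]
    counts <- table(factor(win, levels = words))
    total <- sum(counts)
    freq <- if (total > 0) as.numeric(counts) / total else rep(0, length(words))
    tibble::tibble(sequence_id = seqs$id[i], k = as.integer(k),
                   word = words, frequency = freq)
  })
  dplyr::bind_rows(profiles)
}

#' Squared-difference distance between two k-mer usage profiles
#'
#' Each word frequency of one profile is subtracted from the corresponding
#' frequency of the other, squared, and the squares summed over all `4^k`
#' words - a squared Euclidean measure of oligonucleotide usage
#' difference. Symmetric; zero iff the profiles are identical.
#'
#' @param p,q profile tibbles from [kmer_frequencies()], one sequence
#'   each, with equal `k`.
#' @return Nonnegative numeric scalar.
#' @export
usage_distance <- function(p, q) {
  stopifnot(is.data.frame(p), is.data.frame(q),
            all(c("word", "frequency", "k") %in% names(p)),
            all(c("word", "frequency", "k") %in% names(q)))
  if (length(unique(p$k)) != 1 || length(unique(q$k)) != 1 ||
      p$k[1] != q$k[1]) {
    stop("profiles have mismatched k", call. = FALSE)
  }
  qf <- setNames(q$frequency, q$word)
  sum((p$frequency - qf[p$word])^2)
}

#' Dimer and trimer usage distances for virus-host pairs
#'
#' Computes the squared-difference usage distance at k = 2 and k = 3 for
#' each (virus, host) pair, looking both genomes up in `sequences` by id.
#' Multi-replicon hosts are *not* auto-concatenated: exactly the sequences
#' supplied (e.g., chromosome 1 only) are compared.
#'
#' @param pairs a data frame with columns `virus_id` and `host_id`, plus
#'   any grouping columns (e.g., `host`, `metagenome`) carried through.
#' @param sequences a sequence tibble containing every referenced genome.
#' @return `pairs` with numeric columns `d2` and `d3` appended.
#' @export
usage_distance_pairs <- function(pairs, sequences) {
  stopifnot(is.data.frame(pairs),
            all(c("virus_id", "host_id") %in% names(pairs)))
  sequences <- validate_seq_tbl(sequences, "genome set")
  missing <- setdiff(unique(c(pairs$virus_id, pairs$host_id)), sequences$id)
  if (length(missing) > 0) {
    stop("genome(s) not found in sequence set: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  ids <- unique(c(pairs$virus_id, pairs$host_id))
  needed <- sequences[sequences$id %in% ids, , drop = FALSE]
  prof <- list(
    `2` = kmer_frequencies(needed, k = 2),
    `3` = kmer_frequencies(needed, k = 3))
  dist_k <- function(virus, host, k) {
    pk <- prof[[as.character(k)]]
    mapply(function(v, h) {
      usage_distance(pk[pk$sequence_id == v, ], pk[pk$sequence_id == h, ])
    }, virus, host, USE.NAMES = FALSE)
  }
  pairs <- tibble::as_tibble(pairs)
  pairs$d2 <- dist_k(pairs$virus_id, pairs$host_id, 2)
  pairs$d3 <- dist_k(pairs$virus_id, pairs$host_id, 3)
  pairs
}

#' Group summaries of usage distances
#'
#' Per group (e.g., per host, or per metagenome) and per word length,
#' reports the number of virus-host pairs, the mean distance, the standard
#' error of the mean (`sd/sqrt(n)`, 0 for singleton groups) and the
#' approximate 95% interval `mean +/- 2*SE`.
#'
#' @param pair_distances output of [usage_distance_pairs()] (columns `d2`,
#'   `d3` plus grouping columns).
#' @param group_by name of the grouping column (string).
#' @return A tibble with columns `group`, `k`, `n`, `mean`, `se`, `lower`,
#'   `upper`.
#' @export
summarize_pairs <- function(pair_distances, group_by) {
  stopifnot(is.data.frame(pair_distances),
            group_by %in% names(pair_distances),
            all(c("d2", "d3") %in% names(pair_distances)))
  long <- tidyr::pivot_longer(pair_distances, c("d2", "d3"),
                              names_to = "k", values_to = "distance")
  long$k <- as.integer(sub("^d", "", long$k))
  drop <- is.na(long$distance)
  if (any(drop)) {
    warning(sum(drop), " pair distance(s) missing; omitted from summaries",
            call. = FALSE)
    long <- long[!drop, , drop = FALSE]
  }
  long |>
    dplyr::group_by(group = .data[[group_by]], .data$k) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$distance),
      se = ifelse(dplyr::n() > 1, sd(.data$distance) / sqrt(dplyr::n()), 0),
      .groups = "drop") |>
    dplyr::mutate(lower = .data$mean - 2 * .data$se,
                  upper = .data$mean + 2 * .data$se)
}
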