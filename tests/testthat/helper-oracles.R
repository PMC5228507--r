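# Independent oracles used across the suite. These deliberately avoid the
# package's own C++ kernels: edit distances come from a small pure-R dynamic
# program (or utils::adist on N-free sequences), alignment identities from
# Biostrings, and chaining from exhaustive subset enumeration.

# Pure-R unit-cost edit distance; N never matches anything (itself included).
oracle_lev <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  d <- matrix(0L, m + 1, n + 1)
  d[, 1] <- 0:m; d[1, ] <- 0:n
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      cost <- if (a[i] == b[j] && a[i] != "N") 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j] + cost, d[i, j + 1] + 1L,
                             d[i + 1, j] + 1L)
    }
  }
  d[m + 1, n + 1]
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Naive substring-scan oracle for find_occurrences, N-free sequences only
# (distances via utils::adist, an independent C implementation of the same
# unit-cost edit distance). Per end position, the best candidate is
# (minimum edits, then the largest start = shortest span); overlapping
# candidates are then collapsed transitively with the same preference.
oracle_occurrences_one <- function(read, pattern, d_max) {
  n <- nchar(read); m <- nchar(pattern)
  lens <- max(1, m - d_max):(m + d_max)
  grid <- expand.grid(end = seq_len(n), len = lens)
  grid$start <- grid$end - grid$len + 1
  grid <- grid[grid$start >= 1, , drop = FALSE]
  grid$d <- drop(utils::adist(substring(read, grid$start, grid$end),
                              pattern))
  best <- stats::ave(grid$d, grid$end, FUN = min)
  grid <- grid[grid$d == best & grid$d <= d_max, , drop = FALSE]
  if (nrow(grid) > 0) {
    pick <- stats::ave(grid$start, grid$end, FUN = max)
    grid <- grid[grid$start == pick, , drop = FALSE]
  }
  cand <- data.frame(start = grid$start - 1L, end = grid$end,
                     edits = grid$d)
  # also the empty substring (relevant only for tiny patterns)
  if (m <= d_max) cand <- rbind(data.frame(start = 0L, end = 0L, edits = m),
                                cand)
  if (nrow(cand) == 0) {
    return(data.frame(start = integer(), end = integer(), edits = integer()))
  }
  cand <- cand[order(cand$start, cand$end), , drop = FALSE]
  grp <- cumsum(c(TRUE, cand$start[-1] >= cummax(cand$end)[-nrow(cand)]))
  keep <- vapply(split(seq_len(nrow(cand)), grp), function(idx) {
    s <- cand[idx, , drop = FALSE]
    idx[order(s$edits, s$end - s$start, s$start)[1]]
  }, integer(1))
  cand[sort(keep), , drop = FALSE]
}

oracle_occurrences <- function(read, queries, d_max, both_strands = TRUE) {
  out <- NULL
  for (q in seq_len(nrow(queries))) {
    for (strand in if (both_strands) c("+", "-") else "+") {
      pat <- if (strand == "+") queries$residues[q] else
        revcomp(queries$residues[q])
      cc <- oracle_occurrences_one(read, pat, d_max)
      if (nrow(cc) > 0) {
        cc$query_id <- queries$id[q]; cc$strand <- strand
        out <- rbind(out, cc)
      }
    }
  }
  if (is.null(out)) {
    return(data.frame(query_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      edits = integer()))
  }
  out[order(out$start, out$end, out$query_id, out$strand), ]
}

# Exhaustive chaining oracle: over all pairwise non-overlapping subsets of
# <= 12 matches, return the quality-lexicographic optimum (chains compared
# by their quality-sorted match keys element-wise; a proper prefix loses).
match_key <- function(m) {
  sprintf("%03d|%03d|%04d|%s|%s", m$edits, 999 - (m$end - m$start),
          m$start, m$query_id, m$strand)
}

oracle_chain <- function(matches) {
  n <- nrow(matches)
  stopifnot(n <= 12)
  best_sig <- NULL; best_idx <- integer(0)
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) > 1) {
      s <- matches$start[idx]; e <- matches$end[idx]
      o <- order(s)
      if (any(s[o][-1] < cummax(e[o])[-length(idx)])) next
    }
    sig <- sort(match_key(matches[idx, , drop = FALSE]))
    if (is.null(best_sig)) { best_sig <- sig; best_idx <- idx; next }
    k <- min(length(sig), length(best_sig))
    cmp <- 0L
    if (k > 0) {
      diff <- which(sig[seq_len(k)] != best_sig[seq_len(k)])
      if (length(diff) > 0) {
        cmp <- if (sig[diff[1]] < best_sig[diff[1]]) 1L else -1L
      }
    }
    if (cmp == 0L && length(sig) > length(best_sig)) cmp <- 1L
    if (cmp > 0L) { best_sig <- sig; best_idx <- idx }
  }
  out <- matches[best_idx, , drop = FALSE]
  out[order(out$start, out$end), , drop = FALSE]
}

# Minimum edits of any read substring ending (side = "left") or starting
# (side = "right") at pos against the pattern: the direct-DP audit of a
# reported spacer flank.
oracle_flank_edits <- function(read, pos, pattern, side, d_max) {
  m <- nchar(pattern)
  if (side == "left") {
    starts <- max(0, pos - m - d_max):max(0, pos - max(0, m - d_max))
    subs <- substring(read, starts + 1, pos)
  } else {
    ends <- min(nchar(read), pos + max(0, m - d_max)):
      min(nchar(read), pos + m + d_max)
    subs <- substring(read, pos + 1, ends)
  }
  min(vapply(subs, oracle_lev, integer(1), b = pattern))
}

# Biostrings maximal-identity global alignment (free gaps): the independent
# route to the identity numerator.
oracle_max_matches <- function(a, b) {
  skip_if_not_installed("Biostrings")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                  baseOnly = TRUE)
  as.integer(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 0,
    type = "global", scoreOnly = TRUE))
}

# Exhaustive all-diagonals ungapped scan: best (score, identities) between a
# query orientation and a subject.
oracle_best_ungapped <- function(q, s, match = 1, mismatch = -2) {
  qv <- strsplit(q, "")[[1]]; sv <- strsplit(s, "")[[1]]
  best <- -Inf
  for (d in (-(length(qv) - 1)):(length(sv) - 1)) {
    i <- max(1, 1 - d):min(length(qv), length(sv) - d)
    if (length(i) == 0) next
    v <- ifelse(qv[i] == sv[i + d] & qv[i] != "N", match, mismatch)
    cur <- 0; run_best <- -Inf
    for (x in v) {
      cur <- if (cur <= 0) x else cur + x
      run_best <- max(run_best, cur)
    }
    best <- max(best, run_best)
  }
  best
}

# A tiny deterministic fixture reused by several files.
make_fixture_queries <- function(n = 3, len = 30, seed = 11) {
  set.seed(seed)
  as_dr_queries(tibble::tibble(
    id = sprintf("Q%02d", seq_len(n)),
    residues = vapply(rep(len, n), random_seq, character(1)),
    host_taxon = sprintf("taxon_%d", seq_len(n))))
}
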