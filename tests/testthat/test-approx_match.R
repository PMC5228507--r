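test_that("levenshtein matches a pure-R dynamic program, with N rules", {
  expect_equal(levenshtein("ACGT", "ACGT"), 0)
  expect_equal(levenshtein("", "ACGT"), 4)
  expect_equal(levenshtein("ACGT", "AGGT"), 1)
  # N counts as a mismatch against everything, including N
  expect_equal(levenshtein("ANT", "ANT"), 1)
  expect_equal(levenshtein("N", "N"), 1)
  set.seed(21)
  for (i in 1:40) {
    a <- random_seq(sample(0:25, 1), c("A", "C", "G", "T", "N"))
    b <- random_seq(sample(0:25, 1), c("A", "C", "G", "T", "N"))
    expect_equal(levenshtein(a, b), oracle_lev(a, b))
    expect_equal(levenshtein(a, b), levenshtein(b, a))
  }
})

test_that("an exactly planted query yields exactly one exact match", {
  set.seed(31)
  q <- make_fixture_queries(1)
  read <- seq_tbl("r1", paste0(random_seq(50), q$residues[1],
                               random_seq(50)))
  hits <- find_occurrences(read, q, detection_params(d_max = 0))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 50)
  expect_equal(hits$end, 50 + nchar(q$residues[1]))
  expect_equal(hits$edits, 0)
  expect_equal(hits$strand, "+")
})

test_that("a single substitution is found at d_max 1 but not 0", {
  set.seed(32)
  q <- make_fixture_queries(1)
  mut <- q$residues[1]
  substr(mut, 15, 15) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 15, 15))[1]
  read <- seq_tbl("r1", paste0(random_seq(50), mut, random_seq(50)))
  h1 <- find_occurrences(read, q, detection_params(d_max = 1))
  expect_equal(nrow(h1), 1)
  expect_equal(h1$edits, 1)
  h0 <- find_occurrences(read, q, detection_params(d_max = 0))
  expect_equal(nrow(h0), 0)
})

test_that("reverse-complement occurrences respect the strand switch", {
  set.seed(33)
  q <- make_fixture_queries(1)
  read <- seq_tbl("r1", paste0(random_seq(40), revcomp(q$residues[1]),
                               random_seq(40)))
  h <- find_occurrences(read, q, detection_params(d_max = 0))
  expect_equal(h$strand, "-")
  h_fwd_only <- find_occurrences(
    read, q, detection_params(d_max = 0, both_strands = FALSE))
  expect_equal(nrow(h_fwd_only), 0)
})

test_that("find_occurrences equals the naive substring-scan oracle", {
  set.seed(34)
  for (i in 1:60) {
    d_max <- sample(0:3, 1)
    queries <- as_dr_queries(suppressWarnings(tibble::tibble(
      id = "q1", residues = random_seq(sample(23:47, 1)))))
    read <- seq_tbl("r1", random_seq(sample(60:300, 1)))
    got <- find_occurrences(read, queries, detection_params(d_max = d_max))
    want <- oracle_occurrences(read$residues, queries, d_max)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$edits, want$edits)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("reported matches re-verify by direct DP and respect monotonicity", {
  set.seed(35)
  q <- make_fixture_queries(2)
  reads <- seq_tbl(sprintf("r%d", 1:20),
                   vapply(rep(250, 20), random_seq, character(1)))
  # plant mutated copies in half the reads
  for (i in 1:10) {
    copy <- q$residues[1 + i %% 2]
    e <- i %% 4
    if (e > 0) {
      x <- strsplit(copy, "")[[1]]
      pos <- sample(5:(length(x) - 5), e)
      for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
      copy <- paste(x, collapse = "")
    }
    stringi::stri_sub(reads$residues[i], 100, 99 + nchar(copy)) <- copy
  }
  prev <- 0
  for (d in 0:3) {
    h <- find_occurrences(reads, q, detection_params(d_max = d))
    for (r in seq_len(nrow(h))) {
      pat <- q$residues[q$id == h$query_id[r]]
      if (h$strand[r] == "-") pat <- revcomp(pat)
      seg <- substr(reads$residues[reads$id == h$read_id[r]],
                    h$start[r] + 1, h$end[r])
      expect_equal(oracle_lev(seg, pat), h$edits[r])
    }
    expect_gte(nrow(h), prev)
    prev <- nrow(h)
  }
})

test_that("chaining keeps disjoint matches and resolves overlap by quality", {
  m <- tibble::tibble(read_id = "r1", query_id = c("a", "b"),
                      start = c(0, 60), end = c(30, 90),
                      strand = "+", edits = c(2, 0))
  expect_equal(nrow(chain_nonoverlapping(m)), 2)
  m$start <- c(0, 10); m$end <- c(30, 40)
  kept <- chain_nonoverlapping(m)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$edits, 0)
})

test_that("chaining equals the exhaustive subset oracle", {
  set.seed(36)
  for (i in 1:40) {
    n <- sample(3:9, 1)
    start <- sample(0:80, n, replace = TRUE)
    len <- sample(20:40, n, replace = TRUE)
    m <- tibble::tibble(read_id = "r1",
                        query_id = sample(c("a", "b", "c"), n, TRUE),
                        start = start, end = start + len,
                        strand = sample(c("+", "-"), n, TRUE),
                        edits = sample(0:3, n, TRUE))
    m <- m[!duplicated(m[, c("start", "end", "query_id", "strand")]), ]
    got <- chain_nonoverlapping(m)
    want <- oracle_chain(m)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$query_id, want$query_id)
    expect_equal(got$edits, want$edits)
  }
})
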