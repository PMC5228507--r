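# Build a read carrying DR (+ spacer + DR)* with given per-copy edits.
plant_array <- function(query, spacers, copy_edits = NULL, flank = 60,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_copies <- length(spacers) + 1
  if (is.null(copy_edits)) copy_edits <- rep(0, n_copies)
  copies <- vapply(copy_edits, function(e) {
    x <- strsplit(query, "")[[1]]
    if (e > 0) {
      pos <- sample(5:(length(x) - 5), e)
      for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
    }
    paste(x, collapse = "")
  }, character(1))
  parts <- character(2 * length(spacers) + 1)
  parts[seq(1, by = 2, length.out = n_copies)] <- copies
  if (length(spacers) > 0) {
    parts[seq(2, by = 2, length.out = length(spacers))] <- spacers
  }
  paste0(random_seq(flank), paste(parts, collapse = ""), random_seq(flank))
}

test_that("recruit_reads returns exactly the DR-containing reads", {
  set.seed(41)
  q <- make_fixture_queries(2)
  planted <- vapply(1:3, function(i) {
    plant_array(q$residues[1], random_seq(30))
  }, character(1))
  reads <- seq_tbl(sprintf("r%d", 1:10),
                   c(planted, vapply(rep(400, 7), random_seq, character(1))))
  rec <- recruit_reads(reads, q, detection_params(d_max = 0))
  expect_equal(sort(rec$id), c("r1", "r2", "r3"))
  expect_true(all(vapply(rec$matches, nrow, integer(1)) >= 1))
  expect_error(recruit_reads(reads[0, ], q), "empty")
})

test_that("recruitment at an exhausted edit budget finds nothing", {
  set.seed(42)
  q <- make_fixture_queries(1)
  reads <- seq_tbl("r1", plant_array(q$residues[1], random_seq(30),
                                     copy_edits = c(1, 1)))
  expect_equal(nrow(recruit_reads(reads, q, detection_params(d_max = 0))), 0)
  expect_equal(nrow(recruit_reads(reads, q, detection_params(d_max = 1))), 1)
})

test_that("call_spacers emits the planted inter-repeat fragments", {
  set.seed(43)
  q <- make_fixture_queries(1)
  s1 <- random_seq(30); s2 <- random_seq(40)
  reads <- seq_tbl(c("one", "two"),
                   c(plant_array(q$residues[1], s1),
                     plant_array(q$residues[1], c(s1, s2))))
  params <- detection_params(d_max = 0)
  chained <- chain_nonoverlapping(find_occurrences(reads, q, params))
  sp <- call_spacers(reads, chained, params)
  expect_equal(sp$residues[sp$read_id == "one"], s1)
  # a repeat triplet yields exactly two spacers, not three
  expect_equal(sp$residues[sp$read_id == "two"], c(s1, s2))
})

test_that("repeat pairs further apart than max_spacer are not spacers", {
  set.seed(44)
  q <- make_fixture_queries(1)
  reads <- seq_tbl("r1", plant_array(q$residues[1], random_seq(70)))
  params <- detection_params(d_max = 0, max_spacer = 60)
  chained <- chain_nonoverlapping(find_occurrences(reads, q, params))
  expect_equal(nrow(call_spacers(reads, chained, params)), 0)
  wide <- detection_params(d_max = 0, max_spacer = 80)
  expect_equal(nrow(call_spacers(reads, chained, wide)), 1)
})

test_that("minus-strand spacers come back in query orientation", {
  set.seed(45)
  q <- make_fixture_queries(1)
  s <- random_seq(34)
  fwd <- plant_array(q$residues[1], s)
  reads <- seq_tbl("r1", revcomp(fwd))
  sp <- detect_spacers(reads, q, detection_params(d_max = 0))
  expect_equal(nrow(sp), 1)
  expect_equal(sp$residues, s)
  expect_equal(spacer_provenance(sp)$strand, "-")
})

test_that("duplicate spacers collapse with full provenance retained", {
  set.seed(46)
  q <- make_fixture_queries(1)
  s <- random_seq(32)
  reads <- seq_tbl(sprintf("r%d", 1:5),
                   vapply(1:5, function(i) {
                     plant_array(q$residues[1], s)
                   }, character(1)))
  sp <- detect_spacers(reads, q, detection_params(d_max = 0))
  expect_equal(nrow(sp), 1)
  expect_equal(sp$n_occurrences, 5)
  expect_equal(nrow(spacer_provenance(sp)), 5)
  expect_equal(sp$host_taxon, "taxon_1")
})

test_that("detection is deterministic: identical runs, identical FASTA", {
  set.seed(47)
  q <- make_fixture_queries(2)
  reads <- seq_tbl(sprintf("r%d", 1:6),
                   vapply(1:6, function(i) {
                     plant_array(q$residues[1 + i %% 2],
                                 random_seq(28 + i),
                                 copy_edits = c(i %% 3, 0))
                   }, character(1)))
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_spacers(detect_spacers(reads, q), f1)
  write_spacers(detect_spacers(reads, q), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("shared spacer counting is strand-aware as configured", {
  s <- "ACCGTTAGGCATTCCGGATACCGGTANAT"
  expect_equal(nrow(shared_spacers(c("AAAA"), c("TTTT"),
                                   strand_insensitive = FALSE)), 0)
  expect_equal(nrow(shared_spacers(s, revcomp(s))), 1)
  expect_equal(nrow(shared_spacers(s, revcomp(s),
                                   strand_insensitive = FALSE)), 0)
  set.seed(48)
  a <- vapply(rep(30, 20), random_seq, character(1))
  b <- c(sample(a, 8), vapply(rep(30, 12), random_seq, character(1)))
  expect_lte(nrow(shared_spacers(a, b)), min(length(unique(a)),
                                             length(unique(b))))
  expect_gte(nrow(shared_spacers(a, b)), 8)
})

test_that("spacer_rate normalizes to spacers per million reads", {
  expect_equal(spacer_rate(9, 1.5e6), 6.0)
  expect_equal(spacer_rate(0, 12345), 0)
  expect_equal(spacer_rate(80, 971000), 80 / 0.971, tolerance = 1e-12)
  expect_error(spacer_rate(1, 0), "positive")
})
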