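small_sim_params <- function(seed = 9, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_queries = 5, n_viruses = 4,
         virus_length = c(3000, 8000), n_array_reads = 12,
         n_background_reads = 25),
    list(...))
  do.call(sim_params, args)
}

test_that("virus simulation is reproducible and respects its parameters", {
  p <- small_sim_params()
  v1 <- simulate_viruses(p)
  v2 <- simulate_viruses(p)
  expect_identical(v1, v2)
  expect_equal(nrow(v1), 4)
  expect_true(all(nchar(v1$residues) >= 3000 & nchar(v1$residues) <= 8000))
  v3 <- simulate_viruses(sim_params(seed = 10, n_viruses = 4,
                                    virus_length = c(3000, 8000)))
  expect_false(identical(v1$residues, v3$residues))
  # GC within 3 sd of the binomial expectation at gc = 0.5
  L <- sum(nchar(v1$residues))
  gc_obs <- sum(stringr::str_count(v1$residues, "[GC]"))
  expect_lt(abs(gc_obs - 0.5 * L), 3 * sqrt(L * 0.25))
})

test_that("planted truth is self-consistent: spacers, coordinates, edits", {
  sim <- simulate_metagenome(small_sim_params())
  expect_equal(nrow(sim$reads), 12 + 25)
  expect_gte(nrow(sim$truth), 12)
  res <- setNames(sim$viruses$residues, sim$viruses$id)
  for (i in seq_len(nrow(sim$truth))) {
    t <- sim$truth[i, ]
    expect_equal(stringi::stri_sub(res[[t$virus_id]], t$virus_start + 1,
                                   t$virus_end),
                 t$spacer_residues)
  }
  # recorded DR-copy edits re-verify by direct DP via the detection route
  params <- detection_params(d_max = 3)
  occ <- chain_nonoverlapping(find_occurrences(sim$reads, sim$queries,
                                               params))
  reads <- setNames(sim$reads$residues, sim$reads$id)
  for (r in seq_len(nrow(occ))) {
    pat <- sim$queries$residues[sim$queries$id == occ$query_id[r]]
    if (occ$strand[r] == "-") pat <- revcomp(pat)
    seg <- substr(reads[[occ$read_id[r]]], occ$start[r] + 1, occ$end[r])
    expect_equal(oracle_lev(seg, pat), occ$edits[r])
  }
})

test_that("zero-mutation plantings embed the query verbatim", {
  sim <- simulate_metagenome(small_sim_params(dr_mutation_edits = 0))
  expect_true(all(sim$truth$edits_left == 0 & sim$truth$edits_right == 0))
  qres <- setNames(sim$queries$residues, sim$queries$id)
  occ <- find_occurrences(sim$reads, sim$queries,
                          detection_params(d_max = 0))
  planted_reads <- unique(sim$truth$read_id)
  expect_setequal(intersect(unique(occ$read_id), planted_reads),
                  planted_reads)
  expect_true(all(occ$edits == 0))
})

test_that("background reads are repeat-free and the mixture is shuffled", {
  sim <- simulate_metagenome(small_sim_params())
  bg <- sim$reads[startsWith(sim$reads$id, "bg_read"), ]
  occ <- find_occurrences(bg, sim$queries, detection_params(d_max = 3))
  expect_equal(nrow(occ), 0)
  expect_false(identical(sim$reads$id, sort(sim$reads$id)))
  # read lengths: mean within 3 sd of the configured mean
  arr <- sim$reads[!startsWith(sim$reads$id, "bg_read"), ]
  lens <- nchar(bg$residues)
  expect_lt(abs(mean(lens) - 480), 3 * 40 / sqrt(length(lens)) + 5)
})

test_that("simulation output files are byte-identical for a fixed seed", {
  p <- small_sim_params(n_background_reads = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_metagenome(p), d1)
  write_simulation(simulate_metagenome(p), d2)
  for (f in c("reads.fasta", "viruses.fasta", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # FASTQ flavour round-trips through the FASTQ reader
  write_simulation(simulate_metagenome(p), d1, fastq = TRUE)
  rq <- read_fastq(file.path(d1, "reads.fastq"))
  expect_equal(sort(rq$id), sort(simulate_metagenome(p)$reads$id))
})

test_that("score_detection applies the budget to the eligible denominator", {
  sim <- simulate_metagenome(small_sim_params(seed = 14))
  sp3 <- detect_spacers(sim$reads, sim$queries, detection_params(d_max = 3))
  s3 <- score_detection(sim$truth, sp3, d_max = 3, reads = sim$reads)
  expect_equal(s3$recall, 1.0)
  expect_equal(s3$precision, 1.0)
  expect_equal(s3$n_detectable, nrow(sim$truth))

  sp1 <- detect_spacers(sim$reads, sim$queries, detection_params(d_max = 1))
  s1 <- score_detection(sim$truth, sp1, d_max = 1, reads = sim$reads)
  eligible1 <- sum(sim$truth$edits_left <= 1 & sim$truth$edits_right <= 1)
  expect_equal(s1$n_detectable, eligible1)
  expect_equal(s1$recall, 1.0)

  # empty detection: precision reported as 1 with the n_detected = 0 flag
  sp_none <- detect_spacers(sim$reads[startsWith(sim$reads$id, "bg_read"), ],
                            sim$queries, detection_params(d_max = 0))
  s0 <- score_detection(sim$truth, sp_none, d_max = 0)
  expect_equal(s0$n_detected, 0)
  expect_equal(s0$precision, 1.0)
  eligible0 <- sum(sim$truth$edits_left == 0 & sim$truth$edits_right == 0)
  expect_equal(s0$recall, if (eligible0 > 0) 0 else NA_real_)

  expect_error(score_detection(sim$truth, sp3, d_max = 3,
                               reads = sim$reads[1:3, ]),
               "read universes")
})
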