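test_that("Karlin lambda solves the scoring-system equation", {
  lam <- karlin_lambda(1, -2)
  expect_equal(exp(lam) / 4 + 3 * exp(-2 * lam) / 4, 1, tolerance = 1e-9)
  expect_gt(lam, 0)
})

test_that("E-value formula: value at S = 0, monotonicity and linearity", {
  p <- align_params(lambda = 1.0, kappa = 0.5)
  expect_equal(evalue(0, 30, 1000, p), 0.5 * 30 * 1000)
  expect_equal(evalue(10, 30, 1000, p), 0.5 * 30 * 1000 * exp(-10))
  expect_equal(evalue(10, 30, 1000, p), 0.681, tolerance = 1e-3)
  # grid: decreasing in S, linear in n and in m
  for (s in c(0, 5, 12, 30)) {
    expect_gt(evalue(s, 30, 1000, p), evalue(s + 1, 30, 1000, p))
    expect_equal(evalue(s, 30, 2000, p), 2 * evalue(s, 30, 1000, p))
    expect_equal(evalue(s, 60, 1000, p), 2 * evalue(s, 30, 1000, p))
  }
  expect_error(evalue(1, 0, 100, p), "positive")
})

test_that("a planted protospacer is recovered exactly, strand and all", {
  set.seed(61)
  virus <- seq_tbl("v1", random_seq(5000))
  sp_fwd <- substr(virus$residues, 2001, 2030)
  hits <- align_spacers(tibble::tibble(id = "s1", residues = sp_fwd), virus,
                        align_params())
  top <- hits[1, ]
  expect_equal(top$identities, 30)
  expect_equal(top$mismatches, 0)
  expect_equal(top$strand, "+")
  expect_equal(top$subject_start, 2000)
  expect_equal(top$subject_end, 2030)
  # reverse-complement planting maps to the minus strand, same interval
  hits_rc <- align_spacers(tibble::tibble(id = "s1",
                                          residues = revcomp(sp_fwd)),
                           virus, align_params())
  expect_equal(hits_rc$strand[1], "-")
  expect_equal(hits_rc$subject_start[1], 2000)
  expect_equal(hits_rc$subject_end[1], 2030)
})

test_that("no shared seed means no hits; short spacers warn", {
  virus <- seq_tbl("v1", strrep("AC", 1000))
  expect_equal(nrow(align_spacers(tibble::tibble(id = "s1",
                                                 residues = strrep("G", 30)),
                                  virus, align_params())), 0)
  expect_warning(
    align_spacers(tibble::tibble(id = c("tiny", "ok"),
                                 residues = c("ACGTACG", strrep("AC", 15))),
                  virus, align_params()),
    "seed length")
})

test_that("best hit per subject equals the exhaustive diagonal-scan oracle", {
  set.seed(62)
  for (i in 1:8) {
    virus <- seq_tbl("v1", random_seq(4000))
    spacer <- substr(virus$residues, 1001, 1034)
    # plant 2 central mismatches
    x <- strsplit(spacer, "")[[1]]
    for (p in c(16, 18)) x[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                x[p]), 1)
    spacer <- paste(x, collapse = "")
    hits <- align_spacers(tibble::tibble(id = "s1", residues = spacer),
                          virus, align_params())
    want <- max(oracle_best_ungapped(spacer, virus$residues),
                oracle_best_ungapped(revcomp(spacer), virus$residues))
    expect_equal(max(hits$score), want)
  }
})

test_that("tabular hit ingestion converts coordinates and filters by E", {
  path <- withr::local_tempfile(fileext = ".tsv")
  rows <- c(
    "s1\tv1\t100.00\t30\t0\t0\t1\t30\t101\t130\t1e-05\t60.0",
    "s1\tv2\t96.67\t30\t1\t0\t1\t30\t100\t71\t2e-04\t52.0",
    "s2\tv1\t90.00\t30\t3\t0\t1\t30\t501\t530\t1e-02\t40.0")
  writeLines(rows, path)
  expect_message(read_tabular_hits(path, 1e-3), "1 hit")
  hits <- suppressMessages(read_tabular_hits(path, 1e-3))
  expect_equal(nrow(hits), 2)
  expect_equal(attr(hits, "n_dropped"), 1)
  minus <- hits[hits$subject_id == "v2", ]
  expect_equal(minus$strand, "-")
  expect_equal(minus$subject_start, 70)
  expect_equal(minus$subject_end, 100)
  expect_equal(minus$identities, 29)
  plus <- hits[hits$subject_id == "v1", ]
  expect_equal(plus$subject_start, 100)
  expect_equal(plus$spacer_start, 0)
  writeLines("s1\tv1\tbroken", path)
  expect_error(read_tabular_hits(path), "12 tab-separated")
})

test_that("network edges aggregate hits and carry only the DR's host label", {
  hits <- tibble::tibble(
    spacer_id = c("a", "a", "a", "b"),
    subject_id = c("v1", "v1", "v2", "v2"),
    evalue = c(1e-6, 1e-4, 1e-5, 1e-7))
  spac <- tibble::tibble(spacer_id = c("a", "b"),
                         host_taxon = c("Haloquadratum", "unknown"))
  net <- build_network(hits, spac)
  expect_equal(nrow(net), 3)                     # a-v1, a-v2, b-v2
  a_v1 <- net[net$spacer_id == "a" & net$virus_id == "v1", ]
  expect_equal(a_v1$n_hits, 2)
  expect_equal(a_v1$best_evalue, 1e-6)
  expect_equal(sum(net$virus_id == "v2"), 2)     # hub virus, degree 2
  expect_equal(net$host_taxon[net$spacer_id == "b"], c("unknown"))
  expect_error(build_network(hits, spac[1, ]), "unknown spacer id")
})

test_that("network files round-trip the edge multiset, including empty", {
  hits <- tibble::tibble(spacer_id = c("a", "b"), subject_id = "v1",
                         evalue = c(1e-6, 1e-8))
  spac <- tibble::tibble(spacer_id = c("a", "b"), host_taxon = "t1")
  net <- build_network(hits, spac)
  dir <- withr::local_tempdir()
  write_network(net, file.path(dir, "net"))
  sif <- read.table(file.path(dir, "net.sif"), sep = "\t")
  expect_equal(nrow(sif), 2)
  edges <- readr::read_tsv(file.path(dir, "net.edges.tsv"),
                           show_col_types = FALSE)
  expect_setequal(paste(edges$spacer_id, edges$virus_id),
                  paste(net$spacer_id, net$virus_id))
  nodes <- readr::read_tsv(file.path(dir, "net.nodes.tsv"),
                           show_col_types = FALSE)
  expect_setequal(nodes$type, c("spacer", "virus"))
  expect_true(all(grepl("^t1 \\(", nodes$label[nodes$type == "spacer"])))

  write_network(net[0, ], file.path(dir, "empty"))
  expect_equal(length(readLines(file.path(dir, "empty.sif"))), 0)
  expect_equal(nrow(readr::read_tsv(file.path(dir, "empty.edges.tsv"),
                                    show_col_types = FALSE)), 0)
})
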