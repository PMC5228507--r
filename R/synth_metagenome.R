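#' Simulation parameters
#'
#' Conditions of the synthetic study: pyrosequencing-style read lengths
#' (normal, mean 480 bp, sd 40, truncated at 100 bp, emulating the
#' 429-523 bp per-site averages of the saltern metagenomes this package's
#' defaults are anchored to), a query set of 29 direct repeats (the size
#' of the halobacterial query set used in the original study), planted
#' repeat-spacer-repeat arrays whose repeat copies carry an exact,
#' recorded number of edits, spacers excised from simulated viral
#' genomes, and a repeat-free random background.
#'
#' @param seed integer RNG seed; every artifact of the generator is a pure
#'   function of (params, seed).
#' @param n_queries number of synthetic query DRs (default 29).
#' @param query_length range of DR lengths, bp (default the empirical
#'   23-47 range).
#' @param n_viruses,virus_length viral library size and genome length
#'   range, bp.
#' @param n_array_reads,n_background_reads mixture composition.
#' @param read_length_mean,read_length_sd,read_length_min read length
#'   distribution (normal, truncated below).
#' @param dr_mutation_edits maximum edits per planted DR copy; each copy
#'   draws `e` uniformly from `0:dr_mutation_edits` and receives *exactly*
#'   `e` edits (so detectability at every budget is knowable a priori).
#' @param spacer_length planted spacer length range, bp.
#' @param spacers_per_array range of spacers per planted array (2 spacers
#'   means 3 repeat copies in one read).
#' @param gc GC content of simulated genomes, background reads and flanks.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(seed = 1L, n_queries = 29, query_length = c(23, 47),
                       n_viruses = 10, virus_length = c(5000, 50000),
                       n_array_reads = 50, n_background_reads = 950,
                       read_length_mean = 480, read_length_sd = 40,
                       read_length_min = 100, dr_mutation_edits = 3,
                       spacer_length = c(26, 50),
                       spacers_per_array = c(1, 2), gc = 0.5) {
  stopifnot(n_queries >= 1, n_viruses >= 0, n_array_reads >= 0,
            n_background_reads >= 0, dr_mutation_edits >= 0,
            spacer_length[1] <= spacer_length[2], gc > 0, gc < 1,
            read_length_min > 0)
  structure(list(seed = as.integer(seed), n_queries = as.integer(n_queries),
                 query_length = as.integer(query_length),
                 n_viruses = as.integer(n_viruses),
                 virus_length = as.integer(virus_length),
                 n_array_reads = as.integer(n_array_reads),
                 n_background_reads = as.integer(n_background_reads),
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 read_length_min = as.integer(read_length_min),
                 dr_mutation_edits = as.integer(dr_mutation_edits),
                 spacer_length = as.integer(spacer_length),
                 spacers_per_array = as.integer(spacers_per_array),
                 gc = gc),
            class = "sim_params")
}

random_dna <- function(n, len, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(rep_len(len, n), function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# Apply exactly e edit operations (substitution/insertion/deletion, interior
# positions only) and re-verify the Levenshtein distance equals e; redraw on
# the rare cancelling combinations. Interior placement keeps the terminal
# bases of a mutated repeat copy exact, so the planted boundary is the
# minimal-edit boundary.
mutate_exact <- function(s, e, gc, margin = 4) {
  if (e == 0) return(s)
  bases <- c("A", "C", "G", "T")
  for (try in 1:200) {
    x <- strsplit(s, "")[[1]]
    for (k in seq_len(e)) {
      lo <- margin + 1; hi <- length(x) - margin
      if (hi < lo) { lo <- 2; hi <- length(x) - 1 }
      pos <- sample(lo:hi, 1)
      op <- sample(c("sub", "ins", "del"), 1)
      if (op == "sub") {
        x[pos] <- sample(setdiff(bases, x[pos]), 1)
      } else if (op == "ins") {
        x <- append(x, sample(bases, 1), after = pos)
      } else {
        x <- x[-pos]
      }
    }
    out <- paste(x, collapse = "")
    if (cpp_levenshtein(out, s) == e) return(out)
  }
  stop("could not realize an exact-", e, "-edit mutation", call. = FALSE)
}

#' Simulate a synthetic query DR set
#'
#' @param params a [sim_params()] object; uses `n_queries`, `query_length`,
#'   `gc` and `seed`.
#' @return A DR query tibble with synthetic host-taxon labels
#'   (`taxon_01`, ...).
#' @export
simulate_dr_queries <- function(params = sim_params()) {
  set.seed(params$seed)
  sim_dr_queries_impl(params)
}

sim_dr_queries_impl <- function(params) {
  lens <- sample(params$query_length[1]:params$query_length[2],
                 params$n_queries, replace = TRUE)
  as_dr_queries(tibble::tibble(
    id = sprintf("DR_%02d", seq_len(params$n_queries)),
    residues = random_dna(params$n_queries, lens, params$gc),
    host_taxon = sprintf("taxon_%02d",
                         1 + (seq_len(params$n_queries) - 1) %% 6)))
}

#' Simulate a viral genome library
#'
#' @param params a [sim_params()] object.
#' @return A sequence tibble of `n_viruses` i.i.d. genomes at the stated GC
#'   with lengths uniform in `virus_length`; byte-identical for a fixed
#'   seed.
#' @export
simulate_viruses <- function(params = sim_params()) {
  set.seed(params$seed)
  sim_viruses_impl(params)
}

sim_viruses_impl <- function(params) {
  stopifnot(params$n_viruses >= 1)
  lens <- sample(params$virus_length[1]:params$virus_length[2],
                 params$n_viruses, replace = TRUE)
  tibble::tibble(id = sprintf("virus_%03d", seq_len(params$n_viruses)),
                 description = "synthetic viral genome",
                 residues = random_dna(params$n_viruses, lens, params$gc))
}

# Verify a planted read against the detector's own geometry: the chained
# match set for the full query collection must equal the planted repeat
# copies (interval, edits, query, strand). Reads whose mutated repeats admit
# an equally parsimonious alternative boundary (or whose random flanks or
# excised spacers contain a chance repeat occurrence) are rejected, keeping
# the truth manifest exact.
verify_planted <- function(read_tbl, queries, planted, d_max) {
  occ <- find_occurrences(read_tbl, queries,
                          detection_params(d_max = d_max))
  chained <- chain_nonoverlapping(occ)
  if (nrow(chained) != nrow(planted)) return(FALSE)
  all(chained$query_id == planted$query_id,
      chained$start == planted$start,
      chained$end == planted$end,
      chained$edits == planted$edits,
      chained$strand == planted$strand)
}

# One planted array read plus its truth rows. RNG state is the caller's.
sim_array_read_impl <- function(read_id, queries, viruses, params,
                                verify_budget) {
  for (try in 1:50) {
    qi <- sample(nrow(queries), 1)
    query <- queries$residues[qi]
    n_sp <- sample(params$spacers_per_array[1]:params$spacers_per_array[2], 1)
    n_copies <- n_sp + 1
    copy_edits <- sample(0:params$dr_mutation_edits, n_copies, replace = TRUE)
    copies <- vapply(copy_edits, function(e) mutate_exact(query, e, params$gc),
                     character(1))
    vi <- sample(nrow(viruses), n_sp, replace = TRUE)
    sp_len <- sample(params$spacer_length[1]:params$spacer_length[2], n_sp,
                     replace = TRUE)
    v_start <- vapply(seq_len(n_sp), function(j) {
      sample(nchar(viruses$residues[vi[j]]) - sp_len[j], 1)
    }, integer(1)) - 1L  # 0-based
    spacers <- vapply(seq_len(n_sp), function(j) {
      stringi::stri_sub(viruses$residues[vi[j]], v_start[j] + 1,
                        length = sp_len[j])
    }, character(1))
    parts <- character(2 * n_sp + 1)
    parts[seq(1, by = 2, length.out = n_copies)] <- copies
    parts[seq(2, by = 2, length.out = n_sp)] <- spacers
    array_seq <- paste(parts, collapse = "")
    arr_len <- nchar(array_seq)
    read_len <- max(round(rnorm(1, params$read_length_mean,
                                params$read_length_sd)),
                    params$read_length_min, arr_len + 10)
    flank_total <- read_len - arr_len
    left_len <- sample(0:flank_total, 1)
    read_fwd <- paste0(random_dna(1, left_len, params$gc), array_seq,
                       random_dna(1, flank_total - left_len, params$gc))
    strand <- sample(c("+", "-"), 1)
    read_seq <- if (strand == "+") read_fwd else revcomp(read_fwd)
    # planted repeat-copy intervals in final read coordinates
    cum <- cumsum(c(0, nchar(parts)))
    copy_idx <- seq(1, by = 2, length.out = n_copies)
    fwd_start <- cum[copy_idx]; fwd_end <- cum[copy_idx + 1]
    fwd_start <- fwd_start + left_len; fwd_end <- fwd_end + left_len
    if (strand == "+") {
      c_start <- fwd_start; c_end <- fwd_end
      c_edits <- copy_edits
    } else {
      c_start <- rev(read_len - fwd_end); c_end <- rev(read_len - fwd_start)
      c_edits <- rev(copy_edits)
    }
    planted <- tibble::tibble(query_id = queries$id[qi], start = c_start,
                              end = c_end, edits = c_edits, strand = strand)
    read_tbl <- tibble::tibble(id = read_id, description = "planted array",
                               residues = read_seq)
    if (!verify_planted(read_tbl, queries, planted, verify_budget)) next
    i <- seq_len(n_sp)
    truth <- tibble::tibble(
      read_id = read_id, query_id = queries$id[qi], strand = strand,
      spacer_index = i, spacer_residues = spacers,
      virus_id = viruses$id[vi], virus_start = v_start,
      virus_end = v_start + sp_len,
      edits_left = copy_edits[i], edits_right = copy_edits[i + 1],
      detectable = TRUE)
    return(list(read = read_tbl, truth = truth))
  }
  stop("failed to plant an unambiguous array read after 50 attempts",
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a synthetic metagenome with planted CRISPR arrays
#'
#' Generates (or accepts) a query DR set and a viral library, plants
#' `n_array_reads` reads each carrying a repeat-spacer-repeat array (repeat
#' copies independently mutated by an exact, recorded number of edits;
#' spacers excised from the viral genomes at recorded coordinates; the
#' whole array on either strand), adds `n_background_reads` repeat-free
#' background reads (rejection-sampled so no background read contains any
#' query within the admissible edit budget), shuffles the mixture, and
#' returns the truth manifest. Fixed seed implies byte-identical output.
#'
#' @param params a [sim_params()] object.
#' @param queries optional DR query tibble (generated from `params` when
#'   `NULL`).
#' @param viruses optional virus library (generated when `NULL`).
#' @return A list of class `crisprscout_sim` with elements `reads`,
#'   `queries`, `viruses` (sequence tibbles), `truth` (one row per planted
#'   spacer) and `params`.
#' @export
simulate_metagenome <- function(params = sim_params(), queries = NULL,
                                viruses = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  if (is.null(queries)) queries <- sim_dr_queries_impl(params)
  if (is.null(viruses)) viruses <- sim_viruses_impl(params)
  verify_budget <- max(3L, params$dr_mutation_edits)
  array_out <- lapply(seq_len(params$n_array_reads), function(i) {
    sim_array_read_impl(sprintf("array_read_%04d", i), queries, viruses,
                        params, verify_budget)
  })
  bg <- character(params$n_background_reads)
  qres <- queries$residues
  for (i in seq_len(params$n_background_reads)) {
    repeat {
      L <- max(round(rnorm(1, params$read_length_mean,
                           params$read_length_sd)), params$read_length_min)
      cand <- random_dna(1, L, params$gc)
      if (!cpp_has_occurrence(cand, qres, verify_budget, TRUE)) break
    }
    bg[i] <- cand
  }
  reads <- dplyr::bind_rows(
    dplyr::bind_rows(lapply(array_out, `[[`, "read")),
    tibble::tibble(id = sprintf("bg_read_%04d",
                                seq_len(params$n_background_reads)),
                   description = "background", residues = bg))
  reads <- reads[sample(nrow(reads)), , drop = FALSE]
  truth <- dplyr::bind_rows(lapply(array_out, `[[`, "truth"))
  structure(list(reads = tibble::as_tibble(reads), queries = queries,
                 viruses = viruses, truth = truth, params = params),
            class = "crisprscout_sim")
}

#' Write a simulated metagenome to disk
#'
#' Writes `reads.fasta` (or `reads.fastq` with dummy qualities),
#' `viruses.fasta`, `queries.tsv`, `truth.tsv` and `params.json` under
#' `dir`.
#'
#' @param sim a `crisprscout_sim` object.
#' @param dir output directory (created if needed).
#' @param fastq write reads as FASTQ with constant dummy qualities?
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir, fastq = FALSE) {
  stopifnot(inherits(sim, "crisprscout_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reads = file.path(dir, if (fastq) "reads.fastq" else "reads.fasta"),
    viruses = file.path(dir, "viruses.fasta"),
    queries = file.path(dir, "queries.tsv"),
    truth = file.path(dir, "truth.tsv"),
    params = file.path(dir, "params.json"))
  if (fastq) {
    qual <- vapply(nchar(sim$reads$residues),
                   function(n) strrep("I", n), character(1))
    writeLines(paste0("@", sim$reads$id, "\n", sim$reads$residues, "\n+\n",
                      qual), paths[["reads"]])
  } else {
    write_fasta(sim$reads, paths[["reads"]])
  }
  write_fasta(sim$viruses, paths[["viruses"]])
  readr::write_tsv(sim$queries, paths[["queries"]], progress = FALSE)
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  jsonlite::write_json(unclass(sim$params), paths[["params"]],
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Score a detection run against the truth manifest
#'
#' Recall is the fraction of budget-detectable plantings (geometry
#' detectable and both flanking repeat copies within `d_max` edits) whose
#' exact spacer sequence was detected in the correct read; precision is
#' the fraction of detected spacers tracing back to a planting. When
#' nothing was detected, precision is reported as 1.0 with
#' `n_detected = 0` flagging the convention.
#'
#' @param truth the truth tibble of a `crisprscout_sim`.
#' @param spacers a `crisprscout_spacers` tibble detected on the same read
#'   set.
#' @param d_max the edit budget the detector ran with.
#' @param reads optional read tibble; when supplied, truth and detection
#'   read ids are checked against it and a mismatch is an error.
#' @return A one-row tibble: `n_detectable`, `n_detected_plantings`,
#'   `recall`, `n_detected`, `n_traced`, `precision`; the per-planting
#'   diagnostic table is attached as attribute `"per_planting"`.
#' @export
score_detection <- function(truth, spacers, d_max = 3, reads = NULL) {
  stopifnot(is.data.frame(truth), inherits(spacers, "crisprscout_spacers"))
  prov <- spacer_provenance(spacers)
  det <- dplyr::left_join(prov, spacers[, c("spacer_id", "residues")],
                          by = "spacer_id")
  if (!is.null(reads)) {
    if (length(setdiff(truth$read_id, reads$id)) > 0 ||
        length(setdiff(det$read_id, reads$id)) > 0) {
      stop("truth and detection reference different read universes",
           call. = FALSE)
    }
  }
  eligible <- truth$detectable & truth$edits_left <= d_max &
    truth$edits_right <= d_max
  key <- function(rid, res) paste(rid, res, sep = "\r")
  det_keys <- key(det$read_id, det$residues)
  per <- tibble::tibble(
    read_id = truth$read_id, spacer_index = truth$spacer_index,
    eligible = eligible,
    detected = key(truth$read_id, truth$spacer_residues) %in% det_keys)
  truth_keys <- key(truth$read_id, truth$spacer_residues)
  traced <- vapply(split(det_keys %in% truth_keys, det$spacer_id), any,
                   logical(1))
  n_detected <- nrow(spacers)
  out <- tibble::tibble(
    n_detectable = sum(eligible),
    n_detected_plantings = sum(per$detected & per$eligible),
    recall = ifelse(sum(eligible) > 0,
                    sum(per$detected & per$eligible) / sum(eligible), NA),
    n_detected = n_detected,
    n_traced = sum(traced),
    precision = ifelse(n_detected > 0, sum(traced) / n_detected, 1.0))
  attr(out, "per_planting") <- per
  out
}
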