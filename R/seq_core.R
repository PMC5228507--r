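#' Sequence tables
#'
#' Sequences move through the pipeline as plain tibbles with columns `id`
#' (unique within a table), `description` (free text, may be empty) and
#' `residues` (uppercase string over the alphabet A, C, G, T, N). All
#' coordinates anywhere in the package are 0-based, half-open `[start, end)`.
#'
#' @param id character vector of unique sequence identifiers.
#' @param residues character vector of sequences over `{A,C,G,T,N}`
#'   (lowercase accepted and uppercased).
#' @param description optional character vector of free-text descriptions.
#' @return A tibble with columns `id`, `description`, `residues`.
#' @examples
#' seq_tbl(c("s1", "s2"), c("acgt", "TTTT"))
#' @export
seq_tbl <- function(id, residues, description = "") {
  out <- tibble::tibble(
    id = as.character(id),
    description = rep_len(as.character(description), length(id)),
    residues = toupper(as.character(residues))
  )
  validate_seq_tbl(out)
}

validate_seq_tbl <- function(x, source = "sequence table") {
  stopifnot(is.data.frame(x), all(c("id", "residues") %in% names(x)))
  if (!"description" %in% names(x)) x$description <- ""
  if (nrow(x) == 0) stop(source, " is empty", call. = FALSE)
  if (any(!nzchar(x$id))) stop("empty sequence id in ", source, call. = FALSE)
  dup <- x$id[duplicated(x$id)]
  if (length(dup) > 0) {
    stop("duplicate sequence id(s) in ", source, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(x$residues))) {
    stop("empty residues for record '", x$id[!nzchar(x$residues)][1],
         "' in ", source, call. = FALSE)
  }
  bad <- stringr::str_locate(x$residues, "[^ACGTN]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    stop("invalid residue in record '", x$id[i], "' at position ", bad[i],
         " (alphabet is A, C, G, T, N)", call. = FALSE)
  }
  tibble::as_tibble(x[c("id", "description", "residues")])
}

#' Read a FASTA file
#'
#' @param path path to a (multi-record, possibly line-wrapped) FASTA file.
#' @return A sequence tibble (see [seq_tbl()]); record order is preserved,
#'   residues are uppercased.
#' @details Records with residues outside `{A,C,G,T,N}` raise an error naming
#'   the record and offending position; duplicate ids and empty files are
#'   errors.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) stop("not a FASTA file (first line is not a header): ", path,
                       call. = FALSE)
  rec <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- vapply(split(lines[!is_hdr], rec[!is_hdr]),
                     paste0, character(1), collapse = "")
  residues <- residues[as.character(seq_along(headers))]
  residues[is.na(residues)] <- ""
  out <- tibble::tibble(id = id, description = description,
                        residues = toupper(unname(residues)))
  validate_seq_tbl(out, source = paste0("FASTA file '", path, "'"))
}

#' Read a FASTQ file (qualities are discarded)
#'
#' The pipeline operates on base calls only, so quality strings are checked
#' for length consistency and then dropped.
#'
#' @param path path to a 4-line-per-record FASTQ file.
#' @return A sequence tibble, same contracts as [read_fasta()].
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) stop("empty FASTQ file: ", path, call. = FALSE)
  if (length(lines) %% 4 != 0) {
    stop("truncated FASTQ record ", length(lines) %/% 4 + 1, " in ", path,
         call. = FALSE)
  }
  n <- length(lines) %/% 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seqs <- lines[seq(2, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad) > 0) {
    stop("malformed FASTQ record ", bad[1], " in ", path, call. = FALSE)
  }
  bad_len <- which(nchar(seqs) != nchar(qual))
  if (length(bad_len) > 0) {
    stop("FASTQ record ", bad_len[1],
         ": sequence and quality lengths differ", call. = FALSE)
  }
  hdr <- sub("^@", "", hdr)
  out <- tibble::tibble(
    id = sub("\\s.*$", "", hdr),
    description = ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), ""),
    residues = toupper(seqs)
  )
  validate_seq_tbl(out, source = paste0("FASTQ file '", path, "'"))
}

#' Write sequences to FASTA
#'
#' @param seqs a sequence tibble.
#' @param path output path.
#' @param line_width residues per line (default 70).
#' @return `path`, invisibly. Round-trips with [read_fasta()] on
#'   (`id`, `residues`).
#' @export
write_fasta <- function(seqs, path, line_width = 70) {
  seqs <- validate_seq_tbl(seqs)
  stopifnot(line_width >= 1)
  hdr <- ifelse(nzchar(seqs$description),
                paste0(">", seqs$id, " ", seqs$description),
                paste0(">", seqs$id))
  body <- vapply(seqs$residues, function(s) {
    starts <- seq(1, nchar(s), by = line_width)
    paste(stringi::stri_sub(s, starts, length = line_width), collapse = "\n")
  }, character(1))
  writeLines(paste0(hdr, "\n", body), path)
  invisible(path)
}

#' Reverse complement
#'
#' Vectorized over sequences; `N` is its own complement. An involution:
#' `revcomp(revcomp(x)) == x`.
#'
#' @param x character vector over `{A,C,G,T,N}` (lowercase accepted).
#' @return character vector of reverse complements (uppercase).
#' @examples
#' revcomp("AAAC") # "GTTT"
#' @export
revcomp <- function(x) {
  x <- toupper(x)
  bad <- stringr::str_detect(x, "[^ACGTN]")
  if (any(bad)) stop("invalid residue in sequence ", which(bad)[1],
                     " (alphabet is A, C, G, T, N)", call. = FALSE)
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' Direct-repeat query tables
#'
#' Query direct repeats (DRs) are the known CRISPR repeat sequences searched
#' for in reads. Each carries an optional `host_taxon` label (the taxon whose
#' genomes the DR was originally found in); a missing label propagates as
#' `"unknown"` through the virus-host network. Query lengths outside the
#' empirical CRISPR repeat range of 23-47 bp trigger a warning, not an error.
#'
#' @param x a data frame with columns `id`, `residues` and optionally
#'   `host_taxon`.
#' @return A tibble with columns `id`, `residues`, `host_taxon`.
#' @export
as_dr_queries <- function(x) {
  stopifnot(is.data.frame(x), all(c("id", "residues") %in% names(x)))
  if (!"host_taxon" %in% names(x)) x$host_taxon <- NA_character_
  x$host_taxon <- as.character(x$host_taxon)
  x$host_taxon[is.na(x$host_taxon) | !nzchar(x$host_taxon)] <- "unknown"
  core <- validate_seq_tbl(tibble::tibble(id = x$id, residues = x$residues),
                           source = "DR query table")
  len <- nchar(core$residues)
  out_of_range <- len < 23 | len > 47
  if (any(out_of_range)) {
    warning(sum(out_of_range), " DR query(ies) outside the empirical ",
            "23-47 bp repeat length range: ",
            paste(head(core$id[out_of_range], 5), collapse = ", "),
            call. = FALSE)
  }
  tibble::tibble(id = core$id, residues = core$residues,
                 host_taxon = x$host_taxon)
}

#' Read DR queries from FASTA or TSV
#'
#' FASTA descriptions of the form `host=<taxon>` (or the whole description,
#' if non-empty) populate `host_taxon`; a TSV must have columns `id`,
#' `residues` and optionally `host_taxon`.
#'
#' @param path input path.
#' @param format `"auto"` (by extension), `"fasta"` or `"tsv"`.
#' @return A DR query tibble (see [as_dr_queries()]).
#' @export
read_dr_queries <- function(path, format = c("auto", "fasta", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "tsv" else "fasta"
  }
  if (format == "tsv") {
    x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    return(as_dr_queries(x))
  }
  x <- read_fasta(path)
  taxon <- ifelse(grepl("host=", x$description),
                  sub(".*host=(\\S+).*", "\\1", x$description),
                  x$description)
  as_dr_queries(tibble::tibble(id = x$id, residues = x$residues,
                               host_taxon = taxon))
}
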