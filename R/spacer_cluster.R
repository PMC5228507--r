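#' Clustering parameters
#'
#' @param threshold minimum member-to-representative identity for cluster
#'   membership; the study clustered spacers at 0.9 ("a pairwise similarity
#'   of 90% or greater").
#' @param strand_insensitive compare each sequence in both orientations
#'   against the representative (the usual choice for unoriented
#'   metagenomic spacers)?
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(threshold = 0.9, strand_insensitive = TRUE) {
  stopifnot(threshold > 0.5, threshold <= 1.0)
  structure(list(threshold = threshold,
                 strand_insensitive = isTRUE(strand_insensitive)),
            class = "cluster_params")
}

#' Pairwise sequence identity
#'
#' Identity is the maximum number of identical aligned positions over all
#' global alignments of the pair, divided by the length of the shorter
#' sequence (the short-sequence denominator convention of greedy identity
#' clustering tools). The numerator equals the longest common subsequence
#' length; `N` never counts as identical. With `strand_insensitive`, the
#' larger of the identities to `b` and to its reverse complement is
#' returned. Symmetric, in `[0, 1]`.
#'
#' @param a,b character vectors of sequences, recycled to a common length.
#' @param strand_insensitive also compare against `revcomp(b)`?
#' @return Numeric vector of identities.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT") # 1
#' @export
pairwise_identity <- function(a, b, strand_insensitive = TRUE) {
  n <- max(length(a), length(b))
  a <- toupper(rep_len(a, n)); b <- toupper(rep_len(b, n))
  stopifnot(all(nzchar(a)), all(nzchar(b)))
  fwd <- mapply(cpp_lcs, a, b, USE.NAMES = FALSE)
  best <- fwd
  if (strand_insensitive) {
    rev <- mapply(cpp_lcs, a, revcomp(b), USE.NAMES = FALSE)
    best <- pmax(fwd, rev)
  }
  best / pmin(nchar(a), nchar(b))
}

#' Greedy identity clustering of spacers
#'
#' Reproduces the semantics of greedy incremental clustering at an identity
#' threshold: sequences are sorted by decreasing length (ties broken by id,
#' ascending) and scanned in order; each sequence joins the first existing
#' cluster whose representative it matches at identity at least
#' `threshold`, otherwise it founds a new cluster with itself as
#' representative. Clusters therefore partition the input, and every
#' representative is at least as long as each of its members. The word-
#' filter speed heuristics of the original tool are not reproduced; the
#' clustering semantics are.
#'
#' @param spacers a `crisprscout_spacers` tibble, any data frame with
#'   columns `residues` and an id column (`spacer_id` or `id`), or a
#'   character vector of sequences (ids are generated).
#' @param params a [cluster_params()] object.
#' @return A tibble of class `crisprscout_clusters` with one row per input
#'   sequence: `cluster_id`, `member_id`, `residues`, `length`, `identity`
#'   (to the representative; 1 for representatives) and
#'   `is_representative`.
#' @export
greedy_cluster <- function(spacers, params = cluster_params()) {
  stopifnot(inherits(params, "cluster_params"))
  if (is.character(spacers)) {
    spacers <- tibble::tibble(
      spacer_id = sprintf("seq_%03d", seq_along(spacers)),
      residues = spacers)
  }
  stopifnot(is.data.frame(spacers), "residues" %in% names(spacers))
  id_col <- if ("spacer_id" %in% names(spacers)) "spacer_id" else "id"
  stopifnot(id_col %in% names(spacers))
  x <- tibble::tibble(member_id = as.character(spacers[[id_col]]),
                      residues = toupper(spacers$residues),
                      length = nchar(spacers$residues))
  if (nrow(x) == 0) stop("no sequences to cluster", call. = FALSE)
  x <- x[order(-x$length, x$member_id), , drop = FALSE]
  rep_res <- character(0)
  cluster_of <- integer(nrow(x))
  identity_of <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    assigned <- FALSE
    if (length(rep_res) > 0) {
      ident <- pairwise_identity(rep_res, x$residues[i],
                                 strand_insensitive = params$strand_insensitive)
      hit <- which(ident >= params$threshold)
      if (length(hit) > 0) {
        cluster_of[i] <- hit[1]
        identity_of[i] <- ident[hit[1]]
        assigned <- TRUE
      }
    }
    if (!assigned) {
      rep_res <- c(rep_res, x$residues[i])
      cluster_of[i] <- length(rep_res)
      identity_of[i] <- 1
    }
  }
  first_member <- !duplicated(cluster_of)
  out <- tibble::tibble(
    cluster_id = sprintf("cluster_%04d", cluster_of),
    member_id = x$member_id,
    residues = x$residues,
    length = x$length,
    identity = identity_of,
    is_representative = first_member)
  out <- out[order(out$cluster_id, -out$is_representative, out$member_id), ]
  structure(out, params = params,
            class = c("crisprscout_clusters", class(out)))
}

#' Cluster representatives as a sequence tibble
#'
#' @param clusters a `crisprscout_clusters` tibble.
#' @return A sequence tibble of representatives (id = member id of the
#'   representative).
#' @export
cluster_representatives <- function(clusters) {
  stopifnot(inherits(clusters, "crisprscout_clusters"))
  reps <- clusters[clusters$is_representative, , drop = FALSE]
  tibble::tibble(id = reps$member_id,
                 description = reps$cluster_id,
                 residues = reps$residues)
}

#' Write clustering results
#'
#' Writes the representatives FASTA, a membership file in the `.clstr`-like
#' layout of greedy clustering tools, and a plain TSV
#' (`cluster_id`, `member_id`, `identity`, `is_representative`).
#'
#' @param clusters a `crisprscout_clusters` tibble.
#' @param representatives_fasta,clstr_path,tsv_path output paths (any may
#'   be `NULL` to skip).
#' @return Invisibly, a character vector of the paths written.
#' @export
write_clusters <- function(clusters, representatives_fasta = NULL,
                           clstr_path = NULL, tsv_path = NULL) {
  stopifnot(inherits(clusters, "crisprscout_clusters"))
  written <- character(0)
  if (!is.null(representatives_fasta)) {
    write_fasta(cluster_representatives(clusters), representatives_fasta)
    written <- c(written, representatives_fasta)
  }
  if (!is.null(clstr_path)) {
    lines <- unlist(lapply(split(clusters, clusters$cluster_id), function(cl) {
      hdr <- paste0(">", cl$cluster_id[1])
      body <- sprintf("%d\t%dnt, >%s... %s", seq_len(nrow(cl)) - 1,
                      cl$length, cl$member_id,
                      ifelse(cl$is_representative, "*",
                             sprintf("at %.2f%%", 100 * cl$identity)))
      c(hdr, body)
    }))
    writeLines(lines, clstr_path)
    written <- c(written, clstr_path)
  }
  if (!is.null(tsv_path)) {
    readr::write_tsv(clusters[, c("cluster_id", "member_id", "identity",
                                  "is_representative")],
                     tsv_path, progress = FALSE)
    written <- c(written, tsv_path)
  }
  invisible(written)
}
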