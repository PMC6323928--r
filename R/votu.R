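#' Parameters for vOTU clustering
#'
#' Viral operational taxonomic units (vOTUs) are species-rank clusters
#' defined by sequence identity: two sequences are linked when their
#' average nucleotide identity (ANI) is at least `min_ani_pct` over at
#' least `min_af_pct` of the length of the shorter sequence, and clusters
#' are the connected components of this link graph (single linkage).
#'
#' @param min_ani_pct Minimum ANI (%) for a link. Default 95.
#' @param min_af_pct Minimum aligned fraction (%) of the shorter sequence.
#'   Default 85.
#' @return An object of class `clustering_params`.
#' @export
clustering_params <- function(min_ani_pct = 95, min_af_pct = 85) {
  assert_scalar_number(min_ani_pct, "min_ani_pct")
  assert_scalar_number(min_af_pct, "min_af_pct")
  if (min_ani_pct > 100 || min_af_pct > 100) {
    stop("thresholds must be in (0, 100]", call. = FALSE)
  }
  structure(list(min_ani_pct = min_ani_pct, min_af_pct = min_af_pct),
            class = "clustering_params")
}

# Scoring scheme for local alignments: blastn-like match/mismatch with an
# explicit N row so that N never scores as a match (including N vs N).
ani_submat <- function(match = 2, mismatch = -3) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- mismatch
  m[, "N"] <- mismatch
  m
}

# Greedy non-overlapping local alignment blocks of query against subject
# (one orientation). Iteratively takes the best local alignment, records
# identities/columns/query coverage, masks the aligned query range with N
# and realigns, so later blocks cannot reuse covered query bases.
ani_blocks_one_strand <- function(query, subject, max_blocks = 5L,
                                  min_block_score = 50) {
  submat <- ani_submat()
  qm <- query
  qlen <- nchar(query)
  matched <- 0
  cols <- 0
  covered <- logical(qlen)
  for (k in seq_len(max_blocks)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = qm, subject = subject, type = "local",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
    if (Biostrings::score(aln) < min_block_score) break
    pc <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
    sc <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
    matched <- matched + sum(pc == sc & pc != "-" & pc != "N")
    cols <- cols + length(pc)
    qs <- BiocGenerics::start(Biostrings::pattern(aln))
    qe <- BiocGenerics::end(Biostrings::pattern(aln))
    covered[qs:qe] <- TRUE
    substr(qm, qs, qe) <- strrep("N", qe - qs + 1L)
    if (all(covered)) break
  }
  list(matched = matched, cols = cols, covered = sum(covered))
}

#' Pairwise ANI and aligned fraction
#'
#' Computes the average nucleotide identity between two sequences from
#' greedy non-overlapping local alignment blocks, considering both strands
#' of the second sequence and keeping the better orientation. The shorter
#' sequence is always designated the query (ties broken by sequence
#' content), which makes the result symmetric in its two arguments.
#'
#' ANI is 100 x (identical aligned columns) / (aligned columns, gaps
#' included), length-weighted across blocks. AF is 100 x (query bases
#' covered by any block) / (length of the shorter sequence). `N` bases
#' never count as identities.
#'
#' @param a,b Nucleotide strings or [viral_contig] objects; both non-empty.
#' @return A list of class `ani_result` with elements `ani_pct` and
#'   `af_pct` (aligned fraction of the shorter sequence), both in
#'   \[0, 100\]. `ani_pct` is `NA` when no alignment block is found
#'   (`af_pct` is then 0).
#' @examples
#' r <- pairwise_ani("ACGTACGTACGTACGTACGTACGTACGT", "ACGTACGTACGTACGTACGTACGTACGT")
#' r$ani_pct  # 100
#' @export
pairwise_ani <- function(a, b) {
  sa <- as_sequence_string(a)
  sb <- as_sequence_string(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("sequences must be non-empty", call. = FALSE)
  # deterministic query/subject designation: shorter first, ties by content
  if (nchar(sa) > nchar(sb) || (nchar(sa) == nchar(sb) && sa > sb)) {
    tmp <- sa; sa <- sb; sb <- tmp
  }
  fwd <- ani_blocks_one_strand(sa, sb)
  rev <- ani_blocks_one_strand(sa, revcomp_chr(sb))
  best <- if (rev$matched > fwd$matched) rev else fwd
  ani <- if (best$cols > 0) 100 * best$matched / best$cols else NA_real_
  af <- 100 * best$covered / nchar(sa)
  structure(list(ani_pct = ani, af_pct = af), class = "ani_result")
}

#' @export
print.ani_result <- function(x, ...) {
  cat(sprintf("<ani_result> ANI %.2f%%, AF %.2f%% of shorter sequence\n",
              x$ani_pct, x$af_pct))
  invisible(x)
}

#' All-vs-all ANI/AF table
#'
#' @param contigs A named list of [viral_contig] objects (or a named
#'   character vector of sequences).
#' @return A data frame with one row per unordered pair: `id1`, `id2`,
#'   `ani_pct`, `af_pct`.
#' @export
pairwise_ani_table <- function(contigs) {
  if (is.character(contigs)) {
    ids <- names(contigs)
    seqs <- unname(contigs)
  } else {
    ids <- contig_ids(contigs)
    seqs <- vapply(contigs, `[[`, character(1), "sequence")
  }
  if (anyDuplicated(ids)) stop("sequence ids must be unique", call. = FALSE)
  n <- length(ids)
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        r <- pairwise_ani(seqs[i], seqs[j])
        rows[[length(rows) + 1L]] <- data.frame(
          id1 = ids[i], id2 = ids[j],
          ani_pct = r$ani_pct, af_pct = r$af_pct,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(id1 = character(), id2 = character(),
                      ani_pct = numeric(), af_pct = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Cluster sequences into vOTUs by single linkage
#'
#' Builds the graph with an edge between two sequences when ANI >=
#' `min_ani_pct` and AF >= `min_af_pct`, and takes connected components as
#' vOTUs. Components with two or more members are named `vc_1`, `vc_2`,
#' ... and singletons `sg_1`, `sg_2`, ...; within each prefix, clusters
#' are ordered by decreasing size, then by the lexicographically smallest
#' member id.
#'
#' @param contigs A named list of [viral_contig] objects or a named
#'   character vector of sequences; ids must be unique.
#' @param params A [clustering_params] object.
#' @param ani_table Optional precomputed pairwise table (as returned by
#'   [pairwise_ani_table]); when supplied, alignment is skipped.
#' @return An object of class `votu_set`: a list of vOTUs, each a list
#'   with `name` and `member_ids`. Coerce with `as.data.frame()` to get a
#'   per-sequence table (`seq_id`, `votu_name`, `n_members`).
#' @export
build_votus <- function(contigs, params = clustering_params(),
                        ani_table = NULL) {
  ids <- if (is.character(contigs)) names(contigs) else contig_ids(contigs)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop("sequence ids must be present and unique", call. = FALSE)
  }
  if (is.null(ani_table)) ani_table <- pairwise_ani_table(contigs)
  keep <- !is.na(ani_table$ani_pct) &
    ani_table$ani_pct >= params$min_ani_pct &
    ani_table$af_pct >= params$min_af_pct
  edges <- ani_table[keep, c("id1", "id2"), drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)
  membership <- comp$membership[ids]
  groups <- split(ids, membership)
  sizes <- lengths(groups)
  minid <- vapply(groups, function(m) min(m), character(1))
  ord <- order(-sizes, minid)
  groups <- groups[ord]
  sizes <- sizes[ord]
  votus <- vector("list", length(groups))
  n_vc <- 0L
  n_sg <- 0L
  for (k in seq_along(groups)) {
    if (sizes[k] >= 2L) {
      n_vc <- n_vc + 1L
      nm <- paste0("vc_", n_vc)
    } else {
      n_sg <- n_sg + 1L
      nm <- paste0("sg_", n_sg)
    }
    votus[[k]] <- list(name = nm, member_ids = sort(unname(groups[[k]])))
  }
  structure(votus, class = "votu_set")
}

#' @export
print.votu_set <- function(x, ...) {
  n_vc <- sum(vapply(x, function(v) length(v$member_ids) >= 2L, logical(1)))
  cat(sprintf("<votu_set> %d vOTUs: %d clusters (vc_), %d singletons (sg_)\n",
              length(x), n_vc, length(x) - n_vc))
  invisible(x)
}

#' @export
as.data.frame.votu_set <- function(x, ...) {
  do.call(rbind, lapply(x, function(v) {
    data.frame(seq_id = v$member_ids, votu_name = v$name,
               n_members = length(v$member_ids), stringsAsFactors = FALSE)
  })) %||% data.frame(seq_id = character(), votu_name = character(),
                      n_members = integer(), stringsAsFactors = FALSE)
}
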