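#' Split a ranked host lineage into its ranks
#'
#' Lineages are `;`-separated taxonomy paths ordered from domain downward,
#' e.g. `"Bacteria;Firmicutes;Bacilli"`.
#'
#' @param x Lineage string.
#' @return Character vector of ranks.
#' @export
parse_lineage <- function(x) {
  ranks <- trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
  ranks[nzchar(ranks)]
}

#' Lowest common ancestor of host lineages
#'
#' @param lineages Character vector of `;`-separated lineages.
#' @return The longest shared rank prefix as a lineage string, or `""`
#'   when the lineages disagree already at the first rank.
#' @export
lineage_lca <- function(lineages) {
  parts <- lapply(lineages, parse_lineage)
  depth <- min(lengths(parts))
  if (depth == 0L) return("")
  common <- 0L
  for (d in seq_len(depth)) {
    vals <- vapply(parts, `[`, character(1), d)
    if (length(unique(vals)) > 1L) break
    common <- d
  }
  if (common == 0L) return("")
  paste(parts[[1L]][seq_len(common)], collapse = ";")
}

#' Propagate host labels through vOTU co-membership
#'
#' Viruses in the same vOTU infect the same (or very closely related)
#' hosts, so a cluster containing at least one sequence with a known host
#' -- an isolate genome or a curated prophage -- lends that host to its
#' unlabelled members. When a cluster carries several labels, members
#' receive the lowest common ancestor of all labelled lineages.
#' Pre-existing labels are never overwritten, and singletons or
#' label-free clusters are left unchanged.
#'
#' @param votus A `votu_set` (see [build_votus]) or its data frame form.
#' @param labels Host label data frame (see [read_host_table]); labels
#'   whose `seq_id` is not a cluster member are skipped with a warning.
#' @return A data frame of labels: the usable input labels plus one row
#'   per newly labelled sequence with `source = "cluster"`.
#' @export
propagate_cluster_hosts <- function(votus, labels) {
  if (inherits(votus, "votu_set")) votus_df <- as.data.frame(votus)
  else votus_df <- votus
  stopifnot(all(c("seq_id", "votu_name") %in% names(votus_df)))
  known <- labels$seq_id %in% votus_df$seq_id
  if (any(!known)) {
    warning(sprintf("host label(s) for unknown sequence id(s) skipped: %s",
                    paste(unique(labels$seq_id[!known]), collapse = ", ")),
            call. = FALSE)
    labels <- labels[known, , drop = FALSE]
  }
  out <- labels
  for (votu in split(votus_df$seq_id, votus_df$votu_name)) {
    if (length(votu) < 2L) next
    lab <- labels[labels$seq_id %in% votu, , drop = FALSE]
    if (nrow(lab) == 0L) next
    lca <- lineage_lca(lab$host_lineage)
    if (!nzchar(lca)) next
    unlabelled <- setdiff(votu, labels$seq_id)
    if (length(unlabelled) == 0L) next
    out <- rbind(out, data.frame(seq_id = unlabelled, host_lineage = lca,
                                 source = "cluster", stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Match CRISPR spacers against viral contigs
#'
#' CRISPR arrays store short (25-65 bp) virus-derived segments; an
#' (almost) exact occurrence of a spacer in a viral contig links the
#' contig to the spacer's microbial host. Matching is over the full
#' spacer length on either strand, allowing up to `max_mismatches`
#' substitutions and no indels; `N` positions always count as mismatches.
#' Spacers outside the 25-65 bp length range are skipped with a warning.
#'
#' @param contigs A named list of [viral_contig] objects or a named
#'   character vector of sequences.
#' @param spacers A named character vector of spacer sequences (or a data
#'   frame with columns `spacer_id` and `sequence`, as produced by
#'   [make_spacer_set]).
#' @param max_mismatches Maximum substitutions allowed. Default 1.
#' @param len_range Admissible spacer length range in bp. Default
#'   `c(25, 65)`.
#' @return A data frame of matches: `spacer_id`, `contig_id`, `position`
#'   (1-based start on the contig's forward strand), `strand` (`"+"` or
#'   `"-"`), `mismatches`.
#' @export
match_spacers <- function(contigs, spacers, max_mismatches = 1L,
                          len_range = c(25L, 65L)) {
  if (is.data.frame(spacers)) {
    spc <- stats::setNames(toupper(spacers$sequence), spacers$spacer_id)
  } else {
    if (is.null(names(spacers))) stop("spacers must be named", call. = FALSE)
    spc <- toupper(spacers)
  }
  lens <- nchar(spc)
  bad <- lens < len_range[1L] | lens > len_range[2L]
  if (any(bad)) {
    warning(sprintf("spacer(s) outside [%d, %d] bp skipped: %s",
                    len_range[1L], len_range[2L],
                    paste(names(spc)[bad], collapse = ", ")), call. = FALSE)
    spc <- spc[!bad]
  }
  if (is.character(contigs)) {
    cids <- names(contigs)
    cseqs <- toupper(unname(contigs))
  } else {
    cids <- contig_ids(contigs)
    cseqs <- vapply(contigs, `[[`, character(1), "sequence")
  }
  rows <- list()
  for (ci in seq_along(cids)) {
    subject <- Biostrings::DNAString(cseqs[ci])
    cchars <- seq_chars(cseqs[ci])
    for (si in seq_along(spc)) {
      for (strand in c("+", "-")) {
        pat <- if (strand == "+") spc[[si]] else revcomp_chr(spc[[si]])
        m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                      max.mismatch = max_mismatches,
                                      with.indels = FALSE, fixed = TRUE)
        if (length(m) == 0L) next
        starts <- BiocGenerics::start(m)
        ends <- BiocGenerics::end(m)
        for (k in seq_along(starts)) {
          # recount mismatches with N forced to mismatch (matchPattern
          # treats N-vs-N as equal letters)
          window <- cchars[starts[k]:ends[k]]
          pchars <- seq_chars(pat)
          mm <- sum(window != pchars | window == "N" | pchars == "N")
          if (mm > max_mismatches) next
          rows[[length(rows) + 1L]] <- data.frame(
            spacer_id = names(spc)[si], contig_id = cids[ci],
            position = starts[k], strand = strand, mismatches = mm,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(spacer_id = character(), contig_id = character(),
                      position = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise predicted hosts by phylum
#'
#' @param labels Host label data frame with `seq_id` and `host_lineage`;
#'   the phylum is the second rank of the lineage. Labels lacking a
#'   phylum rank are ignored; identical (sequence, phylum) pairs are
#'   counted once.
#' @return A data frame `phylum`, `n_contigs`, in decreasing count order.
#' @export
summarize_host_phyla <- function(labels) {
  if (nrow(labels) == 0L) {
    return(data.frame(phylum = character(), n_contigs = integer(),
                      stringsAsFactors = FALSE))
  }
  phyla <- vapply(labels$host_lineage, function(x) {
    r <- parse_lineage(x)
    if (length(r) >= 2L) r[2L] else NA_character_
  }, character(1), USE.NAMES = FALSE)
  keep <- !is.na(phyla)
  if (!any(keep)) {
    return(data.frame(phylum = character(), n_contigs = integer(),
                      stringsAsFactors = FALSE))
  }
  pairs <- unique(data.frame(seq_id = labels$seq_id[keep],
                             phylum = phyla[keep], stringsAsFactors = FALSE))
  counts <- sort(table(pairs$phylum), decreasing = TRUE)
  data.frame(phylum = names(counts), n_contigs = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}
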