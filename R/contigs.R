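#' Construct a viral contig record
#'
#' A `viral_contig` is the unit of data passed through the curation
#' pipeline: a nucleotide sequence plus the annotations that accumulate as
#' the contig moves through circularity detection, clustering, completeness
#' estimation and host prediction.
#'
#' Sequences are restricted to the alphabet `A/C/G/T/N` and stored in upper
#' case. `N` is allowed but never counts as a match in any repeat, identity
#' or spacer computation.
#'
#' @param id Sequence identifier (non-empty string).
#' @param sequence Nucleotide string over `A/C/G/T/N` (case-insensitive).
#' @param source_class Provenance of the sequence: `"uvig"` (uncultivated
#'   viral genome, the default), `"isolate"` (cultivated reference genome)
#'   or `"prophage"` (curated prophage region).
#' @return An object of class `viral_contig`: a list with elements `id`,
#'   `sequence`, `length`, `source_class`, `circularity` (a
#'   [circularity_call] or `NULL`), `completeness_pct` and `quality_tier`.
#' @examples
#' vc <- viral_contig("c1", "ACGTACGT")
#' vc$length
#' @export
viral_contig <- function(id, sequence,
                         source_class = c("uvig", "isolate", "prophage")) {
  source_class <- match.arg(source_class)
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("'id' must be a non-empty string", call. = FALSE)
  }
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    stop("'sequence' must be a single string", call. = FALSE)
  }
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) {
    stop("sequence must have length > 0", call. = FALSE)
  }
  bad <- gsub("[ACGTN]", "", sequence)
  if (nzchar(bad)) {
    stop(sprintf("sequence of '%s' contains characters outside A/C/G/T/N: %s",
                 id, paste(unique(seq_chars(bad)), collapse = ", ")),
         call. = FALSE)
  }
  structure(
    list(id = id,
         sequence = sequence,
         length = nchar(sequence),
         source_class = source_class,
         circularity = NULL,
         completeness_pct = NA_real_,
         quality_tier = NA_character_),
    class = "viral_contig"
  )
}

#' @export
print.viral_contig <- function(x, ...) {
  circ <- if (is.null(x$circularity)) "not assessed"
          else if (x$circularity$is_circular)
            sprintf("circular (%s, %d bp repeat)",
                    x$circularity$mechanism, x$circularity$repeat_length)
          else "linear"
  cat(sprintf("<viral_contig> %s: %d bp, %s, %s\n",
              x$id, x$length, x$source_class, circ))
  if (!is.na(x$completeness_pct)) {
    cat(sprintf("  completeness: %.1f%%\n", x$completeness_pct))
  }
  if (!is.na(x$quality_tier)) {
    cat(sprintf("  quality tier: %s\n", x$quality_tier))
  }
  invisible(x)
}

contig_ids <- function(contigs) vapply(contigs, `[[`, character(1), "id")

contig_lengths <- function(contigs) {
  stats::setNames(vapply(contigs, `[[`, numeric(1), "length"),
                  contig_ids(contigs))
}

#' Read contigs from a FASTA file
#'
#' Record identifiers are the first whitespace-delimited token of each
#' header line; the remainder of the header is discarded. Sequences are
#' uppercased and validated against the `A/C/G/T/N` alphabet.
#'
#' @param path Path to a FASTA file (multi-line records allowed).
#' @param source_class Source class applied to every record (see
#'   [viral_contig]).
#' @return A named list of [viral_contig] objects (names are the ids).
#' @seealso [write_fasta]
#' @export
read_fasta <- function(path, source_class = "uvig") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop(sprintf("no sequences found in '%s'", path), call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate sequence id(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  seqs <- as.character(set)
  contigs <- mapply(function(i, s) viral_contig(i, s, source_class),
                    ids, seqs, SIMPLIFY = FALSE)
  stats::setNames(contigs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param x A list of [viral_contig] objects or a named character vector of
#'   sequences.
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(x, path, width = 70L) {
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) stop("character input must be named", call. = FALSE)
    seqs <- unname(x)
  } else {
    ids <- contig_ids(x)
    seqs <- vapply(x, `[[`, character(1), "sequence")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(ids)) {
    writeLines(paste0(">", ids[k]), con)
    s <- seqs[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s table '%s' is missing column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Taxon classes recognised by the marker-affiliation rules
#' @keywords internal
TAXON_CLASSES <- c("dsDNA", "NCLDV", "ssDNA", "RNA")

#' Read a taxonomic marker hit table
#'
#' The table links contigs to taxonomic marker gene models (VOGs) carrying
#' a taxon label: a genus for dsDNA viruses, a family for ssDNA and RNA
#' viruses. Tab-delimited with a header row and columns `contig_id`,
#' `model_id`, `taxon`, `taxon_class`; `taxon_class` must be one of
#' `dsDNA`, `NCLDV`, `ssDNA`, `RNA`.
#'
#' @param path Path to the tab-delimited hit table.
#' @return A data frame with the four columns, rows in file order.
#' @export
read_hit_table <- function(path) {
  df <- read_tsv_checked(path, c("contig_id", "model_id", "taxon",
                                 "taxon_class"), "marker hit")
  bad <- setdiff(unique(df$taxon_class), TAXON_CLASSES)
  if (length(bad) > 0L) {
    stop(sprintf("unknown taxon_class value(s): %s (expected %s)",
                 paste(bad, collapse = ", "),
                 paste(TAXON_CLASSES, collapse = "/")), call. = FALSE)
  }
  df
}

#' Read a genus-level group membership table
#'
#' Genus-level groups (e.g. produced by a gene-sharing network tool) are
#' consumed as input. Columns: `seq_id`, `group_id`, `member_class` with
#' values `isolate_reference`, `circular` or `linear`. Each sequence may
#' belong to at most one group.
#'
#' @param path Path to the tab-delimited membership table.
#' @return A data frame with the three columns.
#' @export
read_group_table <- function(path) {
  df <- read_tsv_checked(path, c("seq_id", "group_id", "member_class"),
                         "group membership")
  bad <- setdiff(unique(df$member_class),
                 c("isolate_reference", "circular", "linear"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown member_class value(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  dup <- df$seq_id[duplicated(df$seq_id)]
  if (length(dup) > 0L) {
    stop(sprintf("sequence(s) assigned to more than one group: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  df
}

#' Read a reference genome length table
#'
#' Lengths (bp) of external reference sequences (e.g. isolate genomes that
#' are group members but not part of the input FASTA). Columns: `seq_id`,
#' `length`.
#'
#' @param path Path to the tab-delimited table.
#' @return A data frame with columns `seq_id` and `length`.
#' @export
read_ref_lengths <- function(path) {
  df <- read_tsv_checked(path, c("seq_id", "length"), "reference length")
  df$length <- as.numeric(df$length)
  if (any(is.na(df$length) | df$length <= 0)) {
    stop("reference lengths must be positive numbers", call. = FALSE)
  }
  df
}

#' Read a taxon average genome length table
#'
#' Average genome lengths of isolates per taxon (genus for dsDNA viruses,
#' family for ssDNA/RNA), used as the completeness reference for
#' marker-affiliated contigs. Columns: `taxon`, `mean_length`.
#'
#' @param path Path to the tab-delimited table.
#' @return A data frame with columns `taxon` and `mean_length`.
#' @export
read_taxon_lengths <- function(path) {
  df <- read_tsv_checked(path, c("taxon", "mean_length"), "taxon length")
  df$mean_length <- as.numeric(df$mean_length)
  if (any(is.na(df$mean_length) | df$mean_length <= 0)) {
    stop("taxon mean lengths must be positive numbers", call. = FALSE)
  }
  df
}

#' Read a host label table
#'
#' Known virus-host links for isolates, prophages or CRISPR spacers.
#' Columns: `seq_id` (a contig id, or a spacer id for `source = "spacer"`),
#' `host_lineage` (ranked taxonomy path, ranks separated by `;`, e.g.
#' `"Bacteria;Firmicutes;Bacilli"`), `source` (`isolate`, `prophage` or
#' `spacer`).
#'
#' @param path Path to the tab-delimited table.
#' @return A data frame with the three columns.
#' @export
read_host_table <- function(path) {
  df <- read_tsv_checked(path, c("seq_id", "host_lineage", "source"),
                         "host label")
  bad <- setdiff(unique(df$source), c("isolate", "prophage", "spacer"))
  if (length(bad) > 0L) {
    stop(sprintf("unknown host label source(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (any(!nzchar(df$host_lineage))) {
    stop("host_lineage must be non-empty", call. = FALSE)
  }
  df
}

#' Columns of the consolidated curation report
#' @keywords internal
REPORT_COLUMNS <- c("contig_id", "length", "circular", "circular_mechanism",
                    "false_positive_circular", "votu", "taxon",
                    "predicted_genome_size", "completeness_pct",
                    "quality_tier", "host_domain", "host_prediction",
                    "host_method")

#' Write the consolidated curation report
#'
#' Emits a tab-delimited table with one row per contig and a fixed set of
#' 13 columns; undefined values are written as `NA`. Completeness is
#' rounded to one decimal place for reporting (internal comparisons use
#' unrounded values).
#'
#' @param records A data frame carrying the report columns (see
#'   `uvigcurate:::REPORT_COLUMNS`); missing columns are filled with `NA`.
#' @param path Output path.
#' @return Invisibly, the data frame as written.
#' @export
write_report <- function(records, path) {
  if (!is.data.frame(records)) stop("'records' must be a data frame", call. = FALSE)
  for (col in setdiff(REPORT_COLUMNS, names(records))) {
    records[[col]] <- rep(NA, nrow(records))
  }
  records <- records[, REPORT_COLUMNS, drop = FALSE]
  if (nrow(records) > 0L && is.numeric(records$completeness_pct)) {
    records$completeness_pct <- ifelse(is.na(records$completeness_pct),
                                       NA_character_,
                                       sprintf("%.1f", records$completeness_pct))
  }
  ok <- tryCatch({
    utils::write.table(records, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    TRUE
  }, error = function(e) {
    stop(sprintf("cannot write report to '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(records)
}
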