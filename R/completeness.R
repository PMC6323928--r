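#' Minimum consistent marker counts per taxon class
#'
#' Affiliating a contig to a taxon from marker gene (VOG) hits requires at
#' least two consistent markers for dsDNA viruses, five for
#' nucleocytoplasmic large DNA viruses (NCLDV, whose gene repertoires
#' overlap cellular genomes), and a single marker for ssDNA and RNA
#' viruses (whose small genomes rarely carry more than one).
#'
#' @keywords internal
MARKER_MINIMA <- c(dsDNA = 2L, NCLDV = 5L, ssDNA = 1L, RNA = 1L)

#' Affiliate a contig to a taxon from marker hits
#'
#' Markers are grouped by taxon label; markers are "consistent" when they
#' agree on the same taxon. The taxon with the most consistent markers
#' wins if its count meets the class-specific minimum (dsDNA: 2, NCLDV: 5,
#' ssDNA: 1, RNA: 1); a tie for the top count, or a top count below the
#' minimum, yields no affiliation.
#'
#' @param hits Marker hit data frame (see [read_hit_table]).
#' @param contig_id Contig to affiliate; `hits` is filtered to this id.
#' @param taxon_lengths Optional taxon average genome length table (see
#'   [read_taxon_lengths]) used to fill `mean_taxon_genome_length`.
#' @return A list of class `taxon_affiliation` with fields `contig_id`,
#'   `taxon`, `taxon_class`, `n_supporting_markers`,
#'   `mean_taxon_genome_length` (`NA` when unknown), or `NULL` when no
#'   taxon meets its minimum.
#' @export
affiliate_by_markers <- function(hits, contig_id, taxon_lengths = NULL) {
  h <- hits[hits$contig_id == contig_id, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  bad_class <- setdiff(unique(h$taxon_class), names(MARKER_MINIMA))
  if (length(bad_class) > 0L) {
    stop(sprintf("unknown taxon_class: %s", paste(bad_class, collapse = ", ")),
         call. = FALSE)
  }
  classes <- tapply(h$taxon_class, h$taxon, function(x) length(unique(x)))
  if (any(classes > 1L)) {
    stop(sprintf("conflicting taxon_class for taxon label(s): %s",
                 paste(names(classes)[classes > 1L], collapse = ", ")),
         call. = FALSE)
  }
  counts <- sort(table(h$taxon), decreasing = TRUE)
  top <- counts[1L]
  if (sum(counts == top) > 1L) return(NULL)   # tie: no affiliation
  taxon <- names(counts)[1L]
  klass <- h$taxon_class[h$taxon == taxon][1L]
  if (top < MARKER_MINIMA[[klass]]) return(NULL)
  mean_len <- NA_real_
  if (!is.null(taxon_lengths)) {
    m <- match(taxon, taxon_lengths$taxon)
    if (!is.na(m)) mean_len <- taxon_lengths$mean_length[m]
  }
  structure(
    list(contig_id = contig_id, taxon = taxon, taxon_class = klass,
         n_supporting_markers = as.integer(top),
         mean_taxon_genome_length = mean_len),
    class = "taxon_affiliation"
  )
}

#' Construct a genus-level group
#'
#' A genus-level group collects sequences believed to belong to the same
#' (approximate) viral genus; the group is consumed as input, and the
#' lengths of its complete members are used to predict a genome size for
#' its linear members.
#'
#' @param group_id Group identifier.
#' @param isolate_lengths Lengths (bp) of isolate reference genomes in the
#'   group.
#' @param circular_lengths Lengths (bp) of circular contigs in the group
#'   that are treated as complete genomes (false positives excluded).
#' @param linear_lengths Lengths (bp) of linear contig members.
#' @param linear_ids Optional ids of the linear members.
#' @return An object of class `genus_group`.
#' @export
genus_group <- function(group_id, isolate_lengths = numeric(),
                        circular_lengths = numeric(),
                        linear_lengths = numeric(),
                        linear_ids = character()) {
  structure(
    list(group_id = group_id,
         isolate_lengths = as.numeric(isolate_lengths),
         circular_lengths = as.numeric(circular_lengths),
         linear_lengths = as.numeric(linear_lengths),
         linear_ids = linear_ids),
    class = "genus_group"
  )
}

#' Predicted genome size of a genus-level group
#'
#' The mean of isolate and (non-false-positive) circular member lengths is
#' taken as the group's predicted genome size, but only if the standard
#' deviation of those lengths is at most 15% of their mean -- otherwise
#' the group's genome sizes are too heterogeneous to borrow. The SD is the
#' population standard deviation (divide by n), so a single contributing
#' length has SD 0 and yields a defined size.
#'
#' @param group A [genus_group].
#' @param max_sd_frac Maximum SD as a fraction of the mean. Default 0.15.
#' @return The predicted size in bp (with attribute `"sd"`), or `NA` when
#'   the group has no complete members or is too heterogeneous.
#' @export
predicted_genome_size <- function(group, max_sd_frac = 0.15) {
  lens <- c(group$isolate_lengths, group$circular_lengths)
  if (length(lens) == 0L) return(NA_real_)
  m <- mean(lens)
  sd_pop <- sqrt(mean((lens - m)^2))
  if (sd_pop > max_sd_frac * m) return(NA_real_)
  structure(m, sd = sd_pop)
}

#' Flag a circular contig as a false-positive complete genome
#'
#' Terminal repeats occasionally arise without the contig being a complete
#' circular genome. A circular contig is flagged as a false positive when
#' any of these holds:
#'
#' 1. its group contains isolate references and the contig is shorter than
#'    80% of the minimum isolate length;
#' 2. its group has no isolates and the contig is shorter than 80% of the
#'    longest linear member;
#' 3. it is shorter than 10 kb and carries no marker affiliation to an
#'    ssDNA or RNA virus (small circles without such markers most likely
#'    derive from fragmented dsDNA virus genomes).
#'
#' Flagged contigs are thereafter treated as linear for completeness
#' estimation.
#'
#' @param contig A [viral_contig] with a positive circularity call.
#' @param group The contig's [genus_group], or `NULL` if ungrouped.
#' @param affiliation The contig's `taxon_affiliation`, or `NULL`.
#' @param length_fraction Fraction of the reference length below which a
#'   circular contig is suspect. Default 0.8.
#' @param min_circular_len Length floor (bp) for rule 3. Default 10000.
#' @return A list with `false_positive` (logical) and `reason` (the
#'   triggering rule, or `""`).
#' @export
flag_false_positive_circular <- function(contig, group = NULL,
                                         affiliation = NULL,
                                         length_fraction = 0.8,
                                         min_circular_len = 10000) {
  if (!inherits(contig, "viral_contig")) {
    stop("'contig' must be a viral_contig", call. = FALSE)
  }
  if (is.null(contig$circularity) || !contig$circularity$is_circular) {
    stop(sprintf("contig '%s' has no positive circularity call", contig$id),
         call. = FALSE)
  }
  len <- contig$length
  if (!is.null(group) && length(group$isolate_lengths) > 0L) {
    if (len < length_fraction * min(group$isolate_lengths)) {
      return(list(false_positive = TRUE, reason = "below_min_isolate_length"))
    }
  } else if (!is.null(group) && length(group$linear_lengths) > 0L) {
    if (len < length_fraction * max(group$linear_lengths)) {
      return(list(false_positive = TRUE, reason = "below_max_linear_length"))
    }
  }
  ssrna <- !is.null(affiliation) &&
    affiliation$taxon_class %in% c("ssDNA", "RNA")
  if (len < min_circular_len && !ssrna) {
    return(list(false_positive = TRUE,
                reason = "short_without_ssdna_rna_marker"))
  }
  list(false_positive = FALSE, reason = "")
}

#' Estimate genome completeness of a linear contig
#'
#' Completeness is the contig length as a percentage of a reference genome
#' size -- the taxon average for marker-affiliated contigs, or the group's
#' predicted genome size otherwise. A linear contig longer than the
#' reference is capped at 99%: it is likely near-complete, but linearity
#' means completeness cannot be asserted. The returned value is unrounded;
#' reporting rounds to one decimal place.
#'
#' @param contig A [viral_contig], or a single length in bp.
#' @param size_ref Reference genome size in bp, or `NA` when no prediction
#'   is available.
#' @param cap_pct Completeness assigned when length exceeds `size_ref`.
#'   Default 99.
#' @return Completeness percentage in (0, 99\], or `NA` when `size_ref` is
#'   undefined.
#' @export
estimate_completeness <- function(contig, size_ref, cap_pct = 99) {
  len <- if (inherits(contig, "viral_contig")) contig$length
         else as.numeric(contig)
  if (is.null(size_ref) || is.na(size_ref)) return(NA_real_)
  if (size_ref <= 0) stop("size_ref must be positive", call. = FALSE)
  if (len > size_ref) return(cap_pct)
  100 * len / size_ref
}

#' Quality tiers
#' @keywords internal
QUALITY_TIERS <- c("finished", "complete_circular", "high_quality_draft",
                   "genome_fragment")

#' Assign a genome quality tier
#'
#' Isolate reference genomes are `finished`; circular contigs not flagged
#' as false positives are `complete_circular` (likely complete genomes);
#' linear contigs with estimated completeness of at least 90% are
#' `high_quality_draft`; all remaining linear contigs -- low completeness
#' or no predicted genome size -- are `genome_fragment`. The 90% threshold
#' is compared against the unrounded completeness.
#'
#' @param contig A [viral_contig] (its `source_class` and `circularity`
#'   are consulted).
#' @param false_positive Whether the contig's circularity call was flagged
#'   as a false positive (ignored for non-circular contigs).
#' @param completeness_pct Estimated completeness (%), or `NA`.
#' @param hq_min_completeness Completeness threshold for the high-quality
#'   draft tier. Default 90.
#' @return One of `"finished"`, `"complete_circular"`,
#'   `"high_quality_draft"`, `"genome_fragment"`.
#' @export
assign_quality_tier <- function(contig, false_positive = FALSE,
                                completeness_pct = NA_real_,
                                hq_min_completeness = 90) {
  if (inherits(contig, "viral_contig") && contig$source_class == "isolate") {
    return("finished")
  }
  circ <- inherits(contig, "viral_contig") &&
    !is.null(contig$circularity) && contig$circularity$is_circular
  if (circ && !false_positive) return("complete_circular")
  if (!is.na(completeness_pct) && completeness_pct >= hq_min_completeness) {
    return("high_quality_draft")
  }
  "genome_fragment"
}
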