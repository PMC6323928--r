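#' Default pipeline parameters
#'
#' Collects every tunable constant of the curation pipeline with its
#' default: terminal-repeat floors (10/20 bp) and window (50 bp), vOTU
#' thresholds (95% ANI / 85% AF), marker minima (2 dsDNA / 5 NCLDV / 1
#' ssDNA / 1 RNA), the false-positive length fraction (0.8) and circular
#' length floor (10 kb), the group size-consistency bound (SD <= 15% of
#' mean), the high-quality-draft completeness threshold (90%), the
#' near-complete cap (99%), the VPF average hits (6.8), the admissible
#' spacer length range (25-65 bp) and spacer mismatch allowance (1).
#'
#' @param ... Named overrides of individual defaults.
#' @return A named list of class `pipeline_params`.
#' @export
pipeline_params <- function(...) {
  p <- list(
    min_dtr_len = 10L,
    min_terminal_repeat_len = 20L,
    terminal_window = 50L,
    max_repeat_len = 1000L,
    min_ani_pct = 95,
    min_af_pct = 85,
    fp_length_fraction = 0.8,
    min_circular_len = 10000,
    max_group_sd_frac = 0.15,
    hq_min_completeness = 90,
    near_complete_pct = 99,
    average_vpf_hits = 6.8,
    spacer_min_len = 25L,
    spacer_max_len = 65L,
    spacer_max_mismatches = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0L) {
    stop(sprintf("unknown parameter(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  p[names(over)] <- over
  structure(p, class = "pipeline_params")
}

#' Read pipeline parameters from a flat key=value file
#'
#' One `key=value` pair per line; blank lines and lines starting with `#`
#' are ignored. Keys must match the names in [pipeline_params]; values
#' are parsed as numbers.
#'
#' @param path Path to the config file.
#' @return A `pipeline_params` object with file values overriding the
#'   defaults.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(pipeline_params())
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) {
    stop("config lines must be 'key=value'", call. = FALSE)
  }
  keys <- trimws(vapply(kv, `[`, character(1), 1L))
  vals <- as.numeric(trimws(vapply(kv, `[`, character(1), 2L)))
  if (any(is.na(vals))) stop("config values must be numeric", call. = FALSE)
  do.call(pipeline_params, stats::setNames(as.list(vals), keys))
}

stage_log <- function(quiet, fmt, ...) {
  if (!quiet) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  }
}

# Assemble genus_group objects for the current circular/linear status of
# each contig. `circular_ids` are the contigs currently treated as
# complete circles; external members take their lengths from ref_lengths.
build_groups <- function(groups_df, lengths_by_id, ref_lengths,
                         circular_ids) {
  ref <- if (is.null(ref_lengths)) {
    stats::setNames(numeric(), character())
  } else {
    stats::setNames(ref_lengths$length, ref_lengths$seq_id)
  }
  out <- list()
  for (gid in unique(groups_df$group_id)) {
    g <- groups_df[groups_df$group_id == gid, , drop = FALSE]
    iso <- numeric(); circ <- numeric(); lin <- numeric(); lin_ids <- character()
    for (k in seq_len(nrow(g))) {
      sid <- g$seq_id[k]
      len <- if (sid %in% names(lengths_by_id)) lengths_by_id[[sid]]
             else if (sid %in% names(ref)) ref[[sid]]
             else NA_real_
      if (is.na(len)) next
      if (g$member_class[k] == "isolate_reference") {
        iso <- c(iso, len)
      } else if (sid %in% names(lengths_by_id)) {
        # our contig: trust the detector, not the table's class
        if (sid %in% circular_ids) circ <- c(circ, len)
        else { lin <- c(lin, len); lin_ids <- c(lin_ids, sid) }
      } else if (g$member_class[k] == "circular") {
        circ <- c(circ, len)
      } else {
        lin <- c(lin, len); lin_ids <- c(lin_ids, sid)
      }
    }
    out[[gid]] <- genus_group(gid, iso, circ, lin, lin_ids)
  }
  out
}

#' Run the full curation pipeline
#'
#' Executes the stages in dependency order: circularity detection, vOTU
#' clustering, marker affiliation, false-positive circular filtering,
#' predicted genome size and completeness, quality tiering, host-domain
#' classification and host assignment (cluster propagation plus CRISPR
#' spacer matching), then writes the consolidated 13-column report.
#' Stages whose inputs are not supplied are skipped and their report
#' columns left `NA`. Stage progress is logged to standard error.
#'
#' @param fasta Path to the contig FASTA, or a named list of
#'   [viral_contig] objects.
#' @param hits Optional marker hit table: path or data frame (see
#'   [read_hit_table]).
#' @param groups Optional genus-level group membership: path or data
#'   frame (see [read_group_table]).
#' @param ref_lengths Optional reference genome lengths: path or data
#'   frame (see [read_ref_lengths]).
#' @param taxon_lengths Optional taxon average genome lengths: path or
#'   data frame (see [read_taxon_lengths]).
#' @param vpf_hits Optional VPF scoring table: path or data frame with
#'   columns `model_id`, `domain`.
#' @param contig_vpf_hits Optional contig-to-VPF hit table: path or data
#'   frame with columns `contig_id`, `model_id`.
#' @param hosts Optional host label table: path or data frame (see
#'   [read_host_table]).
#' @param spacers Optional CRISPR spacer sequences: path to a FASTA or a
#'   named character vector.
#' @param out Optional output path for the report (see [write_report]).
#' @param params A [pipeline_params] object.
#' @param quiet Suppress stage logging.
#' @return Invisibly, the report data frame.
#' @export
run_pipeline <- function(fasta, hits = NULL, groups = NULL,
                         ref_lengths = NULL, taxon_lengths = NULL,
                         vpf_hits = NULL, contig_vpf_hits = NULL,
                         hosts = NULL, spacers = NULL, out = NULL,
                         params = pipeline_params(), quiet = FALSE) {
  # pre-flight: every supplied path must exist before any stage runs
  for (arg in list(fasta, hits, groups, ref_lengths, taxon_lengths,
                   vpf_hits, contig_vpf_hits, hosts, spacers)) {
    if (is.character(arg) && length(arg) == 1L && is.null(names(arg)) &&
        !file.exists(arg)) {
      stop(sprintf("input file not found: %s", arg), call. = FALSE)
    }
  }
  load_tbl <- function(x, reader) {
    if (is.null(x) || is.data.frame(x)) x else reader(x)
  }
  contigs <- if (is.character(fasta)) read_fasta(fasta) else fasta
  hits <- load_tbl(hits, read_hit_table)
  groups <- load_tbl(groups, read_group_table)
  ref_lengths <- load_tbl(ref_lengths, read_ref_lengths)
  taxon_lengths <- load_tbl(taxon_lengths, read_taxon_lengths)
  vpf_hits <- load_tbl(vpf_hits, function(p)
    read_tsv_checked(p, c("model_id", "domain"), "VPF scoring"))
  contig_vpf_hits <- load_tbl(contig_vpf_hits, function(p)
    read_tsv_checked(p, c("contig_id", "model_id"), "contig VPF hit"))
  hosts <- load_tbl(hosts, read_host_table)
  if (is.character(spacers) && length(spacers) == 1L && is.null(names(spacers))) {
    spacers <- vapply(read_fasta(spacers), `[[`, character(1), "sequence")
  }

  ids <- contig_ids(contigs)
  names(contigs) <- ids
  lens <- contig_lengths(contigs)
  stage_log(quiet, "input: %d contigs", length(contigs))

  cparams <- circularity_params(params$min_dtr_len,
                                params$min_terminal_repeat_len,
                                params$terminal_window,
                                params$max_repeat_len)
  circ <- detect_circularity_all(contigs, cparams)
  contigs <- circ$contigs
  stage_log(quiet, "circularity: %d/%d circular",
            sum(circ$table$circular), length(contigs))

  votus <- build_votus(contigs,
                       clustering_params(params$min_ani_pct,
                                         params$min_af_pct))
  votu_df <- as.data.frame(votus)
  stage_log(quiet, "clustering: %d vOTUs for %d sequences",
            length(votus), nrow(votu_df))

  affiliations <- stats::setNames(vector("list", length(ids)), ids)
  if (!is.null(hits)) {
    for (id in ids) {
      affiliations[[id]] <- affiliate_by_markers(hits, id, taxon_lengths)
    }
    stage_log(quiet, "affiliation: %d/%d contigs affiliated",
              sum(!vapply(affiliations, is.null, logical(1))), length(ids))
  }

  circular_ids <- circ$table$contig_id[circ$table$circular]
  group_of <- if (!is.null(groups)) {
    stats::setNames(groups$group_id, groups$seq_id)
  } else stats::setNames(character(), character())

  # false-positive filtering against the initial groups, then rebuild the
  # groups with flagged circles demoted to linear before size prediction
  fp <- stats::setNames(rep(FALSE, length(ids)), ids)
  fp_reason <- stats::setNames(rep("", length(ids)), ids)
  if (length(circular_ids) > 0L) {
    glist <- if (!is.null(groups)) {
      build_groups(groups, lens, ref_lengths, circular_ids)
    } else list()
    for (id in circular_ids) {
      grp <- if (id %in% names(group_of)) glist[[group_of[[id]]]] else NULL
      res <- flag_false_positive_circular(
        contigs[[id]], grp, affiliations[[id]],
        length_fraction = params$fp_length_fraction,
        min_circular_len = params$min_circular_len)
      fp[id] <- res$false_positive
      fp_reason[id] <- res$reason
    }
    stage_log(quiet, "false-positive filter: %d/%d circular contigs flagged",
              sum(fp[circular_ids]), length(circular_ids))
  }
  complete_circular_ids <- setdiff(circular_ids, names(fp)[fp])

  predicted_size <- stats::setNames(rep(NA_real_, length(ids)), ids)
  if (!is.null(groups)) {
    glist <- build_groups(groups, lens, ref_lengths, complete_circular_ids)
    gsize <- vapply(glist, function(g)
      as.numeric(predicted_genome_size(g, params$max_group_sd_frac)),
      numeric(1))
    in_group <- ids %in% names(group_of)
    predicted_size[in_group] <-
      gsize[unname(group_of[ids[in_group]])]
    stage_log(quiet, "genome size: %d/%d groups with a predicted size",
              sum(!is.na(gsize)), length(gsize))
  }

  completeness <- stats::setNames(rep(NA_real_, length(ids)), ids)
  tier <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (id in ids) {
    is_complete_circ <- id %in% complete_circular_ids
    if (is_complete_circ) {
      completeness[id] <- 100
    } else {
      aff <- affiliations[[id]]
      size_ref <- if (!is.null(aff) && !is.na(aff$mean_taxon_genome_length)) {
        aff$mean_taxon_genome_length
      } else {
        predicted_size[[id]]
      }
      completeness[id] <- estimate_completeness(
        contigs[[id]], size_ref, cap_pct = params$near_complete_pct)
    }
    tier[id] <- assign_quality_tier(
      contigs[[id]], false_positive = fp[[id]],
      completeness_pct = if (is_complete_circ) NA_real_ else completeness[[id]],
      hq_min_completeness = params$hq_min_completeness)
  }
  stage_log(quiet, "quality: %s",
            paste(sprintf("%s=%d", names(table(tier)), as.integer(table(tier))),
                  collapse = ", "))

  host_domain <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(vpf_hits) && !is.null(contig_vpf_hits)) {
    ctx <- scoring_context(average_hits = params$average_vpf_hits)
    profiles <- vpf_profiles(vpf_hits, ctx)
    signatures <- select_signature_vpfs(profiles, ctx)
    for (id in ids) {
      mh <- contig_vpf_hits$model_id[contig_vpf_hits$contig_id == id]
      host_domain[id] <- classify_host_domain(mh, signatures)
    }
    stage_log(quiet, "host domain: %d signature VPFs, %d/%d contigs classified",
              nrow(signatures), sum(host_domain != "unclassified"), length(ids))
  }

  host_pred <- stats::setNames(rep(NA_character_, length(ids)), ids)
  host_method <- stats::setNames(rep(NA_character_, length(ids)), ids)
  if (!is.null(hosts)) {
    contig_labels <- hosts[hosts$source != "spacer", , drop = FALSE]
    propagated <- propagate_cluster_hosts(votu_df, contig_labels)
    for (k in seq_len(nrow(propagated))) {
      id <- propagated$seq_id[k]
      if (id %in% ids && is.na(host_pred[id])) {
        host_pred[id] <- propagated$host_lineage[k]
        host_method[id] <- propagated$source[k]
      }
    }
    if (!is.null(spacers)) {
      spacer_labels <- hosts[hosts$source == "spacer", , drop = FALSE]
      matches <- match_spacers(
        contigs, spacers,
        max_mismatches = params$spacer_max_mismatches,
        len_range = c(params$spacer_min_len, params$spacer_max_len))
      for (k in seq_len(nrow(matches))) {
        lab <- spacer_labels$host_lineage[
          spacer_labels$seq_id == matches$spacer_id[k]]
        if (length(lab) == 0L) next
        id <- matches$contig_id[k]
        if (is.na(host_pred[id])) {
          host_pred[id] <- lab[1L]
          host_method[id] <- "spacer"
        } else if (host_method[id] != "spacer") {
          # keep both lines of evidence, tagged by method
          host_method[id] <- paste(host_method[id], "spacer", sep = "+")
          if (!identical(host_pred[id], lab[1L])) {
            host_pred[id] <- paste(host_pred[id], lab[1L], sep = "|")
          }
        }
      }
    }
    stage_log(quiet, "host assignment: %d/%d contigs with a host",
              sum(!is.na(host_pred)), length(ids))
  }

  votu_of <- stats::setNames(votu_df$votu_name, votu_df$seq_id)
  report <- data.frame(
    contig_id = ids,
    length = unname(lens),
    circular = circ$table$circular,
    circular_mechanism = ifelse(circ$table$circular, circ$table$mechanism, NA),
    false_positive_circular = ifelse(circ$table$circular, unname(fp[ids]), NA),
    votu = unname(votu_of[ids]),
    taxon = vapply(ids, function(id) {
      a <- affiliations[[id]]; if (is.null(a)) NA_character_ else a$taxon
    }, character(1)),
    predicted_genome_size = unname(predicted_size[ids]),
    completeness_pct = unname(completeness[ids]),
    quality_tier = unname(tier[ids]),
    host_domain = unname(host_domain[ids]),
    host_prediction = unname(host_pred[ids]),
    host_method = unname(host_method[ids]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (!is.null(out)) {
    write_report(report, out)
    stage_log(quiet, "report: %d rows -> %s", nrow(report), out)
  }
  invisible(report)
}
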