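#' Random nucleotide sequence
#'
#' Draws a sequence with uniform base composition over `A/C/G/T` from the
#' current RNG stream (wrap in a seeded context, or use the seeded
#' generators below, for reproducibility).
#'
#' @param n Length in bp.
#' @return A nucleotide string.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

plant_segment <- function(seqstr, segment, start0) {
  # start0 is 0-based
  substr(seqstr, start0 + 1L, start0 + nchar(segment)) <- segment
  seqstr
}

#' Generate a contig with a planted terminal repeat
#'
#' Builds a random backbone and plants the requested repeat, for
#' exercising the circularity detector with a known ground truth:
#'
#' * `direct_terminal`: the first `repeat_len` bases are copied over the
#'   3' end (a direct terminal repeat of exactly `repeat_len`);
#' * `direct_windowed`: two copies of a random `repeat_len`-mer, the 5'
#'   copy starting 3 bp from the 5' end and the 3' copy ending 3 bp
#'   before the 3' end;
#' * `inverted`: as `direct_windowed`, with the 3' copy
#'   reverse-complemented.
#'
#' With `repeat_len = 0` a plain backbone is returned. A rejection loop
#' regenerates the backbone until the planted repeat is the only signal:
#' the longest prefix/suffix match equals the planted length (or stays
#' below `verify_params$min_dtr_len`), and no incidental windowed repeat
#' reaches the detection floor.
#'
#' @param seed Integer seed; the same seed and arguments always return
#'   the same contig.
#' @param length Contig length in bp.
#' @param repeat_len Planted repeat length in bp (0 for none).
#' @param mode One of `"direct_terminal"`, `"direct_windowed"`,
#'   `"inverted"`.
#' @param id Contig id; a descriptive default is derived from the
#'   arguments.
#' @param verify_params [circularity_params] defining the detection
#'   floors the rejection loop guards against.
#' @return A [viral_contig].
#' @export
make_circular_genome <- function(seed, length = 5000L, repeat_len = 12L,
                                 mode = c("direct_terminal",
                                          "direct_windowed", "inverted"),
                                 id = NULL,
                                 verify_params = circularity_params()) {
  mode <- match.arg(mode)
  length <- as.integer(length)
  repeat_len <- as.integer(repeat_len)
  if (repeat_len >= length / 2) {
    stop("repeat_len must be < length / 2", call. = FALSE)
  }
  w <- verify_params$terminal_window
  if (repeat_len > 0L && mode != "direct_terminal" &&
      repeat_len + 3L > w + verify_params$max_repeat_len) {
    stop("planted repeat does not fit the terminal window", call. = FALSE)
  }
  id <- id %||% sprintf("fix_%s_len%d_k%d_seed%d", mode, length, repeat_len,
                        seed)
  with_seed(seed, {
    for (attempt in 1:200) {
      s <- random_dna(length)
      if (repeat_len > 0L) {
        if (mode == "direct_terminal") {
          s <- plant_segment(s, substr(s, 1L, repeat_len),
                             length - repeat_len)
        } else {
          motif <- random_dna(repeat_len)
          s <- plant_segment(s, motif, 3L)
          tail_copy <- if (mode == "inverted") revcomp_chr(motif) else motif
          s <- plant_segment(s, tail_copy, length - 3L - repeat_len)
        }
      }
      ch <- seq_chars(s)
      border <- longest_clean_border(ch)
      dscan <- scan_terminal_repeat(ch, w, 1L, verify_params$max_repeat_len,
                                    inverted = FALSE)
      vscan <- scan_terminal_repeat(ch, w, 1L, verify_params$max_repeat_len,
                                    inverted = TRUE)
      dmax <- dscan$len
      vmax <- vscan$len
      floor_ok <- switch(
        mode,
        direct_terminal =
          border == repeat_len &&
          # the planted DTR itself is visible to the windowed scan, so
          # accept dmax == repeat_len; anything else must stay sub-floor
          (dmax == repeat_len ||
             dmax < verify_params$min_terminal_repeat_len) &&
          vmax < verify_params$min_terminal_repeat_len,
        direct_windowed =
          border < verify_params$min_dtr_len &&
          dmax == repeat_len &&
          vmax < verify_params$min_terminal_repeat_len,
        inverted =
          border < verify_params$min_dtr_len &&
          dmax < verify_params$min_terminal_repeat_len &&
          vmax == repeat_len
      )
      if (repeat_len == 0L) {
        floor_ok <- border < verify_params$min_dtr_len &&
          dmax < verify_params$min_terminal_repeat_len &&
          vmax < verify_params$min_terminal_repeat_len
      }
      if (floor_ok) {
        ct <- viral_contig(id, s)
        # attach the call implied by the verified repeat content, so the
        # fixture is usable directly by downstream stages
        ct$circularity <- if (border >= verify_params$min_dtr_len) {
          new_circularity_call(TRUE, "DTR", border, 0L, length - border)
        } else if (dscan$len >= verify_params$min_terminal_repeat_len) {
          new_circularity_call(TRUE, "direct_internal", dscan$len,
                               dscan$p5, dscan$p3)
        } else if (vscan$len >= verify_params$min_terminal_repeat_len) {
          new_circularity_call(TRUE, "inverted", vscan$len, vscan$p5,
                               vscan$p3)
        } else {
          new_circularity_call(FALSE)
        }
        return(ct)
      }
    }
    stop("could not generate a clean backbone in 200 attempts", call. = FALSE)
  })
}

#' Mutate a sequence to a target identity
#'
#' Substitutes exactly `round((1 - target/100) * length)` positions, drawn
#' without replacement, each to a different base (so the realised identity
#' to the input is exactly the target, up to rounding). `N` positions are
#' never introduced.
#'
#' @param seq Nucleotide string.
#' @param target_identity_pct Target identity in (0, 100\].
#' @param seed Integer seed.
#' @return The mutated sequence.
#' @export
mutate_to_identity <- function(seq, target_identity_pct, seed) {
  if (target_identity_pct <= 0 || target_identity_pct > 100) {
    stop("target identity must be in (0, 100]", call. = FALSE)
  }
  n <- nchar(seq)
  k <- round((1 - target_identity_pct / 100) * n)
  if (k == 0) return(seq)
  with_seed(seed, {
    pos <- sample.int(n, k)
    ch <- seq_chars(seq)
    bases <- c("A", "C", "G", "T")
    for (p in pos) {
      alt <- setdiff(bases, ch[p])
      ch[p] <- alt[sample.int(length(alt), 1L)]
    }
    paste(ch, collapse = "")
  })
}

#' Build a VPF hit table with chosen per-domain counts
#'
#' @param spec A named list: model id -> named count vector, e.g.
#'   `list(m1 = c(prokaryotic = 7), m2 = c(prokaryotic = 3, eukaryotic = 3))`.
#' @return A data frame with columns `model_id`, `domain`, one row per
#'   hit, in deterministic order.
#' @export
make_vpf_hit_table <- function(spec) {
  if (length(spec) == 0L) {
    return(data.frame(model_id = character(), domain = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(names(spec), function(m) {
    counts <- spec[[m]]
    bad <- setdiff(names(counts), HOST_DOMAINS)
    if (length(bad) > 0L) {
      stop(sprintf("unknown domain(s) in spec: %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    data.frame(model_id = m,
               domain = rep(names(counts), times = counts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Draw synthetic CRISPR spacers from contigs
#'
#' Extracts `n` substrings with lengths uniform in `len_range`, from
#' random contigs, positions and strands, and applies exactly
#' `mismatches` forced substitutions to each. The returned table records
#' the ground truth, so recovery by [match_spacers] can be checked
#' exactly.
#'
#' @param contigs A named list of [viral_contig] objects or named
#'   character vector.
#' @param n Number of spacers.
#' @param len_range Length range in bp. Default `c(25, 65)`.
#' @param mismatches Substitutions planted per spacer. Default 0.
#' @param seed Integer seed.
#' @return A data frame: `spacer_id`, `sequence`, `contig_id`, `position`
#'   (1-based start of the source window on the forward strand),
#'   `strand`, `mismatches`.
#' @export
make_spacer_set <- function(contigs, n, len_range = c(25L, 65L),
                            mismatches = 0L, seed = 1L) {
  if (is.character(contigs)) {
    ids <- names(contigs)
    seqs <- toupper(unname(contigs))
  } else {
    ids <- contig_ids(contigs)
    seqs <- vapply(contigs, `[[`, character(1), "sequence")
  }
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(k) {
      len <- sample(len_range[1L]:len_range[2L], 1L)
      ci <- sample.int(length(ids), 1L)
      L <- nchar(seqs[ci])
      if (L < len) stop("contig shorter than requested spacer", call. = FALSE)
      start <- sample.int(L - len + 1L, 1L)
      strand <- sample(c("+", "-"), 1L)
      s <- substr(seqs[ci], start, start + len - 1L)
      if (strand == "-") s <- revcomp_chr(s)
      if (mismatches > 0L) {
        ch <- seq_chars(s)
        pos <- sample.int(len, mismatches)
        for (p in pos) {
          alt <- setdiff(c("A", "C", "G", "T"), ch[p])
          ch[p] <- alt[sample.int(3L, 1L)]
        }
        s <- paste(ch, collapse = "")
      }
      data.frame(spacer_id = sprintf("spacer_%d", k), sequence = s,
                 contig_id = ids[ci], position = start, strand = strand,
                 mismatches = mismatches, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
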