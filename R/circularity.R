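#' Parameters for terminal-repeat circularity detection
#'
#' Assembled circular genomes leave a signature in linear contigs: an
#' identical sequence at the 5' and 3' ends (a direct terminal repeat,
#' DTR), or a direct or inverted repeat close to both ends. The defaults
#' encode the detection rules used here: a DTR of at least 10 bp, or a
#' direct/inverted repeat of at least 20 bp whose copies lie within 50 bp
#' of the respective contig ends.
#'
#' @param min_dtr_len Minimum length (bp) of an exact prefix/suffix match
#'   to call a direct terminal repeat. Default 10.
#' @param min_terminal_repeat_len Minimum length (bp) of a windowed direct
#'   or inverted repeat. Default 20.
#' @param terminal_window Window (bp): the 5' copy must start within this
#'   distance of the 5' end and the 3' copy must end within this distance
#'   of the 3' end. Default 50.
#' @param max_repeat_len Longest windowed repeat the scanner considers
#'   (bp); bounds the search region at each terminus. Default 1000.
#' @return An object of class `circularity_params`.
#' @export
circularity_params <- function(min_dtr_len = 10L,
                               min_terminal_repeat_len = 20L,
                               terminal_window = 50L,
                               max_repeat_len = 1000L) {
  assert_scalar_number(min_dtr_len, "min_dtr_len")
  assert_scalar_number(min_terminal_repeat_len, "min_terminal_repeat_len")
  assert_scalar_number(terminal_window, "terminal_window")
  assert_scalar_number(max_repeat_len, "max_repeat_len")
  if (min_dtr_len > min_terminal_repeat_len) {
    stop("min_dtr_len must not exceed min_terminal_repeat_len", call. = FALSE)
  }
  structure(
    list(min_dtr_len = as.integer(min_dtr_len),
         min_terminal_repeat_len = as.integer(min_terminal_repeat_len),
         terminal_window = as.integer(terminal_window),
         max_repeat_len = as.integer(max_repeat_len)),
    class = "circularity_params"
  )
}

new_circularity_call <- function(is_circular, mechanism = "none",
                                 repeat_length = 0L,
                                 five_prime_pos = NA_integer_,
                                 three_prime_pos = NA_integer_) {
  structure(
    list(is_circular = is_circular,
         mechanism = mechanism,
         repeat_length = as.integer(repeat_length),
         five_prime_pos = five_prime_pos,
         three_prime_pos = three_prime_pos),
    class = "circularity_call"
  )
}

#' @export
print.circularity_call <- function(x, ...) {
  if (x$is_circular) {
    cat(sprintf(
      "<circularity_call> circular: %s, %d bp repeat (5' copy at %d, 3' copy at %d; 0-based)\n",
      x$mechanism, x$repeat_length, x$five_prime_pos, x$three_prime_pos))
  } else {
    cat("<circularity_call> not circular\n")
  }
  invisible(x)
}

# Longest proper prefix of `ch` that is also a suffix (a "border"),
# excluding any border containing N. Standard KMP failure function; the
# chain f[L], f[f[L]], ... enumerates all borders longest-first, so we walk
# it until an N-free border is found.
longest_clean_border <- function(ch) {
  L <- length(ch)
  if (L < 2L) return(0L)
  f <- integer(L)
  k <- 0L
  for (i in 2:L) {
    while (k > 0L && ch[i] != ch[k + 1L]) k <- f[k]
    if (ch[i] == ch[k + 1L]) k <- k + 1L
    f[i] <- k
  }
  b <- f[L]
  while (b > 0L) {
    if (!any(ch[seq_len(b)] == "N")) return(b)
    b <- f[b]
  }
  0L
}

# Scan for the longest exact repeat whose 5' copy starts within `w` of the
# 5' end and whose 3' copy (reverse-complemented when inverted = TRUE) ends
# within `w` of the 3' end. Works on two terminal regions of length
# w + cap, sliding one against the other; matches are maximal runs in the
# per-shift equality vector (N never matches). All coordinates 0-based.
scan_terminal_repeat <- function(ch, w, min_len, cap, inverted = FALSE) {
  L <- length(ch)
  lenA <- min(L, w + cap)
  A <- ch[seq_len(lenA)]
  b0 <- max(0L, L - (w + cap))          # 0-based offset of region B
  B <- ch[(b0 + 1L):L]
  lenB <- length(B)
  if (inverted) B <- rev(unname(DNA_COMP[B]))
  okA <- A != "N"
  okB <- B != "N"
  best <- list(len = 0L, p5 = NA_integer_, p3 = NA_integer_)
  for (s in (-(lenA - 1L)):(lenB - 1L)) {
    i0 <- max(0L, -s)
    i1 <- min(lenA - 1L, lenB - 1L - s)
    needed <- max(min_len, best$len + 1L)  # only improvements matter
    if (i1 - i0 + 1L < needed) next
    ii <- i0:i1
    eq <- (A[ii + 1L] == B[ii + 1L + s]) & okA[ii + 1L] & okB[ii + 1L + s]
    r <- rle(eq)
    keep <- r$values & r$lengths >= needed
    if (!any(keep)) next
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    p5 <- ii[run_start[keep]]             # 0-based starts of 5' copies
    l <- r$lengths[keep]
    if (!inverted) {
      start3 <- b0 + p5 + s
      end3 <- start3 + l                  # 0-based exclusive
      ok <- p5 <= w & start3 > p5 & (L - end3) <= w
    } else {
      c0 <- p5 + s                        # run starts in the revcomp region
      end3 <- b0 + lenB - c0
      start3 <- end3 - l
      ok <- p5 <= w & c0 <= w & start3 > p5
    }
    if (any(ok)) {
      j <- which(ok)[which.max(l[ok])]
      best <- list(len = l[j], p5 = p5[j], p3 = start3[j])
    }
  }
  best
}

#' Detect circularity of a contig from terminal repeats
#'
#' Applies three rules in order; the first satisfied rule determines the
#' mechanism, and the longest qualifying repeat for that mechanism is
#' reported:
#'
#' 1. **DTR**: the longest exact match between a prefix and a suffix of the
#'    sequence is at least `min_dtr_len` (default 10 bp).
#' 2. **direct_internal**: an exact direct repeat of at least
#'    `min_terminal_repeat_len` (default 20 bp) whose 5' copy starts within
#'    `terminal_window` (default 50 bp) of the 5' end and whose 3' copy
#'    ends within the window of the 3' end.
#' 3. **inverted**: as rule 2, but the 3' copy is the reverse complement of
#'    the 5' copy (inverted terminal repeat).
#'
#' Matches are exact; `N` never matches anything, including another `N`.
#' Positions in the returned call are 0-based offsets of the two copies'
#' starts.
#'
#' @param x A [viral_contig] or a nucleotide string.
#' @param params A [circularity_params] object.
#' @return A `circularity_call` with fields `is_circular`, `mechanism`
#'   (`"DTR"`, `"direct_internal"`, `"inverted"` or `"none"`),
#'   `repeat_length`, `five_prime_pos`, `three_prime_pos`.
#' @examples
#' s <- paste(rep("ACGTTGCAGG", 30), collapse = "")
#' # too short relative to the terminal window: warns and returns no call
#' @export
detect_circularity <- function(x, params = circularity_params()) {
  seqstr <- as_sequence_string(x)
  L <- nchar(seqstr)
  if (L <= 2L * params$terminal_window) {
    warning(sprintf(
      "sequence length %d <= 2 * terminal_window (%d); circularity undefined",
      L, 2L * params$terminal_window), call. = FALSE)
    return(new_circularity_call(FALSE))
  }
  ch <- seq_chars(seqstr)

  # Rule 1: direct terminal repeat (strictly terminal prefix/suffix match)
  b <- longest_clean_border(ch)
  if (b >= params$min_dtr_len) {
    return(new_circularity_call(TRUE, "DTR", b, 0L, L - b))
  }

  # Rule 2: direct repeat within the terminal windows
  d <- scan_terminal_repeat(ch, params$terminal_window,
                            params$min_terminal_repeat_len,
                            params$max_repeat_len, inverted = FALSE)
  if (d$len >= params$min_terminal_repeat_len) {
    return(new_circularity_call(TRUE, "direct_internal", d$len, d$p5, d$p3))
  }

  # Rule 3: inverted repeat within the terminal windows
  v <- scan_terminal_repeat(ch, params$terminal_window,
                            params$min_terminal_repeat_len,
                            params$max_repeat_len, inverted = TRUE)
  if (v$len >= params$min_terminal_repeat_len) {
    return(new_circularity_call(TRUE, "inverted", v$len, v$p5, v$p3))
  }

  new_circularity_call(FALSE)
}

#' Detect circularity for a set of contigs
#'
#' Runs [detect_circularity] on each contig and returns both the annotated
#' contigs and a summary table. Reported positions in the table are
#' 1-based inclusive starts.
#'
#' @param contigs A list of [viral_contig] objects.
#' @param params A [circularity_params] object.
#' @return A list with elements `contigs` (input contigs with their
#'   `circularity` field set) and `table` (data frame: `contig_id`,
#'   `length`, `circular`, `mechanism`, `repeat_length`, `five_prime_pos`,
#'   `three_prime_pos`).
#' @export
detect_circularity_all <- function(contigs, params = circularity_params()) {
  calls <- lapply(contigs, detect_circularity, params = params)
  contigs <- mapply(function(con, cl) { con$circularity <- cl; con },
                    contigs, calls, SIMPLIFY = FALSE)
  tab <- data.frame(
    contig_id = contig_ids(contigs),
    length = unname(contig_lengths(contigs)),
    circular = vapply(calls, `[[`, logical(1), "is_circular"),
    mechanism = vapply(calls, `[[`, character(1), "mechanism"),
    repeat_length = vapply(calls, `[[`, integer(1), "repeat_length"),
    five_prime_pos = vapply(calls, function(cl)
      if (is.na(cl$five_prime_pos)) NA_integer_ else cl$five_prime_pos + 1L,
      integer(1)),
    three_prime_pos = vapply(calls, function(cl)
      if (is.na(cl$three_prime_pos)) NA_integer_ else cl$three_prime_pos + 1L,
      integer(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(contigs = contigs, table = tab)
}
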