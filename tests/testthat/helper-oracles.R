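# Independent brute-force oracles used to cross-check the package's
# optimised implementations on small inputs.

CHARMAP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

chars_of <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

revcomp_of <- function(s) paste(rev(unname(CHARMAP[chars_of(s)])), collapse = "")

# Longest exact prefix/suffix match (N excluded), by checking every length
# from the longest down.
oracle_dtr_len <- function(seqstr) {
  ch <- chars_of(seqstr)
  L <- length(ch)
  for (len in (L - 1L):1L) {
    pre <- ch[seq_len(len)]
    if (any(pre == "N")) next
    if (all(pre == ch[(L - len + 1L):L])) return(len)
  }
  0L
}

# Longest direct (or inverted) repeat with the 5' copy starting within w of
# the 5' end and the 3' copy ending within w of the 3' end. Scans every
# alignment shift of the full sequence against itself (or its reverse
# complement); no search-region shortcuts, no length cap.
oracle_windowed_repeat_len <- function(seqstr, w, min_len, inverted = FALSE) {
  ch <- chars_of(seqstr)
  L <- length(ch)
  other <- if (inverted) rev(unname(CHARMAP[ch])) else ch
  ok1 <- ch != "N"
  ok2 <- other != "N"
  best <- 0L
  shifts <- if (inverted) (-w):w else 1L:(L - 1L)
  for (s in shifts) {
    i0 <- max(1L, 1L - s)
    i1 <- min(L, L - s)
    if (i1 < i0) next
    idx <- i0:i1
    eq <- (ch[idx] == other[idx + s]) & ok1[idx] & ok2[idx + s]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= max(min_len, best + 1L))) {
      i <- idx[starts[k]]          # 1-based start of 5' copy
      l <- r$lengths[k]
      j <- i + s                   # 1-based start in `other`
      if (i - 1L > w) next
      if (!inverted) {
        # partner copy in sequence coordinates starts at j
        if (j <= i) next
        if (L - (j + l - 1L) > w) next
      } else {
        # `other` position j maps to sequence position L + 1 - j; the
        # partner copy ends at L + 1 - j and must be within w of the end
        if (j - 1L > w) next
        p3_start <- L + 1L - (j + l - 1L)
        if (p3_start <= i) next
      }
      if (l > best) best <- l
    }
  }
  best
}

# Full circularity decision from the oracles, mirroring the rule order.
oracle_circularity <- function(seqstr, min_dtr = 10L, min_rep = 20L,
                               w = 50L) {
  b <- oracle_dtr_len(seqstr)
  if (b >= min_dtr) return(list(circular = TRUE, mechanism = "DTR", len = b))
  d <- oracle_windowed_repeat_len(seqstr, w, min_rep, inverted = FALSE)
  if (d >= min_rep) {
    return(list(circular = TRUE, mechanism = "direct_internal", len = d))
  }
  v <- oracle_windowed_repeat_len(seqstr, w, min_rep, inverted = TRUE)
  if (v >= min_rep) {
    return(list(circular = TRUE, mechanism = "inverted", len = v))
  }
  list(circular = FALSE, mechanism = "none", len = 0L)
}

# Sliding-window spacer matcher: every offset, both strands, full-length
# comparison with N counting as a mismatch.
oracle_spacer_matches <- function(contig_seq, spacer_seq, max_mm) {
  x <- chars_of(toupper(contig_seq))
  L <- length(x)
  out <- list()
  for (strand in c("+", "-")) {
    p <- if (strand == "+") toupper(spacer_seq) else revcomp_of(toupper(spacer_seq))
    pch <- chars_of(p)
    m <- length(pch)
    if (L < m) next
    mm <- integer(L - m + 1L)
    for (k in seq_len(m)) {
      xi <- x[k:(L - m + k)]
      mm <- mm + (xi != pch[k] | xi == "N" | pch[k] == "N")
    }
    hit <- which(mm <= max_mm)
    if (length(hit) > 0L) {
      out[[strand]] <- data.frame(position = hit, strand = strand,
                                  mismatches = mm[hit],
                                  stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(position = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$strand, res$position), , drop = FALSE]
}

# Plain union-find over an explicit edge list.
uf_clusters <- function(ids, edges) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(edges) > 0L) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges$id1[k])
      rb <- find(edges$id2[k])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(ids, find, character(1))
  unname(lapply(split(ids, roots), sort))
}

# Canonical form of a clustering for set comparison.
cluster_signature <- function(members_list) {
  sig <- sort(vapply(members_list, function(m) paste(sort(m), collapse = ","),
                     character(1)))
  sig
}
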