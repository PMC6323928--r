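# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Complement lookup for the restricted alphabet used throughout the package.
DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

revcomp_chr <- function(x) {
  paste(rev(unname(DNA_COMP[seq_chars(x)])), collapse = "")
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible sub-seed from a top-level seed, kept inside the
# 32-bit integer range accepted by set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647)
}

assert_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# Extract the plain nucleotide string from the various sequence
# representations accepted by user-facing functions.
as_sequence_string <- function(x) {
  if (inherits(x, "viral_contig")) return(x$sequence)
  if (inherits(x, "DNAString") || inherits(x, "DNAStringSet")) {
    return(toupper(as.character(x)[1L]))
  }
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  stop("expected a viral_contig, DNAString or single character string",
       call. = FALSE)
}
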