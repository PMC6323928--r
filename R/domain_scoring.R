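#' Context for VPF host-domain scoring
#'
#' Viral protein families (VPFs) are scored for how uniformly their hits
#' to known viral genomes fall into a single host domain (prokaryotic vs
#' eukaryotic viruses). The score is penalised for families seen in fewer
#' genomes than the database-wide average number of hits per model.
#'
#' @param average_hits Database-wide average number of hits per VPF model.
#'   Default 6.8, the value derived from the reference virus database; it
#'   is a supplied parameter, not recomputed, but see
#'   [average_hits_from_profiles] to recompute it from a hit table.
#' @param signature_threshold Score a VPF must reach to count as a
#'   domain signature. Default 1.0.
#' @return An object of class `scoring_context`.
#' @export
scoring_context <- function(average_hits = 6.8, signature_threshold = 1.0) {
  assert_scalar_number(average_hits, "average_hits")
  assert_scalar_number(signature_threshold, "signature_threshold")
  structure(list(average_hits = average_hits,
                 signature_threshold = signature_threshold),
            class = "scoring_context")
}

HOST_DOMAINS <- c("prokaryotic", "eukaryotic")

#' VPF host-domain uniformity score
#'
#' For a model with hit counts per host domain, the base score is
#' (#uniform hits / #total hits), where the uniform hits are those in the
#' dominant domain (so a model hitting a single domain scores 1 before
#' correction). When the total number of hits is below `average_hits`,
#' the score is multiplied by (#total hits / average hits); the result is
#' clamped to \[0, 1\].
#'
#' The reading of "uniform hits" as the dominant-domain count is one of
#' two defensible interpretations; `mode = "strict"` implements the
#' alternative, where uniform hits equal the total only when every hit is
#' in one domain and are zero otherwise.
#'
#' @param hits_per_domain Named numeric vector of hit counts, names in
#'   `c("prokaryotic", "eukaryotic")`; total must be at least 1.
#' @param ctx A [scoring_context].
#' @param mode `"majority"` (default) or `"strict"` (see above).
#' @return Score in \[0, 1\].
#' @examples
#' vpf_uniformity_score(c(prokaryotic = 7))                 # 1.0
#' vpf_uniformity_score(c(prokaryotic = 6))                 # 6/6 * 6/6.8
#' vpf_uniformity_score(c(prokaryotic = 5, eukaryotic = 5)) # 0.5
#' @export
vpf_uniformity_score <- function(hits_per_domain, ctx = scoring_context(),
                                 mode = c("majority", "strict")) {
  mode <- match.arg(mode)
  if (is.null(names(hits_per_domain)) ||
      !all(names(hits_per_domain) %in% HOST_DOMAINS)) {
    stop(sprintf("hit counts must be named with domains in {%s}",
                 paste(HOST_DOMAINS, collapse = ", ")), call. = FALSE)
  }
  if (any(hits_per_domain < 0)) stop("hit counts must be >= 0", call. = FALSE)
  total <- sum(hits_per_domain)
  if (total < 1) stop("total hits must be >= 1", call. = FALSE)
  uniform <- if (mode == "majority") {
    max(hits_per_domain)
  } else {
    if (sum(hits_per_domain > 0) == 1L) total else 0
  }
  score <- uniform / total
  if (total < ctx$average_hits) score <- score * (total / ctx$average_hits)
  min(max(score, 0), 1)
}

#' Build per-model hit profiles from a VPF hit table
#'
#' @param hit_table Data frame with columns `model_id` and `domain` (one
#'   row per hit of the model to a known viral genome; `domain` in
#'   `c("prokaryotic", "eukaryotic")`).
#' @param ctx A [scoring_context].
#' @param mode Passed to [vpf_uniformity_score].
#' @return A data frame with one row per model: `model_id`,
#'   `prokaryotic`, `eukaryotic` (hit counts), `total_hits`,
#'   `uniform_hits`, `score`, `domain` (dominant domain, `NA` on a tie).
#' @export
vpf_profiles <- function(hit_table, ctx = scoring_context(),
                         mode = "majority") {
  stopifnot(all(c("model_id", "domain") %in% names(hit_table)))
  bad <- setdiff(unique(hit_table$domain), HOST_DOMAINS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown domain(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(hit_table) == 0L) {
    return(data.frame(model_id = character(), prokaryotic = integer(),
                      eukaryotic = integer(), total_hits = integer(),
                      uniform_hits = integer(), score = numeric(),
                      domain = character(), stringsAsFactors = FALSE))
  }
  tab <- table(hit_table$model_id, factor(hit_table$domain, HOST_DOMAINS))
  models <- rownames(tab)
  prok <- as.integer(tab[, "prokaryotic"])
  euk <- as.integer(tab[, "eukaryotic"])
  res <- data.frame(model_id = models, prokaryotic = prok, eukaryotic = euk,
                    total_hits = prok + euk, stringsAsFactors = FALSE)
  res$uniform_hits <- pmax(prok, euk)
  res$score <- vapply(seq_len(nrow(res)), function(i) {
    vpf_uniformity_score(c(prokaryotic = prok[i], eukaryotic = euk[i]),
                         ctx = ctx, mode = mode)
  }, numeric(1))
  res$domain <- ifelse(prok > euk, "prokaryotic",
                       ifelse(euk > prok, "eukaryotic", NA_character_))
  rownames(res) <- NULL
  res
}

#' Recompute the average hits per model from profiles
#'
#' @param profiles Output of [vpf_profiles] (models without hits are not
#'   represented and do not enter the average).
#' @return Mean of `total_hits`.
#' @export
average_hits_from_profiles <- function(profiles) {
  if (nrow(profiles) == 0L) stop("no profiles", call. = FALSE)
  mean(profiles$total_hits)
}

#' Select signature VPFs
#'
#' Signature VPFs are the models that reach the maximum uniformity score
#' (1.0): models seen in at least the average number of known viral
#' genomes, all from one host domain. Equality with 1.0 is tested as
#' `score >= threshold - 1e-9` to tolerate floating point.
#'
#' @param profiles Output of [vpf_profiles].
#' @param ctx A [scoring_context] (supplies `signature_threshold`).
#' @return A data frame `model_id`, `domain` of signature models.
#' @export
select_signature_vpfs <- function(profiles, ctx = scoring_context()) {
  keep <- profiles$score >= ctx$signature_threshold - 1e-9
  out <- profiles[keep, c("model_id", "domain"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a contig's host domain from signature VPF hits
#'
#' Counts the contig's hits to prokaryotic-signature and
#' eukaryotic-signature VPFs; a strict majority decides the domain, and a
#' tie or no signature hits leaves the contig unclassified.
#'
#' @param contig_vpf_hits Character vector of model ids hit by the contig
#'   (duplicates count as repeated hits).
#' @param signatures Signature table from [select_signature_vpfs].
#' @return `"prokaryotic"`, `"eukaryotic"` or `"unclassified"`.
#' @export
classify_host_domain <- function(contig_vpf_hits, signatures) {
  dom <- signatures$domain[match(contig_vpf_hits, signatures$model_id)]
  n_prok <- sum(dom == "prokaryotic", na.rm = TRUE)
  n_euk <- sum(dom == "eukaryotic", na.rm = TRUE)
  if (n_prok > n_euk) return("prokaryotic")
  if (n_euk > n_prok) return("eukaryotic")
  "unclassified"
}
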