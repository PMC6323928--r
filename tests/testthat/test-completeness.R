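mk_hits <- function(contig_id, taxa, classes, models = NULL) {
  n <- length(taxa)
  data.frame(contig_id = rep(contig_id, n),
             model_id = models %||% sprintf("VOG%03d", seq_len(n)),
             taxon = taxa, taxon_class = classes, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("marker affiliation enforces the per-class minima", {
  # two consistent dsDNA genus markers suffice
  a <- affiliate_by_markers(mk_hits("c1", c("GenusA", "GenusA"),
                                    c("dsDNA", "dsDNA")), "c1")
  expect_equal(a$taxon, "GenusA")
  expect_equal(a$n_supporting_markers, 2L)

  # a single dsDNA marker does not
  expect_null(affiliate_by_markers(mk_hits("c1", "GenusA", "dsDNA"), "c1"))

  # one ssDNA family marker is enough
  a <- affiliate_by_markers(mk_hits("c1", "FamB", "ssDNA"), "c1")
  expect_equal(a$taxon_class, "ssDNA")

  # NCLDV needs five markers
  expect_null(affiliate_by_markers(
    mk_hits("c1", rep("Mimi", 4), rep("NCLDV", 4)), "c1"))
  a <- affiliate_by_markers(mk_hits("c1", rep("Mimi", 5), rep("NCLDV", 5)), "c1")
  expect_equal(a$n_supporting_markers, 5L)
})

test_that("ties and class conflicts block affiliation", {
  expect_null(affiliate_by_markers(
    mk_hits("c1", c("GenusA", "GenusA", "GenusB", "GenusB"), rep("dsDNA", 4)),
    "c1"))
  expect_error(affiliate_by_markers(
    mk_hits("c1", c("GenusA", "GenusA"), c("dsDNA", "ssDNA")), "c1"),
    "conflicting")
  expect_null(affiliate_by_markers(mk_hits("c9", "GenusA", "dsDNA"), "c1"))
})

test_that("taxon mean genome length is filled from the lookup table", {
  tl <- data.frame(taxon = "GenusA", mean_length = 42000,
                   stringsAsFactors = FALSE)
  a <- affiliate_by_markers(mk_hits("c1", c("GenusA", "GenusA"),
                                    c("dsDNA", "dsDNA")), "c1", tl)
  expect_equal(a$mean_taxon_genome_length, 42000)
})

test_that("predicted genome size applies the 15% SD consistency rule", {
  g <- genus_group("g1", isolate_lengths = c(40000, 41000, 39000))
  size <- predicted_genome_size(g)
  expect_equal(as.numeric(size), 40000)
  expect_lt(attr(size, "sd"), 6000)
  expect_equal(attr(size, "sd"), sqrt(mean((c(40000, 41000, 39000) - 40000)^2)))

  # heterogeneous group: SD 15000 > 0.15 * 25000
  g <- genus_group("g2", isolate_lengths = c(10000, 40000))
  expect_true(is.na(predicted_genome_size(g)))

  # a single member has SD 0
  g <- genus_group("g3", circular_lengths = 40000)
  expect_equal(as.numeric(predicted_genome_size(g)), 40000)

  # no complete members at all
  expect_true(is.na(predicted_genome_size(genus_group("g4",
                                                      linear_lengths = 3e4))))

  # invariant to member order
  g1 <- genus_group("g", isolate_lengths = c(39000, 41000, 40000))
  g2 <- genus_group("g", isolate_lengths = c(41000, 40000, 39000))
  expect_identical(predicted_genome_size(g1), predicted_genome_size(g2))
})

circ_contig <- function(len, seed = 1) {
  make_circular_genome(seed, len, 20, "direct_terminal",
                       id = sprintf("circ%d", len))
}

test_that("false-positive circular rules fire in order with named reasons", {
  grp_iso <- genus_group("g", isolate_lengths = c(40000, 50000))
  r <- flag_false_positive_circular(circ_contig(30000), grp_iso)
  expect_true(r$false_positive)
  expect_equal(r$reason, "below_min_isolate_length")

  # 33 kb >= 0.8 * 40 kb: passes the isolate rule (and the 10 kb rule)
  r <- flag_false_positive_circular(circ_contig(33000), grp_iso)
  expect_false(r$false_positive)

  # no isolates: compare to the longest linear member
  grp_lin <- genus_group("g", linear_lengths = c(20000, 40000))
  r <- flag_false_positive_circular(circ_contig(30000), grp_lin)
  expect_true(r$false_positive)
  expect_equal(r$reason, "below_max_linear_length")

  # short circle without ssDNA/RNA affiliation
  r <- flag_false_positive_circular(circ_contig(8000))
  expect_true(r$false_positive)
  expect_equal(r$reason, "short_without_ssdna_rna_marker")

  # the ssDNA exemption
  aff <- affiliate_by_markers(mk_hits("c", "FamB", "ssDNA"), "c")
  r <- flag_false_positive_circular(circ_contig(8000), affiliation = aff)
  expect_false(r$false_positive)

  expect_error(flag_false_positive_circular(viral_contig("lin", "ACGT")),
               "circularity")
})

test_that("false-positive flagging is monotone in contig length", {
  grp <- genus_group("g", isolate_lengths = 40000)
  flags <- vapply(c(20000, 30000, 31999, 32000, 35000), function(len) {
    flag_false_positive_circular(circ_contig(len), grp)$false_positive
  }, logical(1))
  expect_false(is.unsorted(rev(flags)))   # TRUEs before FALSEs
  expect_equal(flags, c(TRUE, TRUE, TRUE, FALSE, FALSE))
})

test_that("completeness is length over reference with a 99% cap", {
  expect_equal(estimate_completeness(20000, 40000), 50)
  expect_equal(estimate_completeness(45000, 40000), 99)
  expect_true(is.na(estimate_completeness(20000, NA)))
  expect_error(estimate_completeness(20000, -1), "positive")
  ct <- viral_contig("c", strrep("ACGT", 1000))
  expect_equal(estimate_completeness(ct, 8000), 50)
})

test_that("quality tiers follow source, circularity and completeness", {
  iso <- viral_contig("i", "ACGTACGT", source_class = "isolate")
  expect_equal(assign_quality_tier(iso), "finished")

  circ <- circ_contig(12000)
  expect_equal(assign_quality_tier(circ, false_positive = FALSE),
               "complete_circular")
  expect_equal(assign_quality_tier(circ, false_positive = TRUE,
                                   completeness_pct = 30),
               "genome_fragment")

  lin <- viral_contig("l", strrep("ACGT", 1000))
  expect_equal(assign_quality_tier(lin, completeness_pct = 92),
               "high_quality_draft")
  expect_equal(assign_quality_tier(lin, completeness_pct = NA_real_),
               "genome_fragment")
})

test_that("the fragment-to-draft transition happens exactly once, at 90%", {
  size_ref <- 50000
  lens <- seq(0.80, 0.95, by = 0.01) * size_ref
  tiers <- vapply(lens, function(len) {
    assign_quality_tier(viral_contig("x", "ACGT"),
                        completeness_pct = estimate_completeness(len, size_ref))
  }, character(1))
  is_hq <- tiers == "high_quality_draft"
  expect_equal(sum(diff(is_hq) != 0), 1L)
  expect_equal(min(100 * lens[is_hq] / size_ref), 90)
})
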