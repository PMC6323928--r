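votus_df <- function(...) {
  clusters <- list(...)
  do.call(rbind, lapply(names(clusters), function(nm) {
    data.frame(seq_id = clusters[[nm]], votu_name = nm,
               n_members = length(clusters[[nm]]), stringsAsFactors = FALSE)
  }))
}

labels_df <- function(ids, lineages, source = "isolate") {
  data.frame(seq_id = ids, host_lineage = lineages, source = source,
             stringsAsFactors = FALSE)
}

test_that("cluster co-membership propagates host labels to unlabelled members", {
  v <- votus_df(vc_1 = c("iVG1", "U1", "U2"), sg_1 = "U3")
  lab <- labels_df("iVG1", "Bacteria;Firmicutes")
  out <- propagate_cluster_hosts(v, lab)
  got <- out[out$source == "cluster", ]
  expect_setequal(got$seq_id, c("U1", "U2"))
  expect_equal(unique(got$host_lineage), "Bacteria;Firmicutes")
  # the singleton stays unlabelled
  expect_false("U3" %in% out$seq_id)
})

test_that("conflicting labels collapse to their lowest common ancestor", {
  v <- votus_df(vc_1 = c("iVG1", "pro1", "U1"))
  lab <- labels_df(c("iVG1", "pro1"),
                   c("Bacteria;Firmicutes;Bacilli", "Bacteria;Proteobacteria"),
                   source = c("isolate", "prophage"))
  out <- propagate_cluster_hosts(v, lab)
  expect_equal(out$host_lineage[out$seq_id == "U1"], "Bacteria")
  # domain-level disagreement: no propagation
  lab2 <- labels_df(c("iVG1", "pro1"), c("Bacteria;Firmicutes", "Archaea"),
                    source = c("isolate", "prophage"))
  out2 <- propagate_cluster_hosts(v, lab2)
  expect_false("U1" %in% out2$seq_id)
})

test_that("propagation never overwrites an existing label and skips unknown ids", {
  v <- votus_df(vc_1 = c("iVG1", "U1"))
  lab <- labels_df(c("iVG1", "U1", "ghost"),
                   c("Bacteria;Firmicutes", "Bacteria;Bacteroidetes",
                     "Archaea;Euryarchaeota"))
  expect_warning(out <- propagate_cluster_hosts(v, lab), "ghost")
  expect_equal(out$host_lineage[out$seq_id == "U1"], "Bacteria;Bacteroidetes")
  expect_equal(sum(out$seq_id == "U1"), 1L)
})

test_that("lineage LCA handles depth differences and total disagreement", {
  expect_equal(lineage_lca(c("Bacteria;Firmicutes;Bacilli",
                             "Bacteria;Firmicutes")), "Bacteria;Firmicutes")
  expect_equal(lineage_lca(c("Bacteria;Firmicutes", "Archaea;Euryarchaeota")),
               "")
  expect_equal(lineage_lca("Bacteria;Firmicutes"), "Bacteria;Firmicutes")
})

test_that("spacer matching finds exact and near-exact occurrences on both strands", {
  set.seed(20)
  contig <- random_dna(3000)
  sp_plus <- substr(contig, 501, 530)            # exact 30-mer
  sp_minus <- revcomp_of(substr(contig, 1201, 1235))
  spacers <- c(sp1 = sp_plus, sp2 = sp_minus)
  m <- match_spacers(c(c1 = contig), spacers, max_mismatches = 1)
  m1 <- m[m$spacer_id == "sp1", ]
  expect_true(any(m1$position == 501 & m1$strand == "+" & m1$mismatches == 0))
  m2 <- m[m$spacer_id == "sp2", ]
  expect_true(any(m2$position == 1201 & m2$strand == "-" & m2$mismatches == 0))
})

test_that("the mismatch budget is a hard full-length limit with no indels", {
  set.seed(21)
  contig <- random_dna(2000)
  sp <- substr(contig, 301, 330)
  two_mm <- chars_of(sp)
  two_mm[5] <- setdiff(c("A", "C", "G", "T"), two_mm[5])[1]
  two_mm[20] <- setdiff(c("A", "C", "G", "T"), two_mm[20])[1]
  two_mm <- paste(two_mm, collapse = "")
  m <- match_spacers(c(c1 = contig), c(s2 = two_mm), max_mismatches = 1)
  expect_equal(nrow(m[m$position == 301, ]), 0L)
  m <- match_spacers(c(c1 = contig), c(s2 = two_mm), max_mismatches = 2)
  expect_true(any(m$position == 301 & m$mismatches == 2))
})

test_that("spacers outside 25-65 bp are skipped and N always mismatches", {
  set.seed(22)
  contig <- random_dna(1000)
  short <- substr(contig, 1, 20)
  expect_warning(m <- match_spacers(c(c1 = contig), c(tiny = short)), "skipped")
  expect_equal(nrow(m), 0L)

  sp <- substr(contig, 101, 130)
  contig_n <- contig
  substr(contig_n, 110, 110) <- "N"
  m <- match_spacers(c(c1 = contig_n), c(s = sp), max_mismatches = 0)
  expect_false(any(m$position == 101))
  m <- match_spacers(c(c1 = contig_n), c(s = sp), max_mismatches = 1)
  expect_true(any(m$position == 101 & m$mismatches == 1))
})

test_that("host phylum summary counts distinct contigs in decreasing order", {
  lab <- labels_df(c("a", "b", "c", "d", "a"),
                   c("Bacteria;Firmicutes", "Bacteria;Firmicutes",
                     "Bacteria;Firmicutes", "Archaea;Euryarchaeota",
                     "Bacteria;Firmicutes"))
  s <- summarize_host_phyla(lab)
  expect_equal(s$phylum, c("Firmicutes", "Euryarchaeota"))
  expect_equal(s$n_contigs, c(3L, 1L))
  expect_equal(nrow(summarize_host_phyla(lab[0, ])), 0L)
  # a domain-only lineage has no phylum to count
  s <- summarize_host_phyla(labels_df("x", "Bacteria"))
  expect_equal(nrow(s), 0L)
})
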