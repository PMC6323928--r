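# uvigcurate

Curation toolkit for **uncultivated viral genomes (UViGs)** assembled from
shotgun metagenomes. Metagenome assembly yields a heterogeneous mix of
viral contigs, from short fragments to complete genomes, with no intrinsic
indication of which is which. `uvigcurate` implements the standard
curation chain that turns raw viral contigs into quality-annotated,
species-clustered, host-annotated genome records:

1. **Circularity detection** — a contig assembled from a circular genome
   carries a direct terminal repeat (DTR): an identical sequence at its
   5' and 3' ends. Contigs are called circular given a DTR of ≥ 10 bp, or
   a direct or inverted repeat of ≥ 20 bp whose copies lie within 50 bp of
   the contig ends.
2. **vOTU clustering** — viral operational taxonomic units are built by
   single-linkage clustering of sequences with ANI ≥ 95% over ≥ 85% of the
   length of the shorter sequence (AF). ANI = identical aligned columns /
   aligned columns over non-overlapping local alignment blocks (both
   strands considered); AF = covered fraction of the shorter sequence.
   Clusters with ≥ 2 members are named `vc_k`, singletons `sg_k`.
3. **Completeness and quality tiers** — contigs are affiliated to taxa
   from marker-gene (VOG) hits (≥ 2 consistent markers; ≥ 5 for NCLDV; 1
   for ssDNA/RNA viruses). Circular contigs that are suspiciously short
   relative to their genus-level group (< 80% of the minimum isolate
   length, or of the longest linear member in isolate-free groups), or
   < 10 kb without an ssDNA/RNA marker, are flagged as false positives and
   treated as linear. Each genus-level group predicts a genome size as the
   mean length of its isolates and complete circles, accepted when the SD
   is ≤ 15% of the mean. Completeness = 100 × length / predicted size,
   capped at 99% for linear contigs exceeding the prediction. Tiers:
   `finished` (isolates), `complete_circular`, `high_quality_draft`
   (linear, ≥ 90% complete), `genome_fragment`.
4. **Host-domain scoring** — each viral protein family (VPF) is scored for
   host-domain uniformity: `score = uniform_hits / total_hits`, multiplied
   by `total_hits / average_hits` when the model has fewer hits than the
   database average (6.8). Families scoring exactly 1.0 are domain
   signatures; a strict majority of signature hits classifies a contig as
   a prokaryotic or eukaryotic virus.
5. **Host assignment** — host labels of isolate genomes and curated
   prophages propagate to unlabelled members of the same vOTU (conflicts
   collapse to the lowest-common-ancestor lineage), and CRISPR spacers
   (25–65 bp) matched at ≤ 1 substitution over their full length link
   contigs to the spacers' microbial hosts.

Deterministic synthetic-data generators (`make_circular_genome`,
`mutate_to_identity`, `make_vpf_hit_table`, `make_spacer_set`) emulate all
input types so every stage is testable without external databases.

## Worked example

```r
library(uvigcurate)

contig <- make_circular_genome(seed = 7, length = 12000, repeat_len = 14,
                               mode = "direct_terminal", id = "uvig_1")
detect_circularity(contig)
#> <circularity_call> circular: DTR, 14 bp repeat (5' copy at 0, 3' copy at 11986; 0-based)

grp  <- genus_group("g1", isolate_lengths = c(41000, 39500, 40200))
size <- predicted_genome_size(grp)
as.numeric(size)                              # 40233.33 bp (SD 613 bp <= 15%)
estimate_completeness(33000, as.numeric(size))
#> 82.02154
assign_quality_tier(viral_contig("lin", "ACGT"), completeness_pct = 82.0)
#> "genome_fragment"

vpf_uniformity_score(c(prokaryotic = 7))      # 1.0  (signature VPF)
vpf_uniformity_score(c(prokaryotic = 6))      # 0.8824 = (6/6) * (6/6.8)

base <- make_circular_genome(8, 3000, 0)$sequence
seqs <- c(A = base,
          B = mutate_to_identity(base, 97, 1),   # above the 95% threshold
          C = mutate_to_identity(base, 90, 2))   # below it
as.data.frame(build_votus(seqs))
#>   seq_id votu_name n_members
#> 1      A      vc_1         2
#> 2      B      vc_1         2
#> 3      C      sg_1         1
```

The 14 bp terminal repeat marks `uvig_1` as a putative complete circular
genome; the genus group's member lengths are consistent enough (SD 613 bp)
to predict a 40.2 kb genome size, making a 33 kb linear member an 82%
`genome_fragment`; a VPF with seven single-domain hits is a maximal-score
domain signature; and the 97%-identical sequence joins the base sequence
in cluster `vc_1` while the 90% one stays a singleton.

`run_pipeline()` chains all stages over FASTA/TSV inputs and writes a
13-column report; `inst/cli/uvigcurate.R` exposes each stage (and
`run-all`) as shell subcommands.

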