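---
title: "Methods: curating uncultivated viral genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curating uncultivated viral genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvigcurate)
```

This vignette documents the models, rules and numerical choices behind
`uvigcurate`, in the order the pipeline applies them. It is the package's
reference for *why* each operation behaves as it does; function manuals
describe *what* each does.

## The curation problem

Viral contigs assembled from metagenomes arrive without the annotations
that make genome collections usable: whether a contig is a complete
genome, which contigs are the same virus species, how complete a fragment
is, and what the virus infects. None of these can be read directly off
the sequence; each is inferred from sequence signatures (terminal
repeats, identity to other sequences, marker-gene content, spacer
matches) plus reference information (genus-level groups, isolate genome
lengths, labelled hosts). The package implements those inferences as
small, composable operations with a thin pipeline on top.

## Circularity from terminal repeats

An assembler walking around a circular genome emits a linear contig whose
two ends overlap: a direct terminal repeat (DTR). Some linear viral
genomes instead carry long terminal repeats (direct) or inverted terminal
repeats near their ends. Three rules are applied in order, the first
match deciding the mechanism:

1. **DTR**: longest exact match between a prefix and a suffix, called at
   ≥ `min_dtr_len` = 10 bp. Rule 1 requires the repeat to be strictly
   terminal (starting at the first base, ending at the last); repeats
   that are merely *near* the ends are the province of rules 2–3.
2. **Windowed direct repeat** at ≥ `min_terminal_repeat_len` = 20 bp: the
   5' copy starts within `terminal_window` = 50 bp of the 5' end and the
   3' copy ends within 50 bp of the 3' end. "Within 50 bp of the ends"
   needs an anchor; we anchor the 5' copy by its start and the 3' copy by
   its end, the reading under which each copy hugs its respective
   terminus.
3. **Windowed inverted repeat**: rule 2 with the 3' copy
   reverse-complemented.

Numerical and policy choices:

* **Exact matching.** Repeat copies must match exactly. No mismatch
  allowance is defined for terminal repeats, and exactness is what makes
  the brute-force oracle used in the tests unambiguous.
* **`N` never matches**, not even another `N`. An `N` is absence of
  evidence; letting it match would manufacture repeats from missing data.
* **Tie between mechanisms**: a sequence may satisfy several rules; DTR
  wins, as the rule order implies and as the conventional signal of a
  complete genome.
* **Search cap.** The windowed scanner searches the two terminal regions
  of `terminal_window + max_repeat_len` bp (default 50 + 1000). Repeats
  longer than 1 kb per copy would be truncated to 1 kb; terminal repeats
  of real viral genomes are far below this, and the cap keeps the scan
  linear in practice. `max_repeat_len` is a parameter for the rare user
  who needs more.
* **DTR via border decomposition.** Rule 1 is the classic
  "longest border" problem (longest proper prefix that is also a
  suffix), solved with the Knuth–Morris–Pratt failure function; the
  border chain is walked until an `N`-free border is found, since a
  border containing `N` would rely on `N`–`N` matches.
* Sequences not longer than `2 * terminal_window` are refused (with a
  warning, returning a non-circular call): both windows would overlap and
  "terminal" loses meaning.

Positions are 0-based half-open internally; tabular outputs report
1-based inclusive starts, the common genomics reporting convention.

## vOTU clustering at 95% ANI / 85% AF

Two sequences belong to the same viral species-rank unit (vOTU) when
their average nucleotide identity is at least 95% over at least 85% of
the shorter sequence, and clusters are connected components of the
resulting graph (single linkage). The package computes:

* **Blocks**: greedy non-overlapping local alignments of the shorter
  sequence (query) against the longer, on both strands of the latter,
  keeping the better orientation. The best local alignment is taken
  (Smith–Waterman via `Biostrings::pairwiseAlignment`), its query range
  masked, and the alignment repeated — up to 5 blocks or until the query
  is covered, discarding blocks scoring below 50. Scoring is
  blastn-like: match +2, mismatch −3, gap open 5, gap extend 2, with `N`
  scored as a mismatch against everything including itself.
* **ANI** = 100 × identical columns / aligned columns (gap columns
  included), length-weighted across blocks.
* **AF** = 100 × query bases covered by any block / query length. AF
  uses the union of covered bases, not the single best block: a genome
  fragmented into several alignment blocks against a rearranged relative
  is still the same species, and the union is what the community's vOTU
  scripts measure.

Symmetry is by construction: the shorter sequence is always the query,
with ties on length broken by sequence content, so `pairwise_ani(a, b)`
and `pairwise_ani(b, a)` run the identical computation. The minimum
block score of 50 (≥ 25 identical bases) suppresses the chance ~12 bp
local matches that any two random sequences share; unrelated pairs thus
report no alignment (`NA` ANI, AF 0) rather than a misleading
100%-identity speck.

Cluster naming (`vc_`/`sg_` by decreasing size, then smallest member id)
is fixed purely for determinism; only the prefixes carry meaning.

## Completeness and quality tiers

**Marker affiliation.** Markers are "consistent" when they agree on a
taxon label; the label with the most markers wins if it meets the
class minimum (dsDNA 2, NCLDV 5, ssDNA/RNA 1), and a tie for the top
count blocks affiliation rather than guessing. A label carrying two
different taxon classes in one contig's hits is a data error and raises
one.

**False-positive circles.** A circular call on a contig much shorter
than its relatives is more plausibly an artefact (e.g. a tandem-repeat
collapse) than a miniature genome. The three filters (< 80% of the
group's minimum isolate length; < 80% of the longest linear member in
isolate-free groups; < 10 kb without an ssDNA/RNA marker, since the
detection pipeline targets mostly dsDNA viruses whose genomes are
larger) are checked in that order and the first hit names the reason.
Flagged contigs re-enter the pool as linear.

**Predicted genome size.** Mean length of a group's isolates and
surviving circles, accepted when the *population* standard deviation
(divide by *n*) is ≤ 15% of the mean. Population SD is used because the
group's complete members are the entire population under consideration,
not a sample from a larger one; a single member therefore has SD 0 and
still defines a size.

**Completeness** = 100 × length / reference size, where the reference is
the taxon's mean isolate genome length for marker-affiliated contigs and
the group prediction otherwise. Linear contigs longer than the reference
are set to 99%: likely near-complete, but linearity forbids claiming
completeness. The 99% cap is applied uniformly to both reference
sources — nothing distinguishes "longer than the taxon mean" from
"longer than the group mean" in reliability terms. Values are kept
unrounded internally; the report rounds to one decimal, and the ≥ 90%
tier comparison uses the unrounded value so that 89.96% does not slip
into the draft tier via rounding.

**Tiers.** `finished` (isolate references), `complete_circular`
(non-flagged circles — kept distinct from `finished` because isolate
genomes and predicted-complete contigs are different kinds of evidence),
`high_quality_draft` (linear, ≥ 90%), `genome_fragment` (everything
else, including contigs with no predicted size).

## Host-domain scoring of VPFs

For a viral protein family with hit counts per host domain
(prokaryotic/eukaryotic viruses) in a reference virus set:

```
base  = uniform_hits / total_hits
score = base * min(1, total_hits / average_hits),  clamped to [0, 1]
```

with `average_hits` = 6.8, the reference database's average hits per
model — a property of the database the scores were calibrated on, hence
a supplied parameter rather than something recomputed from whatever
table the user passes (`average_hits_from_profiles()` exists for users
who do want to recompute it). With that average, any single-domain model
with ≥ 7 hits scores exactly 1.0, and those 1.0-score models are the
domain signatures.

"Uniform hits" admits two readings, and the package implements both:
the default (`mode = "majority"`) counts the dominant domain's hits, so
a 5/5 split scores 0.5; `mode = "strict"` counts the total only when a
single domain holds every hit and zero otherwise. The majority reading
is the default because it degrades gracefully — a 9/1 model is nearly
uniform and scores 0.9 rather than 0 — while both agree on every
single-domain profile, including all signatures. Signature selection
tests `score >= 1 - 1e-9` rather than exact equality, as the corrected
score may arrive via floating-point division.

Contigs are classified by a strict majority of signature hits per
domain; ties and zero hits leave `unclassified`. Majority voting is the
package's choice (presence of signatures alone does not resolve contigs
hitting both domains); it is order-invariant and errs toward
`unclassified`.

## Host assignment

**Cluster propagation.** A vOTU containing a host-labelled member
(isolate or curated prophage — treated identically, since both are
direct observations of a virus–host pair) lends its host to unlabelled
members. Multiple labels collapse to the lowest common ancestor of the
lineages; if they disagree at the domain rank no label is propagated.
Existing labels are never overwritten. Propagated labels carry the
method tag `cluster`.

**CRISPR spacers.** Spacers (25–65 bp; anything outside is skipped with
a warning) are matched over their full length on both strands with at
most one substitution and no indels — the common practice for
spacer-based host prediction, configurable via `max_mismatches`. `N`
counts as a mismatch on either side. When cluster propagation and
spacer evidence disagree for a contig, the pipeline reports both
lineages with both method tags rather than ranking one above the other.

## Synthetic data: what it emulates and what it does not

The generators produce uniform-composition random backbones with exactly
planted features: terminal repeats of known length, kind and position
(`make_circular_genome`, with a rejection loop that regenerates any
backbone carrying an incidental repeat at or above the detection floors,
so the planted repeat is provably the only signal); sequence pairs at an
exact identity (`mutate_to_identity` substitutes a forced count of
positions); VPF hit tables with requested per-domain counts; and spacers
cut from contigs with a forced number of substitutions. Each generator
is seeded and returns byte-identical output for identical arguments,
without disturbing the caller's RNG stream.

These fixtures validate the *rules*: thresholds, boundary placement,
oracle equivalence of the optimised scanners, and recovery of planted
signals. They do not emulate real viral genomes — no gene content, codon
bias, repeat families, assembly chimerism or uneven coverage — so
passing tests demonstrate correctness of the implemented criteria, not
field performance of the criteria themselves on environmental data.

## Problem sizes and numerical conventions in the test suite

The oracle-equivalence suites run the circularity detector against a
full-shift quadratic scanner on 200 sequences of 0.5–2 kb (110 plain
random, 90 with planted repeats straddling the floors), the spacer
matcher against a sliding-window comparer on 100 spacers over three
contigs, and the clusterer against union-find over brute-force edges on
a 20-sequence set; identity-ladder recovery covers 80–100% in 1% steps
at 1 kb for three seeds. Boundary scans use 5 kb backbones for the DTR
floor and 8–12 kb circles for the false-positive threshold. These sizes
exercise every code path while keeping the default suite to a few
minutes on one CPU.

Degenerate inputs are handled explicitly: empty sequences error; contigs
shorter than twice the terminal window warn and return a non-circular
call; an empty group yields an undefined genome size; a zero-hit VPF
profile errors; labels for unknown sequence ids warn and are skipped.

## Known limitations

* ANI from greedy masked re-alignment can differ from blast-style HSP
  sets on genomes with large duplications (a duplicated query region is
  only counted once); for the contiguous-homology cases vOTU thresholds
  target, the two agree.
* The windowed repeat scanner's `max_repeat_len` cap (1 kb) truncates
  pathologically long terminal repeats.
* Marker affiliation trusts the hit table; it does not re-score or
  re-filter HMM hits, and profile searches themselves are out of scope.
* Genus-level grouping is consumed as input; the package neither builds
  nor audits the groups.
* All-vs-all clustering is quadratic in the number of contigs and meant
  for curation-scale sets, not database-scale sweeps.
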