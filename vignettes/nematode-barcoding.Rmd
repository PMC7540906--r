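---
title: "Specimen-level nematode barcoding from multi-region 18S amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specimen-level nematode barcoding from multi-region 18S amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Soil nematodes are abundant, trophically diverse, and hard to identify
morphologically. A practical alternative is specimen-level DNA barcoding:
isolate individual nematodes, amplify several sub-regions of the 18S
small-subunit (SSU) rRNA gene from each specimen with region-specific
primer pairs, sequence the amplicons deeply, and work with exact denoised
sequence variants (SVs) rather than clustered OTUs. `nematax` implements
the downstream analysis of such a survey:

1. **In-silico PCR** — locating IUPAC-degenerate primer pairs on
   full-length reference sequences and excising the primer-trimmed
   regional inserts, plus building artificially concatenated long
   sequences (e.g. `R2_3_4` = regions 2, 3, 4 pasted in order).
2. **Per-sample QC** — keeping samples with more than 1,000
   nematode-derived reads *and* a nematode relative abundance above 65%,
   and summarising phylum-level composition (phylum fractions below 1%
   dropped after summation).
3. **Minor-SV resolution** — deciding, for each sample and region,
   whether the second-most-abundant nematode SV is a polymorphic rDNA
   allele of the dominant SV (few edits, same order, often recurring in
   the same major/minor pairing across samples), a second nematode
   (different order; predation or carcass contamination), or unresolvable.
4. **rOTU clustering** — grouping isolates that share identical major SVs
   in every region where both have data into SSU-derived OTUs (rOTUs),
   with the `Z01rOTU01`-style naming, polymorphic regional rOTUs
   (`_R1a`), and order/feeding-type composition summaries.
5. **Phylogenetics** — Jukes–Cantor (or p-) distances with pairwise
   deletion, neighbor-joining trees, column-resampling bootstrap,
   outgroup rooting on a tardigrade-like leaf, and the tree-evaluation
   metric: the number of maximal single-order clades per tree, compared
   across regional and concatenated sequence sets.
6. **Synthetic communities** — a seeded generator producing reference
   sets and SV tables with full ground truth, so every stage above is
   testable without any sequence download.

## The clustering rule and why conflicts must block merging

Two isolates co-cluster iff their major SVs agree in *every* region where
both have data, and they share at least one region. Agreement in one
region is not enough: in the bundled worked example, one region-3 SV is
shared by three different rOTUs that differ in the other regions, so a
single-region match must never merge clusters, even transitively through
an isolate with partial region coverage. `cluster_isolates()` therefore
builds match edges (all shared regions equal) and takes connected
components, but refuses any union that would bring a conflicting pair
(equal somewhere, different elsewhere) into one cluster. Isolates flagged
unresolvable by `flag_ambiguous_isolates()` are excluded *before*
clustering.

Ranking is by descending member count, ties by the smallest member sample
number, ids zero-padded to width 2 behind a configurable experiment code.

## Thresholds, with units and defaults

| parameter | default | meaning |
|---|---|---|
| `min_reads` | 1000 | nematode-derived reads a sample must exceed (strict `>`) |
| `min_nem_frac` | 0.65 | nematode share of total reads a sample must exceed (strict `>`) |
| `minor_floor` | 0.07 | share of the sample's *nematode* reads a minor SV must exceed to be considered (and to count toward the 65%) |
| `phylum_min_frac` | 0.01 | phylum fractions strictly below this are dropped, after summation; exactly 1% is kept |
| `max_allele_edits` | 5 | Levenshtein ceiling for a same-order minor to be called an allele; covers the observed worst case (four T/C sites; substitution + 2-nt insertion) |
| `bootstrap` | 1000 | column-resampling replicates per tree |
| distance model | JC | Jukes–Cantor with pairwise deletion; `"p"` exposed as alternative |

Two readings of the survey rules were genuinely open and are fixed here
explicitly. First, the allowance for "polymorphic SVs" in the 65% rule is
implemented as: a minor nematode SV counts toward the nematode fraction
only when its own share of the sample's nematode reads exceeds
`minor_floor`. Second, allele status does **not** require recurrence
across two or more samples — recurrence is recorded as supporting
evidence (`n_cooccurring_samples`) because single-isolate allele pairs do
occur legitimately; requiring recurrence would misclassify them.

Percentages are rounded half away from zero to one decimal
(`round_half_up()`), a fixed convention chosen over base R's half-to-even
so printed summaries are platform-stable.

## Numerical and algorithmic choices

* **Distances.** p-distance with pairwise deletion of columns containing
  gaps/`N` in either sequence; Jukes–Cantor correction
  $d = -\tfrac{3}{4}\ln(1-\tfrac{4}{3}p)$. Saturated pairs
  ($p \ge 3/4$) are set to a configurable cap (default 5 substitutions
  per site) instead of propagating `NaN`. A pair with zero comparable
  columns is an error naming the pair.
* **Neighbor joining** delegates to `ape::nj` (the classic Q-criterion
  algorithm); inputs are put in canonical label order first so that ties
  resolve identically regardless of input order, and negative branch
  lengths are clamped to zero with the deficit moved to the adjacent
  edge, preserving path lengths.
* **Bootstrap.** Column resampling is implemented as a weight vector over
  alignment columns; replicate distances are a single matrix product of
  precomputed per-pair mismatch/comparability indicators with the
  weights, so 1,000 replicates on ~60 sequences stay cheap. Supports are
  bipartition counts (`ape::prop.clades`, unrooted) on the base tree.
  The resampling depends only on the seed and the column count, which
  makes supports invariant to leaf input order.
* **Rooting** places the root at the midpoint of the outgroup's pendant
  edge; ingroup patristic distances are untouched.
* **Cluster counting** marks every node pure/impure for each order
  bottom-up and counts pure nodes whose parent is impure. rOTU and
  outgroup leaves break purity deliberately: the metric measures how the
  references organise *in the presence of* the query sequences. A pure
  clade containing the root counts as one cluster. Tests verify equality
  with an independent brute-force oracle (MRCA purity for every leaf
  pair, components via igraph) on a thousand random labeled trees.
* **Order assignment** walks from an rOTU leaf to progressively larger
  ancestral clades and takes the first unanimous (else majority;
  ties defer upward) reference order. Feeding types transfer from the
  reference leaf at minimal patristic distance, ties to the smaller
  label; an rOTU absent from the full concatenation tree (missing a
  region) falls back to the longest tree that contains it.

## What the synthetic generator emulates — and what it does not

Each reference sequence is a fixed scaffold of the eight primer sites
(one concrete base drawn per degenerate position) separated by variable
blocks. Regions 3 and 4 share a 63-nt core block (and region 3's insert
contains the region-4 forward site), reproducing the designed overlap of
those two amplicons. Variable blocks evolve by substitution only — orders
from a common root at `div_between = 0.12` substitutions/site, species
within an order at `div_within = 0.015`, the outgroup at 0.30 — so
within-order divergence stays below between-order divergence and all
inserts of a region are equal-length and gap-free, i.e. trivially
aligned. That is a deliberate simplification: real SSU regions need
multiple alignment, which is out of scope here (inputs to the phylogeny
stage are gap-free or externally aligned).

Samples draw a source species uniformly; read counts are multinomial
over the sample's composition at a log-normal depth around `depth_mean`
(failed samples draw 80–900 reads, below the 1,000-read rule). Allele
pairs are defined once per species — so the same major/minor pairing
recurs across samples of that species, as observed in real data — and
differ by exactly `allele_edit_count` Levenshtein edits placed at
well-separated positions (mostly substitutions, occasionally a
single-base insertion). The allelic minor draws 10–45% of the nematode
reads (capped at 30% when a second nematode is present so the dominant
SV always exceeds half the reads); contaminated samples put 40–60% of
reads into fungal/chordate SVs, guaranteeing they fail the 65% rule;
clean samples occasionally carry a 0.4% fungal background that the 1%
phylum floor removes.

The generator does **not** model read-level error, chimeras, PCR bias,
copy-number variation of the rDNA array, or taxonomy misannotation.
Passing tests on synthetic data therefore demonstrate the correctness of
the *logic* (thresholds, classification, clustering, tree metrics), not
robustness to denoising artefacts — the upstream denoisers own that
problem.

## Problem sizes used by the test-suite

The bundled worked example (68 isolates, 18 rOTUs) runs in well under a
second. Property suites use: exhaustive NJ topology checks up to 6 taxa
(105 topologies); 1,000 random labeled trees of up to 30 leaves for the
cluster-count oracle; a 96-sample simulated plate for allele-call
sensitivity/specificity; and a full pipeline run with 100 bootstrap
replicates over ~60 reference sequences of 1,200 nt across all eight
region sets, which completes in roughly a minute on one core. The same
machinery scales to 1,000 replicates linearly.

## Known limitations

* No multiple alignment: real reference sets must be aligned externally
  before `pairwise_distance()`; the simulator sidesteps this by
  construction.
* The cluster-count metric depends on the rooting; the package counts on
  the outgroup-rooted tree and treats a root-containing pure clade as
  one cluster.
* Order assignment assumes the reference set brackets the queries; an
  rOTU from an unrepresented order will be forced into the nearest
  represented one.
* `edit_summary()` reports one optimal alignment's edit script; when
  several optimal scripts exist the reported positions (not the
  distance) may differ from another tool's description.
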