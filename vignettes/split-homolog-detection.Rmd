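---
title: "Detecting full-length and split homologs of human proteins in gut microbial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting full-length and split homologs of human proteins in gut microbial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsplit)
```

## The problem

Many human proteins — in particular broad-specificity xenobiotic and
drug-metabolizing enzymes, and central metabolic enzymes targeted by
substrate-analog drugs — have recognizable homologs in gut bacteria.
A one-to-one homology search misses an important class of these:
because gene fusion and fission reshuffle domains between lineages, a
single human protein may correspond to *several adjacent bacterial
genes* in one operon-like neighborhood. `gutsplit` detects both kinds
of homolog from a protein-vs-proteome local-alignment table (BLAST
tabular, 12 standard columns plus query and subject length) and a
gene-order table for the microbial genomes:

* a **full-length homolog** is a single microbial protein whose
  alignment covers most of the human protein;
* a **split homolog** is a set of two or more neighboring, same-strand
  genes on one contig whose alignments to the human protein *jointly,
  but not individually*, reach the same coverage.

Downstream, the package provides the statistics used to characterize
such homolog sets: Gene Ontology over-representation with
Benjamini–Hochberg correction, mitochondrial-localization odds ratios,
regex classification of xenobiotic enzyme families, Faith's
phylogenetic diversity of the species carrying each family, and
filtering of pharmacogenomic chemical/reaction tables down to
drug-relevant enzymes.

## The detection model

All coordinates are 1-based inclusive amino-acid positions, as in
BLAST tabular output. Coverage of a sequence of length $L$ by an
alignment spanning $[a, b]$ is $(b - a + 1)/L$; joint coverage of a set
of alignments is the size of the *union* of their subject intervals
divided by $L$, so overlaps are never double-counted.

Both branches share two initial steps:

1. **Best human hit** — for each microbial query, keep only the human
   protein with the highest bitscore. Ties break deterministically by
   lower e-value, then lexicographically smaller accession (the input
   order never matters).
2. **Microbe coverage** — keep alignments covering at least 2/3 of the
   microbial query, and queries of at least 80 aa. The threshold is
   the exact rational `2/3`, so a 60/90 alignment passes as a true
   boundary equality rather than by rounding. All comparisons here and
   below are inclusive (“at least”).

The **full-length branch** then applies:

3. **Human coverage** — the single alignment must cover at least 70%
   of the human protein.
4. **Contamination** — human-sequence contamination in microbial
   assemblies produces near-identical alignments that are not ancient
   homology. The percent-identity cutoff is estimated as
   $\bar{x} + k\,s$ (sample SD, $k = 3$) on the survivors of step 3,
   and alignments above it are removed. At the package's design point
   (identity mean 30%, SD 7.27%) the cutoff is 51.8% identity.

The cutoff is estimated once, on the full-length candidates, and the
frozen value is reused by the split branch; it is never re-estimated
on split candidates, whose identity distribution is not the reference
distribution. Whether the estimation set should be taken before or
after the human-coverage filter is genuinely open; we default to
after (the estimate then describes accepted full-length homologs,
which is what the cutoff is defined against) and
`call_full_length(cutoff = ...)` lets you freeze any alternative.

The **split branch** applies, to the survivors of steps 1–2:

* **Same genome** — alignments are expanded to every genome encoding
  the cluster; genomes encoding fewer than two distinct clusters for a
  human protein are dropped.
* **Joint human coverage** — the union of the genome's alignments to
  the human protein must cover at least 70% of it.
* **Feature distance** — members must lie on the same contig and
  strand, within 3 gene-order ranks of one another. Distance is
  measured in feature ranks, not base pairs, because gene density
  varies and the biological question is adjacency in the gene order.
  Pairs within the gap limit are chained transitively into connected
  components; since connectivity on integer ranks depends only on
  consecutive gaps, sorting by rank and cutting where the gap exceeds
  the limit is exactly the connected-component partition. The
  joint-coverage check is re-run per component, because a component
  need not inherit the whole genome's coverage.
* **Contamination** — members above the frozen cutoff are removed;
  components are then re-formed from the survivors (removal can
  disconnect a chain) and joint coverage is re-checked once more.
* **Jointly but not individually** — a component in which any single
  member reaches the 70% threshold on its own is not a split call.
  The comparison is strict (`<`), so boundary cases route to the
  full-length branch; this also guarantees that no split-call member
  is simultaneously a full-length call for the same protein.

A cluster occurring at two loci in one genome can seed two distinct
neighborhoods; calls are per-locus. Split homologs spanning contig
boundaries are out of scope by construction (assembly breaks are
indistinguishable from genuine separation).

## Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `microbe_cov` | 2/3 | fraction | minimum query coverage (step 2) |
| `human_cov` | 0.70 | fraction | minimum (joint) subject coverage |
| `min_microbe_len` | 80 | aa | minimum query length |
| `max_feature_gap` | 3 | gene ranks | maximum member distance |
| `contamination_sd` | 3.0 | SDs | identity cutoff multiplier |

`pipeline_thresholds()` bundles these; every output TSV records them
in a `#`-prefixed provenance header along with the package version.

## Downstream statistics

**Enrichment.** Annotations are first propagated up the ontology
(true-path rule). Term over-representation uses a one-sided Fisher
exact test per term with BH adjustment across terms — one-sided
because only over-representation is of interest for term enrichment.
The 2×2 localization test is two-sided, standard for a contingency
comparison. The headline odds ratio is the conditional-MLE estimate
of `fisher.test()` with its exact CI; the sample odds ratio $ad/bc$
is reported alongside, with a Haldane–Anscombe 0.5 correction (and a
flag) when a cell is zero. An `elim`-style variant
(`algorithm = "elim"`) decorrelates the DAG by removing the proteins
of significant specific terms from their ancestors before testing
them; the default is the plain (“classic”) test, whose p-values are
exactly hypergeometric and therefore oracle-checkable. Mitochondrial
localization is flagged by matching cellular-component term names
against `[Mm]itochondr`.

**Phylogenetic diversity.** Faith's PD of a species set is the total
branch length of the minimal subtree spanning those tips. We use the
root-inclusive convention (the subtree always connects to the root,
matching `picante::pd(include.root = TRUE)`); a single tip then
contributes its full root path. The convention is a choice, not a
theorem, so `include_root = FALSE` is available; rankings of nested
species sets rarely change between the two. Trees are midpoint-rooted
before PD, which preserves total branch length and all pairwise tip
distances. Enzyme families are assigned by the first matching regular
expression over UniProt-style family description strings, in the
declared rule order; the eleven default rules (SDR, aldo-keto
reductases, UDP-glycosyltransferases, GSTs, arylamine
N-acetyltransferases, GDXG lipases, cytochrome P450s, type-B
carboxylesterases, flavin monooxygenases, quinone oxidoreductases,
aldehyde dehydrogenases) do not overlap in practice.

**Counting units.** “How many split homologs does protein X have” has
no single natural unit: distinct clusters, distinct genomes, and
distinct neighborhoods all measure something real. The default is
distinct clusters on both branches (symmetric, and robust to genome
redundancy); the unit is a configuration knob and is stamped into the
output provenance. Category assignment is strict: *split-majority*
means strictly more split than full-length homologs, so ties are
full-majority. Exclusion in ontology-class queries
(`go_class_members()`) is gene-level: one annotation anywhere in an
excluded subtree removes the protein entirely.

## The synthetic benchmark

`generate_synthetic()` produces an alignment table, a feature table,
annotation fixtures, a species tree, and a ground-truth ledger. Its
defaults are the package's study conditions: 200 genomes, 300 human
proteins (350–1200 aa), a full-length plant in 30% and a split plant
in 20% of (protein, genome) cells, fragments of 2–3 genes with
inter-member gaps of 1–3 ranks, and genuine identities from a Normal
truncated to [10, 50]% with mean 30% and SD 7.27% — the distribution
whose mean + 3 SD reproduces the 51.8% contamination cutoff. The
parent SD is inflated so the *truncated* moments equal the nominal
ones, keeping the parameters interpretable; truncation bounds are
recorded in the bundle manifest. Contaminants draw identities from
[90, 100]%. Decoys are planted as labeled, mutually exclusive classes
— wrong strand, wrong contig, gap of 4, joint coverage ~55%, one
member individually covering ≥70%, and contaminant — so that each
filter's necessity is individually testable; rates are expected
instances per human protein, which keeps the contaminant fraction of
the identity distribution realistically small. Each plant uses its
own protein cluster and full/split plants for one cell are kept on
different contigs, so planted signals never interact; bitscores are a
simple increasing function of alignment length × identity.

What the generator does **not** emulate: real sequences or BLAST
score statistics, clusters shared across genomes, multiple HSPs per
query-subject pair, overlapping decoy classes, contig-spanning
splits, and taxonomic structure in which species carry which
proteins. Perfect precision/recall on this benchmark therefore
demonstrates that the filter logic implements its specification — not
that real-data error modes (chimeric assemblies, fragmented gene
calls, paralog confusion) are handled; on real data the contamination
cutoff and the coverage thresholds are the operative defenses, and
their values are the ones to re-examine first.

A fixed master seed makes the bundle byte-identical across runs; each
output table derives its own RNG stream from the master seed, so
adding a table does not perturb existing ones.

## Numerical choices and degenerate inputs

* Boundary comparisons are inclusive everywhere; `microbe_cov` is the
  exact rational 2/3.
* The best-hit tie-break (bitscore, then e-value, then accession) is a
  deterministic stand-in — any fixed rule works, but it must be fixed.
* Cutoff estimation needs at least two identities (sample SD);
  with fewer full-length candidates the pipeline returns calls without
  a contamination filter and records the absence in the sidecar.
* Multiple HSPs per (query, subject) pair are *not* merged in the
  full-length branch — each alignment stands alone, matching the
  per-alignment coverage definition. Interval-union merging is exactly
  what the split branch's joint coverage provides.
* Empty inputs flow through every stage as empty, typed tables.

## Testing strategy and problem sizes

Every nontrivial primitive is checked against an independent oracle:
interval-union coverage against a position bitmask (10⁴ random
instances), neighborhood components against brute-force transitive
closure (10³ instances of ≤12 features), Fisher p-values against
direct hypergeometric summation (exhaustive over all tables of total
≤20 and 40, plus 2,000 random tables up to total 200), and Faith's PD
against `picante` (100 random trees of ≤64 tips). End-to-end recovery
and decoy rejection run at the full study conditions (200 × 300);
unit tests use 20 × 30 bundles. These sizes make the oracle
comparisons dense while keeping the default test run fast.

## Limitations

* Feature order must be supplied (TSV, GFF3 CDS rank, or gene-id
  suffix); the package does not call genes.
* The enrichment defaults do not reproduce any particular topGO
  configuration; `elim` here is a variant in the same spirit, not a
  reimplementation.
* Species assignment of clusters is an explicit input mapping;
  no taxonomy is inferred.
* The pharmacogenomic layer consumes curated tables; it does not
  fetch or parse any live database.
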