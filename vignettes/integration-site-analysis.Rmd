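---
title: "Mapping and quantifying retroviral integration sites: methods and design"
author: "ltrsites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping and quantifying retroviral integration sites: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrsites)
```

## The problem

When a retrovirus such as HIV-1 infects a cell, reverse transcription
produces a double-stranded DNA copy of the viral genome that can become a
*provirus*: a permanent insertion into host chromosomal DNA. The provirus
is flanked by two identical long terminal repeats (LTRs) whose outermost
dinucleotides — 5' TG ... CA 3' — are the signature of insertion by the
viral integrase, which also duplicates a few bases of the host target site
(a target-site duplication, TSD) on either side of the insertion.
Junctions can instead arise by homologous recombination or end joining, in
which case the LTR terminus is typically eroded and no TSD is formed.

`ltrsites` implements the computational side of an integration-site survey
in a host genome sampled from many cells at once (for example a pool of
larval-stage parasites exposed to pseudotyped virions). Two independent
evidence streams are analysed:

1. **LTR-anchored amplicon sequencing** (a modified TraDIS / splinkerette
   protocol): genomic DNA is fragmented, splinkerette adapters are
   ligated, and nested PCR with LTR-specific primers enriches fragments
   that start inside an LTR and run into flanking host sequence. Paired
   ~100-bp reads over 200–400-bp fragments locate individual junctions.
2. **Whole-genome shotgun sequencing (WGS)**: unenriched paired reads at
   high fold coverage, in which integration evidence appears as chimeric
   (virus–host) reads or as read pairs split between the two references.
   Because WGS is unbiased, it supports an absolute estimate of the
   integration burden per nucleus.

Because the original sequencing data is not packaged here, a first-class
synthetic-data module generates host genomes, planted proviruses, and
both kinds of read set with ground truth, so every stage of the pipeline
is verifiable end to end at desk scale.

## The anchored-library caller

### Read preparation

Read pairs are merged into a single fragment-length read when the mates
overlap by at least 10 bp (`merge_pairs()`); disagreeing overlap columns
take the higher-quality base, with ties going to read 1. Merged reads and
unmerged pairs are carried through separately as the `merged` and
`paired` evidence classes.

Each candidate read must then begin with the library's **anchor**: the
terminal 37 bp of the 3'-LTR for a 3'-end library, or the reverse
complement of the first 32 bp of the 5'-LTR for a 5'-end library (so in
read orientation both anchors end with the CA terminus). `strip_anchor()`
matches the anchor as an exact prefix (mismatch tolerance 0 by default)
but allows up to `max_erosion = 5` terminal bases to be absent, so that
recombination-style junctions — whose LTR terminus is eroded — are still
recovered while being flagged `anchor_complete = FALSE`. Reads in which
the splinkerette adapter starts within 5 bp of the anchor end are empty
inserts and are rejected; trailing adapter sequence is trimmed from the
host flank (`trim_splinkerette()`).

### The four authenticity criteria

`call_sites()` emits a junction call only when

i. the read begins with the library anchor;
ii. the anchor is *not* immediately followed by splinkerette adapter;
iii. the remaining host flank maps uniquely (a single co-optimal
     placement) over at least 30 bp; and
iv. the mapping quality is at least Q30.

The junction coordinate is the first host base adjacent to the LTR
terminus: the host alignment must start at the first base of the flank,
and the call is placed at the alignment's anchor-proximal boundary
(alignment start on `+`, end − 1 on `-`). Rejected reads are tallied by
their first failing criterion.

PCR duplicates collapse to **unique positions** — identical (chromosome,
position, strand, LTR end) calls count once (`dedup_and_unique()`) — and
unique positions within 250 bp chain into **unique clusters**
(`cluster_positions()`). Chaining is transitive single linkage: a run of
positions 0, 200, 400 is one cluster. We chose chaining over
fixed-windows because the clusters are defined by merging *neighbouring*
positions sequentially; the cluster count is then invariant under input
order, and the number of clusters can never exceed the number of unique
positions. Unique positions are keyed with strand; the 5'- and 3'-end
libraries are never merged into joint events and are reported separately
throughout.

### Junction classification

A call is **integrase-catalyzed** when the complete anchor is present
(intact CA terminus in read orientation) and the host alignment begins at
the very next base. It is **unresolved** when the terminus is eroded, or
when the host flank itself begins with the terminal dinucleotide — a
microhomologous junction whose boundary cannot be assigned to either
genome. Everything downstream (counts, rates, region classification)
treats the two classes identically; the split is reported in the library
summary.

### The mapper

Host chromosomes and the provirus are indexed together (15-mer hash,
`build_index()`), so each read competes across both references and the
best-scoring placement decides its assignment. `map_reads()` performs
seed-and-extend, ungapped: seed k-mers are taken every 5 bp along the
read (plus the read tail), candidate diagonals are ranked by seed votes,
and each candidate is scored by the maximal-scoring contiguous segment
(match +1, mismatch −3). That segment is what makes chimeric junction
reads tractable without gapped alignment: the host part and the provirus
part of a split read surface as two partial alignments in complementary
query spans. Mapping quality is `min(60, 2 × (best − second-best
score))`, forced to 0 whenever two placements tie, so the Q30 criterion
reads as "unique and confident". Ungapped extension is a deliberate
restriction — the junction criteria operate on clipped prefix/suffix
structure, not indels — and alignments from an external gapped aligner
can be substituted through the SAM interface.

## The WGS burden estimator

### Pair categories

`categorize_read_pairs()` assigns each pair to one of three categories:

- **partial** — one read has an anchor-free split: a ≥20-bp prefix
  aligning to one reference and the remaining ≥20-bp suffix to the other
  (the junction lies inside the read);
- **independent** — one mate maps only to host, the other only to the
  provirus (the junction lies between the mates);
- **virus_only** — both mates are provirus-internal (unintegrated or
  deeply internal proviral DNA; no positional evidence).

A provirus-side match counts only when it beats every host placement of
the same read by score, which suppresses false positives from host
elements that resemble the provirus. Host-only pairs are dropped.

`count_integrations()` turns categories into an event count `x`: partial
junctions are deduplicated by single-linkage chaining at one fragment
length (both junctions of one provirus map to nearly the same host
coordinate, so they merge into one event), and an independent event
within one insert length of a counted partial junction is suppressed as
re-evidence of the same provirus. A `suppress_independent = FALSE` flag
restores purely additive counting.

### The estimator

With `R` properly paired read pairs (each approximately one sequenced
100-base segment), a diploid genome contributes `S = 2 × Σ lengths /
read_length` segments, and the expected burden per nucleus is

> per_nucleus = x · S / R,

with an exact Clopper–Pearson interval on the binomial proportion `x/R`,
scaled by `S`. The bounds are computed through the incomplete-beta
inverse (`qbeta`), which is algebraically the inversion of the binomial
tail probabilities; the package checks them against a direct CDF
bisection oracle at 1e-9. Multiplying by the nuclei per organism gives
the per-organism burden, and `nuclei_from_mass()` converts the input DNA
mass to the number of nuclei represented in the library (mass in ng ×
1000 / diploid genome mass in pg).

### What the synthetic WGS pool emulates — and what it does not

In the real survey the sample contains millions of nuclei, each carrying
its own handful of integration sites, and the run samples far less than
one genome-equivalent per nucleus: every detected event is seen in about
one read, and `x` grows linearly with sequencing effort. At desk scale we
emulate the mosaic with `simulate_wgs_pool()`: `K` genomes are planted
independently with the per-nucleus burden and pooled so total coverage
reaches the configured fold. The default `K` equals the number of
diploid-genome-equivalents the run samples (`R/S`, i.e. coverage/4 for
100-bp pairs). In that regime every planted provirus is deeply covered
and recoverable, so `x` equals the number of planted events in the pool
and the estimator's CI coverage can be assessed against the known burden.

The regime matters because fragment geometry makes a junction detectable
over a window wider than the estimator's nominal single 100-bp segment:
each provirus has two junctions, each visible to read-spanning windows of
about `2 × (read_length − 20)` bp plus the between-mates gap. In a sparse
mosaic this inflates `x` by roughly the ratio of the true window to one
segment (about 1.7× at the default geometry), an upward bias inherent to
the segment-counting model rather than to this implementation. In the
saturated pool the inflation disappears — multiple evidence pairs for one
provirus deduplicate to one event — which is why the recovery tests run
there. Conclusions about sparse-mosaic accuracy should therefore not be
drawn from the recovery tests; they validate detection, deduplication,
counting and interval arithmetic.

## Region annotation and the bias test

`genome_composition()` computes the exon / intron / intergenic bp
fractions of the annotated genome, with exon taking precedence where
transcripts overlap (intron = gene span minus exon union; UTRs are not
modelled — the annotation schema is gene/exon only). Sites are classified
by their cluster representative, defined as the minimum member position
(the choice is arbitrary; at a 250-bp radius it moves a site across a
region boundary only for clusters straddling one). `noncoding_bias_test()`
is the exact upper-tail binomial probability of seeing at least the
observed number of non-coding sites if integration followed genome
composition — a single pre-registered comparison, so no multiple-testing
correction is applied. Per-chromosome per-Mb rate tables
(`rate_table()`) keep full precision internally and round to one decimal
only in written reports.

## The synthetic-data module

`simulate_genome()` lays out random chromosomes with multi-exon gene
models targeting the study composition of 4% exon, 39% intron and 57%
intergenic sequence; realized fractions land within about two percentage
points of target. Genes draw 6–12 exons of 100–300 bp with introns scaled
to the in-gene exon fraction, and intergenic gaps absorb the remainder.

`plant_integrations()` inserts the provirus right-to-left so that truth
positions stay in reference coordinates. Integrase events are full length
with a 5-bp TSD (configurable 0–10; standard for HIV-1 integrase —
downstream callers deliberately ignore TSDs and report the first aligned
host base). Recombination-style events erode *both* termini by draws from
the truncation spectrum (default uniform 1–200 bp, since truncated
proviral forms are reported without sizes) and create no TSD. Planting
redraws any site whose junction flank would begin with the terminal
dinucleotide (`avoid_microhomology = TRUE`), keeping ground-truth
junction classes unambiguous; real data contains such junctions, which is
exactly why the caller has an `unresolved` class.

`simulate_tradis_reads()` builds amplicons that start exactly at the
anchor (the protocol's nested primer defines the read start; whether real
amplicons ever start upstream of the anchor is not modelled) and extend
into host flank, with splinkerette on the far end, host-only decoy
fragments (10% by default) to exercise rejection paths, and a small
empty-insert rate. Qualities are constant Q37 with injected errors at
Q10; no quality-by-cycle error model is attempted since no filter in the
pipeline reads base qualities except through merge disagreement
resolution. An event whose terminal erosion exceeds the anchor length is
invisible to that library end, as in the real protocol.

`simulate_wgs_reads()` samples fragments uniformly at the configured
coverage; partial, independent and virus-only pairs arise purely from
geometry.

## Numerical and scale choices

- Internal coordinates are 0-based half-open everywhere; 1-based closed
  appears only at the GFF3 boundary and in printed reports. BED output is
  0-based half-open.
- The mapper's stride-5 seeding guarantees a seed for any exact segment
  of ≥ 19 bp, below both the 20-bp split minimum and the 30-bp host
  minimum.
- Clopper–Pearson bounds: `x = 0` pins the lower bound at 0 and `x = n`
  the upper at 1; elsewhere `qbeta` is used at full precision and
  rounding happens only in reports.
- Test and validation problem sizes: 2-Mb genomes, 20 planted events for
  the error-free recovery runs, 200 events for the junction-class mix
  (terminal erosion 2–5 bp, within the caller's erosion window — erosion
  of a single base can be genuinely ambiguous when the flank base
  coincides with the terminus), and twenty 48× WGS replicates for CI
  coverage. These sizes give stable statistics while keeping a full run
  in the minutes range on one core.
- With zero planted events the pipeline returns empty call sets and the
  estimator refuses `R = 0`; `x = 0` yields a zero estimate with a
  one-sided interval.

## Known limitations

- The mapper is ungapped; indel-containing junction flanks will be
  clipped rather than aligned, shifting (rarely losing) a call. External
  gapped alignments can be supplied as SAM.
- Mapping-quality calibration follows the score-gap convention above and
  is not numerically identical to any external aligner; only the Q30
  threshold semantics carry over.
- The WGS estimator inherits the segment-model bias discussed above when
  the sample is a sparse mosaic.
- Repeat-rich real genomes will push more flanks below the uniqueness
  criterion than the random synthetic genomes used here; the recovery
  rates measured on synthetic data are upper bounds in that respect.
- The annotation model is gene/exon only: no UTRs, no nested isoform
  resolution beyond exon-over-intron precedence.
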