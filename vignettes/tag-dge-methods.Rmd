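---
title: "Methods: restriction-tag digital gene expression profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: restriction-tag digital gene expression profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tagdge)
```

## The measurement model

Tag-based digital gene expression (DGE) profiling quantifies a transcriptome
by sequencing short restriction-anchored cDNA tags rather than whole
transcripts. In the NlaIII/MmeI protocol this package models, oligo-dT-captured
cDNA is digested with NlaIII, which cuts at every CATG; the bead-bound 3'
fragment is retained, an adaptor is ligated at the CATG junction, and MmeI —
whose recognition site sits in that adaptor — cuts 17 bp downstream. Each
transcript molecule therefore yields one 21 bp tag: the 3'-most CATG of the
sense strand plus the 17 following bases, embedded in a 49 bp sequencer read
padded with adaptor. Tag counts are a digital proxy for transcript abundance.

Two protocol consequences shape everything downstream:

* a gene with no CATG, or whose 3'-most CATG has fewer than 17 downstream
  bases, can never produce a tag (a structural dropout, not a sampling zero);
* sequencing errors and tags shared between genes produce reads that must be
  rescued (1-mismatch mapping) or excluded (ambiguity filtering) rather than
  counted naively.

## Virtual tag database

`build_tag_index()` enumerates *all* CATG+17 windows of every reference
sequence, not only the 3'-most: incomplete NlaIII digestion lets real
libraries sample internal sites, so internal windows are legitimate mapping
targets even though the clean protocol emits only the 3'-most tag. Windows
are taken from the sense strand by default — unigene orientation is fixed in
the reference — with reverse-complement indexing available behind
`include_revcomp = TRUE` for references of uncertain orientation. Overlapping
CATG occurrences each contribute their own window.

## Read cleaning

`clean_reads()` reduces raw 49 bp reads to clean 21 bp tags. A read is
discarded as *empty* when no CATG sits at the tag position (adaptor-only
reads, or reads too short to hold a tag) and as *N-contaminated* when the tag
region contains an `N`. The accounting identity
`empty + N + clean == raw` is asserted on every run, and cleaning is
idempotent. Two configurable points the protocol itself does not fix:

* the tag's offset within the read defaults to position 1;
* "low quality" is operationalized as `N` inside the 21 bp tag; no
  quality-score filter is applied by default, since the tag region is short
  and the anchor check already rejects unusable reads.

## Tag mapping with one mismatch

`map_tags()` resolves each distinct clean tag in two passes. Exact matches
are found first; only tags with no exact hit anywhere are compared against
all 51 single-substitution neighbours of their 17 variable bases. The CATG
anchor must match exactly — it is enzymatically fixed, so a mismatch there
signals an unusable read, not a sequencing error to rescue. Exact-match
precedence is a deliberate choice: without it, error-tolerant matching would
manufacture ambiguity for perfectly matching tags that happen to sit one
substitution away from another gene's window.

A tag whose resolved gene set has exactly one gene is *unambiguous*; tags
hitting several genes are *ambiguous* and excluded from gene counts (hitting
several windows of the *same* gene is still unambiguous); tags matching
nothing within the budget are *unknown*. The three totals partition the
clean total, asserted on every run. The implementation is hash-based lookup
over the window table; at tag-library scale nothing fancier is warranted,
and the test suite pins the implementation to a brute-force all-pairs
Hamming oracle on randomized fixtures.

## Normalization and the count test

Per-gene expression is the unambiguous tag count normalized to TPM
(transcripts per million *clean* tags): `count / total_clean * 1e6`. The
denominator is deliberately the clean total, not the mapped total, so TPMs
sum to `1e6 *` (mapped fraction), another asserted identity.

Differential expression between two libraries — one library per condition,
as this protocol is typically run — uses the Audic–Claverie exact count
test. Conditioning on count `x` among `N1` clean tags, the null law of the
count `y` among `N2` tags is

$$P(y \mid x) \;=\; \Big(\tfrac{N_2}{N_1}\Big)^{y}\,
  \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}},$$

which is exactly the negative binomial with size $x+1$ and success
probability $N_1/(N_1+N_2)$. `ac_test()` evaluates tails through that
identity (`pnbinom`), which is numerically stable for counts far beyond
$10^5$; the test suite verifies agreement with exact-rational tail sums to
$10^{-10}$ relative error. The two-sided p-value doubles the smaller tail
with the observed value included in both tails, capped at 1:
`p = min(1, 2 * min(P(Y <= y), P(Y >= y)))`. One discretization subtlety is
worth recording: the *probabilities* $P(y \mid x)$ are exchange-symmetric in
$(x, N_1) \leftrightarrow (y, N_2)$ after removing the library-size
prefactor, but the doubled-tail p-value is only approximately so, because the
two directions' tail sums differ by boundary terms. The package reports the
tail as defined above rather than forcing symmetry.

Multiple testing uses Benjamini–Hochberg step-up adjustment (`bh_adjust()`,
delegating to `stats::p.adjust`). A gene is called differentially expressed
when `FDR <= 0.001` **and** `|log2 ratio| >= 1` (both thresholds
configurable). For the ratio, zero counts are floored at one tag-equivalent —
so a gene seen only in one library still reports a finite ratio, bounded by
`log2(count)` at equal depths — while genes with zero in *both* libraries
have no defined ratio, are rendered `-`, and are never significant. The floor
applies to the ratio only, never to the test. Time-course phase
classification (`classify_phase()`) assigns each gene its earliest
significant up-regulation: phase 1 at 1 h, phase 2 first at 5 h, phase 3
first at 24 h.

## Enrichment

`enrich_terms()` tests term over-representation among DEGs with the exact
hypergeometric upper tail $P(X \ge k)$ on the contingency $(N, K, n, k)$.
The background $N$ is the set of genes carrying *any* term annotation — not
the whole reference — and the DEG set is intersected with it; both
conventions match how pathway-annotated denominators are conventionally
reported, and the DEG denominator $n$ is always derived from the data rather
than taken from a caption constant. Q-values are Benjamini–Hochberg across
the tested terms of one comparison; `q <= 0.05` flags significance. The test
is upper-tail only (enrichment, not depletion).

## Saturation analysis

`saturation_curve()` asks whether detection has plateaued with depth: tags
are subsampled without replacement at a grid of sizes and detected genes
(>= 1 unambiguous tag) counted. Rather than drawing an independent
hypergeometric subsample per grid point, the implementation permutes the
expanded tag multiset once under the run's seed and reads each grid size off
a prefix. Each prefix is exactly a uniform without-replacement subsample, so
the per-point distribution is unchanged, and nesting makes the curve
monotone sample-wise with the full-library endpoint exact — properties the
independent-draw design only has in expectation.

## What the simulator emulates — and what it does not

`simulate_transcriptome()`, `simulate_expression()` and
`simulate_tag_library()` generate study-like data with known truth:

* **Reference**: random A/C/G/T unigenes, log-normal lengths around a mean
  of 560 bp (the scale of short-read de novo unigene sets). A configurable
  fraction (default 5%) is guaranteed CATG-free; the rest are guaranteed
  taggable at the 3'-most site.
* **Abundance**: log-normal with log-SD `dispersion = 3`. This default was
  calibrated once, to the qualitative shape of real tag libraries in which
  most detected genes carry fewer than 10 copies at around a million tags of
  depth, and is not tuned per analysis.
* **Differential structure**: one planted gene subset (default 10%) with
  up/down signs split evenly and a fixed log2 effect applied in every
  non-control condition, then renormalized. Recorded effects are the
  pre-normalization multipliers; with small DE fractions the compositional
  shift this ignores is a fraction of a log2 unit and falls inside the ratio
  threshold.
* **Reads**: tag reads carry the gene's 3'-most tag with independent
  substitution errors on the 17 variable bases (default 1% per base, an
  early-Illumina scale; the anchor is left intact since anchor errors
  produce unparseable reads, which the contamination categories already
  model). Adaptor-only reads (default 5%) and N-contaminated reads (default
  3%) are injected so that roughly 92% of raw reads survive cleaning,
  matching the raw-to-clean retention of real libraries. The adaptor filler
  is a fixed constant whose identity is irrelevant downstream.

Not modelled: PCR-amplification bias, cluster formation, realistic quality
strings, antisense tags (the simulator is sense-only, consistent with the
default index), and — most consequentially — an incomplete reference.
Real libraries lose half or more of their distinct tags as *unknown* because
the reference misses transcripts and alleles; simulated libraries, mapped
against their own generating reference, have unknown rates set only by the
error model. Passing tests therefore validate the machinery and its
calibration, not the unknown-tag economics of any real experiment.

## Numerical and design choices

* Ties at the observed count enter both tails of the two-sided p (and `x = y`
  with equal library sizes gives exactly `p = 1`).
* The 1-tag zero floor for ratios keeps single-library detections finite and
  bounded by `log2(N)`-scale values at library depth; a constant TPM floor is
  available through `zero_floor` but is not the default.
* Degenerate enrichment inputs are defined, not errors: `k = 0` and `K = N`
  both give `p = 1`; an empty annotated DEG set returns an empty table.
* Percentages are reported to 2 decimal places throughout.
* Determinism: every stochastic function takes a `seed`; the pipeline derives
  stage seeds from the run seed, and identical configurations produce
  byte-identical stage tables.

The test suite exercises these conditions at deliberately chosen scales:
references of 2,000–10,000 genes, libraries of $10^5$ tags for null
calibration (50 seed pairs) and $10^6$ tags per library for effect recovery
(8-fold planted effects, 5% DE fraction), with sensitivity assessed on
truly-DE genes whose expected baseline count is at least 20 — below that,
a single-library count test has little power at any threshold this strict.

## Limitations

* One library per condition: no replicate-aware dispersion modelling
  (negative binomial with estimated dispersion, as in modern RNA-seq); the
  Audic–Claverie test treats all extra-Poisson variation as signal, which is
  the method's historical behaviour and its known weakness.
* Tags are fixed-length substitution-only objects; indels and spliced
  alignment are out of scope.
* The enrichment stage consumes caller-supplied annotation maps; it performs
  no ontology retrieval or pathway topology analysis.
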