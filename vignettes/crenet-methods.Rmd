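---
title: "Methods: integrative cis-regulatory network inference with crenet"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative cis-regulatory network inference with crenet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`crenet` places a transcription factor (TF) inside a cis-regulatory network
by integrating replicated ChIP-seq peak calls for a panel of factors,
a classified catalog of candidate cis-regulatory elements (cCREs),
signal tracks, an RNA-seq count matrix from a perturbation experiment,
and genomic sequence. Every stage is a small, separately testable
procedure; a deterministic synthetic-data module plants ground truth for
all of them. This vignette documents the statistical and algorithmic
choices; it makes no empirical claims beyond what the test suite computes.

# Replicate consensus

Two replicate peak lists are reduced to a consensus set
(`consensusPeaks()`):

1. Candidate pairs must overlap **reciprocally**: the shared bases must be
   at least a fraction `minReciprocalOverlap` (default 0.5) of *each*
   peak's width. Reciprocity removes asymmetric matches where a broad,
   weak peak swallows a narrow one.
2. Pairing is **greedy one-to-one** by descending combined score, so each
   peak supports at most one consensus region and strong concordant peaks
   are paired first. The retained interval is the union span of the pair.
3. A **rank-fraction filter** keeps a pair only if both members lie in the
   top `rankFraction` of their own replicate's score ranking (index bound
   `floor(f * n + 1e-9)`, the small epsilon guarding against binary
   floating-point representations of fractions like 0.7).
4. The Spearman correlation of paired scores is reported; below 0.5 the
   replicates are flagged as weakly concordant with a warning rather than
   an error, because downstream stages remain well defined.
5. Per-pair reproducibility is summarized as
   `pmin(1 - rankA/nA, 1 - rankB/nB)`: a pair is only as reproducible as
   its weaker member.

# cCRE classification

`classifyElements()` implements a SCREEN-style decision list over
DNase, H3K4me3 and H3K27ac element-level Z-scores plus the distance from
element center to the nearest TSS:

* **PLS**: distance ≤ 200 bp, high DNase and high H3K4me3;
* **pELS / dELS**: not PLS, high DNase and high H3K27ac, split at 2 kb;
* **DNase-H3K4me3**: high DNase and H3K4me3, low H3K27ac, beyond 200 bp;
* **DNase-only**: high DNase, low H3K4me3 and H3K27ac;
* otherwise unclassified.

"High" means Z ≥ 1.64 and "low" means Z < 1.64 — the one-sided 5% normal
point, so the high/low split is an explicit significance statement rather
than a tuned threshold. `computeMaxZ()` standardizes the maximum track
signal over each element with the **population** standard deviation
(divisor *n*), matching the convention of signal-compendium Z-scores; a
zero-variance signal is an error, not a silent zero.

Peaks inherit the class of the catalog element sharing the most bases
(`assignPeakClasses()`, ties broken by genomic order), and
`classDistribution()` reports the fraction of peaks per class.

# Co-occupancy

For a panel of factors, consensus peak sets are merged into a single
region universe (`buildMergedRegions()`). The score of factor *f* on
region *r* is the **length-weighted mean** of *f*'s signal track over *r*
(uncovered bases count as zero): length weighting makes the score
invariant to how a track is split into blocks. Factor similarity is the
Spearman correlation over regions (robust to monotone track rescaling),
clustered with average linkage on distance 1 − ρ; columns are ordered
alphabetically first so leaf order is deterministic. Regions with zero
signal in every factor carry no rank information and are dropped (their
count is reported). A base-level Jaccard matrix over peak footprints is
provided as a rank-free cross-check, and dendrograms export to Newick.

# Peak-to-gene association

`buildRegulatoryDomains()` builds basal-plus-extension regulatory
domains: each gene owns a strand-aware basal window (5 kb upstream, 1 kb
downstream of its TSS) extended up to 1 Mb in each direction but stopping
at the nearest neighboring basal domain; basal domains themselves are
never truncated. A peak is associated with a gene when its **center**
falls inside the gene's domain (center containment avoids double counting
from marginal edge overlaps; an overlap mode is available). Distances are
signed relative to gene strand, negative upstream.

# Network inference

`inferNetwork()` keeps only peaks whose cCRE class is regulatory
(PLS, pELS or dELS — classes with promoter or enhancer evidence),
associates them with genes through the regulatory domains, and emits one
directed edge per (factor, gene) pair with the supporting peak count as
weight and the full peak-level evidence retained. Self-loops are allowed:
a factor bound at its own locus is biologically meaningful
autoregulation. Node statistics (in/out degree, TF–TF interconnectivity)
and TSV/GraphML export round out the module.

# Expression integration

* **CPM** uses effective library sizes `libSize * normFactor`.
* **Low-expression filter**: keep genes with CPM ≥ 1 in at least 3
  samples (computed on unnormalized CPM, as in common edgeR practice).
* **TMM** is implemented directly on raw-count ratios: M and A values
  between each sample and a reference column, double trimming (30% of M,
  5% of A), inverse-asymptotic-variance precision weights, and a final
  rescaling so factors have geometric mean 1. The implementation is
  cross-checked in the test suite against `edgeR::calcNormFactors` after
  converting edgeR's library-size-relative factors to the same scale.
* **Differential expression** for the synthetic path uses
  `edgeR::exactTest` with common dispersion; `callDE()` applies the
  thresholds FDR < 0.05 and |log2FC| > 0.2 — an intentionally permissive
  fold-change floor suited to knockdown designs where direct targets can
  shift modestly.
* **Bound-versus-regulated overlap** (`boundDeOverlap()`) reports the
  fraction of bound genes that are down- (and up-) regulated and
  one-sided hypergeometric enrichment p-values over an explicit gene
  universe.

# Motif enrichment

IUPAC consensus motifs (e.g. `NCGGAAMM`) are scanned with an allow-matrix
over the classes A/C/G/T/other; any byte outside ACGT (including N)
matches only motif positions whose code is N, so ambiguous reference
bases never create spurious matches. Reverse-strand matching scans the
reverse-complemented motif forward, which is equivalent to scanning the
reverse-complemented sequence. Backgrounds are either user-supplied or
generated by an Altschul–Erickson **dinucleotide shuffle** (exact
preservation of dinucleotide counts and endpoints via a random Eulerian
trail), which protects against CpG-type composition artifacts.

Enrichment is a one-sided binomial test of the foreground count of
sequences with ≥ 1 hit against the **plug-in** background hit fraction.
A plug-in test treats the background rate as known; with equal arm sizes
its null size is inflated (roughly Φ̄(z₀.₀₅/√2) ≈ 0.12), so calibration
requires a background arm much larger than the foreground. The synthetic
calibration design therefore uses a 20:1 background, for which the same
normal approximation gives size ≈ 0.054; this ratio was chosen from the
formula, not tuned to simulation outcomes. When the background has zero
hits the fold change is reported as infinite with a flag rather than
clamped.

# Synthetic data

`simConfig()` freezes a complete study design; its defaults *are* the
study conditions under test: a 928-peak target landscape with class
proportions 0.48/0.134/0.097/0.12/0.08
(PLS/pELS/dELS/DNase-H3K4me3/DNase-only), 500 shared + 250 private peaks
per replicate with ±50 bp jitter, a 13-factor panel in two co-binding
groups (within-group signal correlation 0.8), 30 planted targets per
factor, negative-binomial counts (dispersion 0.1) with 15% of genes
differentially expressed at |log2FC| = 2, and motif occurrence rates of
0.30 (foreground) versus 0.05 (background) for `NCGGAAMM` in 200 bp
sequences. `simulateStudy()` writes a full on-disk study (chrom.sizes,
BED, narrowPeak, bedGraph, FASTA, TSV counts and a manifest with
relative paths) plus ground-truth tables; identical configurations give
byte-identical output, and all random generation saves and restores the
caller's RNG state.

# Pipeline

`runPipeline()` consumes a YAML configuration validated against a strict
schema before any computation, then runs consensus → annotation →
co-occupancy → peak-to-gene → network → expression → motif, each stage
individually skippable. All outputs are plain text; the JSON run report
carries no timestamps, so identical inputs give byte-identical runs. A
command-line front end is installed at
`system.file("scripts", "regnet.R", package = "crenet")`.

# Limitations

* The NB exact test with common dispersion is a deliberate simplification
  of tagwise-dispersion workflows; it is calibrated on the synthetic
  designs but not a drop-in for production RNA-seq analysis.
* The plug-in binomial enrichment test requires a large background; for
  small backgrounds an exact two-sample test would be preferable.
* Element classification consumes precomputed Z-scores or rectangular
  signal tracks; it does not model read-level noise.
* Peak-to-gene association is proximity-based; it does not use chromatin
  conformation data.
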