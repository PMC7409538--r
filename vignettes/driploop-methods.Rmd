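---
title: "driploop: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{driploop: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

driploop re-implements, as a tested and reusable pipeline, a genome-wide
DRIP-seq analysis of R-loop regulation: per-sample broad peak calling versus
input with an RNase-H specificity control, consensus peak construction across
conditions, negative-binomial Wald tests for R-loop gain/loss under siRNA
knockdowns, annotation of the peak landscape against gene models, and the
detection of intergenic antisense transcription upstream of the TSSs of genes
hosting R-loop gain peaks, from stranded RNA-seq. Because the original
sequencing libraries of such studies are rarely recomputable at desk scale,
the package ships a first-class synthetic-data generator that plants all of
these effects with machine-readable ground truth, and the test suite
validates the pipeline by parameter recovery rather than by matching
published tables.

## Coordinate model and interval primitives

All intervals are 0-based half-open BED-style coordinates internally and in
BED output; GTF files are written and read 1-based inclusive, as each format
defines. The distance between disjoint intervals is the half-open gap
(`next.start - prev.end`), so book-ended intervals are at distance 0 and
merge at `max_gap = 0`. The midpoint of an even-length interval is
`start + floor(length/2)`. Ties (nearest-gene ranking, TSS-vs-TTS side) are
always broken deterministically — lexicographically by (chromosome, start,
gene id), and toward TSS — so every output is reproducible.

Two nearest-gene definitions coexist in the literature and both are exposed:
`endpoint` mode ranks genes by the smaller of |peak midpoint − TSS| and
|peak midpoint − TTS| (the definition used for annotation), and `interval`
mode ranks by the gap to the gene body (bedtools-closest style, used for the
neighbor-distance analyses). The "neighbor" of a peak is the second-nearest
gene. Peak-to-category assignment uses the peak midpoint base; whether the
original analysis used midpoints or bp-overlap fractions is not documented,
so the midpoint convention is adopted and stated here.

## Feature map

Every base of the genome is assigned exactly one category with priority
`promoter-TSS > TTS > 5'UTR > 3'UTR > exon > intron > noncoding >
intergenic`. The promoter window is `[TSS − 1000, TSS + 100)` and the TTS
window `[TTS − 100, TTS + 1000)`, both oriented along the gene; the windows
are configurable because the upstream tooling this stands in for does not
print its settings. The per-base representation makes the partition property
(category bp totals sum exactly to genome length) true by construction, and
the tests verify it against an independent per-base labeling oracle.

## Peak calling

The broad-mode caller is a fully specified stand-in, not a re-implementation
of the cited tool: the genome is tiled into 100-bp bins; the expected IP
count per bin is `max(genome-wide input rate, local 5-kb input rate) ×
(IP library / input library)`; per-bin Poisson upper-tail p-values (bins with
at least one IP read) are Benjamini–Hochberg corrected genome-wide per
sample; bins with q < 0.1 are merged across gaps up to 500 bp and peaks
shorter than 200 bp are dropped. Downstream analyses depend only on the peak
intervals, which is why a deterministic and testable caller is preferred.
Consensus peaks are the union of all per-sample peaks merged at gap 0
(`min_support = 1` by default, matching a plain union; a replicate-consistent
mode is available). RNase-H sensitivity is annotated, not filtered, by
default: a peak is a credible DNA/RNA hybrid when its library-normalized
RNase-H/IP signal ratio falls below 0.5 (pseudocount one read on both sides).

## Differential model

Counting, normalization and testing are shared by DRIP peaks, genes and
intergenic windows. Size factors use the median-of-ratios estimator rescaled
to geometric mean 1, with an automatic fallback to total-count scaling when
no feature has all-positive counts. The NB model is `Var(q) = mu/s_j +
alpha mu^2`. Dispersion is estimated per feature by the method of moments
from normalized counts pooled within conditions, floored at `alpha_min`, and
shrunk toward an `a0/mu + a1` trend fitted by least squares over features
with mean > 1, mixing geometrically with weight `w` on the feature-wise
estimate.

**Why `w = 0` by default.** With two replicates per condition the moment
estimate has two degrees of freedom; around 40% of null features have sample
variance below the mean and collapse to the floor, and a log-space mix with
any weight on those values drags dispersions toward zero, inflating Wald
statistics (measured null p < 0.05 rate ≈ 0.14 at `w = 0.5`, versus the
required 3–8% band). Full shrinkage to the trend restores calibration (null
p < 0.05 ≈ 0.05; q < 0.1 rate ≈ 0.02%) while leaving recall for planted
|log2FC| = 2 effects at 100% with realized FDR ≈ 6% and |bias| < 0.08. The
weight remains a parameter for designs with more replicates.

The Wald statistic is `log2FC / se` with `log2FC = log2((mu_t + 0.5) /
(mu_c + 0.5))` and a delta-method standard error; p-values are two-sided
normal, BH-corrected excluding all-zero features (reported with p = q = 1).
Classification uses |log2FC| > 1 at FDR < 0.1 for DRIP contrasts and
FDR < 0.05 for RNA-seq differential expression. No fold-change shrinkage is
applied; the 0.5 pseudocount stabilizes low counts.

## Landscape statistics

Feature-category distributions are reported per classified subset and always
sum to 100%. Neighbor-distance comparisons (gain vs unchanged, loss vs
unchanged) use Welch's t-test with Welch–Satterthwaite degrees of freedom.
Per-chromosome gain/unchanged and loss/unchanged ratios are reported against
the chromosome's mean neighbor distance (an inverse gene-density proxy);
0/0 is an NA sentinel. Overlap enrichment between gain (or loss) sets uses
the one-sided hypergeometric upper tail computed by log-space summation with
the consensus peak id set as the universe — the original universe definition
is not stated, so the printed p-value bounds of the source study are not
reproduction targets; the implementation is instead validated against an
exact enumeration oracle. Metagene profiles scale each gene body to 50 bins
with 5-kb/25-bin flanks (strand-oriented, TSS left), assign read midpoints to
bins, average reads-per-million over genes, and optionally subtract a control
condition bin-wise; `intergenic` mode keeps reads overlapping no gene body,
`intronic` mode reads overlapping an intron. Sample QC reports Pearson
correlations and an SVD PCA of the 500 most variable features on
`log2(normalized + 1)` — a deliberately simple, monotone stand-in for
variance-stabilizing transforms.

## Antisense detection

For every distinct nearest gene of a gain peak, a 5-kb window upstream of the
TSS and one downstream of the TTS are constructed strand-awarely, intersected
with the intergenic mask (complement of the union of gene bodies), and
dropped when fewer than 200 masked bp survive; each window records the
nearest gain peak within 5 kb. Intergenic reads (overlapping no gene body)
are counted in the full 5-kb and the gene-adjacent 2-kb windows separately;
the Wald test runs with the gene-level size factors because the windows are
too few and too signal-biased to self-normalize. A hit must satisfy all four
published thresholds: (1) adjacent-window log2FC > 0, (2) nearest-gene
expression log2FC < 2, (3) peak log2FC > 1, (4) peak FDR < 0.1. Threshold
(2) is implemented literally; the stricter alternative reading ("not
significantly up-regulated": not (log2FC > 1 and q < 0.05)) is available via
`strict_gene = TRUE`. Two guards are additions of this artifact and are
reported in the output: a minimum treatment-condition mean normalized
adjacent-window count of 5 (suppresses 0→1 count artifacts), and a 0.75
strand-purity cutoff for orientation (the original orientation calls came
from RT-primer assays, which print no fraction): TSS-upstream windows with
≥ 75% opposite-strand reads are `antisense`, TTS-downstream windows with
≥ 75% gene-strand reads are `sense-readthrough`, all else `ambiguous`. Only
the 2-kb test is enforced as threshold (1); the 5-kb fold change is reported
but not gated, since the source procedure is ambiguous on this point.

## Synthetic data: the stated world

The generator's defaults are the study design being emulated: one 10-Mb
chromosome; 300 non-overlapping genes (log-normal lengths, median ≈ 8 kb,
≥ 3 kb spacing, 10% noncoding, one transcript each with exons and a CDS);
four conditions (control plus three knockdowns) with two DRIP replicates and
three RNA-seq replicates; 100 planted R-loop peaks of 2 kb at 8× enrichment
over a 0.01 reads/bp Poisson background, placed 40/30/20/10% at
TSS/TTS/intron/intergenic positions; 25 gains (log2FC = +2) and 5 losses
(−2) per knockdown; gamma-Poisson replicate noise with dispersion 0.05
shared with the differential model so parameter recovery is well-posed; one
pooled input (background only) and one pooled RNase-H control retaining
ρ = 0.05 of peak signal (the source study only states that most peaks were
sensitive, so ρ is a simulator knob, not a measured value); promoter
sequence at GC 0.60 versus background 0.40 with the CpG dinucleotide rate
doubled via a conditional-probability boost whose base composition is
root-solved so realized GC still hits the target. RNA-seq plants gene
expression (log-normal), 30 differentially expressed genes per knockdown at
|log2FC| in [1, 2.5], a 10% intronic nascent fraction, a sparse intergenic
background of 0.001 reads/bp with random strand (real intergenic coverage is
sparse; this level also makes the min-mean hit filter meaningful), and
antisense loci attached to genes hosting TSS gain peaks of the first
knockdown: each emits opposite-strand reads in the 2 kb upstream of the TSS
at fold × background (fold 4) in the planted condition and 1× elsewhere.
Reads are emitted as already-aligned BED6 intervals — trimming, alignment,
duplicate removal, restriction-fragment structure, mappability and
sequencing error are upstream of the analyses reproduced here and are
deliberately not modeled. A green test therefore establishes that the
pipeline recovers planted effects under NB noise, not that it is robust to
alignment artifacts.

All randomness descends from a single seed through named substreams
(`substream_seed(seed, stage_name)`), so outputs are byte-identical across
runs and adding a stage never perturbs another stage's draws.

## Numerical choices and degenerate inputs

Poisson tails use the exact CDF; the hypergeometric tail is summed in log
space; BH is the standard step-up clipped at 1. Zero-input libraries are an
error in the peak caller; RNase-H ratios are guarded by one-read
pseudocounts; empty peak subsets warn and return empty tables; windows with
no reads classify as `ambiguous` with a warning; degenerate features (all
zero counts) are excluded from multiplicity correction. Intergenic read
membership, window masking and the feature-map partition are exact interval
computations, not approximations.

## Known limitations

The peak caller is a stand-in and will not reproduce the cited tool's
intervals bit-for-bit on real data. Dispersion estimation at n = 2 leans
entirely on the trend, so feature-specific overdispersion outliers are not
down-weighted (no outlier filtering is implemented by design). Only one
transcript per gene is modeled — no isoforms, no overlapping-transcript
quantification. Fisher overlap p-values depend on the peak-id universe
choice, which differs from whatever the source study used. The simulator
does not model fragment-level effects, GC bias, or mappability.
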