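---
title: "Methods: pausing indices, enhancer logic and the synthetic aging cohort"
author: "polpause"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pausing indices, enhancer logic and the synthetic aging cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `polpause`, in the spirit of how count-model and genomics packages
describe their internals. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Coordinates and windows

All intervals are 0-based half-open internally. GTF input (1-based
closed) is converted on load; BED-family files are native. The TSS and
TES of a gene are the 5' and 3' boundaries of its canonical open reading
frame: the canonical transcript is the one with the longest coding
sequence if the gene has translated transcripts, else the longest cDNA,
with ties broken by the lexicographically smallest transcript id so the
choice is deterministic.

Window conventions, chosen once and used everywhere:

* **Promoter window** "TSS ± 200 bp" is read inclusively on both ends:
  401 bp, half-open `[tss−200, tss+201)` on the plus strand and the
  mirror image on the minus strand. The same construction with
  half-width 1000 yields the TSS ± 1 kb enhancer exclusion zone
  (2001 bp).
* **Gene body** runs from 200 bp downstream of the TSS to 200 bp
  upstream of the TES, strand-oriented.
* **Narrow pause window** "TSS +20 to +100" is the half-open 80-bp
  window `[tss+20, tss+100)` — the region where paused polymerase
  typically sits, deliberately narrower than the standard promoter
  window so the two variants probe different geometry.

All window derivations are strand-involutive (mirroring coordinates and
flipping strands mirrors the windows); the test suite asserts this
property on random genes.

Gene selection keeps protein-coding genes with span strictly greater
than 2 kb whose envelope (2.5 kb upstream of the TSS and downstream of
the TES) overlaps no other annotated gene's span. The isolation test
deliberately uses the *other* genes' spans, not their envelopes, to
avoid double-counting the buffer. A phrase in the source material
attaches "± 200 bp" to the TES definition; we read it as descriptive of
the TES rather than an extra buffer, and apply none. The coverage filter
computes RPKM over the full gene span from sense-strand 5'-end counts
(an exonic-length variant is available via `length_mode = "exonic"`),
because span-based RPKM is the simplest faithful reading when only
"RPKM > 1" is stated.

## Pausing index

Per gene and sample, PI is the ratio of mean sense 5'-end density in the
promoter window to mean sense density in the gene body. Only sense
transcription enters either window. Three conventions matter:

* Genes with zero body signal in any sample are **excluded and
  logged** rather than assigned an infinite PI — the downstream cap
  filter (retain only PI ≤ 10 in all samples, boundary inclusive)
  presumes finite values.
* Per-condition PI for fold changes is the **arithmetic mean of
  replicate PIs**; the contrast is `log2(PI_b / PI_a)`.
* Category boundaries: high PI ≥ 3, moderate 1.5 ≤ PI < 3, low
  PI < 1.5. The boundary value 1.5 is assigned to *moderate* by
  default; `convention = "low_inclusive"` restores the alternative
  reading (low: PI ≤ 1.5), since both appear in the literature this
  package follows.

PI is scale-invariant: multiplying a track by any positive constant
leaves every PI unchanged, so RPM or RPGC scaling cannot affect it. The
promoter window is shared base-for-base between the PI numerator and the
ATAC promoter-accessibility quantification, which makes the
accessibility-versus-pausing quadrant analysis coherent: a gene is
counted in the "accessibility up / pausing down" quadrant when its
accessibility log2 fold change is strictly positive and its PI log2 fold
change is not (zeros fall on the "down" side of both axes).

## Density recording

The 5' end of a stranded nascent-transcription read marks the polymerase
position: plus-strand reads contribute their leftmost base, minus-strand
reads their rightmost. ATAC cut sites are the 5' ends of both mates with
strand collapsed to unstranded; no Tn5 +4/−5 shift is applied by default
(a flag exists) so the accessibility recording mirrors the
nascent-transcription convention. Library size counts mapped primary
records; supplementary alignments are excluded along with secondary ones
for robustness. The MAPQ threshold is > 10 and configurable. Tracks are
sparse per-base maps; RPM multiplies by 1e6/library size, RPGC rescales
so the genome-wide mean per-base signal is exactly 1 (the effective
genome size is a required argument — for synthetic runs it is the
simulated genome length).

## Consensus peaks and enhancers

Overlap semantics are ≥ 1 bp for "overlap" and 0 bp for "do not
overlap", matching standard interval-tool defaults. Consensus regions
are the merged union of all replicate peaks restricted to regions
supported by at least `min_support` distinct samples ("non-redundant"
is read as union-merge). Retention is monotone in `min_support`.
Enhancers are H3K27ac consensus regions passing three conjunctive rules
(no H3K4me3 overlap; outside TSS ± 1 kb; ≥ 1 bp ATAC overlap); the rule
trail of every candidate is preserved. Region annotation uses midpoint
containment with fixed precedence promoter > 5' UTR > exon > intron >
distal intergenic (configurable), since annotation packages differ in
their precedence and midpoint rules. An optional blacklist BED is
subtracted from consensus regions by plain interval arithmetic.

## Count statistics

The differential machinery is an intentionally lightweight stand-in for
a full count-model framework — comparable in direction and FDR
behaviour, not numerically identical to any particular package:

* **Size factors**: median-of-ratios over rows with all-positive
  counts, rescaled to geometric mean 1.
* **Dispersion**: per-region method of moments from within-group
  variances of normalized counts, floored at 1e-8 (Poisson fallback).
  With three replicates per group the raw per-region estimate is noisy,
  and its underestimates alone push the Wald null type-I error to
  roughly twice the nominal level; each region's dispersion is
  therefore additionally floored at the across-region *median* MoM
  estimate. This trend-free guard leaves Poisson-like data untouched
  and restores calibration (the acceptance suite checks type-I error
  within 0.05 ± 0.02 on 2,000 null negative-binomial regions for both
  tests).
* **Wald test**: group means of normalized counts; `log2FC / SE` with a
  delta-method standard error; two-sided normal p-values; BH across
  regions. All-zero regions are flagged inert (p = 1, log2FC = 0);
  zero-mean groups get a half-count continuity floor and a flag.
* **LRT**: one NB mean per condition versus a single shared mean, with
  the shared per-region dispersion; statistic against χ² with
  (levels − 1) degrees of freedom. Group means are size-factor-weighted
  count sums (the exact Poisson MLE, a good NB proxy at these depths).
* **rlog replacement**: clustering input is `log2(normalized + 1)`, a
  documented divergence from regularized-log transforms.

One practical caveat the tests make explicit: when *every* region of one
condition is shifted by the same factor, median-of-ratios absorbs the
shift into the size factors — that is the intended behaviour of
composition-based normalization. Power checks therefore supply unit size
factors when the programmed effect is global.

Classical tests are delegated where base R already provides them: the
rank-sum test uses the standard implementation (exact for small untied
samples — the test suite checks agreement with exhaustive enumeration at
n ≤ 8 — and tie-corrected normal otherwise), BH adjustment uses the
stock step-up procedure, and Kendall's τ (tie-corrected, τ-b) comes from
the standard correlation routine. The two-proportion z-test uses the
pooled closed form without continuity correction.

## Trajectory clustering

The gene–gene distance is `1 − τ` between across-condition profiles
(range [0, 2]; the exact transform used by the upstream literature is
unstated, so the simplest one is chosen). Constant profiles have
undefined τ and are excluded with a log message. Divisive clustering is
the classical splinter algorithm: repeatedly split the cluster with the
largest diameter; seed the splinter group with the object of maximal
average dissimilarity; migrate objects while they are on average closer
to the splinter group than to the remainder; stop at `k` clusters. All
ties break to the lowest object index, making the result deterministic;
an established independent implementation of divisive clustering serves
as a cross-check in the test suite, never as the implementation. The
number of clusters defaults to 4 and is a plain parameter — the
heuristic the original analysis used to arrive at its cluster count is
not re-implemented.

## Metagene profiles

Rows are anchors (typically TSSs), columns are fixed-width bins over
`[pos − flank, pos + flank)`; minus-strand rows are reversed so
transcription runs left to right; a uniform 1×-normalized track
therefore gives a flat profile at 1.0. The confidence band of the mean
profile is a percentile bootstrap over anchors (default 1,000 resamples
under the caller's RNG), chosen because the band's original construction
is unstated. Anchors too close to a chromosome edge (when sizes are
known) are padded with missing values and logged. Percentages in
proportion reports round half-up at each item's stated precision, since
printed reports mix precisions and half-even rounding would disagree
with printed values at exact halves.

## The synthetic aging cohort

The generator emulates the statistical structure the analysis assumes,
with every quantity needed for recovery tests known in closed form:

* **Annotation**: genes with alternating strands, spans drawn from
  2.4–3 kb, intergenic gaps from 5.5–8 kb — every gene passes the
  length (> 2 kb) and isolation (2.5 kb) filters by construction. Each
  gene has one coding transcript whose CDS is inset 100 bp, so the
  ORF-anchored TSS/TES convention round-trips through the GTF parser.
* **tNET reads**: per gene, `N ~ Poisson(2000)` sense reads; each 5'
  end falls in the pause zone (TSS +20..+100, uniform) with the
  condition's pause weight π, else uniformly in the gene body.
  Antisense (5%) and uniform intergenic noise (5%) reads are added.
  The defaults π = 0.6 / 0.45 / 0.3 for young / middle / aged program
  the age-related pausing decline; promoter accessibility enrichment
  rises 1.0 / 1.5 / 2.0 in the same order, so the dominant quadrant of
  the integration is accessibility-up / pausing-down.
* **Closed-form PI**: for a promoter window of length `Lw` containing a
  fraction `zfrac` of the pause zone and overlapping the body region by
  `o` bp, with body length `Lb`,
  `E[PI] ≈ (π · zfrac · Lb / (1 − π) + o) / Lw`.
  This expression was derived for the emission model above and verified
  against a 10⁶-read Monte-Carlo before being frozen into the tests
  (agreement to ~0.3%, the sampling error at that depth). With the
  standard window `zfrac = 1` and `o = 1`; with the narrow window
  `zfrac = 1`, `o = 0`, `Lw = 80`. Gene spans are capped at 3 kb so
  that even at π = 0.6 the expected PI stays below the cap of 10 and
  the extreme-PI filter removes nothing by construction.
* **ATAC fragments**: a uniform genomic background plus
  `(factor − 1)`-weighted excess fragments placed wholly inside
  promoter windows and active enhancers, with sub-nucleosomal (~60 bp)
  and mono-nucleosomal (~200 bp) length components. Placing the excess
  fragments entirely inside their region makes the measured cut-site
  density at promoters scale as the programmed enrichment factor, so
  the aged/young promoter accessibility ratio recovers the programmed
  2.0.
* **Peaks**: true enhancers emit H3K27ac + ATAC peaks, promoters emit
  H3K27ac + H3K4me3 + ATAC peaks, and decoy H3K27ac peaks lack ATAC
  support; edges are jittered (sd 20 bp) and whole peaks drop out per
  replicate with probability 0.1. With zero dropout the enhancer rules
  recover exactly the truth set; with dropout, all-sample consensus
  trades recall for precision relative to support-2 consensus, and the
  suite asserts that ordering rather than a recall level.
* **Count matrices**: negative-binomial with lognormal baselines
  (mean 100, dispersion 0.05), per-sample size multipliers and
  programmed ±1 log2 fold changes on a stated fraction of regions.

What the generator does **not** emulate: sequence content and mappability
(no FASTQ, no alignment errors), PCR duplicates, fragment-length biases
beyond the two-component mixture, chromatin-state heterogeneity along
gene bodies, splicing, and overlapping or nested transcription units.
Passing recovery tests therefore demonstrates the correctness of the
pipeline's arithmetic and logic under the stated model, not robustness
to every artefact of real libraries.

## Problem sizes and runtime choices

The packaged aging-demo scenario uses 100 genes on two 1-Mb
chromosomes, three conditions × three replicates, 2,000 sense reads per
gene and sample, 30 true enhancers plus 10 decoys, 50,000 ATAC fragments
per sample, and 2,000-region count matrices — large enough for stable
medians and calibration estimates, small enough that the full pipeline
and the complete test suite each run in well under a minute per
invocation on a single CPU. Null-calibration tests use 2,000 regions;
recovery tests use 500. The metagene bootstrap in the pipeline summary
uses 200 resamples (1,000 is the function default).

## Known limitations

* The NB tests have no dispersion shrinkage toward a mean-variance
  trend, no outlier filtering and no independent filtering; with very
  few regions the median-dispersion floor can over-moderate
  heterogeneous dispersions.
* Fragment-mode counting double counts fragments spanning two regions
  (by documented choice) and warns when regions overlap.
* The divisive clustering is exact but O(n²) per split; it is meant for
  the hundreds-to-thousands of trajectory genes typical here, not for
  tens of thousands of objects.
* Differential results on real data depend on upstream peak calling and
  alignment choices that are out of scope; the package starts from
  alignment records and peak calls.
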