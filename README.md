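# polpause

Integrative analysis of promoter-proximal RNA polymerase II pausing and
chromatin accessibility, built for nascent-transcription (tNET-seq) and
ATAC-seq studies of tissue aging.

In aging liver, promoters become more accessible while promoter-proximal
Pol II pausing declines. Quantifying that axis requires several
coordinated pieces: nucleotide-resolution Pol II density from the 5' ends
of stranded reads, a carefully filtered gene set, strand-aware promoter
and gene-body windows, pausing indices and their fold changes, promoter
accessibility measured over the *same* windows, enhancer calls from
histone-mark peak logic, and count-based differential testing with
trajectory clustering. `polpause` implements this pipeline end to end,
together with a synthetic-data generator whose ground truth is known in
closed form, so every stage is testable without any external download.

## The central statistic

For a gene with transcription start site (TSS) and end site (TES), the
**pausing index** is

    PI = mean sense Pol II density in the promoter window (TSS ± 200 bp)
         ------------------------------------------------------------
         mean sense Pol II density in the gene body (TSS+200 … TES−200)

where density is the per-base count of read 5' ends (the polymerase
position in tNET-seq), RPM-scaled per sample. PI is invariant under any
positive rescaling of a track, so normalization cannot change it. A
narrow variant uses the canonical pause zone TSS +20..+100 bp as the
numerator window. Genes are analyzed only if they are protein coding,
longer than 2 kb, isolated within 2.5 kb, covered at RPKM > 1, and have
PI ≤ 10 in all samples.

Enhancers are identified as H3K27ac consensus peaks that (i) do not
overlap H3K4me3 peaks, (ii) lie outside TSS ± 1 kb, and (iii) overlap
accessible (ATAC) regions. Differential quantities use a lightweight
negative-binomial framework: median-of-ratios size factors, per-region
method-of-moments dispersion, a two-group Wald test and a multi-condition
likelihood-ratio test, with Benjamini–Hochberg control. Trajectories of
differential genes are clustered by divisive (DIANA) clustering on
Kendall distances (1 − τ) between z-scored condition profiles.

## Worked example

A miniature aging cohort (30 genes, three age groups, one track each)
from the packaged generator:

```r
library(polpause)

cfg <- aging_demo_config(seed = 1, n_genes = 30L,
                         n_enhancers = 12L, n_decoy_peaks = 4L)
set.seed(cfg$seed)
genes <- simulate_annotation(cfg)
gs <- select_tnet_genes(genes)
print(gs)
#> gene_set: 30 genes retained of 30
#>   retained: 30

tracks <- list()
for (cond in cfg$conditions) {
  sim <- simulate_tnet_reads(cfg, cond, gs$genes,
                             seed = 100 + match(cond, cfg$conditions))
  aln <- filter_alignments(sim$alignments)
  tracks[[cond]] <- build_density(five_prime_positions(aln),
                                  library_size = count_primary_aligned(aln),
                                  mode = "RPM")
}
pt <- compute_pi_table(tracks, gs,
                       condition = setNames(cfg$conditions, cfg$conditions))
print(pt)
#> pausing_table: 30 genes x 3 samples ( standard window )
#>   median PI by condition:
#>     young: 8.325
#>     middle: 4.527
#>     aged: 2.386

table(classify_pausing(rowMeans(pt$pi[, "young", drop = FALSE])))
#>      low moderate     high
#>        0        0       30
```

The median pausing index falls monotonically across the three age groups
because the generator programs a declining pause weight (0.6, 0.45, 0.3)
— the recovered medians track the closed-form expectations stored in the
generator's truth table. `run_pipeline(aging_demo_config(seed = 1))`
executes the full chain (gene selection → density → pausing → ATAC
integration → enhancers → differential tests → clustering → metagene) and
returns all intermediate tables plus a JSON-serializable summary.

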