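# Synthetic-data generators with known ground truth.
#
# The generators emulate the statistical structure of a tissue nascent
# transcription + accessibility study: stranded single-base Pol II 5'-end
# densities with an elevated promoter-proximal pause zone whose strength
# declines across age groups, unstranded ATAC cut sites enriched at
# promoters and enhancers, replicate peak sets with edge jitter and
# dropout, and negative-binomial count matrices with programmed effects.
#
# Emission model for a gene with pause weight `pi_weight`: each sense
# read's 5' end falls in the pause zone (TSS +20..+100, uniform) with
# probability pi_weight, and otherwise uniformly in the gene-body region
# (TSS +200 to TES -200). The expected pausing index for any promoter
# window then has the closed form implemented by expected_pausing_index(),
# which was checked against a 1e6-read Monte-Carlo before being frozen
# into the tests.

#' Configuration for the synthetic aging scenario
#'
#' Defaults describe the packaged "aging-demo" scenario: 100 genes on two
#' chromosomes, three age groups (young, middle, aged) with three
#' replicates each, 2,000 sense reads per gene and sample, and a pause
#' weight declining with age (0.6, 0.45, 0.3) while promoter accessibility
#' rises (enrichment 1.0, 1.5, 2.0) -- accessibility up, pausing down.
#'
#' @param seed integer run seed; every generator draw derives from it.
#' @param n_genes number of genes.
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param gene_length_range min/max gene span in bp (> 2 kb so all genes
#'   pass the length filter).
#' @param spacing_range min/max intergenic gap in bp (> 5 kb so all genes
#'   pass the isolation filter).
#' @param conditions character vector of condition names.
#' @param n_replicates replicates per condition.
#' @param reads_per_gene mean sense reads per gene per sample.
#' @param pause_weight named per-condition probability that a read derives
#'   from the pause zone.
#' @param pause_zone `"narrow"` (TSS +20..+100) -- the zone where paused
#'   polymerase sits; kept distinct from the wider standard PI window so
#'   window/zone mismatch is exercised.
#' @param antisense_fraction antisense reads as a fraction of sense reads.
#' @param noise_rate intergenic noise reads as a fraction of sense reads.
#' @param read_length read length in bp.
#' @param n_enhancers number of true enhancers.
#' @param enhancer_width enhancer width in bp.
#' @param n_decoy_peaks H3K27ac decoy peaks without ATAC support.
#' @param atac_fragments ATAC fragments per sample.
#' @param promoter_enrichment named per-condition accessibility enrichment
#'   factor at promoters relative to background.
#' @param enhancer_enrichment accessibility enrichment factor at enhancers.
#' @param peak_jitter_sd standard deviation (bp) of peak edge jitter.
#' @param peak_dropout per-replicate probability that a true peak is
#'   missed.
#' @param nb_regions,nb_mean,nb_dispersion,nb_effect_fraction,nb_log2fc
#'   negative-binomial count-matrix parameters (regions, mean, dispersion,
#'   fraction of regions with a programmed effect, effect magnitude).
#' @return a validated list of class `synthetic_config`.
#' @export
aging_demo_config <- function(seed = 1L,
                              n_genes = 100L,
                              n_chroms = 2L,
                              chrom_length = 1000000L,
                              gene_length_range = c(2400L, 3000L),
                              spacing_range = c(5500L, 8000L),
                              conditions = c("young", "middle", "aged"),
                              n_replicates = 3L,
                              reads_per_gene = 2000,
                              pause_weight = c(young = 0.6, middle = 0.45,
                                               aged = 0.3),
                              pause_zone = "narrow",
                              antisense_fraction = 0.05,
                              noise_rate = 0.05,
                              read_length = 50L,
                              n_enhancers = 30L,
                              enhancer_width = 400L,
                              n_decoy_peaks = 10L,
                              atac_fragments = 50000L,
                              promoter_enrichment = c(young = 1.0,
                                                      middle = 1.5,
                                                      aged = 2.0),
                              enhancer_enrichment = 3.0,
                              peak_jitter_sd = 20,
                              peak_dropout = 0.1,
                              nb_regions = 2000L,
                              nb_mean = 100,
                              nb_dispersion = 0.05,
                              nb_effect_fraction = 0.1,
                              nb_log2fc = 1.0) {
  cfg <- list(seed = as.integer(seed), n_genes = n_genes,
              n_chroms = n_chroms, chrom_length = chrom_length,
              gene_length_range = gene_length_range,
              spacing_range = spacing_range, conditions = conditions,
              n_replicates = n_replicates, reads_per_gene = reads_per_gene,
              pause_weight = pause_weight, pause_zone = pause_zone,
              antisense_fraction = antisense_fraction,
              noise_rate = noise_rate, read_length = read_length,
              n_enhancers = n_enhancers, enhancer_width = enhancer_width,
              n_decoy_peaks = n_decoy_peaks,
              atac_fragments = atac_fragments,
              promoter_enrichment = promoter_enrichment,
              enhancer_enrichment = enhancer_enrichment,
              peak_jitter_sd = peak_jitter_sd, peak_dropout = peak_dropout,
              nb_regions = nb_regions, nb_mean = nb_mean,
              nb_dispersion = nb_dispersion,
              nb_effect_fraction = nb_effect_fraction,
              nb_log2fc = nb_log2fc)
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' Validate a synthetic configuration
#'
#' @param cfg a configuration list.
#' @return invisibly `TRUE`; errors name the offending key.
#' @export
validate_config <- function(cfg) {
  known <- c("seed", "n_genes", "n_chroms", "chrom_length",
             "gene_length_range", "spacing_range", "conditions",
             "n_replicates", "reads_per_gene", "pause_weight", "pause_zone",
             "antisense_fraction", "noise_rate", "read_length",
             "n_enhancers", "enhancer_width", "n_decoy_peaks",
             "atac_fragments", "promoter_enrichment",
             "enhancer_enrichment", "peak_jitter_sd", "peak_dropout",
             "nb_regions", "nb_mean", "nb_dispersion",
             "nb_effect_fraction", "nb_log2fc")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) stop("unknown config key(s): ",
                          paste(extra, collapse = ", "))
  missing <- setdiff(known, names(cfg))
  if (length(missing)) stop("missing config key(s): ",
                            paste(missing, collapse = ", "))
  probs <- c(cfg$pause_weight, cfg$antisense_fraction, cfg$noise_rate,
             cfg$peak_dropout, cfg$nb_effect_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  if (min(cfg$gene_length_range) <= 2000) {
    stop("gene_length_range must exceed 2000 bp")
  }
  if (min(cfg$spacing_range) <= 5000) {
    stop("spacing_range must exceed 5000 bp")
  }
  if (!all(cfg$conditions %in% names(cfg$pause_weight)) ||
      !all(cfg$conditions %in% names(cfg$promoter_enrichment))) {
    stop("pause_weight/promoter_enrichment must cover all conditions")
  }
  invisible(TRUE)
}

#' Simulate a gene annotation
#'
#' Places genes with alternating strands along the configured chromosomes,
#' separated by intergenic gaps large enough that every gene passes the
#' length and isolation filters by construction. Each gene has one coding
#' transcript whose CDS is inset 100 bp from each end (so a 5' UTR
#' exists), one exon spanning the transcript.
#'
#' @param cfg a `synthetic_config`.
#' @param gtf_path optional path; when given, a valid Ensembl-dialect GTF
#'   and a `<path>.chrom.sizes` file are written.
#' @return gene table in [load_annotation()] layout, with `chrom_sizes`
#'   attribute.
#' @export
simulate_annotation <- function(cfg, gtf_path = NULL) {
  genes <- list()
  gid <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    chrom <- paste0("chr", ci)
    pos <- 0L
    repeat {
      gap <- sample(cfg$spacing_range[1]:cfg$spacing_range[2], 1)
      len <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], 1)
      start <- pos + gap
      end <- start + len
      if (end + cfg$spacing_range[1] > cfg$chrom_length ||
          gid >= cfg$n_genes) break
      gid <- gid + 1L
      strand <- if (gid %% 2 == 1) "+" else "-"
      # TSS/TES anchored at the ORF (CDS inset 100 bp from the transcript
      # ends), matching the annotation loader's convention
      cds_start <- start + 100L
      cds_end <- end - 100L
      genes[[gid]] <- data.frame(
        gene_id = sprintf("gene%03d", gid), chrom = chrom,
        strand = strand,
        tss = if (strand == "+") cds_start else cds_end,
        tes = if (strand == "+") cds_end else cds_start,
        start = cds_start, end = cds_end, biotype = "protein_coding",
        canonical_transcript_id = sprintf("tx%03d", gid),
        cds_start = cds_start, cds_end = cds_end,
        tx_start = start, tx_end = end,
        stringsAsFactors = FALSE)
      pos <- end
    }
    if (gid >= cfg$n_genes) break
  }
  if (gid < cfg$n_genes) stop("genes do not fit on the chromosomes")
  out <- do.call(rbind, genes)
  exons <- data.frame(gene_id = out$gene_id, chrom = out$chrom,
                      start = out$tx_start, end = out$tx_end,
                      strand = out$strand, stringsAsFactors = FALSE)
  attr(out, "exons") <- exons
  sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms),
                           paste0("chr", seq_len(cfg$n_chroms)))
  attr(out, "chrom_sizes") <- sizes
  if (!is.null(gtf_path)) {
    .write_gtf(out, gtf_path)
    utils::write.table(
      data.frame(names(sizes), unname(sizes)),
      paste0(gtf_path, ".chrom.sizes"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
  }
  out
}

# Ensembl-dialect GTF writer (1-based closed coordinates).
.write_gtf <- function(genes, path) {
  attrs <- function(g, tx = FALSE) {
    a <- sprintf('gene_id "%s"; gene_biotype "%s";', g$gene_id, g$biotype)
    if (tx) {
      a <- sprintf('%s transcript_id "%s"; transcript_biotype "%s";',
                   a, g$canonical_transcript_id, g$biotype)
    }
    a
  }
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    row <- function(type, s, e, tx) {
      sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, type, s + 1L, e, g$strand, attrs(g, tx))
    }
    tx_start <- if ("tx_start" %in% names(g)) g$tx_start else g$start
    tx_end <- if ("tx_end" %in% names(g)) g$tx_end else g$end
    lines <- c(lines,
               row("gene", tx_start, tx_end, FALSE),
               row("transcript", tx_start, tx_end, TRUE),
               row("exon", tx_start, tx_end, TRUE),
               row("CDS", g$cds_start, g$cds_end, TRUE))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Closed-form expected pausing index of the emission model
#'
#' For a gene whose sense 5' ends fall in the pause zone with probability
#' `pi_weight` (uniform within the zone) and otherwise uniformly in the
#' gene-body region, the expected PI for a promoter window W is
#' `(pi_weight * zfrac * Lb / (1 - pi_weight) + o) / Lw`, with `Lw` the
#' window length, `Lb` the body length, `zfrac` the fraction of the pause
#' zone inside W and `o` the overlap (bp) between W and the body region.
#'
#' @param pi_weight pause-zone emission probability (< 1).
#' @param genes gene table row(s).
#' @param window `"standard"` or `"narrow"`.
#' @return numeric expected PI per gene.
#' @export
expected_pausing_index <- function(pi_weight, genes,
                                   window = c("standard", "narrow")) {
  window <- match.arg(window)
  stopifnot(pi_weight < 1)
  w <- if (window == "standard") promoter_window(genes) else
    narrow_pause_window(genes)
  zone <- narrow_pause_window(genes)
  body <- gene_body_region(genes)
  ov <- function(a, b) {
    pmax(0, pmin(a$end, b$end) - pmax(a$start, b$start))
  }
  lw <- w$end - w$start
  lb <- body$end - body$start
  zfrac <- ov(w, zone) / (zone$end - zone$start)
  o <- ov(w, body)
  (pi_weight * zfrac * lb / (1 - pi_weight) + o) / lw
}

#' Simulate stranded nascent-transcription (tNET-seq) reads
#'
#' Per gene, `N ~ Poisson(reads_per_gene)` sense reads whose 5' ends follow
#' the pause/body emission mixture for the condition's pause weight;
#' antisense reads (uniform over the gene span, opposite strand) and
#' intergenic noise reads are added at the configured rates.
#'
#' @param cfg a `synthetic_config`.
#' @param condition condition name (selects the pause weight).
#' @param genes gene table from [simulate_annotation()].
#' @param seed optional seed for this sample's substream.
#' @return list with `alignments` (alignment data.frame) and `truth`
#'   (per-gene data.frame with the condition's pause weight and
#'   closed-form expected PI for both window variants).
#' @export
simulate_tnet_reads <- function(cfg, condition, genes, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pw <- cfg$pause_weight[[condition]]
  zone <- narrow_pause_window(genes)
  body <- gene_body_region(genes)
  rl <- cfg$read_length
  chrom <- character(0); p5 <- integer(0); strand <- character(0)
  for (i in seq_len(nrow(genes))) {
    n <- stats::rpois(1, cfg$reads_per_gene)
    paused <- stats::runif(n) < pw
    pos <- integer(n)
    nz <- sum(paused)
    pos[paused] <- sample(zone$start[i]:(zone$end[i] - 1L), nz,
                          replace = TRUE)
    pos[!paused] <- sample(body$start[i]:(body$end[i] - 1L), n - nz,
                           replace = TRUE)
    n_anti <- stats::rpois(1, cfg$reads_per_gene * cfg$antisense_fraction)
    anti_pos <- sample(genes$start[i]:(genes$end[i] - 1L), n_anti,
                       replace = TRUE)
    chrom <- c(chrom, rep(genes$chrom[i], n + n_anti))
    p5 <- c(p5, pos, anti_pos)
    strand <- c(strand, rep(genes$strand[i], n),
                rep(if (genes$strand[i] == "+") "-" else "+", n_anti))
  }
  n_noise <- stats::rpois(1, cfg$n_genes * cfg$reads_per_gene *
                            cfg$noise_rate)
  noise_chrom <- sprintf("chr%d", sample.int(cfg$n_chroms, n_noise,
                                             replace = TRUE))
  noise_pos <- sample.int(cfg$chrom_length - rl, n_noise,
                          replace = TRUE) - 1L
  noise_strand <- sample(c("+", "-"), n_noise, replace = TRUE)
  chrom <- c(chrom, noise_chrom)
  p5 <- c(p5, noise_pos)
  strand <- c(strand, noise_strand)
  plus <- strand == "+"
  start <- ifelse(plus, p5, pmax(p5 - rl + 1L, 0L))
  end <- ifelse(plus, pmin(p5 + rl, cfg$chrom_length), p5 + 1L)
  aln <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end),
                    name = sprintf("read%06d", seq_along(p5)),
                    mapq = 60L, strand = strand, stringsAsFactors = FALSE)
  truth <- data.frame(
    gene_id = genes$gene_id, pause_weight = pw,
    expected_pi_standard = expected_pausing_index(pw, genes, "standard"),
    expected_pi_narrow = expected_pausing_index(pw, genes, "narrow"),
    stringsAsFactors = FALSE)
  list(alignments = aln, truth = truth)
}

#' Place true enhancers (and decoy peaks) in intergenic gaps
#'
#' Enhancers are centred in intergenic gaps so they sit more than 1 kb
#' from every TSS; decoys occupy other gaps and are marked inactive.
#'
#' @param cfg a `synthetic_config`.
#' @param genes gene table.
#' @return data.frame `chrom`, `start`, `end`, `active` (decoys `FALSE`).
#' @export
simulate_enhancer_truth <- function(cfg, genes) {
  gaps <- list()
  for (chrom in unique(genes$chrom)) {
    g <- genes[genes$chrom == chrom, ]
    g <- g[order(g$start), ]
    if (nrow(g) < 2) next
    gaps[[chrom]] <- data.frame(
      chrom = chrom,
      gap_start = g$end[-nrow(g)], gap_end = g$start[-1])
  }
  gaps <- do.call(rbind, gaps)
  need <- cfg$n_enhancers + cfg$n_decoy_peaks
  if (nrow(gaps) < need) stop("not enough intergenic gaps for enhancers")
  pick <- sample.int(nrow(gaps), need)
  mid <- floor((gaps$gap_start[pick] + gaps$gap_end[pick]) / 2)
  half <- cfg$enhancer_width %/% 2
  data.frame(chrom = gaps$chrom[pick],
             start = as.integer(mid - half),
             end = as.integer(mid + half),
             active = rep(c(TRUE, FALSE),
                          c(cfg$n_enhancers, cfg$n_decoy_peaks)),
             stringsAsFactors = FALSE)
}

#' Simulate paired ATAC-seq fragments
#'
#' Fragments are drawn from a mixture of uniform genomic background,
#' promoter windows (enriched by the condition's factor) and active
#' enhancers; fragment lengths follow a sub-nucleosomal (~60 bp) /
#' mono-nucleosomal (~200 bp) mixture. Each fragment yields two properly
#' paired mates.
#'
#' @param cfg a `synthetic_config`.
#' @param condition condition name (selects the promoter enrichment).
#' @param genes gene table.
#' @param enhancers enhancer truth table from [simulate_enhancer_truth()].
#' @param seed optional substream seed.
#' @return list with `fragments` (data.frame `chrom`, `start`, `end`) and
#'   `alignments` (paired alignment data.frame, two mates per fragment).
#' @export
simulate_atac <- function(cfg, condition, genes, enhancers, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  f_prom <- cfg$promoter_enrichment[[condition]]
  prom <- promoter_window(genes)
  enh <- enhancers[enhancers$active, , drop = FALSE]
  genome_bp <- cfg$n_chroms * cfg$chrom_length
  prom_bp <- sum(prom$end - prom$start)
  enh_bp <- sum(enh$end - enh$start)
  # uniform background over the whole genome plus (f - 1)-weighted excess
  # fragments placed wholly inside enriched regions, so the cut-site
  # density at a region scales as its enrichment factor
  w <- c(background = genome_bp,
         promoter = prom_bp * max(0, f_prom - 1),
         enhancer = enh_bp * max(0, cfg$enhancer_enrichment - 1))
  n <- cfg$atac_fragments
  cat_draw <- sample(names(w), n, replace = TRUE, prob = w / sum(w))
  nuc <- stats::runif(n) < 0.5
  len <- as.integer(ifelse(nuc, pmax(30, round(stats::rnorm(n, 200, 25))),
                           pmax(20, round(stats::rnorm(n, 60, 15)))))
  chrom <- character(n)
  left <- integer(n)
  bg <- cat_draw == "background"
  nbg <- sum(bg)
  chrom[bg] <- sprintf("chr%d", sample.int(cfg$n_chroms, nbg,
                                           replace = TRUE))
  left[bg] <- sample.int(cfg$chrom_length - 400L, nbg,
                         replace = TRUE) - 1L
  place_in <- function(regions, count, lens) {
    idx <- sample.int(nrow(regions), count, replace = TRUE,
                      prob = regions$end - regions$start)
    room <- pmax(1L, regions$end[idx] - regions$start[idx] - lens)
    offs <- floor(stats::runif(count) * room)
    list(chrom = regions$chrom[idx],
         pos = as.integer(regions$start[idx] + offs))
  }
  for (cat in c("promoter", "enhancer")) {
    sel <- cat_draw == cat
    if (!any(sel)) next
    regions <- if (cat == "promoter") prom else enh
    pl <- place_in(regions, sum(sel), len[sel])
    chrom[sel] <- pl$chrom
    left[sel] <- pl$pos
  }
  start <- pmax(0L, as.integer(left))
  end <- pmin(cfg$chrom_length, as.integer(left + len))
  frags <- data.frame(chrom = chrom, start = start, end = end,
                      stringsAsFactors = FALSE)
  rl <- min(cfg$read_length, 36L)
  aln <- data.frame(
    chrom = rep(chrom, 2),
    start = c(start, pmax(end - rl, start)),
    end = c(pmin(start + rl, end), end),
    name = rep(sprintf("frag%06d", seq_len(n)), 2),
    mapq = 60L,
    strand = rep(c("+", "-"), each = n),
    is_proper_pair = TRUE,
    stringsAsFactors = FALSE)
  list(fragments = frags, alignments = aln)
}

#' Simulate replicate peak sets for H3K27ac, H3K4me3 and ATAC
#'
#' True enhancers emit H3K27ac and ATAC peaks; promoters emit H3K27ac,
#' H3K4me3 and ATAC peaks; decoy H3K27ac peaks lack ATAC support. Peak
#' edges are jittered per replicate and whole peaks drop out with the
#' configured probability.
#'
#' @param cfg a `synthetic_config`.
#' @param genes gene table.
#' @param enhancers enhancer truth table.
#' @param n_samples number of replicate peak sets per mark.
#' @param dropout overrides `cfg$peak_dropout` when not `NULL`.
#' @param seed optional substream seed.
#' @return named list with elements `k27ac`, `k4me3`, `atac`, each a named
#'   list of per-replicate peak data.frames.
#' @export
simulate_peak_sets <- function(cfg, genes, enhancers, n_samples = 3,
                               dropout = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dropout)) dropout <- cfg$peak_dropout
  prom <- promoter_window(genes, half_width = 300)
  enh <- enhancers[enhancers$active, , drop = FALSE]
  decoy <- enhancers[!enhancers$active, , drop = FALSE]
  templates <- list(
    k27ac = rbind(prom[, c("chrom", "start", "end")],
                  enh[, c("chrom", "start", "end")],
                  decoy[, c("chrom", "start", "end")]),
    k4me3 = prom[, c("chrom", "start", "end")],
    atac = rbind(prom[, c("chrom", "start", "end")],
                 enh[, c("chrom", "start", "end")]))
  jitter_set <- function(tmpl) {
    keep <- stats::runif(nrow(tmpl)) >= dropout
    out <- tmpl[keep, , drop = FALSE]
    j1 <- round(stats::rnorm(nrow(out), 0, cfg$peak_jitter_sd))
    j2 <- round(stats::rnorm(nrow(out), 0, cfg$peak_jitter_sd))
    out$start <- pmax(0L, as.integer(out$start + j1))
    out$end <- as.integer(out$end + j2)
    bad <- out$end <= out$start
    out$end[bad] <- out$start[bad] + 50L
    rownames(out) <- NULL
    out
  }
  lapply(templates, function(tmpl) {
    reps <- lapply(seq_len(n_samples), function(r) jitter_set(tmpl))
    names(reps) <- paste0("rep", seq_len(n_samples))
    reps
  })
}

#' Simulate a negative-binomial count matrix with programmed effects
#'
#' Two-condition NB counts with per-sample size multipliers and a stated
#' fraction of regions carrying a true log2 fold change (half up, half
#' down).
#'
#' @param cfg a `synthetic_config`.
#' @param n_replicates replicates per condition.
#' @param size_multipliers per-sample library-size multipliers (recycled;
#'   default all 1).
#' @param effect_fraction overrides `cfg$nb_effect_fraction` when not
#'   `NULL`.
#' @param seed optional substream seed.
#' @return list with `counts` (a `count_matrix` with conditions `A`/`B`)
#'   and `truth` (data.frame `region`, `true_log2fc`).
#' @export
simulate_count_matrix <- function(cfg, n_replicates = 3,
                                  size_multipliers = NULL,
                                  effect_fraction = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(effect_fraction)) effect_fraction <- cfg$nb_effect_fraction
  n <- cfg$nb_regions
  n_samp <- 2 * n_replicates
  if (is.null(size_multipliers)) size_multipliers <- rep(1, n_samp)
  size_multipliers <- rep_len(size_multipliers, n_samp)
  n_fx <- round(n * effect_fraction)
  lfc <- numeric(n)
  if (n_fx > 0) {
    lfc[seq_len(n_fx)] <- rep_len(c(cfg$nb_log2fc, -cfg$nb_log2fc), n_fx)
  }
  base_mu <- stats::rlnorm(n, meanlog = log(cfg$nb_mean), sdlog = 0.5)
  condition <- rep(c("A", "B"), each = n_replicates)
  mu <- base_mu %o% rep(1, n_samp)
  mu[, condition == "B"] <- mu[, condition == "B"] * 2^lfc
  mu <- sweep(mu, 2, size_multipliers, "*")
  counts <- base::matrix(
    stats::rnbinom(n * n_samp, mu = as.vector(mu),
                   size = 1 / cfg$nb_dispersion),
    nrow = n,
    dimnames = list(paste0("region_", seq_len(n)),
                    paste0(condition, rep(seq_len(n_replicates), 2))))
  cm <- structure(counts,
                  condition = stats::setNames(condition, colnames(counts)),
                  class = c("count_matrix", class(counts)))
  list(counts = cm,
       truth = data.frame(region = rownames(counts), true_log2fc = lfc,
                          stringsAsFactors = FALSE))
}

#' Write alignments in the 6-column BED dialect
#'
#' @param alignments alignment data.frame.
#' @param path output path.
#' @return invisible path.
#' @export
write_alignments_bed <- function(alignments, path) {
  utils::write.table(
    alignments[, c("chrom", "start", "end", "name", "mapq", "strand")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write alignments as a BAM file
#'
#' Emits a SAM text rendering (single-end; 50M-style CIGARs) and converts
#' it with Rsamtools so both pipeline readers can be exercised on the same
#' simulated sample.
#'
#' @param alignments alignment data.frame.
#' @param chrom_sizes named vector of chromosome lengths.
#' @param path output path (`.bam` appended if missing).
#' @return path to the BAM file.
#' @export
write_alignments_bam <- function(alignments, chrom_sizes, path) {
  sam <- sub("\\.bam$", ".sam", path)
  if (identical(sam, path)) path <- paste0(path, ".bam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_sizes),
                   as.integer(chrom_sizes)))
  w <- alignments$end - alignments$start
  flag <- ifelse(alignments$strand == "-", 16L, 0L)
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t*\t*",
                  alignments$name, flag, alignments$chrom,
                  alignments$start + 1L, alignments$mapq, w)
  writeLines(c(hdr, body), sam)
  out <- Rsamtools::asBam(sam, destination = sub("\\.bam$", "", path),
                          overwrite = TRUE, indexDestination = FALSE)
  unlink(sam)
  out
}
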