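# Consensus peaks, enhancer identification and region annotation.
#
# All overlap semantics: ">= 1 bp overlap" counts as overlap, "do not
# overlap" means zero shared bp, matching standard interval-tool defaults.

#' Build a consensus peak set from replicate peak sets
#'
#' Merges the union of all peaks into maximal non-overlapping regions and
#' keeps a region if at least `min_support` distinct samples contribute at
#' least 1 bp of overlap to it.
#'
#' @param peak_sets named list of peak data.frames (`chrom`, `start`,
#'   `end`), one per sample.
#' @param min_support minimum number of supporting samples.
#' @param blacklist optional data.frame of intervals subtracted from the
#'   merged regions before support counting (e.g. ENCODE blacklist).
#' @return object of class `consensus_peaks`: data.frame with `chrom`,
#'   `start`, `end`, `support`, plus attribute `min_support`.
#' @export
consensus_peaks <- function(peak_sets, min_support, blacklist = NULL) {
  if (min_support > length(peak_sets)) {
    stop("min_support exceeds the number of peak sets")
  }
  grl <- lapply(peak_sets, .df_to_gr)
  merged <- GenomicRanges::reduce(do.call(c, unname(grl)),
                                  ignore.strand = TRUE)
  if (!is.null(blacklist)) {
    merged <- GenomicRanges::setdiff(merged, .df_to_gr(blacklist),
                                     ignore.strand = TRUE)
  }
  support <- Reduce(`+`, lapply(grl, function(g) {
    as.integer(GenomicRanges::countOverlaps(merged, g,
                                            ignore.strand = TRUE) > 0)
  }))
  keep <- support >= min_support
  out <- .gr_to_df(merged[keep])
  out$strand <- NULL
  out$support <- support[keep]
  structure(out, class = c("consensus_peaks", "data.frame"),
            min_support = min_support)
}

#' Identify active enhancers from histone-mark and accessibility peaks
#'
#' Enhancers are H3K27ac consensus regions that (i) do not overlap any
#' H3K4me3 consensus region, (ii) do not fall within the TSS exclusion zone
#' (TSS +/- `tss_exclusion` bp) of any gene, and (iii) overlap at least one
#' accessible (ATAC) consensus region. All three rules are conjunctive; the
#' rule trail records each predicate per candidate.
#'
#' @param k27ac H3K27ac `consensus_peaks` (or interval data.frame).
#' @param k4me3 H3K4me3 `consensus_peaks`.
#' @param atac ATAC `consensus_peaks`.
#' @param genes gene table providing TSS positions.
#' @param tss_exclusion half-width of the TSS exclusion zone in bp.
#' @return object of class `enhancer_set`: data.frame of enhancer intervals
#'   with attribute `rule_trail`, a logical data.frame over all candidates
#'   (`no_k4me3_overlap`, `outside_tss_zone`, `atac_overlap`).
#' @export
identify_enhancers <- function(k27ac, k4me3, atac, genes,
                               tss_exclusion = 1000) {
  if (nrow(k27ac) == 0) {
    out <- k27ac[, c("chrom", "start", "end")]
    attr(out, "rule_trail") <- data.frame(no_k4me3_overlap = logical(0),
                                          outside_tss_zone = logical(0),
                                          atac_overlap = logical(0))
    class(out) <- c("enhancer_set", "data.frame")
    return(out)
  }
  cand <- .df_to_gr(k27ac)
  tss_zone <- .df_to_gr(promoter_window(genes, half_width = tss_exclusion))
  trail <- data.frame(
    no_k4me3_overlap = GenomicRanges::countOverlaps(
      cand, .df_to_gr(k4me3), ignore.strand = TRUE) == 0,
    outside_tss_zone = GenomicRanges::countOverlaps(
      cand, tss_zone, ignore.strand = TRUE) == 0,
    atac_overlap = GenomicRanges::countOverlaps(
      cand, .df_to_gr(atac), ignore.strand = TRUE) > 0)
  keep <- trail$no_k4me3_overlap & trail$outside_tss_zone & trail$atac_overlap
  out <- k27ac[keep, c("chrom", "start", "end")]
  rownames(out) <- NULL
  attr(out, "rule_trail") <- trail
  class(out) <- c("enhancer_set", "data.frame")
  out
}

#' Annotate regions by genomic feature
#'
#' Labels each region by the feature containing its midpoint, with fixed
#' precedence promoter (TSS +/- `promoter_half_width`) > 5' UTR > exon >
#' intron > distal intergenic. The 5' UTR is the canonical-transcript
#' stretch between the TSS and the CDS 5' boundary.
#'
#' @param regions interval data.frame.
#' @param genes gene table from [load_annotation()] (with exon attribute).
#' @param promoter_half_width promoter window half-width in bp.
#' @param precedence character vector ordering the labels by priority.
#' @return character vector of feature labels, one per region.
#' @export
annotate_regions <- function(regions, genes, promoter_half_width = 200,
                             precedence = c("promoter", "five_prime_utr",
                                            "exon", "intron", "distal")) {
  .assert_interval_df(regions)
  mid <- floor((regions$start + regions$end) / 2)
  mid_gr <- .df_to_gr(data.frame(chrom = regions$chrom, start = mid,
                                 end = mid + 1L))
  prom_gr <- .df_to_gr(promoter_window(genes,
                                       half_width = promoter_half_width))
  # 5' UTR: from TSS to the CDS 5' boundary, strand-aware
  has_cds <- !is.na(genes$cds_start)
  g <- genes[has_cds, , drop = FALSE]
  utr_start <- ifelse(g$strand == "+", g$tss, g$cds_end)
  utr_end <- ifelse(g$strand == "+", g$cds_start, g$tss)
  utr_ok <- utr_start < utr_end
  utr_gr <- .df_to_gr(data.frame(chrom = g$chrom[utr_ok],
                                 start = utr_start[utr_ok],
                                 end = utr_end[utr_ok]))
  ex <- attr(genes, "exons")
  exon_gr <- if (!is.null(ex) && nrow(ex)) .df_to_gr(ex) else
    GenomicRanges::GRanges()
  span_gr <- .df_to_gr(data.frame(chrom = genes$chrom, start = genes$start,
                                  end = genes$end))
  in_feature <- list(
    promoter = GenomicRanges::countOverlaps(mid_gr, prom_gr,
                                            ignore.strand = TRUE) > 0,
    five_prime_utr = GenomicRanges::countOverlaps(mid_gr, utr_gr,
                                                  ignore.strand = TRUE) > 0,
    exon = GenomicRanges::countOverlaps(mid_gr, exon_gr,
                                        ignore.strand = TRUE) > 0,
    intron = GenomicRanges::countOverlaps(mid_gr, span_gr,
                                          ignore.strand = TRUE) > 0,
    distal = rep(TRUE, nrow(regions)))
  labels <- rep(NA_character_, nrow(regions))
  for (feat in precedence) {
    hit <- is.na(labels) & in_feature[[feat]]
    labels[hit] <- feat
  }
  labels
}

#' Count and fraction of query regions overlapping a target set
#'
#' @param query interval data.frame.
#' @param target interval data.frame.
#' @return list with `count` (query regions with >= 1 bp overlap with any
#'   target region) and `fraction` (`count / nrow(query)`).
#' @export
overlap_fraction <- function(query, target) {
  if (nrow(query) == 0) stop("overlap fraction undefined for empty query")
  hits <- GenomicRanges::countOverlaps(.df_to_gr(query), .df_to_gr(target),
                                       ignore.strand = TRUE)
  count <- sum(hits > 0)
  list(count = count, fraction = count / nrow(query))
}

#' Mean Pol II density at enhancers (eRNA level)
#'
#' Enhancers transcribe short unstable eRNAs; mean nascent Pol II density
#' over an enhancer region (both strands) proxies its activity.
#'
#' @param track an RPM-scaled `density_track`.
#' @param enhancers an `enhancer_set` (or interval data.frame).
#' @return numeric vector of mean densities, one per enhancer.
#' @export
erna_level <- function(track, enhancers) {
  if (nrow(enhancers) == 0) return(numeric(0))
  region_mean_density(track, as.data.frame(enhancers), strand_mode = "both")
}

#' Write a consensus or enhancer set as BED
#'
#' @param x a `consensus_peaks` or `enhancer_set`.
#' @param path output path.
#' @return invisible path.
#' @export
write_peakset_bed <- function(x, path) {
  df <- as.data.frame(x)
  df$name <- if (inherits(x, "consensus_peaks")) {
    paste0("support_", df$support)
  } else {
    "enhancer"
  }
  write_bed(df, path)
}
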