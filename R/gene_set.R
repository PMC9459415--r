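#' Select the analyzable gene set for nascent-transcription analysis
#'
#' Retains protein-coding genes that are long enough and isolated enough
#' that promoter-proximal and gene-body signal cannot be contaminated by a
#' neighbouring transcription unit: the gene span (TSS..TES of the canonical
#' ORF) must be strictly longer than `min_length`, and the envelope
#' `isolation` bp upstream of the TSS and downstream of the TES must not
#' overlap any other annotated gene's span. The isolation test uses other
#' genes' spans, not their envelopes, so the buffer is not double counted.
#'
#' @param genes gene table from [load_annotation()] (all annotated genes;
#'   non-protein-coding genes are used as isolation obstacles but never
#'   retained).
#' @param min_length minimum gene span in bp (strict inequality).
#' @param isolation envelope half-width in bp added upstream of the TSS and
#'   downstream of the TES.
#' @return an object of class `gene_set`: a list with `genes` (the retained
#'   subset of the input table) and `selection_log` (one row per input gene
#'   with the first filter that removed it, or `"retained"`).
#' @export
select_tnet_genes <- function(genes, min_length = 2000, isolation = 2500) {
  log <- data.frame(gene_id = genes$gene_id, status = "retained",
                    stringsAsFactors = FALSE)
  if (nrow(genes) == 0) {
    return(structure(list(genes = genes, selection_log = log),
                     class = "gene_set"))
  }
  span <- abs(genes$tes - genes$tss)

  fail_biotype <- !is.na(genes$biotype) & genes$biotype != "protein_coding"
  fail_length <- !fail_biotype & span <= min_length

  # isolation: envelope vs every *other* gene's span
  env <- data.frame(chrom = genes$chrom,
                    start = pmin(genes$tss, genes$tes) - isolation,
                    end = pmax(genes$tss, genes$tes) + isolation)
  env$start <- pmax(env$start, 0L)
  env_gr <- .df_to_gr(env)
  span_gr <- .df_to_gr(data.frame(chrom = genes$chrom,
                                  start = pmin(genes$tss, genes$tes),
                                  end = pmax(genes$tss, genes$tes)))
  hits <- GenomicRanges::countOverlaps(env_gr, span_gr,
                                       ignore.strand = TRUE)
  fail_iso <- !fail_biotype & !fail_length & hits > 1  # self always overlaps

  log$status[fail_biotype] <- "biotype"
  log$status[fail_length] <- "length"
  log$status[fail_iso] <- "isolation"

  keep <- log$status == "retained"
  kept <- genes[keep, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "exons") <- attr(genes, "exons")
  structure(list(genes = kept, selection_log = log), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  tab <- table(x$selection_log$status)
  cat("gene_set:", nrow(x$genes), "genes retained of",
      nrow(x$selection_log), "\n")
  for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
  invisible(x)
}

#' Filter a gene set by sequencing coverage (RPKM)
#'
#' Retains genes whose sense-strand 5'-end read density over the full gene
#' span exceeds `rpkm_min` reads per kilobase per million library reads.
#'
#' @param gene_set a `gene_set` from [select_tnet_genes()].
#' @param track an unscaled (raw-count) [build_density()] track.
#' @param rpkm_min RPKM threshold (strict inequality).
#' @param length_mode `"span"` (default) uses TSS..TES length; `"exonic"`
#'   uses the summed exon length of the canonical transcript.
#' @return a `gene_set` with low-coverage genes removed and logged.
#' @export
coverage_filter <- function(gene_set, track, rpkm_min = 1.0,
                            length_mode = c("span", "exonic")) {
  length_mode <- match.arg(length_mode)
  stopifnot(inherits(gene_set, "gene_set"))
  if (is.null(track$library_size) || track$library_size <= 0) {
    stop("track has zero or unknown library size")
  }
  genes <- gene_set$genes
  if (nrow(genes) == 0) return(gene_set)
  spans <- data.frame(chrom = genes$chrom,
                      start = pmin(genes$tss, genes$tes),
                      end = pmax(genes$tss, genes$tes),
                      strand = genes$strand)
  counts <- .region_sums(track, spans, strand_mode = "sense")
  len <- if (length_mode == "span") {
    spans$end - spans$start
  } else {
    ex <- attr(genes, "exons")
    vapply(genes$gene_id, function(g) {
      e <- ex[ex$gene_id == g, , drop = FALSE]
      sum(e$end - e$start)
    }, numeric(1))
  }
  vals <- rpkm(counts, len, track$library_size)
  keep <- vals > rpkm_min
  log <- gene_set$selection_log
  dropped <- genes$gene_id[!keep]
  log$status[log$gene_id %in% dropped] <- "coverage"
  kept <- genes[keep, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "exons") <- attr(genes, "exons")
  structure(list(genes = kept, selection_log = log), class = "gene_set")
}

#' Promoter-proximal window around the TSS
#'
#' The window covers `half_width` bp on each side of the TSS base plus the
#' TSS base itself (401 bp for the default 200), oriented so that it is
#' centred on the 5'-most base of the canonical ORF on either strand.
#' With `half_width = 1000` the same construction yields the TSS exclusion
#' zone used for enhancer identification.
#'
#' @param genes gene table (or `gene_set$genes`).
#' @param half_width window half-width in bp.
#' @return data.frame of intervals (`chrom`, `start`, `end`, `strand`,
#'   `gene_id`), 0-based half-open; windows running past the chromosome
#'   start are clipped at 0.
#' @export
promoter_window <- function(genes, half_width = 200) {
  stopifnot(half_width >= 1)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - half_width, genes$tss - half_width - 1L)
  end <- ifelse(plus, genes$tss + half_width + 1L, genes$tss + half_width)
  clipped <- start < 0
  if (any(clipped)) {
    message(sum(clipped), " promoter window(s) clipped at chromosome start")
    start[clipped] <- 0L
  }
  data.frame(chrom = genes$chrom, start = as.integer(start),
             end = as.integer(end), strand = genes$strand,
             gene_id = genes$gene_id, stringsAsFactors = FALSE)
}

#' Gene-body region
#'
#' Strand-oriented interval from `trim` bp downstream of the TSS to `trim`
#' bp upstream of the TES.
#'
#' @param genes gene table.
#' @param trim bp trimmed from each end of the gene span.
#' @return data.frame of intervals with `gene_id`.
#' @export
gene_body_region <- function(genes, trim = 200) {
  span <- abs(genes$tes - genes$tss)
  if (any(span <= 2 * trim)) {
    stop("gene span must exceed 2*trim for a gene-body region")
  }
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss + trim, genes$tes + trim)
  end <- ifelse(plus, genes$tes - trim, genes$tss - trim)
  data.frame(chrom = genes$chrom, start = as.integer(start),
             end = as.integer(end), strand = genes$strand,
             gene_id = genes$gene_id, stringsAsFactors = FALSE)
}

#' Narrow promoter-proximal pause window (TSS +20 to TSS +100)
#'
#' The 80-bp half-open window starting 20 bp downstream of the TSS, i.e.
#' where promoter-proximally paused polymerase typically sits.
#'
#' @param genes gene table.
#' @return data.frame of intervals with `gene_id`.
#' @export
narrow_pause_window <- function(genes) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss + 20L, genes$tss - 100L)
  end <- ifelse(plus, genes$tss + 100L, genes$tss - 20L)
  data.frame(chrom = genes$chrom, start = as.integer(start),
             end = as.integer(end), strand = genes$strand,
             gene_id = genes$gene_id, stringsAsFactors = FALSE)
}

#' Distance from region midpoints to the nearest TSS
#'
#' For each region, the absolute distance (bp) from the region midpoint to
#' the closest TSS over all genes; 0 if any TSS lies inside the region.
#'
#' @param regions data.frame of intervals.
#' @param genes gene table (at least one gene).
#' @return numeric vector, one distance per region.
#' @export
nearest_tss_distance <- function(regions, genes) {
  .assert_interval_df(regions)
  if (nrow(genes) == 0) stop("need at least one gene")
  tss <- sort(genes$tss)
  mid <- floor((regions$start + regions$end) / 2)
  same_chrom <- outer(regions$chrom, genes$chrom, "==")
  vapply(seq_len(nrow(regions)), function(i) {
    t_i <- genes$tss[same_chrom[i, ]]
    if (!length(t_i)) return(Inf)
    inside <- t_i >= regions$start[i] & t_i < regions$end[i]
    if (any(inside)) return(0)
    min(abs(mid[i] - t_i))
  }, numeric(1))
}
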