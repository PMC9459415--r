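#' Load gene models from a GTF annotation
#'
#' Parses an Ensembl-dialect GTF and returns one gene model per gene,
#' choosing the canonical transcript as the one with the longest coding
#' sequence if the gene has any translated transcript, or the longest cDNA
#' otherwise. Ties are broken by the lexicographically smallest transcript
#' id so the choice is deterministic. GTF coordinates (1-based closed) are
#' converted to the package-internal 0-based half-open convention.
#'
#' The returned table stores, per gene, the strand-aware TSS and TES of the
#' canonical open reading frame: `tss` is the 5' boundary coordinate and
#' `tes` the 3' boundary, so that for a plus-strand gene `tss < tes` and for
#' a minus-strand gene `tss > tes`. All downstream windows (promoter, gene
#' body, pause zone) are derived from these two anchors.
#'
#' @param path path to a GTF file with gene/transcript/exon/CDS features and
#'   `gene_id`, `transcript_id`, `gene_biotype` attributes.
#' @param biotype_filter optional character vector; only genes whose
#'   `gene_biotype` is in this set are returned (`NULL` keeps all).
#' @return a `data.frame` with one row per gene (columns `gene_id`, `chrom`,
#'   `strand`, `tss`, `tes`, `start`, `end`, `biotype`,
#'   `canonical_transcript_id`, `cds_start`, `cds_end`) carrying the exon
#'   table of the canonical transcripts as attribute `"exons"` and ids of
#'   transcript-less genes as attribute `"skipped"`.
#' @export
load_annotation <- function(path, biotype_filter = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  .validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  df <- data.frame(
    type       = as.character(md$type),
    chrom      = as.character(GenomicRanges::seqnames(gr)),
    start      = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end        = GenomicRanges::end(gr),
    strand     = as.character(GenomicRanges::strand(gr)),
    gene_id    = as.character(md$gene_id),
    transcript_id = if ("transcript_id" %in% names(md)) as.character(md$transcript_id) else NA_character_,
    biotype    = if ("gene_biotype" %in% names(md)) as.character(md$gene_biotype) else NA_character_,
    stringsAsFactors = FALSE
  )

  tx <- df[df$type == "transcript" & !is.na(df$transcript_id), ]
  exons <- df[df$type == "exon", ]
  cds <- df[df$type == "CDS", ]

  gene_rows <- df[df$type == "gene", ]
  if (nrow(gene_rows) == 0) {  # tolerate GTFs without explicit gene features
    gene_rows <- unique(tx[, c("chrom", "strand", "gene_id", "biotype")])
    sp <- vapply(split(tx$start, tx$gene_id)[gene_rows$gene_id], min, 0L)
    ep <- vapply(split(tx$end, tx$gene_id)[gene_rows$gene_id], max, 0L)
    gene_rows$start <- sp
    gene_rows$end <- ep
  }

  skipped <- setdiff(gene_rows$gene_id, tx$gene_id)
  if (length(skipped)) {
    message(length(skipped), " gene(s) without transcripts skipped")
  }
  gene_rows <- gene_rows[gene_rows$gene_id %in% tx$gene_id, ]
  if (!is.null(biotype_filter)) {
    gene_rows <- gene_rows[gene_rows$biotype %in% biotype_filter, ]
  }

  cds_len <- tapply(cds$end - cds$start, cds$transcript_id, sum)
  exon_len <- tapply(exons$end - exons$start, exons$transcript_id, sum)

  pick_canonical <- function(tids) {
    cl <- cds_len[tids]
    cl[is.na(cl)] <- 0
    if (any(cl > 0)) {
      len <- cl
    } else {
      len <- exon_len[tids]
      len[is.na(len)] <- 0
    }
    # longest; ties -> lexicographically smallest transcript id
    cand <- tids[len == max(len)]
    sort(cand)[1]
  }

  tids_by_gene <- split(tx$transcript_id, tx$gene_id)
  out <- gene_rows[, c("gene_id", "chrom", "strand", "biotype")]
  out$canonical_transcript_id <- vapply(
    tids_by_gene[out$gene_id], pick_canonical, character(1)
  )

  # ORF-anchored TSS/TES: CDS span of the canonical transcript when coding,
  # otherwise the transcript span.
  tx_idx <- match(out$canonical_transcript_id, tx$transcript_id)
  span_start <- tx$start[tx_idx]
  span_end <- tx$end[tx_idx]
  cds_start_by_tx <- tapply(cds$start, cds$transcript_id, min)
  cds_end_by_tx <- tapply(cds$end, cds$transcript_id, max)
  cs <- cds_start_by_tx[out$canonical_transcript_id]
  ce <- cds_end_by_tx[out$canonical_transcript_id]
  anchor_start <- ifelse(is.na(cs), span_start, cs)
  anchor_end <- ifelse(is.na(ce), span_end, ce)

  out$tss <- ifelse(out$strand == "+", anchor_start, anchor_end)
  out$tes <- ifelse(out$strand == "+", anchor_end, anchor_start)
  out$start <- pmin(out$tss, out$tes)
  out$end <- pmax(out$tss, out$tes)
  out$cds_start <- unname(cs)
  out$cds_end <- unname(ce)
  rownames(out) <- NULL

  keep_ex <- exons$transcript_id %in% out$canonical_transcript_id
  ex <- exons[keep_ex, c("gene_id", "chrom", "start", "end", "strand")]
  rownames(ex) <- NULL
  attr(out, "exons") <- ex
  attr(out, "skipped") <- skipped
  out
}

# Cheap structural validation so malformed lines are reported with their
# line number before rtracklayer sees the file.
.validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !grepl("^#", lines) & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nfield < 9]
  if (length(bad)) {
    stop(sprintf("malformed GTF line %d in %s: expected 9 tab-separated fields",
                 bad[1], path))
  }
  invisible(TRUE)
}

#' Write intervals as a BED6 file
#'
#' @param df data.frame with `chrom`, `start`, `end` (0-based half-open) and
#'   optional `name`, `score`, `strand` columns.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  .assert_interval_df(df)
  out <- data.frame(
    chrom = df$chrom, start = df$start, end = df$end,
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) df$score else 0,
    strand = if ("strand" %in% names(df)) df$strand else ".",
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a narrowPeak (or BED3/6) file
#'
#' @param path path to a 10-column narrowPeak or a BED3/BED6 file.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open) plus
#'   `name`, `score`, `strand` and the narrowPeak statistics columns when
#'   present.
#' @export
read_narrowpeak <- function(path) {
  first <- utils::read.table(path, sep = "\t", nrows = 1,
                             stringsAsFactors = FALSE)
  ncols <- ncol(first)
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signalValue", "pValue", "qValue", "peak")
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- cols[seq_len(min(ncols, length(cols)))]
  .assert_interval_df(df, what = path)
  df
}
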