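# Per-base, per-strand signal density from alignment records.
#
# Alignment records are plain data.frames with 0-based half-open `start`,
# `end`, plus `chrom`, `strand`, `mapq` and optional logical flag columns
# `is_secondary`, `is_supplementary`, `is_mapped`, `is_proper_pair`.
# Missing flag columns default to primary/mapped/paired.

.flag_col <- function(alignments, col, default) {
  if (col %in% names(alignments)) alignments[[col]] else
    rep(default, nrow(alignments))
}

#' Read alignments from a 6-column BED dialect
#'
#' Columns: chrom, start, end, name, mapq, strand (0-based half-open).
#'
#' @param path path to the BED file.
#' @return alignment data.frame.
#' @export
read_alignments_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "mapq", "strand"))
  .assert_interval_df(df, what = path)
  df
}

#' Read alignments from a BAM file
#'
#' Extracts chrom/start/end/strand/mapq and the flag bits needed by the
#' density operations. Reference-space widths come from the CIGAR string.
#'
#' @param path path to an indexed or unindexed BAM file.
#' @return alignment data.frame with flag columns.
#' @export
read_alignments_bam <- function(path) {
  p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "mapq", "flag",
                                        "strand", "cigar"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  flag <- b$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  w <- GenomicAlignments::cigarWidthAlongReferenceSpace(b$cigar[mapped])
  start <- b$pos[mapped] - 1L
  data.frame(
    chrom = as.character(b$rname)[mapped],
    start = start,
    end = start + w,
    strand = as.character(b$strand)[mapped],
    mapq = b$mapq[mapped],
    is_secondary = bitwAnd(flag[mapped], 256L) != 0L,
    is_supplementary = bitwAnd(flag[mapped], 2048L) != 0L,
    is_proper_pair = bitwAnd(flag[mapped], 2L) != 0L,
    is_mapped = TRUE,
    stringsAsFactors = FALSE
  )
}

#' Count primary aligned reads (library size)
#'
#' Counts records that are mapped and neither secondary nor supplementary,
#' i.e. the `samtools view -c -F 260` convention with supplementary records
#' additionally excluded.
#'
#' @param alignments alignment data.frame.
#' @return integer library size.
#' @export
count_primary_aligned <- function(alignments) {
  if (nrow(alignments) == 0) return(0L)
  keep <- .flag_col(alignments, "is_mapped", TRUE) &
    !.flag_col(alignments, "is_secondary", FALSE) &
    !.flag_col(alignments, "is_supplementary", FALSE)
  sum(keep)
}

#' Filter alignments to primary, mapped, high-quality records
#'
#' @param alignments alignment data.frame.
#' @param min_mapq minimum mapping quality (strict inequality, i.e.
#'   `mapq > min_mapq`).
#' @return filtered alignment data.frame.
#' @export
filter_alignments <- function(alignments, min_mapq = 10) {
  keep <- .flag_col(alignments, "is_mapped", TRUE) &
    !.flag_col(alignments, "is_secondary", FALSE) &
    !.flag_col(alignments, "is_supplementary", FALSE) &
    alignments$mapq > min_mapq
  alignments[keep, , drop = FALSE]
}

#' Strand-aware 5'-end positions of stranded reads
#'
#' For tNET-seq the 5' end of each read marks the 3' end of the nascent RNA
#' and hence the exact polymerase position: a plus-strand record contributes
#' its leftmost base, a minus-strand record its rightmost base.
#'
#' @param alignments filtered alignment data.frame.
#' @return data.table position stream with `chrom`, `pos`, `strand`.
#' @export
five_prime_positions <- function(alignments) {
  pos <- ifelse(alignments$strand == "+",
                alignments$start, alignments$end - 1L)
  data.table::data.table(chrom = alignments$chrom,
                         pos = as.integer(pos),
                         strand = alignments$strand)
}

#' Tn5 cut sites from paired ATAC-seq reads
#'
#' Emits the strand-aware 5' end of every mate, with strand collapsed to
#' `"."` since accessibility is unstranded. No Tn5 +4/-5 offset is applied
#' by default (the accessibility recording mirrors the nascent-transcription
#' convention).
#'
#' @param alignments filtered paired alignment data.frame.
#' @param tn5_shift apply the +4/-5 Tn5 offset (default `FALSE`).
#' @return unstranded data.table position stream.
#' @export
atac_cut_sites <- function(alignments, tn5_shift = FALSE) {
  paired <- .flag_col(alignments, "is_proper_pair", TRUE)
  if (any(!paired)) {
    warning(sum(!paired), " unpaired record(s) skipped")
    alignments <- alignments[paired, , drop = FALSE]
  }
  if (nrow(alignments) == 0) {
    return(data.table::data.table(chrom = character(), pos = integer(),
                                  strand = character()))
  }
  plus <- alignments$strand == "+"
  pos <- ifelse(plus, alignments$start, alignments$end - 1L)
  if (tn5_shift) pos <- ifelse(plus, pos + 4L, pos - 5L)
  data.table::data.table(chrom = alignments$chrom, pos = as.integer(pos),
                         strand = ".")
}

#' Build a per-base density track from a position stream
#'
#' @param positions data.table/data.frame with `chrom`, `pos`, `strand`.
#' @param library_size number of primary aligned reads (required for RPM).
#' @param mode `"raw"` for integer counts, `"RPM"` for reads-per-million
#'   scaling (each value multiplied by 1e6 / library size).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return object of class `density_track`: list with `values` (data.table
#'   `chrom`, `pos`, `strand`, `value`), `scale`, `library_size`,
#'   `stranded`, `chrom_sizes`.
#' @export
build_density <- function(positions, library_size = NULL,
                          mode = c("raw", "RPM"), chrom_sizes = NULL) {
  mode <- match.arg(mode)
  dt <- data.table::as.data.table(positions)
  vals <- dt[, list(value = as.double(.N)), by = c("chrom", "pos", "strand")]
  data.table::setkeyv(vals, c("chrom", "strand", "pos"))
  scale <- 1.0
  if (mode == "RPM") {
    if (is.null(library_size) || library_size <= 0) {
      stop("RPM scaling requires a positive library size")
    }
    scale <- 1e6 / library_size
    vals[, "value" := vals$value * scale]
  }
  structure(list(values = vals, scale = scale,
                 library_size = library_size,
                 stranded = !all(vals$strand == "."),
                 chrom_sizes = chrom_sizes),
            class = "density_track")
}

#' @export
print.density_track <- function(x, ...) {
  cat("density_track:", nrow(x$values), "non-zero positions;",
      if (x$stranded) "stranded;" else "unstranded;",
      "scale =", format(x$scale), "\n")
  invisible(x)
}

# Vectorized region sums over a density track. `regions` needs chrom,
# start, end and (for sense/antisense) strand. Returns one sum per region.
.region_sums <- function(track, regions, strand_mode = c("sense", "antisense",
                                                         "both")) {
  strand_mode <- match.arg(strand_mode)
  .assert_interval_df(regions)
  n <- nrow(regions)
  if (n == 0) return(numeric(0))
  if (strand_mode != "both") {
    if (!"strand" %in% names(regions) ||
        any(!regions$strand %in% c("+", "-"))) {
      stop("sense/antisense mode requires stranded regions")
    }
    rs <- if (strand_mode == "sense") regions$strand else
      ifelse(regions$strand == "+", "-", "+")
    reg <- data.table::data.table(chrom = regions$chrom, strand = rs,
                                  rstart = regions$start,
                                  rend = regions$end,
                                  rid = seq_len(n))
  } else {
    reg <- data.table::CJ(rid = seq_len(n),
                          strand = unique(track$values$strand))
    reg <- data.table::data.table(
      chrom = regions$chrom[reg$rid], strand = reg$strand,
      rstart = regions$start[reg$rid], rend = regions$end[reg$rid],
      rid = reg$rid)
  }
  j <- track$values[reg,
                    on = c("chrom", "strand", "pos>=rstart", "pos<rend"),
                    list(rid = i.rid, v = x.value), nomatch = NULL]
  out <- numeric(n)
  if (nrow(j)) {
    agg <- j[, list(s = sum(v)), by = "rid"]
    out[agg$rid] <- agg$s
  }
  out
}

#' Mean per-base density of a region
#'
#' Sum of track values at positions inside the region on the selected
#' strand(s), divided by the region length in bp; positions without signal
#' contribute zero. `"sense"` selects read strand equal to the region
#' strand, `"antisense"` the opposite.
#'
#' @param track a `density_track`.
#' @param region single-row interval data.frame (or a many-row data.frame,
#'   in which case one mean per row is returned).
#' @param strand_mode `"sense"`, `"antisense"` or `"both"`.
#' @return numeric mean density (signal per bp).
#' @export
region_mean_density <- function(track, region,
                                strand_mode = c("sense", "antisense",
                                                "both")) {
  strand_mode <- match.arg(strand_mode)
  len <- region$end - region$start
  if (any(len < 1)) stop("region length must be >= 1")
  .region_sums(track, region, strand_mode) / len
}

#' Reads per kilobase per million mapped reads
#'
#' @param count read count in the region.
#' @param region_length region length in bp.
#' @param library_size number of primary aligned reads.
#' @return numeric RPKM value(s).
#' @export
rpkm <- function(count, region_length, library_size) {
  if (any(region_length < 1)) stop("region_length must be >= 1")
  if (is.null(library_size) || library_size <= 0) {
    stop("library_size must be positive")
  }
  count * 1e9 / (region_length * library_size)
}

#' Normalize a raw track to 1x genome coverage (RPGC)
#'
#' Multiplies every value by `effective_genome_size / total signal`, so the
#' genome-wide mean per-base signal equals 1.
#'
#' @param track a raw-count `density_track`.
#' @param effective_genome_size effective genome length in bp.
#' @return a rescaled `density_track`.
#' @export
rpgc_normalize <- function(track, effective_genome_size) {
  stopifnot(effective_genome_size > 0)
  total <- sum(track$values$value)
  if (total == 0) stop("cannot RPGC-normalize an empty track")
  f <- effective_genome_size / total
  vals <- data.table::copy(track$values)
  vals[, "value" := vals$value * f]
  structure(list(values = vals, scale = track$scale * f,
                 library_size = track$library_size,
                 stranded = track$stranded,
                 chrom_sizes = track$chrom_sizes),
            class = "density_track")
}

#' Write a density track as bedGraph
#'
#' One 4-column bedGraph per strand for stranded tracks (suffixes
#' `_plus`/`_minus`), a single file otherwise. Positions are single-base
#' intervals, 0-based half-open.
#'
#' @param track a `density_track`.
#' @param prefix output path prefix; `.bedGraph` is appended.
#' @return invisible character vector of written paths.
#' @export
write_bedgraph <- function(track, prefix) {
  v <- track$values
  strands <- unique(v$strand)
  paths <- character(0)
  for (s in strands) {
    suffix <- switch(s, "+" = "_plus", "-" = "_minus", "")
    path <- paste0(prefix, suffix, ".bedGraph")
    sub <- v[v$strand == s]
    data.table::setorderv(sub, c("chrom", "pos"))
    utils::write.table(
      data.frame(sub$chrom, sub$pos, sub$pos + 1L, sub$value),
      path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read a per-strand bedGraph pair into a density track
#'
#' @param plus_path bedGraph for plus-strand (or unstranded) signal.
#' @param minus_path optional bedGraph for minus-strand signal.
#' @param library_size optional library size to attach.
#' @param scale scale already applied to the values (1 = raw counts).
#' @return a `density_track`.
#' @export
read_bedgraph <- function(plus_path, minus_path = NULL, library_size = NULL,
                          scale = 1.0) {
  read_one <- function(path, strand) {
    df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "value"))
    # expand multi-base intervals to per-base records
    w <- df$end - df$start
    data.table::data.table(
      chrom = rep(df$chrom, w),
      pos = as.integer(unlist(mapply(seq, df$start, df$end - 1L,
                                     SIMPLIFY = FALSE))),
      strand = strand,
      value = rep(df$value, w))
  }
  vals <- read_one(plus_path, if (is.null(minus_path)) "." else "+")
  if (!is.null(minus_path)) {
    vals <- rbind(vals, read_one(minus_path, "-"))
  }
  data.table::setkeyv(vals, c("chrom", "strand", "pos"))
  structure(list(values = vals, scale = scale, library_size = library_size,
                 stranded = !is.null(minus_path), chrom_sizes = NULL),
            class = "density_track")
}
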