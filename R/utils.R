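# Internal helpers shared across modules.
#
# Coordinate convention: all intervals are 0-based half-open [start, end)
# internally. GTF input (1-based closed) and GRanges (1-based closed) are
# converted at the boundary; BED-family files are native 0-based half-open.

#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
.df_to_gr <- function(df, chrom_sizes = NULL) {
  strand <- if ("strand" %in% names(df)) {
    s <- as.character(df$strand)
    s[!s %in% c("+", "-")] <- "*"
    s
  } else rep("*", nrow(df))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges   = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand   = strand
  )
  if (!is.null(chrom_sizes)) {
    GenomicRanges::seqlengths(gr)[names(chrom_sizes)] <- chrom_sizes
  }
  gr
}

.gr_to_df <- function(gr) {
  s <- as.character(GenomicRanges::strand(gr))
  s[s == "*"] <- "."
  data.frame(
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1L,
    end    = GenomicRanges::end(gr),
    strand = s,
    stringsAsFactors = FALSE
  )
}

# Half-up decimal rounding (R's round() is half-even).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

.assert_interval_df <- function(df, what = "regions") {
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stop(sprintf("%s must have columns chrom, start, end", what))
  }
  if (any(df$start >= df$end)) {
    stop(sprintf("%s contain intervals with start >= end", what))
  }
  invisible(df)
}

# Deterministic per-sample seed derived from a run seed; stays within
# 32-bit integer range.
.derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 131L + index * 7919L) %% 2147483647)
}
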