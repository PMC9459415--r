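# Metagene matrices and proportion reporting.

#' Metagene matrix around anchor positions
#'
#' Extracts, for each anchor, the per-base signal in `[pos - flank,
#' pos + flank)`, averages it into bins of `binsize` bp, and reverses
#' minus-strand rows so transcription always runs left to right. Anchors
#' closer than `flank` to a chromosome edge (when the track knows its
#' chromosome sizes) get missing values in the out-of-range bins.
#'
#' @param track a `density_track` (typically RPGC-normalized so a flat
#'   genome gives a profile at 1.0).
#' @param anchors data.frame with `chrom`, `pos`, `strand` (one row per
#'   anchor, e.g. TSS positions).
#' @param flank half-window in bp (must be a multiple of `binsize`).
#' @param binsize bin width in bp.
#' @param strand_mode `"both"` (default), `"sense"` or `"antisense"`
#'   relative to the anchor strand.
#' @param n_boot bootstrap resamples for the confidence band of the mean
#'   profile (0 disables the band).
#' @param conf confidence level of the percentile bootstrap band.
#' @return object of class `metagene_matrix`: list with `matrix` (anchors x
#'   bins), `position` (bin start offsets relative to the anchor) and
#'   `profile` (data.frame `position`, `mean`, `lower`, `upper`).
#' @export
metagene_matrix <- function(track, anchors, flank, binsize = 1,
                            strand_mode = c("both", "sense", "antisense"),
                            n_boot = 1000, conf = 0.95) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(flank >= binsize, flank %% binsize == 0)
  n_bins <- as.integer(2 * flank / binsize)
  n_anchor <- nrow(anchors)
  mat <- base::matrix(0, n_anchor, n_bins)

  v <- track$values
  for (i in seq_len(n_anchor)) {
    a_start <- anchors$pos[i] - flank
    a_end <- anchors$pos[i] + flank
    strands <- switch(strand_mode,
                      both = unique(v$strand),
                      sense = anchors$strand[i],
                      antisense = if (anchors$strand[i] == "+") "-" else "+")
    sub <- v[v$chrom == anchors$chrom[i] & v$strand %in% strands &
               v$pos >= a_start & v$pos < a_end]
    row <- numeric(2 * flank)
    if (nrow(sub)) {
      agg <- sub[, list(val = sum(value)), by = "pos"]
      row[agg$pos - a_start + 1L] <- agg$val
    }
    if (!is.null(track$chrom_sizes)) {
      size <- track$chrom_sizes[[anchors$chrom[i]]]
      if (!is.null(size)) {
        off <- (a_start):(a_end - 1L)
        row[off < 0 | off >= size] <- NA_real_
      }
    }
    binned <- colMeans(base::matrix(row, nrow = binsize))
    if (anchors$strand[i] == "-") binned <- rev(binned)
    mat[i, ] <- binned
  }
  clipped <- sum(apply(mat, 1, function(r) any(is.na(r))))
  if (clipped > 0) {
    message(clipped, " anchor row(s) padded at chromosome edges")
  }
  position <- seq(-flank, flank - binsize, by = binsize)
  mean_prof <- colMeans(mat, na.rm = TRUE)
  lower <- upper <- rep(NA_real_, n_bins)
  if (n_boot > 0 && n_anchor > 1) {
    boots <- base::matrix(0, n_boot, n_bins)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n_anchor, n_anchor, replace = TRUE)
      boots[b, ] <- colMeans(mat[idx, , drop = FALSE], na.rm = TRUE)
    }
    a <- (1 - conf) / 2
    lower <- apply(boots, 2, stats::quantile, probs = a, na.rm = TRUE)
    upper <- apply(boots, 2, stats::quantile, probs = 1 - a, na.rm = TRUE)
  }
  structure(list(
    matrix = mat, position = position,
    profile = data.frame(position = position, mean = mean_prof,
                         lower = lower, upper = upper)),
    class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat("metagene_matrix:", nrow(x$matrix), "anchors x", ncol(x$matrix),
      "bins\n")
  invisible(x)
}

#' Labeled proportion report
#'
#' Computes percentages from labeled numerator/denominator pairs with
#' half-up rounding at a stated precision; the stored counts always
#' recompute their own percentage exactly.
#'
#' @param items data.frame with `label`, `numerator`, `denominator` and
#'   optional `digits` (decimal places, default 1).
#' @return data.frame of class `proportion_report` with a `percentage`
#'   column.
#' @export
proportion_report <- function(items) {
  stopifnot(all(c("label", "numerator", "denominator") %in% names(items)))
  if (any(items$denominator <= 0)) stop("denominators must be positive")
  digits <- if ("digits" %in% names(items)) items$digits else
    rep(1L, nrow(items))
  pct <- mapply(function(num, den, d) {
    round_half_up(100 * num / den, d)
  }, items$numerator, items$denominator, digits)
  out <- data.frame(label = items$label, numerator = items$numerator,
                    denominator = items$denominator, digits = digits,
                    percentage = pct, stringsAsFactors = FALSE)
  class(out) <- c("proportion_report", "data.frame")
  out
}
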