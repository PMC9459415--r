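# Promoter-proximal pausing index machinery.
#
# The pausing index (PI) of a gene is the ratio of its mean sense Pol II
# density in a promoter-proximal window to the mean sense density in the
# gene body. It is scale invariant, so RPM scaling of tracks cannot change
# it; what matters is the window geometry and the sense-only convention.

#' Pausing index from window means
#'
#' @param promoter_mean mean sense density in the promoter-proximal window
#'   (signal/bp).
#' @param body_mean mean sense density in the gene body (signal/bp); must be
#'   positive (genes with zero body signal are excluded upstream rather than
#'   given an infinite index).
#' @return numeric pausing index.
#' @export
pausing_index <- function(promoter_mean, body_mean) {
  if (any(body_mean <= 0)) stop("pausing index undefined for body_mean <= 0")
  promoter_mean / body_mean
}

#' Per-gene, per-sample pausing-index table
#'
#' Computes, for every gene and sample track, the mean sense density in the
#' promoter-proximal window (TSS +/- 200 bp by default, or the narrow
#' TSS +20..+100 pause window) and in the gene body (TSS +200 to TES -200),
#' and their ratio. Genes with zero body signal in any sample are excluded
#' and logged.
#'
#' @param tracks named list of `density_track` objects, one per sample.
#' @param gene_set a `gene_set`.
#' @param window `"standard"` (TSS +/- 200 bp) or `"narrow"` (TSS +20..+100).
#' @param condition named character vector mapping sample name to condition;
#'   defaults to one condition `"all"`.
#' @return object of class `pausing_table`: list with matrices `promoter`,
#'   `body`, `pi` (genes x samples), `condition`, `window`, and `excluded`
#'   (gene ids dropped for zero body signal).
#' @export
compute_pi_table <- function(tracks, gene_set, window = c("standard",
                                                          "narrow"),
                             condition = NULL) {
  window <- match.arg(window)
  stopifnot(inherits(gene_set, "gene_set"))
  genes <- gene_set$genes
  samples <- names(tracks)
  if (is.null(samples)) stop("tracks must be a named list")
  if (is.null(condition)) {
    condition <- stats::setNames(rep("all", length(samples)), samples)
  }
  prom <- if (window == "standard") promoter_window(genes) else
    narrow_pause_window(genes)
  body <- gene_body_region(genes)
  pm <- sapply(tracks, function(tr) region_mean_density(tr, prom, "sense"))
  bm <- sapply(tracks, function(tr) region_mean_density(tr, body, "sense"))
  pm <- matrix(pm, nrow = nrow(genes),
               dimnames = list(genes$gene_id, samples))
  bm <- matrix(bm, nrow = nrow(genes),
               dimnames = list(genes$gene_id, samples))
  ok <- apply(bm > 0, 1, all)
  excluded <- genes$gene_id[!ok]
  if (length(excluded)) {
    message(length(excluded),
            " gene(s) excluded for zero gene-body sense signal")
  }
  pm <- pm[ok, , drop = FALSE]
  bm <- bm[ok, , drop = FALSE]
  kept_genes <- genes[ok, , drop = FALSE]
  rownames(kept_genes) <- NULL
  structure(list(promoter = pm, body = bm, pi = pm / bm,
                 condition = condition[samples], window = window,
                 excluded = excluded, genes = kept_genes),
            class = "pausing_table")
}

#' @export
print.pausing_table <- function(x, ...) {
  cat("pausing_table:", nrow(x$pi), "genes x", ncol(x$pi), "samples (",
      x$window, "window )\n")
  cat("  median PI by condition:\n")
  for (cond in unique(x$condition)) {
    m <- stats::median(x$pi[, x$condition == cond, drop = FALSE])
    cat("    ", cond, ": ", format(m, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Remove genes with extreme pausing indices
#'
#' Drops any gene whose PI exceeds `cap` in at least one sample; keeping a
#' gene requires PI <= cap in all samples (the boundary is inclusive).
#' Idempotent.
#'
#' @param table a `pausing_table`.
#' @param cap maximum tolerated pausing index.
#' @return filtered `pausing_table`; the number removed is reported.
#' @export
filter_extreme_pi <- function(table, cap = 10) {
  stopifnot(inherits(table, "pausing_table"), ncol(table$pi) >= 1)
  keep <- apply(table$pi <= cap, 1, all)
  if (any(!keep)) {
    message(sum(!keep), " gene(s) removed with PI > ", cap,
            " in at least one sample")
  }
  out <- table
  out$promoter <- table$promoter[keep, , drop = FALSE]
  out$body <- table$body[keep, , drop = FALSE]
  out$pi <- table$pi[keep, , drop = FALSE]
  if (!is.null(table$genes)) {
    out$genes <- table$genes[keep, , drop = FALSE]
    rownames(out$genes) <- NULL
  }
  out
}

#' Classify pausing indices into high/moderate/low categories
#'
#' Default boundaries follow the inclusive-moderate convention
#' (high: PI >= 3; moderate: 1.5 <= PI < 3; low: PI < 1.5). Setting
#' `convention = "low_inclusive"` instead treats PI = 1.5 as low
#' (low: PI <= 1.5; moderate: 1.5 < PI < 3).
#'
#' @param pi numeric vector of pausing indices (>= 0).
#' @param high_min lower bound of the high category (inclusive).
#' @param low_max boundary between low and moderate.
#' @param convention `"moderate_inclusive"` (default) or `"low_inclusive"`.
#' @return factor with levels `low`, `moderate`, `high`.
#' @export
classify_pausing <- function(pi, high_min = 3.0, low_max = 1.5,
                             convention = c("moderate_inclusive",
                                            "low_inclusive")) {
  convention <- match.arg(convention)
  stopifnot(all(pi >= 0))
  low <- if (convention == "moderate_inclusive") pi < low_max else
    pi <= low_max
  lab <- ifelse(pi >= high_min, "high", ifelse(low, "low", "moderate"))
  factor(lab, levels = c("low", "moderate", "high"))
}

#' Per-gene log2 fold change of the pausing index between conditions
#'
#' The per-condition PI of a gene is the arithmetic mean of its replicate
#' PIs; the fold change is `log2(PI_b / PI_a)` for contrast `(a, b)`.
#'
#' @param table a `pausing_table` with a condition mapping.
#' @param contrast length-2 character vector `(condition_a, condition_b)`;
#'   positive fold changes mean higher PI in `condition_b`.
#' @return data.frame with `gene_id` and `log2fc`; genes with a zero mean
#'   PI in either condition are excluded and reported.
#' @export
pi_fold_change <- function(table, contrast) {
  stopifnot(inherits(table, "pausing_table"), length(contrast) == 2)
  if (!all(contrast %in% table$condition)) {
    stop("contrast conditions not present in table")
  }
  a <- rowMeans(table$pi[, table$condition == contrast[1], drop = FALSE])
  b <- rowMeans(table$pi[, table$condition == contrast[2], drop = FALSE])
  ok <- a > 0 & b > 0
  if (any(!ok)) message(sum(!ok), " gene(s) excluded for zero mean PI")
  data.frame(gene_id = rownames(table$pi)[ok],
             log2fc = log2(b[ok] / a[ok]),
             stringsAsFactors = FALSE)
}

#' Split genes into k equal-sized groups by a statistic
#'
#' Genes are ranked by `values` (ties broken by name for determinism) and
#' split into `k` groups whose sizes differ by at most one; when the count
#' does not divide evenly the extra members go to the lowest-value groups.
#' Group 1 holds the lowest values.
#'
#' @param values named numeric vector (names = gene ids), finite.
#' @param k number of groups.
#' @return integer vector of group labels (1..k) named like `values`.
#' @export
quantile_groups <- function(values, k = 4) {
  stopifnot(k >= 2, all(is.finite(values)))
  n <- length(values)
  if (n < k) stop("fewer genes than groups")
  nm <- names(values)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  ord <- order(values, nm)
  base <- n %/% k
  rem <- n %% k
  sizes <- rep(base, k) + c(rep(1L, rem), rep(0L, k - rem))
  lab <- rep(seq_len(k), times = sizes)
  out <- integer(n)
  out[ord] <- lab
  stats::setNames(out, nm)
}

#' Join pausing-index and promoter-accessibility fold changes
#'
#' Inner-joins the two per-gene log2 fold-change tables on `gene_id` and
#' reports the fraction of genes in each sign quadrant (accessibility
#' up/down x PI up/down). "Up" means a strictly positive log2 fold change.
#'
#' @param pi_fc data.frame `gene_id`, `log2fc` from [pi_fold_change()].
#' @param acc_fc data.frame `gene_id`, `log2fc` of promoter accessibility
#'   computed over the same promoter windows.
#' @return list with `table` (joined data.frame with columns `pi_log2fc`,
#'   `acc_log2fc`) and `quadrants` (named fractions `acc_up_pi_up`,
#'   `acc_up_pi_down`, `acc_down_pi_up`, `acc_down_pi_down`).
#' @export
integrate_pi_accessibility <- function(pi_fc, acc_fc) {
  joined <- merge(
    data.frame(gene_id = pi_fc$gene_id, pi_log2fc = pi_fc$log2fc),
    data.frame(gene_id = acc_fc$gene_id, acc_log2fc = acc_fc$log2fc),
    by = "gene_id")
  if (nrow(joined) == 0) stop("no shared genes between PI and accessibility")
  acc_up <- joined$acc_log2fc > 0
  pi_up <- joined$pi_log2fc > 0
  n <- nrow(joined)
  quadrants <- c(
    acc_up_pi_up = sum(acc_up & pi_up) / n,
    acc_up_pi_down = sum(acc_up & !pi_up) / n,
    acc_down_pi_up = sum(!acc_up & pi_up) / n,
    acc_down_pi_down = sum(!acc_up & !pi_up) / n)
  list(table = joined, quadrants = quadrants)
}

#' Write a pausing table as TSV
#'
#' @param table a `pausing_table`.
#' @param path output path.
#' @param reference_condition condition used for category labels (default:
#'   first condition).
#' @return invisible path.
#' @export
write_pausing_table <- function(table, path, reference_condition = NULL) {
  if (is.null(reference_condition)) reference_condition <- table$condition[1]
  ref <- rowMeans(table$pi[, table$condition == reference_condition,
                           drop = FALSE])
  df <- data.frame(gene_id = rownames(table$pi), table$pi,
                   category = as.character(classify_pausing(ref)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
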