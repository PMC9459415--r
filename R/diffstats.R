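# Region quantification and count statistics.
#
# The negative-binomial Wald and likelihood-ratio tests are deliberately
# lightweight stand-ins for a full count-model framework: per-region
# method-of-moments dispersion (no shrinkage), group means fitted directly,
# BH multiplicity control. They are meant to match a reference analysis in
# direction and FDR behaviour, not numerically.

#' Count reads or fragments in regions (one sample)
#'
#' `five_prime_sense` counts stranded 5'-end positions falling inside each
#' region on the region's strand. `fragment_overlap` counts fragments with
#' at least 1 bp overlap, each fragment counted once per region (a fragment
#' spanning two regions contributes to both; a warning is raised when
#' regions overlap each other, since a read may then be double counted).
#'
#' @param x a position stream (`chrom`, `pos`, `strand`) for
#'   `five_prime_sense`, or a fragment data.frame (`chrom`, `start`, `end`)
#'   for `fragment_overlap`.
#' @param regions interval data.frame; stranded for `five_prime_sense`.
#' @param mode counting mode.
#' @return integer vector of counts, one per region.
#' @export
count_reads_in_regions <- function(x, regions,
                                   mode = c("five_prime_sense",
                                            "fragment_overlap")) {
  mode <- match.arg(mode)
  .assert_interval_df(regions)
  if (mode == "five_prime_sense") {
    track <- build_density(x, mode = "raw")
    as.integer(.region_sums(track, regions, strand_mode = "sense"))
  } else {
    reg_gr <- .df_to_gr(regions)
    self_hits <- GenomicRanges::countOverlaps(reg_gr, reg_gr,
                                              ignore.strand = TRUE)
    if (any(self_hits > 1)) {
      warning("regions overlap each other; fragments may be double counted")
    }
    as.integer(GenomicRanges::countOverlaps(reg_gr, .df_to_gr(x),
                                            ignore.strand = TRUE))
  }
}

#' Build a region x sample count matrix
#'
#' @param samples named list of per-sample inputs (position streams or
#'   fragment data.frames, see [count_reads_in_regions()]).
#' @param regions interval data.frame; row names of the result come from
#'   its `gene_id`/`name` column if present.
#' @param mode counting mode passed through.
#' @param condition named character vector mapping sample to condition.
#' @return object of class `count_matrix`: integer matrix with attribute
#'   `condition`.
#' @export
build_count_matrix <- function(samples, regions,
                               mode = c("five_prime_sense",
                                        "fragment_overlap"),
                               condition = NULL) {
  mode <- match.arg(mode)
  counts <- sapply(samples, count_reads_in_regions, regions = regions,
                   mode = mode)
  counts <- matrix(as.integer(counts), nrow = nrow(regions),
                   dimnames = list(
                     if ("gene_id" %in% names(regions)) regions$gene_id
                     else if ("name" %in% names(regions)) regions$name
                     else paste0("region_", seq_len(nrow(regions))),
                     names(samples)))
  if (is.null(condition)) {
    condition <- stats::setNames(rep("all", ncol(counts)),
                                 colnames(counts))
  }
  structure(counts, condition = condition[colnames(counts)],
            class = c("count_matrix", class(counts)))
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over rows with
#' all-positive counts of `count / geometric mean of the row`, rescaled so
#' the factors have geometric mean 1.
#'
#' @param matrix integer count matrix (regions x samples).
#' @return numeric vector of positive size factors, one per sample.
#' @export
median_of_ratios <- function(matrix) {
  m <- as.matrix(matrix)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) stop("no row with all-positive counts")
  logm <- log(m[pos, , drop = FALSE])
  log_geo <- rowMeans(logm)
  sf <- exp(apply(logm - log_geo, 2, stats::median))
  sf / exp(mean(log(sf)))
}

# Shared internals for the NB tests -----------------------------------------

# Per-region method-of-moments dispersion from within-group variances of
# size-factor-normalized counts. Var(K/s) = mu * E[1/s] + alpha * mu^2.
# With few replicates the raw per-region estimate is noisy and its
# underestimates inflate Wald/LRT type-I error, so each region's value is
# floored at the across-region median estimate (a trend-free guard that
# leaves Poisson-like data untouched).
.mom_dispersion <- function(norm, condition, sf, floor = 1e-8) {
  lv <- unique(condition)
  ssq <- 0
  df <- 0
  for (l in lv) {
    sub <- norm[, condition == l, drop = FALSE]
    if (ncol(sub) >= 2) {
      mu_l <- rowMeans(sub)
      ssq <- ssq + rowSums((sub - mu_l)^2)
      df <- df + (ncol(sub) - 1)
    }
  }
  if (df == 0) stop("need at least 2 replicates in some condition")
  s2 <- ssq / df
  m <- rowMeans(norm)
  alpha <- (s2 - m * mean(1 / sf)) / m^2
  alpha[!is.finite(alpha)] <- floor
  alpha <- pmax(alpha, floor)
  pmax(alpha, stats::median(alpha))
}

.nb_loglik <- function(k, mu, alpha) {
  # rowwise log-likelihood; Poisson limit for vanishing dispersion
  ll <- matrix(0, nrow(k), ncol(k))
  small <- alpha <= 1e-8
  if (any(small)) {
    ll[small, ] <- stats::dpois(k[small, , drop = FALSE],
                                lambda = mu[small, , drop = FALSE],
                                log = TRUE)
  }
  if (any(!small)) {
    ll[!small, ] <- stats::dnbinom(k[!small, , drop = FALSE],
                                   size = 1 / alpha[!small],
                                   mu = mu[!small, , drop = FALSE],
                                   log = TRUE)
  }
  rowSums(ll)
}

#' Two-condition negative-binomial Wald test
#'
#' Per region: counts are normalized by size factors; a per-region
#' dispersion is estimated by method of moments from within-group variances
#' (floored at 1e-8, i.e. a Poisson fallback); group means are fitted as
#' means of normalized counts; the Wald statistic is `log2FC / SE(log2FC)`
#' with a delta-method standard error, compared against a standard normal;
#' p-values are BH-adjusted across regions.
#'
#' @param matrix `count_matrix` (or integer matrix with a `condition`
#'   argument).
#' @param contrast length-2 character vector `(condition_a, condition_b)`;
#'   positive log2FC means higher counts in `condition_b`.
#' @param size_factors optional size factors; computed by
#'   [median_of_ratios()] when missing.
#' @param condition condition mapping if `matrix` lacks one.
#' @param fdr significance threshold on the adjusted p-value.
#' @return data.frame per region: `baseMean`, `log2FC`, `stat`, `pvalue`,
#'   `padj`, `significant`, `flag` (`"ok"`, `"all_zero"`, `"zero_group"`).
#' @export
nb_wald_test <- function(matrix, contrast, size_factors = NULL,
                         condition = NULL, fdr = 0.05) {
  m <- as.matrix(matrix)
  if (is.null(condition)) condition <- attr(matrix, "condition")
  if (is.null(condition)) stop("no condition mapping supplied")
  stopifnot(length(contrast) == 2, all(contrast %in% condition))
  ia <- condition == contrast[1]
  ib <- condition == contrast[2]
  if (sum(ia) < 2 || sum(ib) < 2) {
    stop("need >= 2 replicates per condition")
  }
  if (is.null(size_factors)) size_factors <- median_of_ratios(m)
  norm <- sweep(m, 2, size_factors, "/")
  keep <- ia | ib
  alpha <- .mom_dispersion(norm[, keep, drop = FALSE], condition[keep],
                           size_factors[keep])
  mu_a <- rowMeans(norm[, ia, drop = FALSE])
  mu_b <- rowMeans(norm[, ib, drop = FALSE])
  na <- sum(ia)
  nb <- sum(ib)
  all_zero <- mu_a == 0 & mu_b == 0
  zero_group <- !all_zero & (mu_a == 0 | mu_b == 0)
  # continuity floor for zero groups: half a normalized count
  mu_a_adj <- pmax(mu_a, 0.5 / na)
  mu_b_adj <- pmax(mu_b, 0.5 / nb)
  var_mean <- function(mu, cols, n) {
    v <- mu %o% (1 / size_factors[cols]) + alpha * mu^2
    rowSums(v) / n^2
  }
  va <- var_mean(mu_a_adj, which(ia), na)
  vb <- var_mean(mu_b_adj, which(ib), nb)
  log2fc <- log2(mu_b_adj / mu_a_adj)
  se <- sqrt(va / mu_a_adj^2 + vb / mu_b_adj^2) / log(2)
  stat <- log2fc / se
  pvalue <- 2 * stats::pnorm(-abs(stat))
  log2fc[all_zero] <- 0
  stat[all_zero] <- 0
  pvalue[all_zero] <- 1
  padj <- bh_adjust(pvalue)
  data.frame(
    region = rownames(m) %||% paste0("region_", seq_len(nrow(m))),
    baseMean = rowMeans(norm),
    log2FC = log2fc, stat = stat, pvalue = pvalue, padj = padj,
    significant = padj < fdr,
    flag = ifelse(all_zero, "all_zero",
                  ifelse(zero_group, "zero_group", "ok")),
    stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Multi-condition negative-binomial likelihood-ratio test
#'
#' Tests, per region, a full model with one NB mean per condition against a
#' reduced single-mean model, sharing a per-region method-of-moments
#' dispersion; the statistic is compared against a chi-squared distribution
#' with (levels - 1) degrees of freedom and BH-adjusted.
#'
#' @inheritParams nb_wald_test
#' @return data.frame per region as in [nb_wald_test()] (without `log2FC`;
#'   `stat` is the LRT statistic).
#' @export
nb_lrt_test <- function(matrix, condition = NULL, size_factors = NULL,
                        fdr = 0.05) {
  m <- as.matrix(matrix)
  if (is.null(condition)) condition <- attr(matrix, "condition")
  if (is.null(condition)) stop("no condition mapping supplied")
  lv <- unique(condition)
  if (length(lv) < 3) stop("LRT requires >= 3 conditions")
  if (is.null(size_factors)) size_factors <- median_of_ratios(m)
  norm <- sweep(m, 2, size_factors, "/")
  alpha <- .mom_dispersion(norm, condition, size_factors)
  sf_row <- base::matrix(size_factors, nrow(m), ncol(m), byrow = TRUE)
  # group means weighted by size factors (exact Poisson MLE, good NB proxy)
  mu_full <- base::matrix(0, nrow(m), ncol(m))
  for (l in lv) {
    cols <- condition == l
    mu_l <- rowSums(m[, cols, drop = FALSE]) / sum(size_factors[cols])
    mu_full[, cols] <- mu_l
  }
  mu0 <- rowSums(m) / sum(size_factors)
  ll_full <- .nb_loglik(m, mu_full * sf_row, alpha)
  ll_red <- .nb_loglik(m, mu0 %o% size_factors, alpha)
  stat <- pmax(2 * (ll_full - ll_red), 0)
  pvalue <- stats::pchisq(stat, df = length(lv) - 1, lower.tail = FALSE)
  all_zero <- rowSums(m) == 0
  stat[all_zero] <- 0
  pvalue[all_zero] <- 1
  padj <- bh_adjust(pvalue)
  data.frame(
    region = rownames(m) %||% paste0("region_", seq_len(nrow(m))),
    baseMean = rowMeans(norm),
    stat = stat, pvalue = pvalue, padj = padj,
    significant = padj < fdr,
    flag = ifelse(all_zero, "all_zero", "ok"),
    stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @return step-up adjusted q-values, monotone and capped at 1.
#' @export
bh_adjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  stats::p.adjust(pvalues, method = "BH")
}

#' Two-sided two-proportion z-test
#'
#' Pooled-variance z statistic for the difference of two proportions,
#' without continuity correction.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with `z` and two-sided `p.value`.
#' @export
two_proportion_z_test <- function(x1, n1, x2, n2) {
  stopifnot(x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2, n1 > 0, n2 > 0)
  p_pool <- (x1 + x2) / (n1 + n2)
  if (p_pool <= 0 || p_pool >= 1) {
    stop("pooled proportion is 0 or 1; z undefined")
  }
  z <- (x1 / n1 - x2 / n2) /
    sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  list(z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact for small untied samples, tie-corrected normal approximation
#' otherwise (the standard rank-sum conventions).
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (Mann-Whitney W) and `p.value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  res <- suppressWarnings(stats::wilcox.test(x, y,
                                             alternative = "two.sided"))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}
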