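# Consensus peaks, enhancer rules, region annotation, overlap fractions.

peak_df <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(end), stringsAsFactors = FALSE)
}

test_that("consensus keeps regions by replicate support and matches the brute-force count", {
  sets <- list(r1 = peak_df(c(100, 500), c(200, 600)),
               r2 = peak_df(c(120, 900), c(210, 950)),
               r3 = peak_df(1500, 1600))
  c2 <- consensus_peaks(sets, min_support = 2)
  expect_equal(nrow(c2), 1)          # only the 100-210 merge has support 2
  expect_equal(c2$support, 2)
  c3 <- consensus_peaks(sets, min_support = 3)
  expect_equal(nrow(c3), 0)
  # identical peak in all sets -> one region with full support
  same <- list(a = peak_df(10, 60), b = peak_df(10, 60),
               c = peak_df(10, 60))
  call <- consensus_peaks(same, min_support = 3)
  expect_equal(nrow(call), 1)
  expect_equal(call$support, 3)
  expect_error(consensus_peaks(same, min_support = 4), "min_support")

  set.seed(71)
  jittered <- lapply(1:4, function(r) {
    s <- sort(sample.int(20000L, 30)) * 10L
    peak_df(s, s + sample(50:300, 30, replace = TRUE))
  })
  names(jittered) <- paste0("r", 1:4)
  for (ms in 2:4) {
    mine <- consensus_peaks(jittered, min_support = ms)
    oracle <- naive_consensus(jittered, ms)
    if (is.null(oracle)) {
      expect_equal(nrow(mine), 0)
    } else {
      expect_equal(mine$start, oracle$start)
      expect_equal(mine$end, oracle$end)
      expect_equal(mine$support, oracle$support)
    }
  }
  # monotone in support
  s2 <- consensus_peaks(jittered, min_support = 2)
  s3 <- consensus_peaks(jittered, min_support = 3)
  expect_true(all(paste(s3$start, s3$end) %in% paste(s2$start, s2$end)))
})

test_that("blacklisted intervals are subtracted from consensus regions", {
  sets <- list(a = peak_df(100, 300), b = peak_df(100, 300))
  bl <- peak_df(150, 200)
  cp <- consensus_peaks(sets, min_support = 2, blacklist = bl)
  expect_equal(cp$start, c(100, 200))
  expect_equal(cp$end, c(150, 300))
})

test_that("enhancer rules are conjunctive with >=1 bp / zero-overlap semantics", {
  genes <- make_genes("g", "chr1", "+", tss = 50000L, tes = 53000L)
  k27 <- structure(peak_df(c(10000, 20000, 30000, 49500),
                           c(10400, 20400, 30400, 49900)),
                   class = c("consensus_peaks", "data.frame"))
  k27$support <- 3
  k4 <- structure(peak_df(10399, 10600), # 1 bp overlap with first peak
                  class = c("consensus_peaks", "data.frame"))
  atac <- structure(peak_df(c(10000, 20000, 30900), c(10400, 20400, 31000)),
                    class = c("consensus_peaks", "data.frame"))
  enh <- identify_enhancers(k27, k4, atac, genes)
  # peak 1: K4me3 overlap; peak 3: no ATAC; peak 4: inside TSS +/- 1 kb
  expect_equal(enh$start, 20000)
  trail <- attr(enh, "rule_trail")
  expect_equal(trail$no_k4me3_overlap, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(trail$atac_overlap, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(trail$outside_tss_zone, c(TRUE, TRUE, TRUE, FALSE))
  # dropping any one rule yields a superset
  keep_all <- trail$no_k4me3_overlap & trail$outside_tss_zone &
    trail$atac_overlap
  for (r in names(trail)) {
    others <- setdiff(names(trail), r)
    relaxed <- Reduce(`&`, trail[others])
    expect_true(all(keep_all <= relaxed))
  }
  # empty candidate set is valid
  empty <- identify_enhancers(k27[0, ], k4, atac, genes)
  expect_equal(nrow(empty), 0)
})

test_that("enhancer identification matches the exhaustive three-predicate oracle and ignores input order", {
  set.seed(72)
  genes <- make_genes(sprintf("g%02d", 1:5), "chr1", "+",
                      tss = seq(100000L, 500000L, by = 100000L),
                      tes = seq(103000L, 503000L, by = 100000L))
  rnd_peaks <- function(n, w) {
    s <- sample.int(600000L, n)
    peak_df(s, s + w)
  }
  k27 <- rnd_peaks(60, 400)
  k4 <- rnd_peaks(25, 300)
  atac <- rnd_peaks(40, 200)
  enh <- identify_enhancers(k27, k4, atac, genes)
  # oracle: per-candidate loops over every rule
  tss_zone <- data.frame(chrom = genes$chrom, start = genes$tss - 1000L,
                         end = genes$tss + 1001L)
  oracle_keep <- sapply(seq_len(nrow(k27)), function(i) {
    cand <- k27[i, ]
    naive_overlap_count(cand, k4) == 0 &&
      naive_overlap_count(cand, tss_zone) == 0 &&
      naive_overlap_count(cand, atac) > 0
  })
  expect_equal(enh$start, k27$start[oracle_keep])
  perm <- sample(nrow(k27))
  enh_perm <- identify_enhancers(k27[perm, ], k4, atac, genes)
  expect_setequal(paste(enh_perm$start, enh_perm$end),
                  paste(enh$start, enh$end))
})

test_that("region annotation uses midpoint containment with fixed precedence", {
  genes <- make_genes("g", "chr1", "+", tss = 10000L, tes = 14000L)
  # widen the 5' UTR so it extends beyond the promoter window
  genes$cds_start <- 10600L
  ex <- attr(genes, "exons")
  ex$end <- 12000L  # exon covers 10000-12000; 12000-14000 is intron
  attr(genes, "exons") <- ex
  regions <- peak_df(c(9900, 10300, 11500, 13000, 50000),
                     c(10100, 10500, 11700, 13200, 50200))
  labels <- annotate_regions(regions, genes)
  expect_equal(labels, c("promoter", "five_prime_utr", "exon", "intron",
                         "distal"))
  # precedence oracle by explicit lookup per midpoint
  mids <- floor((regions$start + regions$end) / 2)
  oracle <- sapply(mids, function(m) {
    if (m >= 10000 - 200 && m < 10000 + 201) "promoter"
    else if (m >= 10000 && m < 10600) "five_prime_utr"
    else if (m >= 10000 && m < 12000) "exon"
    else if (m >= 10000 && m < 14000) "intron"
    else "distal"
  })
  expect_equal(labels, oracle)
})

test_that("overlap fractions reproduce printed-ratio arithmetic and the all-pairs oracle", {
  # disjoint sets
  expect_equal(overlap_fraction(peak_df(0, 10), peak_df(20, 30))$count, 0)
  expect_error(overlap_fraction(peak_df(0, 10)[0, ], peak_df(0, 5)),
               "empty")
  set.seed(73)
  q <- peak_df(sample.int(50000L, 80), sample.int(50000L, 80) + 300L)
  q$end <- q$start + 300L
  t <- peak_df(sample.int(50000L, 40), sample.int(50000L, 40) + 500L)
  t$end <- t$start + 500L
  res <- overlap_fraction(q, t)
  expect_equal(res$count, naive_overlap_count(q, t))
  expect_equal(res$fraction, res$count / nrow(q))
})

test_that("eRNA levels are per-enhancer mean densities over both strands", {
  enh <- structure(peak_df(c(1000, 5000), c(1400, 5400)),
                   class = c("enhancer_set", "data.frame"))
  # uniform both-strand track -> equal values for equal-length enhancers
  vals <- data.table::data.table(
    chrom = "chr1", pos = rep(0:9999, 2),
    strand = rep(c("+", "-"), each = 10000), value = 0.5)
  data.table::setkeyv(vals, c("chrom", "strand", "pos"))
  track <- structure(list(values = vals, scale = 1, library_size = 1e6,
                          stranded = TRUE, chrom_sizes = NULL),
                     class = "density_track")
  lv <- erna_level(track, enh)
  expect_equal(lv, c(1, 1))  # 0.5 per strand per base, both strands
  # zero-signal enhancer
  far <- structure(peak_df(90000, 90400),
                   class = c("enhancer_set", "data.frame"))
  expect_equal(erna_level(track, far), 0)
})
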