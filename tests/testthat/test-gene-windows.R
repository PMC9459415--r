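# Gene selection filters and strand-aware window derivation.

test_that("length filter is strict at 2 kb and isolation rejects close pairs", {
  # isolated gene of exactly 1,999 bp -> removed; 2,001 bp -> kept
  genes <- make_genes(c("short", "ok"), c("chr1", "chr2"), c("+", "+"),
                      tss = c(10000L, 10000L),
                      tes = c(11999L, 12001L))
  gs <- select_tnet_genes(genes)
  expect_equal(gs$genes$gene_id, "ok")
  expect_equal(gs$selection_log$status[gs$selection_log$gene_id == "short"],
               "length")

  # two genes 2,400 bp apart on one chromosome -> both removed at 2.5 kb
  pair <- make_genes(c("a", "b"), "chr1", c("+", "+"),
                     tss = c(10000L, 14900L),
                     tes = c(12500L, 17400L))
  gs2 <- select_tnet_genes(pair)
  expect_equal(nrow(gs2$genes), 0)
  expect_true(all(gs2$selection_log$status == "isolation"))
  # same pair 2,600 bp apart -> both kept
  pair$tss[2] <- 15100L
  pair$tes[2] <- 17600L
  pair$start <- pmin(pair$tss, pair$tes)
  pair$end <- pmax(pair$tss, pair$tes)
  expect_equal(nrow(select_tnet_genes(pair)$genes), 2)
})

test_that("selection retains isolated genes, matches a brute-force pair scan, and is order-independent", {
  set.seed(41)
  n <- 10
  genes <- make_genes(sprintf("g%02d", 1:n), paste0("chr", 1:n),
                      sample(c("+", "-"), n, replace = TRUE),
                      tss = rep(50000L, n),
                      tes = rep(50000L, n) +
                        sample(2100:4000, n) * c(1, -1)[
                          (seq_len(n) %% 2) + 1])
  genes$tss <- pmin(genes$tss, genes$tes) +
    ifelse(genes$strand == "+", 0, abs(genes$tes - genes$tss))
  genes$tes <- ifelse(genes$strand == "+",
                      genes$start + abs(genes$end - genes$start), genes$start)
  genes$start <- pmin(genes$tss, genes$tes)
  genes$end <- pmax(genes$tss, genes$tes)
  gs <- select_tnet_genes(genes)
  expect_equal(nrow(gs$genes), n)  # separate chromosomes: all isolated

  # brute-force: no envelope of a kept gene overlaps another gene's span
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || genes$chrom[i] != genes$chrom[j]) next
      expect_false(intervals_overlap(genes$start[i] - 2500,
                                     genes$end[i] + 2500,
                                     genes$start[j], genes$end[j]))
    }
  }

  # permuting the input changes nothing
  perm <- sample(n)
  gs_perm <- select_tnet_genes(genes[perm, ])
  expect_setequal(gs_perm$genes$gene_id, gs$genes$gene_id)

  # every input gene appears exactly once in the log
  expect_setequal(gs$selection_log$gene_id, genes$gene_id)
  expect_equal(nrow(gs$selection_log), n)
})

test_that("non-protein-coding genes are never retained but still block isolation", {
  genes <- make_genes(c("pc", "linc"), "chr1", c("+", "+"),
                      tss = c(10000L, 14000L), tes = c(12500L, 16500L),
                      biotype = c("protein_coding", "lincRNA"))
  gs <- select_tnet_genes(genes)
  expect_equal(nrow(gs$genes), 0)  # pc blocked by linc within 2.5 kb
  expect_equal(gs$selection_log$status,
               c("isolation", "biotype"))
})

test_that("coverage filter thresholds RPKM over the gene span", {
  genes <- make_genes(c("hi", "lo"), "chr1", c("+", "+"),
                      tss = c(10000L, 50000L), tes = c(12500L, 52500L))
  gs <- as_gene_set(genes)
  # 'hi': 10 sense counts on a 2,500 bp span; 'lo': none.
  track <- make_track(rep("chr1", 10), 10500:10509, rep("+", 10),
                      rep(1, 10), library_size = 1e6)
  filt <- coverage_filter(gs, track, rpkm_min = 1)
  # RPKM(hi) = 10 * 1e9 / (2500 * 1e6) = 4 > 1; RPKM(lo) = 0
  expect_equal(filt$genes$gene_id, "hi")
  expect_equal(filt$selection_log$status,
               c("retained", "coverage"))
  # direct recount oracle
  expect_equal(rpkm(naive_region_sum(track, "chr1", 10000, 12500, "+"),
                    2500, 1e6), 4)
  expect_error(coverage_filter(gs, make_track("chr1", 1L, "+", 1)),
               "library size")
})

test_that("promoter window is a 401-bp window centred on the TSS on either strand", {
  g <- make_genes(c("p", "m"), "chr1", c("+", "-"),
                  tss = c(1000L, 5000L), tes = c(4000L, 2000L))
  w <- promoter_window(g)
  expect_equal(w$start, c(800L, 4799L))
  expect_equal(w$end, c(1201L, 5200L))
  expect_equal(w$end - w$start, c(401L, 401L))
  # half_width 1000 reproduces the enhancer TSS-exclusion width
  w1k <- promoter_window(g, half_width = 1000)
  expect_equal(unique(w1k$end - w1k$start), 2001L)
  # clipping at the chromosome start is logged
  g0 <- make_genes("edge", "chr1", "+", tss = 100L, tes = 3000L)
  expect_message(w0 <- promoter_window(g0), "clipped")
  expect_equal(w0$start, 0L)
})

test_that("gene body and narrow pause windows mirror correctly by strand", {
  g <- make_genes(c("p", "m"), "chr1", c("+", "-"),
                  tss = c(0L, 2000L), tes = c(2000L, 0L))
  b <- gene_body_region(g)
  expect_equal(b$start, c(200L, 200L))
  expect_equal(b$end, c(1800L, 1800L))
  # body length is always span - 2*trim
  expect_equal(b$end - b$start, abs(g$tes - g$tss) - 400L)

  n <- narrow_pause_window(make_genes(c("p", "m"), "chr1", c("+", "-"),
                                      tss = c(1000L, 1000L),
                                      tes = c(4000L, -2000L) + 0L))
  expect_equal(n$start[1], 1020L)
  expect_equal(n$end[1], 1100L)
  expect_equal(n$start[2], 900L)
  expect_equal(n$end[2], 980L)
  expect_equal(unique(n$end - n$start), 80L)

  expect_error(gene_body_region(make_genes("tiny", "chr1", "+",
                                           tss = 0L, tes = 300L)),
               "span")
})

test_that("window derivation is strand-involutive under coordinate mirroring", {
  set.seed(42)
  L <- 100000L
  for (i in 1:5) {
    tss <- sample(3000:60000, 1)
    span <- sample(2500:5000, 1)
    g_plus <- make_genes("g", "chr1", "+", tss = tss, tes = tss + span)
    g_mirror <- make_genes("g", "chr1", "-", tss = L - tss,
                           tes = L - tss - span)
    for (fn in list(promoter_window, gene_body_region,
                    narrow_pause_window)) {
      wp <- fn(g_plus)
      wm <- fn(g_mirror)
      expect_equal(wm$start, L - wp$end)
      expect_equal(wm$end, L - wp$start)
    }
  }
})

test_that("nearest-TSS distances match the exhaustive all-pairs scan", {
  # containment gives zero
  g <- make_genes("g", "chr1", "+", tss = 1000L, tes = 4000L)
  expect_equal(nearest_tss_distance(
    data.frame(chrom = "chr1", start = 990L, end = 1010L), g), 0)
  # midpoint arithmetic
  g2 <- make_genes("g", "chr1", "+", tss = 1005L, tes = 4000L)
  expect_equal(nearest_tss_distance(
    data.frame(chrom = "chr1", start = 0L, end = 10L), g2), 1000)

  set.seed(43)
  genes <- make_genes(sprintf("g%02d", 1:20),
                      sample(c("chr1", "chr2"), 20, replace = TRUE),
                      "+", tss = sample.int(100000L, 20),
                      tes = sample.int(100000L, 20) + 150000L)
  starts <- sample.int(100000L, 50)
  regions <- data.frame(chrom = sample(c("chr1", "chr2"), 50,
                                       replace = TRUE),
                        start = starts, end = starts + 500L)
  expect_equal(nearest_tss_distance(regions, genes),
               naive_nearest_tss(regions, genes))
})
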