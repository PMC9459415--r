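# 5'-end recording, density tracks and normalizations.

test_that("library size counts mapped primary records only", {
  aln <- data.frame(chrom = "chr1", start = c(0, 10, 20, 30, 40),
                    end = c(50, 60, 70, 80, 90), strand = "+", mapq = 30,
                    is_secondary = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(count_primary_aligned(aln), 3L)
  expect_equal(count_primary_aligned(aln[0, ]), 0L)

  set.seed(51)
  n <- 10000
  big <- data.frame(chrom = "chr1", start = seq_len(n),
                    end = seq_len(n) + 50, strand = "+", mapq = 30,
                    is_secondary = rep(c(TRUE, rep(FALSE, 19)), n / 20))
  expect_equal(count_primary_aligned(big), 9500L)
})

test_that("5'-end recording is strand aware and matches a per-read loop", {
  aln <- data.frame(chrom = "chr1", start = c(100L, 100L),
                    end = c(150L, 150L), strand = c("+", "-"), mapq = 30)
  pos <- five_prime_positions(aln)
  expect_equal(pos$pos, c(100L, 149L))
  expect_equal(pos$strand, c("+", "-"))

  set.seed(52)
  n <- 500
  rnd <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                    start = sample.int(10000L, n, replace = TRUE),
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    mapq = 30)
  rnd$end <- rnd$start + 50L
  track <- build_density(five_prime_positions(rnd))
  oracle <- naive_five_prime_hist(rnd)
  v <- track$values
  expect_equal(nrow(v), length(oracle))
  for (i in seq_len(nrow(v))) {
    key <- paste(v$chrom[i], v$pos[i], v$strand[i])
    expect_equal(v$value[i], oracle[[key]])
  }
})

test_that("5'-end recording is an involution under mirroring with strand flip", {
  set.seed(53)
  L <- 10000L
  aln <- data.frame(chrom = "chr1",
                    start = sample.int(L - 60L, 200, replace = TRUE),
                    strand = sample(c("+", "-"), 200, replace = TRUE),
                    mapq = 30)
  aln$end <- aln$start + 50L
  mirrored <- data.frame(chrom = "chr1", start = L - aln$end,
                         end = L - aln$start,
                         strand = ifelse(aln$strand == "+", "-", "+"),
                         mapq = 30)
  p <- five_prime_positions(aln)
  pm <- five_prime_positions(mirrored)
  expect_setequal(L - 1L - p$pos, pm$pos)
})

test_that("ATAC cut sites emit both mate 5' ends, unstranded", {
  mates <- data.frame(chrom = "chr1", start = c(100L, 200L),
                      end = c(150L, 250L), strand = c("+", "-"), mapq = 30,
                      is_proper_pair = TRUE)
  sites <- atac_cut_sites(mates)
  expect_equal(sort(sites$pos), c(100L, 249L))
  expect_true(all(sites$strand == "."))
  expect_equal(nrow(atac_cut_sites(mates[0, ])), 0)
  mates$is_proper_pair[2] <- FALSE
  expect_warning(s2 <- atac_cut_sites(mates), "unpaired")
  expect_equal(s2$pos, 100L)
})

test_that("RPM scaling and raw conservation behave as defined", {
  # one position hit 4x in a 2M-read library -> RPM 2.0
  pos <- make_positions(rep("chr1", 4), rep(500L, 4), rep("+", 4))
  tr <- build_density(pos, library_size = 2e6, mode = "RPM")
  expect_equal(tr$values$value, 2.0)
  expect_error(build_density(pos, library_size = 0, mode = "RPM"),
               "library size")

  set.seed(54)
  n <- 2000
  pos2 <- make_positions(rep("chr1", n),
                         sample.int(5000L, n, replace = TRUE),
                         sample(c("+", "-"), n, replace = TRUE))
  raw <- build_density(pos2)
  expect_equal(sum(raw$values$value), n)  # conservation
  expect_true(all(raw$values$value == round(raw$values$value)))
  rpm <- build_density(pos2, library_size = 4000, mode = "RPM")
  expect_equal(sum(rpm$values$value), 1e6 * n / 4000)
})

test_that("region mean density matches a naive per-base loop and is additive", {
  set.seed(55)
  n <- 300
  pos <- make_positions(rep("chr1", n),
                        sample(1000:1199, n, replace = TRUE),
                        sample(c("+", "-"), n, replace = TRUE))
  track <- build_density(pos)
  reg <- data.frame(chrom = "chr1", start = 1000L, end = 1100L,
                    strand = "+")
  for (mode in c("sense", "antisense", "both")) {
    strands <- switch(mode, sense = "+", antisense = "-",
                      both = c("+", "-"))
    expect_equal(region_mean_density(track, reg, mode),
                 naive_region_sum(track, "chr1", 1000, 1100, strands) / 100)
  }
  # worked example: values {3, 1} in a 100 bp region -> 0.04
  t2 <- make_track(c("chr1", "chr1"), c(10L, 20L), c("+", "+"), c(3, 1))
  expect_equal(region_mean_density(
    t2, data.frame(chrom = "chr1", start = 0L, end = 100L, strand = "+"),
    "sense"), 0.04)
  # empty signal -> 0
  expect_equal(region_mean_density(
    t2, data.frame(chrom = "chr2", start = 0L, end = 50L, strand = "+"),
    "sense"), 0)
  # additivity over a partition (length-weighted)
  whole <- data.frame(chrom = "chr1", start = 1000L, end = 1100L,
                      strand = "+")
  parts <- data.frame(chrom = "chr1", start = c(1000L, 1040L),
                      end = c(1040L, 1100L), strand = "+")
  pm <- region_mean_density(track, parts, "sense")
  expect_equal(region_mean_density(track, whole, "sense"),
               sum(pm * c(40, 60)) / 100)
  # unstranded region rejects sense mode
  expect_error(region_mean_density(
    t2, data.frame(chrom = "chr1", start = 0L, end = 10L, strand = "."),
    "sense"), "stranded")
})

test_that("rpkm follows its closed form and is scale invariant", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(20, 1000, 2e6), rpkm(10, 1000, 1e6))
  expect_error(rpkm(1, 0, 1e6), "region_length")
})

test_that("RPGC normalization gives genome-wide mean 1", {
  set.seed(56)
  n <- 1000
  pos <- make_positions(rep("chr1", n),
                        sample.int(100000L, n, replace = TRUE),
                        rep("+", n))
  track <- build_density(pos)
  # total 1,000 over a 1,000 bp genome -> scale 1, values unchanged
  small <- rpgc_normalize(track, 1000)
  expect_equal(sum(small$values$value), 1000)
  # total n over genome G -> sum of values equals G
  G <- 250000
  norm <- rpgc_normalize(track, G)
  expect_equal(sum(norm$values$value), G)
  # halving input doubles values
  half <- build_density(pos[1:500])
  norm_half <- rpgc_normalize(half, G)
  expect_equal(sum(norm_half$values$value), G)
  expect_error(rpgc_normalize(make_track("chr1", 1L, "+", 0), 100),
               "empty")
})

test_that("tracks round-trip through bedGraph and BAM matches the BED reader", {
  set.seed(57)
  n <- 400
  pos <- make_positions(sample(c("chr1", "chr2"), n, replace = TRUE),
                        sample.int(5000L, n, replace = TRUE),
                        sample(c("+", "-"), n, replace = TRUE))
  track <- build_density(pos, library_size = n, mode = "RPM")
  prefix <- tempfile()
  paths <- write_bedgraph(track, prefix)
  back <- read_bedgraph(paths[1], paths[2], library_size = n,
                        scale = track$scale)
  a <- track$values[order(chrom, strand, pos)]
  b <- back$values[order(chrom, strand, pos)]
  expect_equal(a$pos, b$pos)
  expect_equal(a$value, b$value)

  aln <- data.frame(chrom = sample(c("chr1", "chr2"), 100, replace = TRUE),
                    start = sample.int(4000L, 100, replace = TRUE),
                    strand = sample(c("+", "-"), 100, replace = TRUE),
                    mapq = 60L)
  aln$end <- aln$start + 50L
  aln$name <- sprintf("r%03d", 1:100)
  bed_path <- tempfile(fileext = ".bed")
  write_alignments_bed(aln, bed_path)
  bam_path <- write_alignments_bam(aln, c(chr1 = 10000L, chr2 = 10000L),
                                   tempfile(fileext = ".bam"))
  from_bed <- read_alignments_bed(bed_path)
  from_bam <- read_alignments_bam(bam_path)
  key <- function(df) sort(paste(df$chrom, df$start, df$end, df$strand))
  expect_equal(key(from_bam), key(from_bed))
  expect_equal(count_primary_aligned(from_bam), 100L)
})
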