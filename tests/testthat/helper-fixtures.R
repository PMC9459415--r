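# Shared fixture builders and brute-force oracles. Every oracle is a
# deliberately naive implementation (per-read loops, all-pairs scans,
# exhaustive enumeration) kept independent of the package's vectorized
# code paths.

# minimal gene table with the columns load_annotation() produces
make_genes <- function(gene_id, chrom, strand, tss, tes,
                       biotype = "protein_coding") {
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   tss = tss, tes = tes,
                   start = pmin(tss, tes), end = pmax(tss, tes),
                   biotype = biotype,
                   canonical_transcript_id = paste0("tx_", gene_id),
                   cds_start = pmin(tss, tes) + 100L,
                   cds_end = pmax(tss, tes) - 100L,
                   stringsAsFactors = FALSE)
  attr(df, "exons") <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                                  start = df$start, end = df$end,
                                  strand = df$strand,
                                  stringsAsFactors = FALSE)
  df
}

as_gene_set <- function(genes) {
  structure(list(genes = genes,
                 selection_log = data.frame(gene_id = genes$gene_id,
                                            status = "retained")),
            class = "gene_set")
}

# position stream from parallel vectors
make_positions <- function(chrom, pos, strand) {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = strand)
}

# track from explicit per-base values
make_track <- function(chrom, pos, strand, value, library_size = NULL,
                       scale = 1) {
  vals <- data.table::data.table(chrom = chrom, pos = as.integer(pos),
                                 strand = strand, value = as.double(value))
  data.table::setkeyv(vals, c("chrom", "strand", "pos"))
  structure(list(values = vals, scale = scale,
                 library_size = library_size,
                 stranded = !all(strand == "."), chrom_sizes = NULL),
            class = "density_track")
}

# --- oracles ---------------------------------------------------------------

# per-base loop sum of track values in [start, end) on given strands
naive_region_sum <- function(track, chrom, start, end, strands) {
  v <- as.data.frame(track$values)
  total <- 0
  for (p in start:(end - 1)) {
    hit <- v$chrom == chrom & v$pos == p & v$strand %in% strands
    total <- total + sum(v$value[hit])
  }
  total
}

# per-read loop 5'-end histogram
naive_five_prime_hist <- function(alignments) {
  out <- list()
  for (i in seq_len(nrow(alignments))) {
    p <- if (alignments$strand[i] == "+") alignments$start[i] else
      alignments$end[i] - 1L
    key <- paste(alignments$chrom[i], p, alignments$strand[i])
    out[[key]] <- (out[[key]] %||% 0) + 1
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# all-pairs nearest TSS distance
naive_nearest_tss <- function(regions, genes) {
  sapply(seq_len(nrow(regions)), function(i) {
    best <- Inf
    mid <- floor((regions$start[i] + regions$end[i]) / 2)
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != regions$chrom[i]) next
      t <- genes$tss[j]
      d <- if (t >= regions$start[i] && t < regions$end[i]) 0 else
        abs(mid - t)
      best <- min(best, d)
    }
    best
  })
}

# brute-force interval overlap (>= 1 bp, 0-based half-open)
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

naive_overlap_count <- function(query, target) {
  n <- 0
  for (i in seq_len(nrow(query))) {
    hit <- FALSE
    for (j in seq_len(nrow(target))) {
      if (query$chrom[i] == target$chrom[j] &&
          intervals_overlap(query$start[i], query$end[i],
                            target$start[j], target$end[j])) hit <- TRUE
    }
    if (hit) n <- n + 1
  }
  n
}

# brute-force consensus: merge union by scanning, then count supporting
# samples per merged region
naive_consensus <- function(peak_sets, min_support) {
  all <- do.call(rbind, lapply(peak_sets, function(p) {
    p[, c("chrom", "start", "end")]
  }))
  all <- all[order(all$chrom, all$start), ]
  merged <- list()
  for (i in seq_len(nrow(all))) {
    last <- if (length(merged)) merged[[length(merged)]] else NULL
    if (!is.null(last) && last$chrom == all$chrom[i] &&
        all$start[i] <= last$end) {
      last$end <- max(last$end, all$end[i])
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1]] <- list(chrom = all$chrom[i],
                                           start = all$start[i],
                                           end = all$end[i])
    }
  }
  keep <- list()
  for (m in merged) {
    reg <- data.frame(chrom = m$chrom, start = m$start, end = m$end)
    support <- sum(sapply(peak_sets, function(p) {
      naive_overlap_count(reg, p) > 0
    }))
    if (support >= min_support) {
      reg$support <- support
      keep[[length(keep) + 1]] <- reg
    }
  }
  do.call(rbind, keep)
}

# pair-enumeration Kendall tau-b
naive_kendall_tau <- function(x, y) {
  n <- length(x)
  nc <- nd <- tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[j] - x[i])
      dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) nc <- nc + 1
      else nd <- nd + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (nc - nd) / sqrt((n0 - tx) * (n0 - ty))
}

# exhaustive two-sided rank-sum p-value over all rank assignments
naive_wilcoxon_exact_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2, function(idx) {
    sum(ranks[idx]) - nx * (nx + 1) / 2
  })
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# best bipartition by minimal total within-cluster dissimilarity
naive_best_bipartition <- function(d) {
  n <- nrow(d)
  best <- NULL
  best_cost <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    a <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    b <- setdiff(seq_len(n), a)
    cost <- sum(d[a, a]) + sum(d[b, b])
    if (cost < best_cost) {
      best_cost <- cost
      best <- sort(a)
    }
  }
  best
}
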