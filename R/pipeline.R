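# End-to-end pipeline on a synthetic scenario.

#' Run the integrative pausing/accessibility pipeline on synthetic data
#'
#' Executes every stage on a simulated aging cohort with known ground
#' truth: annotation and gene selection, per-sample Pol II 5'-end density,
#' pausing-index tables (standard and narrow windows) with the extreme-PI
#' filter, promoter accessibility from ATAC cut sites and its integration
#' with PI fold changes, consensus peaks and enhancer identification
#' against the enhancer truth, eRNA levels, NB count-matrix tests with
#' trajectory clustering, a TSS metagene, and a proportion report. All
#' randomness derives from `config$seed`, so a rerun with the same
#' configuration reproduces the summary byte for byte.
#'
#' @param config a `synthetic_config` from [aging_demo_config()].
#' @param outdir optional directory; when given, tables (TSV/BED/bedGraph)
#'   and a JSON summary of the headline statistics are written there.
#' @return list with the per-stage results and `summary` (the headline
#'   statistics list serialized to JSON when `outdir` is set).
#' @export
run_pipeline <- function(config = aging_demo_config(), outdir = NULL) {
  validate_config(config)
  set.seed(config$seed)

  genes <- simulate_annotation(config)
  chrom_sizes <- attr(genes, "chrom_sizes")
  gene_set <- select_tnet_genes(genes)
  enhancer_truth <- simulate_enhancer_truth(config, gene_set$genes)

  samples <- expand.grid(rep = seq_len(config$n_replicates),
                         condition = config$conditions,
                         stringsAsFactors = FALSE)
  sample_names <- paste0(samples$condition, "_", samples$rep)
  condition <- stats::setNames(samples$condition, sample_names)

  # tNET-seq: per-sample stranded 5'-end density
  tracks <- list()
  truth <- NULL
  for (i in seq_len(nrow(samples))) {
    sim <- simulate_tnet_reads(config, samples$condition[i],
                               gene_set$genes,
                               seed = .derive_seed(config$seed, i))
    aln <- filter_alignments(sim$alignments)
    lib <- count_primary_aligned(aln)
    tracks[[sample_names[i]]] <- build_density(
      five_prime_positions(aln), library_size = lib, mode = "RPM",
      chrom_sizes = chrom_sizes)
    if (samples$rep[i] == 1) {
      t <- sim$truth
      t$condition <- samples$condition[i]
      truth <- rbind(truth, t)
    }
  }

  gene_set <- coverage_filter(gene_set, .unscale(tracks[[1]]))

  pi_std <- compute_pi_table(tracks, gene_set, window = "standard",
                             condition = condition)
  pi_narrow <- compute_pi_table(tracks, gene_set, window = "narrow",
                                condition = condition)
  pi_std <- filter_extreme_pi(pi_std, cap = 10)

  contrast <- c(config$conditions[1],
                config$conditions[length(config$conditions)])
  pi_fc <- pi_fold_change(pi_std, contrast)

  # ATAC: promoter accessibility via cut sites over the same windows
  atac_tracks <- list()
  for (i in seq_len(nrow(samples))) {
    sim <- simulate_atac(config, samples$condition[i], gene_set$genes,
                         enhancer_truth,
                         seed = .derive_seed(config$seed, 1000 + i))
    sites <- atac_cut_sites(sim$alignments)
    atac_tracks[[sample_names[i]]] <- build_density(
      sites, library_size = nrow(sim$alignments), mode = "RPM",
      chrom_sizes = chrom_sizes)
  }
  prom <- promoter_window(pi_genes(pi_std))
  acc <- sapply(atac_tracks, function(tr) {
    region_mean_density(tr, prom, strand_mode = "both")
  })
  acc_a <- rowMeans(acc[, condition == contrast[1], drop = FALSE])
  acc_b <- rowMeans(acc[, condition == contrast[2], drop = FALSE])
  ok <- acc_a > 0 & acc_b > 0
  acc_fc <- data.frame(gene_id = prom$gene_id[ok],
                       log2fc = log2(acc_b[ok] / acc_a[ok]))
  integration <- integrate_pi_accessibility(pi_fc, acc_fc)

  # peaks and enhancers
  n_peak_samples <- config$n_replicates * length(config$conditions)
  peak_sets <- simulate_peak_sets(
    config, gene_set$genes, enhancer_truth, n_samples = n_peak_samples,
    seed = .derive_seed(config$seed, 5000))
  cons <- lapply(peak_sets, consensus_peaks, min_support = n_peak_samples)
  enhancers <- identify_enhancers(cons$k27ac, cons$k4me3, cons$atac,
                                  gene_set$genes)
  truth_active <- enhancer_truth[enhancer_truth$active, , drop = FALSE]
  enh_recall <- if (nrow(truth_active)) {
    overlap_fraction(truth_active, enhancers)$fraction
  } else NA_real_
  enh_precision <- if (nrow(enhancers)) {
    overlap_fraction(as.data.frame(enhancers), truth_active)$fraction
  } else NA_real_
  erna <- erna_level(tracks[[1]], enhancers)

  # count matrix: NB tests + trajectory clustering
  nb <- simulate_count_matrix(config,
                              n_replicates = config$n_replicates,
                              seed = .derive_seed(config$seed, 9000))
  wald <- nb_wald_test(nb$counts, contrast = c("A", "B"))

  # gene-body counts across the three ages for the LRT/trajectory stage
  body <- gene_body_region(pi_genes(pi_std))
  body_counts <- sapply(tracks, function(tr) {
    .region_sums(.unscale(tr), body, strand_mode = "sense")
  })
  rownames(body_counts) <- body$gene_id
  body_counts <- round(body_counts)
  sf <- median_of_ratios(body_counts)
  lrt <- nb_lrt_test(body_counts, condition = condition,
                     size_factors = sf)
  sig <- lrt$region[lrt$significant]
  clusters <- NULL
  if (length(sig) >= 8) {
    norm <- sweep(body_counts[sig, , drop = FALSE], 2, sf, "/")
    lognorm <- log2(norm + 1)
    prof <- sapply(config$conditions, function(cd) {
      rowMeans(lognorm[, condition == cd, drop = FALSE])
    })
    z <- zscore_profiles(prof)
    d <- kendall_distance_matrix(z)
    k <- min(4, nrow(d))
    clusters <- diana_clustering(d, k = k)
  }

  # metagene around the TSS (1x-normalized pooled young signal)
  young <- which(condition == config$conditions[1])
  pooled <- data.table::rbindlist(lapply(tracks[young], function(tr) {
    v <- data.table::copy(tr$values)
    v[, "value" := v$value / tr$scale]  # back to raw counts
    v
  }))
  pooled_track <- structure(
    list(values = pooled[, list(value = sum(value)),
                         by = c("chrom", "pos", "strand")],
         scale = 1, library_size = NA, stranded = TRUE,
         chrom_sizes = chrom_sizes),
    class = "density_track")
  data.table::setkeyv(pooled_track$values, c("chrom", "strand", "pos"))
  rpgc <- rpgc_normalize(pooled_track, sum(chrom_sizes))
  anchors <- data.frame(chrom = pi_genes(pi_std)$chrom,
                        pos = pi_genes(pi_std)$tss,
                        strand = pi_genes(pi_std)$strand)
  metagene <- metagene_matrix(rpgc, anchors, flank = 500, binsize = 10,
                              strand_mode = "sense", n_boot = 200)

  # headline statistics
  med_pi <- vapply(config$conditions, function(cd) {
    stats::median(pi_std$pi[, condition[colnames(pi_std$pi)] == cd])
  }, numeric(1))
  truth_std <- truth[match(rownames(pi_std$pi), truth$gene_id), ]
  rel_err <- vapply(config$conditions, function(cd) {
    cols <- condition[colnames(pi_std$pi)] == cd
    emp <- rowMeans(pi_std$pi[, cols, drop = FALSE])
    expd <- truth$expected_pi_standard[truth$condition == cd][
      match(rownames(pi_std$pi), truth$gene_id[truth$condition == cd])]
    stats::median(abs(emp - expd) / expd)
  }, numeric(1))
  report <- proportion_report(data.frame(
    label = c("genes_retained", "enhancers_recovered"),
    numerator = c(nrow(pi_std$pi), round(enh_recall * max(1,
                  nrow(truth_active)))),
    denominator = c(max(1, nrow(gene_set$selection_log)),
                    max(1, nrow(truth_active)))))

  summary <- list(
    seed = config$seed,
    n_genes_retained = nrow(pi_std$pi),
    median_pi = as.list(med_pi),
    median_pi_relative_error = as.list(rel_err),
    quadrant_fractions = as.list(integration$quadrants),
    n_enhancers = nrow(enhancers),
    enhancer_recall = enh_recall,
    enhancer_precision = enh_precision,
    wald_significant_fraction = mean(wald$significant),
    lrt_significant = sum(lrt$significant))

  result <- list(config = config, gene_set = gene_set,
                 pi_standard = pi_std, pi_narrow = pi_narrow,
                 truth = truth, pi_fold_change = pi_fc,
                 accessibility_fold_change = acc_fc,
                 integration = integration, consensus = cons,
                 enhancers = enhancers, enhancer_truth = enhancer_truth,
                 erna = erna, wald = wald, lrt = lrt,
                 clusters = clusters, metagene = metagene,
                 report = report, summary = summary)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_pausing_table(pi_std, file.path(outdir, "pausing_table.tsv"))
    write_peakset_bed(enhancers, file.path(outdir, "enhancers.bed"))
    utils::write.table(wald, file.path(outdir, "wald_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(lrt, file.path(outdir, "lrt_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_bedgraph(tracks[[1]], file.path(outdir, "sample1_rpm"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

# genes data.frame restricted to the rows of a pausing table
pi_genes <- function(pt) {
  if (is.null(pt$genes)) stop("pausing table lacks gene context")
  pt$genes
}

# strip RPM scaling back to raw counts (library size retained)
.unscale <- function(track) {
  v <- data.table::copy(track$values)
  v[, "value" := v$value / track$scale]
  structure(list(values = v, scale = 1, library_size = track$library_size,
                 stranded = track$stranded,
                 chrom_sizes = track$chrom_sizes),
            class = "density_track")
}
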