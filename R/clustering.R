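# Trajectory clustering: Kendall distances between per-gene expression
# profiles across conditions, divisive (DIANA) hierarchical clustering, and
# z-scored profiles for visualization.

#' Kendall distance matrix between gene trajectories
#'
#' Distance between two genes is `1 - tau`, with `tau` the tie-corrected
#' Kendall rank correlation of their across-condition profiles, so
#' identical trajectories have distance 0 and exactly reversed ones 2.
#' Constant profiles (undefined tau) are excluded and reported.
#'
#' @param profiles numeric matrix, genes x conditions (>= 2 conditions).
#' @return symmetric distance matrix over the retained genes, with the
#'   excluded gene ids in attribute `excluded`.
#' @export
kendall_distance_matrix <- function(profiles) {
  m <- as.matrix(profiles)
  stopifnot(ncol(m) >= 2)
  sds <- apply(m, 1, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    message(sum(constant), " constant profile(s) excluded")
    m <- m[!constant, , drop = FALSE]
  }
  tau <- stats::cor(t(m), method = "kendall")
  d <- 1 - tau
  diag(d) <- 0
  attr(d, "excluded") <- rownames(profiles)[constant]
  d
}

#' Divisive hierarchical clustering (DIANA) cut at k clusters
#'
#' Classical divisive analysis: starting from one all-object cluster,
#' repeatedly split the cluster with the largest diameter using the
#' splinter procedure -- the splinter group is seeded with the object of
#' maximal average dissimilarity to its cluster, and objects migrate to it
#' while their average dissimilarity to the remaining members exceeds their
#' average dissimilarity to the splinter group -- until `k` clusters exist.
#' All ties break towards the lowest object index, so the result is
#' deterministic given the distance matrix.
#'
#' @param dist square symmetric dissimilarity matrix with zero diagonal.
#' @param k target number of clusters (2 <= k <= n).
#' @return integer cluster labels (1..k) named by the matrix row names;
#'   clusters are numbered by their lowest member index.
#' @export
diana_clustering <- function(dist, k) {
  d <- as.matrix(dist)
  n <- nrow(d)
  stopifnot(nrow(d) == ncol(d), all(abs(diag(d)) < 1e-12))
  if (k > n) stop("k exceeds the number of objects")
  if (k < 2) stop("k must be >= 2")
  clusters <- list(seq_len(n))
  diameter <- function(m) if (length(m) < 2) 0 else
    max(d[m, m, drop = FALSE])
  while (length(clusters) < k) {
    diams <- vapply(clusters, diameter, numeric(1))
    target <- which.max(diams)  # first max = lowest index on ties
    if (diams[target] == 0) {
      # duplicate points: split the first multi-member cluster
      target <- which(lengths(clusters) > 1)[1]
    }
    split <- .diana_split(d, clusters[[target]])
    clusters <- append(clusters[-target], split)
  }
  clusters <- clusters[order(vapply(clusters, min, numeric(1)))]
  labels <- integer(n)
  for (i in seq_along(clusters)) labels[clusters[[i]]] <- i
  stats::setNames(labels, rownames(d))
}

# One splinter split of cluster `members` under dissimilarity matrix d.
.diana_split <- function(d, members) {
  m <- length(members)
  if (m == 2) return(list(members[1], members[2]))
  avg_to <- function(i, grp) mean(d[i, grp])
  avg_within <- vapply(members, function(i) {
    mean(d[i, setdiff(members, i)])
  }, numeric(1))
  seed <- members[which.max(avg_within)]
  splinter <- seed
  rest <- setdiff(members, seed)
  repeat {
    if (length(rest) == 1) break
    gain <- vapply(rest, function(i) {
      avg_to(i, setdiff(rest, i)) - avg_to(i, splinter)
    }, numeric(1))
    best <- which.max(gain)
    if (gain[best] <= 0) break
    splinter <- c(splinter, rest[best])
    rest <- setdiff(rest, rest[best])
  }
  list(sort(splinter), sort(rest))
}

#' Row-wise z-scored profiles
#'
#' Centres and scales every gene's across-condition profile to mean 0 and
#' (sample) standard deviation 1; constant rows are excluded and reported.
#'
#' @param matrix numeric matrix, genes x conditions.
#' @return z-scored matrix over the retained rows, excluded ids in
#'   attribute `excluded`.
#' @export
zscore_profiles <- function(matrix) {
  m <- as.matrix(matrix)
  stopifnot(ncol(m) >= 2)
  mu <- rowMeans(m)
  sds <- apply(m, 1, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    message(sum(constant), " constant row(s) excluded from z-scoring")
  }
  z <- (m[!constant, , drop = FALSE] - mu[!constant]) / sds[!constant]
  attr(z, "excluded") <- rownames(m)[constant]
  z
}
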