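#' Ward-linkage agglomeration of a dissimilarity matrix
#'
#' Runs agglomerative hierarchical clustering with Ward's minimum-variance
#' criterion applied to the supplied (unsquared) distances — the `ward.D2`
#' convention, in which merge heights are non-decreasing.
#'
#' @param d symmetric nonnegative dissimilarity matrix with zero diagonal (or
#'   a `dist`), at least 2 regions.
#' @return An `hclust` merge tree.
#' @export
ward_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2)
  if (!isTRUE(all.equal(d, t(d))) || any(d < 0) || any(diag(d) != 0)) {
    stop("dissimilarity must be symmetric, nonnegative, zero-diagonal")
  }
  stats::hclust(stats::as.dist(d), method = "ward.D2")
}

#' Cut a merge tree into k clusters
#'
#' Removes the k-1 highest merges.
#'
#' @param tree an `hclust` tree.
#' @param k cluster count, `1 <= k <= n`.
#' @return Integer labels named by region.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k out of range [1, ", n, "]")
  stats::cutree(tree, k = k)
}

# --- internal validity indices on a dissimilarity matrix ------------------
# All operate on the distance matrix alone (no coordinates): sums of squared
# dissimilarities stand in for within-cluster variance, as in Ward's criterion.

pairs_upper <- function(d) d[upper.tri(d)]

wss_from_d <- function(d, labels) {
  sum(vapply(split(seq_along(labels), labels), function(idx) {
    if (length(idx) < 2) return(0)
    sub <- d[idx, idx]
    sum(sub[upper.tri(sub)]^2) / length(idx)
  }, numeric(1)))
}

index_ch <- function(d, labels) {
  n <- length(labels); k <- length(unique(labels))
  tot <- sum(pairs_upper(d)^2) / n
  w <- wss_from_d(d, labels)
  ((tot - w) / (k - 1)) / (w / (n - k))
}

index_silhouette <- function(d, labels) {
  mean(cluster::silhouette(labels, dmatrix = d)[, "sil_width"])
}

index_db <- function(d, labels) {
  ks <- sort(unique(labels))
  scatter <- vapply(ks, function(c1) {
    idx <- which(labels == c1)
    if (length(idx) < 2) return(0)
    mean(pairs_upper(d[idx, idx]))
  }, numeric(1))
  sep <- outer(ks, ks, Vectorize(function(a, b)
    mean(d[labels == a, labels == b, drop = FALSE])))
  ratio <- outer(scatter, scatter, `+`) / sep
  diag(ratio) <- -Inf
  mean(apply(ratio, 1, max))
}

index_dunn <- function(d, labels) {
  ks <- sort(unique(labels))
  diam <- max(vapply(ks, function(c1) {
    idx <- which(labels == c1)
    if (length(idx) < 2) return(0)
    max(d[idx, idx])
  }, numeric(1)))
  sep <- min(vapply(seq_along(ks)[-1], function(i) {
    min(vapply(seq_len(i - 1), function(j)
      min(d[labels == ks[i], labels == ks[j], drop = FALSE]), numeric(1)))
  }, numeric(1)))
  if (diam == 0) return(Inf)
  sep / diam
}

index_cindex <- function(d, labels) {
  within <- outer(labels, labels, `==`)[upper.tri(d)]
  dv <- pairs_upper(d)
  nw <- sum(within)
  s <- sum(dv[within])
  srt <- sort(dv)
  smin <- sum(srt[seq_len(nw)])
  smax <- sum(srt[seq.int(length(srt) - nw + 1L, length(srt))])
  (s - smin) / (smax - smin)
}

index_mcclain <- function(d, labels) {
  within <- outer(labels, labels, `==`)[upper.tri(d)]
  dv <- pairs_upper(d)
  mean(dv[within]) / mean(dv[!within])
}

index_pointbiserial <- function(d, labels) {
  within <- outer(labels, labels, `==`)[upper.tri(d)]
  dv <- pairs_upper(d)
  nw <- sum(within); nb <- sum(!within); nt <- nw + nb
  (mean(dv[!within]) - mean(dv[within])) *
    sqrt(nw * nb / nt^2) / stats::sd(dv)
}

CLUSTER_INDICES <- list(
  calinski_harabasz = list(fn = index_ch, maximize = TRUE),
  silhouette = list(fn = index_silhouette, maximize = TRUE),
  davies_bouldin = list(fn = index_db, maximize = FALSE),
  dunn = list(fn = index_dunn, maximize = TRUE),
  c_index = list(fn = index_cindex, maximize = FALSE),
  mcclain_rao = list(fn = index_mcclain, maximize = FALSE),
  point_biserial = list(fn = index_pointbiserial, maximize = TRUE)
)

#' Optimal cluster count by a multi-index majority vote
#'
#' Cuts the Ward tree at every candidate k and scores each partition with a
#' fixed battery of seven internal validity indices (Calinski-Harabasz,
#' average silhouette width, Davies-Bouldin, Dunn, C-index, McClain-Rao,
#' point-biserial), each computed from the dissimilarity matrix alone. Each
#' index votes for its preferred k; the majority wins, with ties broken toward
#' the smaller k. All index values are returned so divergent votes can be
#' audited.
#'
#' @param d dissimilarity matrix.
#' @param k_range candidate cluster counts, within `[2, n - 1]`.
#' @return list with `k` (the winner), `votes` (named integer: each index's
#'   preferred k) and `index_values` (k-by-index matrix).
#' @export
select_optimal_k <- function(d, k_range = 2:10) {
  stopifnot(is.matrix(d), nrow(d) >= 3)
  k_range <- as.integer(k_range)
  stopifnot(all(k_range >= 2), all(k_range <= nrow(d) - 1L))
  off <- pairs_upper(d)
  if (max(off) - min(off) < 1e-15) stop("degenerate dissimilarity: all distances equal")
  tree <- ward_tree(d)
  vals <- matrix(NA_real_, length(k_range), length(CLUSTER_INDICES),
                 dimnames = list(as.character(k_range), names(CLUSTER_INDICES)))
  for (i in seq_along(k_range)) {
    labels <- cut_tree(tree, k_range[i])
    for (nm in names(CLUSTER_INDICES)) {
      vals[i, nm] <- CLUSTER_INDICES[[nm]]$fn(d, labels)
    }
  }
  votes <- vapply(names(CLUSTER_INDICES), function(nm) {
    v <- vals[, nm]
    if (CLUSTER_INDICES[[nm]]$maximize) k_range[which.max(v)]
    else k_range[which.min(v)]
  }, integer(1))
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  list(k = min(winners), votes = votes, index_values = vals)
}

#' Full clustering stage
#'
#' @param d dissimilarity matrix over selected regions.
#' @param k_range candidate cluster counts.
#' @return list of class `cluster_solution`: `labels` (named integer), `k`,
#'   `tree` (`hclust`), `votes`, `index_values`.
#' @export
cluster_regions <- function(d, k_range = 2:10) {
  sel <- select_optimal_k(d, k_range)
  tree <- ward_tree(d)
  labels <- cut_tree(tree, sel$k)
  names(labels) <- rownames(d)
  structure(list(labels = labels, k = sel$k, tree = tree,
                 votes = sel$votes, index_values = sel$index_values),
            class = "cluster_solution")
}
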