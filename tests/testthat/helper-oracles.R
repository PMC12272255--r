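# Independent brute-force oracles used to validate the fast implementations.

# Ward (ward.D2 convention) agglomeration by the Lance-Williams recurrence on
# squared distances, tracking cluster sizes explicitly. Returns the sequence
# of merge heights and the partition at every k.
ward_oracle <- function(d) {
  n <- nrow(d)
  d2 <- d^2
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  labels <- seq_len(n)                 # current cluster slot per point
  heights <- numeric(n - 1L)
  partitions <- vector("list", n)      # partitions[[k]] = labels with k clusters
  partitions[[n]] <- labels
  for (step in seq_len(n - 1L)) {
    best <- c(NA_integer_, NA_integer_); bestv <- Inf
    act <- which(active)
    for (a in seq_along(act)) for (b in seq_len(a - 1L)) {
      i <- act[b]; j <- act[a]
      if (d2[i, j] < bestv) { bestv <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(bestv)
    for (k in act) {
      if (k == i || k == j) next
      d2[k, i] <- d2[i, k] <-
        ((sizes[i] + sizes[k]) * d2[k, i] + (sizes[j] + sizes[k]) * d2[k, j] -
           sizes[k] * d2[i, j]) / (sizes[i] + sizes[j] + sizes[k])
    }
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    labels[labels == j] <- i
    partitions[[n - step]] <- labels
  }
  list(heights = heights, partitions = partitions)
}

same_partition <- function(a, b) {
  mclust::adjustedRandIndex(a, b) == 1
}

# Exhaustive-enumeration weighted betweenness: enumerate every simple path
# between every ordered node pair, keep the minimum-total-length ones (with a
# relative tolerance for floating-point ties), and accumulate the fraction
# passing through each interior node.
bc_enumeration_oracle <- function(w, rule = c("reciprocal", "one_minus_r"),
                                  normalized = FALSE) {
  rule <- match.arg(rule)
  n <- nrow(w)
  len <- matrix(Inf, n, n)
  pos <- w > 0
  len[pos] <- if (rule == "reciprocal") 1 / w[pos] else pmax(1 - w[pos], 1e-12)
  diag(len) <- Inf
  bc <- numeric(n)
  for (h in seq_len(n)) for (j in seq_len(n)) {
    if (h == j) next
    paths <- list(); lens <- numeric(0)
    rec <- function(node, visited, dist) {
      if (node == j) {
        paths[[length(paths) + 1L]] <<- visited
        lens[length(lens) + 1L] <<- dist
        return(invisible())
      }
      for (nb in which(is.finite(len[node, ]))) {
        if (!(nb %in% visited)) rec(nb, c(visited, nb), dist + len[node, nb])
      }
    }
    rec(h, h, 0)
    if (length(lens) == 0L) next
    dmin <- min(lens)
    shortest <- paths[lens <= dmin * (1 + 1e-12)]
    interior <- setdiff(seq_len(n), c(h, j))
    for (i in interior) {
      frac <- mean(vapply(shortest, function(p) i %in% p, logical(1)))
      bc[i] <- bc[i] + frac
    }
  }
  if (normalized) bc / ((n - 1) * (n - 2)) else bc
}

# random symmetric "correlation" matrix with a controllable fraction of
# nonpositive entries; diagonal 1
random_corr_matrix <- function(n, p_negative = 0.25) {
  m <- matrix(0, n, n)
  up <- upper.tri(m)
  vals <- stats::runif(sum(up), 0.05, 0.95)
  neg <- stats::runif(sum(up)) < p_negative
  vals[neg] <- -vals[neg]
  m[up] <- vals
  m <- m + t(m)
  diag(m) <- 1
  dimnames(m) <- list(paste0("R", seq_len(n)), paste0("R", seq_len(n)))
  m
}

# planted block dissimilarity: k blocks with small within / large between
# distances plus jitter
planted_block_dissimilarity <- function(sizes, within = 0.1, between = 0.9,
                                        jitter = 0.02) {
  labels <- rep(seq_along(sizes), sizes)
  n <- length(labels)
  d <- matrix(between, n, n) +
    matrix(stats::runif(n * n, -jitter, jitter), n, n)
  d[outer(labels, labels, `==`)] <- within
  d <- (d + t(d)) / 2
  d[outer(labels, labels, `==`)] <-
    d[outer(labels, labels, `==`)] +
    stats::runif(sum(outer(labels, labels, `==`)), 0, jitter)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("R", seq_len(n)), paste0("R", seq_len(n)))
  attr(d, "labels") <- labels
  d
}
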