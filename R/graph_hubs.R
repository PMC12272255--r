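#' Positive-correlation network graph
#'
#' Builds the undirected weighted graph of one network for one participant:
#' nodes are the network's member regions, and an edge with weight r exists
#' exactly where the correlation between two members is strictly positive.
#' Negative and zero correlations yield no edge.
#'
#' @param r_matrix symmetric correlation matrix with region dimnames.
#' @param members character vector of member regions (N >= 3; betweenness
#'   normalisation is undefined below that).
#' @return An `igraph` graph with a `weight` edge attribute.
#' @export
build_positive_graph <- function(r_matrix, members) {
  stopifnot(all(members %in% rownames(r_matrix)))
  if (length(members) < 3) stop("network needs at least 3 regions")
  sub <- r_matrix[members, members]
  adj <- ifelse(sub > 0, sub, 0)
  diag(adj) <- 0
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                      weighted = TRUE)
}

#' Weighted degree centrality (strength)
#'
#' The sum of a node's positive edge weights: for region i,
#' `DC_i = sum_j r_ij` over the positive correlations with the other members
#' of its network.
#'
#' @param g a graph from [build_positive_graph()].
#' @return Named numeric vector of strengths.
#' @export
degree_centrality <- function(g) {
  igraph::strength(g)
}

# edge weights -> shortest-path edge lengths
edge_lengths <- function(w, rule) {
  switch(rule,
         reciprocal = 1 / w,
         one_minus_r = pmax(1 - w, 1e-12),
         stop("unknown edge_length_rule: ", rule))
}

#' Weighted betweenness centrality
#'
#' For every ordered pair of other nodes (h, j), the fraction of
#' minimum-total-length paths between h and j that pass through node i is
#' accumulated; unreachable pairs contribute 0. Edge lengths are derived from
#' the correlation weights either as `1/r` (the default convention: strong
#' correlations are short) or as `1 - r` (the alternative in which path cost
#' is low where correlation is high on a linear scale). With
#' `normalized = TRUE` the sum is divided by `(N-1)(N-2)`, the number of
#' ordered pairs excluding i, so a star center scores 1.
#'
#' @param g a graph from [build_positive_graph()].
#' @param edge_length_rule `"reciprocal"` or `"one_minus_r"`.
#' @param normalized divide by `(N-1)(N-2)`? Default FALSE (raw sum over
#'   ordered pairs). Hub detection is invariant to this choice.
#' @return Named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(g,
                                   edge_length_rule = c("reciprocal", "one_minus_r"),
                                   normalized = FALSE) {
  edge_length_rule <- match.arg(edge_length_rule)
  n <- igraph::vcount(g)
  len <- edge_lengths(igraph::E(g)$weight, edge_length_rule)
  # igraph counts unordered pairs on undirected graphs; double for ordered
  bc <- 2 * igraph::betweenness(g, directed = FALSE, weights = len)
  if (normalized) bc <- bc / ((n - 1) * (n - 2))
  bc
}

#' Per-participant centralities for every network
#'
#' @param stack a `connectivity_stack`.
#' @param labels named vector region -> network; networks with fewer than 3
#'   members are skipped with a message.
#' @param edge_length_rule,normalized passed to [betweenness_centrality()].
#' @return Named list (one element per network) of lists with `dc` and `bc`
#'   participant-by-region matrices.
#' @export
participant_centralities <- function(stack, labels,
                                     edge_length_rule = "reciprocal",
                                     normalized = FALSE) {
  lab <- labels[stack$region_ids]
  out <- list()
  for (net in sort(unique(lab))) {
    members <- stack$region_ids[lab == net]
    if (length(members) < 3) {
      log_stage("hubs", sprintf("skipping network %s (%d region(s) < 3)",
                                net, length(members)))
      next
    }
    P <- length(stack$matrices)
    dc <- bc <- matrix(0, P, length(members),
                       dimnames = list(NULL, members))
    for (p in seq_len(P)) {
      g <- build_positive_graph(stack$matrices[[p]], members)
      dc[p, ] <- degree_centrality(g)[members]
      bc[p, ] <- betweenness_centrality(g, edge_length_rule,
                                        normalized)[members]
    }
    out[[net]] <- list(dc = dc, bc = bc)
  }
  out
}

#' Participant-averaged centrality summary with hub thresholds
#'
#' Region means across participants with normal-approximation confidence
#' intervals (mean +/- z * sd/sqrt(n)). The network's hub thresholds are the
#' across-region mean plus one across-region sample standard deviation
#' (denominator N-1) of the participant-averaged values.
#'
#' @param dc,bc participant-by-region centrality matrices (>= 2 participants).
#' @param ci_level confidence level (default 0.95).
#' @return list of class `centrality_summary`: `regions` data.frame
#'   (`region`, `dc_mean`, `dc_ci_low`, `dc_ci_high`, `bc_mean`, `bc_ci_low`,
#'   `bc_ci_high`, `hub`), `dc_threshold`, `bc_threshold`, `ci_level`.
#' @export
summarize_over_participants <- function(dc, bc, ci_level = 0.95) {
  stopifnot(is.matrix(dc), is.matrix(bc), all(dim(dc) == dim(bc)))
  if (nrow(dc) < 2) stop("at least 2 participants are needed for a CI")
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  n <- nrow(dc)
  ci <- function(m) {
    mu <- colMeans(m)
    se <- apply(m, 2, stats::sd) / sqrt(n)
    list(mean = mu, low = mu - z * se, high = mu + z * se)
  }
  d <- ci(dc); b <- ci(bc)
  out <- structure(list(
    regions = data.frame(region = colnames(dc),
                         dc_mean = d$mean, dc_ci_low = d$low, dc_ci_high = d$high,
                         bc_mean = b$mean, bc_ci_low = b$low, bc_ci_high = b$high,
                         hub = NA),
    dc_threshold = hub_threshold(d$mean),
    bc_threshold = hub_threshold(b$mean),
    ci_level = ci_level
  ), class = "centrality_summary")
  out$regions$hub <- detect_hubs(out)
  out
}

#' Mean-plus-one-SD hub threshold
#'
#' @param x participant-averaged centrality values, one per region.
#' @return `mean(x) + sd(x)` (sample SD, denominator N-1).
#' @export
hub_threshold <- function(x) mean(x) + stats::sd(x)

#' Dual-threshold hub detection
#'
#' A region is a hub when its participant-averaged degree AND betweenness both
#' reach their network's mean-plus-one-SD thresholds. Comparisons are
#' inclusive (`>=`) at the precision of the input values, so a region exactly
#' on a threshold qualifies; under `policy = "strict"` it would not.
#'
#' @param summary a `centrality_summary` (or a list with `regions`,
#'   `dc_threshold`, `bc_threshold`).
#' @param policy `"inclusive"` (default) or `"strict"`.
#' @return Logical hub flags, one per region.
#' @export
detect_hubs <- function(summary, policy = c("inclusive", "strict")) {
  policy <- match.arg(policy)
  r <- summary$regions
  if (policy == "inclusive") {
    r$dc_mean >= summary$dc_threshold & r$bc_mean >= summary$bc_threshold
  } else {
    r$dc_mean > summary$dc_threshold & r$bc_mean > summary$bc_threshold
  }
}

#' Centrality summaries for every network in a stack
#'
#' @param stack a `connectivity_stack`.
#' @param labels named vector region -> network.
#' @param cfg a [pipeline_config] (edge-length rule, normalisation, CI level).
#' @return Named list of `centrality_summary`, one per network with >= 3
#'   regions.
#' @export
network_hubs <- function(stack, labels, cfg = pipeline_config()) {
  cents <- participant_centralities(stack, labels,
                                    edge_length_rule = cfg$edge_length_rule,
                                    normalized = cfg$bc_normalized)
  lapply(cents, function(x)
    summarize_over_participants(x$dc, x$bc, ci_level = cfg$ci_level))
}
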