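#' Per-participant mean correlation between two networks
#'
#' For each participant, the arithmetic mean of the Pearson correlations over
#' all (region in A) x (region in B) pairs.
#'
#' @param stack a `connectivity_stack`.
#' @param labels named vector (region -> network) covering all stack regions.
#' @param pair length-2 character vector of distinct network names.
#' @return Numeric vector, one value per participant.
#' @export
participant_pair_mean <- function(stack, labels, pair) {
  stopifnot(inherits(stack, "connectivity_stack"), length(pair) == 2,
            pair[1] != pair[2])
  if (!all(stack$region_ids %in% names(labels))) {
    stop("labels do not cover all stack regions")
  }
  lab <- labels[stack$region_ids]
  ia <- which(lab == pair[1]); ib <- which(lab == pair[2])
  if (length(ia) == 0 || length(ib) == 0) {
    stop("empty network: ", pair[which(c(length(ia), length(ib)) == 0)[1]])
  }
  vapply(stack$matrices, function(m) mean(m[ia, ib]), numeric(1))
}

#' Exact binomial sign test
#'
#' Tests whether values are positive more (or less) often than chance.
#' Exact zeros are dropped; with `m` remaining values and `X ~ Binomial(m,
#' 1/2)`, the two-sided p-value is `min(1, 2 * min(P(X <= n_neg),
#' P(X >= n_pos)))`.
#'
#' @param values per-participant values.
#' @return list with `n_pos`, `n_neg`, `n_zero`, `p`.
#' @export
sign_test <- function(values) {
  stopifnot(all(is.finite(values)))
  n_zero <- sum(values == 0)
  v <- values[values != 0]
  if (length(v) == 0) stop("all values exactly zero")
  n_pos <- sum(v > 0); n_neg <- sum(v < 0)
  m <- n_pos + n_neg
  # under p = 1/2 the two tails P(X <= n_neg) and P(X >= n_pos) coincide;
  # the smaller-count tail is summed by the multiplicative binomial
  # recurrence from 0.5^m, which keeps extreme p-values exact in floating
  # point (e.g. a 130/0 split gives exactly 2^-129)
  k_min <- min(n_pos, n_neg)
  term <- 0.5^m
  tail <- term
  if (k_min > 0) {
    for (k in seq_len(k_min)) {
      term <- term * (m - k + 1) / k
      tail <- tail + term
    }
  }
  p <- min(1, 2 * tail)
  list(n_pos = n_pos, n_neg = n_neg, n_zero = n_zero, p = p)
}

#' Bonferroni-adjusted level over network pairs
#'
#' @param n_networks number of networks (>= 2).
#' @param alpha_family family-wise error rate.
#' @return `alpha_family / choose(n_networks, 2)`.
#' @export
adjusted_alpha <- function(n_networks, alpha_family = 0.05) {
  stopifnot(n_networks >= 2)
  alpha_family / choose(n_networks, 2)
}

#' Inter-network coupling tests for all network pairs
#'
#' For every unordered pair of networks: the per-participant mean
#' cross-network correlation, its plain group mean (not Fisher-averaged, by
#' convention for this between-network summary), and the exact sign test,
#' flagged at the Bonferroni-adjusted level.
#'
#' @param stack a `connectivity_stack`.
#' @param labels named vector region -> network.
#' @param alpha_family family-wise error rate (default 0.05).
#' @return data.frame with one row per network pair: `network_a`, `network_b`,
#'   `group_r`, `n_pos`, `n_neg`, `n_zero`, `p`, `significant`; the adjusted
#'   level is attached as attribute `adjusted_alpha`.
#' @export
internetwork_tests <- function(stack, labels, alpha_family = 0.05) {
  nets <- sort(unique(labels[stack$region_ids]))
  stopifnot(length(nets) >= 2)
  level <- adjusted_alpha(length(nets), alpha_family)
  combs <- utils::combn(nets, 2)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    pair <- combs[, i]
    v <- participant_pair_mean(stack, labels, pair)
    st <- sign_test(v)
    data.frame(network_a = pair[1], network_b = pair[2],
               group_r = mean(v), n_pos = st$n_pos, n_neg = st$n_neg,
               n_zero = st$n_zero, p = st$p, significant = st$p < level)
  })
  out <- do.call(rbind, rows)
  attr(out, "adjusted_alpha") <- level
  out
}
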