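#' One-sample activation test for a region
#'
#' Tests whether a region's task contrast is nonzero on average across
#' participants: the one-sample t statistic of the mean against zero with its
#' two-sided p-value. Significant activation additionally requires `t > 0`
#' (see [conjunction_select()]).
#'
#' @param values per-participant contrast values (length >= 3, finite).
#' @return list with `t` and `p`.
#' @export
activation_test <- function(values) {
  stopifnot(length(values) >= 3, all(is.finite(values)))
  s <- stats::sd(values)
  if (s == 0) stop("zero variance across participants")
  n <- length(values)
  t <- mean(values) / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

#' Paired asymmetry test for a homotopic pair
#'
#' Paired t test on the left-minus-right differences; the sign of `t` encodes
#' the favored hemisphere (positive = left).
#'
#' @param left,right per-participant contrasts for the two hemispheres
#'   (paired, length >= 3).
#' @return list with `t` and `p`.
#' @export
asymmetry_test <- function(left, right) {
  stopifnot(length(left) == length(right))
  d <- left - right
  if (stats::sd(d) == 0 && all(d == 0)) return(list(t = 0, p = 1))
  activation_test(d)
}

# column-wise one-sample t: returns t and two-sided p per column
col_t_test <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  s <- sqrt(colSums((m - matrix(mu, n, ncol(m), byrow = TRUE))^2) / (n - 1))
  if (any(s == 0)) stop("zero variance across participants")
  t <- mu / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

#' Conjunction selection of lateralized regions
#'
#' A homotopic pair contributes (at most) one selected region: the hemisphere
#' favored by a significant asymmetry, provided that hemisphere is also
#' significantly activated with a positive mean. Each test is Bonferroni
#' corrected across pairs (`per_test_alpha = alpha_family / n_pairs`); because
#' selection requires both tests to pass, the overall level of the conjunction
#' is `per_test_alpha^2`. "Significant activation" is two-sided
#' `p < per_test_alpha` together with `t > 0` (a one-sided test at half the
#' level; set `one_sided = TRUE` to use the one-sided p directly instead).
#'
#' @param act data.frame with columns `pair_id`, `t_left`, `p_left`,
#'   `t_right`, `p_right` (per-hemisphere activation tests).
#' @param asym data.frame with columns `pair_id`, `t`, `p` (paired left-right
#'   asymmetry tests).
#' @param cfg a [pipeline_config]; `alpha_family` and `n_pairs` set the
#'   thresholds.
#' @param one_sided convention switch for the activation/asymmetry p-values.
#' @return data.frame with one row per pair (tests, `selected`, assigned
#'   `hemisphere`), with `per_test_alpha` and `conjunction_alpha` attributes.
#' @export
conjunction_select <- function(act, asym, cfg = pipeline_config(),
                               one_sided = FALSE) {
  if (!setequal(act$pair_id, asym$pair_id) ||
      length(act$pair_id) != length(asym$pair_id)) {
    stop("mismatched pair sets between activation and asymmetry tables")
  }
  asym <- asym[match(act$pair_id, asym$pair_id), ]
  alpha <- cfg$alpha_family / cfg$n_pairs
  halve <- function(p, t, favored) {
    if (!one_sided) return(p)
    ifelse(favored, p / 2, 1 - p / 2)
  }
  side_left <- asym$t > 0
  p_asym <- halve(asym$p, asym$t, TRUE)
  t_act <- ifelse(side_left, act$t_left, act$t_right)
  p_act <- ifelse(side_left, act$p_left, act$p_right)
  p_act <- halve(p_act, t_act, TRUE)
  selected <- (p_asym < alpha) & (p_act < alpha) & (t_act > 0) & (asym$t != 0)
  out <- data.frame(
    pair_id = act$pair_id,
    t_left = act$t_left, p_left = act$p_left,
    t_right = act$t_right, p_right = act$p_right,
    t_asym = asym$t, p_asym = asym$p,
    selected = selected,
    hemisphere = ifelse(selected, ifelse(side_left, "Left", "Right"),
                        NA_character_)
  )
  attr(out, "per_test_alpha") <- alpha
  attr(out, "conjunction_alpha") <- alpha^2
  out
}

#' Run the full selection stage on a contrast table
#'
#' Convenience wrapper: computes per-hemisphere activation tests and paired
#' asymmetry tests for every pair, then applies [conjunction_select()].
#'
#' @param ct a `contrast_table`.
#' @param cfg a [pipeline_config].
#' @param one_sided see [conjunction_select()].
#' @return The [conjunction_select()] result.
#' @export
select_regions <- function(ct, cfg = pipeline_config(), one_sided = FALSE) {
  tl <- col_t_test(ct$left)
  tr <- col_t_test(ct$right)
  ta <- col_t_test(ct$left - ct$right)
  act <- data.frame(pair_id = ct$pair_ids, t_left = tl$t, p_left = tl$p,
                    t_right = tr$t, p_right = tr$p)
  asym <- data.frame(pair_id = ct$pair_ids, t = ta$t, p = ta$p)
  conjunction_select(act, asym, cfg, one_sided = one_sided)
}
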