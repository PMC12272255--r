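#' Per-participant Pearson connectivity matrix
#'
#' @param ts regions-by-timepoints matrix for one participant (>= 3
#'   timepoints, no constant rows).
#' @return Symmetric regions-by-regions Pearson correlation matrix with unit
#'   diagonal.
#' @export
participant_correlation <- function(ts) {
  stopifnot(is.matrix(ts), ncol(ts) >= 3)
  sds <- apply(ts, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("constant time series for region(s): ",
         paste(rownames(ts)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(t(ts))
  diag(r) <- 1
  r
}

#' Bundle per-participant correlation matrices
#'
#' @param matrices list of symmetric correlation matrices sharing dimnames.
#' @param region_ids optional region ids; defaults to the first matrix's
#'   rownames.
#' @return A `connectivity_stack`.
#' @export
connectivity_stack <- function(matrices, region_ids = NULL) {
  stopifnot(length(matrices) >= 1)
  if (is.null(region_ids)) region_ids <- rownames(matrices[[1]])
  for (m in matrices) {
    stopifnot(is.matrix(m), nrow(m) == length(region_ids),
              isTRUE(all.equal(m, t(m))), all(abs(diag(m) - 1) < 1e-12),
              all(m >= -1 - 1e-12 & m <= 1 + 1e-12))
  }
  structure(list(matrices = matrices, region_ids = region_ids),
            class = "connectivity_stack")
}

#' Correlation stack for a whole time-series panel
#'
#' @param panel a `ts_panel` from [simulate_rest_timeseries()].
#' @param regions optional subset of region ids to keep.
#' @return A [connectivity_stack()].
#' @export
panel_connectivity <- function(panel, regions = NULL) {
  if (is.null(regions)) regions <- panel$region_ids
  mats <- lapply(panel$series, function(x)
    participant_correlation(x[regions, , drop = FALSE]))
  connectivity_stack(mats, regions)
}

#' Fisher-z group average of a connectivity stack
#'
#' Correlations are variance-stabilised with the inverse hyperbolic tangent,
#' averaged entrywise across participants, and mapped back with the
#' hyperbolic tangent. The diagonal is set to 1.
#'
#' @param stack a `connectivity_stack` with all off-diagonal |r| < 1.
#' @return The group correlation matrix.
#' @export
fisher_group_average <- function(stack) {
  stopifnot(inherits(stack, "connectivity_stack"))
  for (i in seq_along(stack$matrices)) {
    m <- stack$matrices[[i]]
    off <- abs(m) >= 1
    diag(off) <- FALSE
    if (any(off)) {
      idx <- which(off, arr.ind = TRUE)[1, ]
      stop(sprintf("|r| = 1 for pair (%s, %s) in participant %d: Fisher z is infinite",
                   stack$region_ids[idx[1]], stack$region_ids[idx[2]], i))
    }
  }
  z <- Reduce(`+`, lapply(stack$matrices, atanh)) / length(stack$matrices)
  g <- tanh(z)
  diag(g) <- 1
  dimnames(g) <- list(stack$region_ids, stack$region_ids)
  g
}

#' Convert a correlation matrix to a clustering dissimilarity
#'
#' The default maps r = 1 to 0, r = 0 to sqrt(1/2) and r = -1 to 1 via
#' `d = sqrt((1 - r) / 2)`, a strictly decreasing map of `[-1, 1]` onto
#' `[1, 0]` consistent with the lateralized-atlas methodology this analysis
#' follows. The alternative `"one_minus_r2"` (`d = 1 - r^2`) is provided as a
#' documented switch; note it is not monotone in r (it treats correlation and
#' anticorrelation as equally similar).
#'
#' @param r_matrix correlation matrix with entries in `[-1, 1]`.
#' @param method `"sqrt_half"` (default) or `"one_minus_r2"`.
#' @return Symmetric nonnegative dissimilarity matrix with zero diagonal.
#' @export
correlation_to_dissimilarity <- function(r_matrix,
                                         method = c("sqrt_half", "one_minus_r2")) {
  method <- match.arg(method)
  if (any(r_matrix < -1 - 1e-12 | r_matrix > 1 + 1e-12)) {
    stop("correlations outside [-1, 1]")
  }
  r_matrix <- pmin(pmax(r_matrix, -1), 1)
  d <- switch(method,
              sqrt_half = sqrt((1 - r_matrix) / 2),
              one_minus_r2 = 1 - r_matrix^2)
  diag(d) <- 0
  d
}

#' Write / read a square matrix as TSV with ids on both margins
#'
#' @param m square matrix with dimnames.
#' @param path file path.
#' @return `path` invisibly (writer); the matrix (reader).
#' @export
write_square_matrix <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_square_matrix
#' @export
read_square_matrix <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  m
}
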