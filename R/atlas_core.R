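#' @keywords internal
"_PACKAGE"

HEMISPHERES <- c("Left", "Right")
NETWORKS <- c("Visu", "Somato-motor", "Posterior-medial",
              "Temporo-frontal", "Parieto-frontal")

#' Construct a validated region set
#'
#' A region set is an ordered table of atlas regions, one row per region, with
#' a hemisphere label, an optional intrinsic-network label and the MNI
#' coordinates (mm) of the region's center of mass. The pair
#' (abbreviation, hemisphere) must be unique.
#'
#' @param df data.frame with columns `network`, `abbreviation`, `region`,
#'   `hemisphere`, `x`, `y`, `z`. `network` may be `NA` for regions not (yet)
#'   assigned to a network.
#' @param provenance free-text note on where the table came from.
#' @return An object of class `region_set`: the validated data.frame with a
#'   `provenance` attribute.
#' @export
region_set <- function(df, provenance = "") {
  required <- c("network", "abbreviation", "region", "hemisphere", "x", "y", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("region table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[required]
  if (nrow(df) == 0L) stop("no regions")
  df$network <- as.character(df$network)
  df$abbreviation <- as.character(df$abbreviation)
  df$region <- as.character(df$region)
  df$hemisphere <- as.character(df$hemisphere)
  bad_hemi <- setdiff(unique(df$hemisphere), HEMISPHERES)
  if (length(bad_hemi) > 0L) {
    stop("unknown hemisphere label(s): ", paste(bad_hemi, collapse = ", "))
  }
  bad_net <- setdiff(unique(df$network[!is.na(df$network)]), NETWORKS)
  if (length(bad_net) > 0L) {
    stop("unknown network label(s): ", paste(bad_net, collapse = ", "))
  }
  for (cc in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) stop("non-numeric ", cc, " coordinate")
    df[[cc]] <- v
  }
  key <- paste(df$abbreviation, df$hemisphere, sep = "|")
  if (anyDuplicated(key)) {
    stop("duplicate (abbreviation, hemisphere): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance, class = c("region_set", "data.frame"))
}

#' Read a region table from a TSV file
#'
#' The dialect is tab-separated UTF-8 with a single header row and the literal
#' token `NA` for an unassigned network.
#'
#' @param path path to the TSV file.
#' @return A [region_set].
#' @export
load_region_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = "NA",
                          fileEncoding = "UTF-8", check.names = FALSE)
  region_set(df, provenance = path)
}

#' Write a region table to a TSV file
#'
#' Inverse of [load_region_table()]: `load_region_table(write_region_table(rs))`
#' reproduces `rs` field for field. Unassigned networks are written as `NA`.
#'
#' @param rs a [region_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(rs, path) {
  stopifnot(inherits(rs, "region_set"))
  utils::write.table(as.data.frame(rs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged 95-region lateralized atlas table
#'
#' Returns the atlas table shipped with the package: 95 regions showing joint
#' activation and asymmetry during a line bisection judgment task (66 right-,
#' 29 left-hemispheric), each with its final intrinsic-network assignment and
#' MNI center-of-mass coordinates in mm.
#'
#' @return A [region_set] of 95 regions.
#' @export
alans_regions <- function() {
  load_region_table(system.file("extdata", "alans_regions.tsv",
                                package = "alans", mustWork = TRUE))
}

#' Count regions by hemisphere and by network
#'
#' @param rs a [region_set].
#' @return A list with `n_total`, `by_hemisphere` (named integer vector) and
#'   `by_network` (named integer vector; unassigned regions counted under
#'   `"unassigned"`). Both breakdowns sum to `n_total`.
#' @export
summarize_region_set <- function(rs) {
  stopifnot(inherits(rs, "region_set"))
  net <- ifelse(is.na(rs$network), "unassigned", rs$network)
  list(
    n_total = nrow(rs),
    by_hemisphere = table(factor(rs$hemisphere, levels = HEMISPHERES)),
    by_network = table(net)
  )
}

#' Analysis-level configuration
#'
#' Bundles the knobs shared across pipeline stages.
#'
#' @param alpha_family family-wise error rate for each Bonferroni family
#'   (default 0.05).
#' @param n_pairs number of homotopic region pairs tested (default 185).
#' @param k_range candidate cluster counts for the optimal-k vote.
#' @param ci_level confidence level for centrality confidence intervals.
#' @param bc_normalized logical; divide betweenness by (N-1)(N-2)?
#' @param edge_length_rule `"reciprocal"` (shortest paths minimise the sum of
#'   1/r) or `"one_minus_r"` (minimise the sum of 1-r).
#' @param rng_seed integer seed from which all stage seeds are derived.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha_family = 0.05, n_pairs = 185L,
                            k_range = 2:10, ci_level = 0.95,
                            bc_normalized = FALSE,
                            edge_length_rule = c("reciprocal", "one_minus_r"),
                            rng_seed = 1L) {
  edge_length_rule <- match.arg(edge_length_rule)
  stopifnot(alpha_family > 0, alpha_family < 1, n_pairs >= 1,
            length(k_range) >= 1, all(k_range >= 2),
            ci_level > 0, ci_level < 1)
  structure(list(alpha_family = alpha_family, n_pairs = as.integer(n_pairs),
                 k_range = as.integer(k_range), ci_level = ci_level,
                 bc_normalized = isTRUE(bc_normalized),
                 edge_length_rule = edge_length_rule,
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

# one-line stage log to stderr
log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste(sprintf("%s", c(...)), collapse = " ")))
}
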