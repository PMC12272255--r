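#' Run the full atlas-construction pipeline on a synthetic cohort
#'
#' Stages: simulate the cohort, select lateralized regions by the conjunction
#' rule, build per-participant connectivity over the selected regions, Fisher
#' average and convert to a dissimilarity, cluster with Ward linkage and the
#' multi-index k vote, test inter-network coupling with sign tests, and
#' summarise per-network centralities with hub detection. Every stage's table
#' is written under its own subdirectory of `out_dir`, and a manifest with
#' file digests and the seed allows byte-exact replay.
#'
#' Selected regions without a simulated resting series (false positives of
#' the conjunction on unplanted pairs) are dropped from the connectivity
#' stages with a log line.
#'
#' @param cohort a [cohort_config] (its `rng_seed` drives all randomness).
#' @param cfg a [pipeline_config].
#' @param out_dir run directory; created if needed. NULL keeps everything in
#'   memory only.
#' @return Invisibly, a list with `selection`, `group_r`, `dissimilarity`,
#'   `clusters`, `internetwork`, `hubs`, `manifest`.
#' @export
run_pipeline <- function(cohort, cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"))
  persist <- !is.null(out_dir)
  stage_dir <- function(name) {
    d <- file.path(out_dir, name)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    d
  }
  files <- character(0)
  keep <- function(path) { files <<- c(files, path); path }

  log_stage("simulate", "participants:", cohort$n_participants,
            "pairs:", cohort$n_pairs)
  ct <- simulate_contrasts(cohort)
  panel <- simulate_rest_timeseries(cohort)
  if (persist) {
    keep(write_contrast_table(ct, file.path(stage_dir("01_simulate"),
                                            "contrasts.tsv")))
  }

  log_stage("select", "alpha:", cfg$alpha_family, "n_pairs:", cfg$n_pairs)
  sel <- select_regions(ct, cfg)
  selected <- sel$pair_id[sel$selected]
  log_stage("select", "selected:", length(selected))
  if (persist) {
    p <- file.path(stage_dir("02_select"), "selection.tsv")
    utils::write.table(sel, p, sep = "\t", quote = FALSE, row.names = FALSE)
    keep(p)
    meta <- file.path(stage_dir("02_select"), "thresholds.tsv")
    utils::write.table(
      data.frame(per_test_alpha = attr(sel, "per_test_alpha"),
                 conjunction_alpha = attr(sel, "conjunction_alpha")),
      meta, sep = "\t", quote = FALSE, row.names = FALSE)
    keep(meta)
  }

  usable <- intersect(selected, panel$region_ids)
  if (length(usable) < length(selected)) {
    log_stage("connect", "dropping", length(selected) - length(usable),
              "selected region(s) without resting series")
  }
  log_stage("connect", "regions:", length(usable))
  stack <- panel_connectivity(panel, usable)
  group_r <- fisher_group_average(stack)
  d <- correlation_to_dissimilarity(group_r)
  if (persist) {
    keep(write_square_matrix(group_r,
                             file.path(stage_dir("03_connect"), "group_r.tsv")))
    keep(write_square_matrix(d, file.path(stage_dir("03_connect"),
                                          "dissimilarity.tsv")))
  }

  log_stage("cluster", "k range:", paste(range(cfg$k_range), collapse = "-"))
  cl <- cluster_regions(d, cfg$k_range)
  log_stage("cluster", "k*:", cl$k)
  net_labels <- paste0("C", cl$labels)
  names(net_labels) <- names(cl$labels)
  if (persist) {
    p <- file.path(stage_dir("04_cluster"), "labels.tsv")
    utils::write.table(data.frame(region = names(cl$labels),
                                  cluster = cl$labels),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    keep(p)
    p <- file.path(stage_dir("04_cluster"), "index_votes.tsv")
    utils::write.table(data.frame(index = names(cl$votes), k = cl$votes),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    keep(p)
    p <- file.path(stage_dir("04_cluster"), "merge_tree.tsv")
    utils::write.table(data.frame(step = seq_len(nrow(cl$tree$merge)),
                                  left = cl$tree$merge[, 1],
                                  right = cl$tree$merge[, 2],
                                  height = cl$tree$height),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    keep(p)
  }

  log_stage("netcorr", "networks:", cl$k)
  nets <- internetwork_tests(stack, net_labels, cfg$alpha_family)
  if (persist) {
    p <- file.path(stage_dir("05_netcorr"), "network_pairs.tsv")
    utils::write.table(nets, p, sep = "\t", quote = FALSE, row.names = FALSE)
    keep(p)
  }

  log_stage("hubs", "edge length:", cfg$edge_length_rule)
  hubs <- network_hubs(stack, net_labels, cfg)
  if (persist) {
    d6 <- stage_dir("06_hubs")
    for (net in names(hubs)) {
      p <- file.path(d6, paste0("centrality_", net, ".tsv"))
      utils::write.table(hubs[[net]]$regions, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      keep(p)
    }
    p <- file.path(d6, "thresholds.tsv")
    utils::write.table(
      data.frame(network = names(hubs),
                 dc_threshold = vapply(hubs, `[[`, numeric(1), "dc_threshold"),
                 bc_threshold = vapply(hubs, `[[`, numeric(1), "bc_threshold")),
      p, sep = "\t", quote = FALSE, row.names = FALSE)
    keep(p)
  }

  manifest <- list(
    seed = cohort$rng_seed,
    version = as.character(utils::packageVersion("alans")),
    config = list(alpha_family = cfg$alpha_family, n_pairs = cfg$n_pairs,
                  k_range = cfg$k_range, ci_level = cfg$ci_level,
                  edge_length_rule = cfg$edge_length_rule,
                  bc_normalized = cfg$bc_normalized),
    cohort = list(n_participants = cohort$n_participants,
                  n_pairs = cohort$n_pairs,
                  n_timepoints = cohort$n_timepoints),
    files = if (persist) {
      as.list(stats::setNames(as.character(tools::md5sum(files)),
                              sub(paste0("^", out_dir, "/?"), "", files)))
    } else list()
  )
  if (persist) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(selection = sel, group_r = group_r, dissimilarity = d,
                 clusters = cl, internetwork = nets, hubs = hubs,
                 manifest = manifest))
}

#' Verify a run directory against its manifest
#'
#' Recomputes the digest of every file listed in the manifest and reports
#' which match.
#'
#' @param run_dir a directory produced by [run_pipeline()].
#' @return data.frame with `file`, `expected`, `actual`, `match`; attribute
#'   `ok` is TRUE when everything matches.
#' @export
replay <- function(run_dir) {
  mf_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(mf_path)) stop("manifest not found: ", mf_path)
  manifest <- jsonlite::read_json(mf_path)
  files <- names(manifest$files)
  missing <- files[!file.exists(file.path(run_dir, files))]
  if (length(missing) > 0) {
    stop("missing run file(s): ", paste(missing, collapse = ", "))
  }
  actual <- as.character(tools::md5sum(file.path(run_dir, files)))
  expected <- unlist(manifest$files, use.names = FALSE)
  out <- data.frame(file = files, expected = expected, actual = actual,
                    match = expected == actual)
  attr(out, "ok") <- all(out$match)
  out
}

#' Reported network-level centrality summary
#'
#' The published network-level mean and SD of the participant-averaged degree
#' and betweenness centralities, transcribed as a packaged fixture so the
#' threshold and hub rules can be exercised against reported numbers.
#'
#' @return data.frame: `network`, `dc_mean`, `dc_sd`, `bc_mean`, `bc_sd`.
#' @export
reported_network_centrality <- function() {
  utils::read.delim(system.file("extdata", "reported_network_centrality.tsv",
                                package = "alans", mustWork = TRUE))
}

#' Reported per-region centrality values
#'
#' The published participant-averaged DC/BC values (with 95% CIs) for the
#' regions reported individually — the hub candidates of each network.
#'
#' @return data.frame: `abbreviation`, `network`, `dc_mean`, `dc_ci_low`,
#'   `dc_ci_high`, `bc_mean`, `bc_ci_low`, `bc_ci_high`.
#' @export
reported_region_centrality <- function() {
  utils::read.delim(system.file("extdata", "reported_region_centrality.tsv",
                                package = "alans", mustWork = TRUE))
}
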