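#' Zero-phase band-pass filter for fMRI-like series
#'
#' Applies the squared magnitude response of an analog Butterworth band-pass
#' filter in the frequency domain. Using the squared magnitude makes the
#' operation zero-phase (the same attenuation a forward-backward filter pass
#' would give); the default order 4 therefore attenuates at an effective
#' 8th-order roll-off.
#'
#' @param x numeric vector, or matrix with one series per column (time runs
#'   down the rows).
#' @param tr sampling interval in seconds.
#' @param band length-2 passband in Hz, low then high.
#' @param order Butterworth order of each (low/high) edge, default 4.
#' @return Filtered vector/matrix of the same shape.
#' @export
bandpass_filter <- function(x, tr = 2, band = c(0.01, 0.1), order = 4L) {
  stopifnot(length(band) == 2L, band[1] > 0, band[2] > band[1],
            band[2] <= 1 / (2 * tr))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  f <- (seq_len(n) - 1L) / (n * tr)
  f <- pmin(f, 1 / tr - f)  # fold to the one-sided spectrum
  hp <- (f / band[1])^(2L * order) / (1 + (f / band[1])^(2L * order))
  lp <- 1 / (1 + (f / band[2])^(2L * order))
  h2 <- hp * lp
  y <- Re(stats::mvfft(stats::mvfft(x) * h2, inverse = TRUE)) / n
  if (vec) drop(y) else y
}

# band-limited unit-variance columns (time x k)
bandlimited_noise <- function(n_time, k, tr, band, order) {
  z <- bandpass_filter(matrix(stats::rnorm(n_time * k), n_time, k),
                       tr = tr, band = band, order = order)
  scale(z, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Synthetic cohort configuration
#'
#' Describes a simulated study: how many participants and homotopic region
#' pairs, which pairs carry planted activation/asymmetry effects (and on which
#' side), and the block-modular structure of the resting-state series —
#' modules of regions sharing a band-limited latent signal, signed
#' inter-module correlation targets, and designated connector-hub regions.
#'
#' Effects are expressed in units of the contrast noise SD. Inter-module
#' targets are *region-level* expected correlations; the generator compensates
#' internally for the attenuation caused by region noise, so a target of 0.37
#' yields region pairs correlating near 0.37 on average. A hub region loads on
#' its own module with gain `hub_gain` and on a second, partner module with
#' loading `hub_cross`, which both elevates its within-network centrality and
#' couples it to the partner network.
#'
#' @param n_participants cohort size (default 130).
#' @param n_pairs number of homotopic pairs in the task table (default 185).
#' @param pair_ids optional character ids, length `n_pairs`.
#' @param planted data.frame with columns `pair_id` and `hemisphere`
#'   (`"Left"`/`"Right"`, the favored side), or NULL for a pure-null cohort.
#' @param activation_effect mean bilateral contrast of planted pairs, in
#'   noise-SD units.
#' @param asymmetry_effect mean favored-minus-other difference; split as
#'   +/- `asymmetry_effect`/2 around the activation mean so the pair mean stays
#'   equal to `activation_effect`.
#' @param module_spec named list: module name -> character vector of member
#'   region ids (disjoint across modules).
#' @param between_module_r data.frame (`module_a`, `module_b`, `r`) of signed
#'   region-level correlation targets; unlisted module pairs default to 0.
#' @param within_module_r expected correlation between two ordinary members of
#'   the same module (same sub-community when substructure is enabled;
#'   default 0.7).
#' @param module_substructure_r NULL for homogeneous modules (a single latent
#'   factor each), or the latent correlation between the two sub-community
#'   factors of every module. With substructure, members of the same module
#'   but different sub-communities correlate at
#'   `within_module_r * module_substructure_r`, which gives the
#'   within-network heterogeneity real data show and makes betweenness
#'   non-degenerate: connector hubs bridge the two sub-communities.
#' @param hub_spec data.frame (`region`, `partner_module`) of connector hubs,
#'   or NULL.
#' @param hub_gain own-module loading gain for hub regions (default 3).
#' @param hub_cross partner-module loading for hub regions (default 0.5).
#' @param n_timepoints rest volumes per participant (default 240).
#' @param tr_seconds repetition time in seconds (default 2).
#' @param band passband in Hz (default 0.01-0.1).
#' @param filter_order Butterworth order (default 4).
#' @param excluded_pairs integer indices of pairs masked from the contrast
#'   table (emulating susceptibility-artifact exclusions).
#' @param rng_seed integer seed; identical configs give identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 130L, n_pairs = 185L,
                          pair_ids = NULL, planted = NULL,
                          activation_effect = 1.5, asymmetry_effect = 1.0,
                          module_spec = NULL, between_module_r = NULL,
                          within_module_r = 0.7, module_substructure_r = NULL,
                          hub_spec = NULL,
                          hub_gain = 3, hub_cross = 0.5,
                          n_timepoints = 240L, tr_seconds = 2,
                          band = c(0.01, 0.1), filter_order = 4L,
                          excluded_pairs = integer(0), rng_seed = 1L) {
  stopifnot(n_participants >= 2, n_pairs >= 1, n_timepoints >= 8,
            tr_seconds > 0, within_module_r > 0, within_module_r <= 1)
  if (is.null(pair_ids)) pair_ids <- sprintf("pair%03d", seq_len(n_pairs))
  stopifnot(length(pair_ids) == n_pairs, !anyDuplicated(pair_ids))
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    stopifnot(all(c("pair_id", "hemisphere") %in% names(planted)))
    bad <- setdiff(planted$pair_id, pair_ids)
    if (length(bad) > 0L) stop("planted pair(s) not in pair_ids: ",
                               paste(bad, collapse = ", "))
    stopifnot(all(planted$hemisphere %in% c("Left", "Right")))
    if (!is.finite(activation_effect) || !is.finite(asymmetry_effect)) {
      stop("invalid effect sizes")
    }
  }
  if (!is.null(module_spec)) {
    stopifnot(is.list(module_spec), !is.null(names(module_spec)))
    members <- unlist(module_spec, use.names = FALSE)
    if (anyDuplicated(members)) stop("module memberships must be disjoint")
  }
  if (!is.null(between_module_r)) {
    between_module_r <- as.data.frame(between_module_r)
    stopifnot(all(c("module_a", "module_b", "r") %in% names(between_module_r)))
    if (is.null(module_spec)) stop("between_module_r requires module_spec")
    known <- names(module_spec)
    stopifnot(all(between_module_r$module_a %in% known),
              all(between_module_r$module_b %in% known))
    if (any(abs(between_module_r$r) >= within_module_r)) {
      stop("|between_module_r| must be below within_module_r ",
           "(region-level targets cannot exceed within-module coherence)")
    }
    sizes <- lengths(module_spec)
    if (any(sizes < 2L)) {
      stop("module with < 2 members while between-module targets are set")
    }
  }
  if (!is.null(hub_spec)) {
    hub_spec <- as.data.frame(hub_spec)
    stopifnot(all(c("region", "partner_module") %in% names(hub_spec)))
    if (is.null(module_spec)) stop("hub_spec requires module_spec")
    members <- unlist(module_spec, use.names = FALSE)
    stopifnot(all(hub_spec$region %in% members),
              all(hub_spec$partner_module %in% names(module_spec)))
  }
  if (!is.null(module_substructure_r)) {
    stopifnot(module_substructure_r > 0, module_substructure_r < 1)
  }
  stopifnot(all(excluded_pairs %in% seq_len(n_pairs)))
  structure(list(
    n_participants = as.integer(n_participants), n_pairs = as.integer(n_pairs),
    pair_ids = pair_ids, planted = planted,
    activation_effect = activation_effect, asymmetry_effect = asymmetry_effect,
    module_spec = module_spec, between_module_r = between_module_r,
    within_module_r = within_module_r,
    module_substructure_r = module_substructure_r, hub_spec = hub_spec,
    hub_gain = hub_gain, hub_cross = hub_cross,
    n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
    band = band, filter_order = as.integer(filter_order),
    excluded_pairs = as.integer(excluded_pairs), rng_seed = as.integer(rng_seed)
  ), class = "cohort_config")
}

#' Demo cohort at the reference study's dimensions
#'
#' A ready-made configuration emulating the study conditions the analysis was
#' designed for: 130 participants, 185 homotopic pairs of which the packaged
#' 95 atlas regions are planted as lateralized (66 right-, 29 left-favored),
#' resting series of 240 volumes at TR = 2 s band-limited to 0.01-0.1 Hz,
#' five modules matching the atlas networks (sizes 12/25/23/20/15), signed
#' inter-module correlation targets matching the reported inter-network
#' couplings, and one planted connector hub per non-visual network.
#'
#' @param rng_seed integer seed.
#' @return A [cohort_config].
#' @export
demo_cohort_config <- function(rng_seed = 1L) {
  rs <- alans_regions()
  n_filler <- 185L - nrow(rs)
  pair_ids <- c(rs$abbreviation, sprintf("u%03d", seq_len(n_filler)))
  planted <- data.frame(pair_id = rs$abbreviation, hemisphere = rs$hemisphere)
  module_spec <- split(rs$abbreviation, rs$network)[NETWORKS]
  between <- data.frame(
    module_a = c("Somato-motor", "Parieto-frontal", "Temporo-frontal",
                 "Temporo-frontal", "Parieto-frontal", "Parieto-frontal",
                 "Posterior-medial", "Posterior-medial"),
    module_b = c("Visu", "Temporo-frontal", "Somato-motor", "Visu",
                 "Somato-motor", "Visu", "Visu", "Temporo-frontal"),
    r = c(0.37, 0.29, 0.25, 0.14, -0.11, -0.18, 0.11, -0.07)
  )
  hubs <- data.frame(
    region = c("f2_2", "F3t", "PRECU1", "post2"),
    partner_module = c("Temporo-frontal", "Parieto-frontal", "Visu", "Visu")
  )
  cohort_config(n_participants = 130L, n_pairs = 185L, pair_ids = pair_ids,
                planted = planted, activation_effect = 1.5,
                asymmetry_effect = 1.0, module_spec = module_spec,
                between_module_r = between, within_module_r = 0.8,
                module_substructure_r = 0.8,
                hub_spec = hubs, n_timepoints = 240L, tr_seconds = 2,
                band = c(0.01, 0.1), rng_seed = rng_seed)
}

#' Simulate a task-contrast table
#'
#' Every (participant, pair) gets a left and a right contrast value drawn with
#' unit noise SD. Unplanted pairs are zero-mean noise. A planted pair has mean
#' `activation_effect` on both sides, plus `asymmetry_effect/2` added on the
#' favored side and subtracted on the other, so the pair mean equals the
#' activation effect and the favored-minus-other difference has mean
#' `asymmetry_effect`.
#'
#' @param cfg a [cohort_config].
#' @return A `contrast_table`: list with `left` and `right` participant-by-pair
#'   matrices, `participant_ids`, `pair_ids`. Pairs listed in
#'   `cfg$excluded_pairs` are dropped.
#' @export
simulate_contrasts <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  set.seed(cfg$rng_seed)
  P <- cfg$n_participants; K <- cfg$n_pairs
  mu_left <- mu_right <- numeric(K)
  names(mu_left) <- names(mu_right) <- cfg$pair_ids
  if (!is.null(cfg$planted)) {
    for (i in seq_len(nrow(cfg$planted))) {
      id <- cfg$planted$pair_id[i]
      half <- cfg$asymmetry_effect / 2
      if (cfg$planted$hemisphere[i] == "Left") {
        mu_left[id] <- cfg$activation_effect + half
        mu_right[id] <- cfg$activation_effect - half
      } else {
        mu_left[id] <- cfg$activation_effect - half
        mu_right[id] <- cfg$activation_effect + half
      }
    }
  }
  left <- matrix(stats::rnorm(P * K), P, K) +
    matrix(mu_left, P, K, byrow = TRUE)
  right <- matrix(stats::rnorm(P * K), P, K) +
    matrix(mu_right, P, K, byrow = TRUE)
  participant_ids <- sprintf("P%03d", seq_len(P))
  dimnames(left) <- dimnames(right) <- list(participant_ids, cfg$pair_ids)
  keep <- setdiff(seq_len(K), cfg$excluded_pairs)
  structure(list(left = left[, keep, drop = FALSE],
                 right = right[, keep, drop = FALSE],
                 participant_ids = participant_ids,
                 pair_ids = cfg$pair_ids[keep]),
            class = "contrast_table")
}

# region-level inter-module targets -> correlation matrix of the latent
# factors (one per module, or two sub-community factors per module when
# substructure is enabled). `rho` gives each module's sub-community
# integration, recycled over modules.
latent_correlation <- function(cfg, rho = cfg$module_substructure_r) {
  mods <- names(cfg$module_spec)
  nf <- if (is.null(cfg$module_substructure_r)) 1L else 2L
  fac_mod <- rep(mods, each = nf)
  rho <- if (is.null(rho)) numeric(length(mods)) else
    rep_len(rho, length(mods))
  names(rho) <- mods
  K <- length(fac_mod)
  C <- diag(K); dimnames(C) <- list(NULL, NULL)
  between <- matrix(0, length(mods), length(mods),
                    dimnames = list(mods, mods))
  if (!is.null(cfg$between_module_r)) {
    for (i in seq_len(nrow(cfg$between_module_r))) {
      a <- cfg$between_module_r$module_a[i]
      b <- cfg$between_module_r$module_b[i]
      between[a, b] <- between[b, a] <-
        cfg$between_module_r$r[i] / cfg$within_module_r
    }
  }
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    C[i, j] <- if (fac_mod[i] == fac_mod[j]) rho[fac_mod[i]]
               else between[fac_mod[i], fac_mod[j]]
  }
  ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 1e-10) stop("between-module targets give a non-positive-definite ",
                        "latent correlation matrix")
  attr(C, "factor_module") <- fac_mod
  C
}

#' Simulate resting-state time series
#'
#' Per participant, each module has one band-limited latent signal; module
#' latents are correlated according to the (attenuation-compensated)
#' inter-module targets. An ordinary member of module m is
#' `sqrt(w)*latent_m + sqrt(1-w)*noise` with `w = within_module_r`, so two
#' members of one module correlate at about `w` and members of different
#' modules at about the requested region-level target. A hub region instead
#' loads `hub_gain*sqrt(w)` on its own latent and `hub_cross` on its partner
#' module's latent (same noise SD), raising its within-network degree and
#' betweenness and its coupling to the partner network. Latents and noise are
#' both band-pass filtered.
#'
#' @param cfg a [cohort_config] with a non-NULL `module_spec`.
#' @return A `ts_panel`: list with `series` (one regions-by-timepoints matrix
#'   per participant), `region_ids`, `participant_ids`, `tr`, `band`.
#' @export
simulate_rest_timeseries <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (is.null(cfg$module_spec)) stop("module_spec is required")
  set.seed(cfg$rng_seed + 1L)  # independent stream from the contrast stage
  mods <- names(cfg$module_spec)
  regions <- unlist(cfg$module_spec, use.names = FALSE)
  mod_of <- rep(mods, lengths(cfg$module_spec))
  names(mod_of) <- regions
  R <- length(regions); Tn <- cfg$n_timepoints
  C <- latent_correlation(cfg)
  fac_mod <- attr(C, "factor_module")
  a <- sqrt(cfg$within_module_r)
  s <- sqrt(1 - cfg$within_module_r)
  rho <- cfg$module_substructure_r
  # per-region loading matrix onto the latent factors; with substructure the
  # first half of a module's members loads on its first factor, the second
  # half on the second
  L <- matrix(0, R, nrow(C), dimnames = list(regions, NULL))
  for (m in mods) {
    members <- cfg$module_spec[[m]]
    fcols <- which(fac_mod == m)
    if (length(fcols) == 1L) {
      L[members, fcols] <- a
    } else {
      first <- seq_len(ceiling(length(members) / 2))
      L[members[first], fcols[1]] <- a
      L[members[-first], fcols[2]] <- a
    }
  }
  if (!is.null(cfg$hub_spec)) {
    for (i in seq_len(nrow(cfg$hub_spec))) {
      h <- cfg$hub_spec$region[i]
      own <- which(fac_mod == mod_of[h])
      # equal loadings on every factor of the own module, scaled so the
      # factor-driven variance is (hub_gain * a)^2
      cc <- if (length(own) == 1L) cfg$hub_gain * a
            else cfg$hub_gain * a / sqrt(2 * (1 + rho))
      L[h, own] <- cc
      partner <- which(fac_mod == cfg$hub_spec$partner_module[i])[1]
      L[h, partner] <- L[h, partner] + cfg$hub_cross
    }
  }
  participant_ids <- sprintf("P%03d", seq_len(cfg$n_participants))
  series <- vector("list", cfg$n_participants)
  names(series) <- participant_ids
  # sub-community integration fluctuates across participants around its mean
  # (uniform, capped below near-unity), so per-participant graphs carry the
  # bridge structure that group-average coherence smooths over
  subst <- cfg$module_substructure_r
  for (p in seq_len(cfg$n_participants)) {
    C_p <- if (is.null(subst)) C else {
      hi <- 0.98
      lo <- max(0.02, 2 * subst - hi)
      latent_correlation(cfg, rho = stats::runif(length(mods), lo, hi))
    }
    f <- bandlimited_noise(Tn, nrow(C_p), cfg$tr_seconds, cfg$band,
                           cfg$filter_order) %*% chol(C_p)
    e <- bandlimited_noise(Tn, R, cfg$tr_seconds, cfg$band, cfg$filter_order)
    x <- f %*% t(L) + e * s          # time x regions
    series[[p]] <- t(x)
    rownames(series[[p]]) <- regions
  }
  structure(list(series = series, region_ids = regions,
                 participant_ids = participant_ids,
                 tr = cfg$tr_seconds, band = cfg$band),
            class = "ts_panel")
}

#' Ground truth implied by a cohort configuration
#'
#' @param cfg a [cohort_config].
#' @return A list with `selected_regions` (data.frame `pair_id`, `hemisphere`:
#'   one region per planted pair, on the side flagged by the planted
#'   asymmetry), `module_labels` (named character vector region -> module) and
#'   `hub_regions` (character vector).
#' @export
planted_truth <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  selected <- if (is.null(cfg$planted)) {
    data.frame(pair_id = character(0), hemisphere = character(0))
  } else {
    cfg$planted[c("pair_id", "hemisphere")]
  }
  labels <- character(0)
  if (!is.null(cfg$module_spec)) {
    labels <- rep(names(cfg$module_spec), lengths(cfg$module_spec))
    names(labels) <- unlist(cfg$module_spec, use.names = FALSE)
  }
  hubs <- if (is.null(cfg$hub_spec)) character(0) else cfg$hub_spec$region
  list(selected_regions = selected, module_labels = labels,
       hub_regions = hubs)
}

#' Write / read a contrast table as long-format TSV
#'
#' Columns: participant, pair_id, hemisphere, value.
#'
#' @param ct a `contrast_table`.
#' @param path output path.
#' @return `path` invisibly (writer); a `contrast_table` (reader).
#' @export
write_contrast_table <- function(ct, path) {
  long <- rbind(
    data.frame(participant = rep(ct$participant_ids, times = length(ct$pair_ids)),
               pair_id = rep(ct$pair_ids, each = length(ct$participant_ids)),
               hemisphere = "Left", value = as.vector(ct$left)),
    data.frame(participant = rep(ct$participant_ids, times = length(ct$pair_ids)),
               pair_id = rep(ct$pair_ids, each = length(ct$participant_ids)),
               hemisphere = "Right", value = as.vector(ct$right))
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contrast_table
#' @export
read_contrast_table <- function(path) {
  long <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = c("character", "character",
                                           "character", "numeric"))
  participants <- unique(long$participant)
  pairs <- unique(long$pair_id)
  shape <- function(h) {
    sub <- long[long$hemisphere == h, ]
    m <- matrix(NA_real_, length(participants), length(pairs),
                dimnames = list(participants, pairs))
    m[cbind(match(sub$participant, participants),
            match(sub$pair_id, pairs))] <- sub$value
    if (anyNA(m)) stop("incomplete contrast table: missing ", h, " values")
    m
  }
  structure(list(left = shape("Left"), right = shape("Right"),
                 participant_ids = participants, pair_ids = pairs),
            class = "contrast_table")
}
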