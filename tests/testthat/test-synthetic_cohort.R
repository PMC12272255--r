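small_modules <- function(sizes = c(4, 4), prefix = "m") {
  spec <- list()
  idx <- 0L
  for (i in seq_along(sizes)) {
    spec[[paste0(prefix, i)]] <- sprintf("r%02d", idx + seq_len(sizes[i]))
    idx <- idx + sizes[i]
  }
  spec
}

test_that("identical configs give bit-identical cohorts", {
  cfg <- cohort_config(n_participants = 6, n_pairs = 10,
                       planted = data.frame(pair_id = "pair003",
                                            hemisphere = "Right"),
                       module_spec = small_modules(), rng_seed = 7)
  expect_identical(simulate_contrasts(cfg), simulate_contrasts(cfg))
  expect_identical(simulate_rest_timeseries(cfg), simulate_rest_timeseries(cfg))
  cfg2 <- cohort_config(n_participants = 6, n_pairs = 10,
                        module_spec = small_modules(), rng_seed = 8)
  expect_false(identical(simulate_rest_timeseries(cfg)$series,
                         simulate_rest_timeseries(cfg2)$series))
})

test_that("planted pairs carry the configured activation and asymmetry", {
  planted <- data.frame(pair_id = c("pair001", "pair002"),
                        hemisphere = c("Left", "Right"))
  cfg <- cohort_config(n_participants = 4000, n_pairs = 3, planted = planted,
                       activation_effect = 1.5, asymmetry_effect = 1.0,
                       rng_seed = 11)
  ct <- simulate_contrasts(cfg)
  pair_mean <- (colMeans(ct$left) + colMeans(ct$right)) / 2
  expect_equal(unname(pair_mean[1:2]), c(1.5, 1.5), tolerance = 0.05)
  expect_equal(unname(pair_mean[3]), 0, tolerance = 0.05)
  diff_mean <- colMeans(ct$left) - colMeans(ct$right)
  expect_equal(unname(diff_mean[1]), 1.0, tolerance = 0.1)
  expect_equal(unname(diff_mean[2]), -1.0, tolerance = 0.1)
})

test_that("excluded pairs are masked from the contrast table", {
  cfg <- cohort_config(n_participants = 5, n_pairs = 10,
                       excluded_pairs = c(2L, 9L), rng_seed = 1)
  ct <- simulate_contrasts(cfg)
  expect_equal(length(ct$pair_ids), 8L)
  expect_false(any(c("pair002", "pair009") %in% ct$pair_ids))
})

test_that("generated rest series are band-limited", {
  cfg <- cohort_config(n_participants = 3, n_pairs = 5,
                       module_spec = small_modules(c(5, 5)),
                       n_timepoints = 240, tr_seconds = 2,
                       band = c(0.01, 0.1), rng_seed = 3)
  panel <- simulate_rest_timeseries(cfg)
  out_frac <- vapply(panel$series, function(x) {
    spec <- abs(stats::mvfft(t(x)))^2
    f <- (seq_len(nrow(spec)) - 1) / (nrow(spec) * 2)
    f <- pmin(f, 1 / 2 - f)
    inband <- f >= 0.01 & f <= 0.1
    sum(spec[!inband, ]) / sum(spec)
  }, numeric(1))
  expect_true(all(out_frac < 0.05))
})

test_that("zero inter-module target gives near-zero between-module correlation", {
  cfg <- cohort_config(n_participants = 130, n_pairs = 5,
                       module_spec = small_modules(c(5, 5)),
                       between_module_r = data.frame(module_a = "m1",
                                                     module_b = "m2", r = 0),
                       rng_seed = 5)
  panel <- simulate_rest_timeseries(cfg)
  stack <- panel_connectivity(panel)
  g <- fisher_group_average(stack)
  between <- g[cfg$module_spec$m1, cfg$module_spec$m2]
  expect_lt(abs(mean(between)), 0.05)
  within <- g[cfg$module_spec$m1, cfg$module_spec$m1]
  expect_gt(mean(within[upper.tri(within)]), mean(between))
})

test_that("one module with full coherence and no noise gives r = 1 throughout", {
  cfg <- cohort_config(n_participants = 2, n_pairs = 2,
                       module_spec = small_modules(4, prefix = "solo"),
                       within_module_r = 1, rng_seed = 2)
  panel <- simulate_rest_timeseries(cfg)
  r <- participant_correlation(panel$series[[1]])
  expect_equal(unname(r), matrix(1, 4, 4))
})

test_that("cohort_config rejects inconsistent specifications", {
  expect_error(cohort_config(planted = data.frame(pair_id = "nope",
                                                  hemisphere = "Left"),
                             n_pairs = 3), "not in pair_ids")
  expect_error(cohort_config(planted = data.frame(pair_id = "pair001",
                                                  hemisphere = "Left"),
                             n_pairs = 3, activation_effect = NaN),
               "effect sizes")
  expect_error(
    cohort_config(module_spec = list(a = c("r1", "r2"), b = "r1")),
    "disjoint")
  expect_error(
    cohort_config(module_spec = list(a = "r1", b = c("r2", "r3")),
                  between_module_r = data.frame(module_a = "a",
                                                module_b = "b", r = 0.2)),
    "< 2 members")
  expect_error(
    cohort_config(module_spec = small_modules(),
                  between_module_r = data.frame(module_a = "m1",
                                                module_b = "m2", r = 0.9)),
    "within_module_r")
})

test_that("planted truth enumerates the configuration", {
  cc <- demo_cohort_config(1)
  truth <- planted_truth(cc)
  expect_equal(nrow(truth$selected_regions), 95L)
  expect_equal(sort(as.integer(table(truth$module_labels))),
               c(12L, 15L, 20L, 23L, 25L))
  expect_setequal(truth$hub_regions, c("f2_2", "F3t", "PRECU1", "post2"))

  # all pairs planted: one region per pair, on the planted side
  all_planted <- data.frame(pair_id = sprintf("pair%03d", 1:4),
                            hemisphere = c("Left", "Right", "Right", "Left"))
  cfg <- cohort_config(n_participants = 3, n_pairs = 4, planted = all_planted)
  truth2 <- planted_truth(cfg)
  expect_equal(truth2$selected_regions, all_planted)

  cfg3 <- cohort_config(n_participants = 3, n_pairs = 4,
                        module_spec = small_modules())
  expect_length(planted_truth(cfg3)$hub_regions, 0L)
})

test_that("contrast tables round-trip through long-format TSV", {
  cfg <- cohort_config(n_participants = 4, n_pairs = 6, rng_seed = 9)
  ct <- simulate_contrasts(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_contrast_table(ct, path)
  back <- read_contrast_table(path)
  expect_equal(back$left, ct$left)
  expect_equal(back$right, ct$right)
})

test_that("the band-pass filter matches an independent forward-backward filter", {
  skip_if_not_installed("signal")
  set.seed(42)
  x <- rnorm(240)
  mine <- bandpass_filter(x, tr = 2, band = c(0.01, 0.1))
  bf <- signal::butter(4, c(0.01, 0.1) / 0.25, type = "pass")
  ref <- signal::filtfilt(bf, x)
  # same passband content: the two zero-phase filters agree closely away from
  # the edges (different edge handling: circular vs reflective padding)
  core <- 30:210
  expect_gt(stats::cor(mine[core], ref[core]), 0.98)
})
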