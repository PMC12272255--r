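named_matrix <- function(m, ids) { dimnames(m) <- list(ids, ids); m }

test_that("positive-correlation graphs keep exactly the positive edges", {
  ids <- paste0("r", 1:5)
  m <- matrix(0.5, 5, 5); diag(m) <- 1
  m[1, 2] <- m[2, 1] <- -0.4
  m[1, 3] <- m[3, 1] <- 0
  m[4, 5] <- m[5, 4] <- -0.1
  m <- named_matrix(m, ids)
  g <- build_positive_graph(m, ids)
  expect_equal(igraph::ecount(g), choose(5, 2) - 3)
  expect_false(igraph::are_adjacent(g, "r1", "r2"))
  expect_false(igraph::are_adjacent(g, "r1", "r3"))

  allpos <- named_matrix(matrix(0.3, 4, 4) + diag(0.7, 4), paste0("r", 1:4))
  expect_equal(igraph::ecount(build_positive_graph(allpos, paste0("r", 1:4))),
               choose(4, 2))

  expect_error(build_positive_graph(m, ids[1:2]), "at least 3")
})

test_that("degree centrality is the weighted strength", {
  ids <- c("a", "b", "c", "d")
  m <- diag(4)
  m[1, 2] <- m[2, 1] <- 0.5
  m[1, 3] <- m[3, 1] <- 0.25
  m[2, 3] <- m[3, 2] <- -0.6   # excluded edge
  m <- named_matrix(m, ids)
  dc <- degree_centrality(build_positive_graph(m, ids))
  expect_equal(dc[["a"]], 0.75)
  expect_equal(dc[["d"]], 0)   # isolated node

  w <- 0.42
  complete <- named_matrix(matrix(w, 5, 5) + diag(1 - w, 5), paste0("n", 1:5))
  dcc <- degree_centrality(build_positive_graph(complete, paste0("n", 1:5)))
  expect_equal(unname(dcc), rep(4 * w, 5))

  # matrix-level cross-check: DC equals the sum of positive off-diagonal row
  # entries of the source matrix
  set.seed(59)
  rm <- random_corr_matrix(6)
  dcr <- degree_centrality(build_positive_graph(rm, rownames(rm)))
  manual <- vapply(seq_len(6), function(i) {
    v <- rm[i, -i]; sum(v[v > 0])
  }, numeric(1))
  expect_equal(unname(dcr[rownames(rm)]), manual)
})

test_that("betweenness has the star and complete-graph closed forms", {
  n <- 6
  ids <- c("hub", paste0("leaf", 1:(n - 1)))
  m <- diag(n)
  m[1, 2:n] <- m[2:n, 1] <- runif(n - 1, 0.3, 0.9)
  m <- named_matrix(m, ids)   # leaves uncorrelated: a star around "hub"
  g <- build_positive_graph(m, ids)
  raw <- betweenness_centrality(g, "reciprocal", normalized = FALSE)
  expect_equal(raw[["hub"]], (n - 1) * (n - 2))
  expect_equal(unname(raw[-1]), rep(0, n - 1))
  norm <- betweenness_centrality(g, "reciprocal", normalized = TRUE)
  expect_equal(norm[["hub"]], 1)

  complete <- named_matrix(matrix(0.5, 5, 5) + diag(0.5, 5), paste0("n", 1:5))
  bc <- betweenness_centrality(build_positive_graph(complete, paste0("n", 1:5)),
                               "reciprocal")
  expect_equal(unname(bc), rep(0, 5))
})

test_that("betweenness matches exhaustive path enumeration on random graphs", {
  set.seed(61)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    m <- random_corr_matrix(n, p_negative = 0.3)
    g <- build_positive_graph(m, rownames(m))
    adj <- m; adj[adj < 0] <- 0; diag(adj) <- 0
    for (rule in c("reciprocal", "one_minus_r")) {
      got <- betweenness_centrality(g, rule)[rownames(m)]
      want <- bc_enumeration_oracle(adj, rule)
      expect_equal(unname(got), want, tolerance = 1e-10)
    }
  }
})

test_that("disconnected graphs contribute zero for unreachable pairs", {
  ids <- paste0("r", 1:6)
  m <- diag(6)
  m[1, 2] <- m[2, 1] <- 0.8; m[2, 3] <- m[3, 2] <- 0.7
  m[4, 5] <- m[5, 4] <- 0.6; m[5, 6] <- m[6, 5] <- 0.5
  m <- named_matrix(m, ids)
  g <- build_positive_graph(m, ids)
  bc <- betweenness_centrality(g, "reciprocal")
  adj <- m; diag(adj) <- 0
  expect_equal(unname(bc[ids]), bc_enumeration_oracle(adj, "reciprocal"))
  expect_equal(bc[["r2"]], 2)   # bridges the ordered pairs (r1,r3), (r3,r1)
})

test_that("participant summaries yield means, CIs and thresholds", {
  # identical participants: zero-width CI at the common value
  dc <- matrix(rep(c(1, 2, 4), each = 3), 3, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  bc <- matrix(rep(c(0.5, 1, 3), each = 3), 3, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  s <- summarize_over_participants(dc, bc)
  expect_equal(s$regions$dc_mean, c(1, 2, 4))
  expect_equal(s$regions$dc_ci_low, s$regions$dc_ci_high)
  expect_equal(s$dc_threshold, mean(c(1, 2, 4)) + sd(c(1, 2, 4)))

  expect_error(summarize_over_participants(dc[1, , drop = FALSE],
                                           bc[1, , drop = FALSE]),
               "2 participants")
})

test_that("reported network summaries reproduce the published thresholds", {
  # two-point construction with a given mean m and sample SD s: {m - s/sqrt(2),
  # m + s/sqrt(2)}
  two_point <- function(m, s) c(m - s / sqrt(2), m + s / sqrt(2))
  nets <- reported_network_centrality()
  expected <- c(`Parieto-frontal_dc` = 6.02, `Parieto-frontal_bc` = 0.98,
                `Temporo-frontal_dc` = 4.74, `Temporo-frontal_bc` = 3.59,
                `Somato-motor_dc` = 8.89, `Posterior-medial_dc` = 5.41)
  for (nm in names(expected)) {
    parts <- strsplit(nm, "_")[[1]]
    row <- nets[nets$network == parts[1], ]
    vals <- two_point(row[[paste0(parts[2], "_mean")]],
                      row[[paste0(parts[2], "_sd")]])
    expect_equal(hub_threshold(vals), expected[[nm]], tolerance = 1e-9)
  }
})

test_that("dual-threshold hub detection reproduces the published worked example", {
  regs <- reported_region_centrality()
  nets <- reported_network_centrality()
  tf <- nets[nets$network == "Temporo-frontal", ]
  # complete the temporo-frontal network with synthetic non-candidate regions
  # sitting at the published mean (below both thresholds)
  cand <- regs[regs$network == "Temporo-frontal", ]
  filler <- data.frame(region = sprintf("tf%02d", 1:17),
                       dc_mean = tf$dc_mean, bc_mean = tf$bc_mean)
  summary <- list(
    regions = data.frame(region = c(cand$abbreviation, filler$region),
                         dc_mean = c(cand$dc_mean, filler$dc_mean),
                         bc_mean = c(cand$bc_mean, filler$bc_mean)),
    dc_threshold = tf$dc_mean + tf$dc_sd,
    bc_threshold = tf$bc_mean + tf$bc_sd
  )
  hubs <- summary$regions$region[detect_hubs(summary)]
  expect_setequal(hubs, c("F3t", "STS4", "INSa3"))
  # INSa3 sits exactly on the BC threshold and qualifies inclusively
  insa3 <- summary$regions[summary$regions$region == "INSa3", ]
  expect_equal(insa3$bc_mean, summary$bc_threshold)
  strict <- summary$regions$region[detect_hubs(summary, policy = "strict")]
  expect_setequal(strict, c("F3t", "STS4"))
})

test_that("the published parieto-frontal hub is a known discrepancy", {
  # f2_2 is reported as that network's hub, but its printed DC (5.99) sits
  # below the printed DC threshold (6.02): at printed precision the inclusive
  # rule cannot flag it (rounding in the source values is the likely cause)
  regs <- reported_region_centrality()
  nets <- reported_network_centrality()
  pf <- nets[nets$network == "Parieto-frontal", ]
  f22 <- regs[regs$abbreviation == "f2_2", ]
  summary <- list(regions = data.frame(region = "f2_2",
                                       dc_mean = f22$dc_mean,
                                       bc_mean = f22$bc_mean),
                  dc_threshold = pf$dc_mean + pf$dc_sd,
                  bc_threshold = pf$bc_mean + pf$bc_sd)
  expect_gte(f22$bc_mean, summary$bc_threshold)
  expect_false(detect_hubs(summary))   # DC 5.99 < 6.02
})

test_that("hub sets are invariant to betweenness scaling", {
  set.seed(67)
  ids <- paste0("r", 1:8)
  mats <- lapply(1:10, function(p) {
    m <- random_corr_matrix(8, p_negative = 0.1)
    dimnames(m) <- list(ids, ids)
    m
  })
  stack <- connectivity_stack(mats, ids)
  labels <- stats::setNames(rep("N", 8), ids)
  raw <- network_hubs(stack, labels, pipeline_config(bc_normalized = FALSE))
  norm <- network_hubs(stack, labels, pipeline_config(bc_normalized = TRUE))
  expect_equal(raw$N$regions$hub, norm$N$regions$hub)
  expect_equal(raw$N$regions$bc_mean, norm$N$regions$bc_mean * 7 * 6)

  # degenerate: all regions identical -> sd 0, inclusive rule flags all
  const <- matrix(0.5, 8, 8); diag(const) <- 1
  dimnames(const) <- list(ids, ids)
  cstack <- connectivity_stack(list(const, const), ids)
  ch <- network_hubs(cstack, labels)
  expect_true(all(ch$N$regions$hub))
  expect_false(any(detect_hubs(ch$N, policy = "strict")))
})
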