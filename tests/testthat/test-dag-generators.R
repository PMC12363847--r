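test_that("generated topologies are acyclic and respect the stored order", {
  cases <- list(
    generate_ppm_dag(grn_params(n = 80, k = 4, r = 3, m = 0.8), seed = 11),
    generate_ppm_dag(grn_params(n = 80, k = 1, r = 3), seed = 12),
    generate_scalefree_dag(grn_params(n = 80, k = 4, r = 3, m = 0.8, d = 2),
                           seed = 13),
    generate_scalefree_dag(grn_params(n = 80, k = 1, r = 3, d = 30), seed = 14)
  )
  for (topo in cases) {
    e <- topo$edges
    expect_true(all(topo$index[e$from] < topo$index[e$to]))
    expect_false(any(e$from == e$to))
    expect_false(anyDuplicated(paste(e$from, e$to)) > 0)
    g <- grnarch:::topology_igraph(topo)
    expect_true(igraph::is_dag(g))
  }
})

test_that("identical (params, seed) give byte-identical edge lists", {
  p <- grn_params(n = 120, k = 3, r = 4, m = 0.7, d = 2)
  expect_identical(generate_ppm_dag(p, 99), generate_ppm_dag(p, 99))
  expect_identical(generate_scalefree_dag(p, 99),
                   generate_scalefree_dag(p, 99))
  expect_false(identical(generate_ppm_dag(p, 99)$edges,
                         generate_ppm_dag(p, 100)$edges))
})

test_that("r = 0 yields edge-free graphs", {
  expect_identical(
    nrow(generate_ppm_dag(grn_params(n = 100, k = 1, r = 0), 1)$edges), 0L)
  expect_identical(
    nrow(generate_scalefree_dag(grn_params(n = 10, k = 1, r = 0, d = 1),
                                1)$edges), 0L)
})

test_that("PPM calibration: realized in-degree and within-group fraction", {
  p <- grn_params(n = 500, k = 5, r = 4, m = 0.8)
  stats <- purrr::map_dfr(1:60, function(s) {
    topology_stats(generate_ppm_dag(p, s))[, c("n_edges", "mean_in_degree",
                                               "within_group_fraction")]
  })
  # grand means; binomial standard errors
  se_r <- sqrt(p$r / (60 * p$n))
  expect_lt(abs(mean(stats$mean_in_degree) - p$r), 3 * se_r)
  total_edges <- sum(stats$n_edges)
  pooled_within <- sum(stats$within_group_fraction * stats$n_edges) /
    total_edges
  se_m <- sqrt(p$m * (1 - p$m) / total_edges)
  expect_lt(abs(pooled_within - p$m), 3 * se_m)
})

test_that("scale-free generator hits r and m on average", {
  p <- grn_params(n = 500, k = 5, r = 4, m = 0.8, d = 3)
  stats <- purrr::map_dfr(1:40, function(s) {
    topology_stats(generate_scalefree_dag(p, s))[
      , c("n_edges", "mean_in_degree", "within_group_fraction")]
  })
  se_r <- sqrt(p$r / (40 * p$n))
  expect_lt(abs(mean(stats$mean_in_degree) - p$r), 3 * se_r)
  pooled_within <- sum(stats$within_group_fraction * stats$n_edges) /
    sum(stats$n_edges)
  # weighted sampling only approximates the within-group calibration
  expect_lt(abs(pooled_within - p$m), 0.05)
})

test_that("out-degree variance decreases in d (hubs at small d)", {
  grid <- c(1, 3, 10, 30)
  vars <- sapply(grid, function(d) {
    mean(sapply(1:25, function(s) {
      topology_stats(generate_scalefree_dag(
        grn_params(n = 300, k = 1, r = 4, d = d), s))$out_degree_var
    }))
  })
  expect_true(all(diff(vars) <= 0))
})

test_that("large d recovers the ER out-degree distribution", {
  v_sf <- mean(sapply(1:40, function(s) {
    topology_stats(generate_scalefree_dag(
      grn_params(n = 500, k = 1, r = 4, d = 1e6), s))$out_degree_var
  }))
  v_er <- mean(sapply(1:40, function(s) {
    topology_stats(generate_ppm_dag(grn_params(n = 500, k = 1, r = 4),
                                    s))$out_degree_var
  }))
  expect_lt(abs(v_sf / v_er - 1), 0.1)
})

test_that("topology_stats matches hand counts", {
  chain <- make_topology(3, from = c(1, 2), to = c(2, 3))
  s <- topology_stats(chain)
  expect_equal(s$mean_in_degree, 2 / 3)
  expect_equal(s$n_edges, 2L)

  empty <- make_topology(5)
  expect_equal(topology_stats(empty)$mean_in_degree, 0)

  full4 <- make_topology(4, from = c(1, 1, 1, 2, 2, 3), to = c(2, 3, 4, 3, 4, 4))
  expect_equal(topology_stats(full4)$mean_in_degree, 1.5)
})

test_that("edge-list TSV round-trips topologies and signed networks", {
  p <- grn_params(n = 40, k = 3, r = 2, m = 0.9)
  topo <- generate_ppm_dag(p, 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edges(topo, path)
  back <- read_edges(path)
  expect_identical(back$edges, topo$edges)
  expect_identical(back$groups, topo$groups)
  expect_identical(back$index, topo$index)

  grn <- assign_signs(topo, 0.6, 0.35, seed = 2)
  write_edges(grn, path)
  back2 <- read_edges(path, gamma = 0.35)
  expect_identical(back2$sign, grn$sign)
  expect_identical(back2$topology$edges, topo$edges)
})
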