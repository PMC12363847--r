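test_that("total effects on worked examples match the path-product series", {
  # no edges -> identity
  none <- make_signed(make_topology(4), rep(1, 4), 0.5)
  expect_equal(as.matrix(total_effects(none)$L), diag(4), ignore_attr = TRUE)

  # chain A -> B -> C, gamma = 0.5
  eff <- total_effects(chain_grn())
  expect_equal(eff$L[1, 3], 0.25)
  expect_equal(eff$L[2, 3], 0.5)

  # incoherent feed-forward: B represses, paths cancel partially
  eff2 <- total_effects(ffl_grn(sign = c(1, -1, 1)))
  expect_equal(eff2$L[1, 3], 0.5 + 0.5 * (-0.5))
})

test_that("L equals the explicit path sum on random networks", {
  for (seed in 1:6) {
    grn <- random_grn(n = 40, r = 3, gamma = 0.4, p_plus = 0.6, seed = seed)
    L <- as.matrix(total_effects(grn)$L)
    expect_equal(L, path_sum_L(grn), tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("sparse and dense solves agree", {
  for (seed in 1:4) {
    grn <- random_grn(n = 150, r = 4, gamma = 0.3, p_plus = 0.5, seed = seed)
    expect_equal(as.matrix(total_effects(grn, "sparse")$L),
                 total_effects(grn, "dense")$L,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("variance decomposition reproduces the worked chain and triangle", {
  vd <- variance_decomposition(total_effects(chain_grn()))
  expect_equal(vd$v_g[3], 1.3125)
  expect_equal(vd$cis_fraction, c(1, 0.8, 1 / 1.3125))
  expect_equal(vd$lead_trans_fraction[3], 0.25 / 1.3125)
  expect_equal(vd$n_ancestors, c(0L, 1L, 2L))

  vf <- variance_decomposition(total_effects(ffl_grn()))
  expect_equal(vf$v_g[3], 1.8125)
  expect_equal(vf$cis_fraction[3], 1 / 1.8125)
  expect_equal(vf$lead_trans_fraction[3], 0.5625 / 1.8125)
  # root gene: all cis
  expect_equal(vf$cis_fraction[1], 1)
  expect_equal(vf$lead_trans_fraction[1], 0)
})

test_that("cis + trans contributions conserve exactly", {
  for (seed in 1:5) {
    grn <- random_grn(n = 60, r = 4, gamma = 0.5, p_plus = 0.3, seed = seed)
    eff <- total_effects(grn)
    L <- as.matrix(eff$L)
    vd <- variance_decomposition(eff)
    for (i in seq_len(60)) {
      b2 <- L[-i, i]^2 / vd$v_g[i]
      expect_lt(abs(vd$cis_fraction[i] + sum(b2) - 1), 1e-10)
    }
  }
})

test_that("distance decomposition telescopes to 1 and matches the chain", {
  dd <- distance_decomposition(total_effects(chain_grn()))
  c_rows <- dd[dd$gene == 3, ]
  expect_equal(c_rows$distance, 0:2)
  expect_equal(c_rows$fraction,
               c(1, 0.25, 0.0625) / 1.3125, tolerance = 1e-12)

  # triangle: A is at shortest distance 1 from C, pooled with B
  df <- distance_decomposition(total_effects(ffl_grn()))
  c_rows <- df[df$gene == 3, ]
  expect_equal(c_rows$distance, 0:1)
  expect_equal(c_rows$fraction, c(1 / 1.8125, 0.8125 / 1.8125),
               tolerance = 1e-12)

  for (seed in 1:4) {
    grn <- random_grn(n = 50, r = 3, gamma = 0.4, p_plus = 0.8, seed = seed)
    dd <- distance_decomposition(total_effects(grn))
    sums <- tapply(dd$fraction, dd$gene, sum)
    expect_lt(max(abs(sums - 1)), 1e-10)
    # cumulative is non-decreasing in d
    cum1 <- cumulative_by_distance(dd, 1)$cumulative
    cum2 <- cumulative_by_distance(dd, 2)$cumulative
    expect_true(all(cum2 >= cum1 - 1e-12))
    expect_equal(cumulative_by_distance(dd, 50)$cumulative, rep(1, 50),
                 tolerance = 1e-10)
  }
})

test_that("Monte-Carlo simulation converges to the analytic decomposition", {
  n_ind <- 40000
  grn <- chain_grn()
  sim <- simulate_individuals(grn, n_ind, q_per_gene = 2, sigma2 = 0,
                              seed = 3)
  vg <- variance_decomposition(total_effects(grn))$v_g
  emp <- apply(sim$y, 2, var)
  expect_true(all(abs(emp - vg) < 3 * sqrt(2 / n_ind) * vg))
  # aggregate cis variance per gene is ~1
  expect_true(all(abs(apply(sim$cis, 2, var) - 1) < 3 * sqrt(2 / n_ind)))
})

test_that("noise enters only through the heritability scale", {
  grn <- make_signed(make_topology(4), rep(1, 4), 0)
  sim <- simulate_individuals(grn, 30000, sigma2 = 1, seed = 8)
  emp <- apply(sim$y, 2, var)
  expect_true(all(abs(emp - 2) < 3 * sqrt(2 / 30000) * 2 * 1.5))
  expect_equal(heritability_scaling(0), 1)
  expect_equal(heritability_scaling(1), 0.5)
  expect_equal(heritability_scaling(3), 0.25)
})

test_that("simulation is deterministic given the seed", {
  grn <- random_grn(20, seed = 4)
  s1 <- simulate_individuals(grn, 100, seed = 5)
  s2 <- simulate_individuals(grn, 100, seed = 5)
  expect_identical(s1$y, s2$y)
})

test_that("sign assignment respects p_plus", {
  topo <- make_topology(10000)
  expect_true(all(assign_signs(topo, 1, 0.3, 1)$sign == 1L))
  expect_true(all(assign_signs(topo, 0, 0.3, 1)$sign == -1L))
  frac <- mean(assign_signs(topo, 0.5, 0.3, 7)$sign == 1L)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("decomposition TSV writer emits the documented schema", {
  grn <- random_grn(20, seed = 2)
  eff <- total_effects(grn)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_decomposition(variance_decomposition(eff), path,
                      distance = distance_decomposition(eff))
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  expect_named(tbl, c("gene", "cis_fraction", "lead_trans_fraction",
                      "lead_ratio", "n_ancestors"))
  dist <- readr::read_tsv(paste0(path, ".distance.tsv"),
                          show_col_types = FALSE)
  expect_named(dist, c("gene", "distance", "fraction"))
})
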