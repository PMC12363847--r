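test_that("closed forms match their arithmetic values", {
  expect_equal(expected_cis_fraction_v(0, 0), 1)
  expect_equal(expected_cis_fraction_v(6, 0.4), 1 / 2.12, tolerance = 1e-12)
  expect_equal(expected_cis_fraction_v(0, 0.4), 1 / 1.16, tolerance = 1e-12)

  expect_equal(expected_cis_fraction_diamond(6, 0.4, 1), 1 / 2.8816,
               tolerance = 1e-12)
  expect_equal(expected_cis_fraction_diamond(1, 0.4, 0.3), 1 / 1.1856,
               tolerance = 1e-12) # C(1,2) term vanishes for any p_plus
  expect_equal(expected_cis_fraction_diamond(4, 0, 0.9), 1)

  expect_equal(expected_cis_fraction_triangle(6, 0.4, 1), 1 / 3.8096,
               tolerance = 1e-12)
  expect_equal(expected_cis_fraction_triangle(2, 0.4, 1), 1 / 1.8384,
               tolerance = 1e-12)
  expect_equal(expected_cis_fraction_triangle(0, 0.4, 0.2), 1 / 1.16,
               tolerance = 1e-12) # r = 0: single direct master edge
})

test_that("sign-enumeration oracle agrees with the closed forms", {
  # spot grid here; the full acceptance grid lives in test-acceptance.R
  for (r in c(0, 1, 3)) {
    for (p_plus in c(0, 0.25, 1)) {
      expect_equal(sign_enumeration_oracle("v", r, 0.4, p_plus),
                   expected_cis_fraction_v(r, 0.4), tolerance = 1e-12)
      expect_equal(sign_enumeration_oracle("triangle", r, 0.4, p_plus),
                   expected_cis_fraction_triangle(r, 0.4, p_plus),
                   tolerance = 1e-12)
      if (r >= 1) {
        expect_equal(sign_enumeration_oracle("diamond", r, 0.4, p_plus),
                     expected_cis_fraction_diamond(r, 0.4, p_plus),
                     tolerance = 1e-12)
      }
    }
  }
  expect_error(sign_enumeration_oracle("v", 13, 0.4, 0.5), "r <= 12")
})

test_that("balanced signs kill the covariance terms in the diamond", {
  for (r in c(2, 5)) {
    expect_equal(sign_enumeration_oracle("diamond", r, 0.3, 0.5),
                 1 / (1 + r * 0.09 + r * 0.0081), tolerance = 1e-12)
  }
})

test_that("diamond is symmetric in p_plus about 1/2; triangle is not", {
  expect_equal(expected_cis_fraction_diamond(4, 0.4, 0.2),
               expected_cis_fraction_diamond(4, 0.4, 0.8))
  expect_false(isTRUE(all.equal(expected_cis_fraction_triangle(4, 0.4, 0.2),
                                expected_cis_fraction_triangle(4, 0.4, 0.8))))
})

test_that("coherent motifs order by expected cis fraction at p_plus = 1", {
  # The triangle has the most trans variance (it adds the direct master edge
  # and coherent path covariance), so its ratio is smallest everywhere. The
  # diamond-vs-V comparison trades the master's direct edge (V has r + 1
  # regulators, the diamond r) against two-hop variance and covariance; the
  # diamond falls below V exactly when r * gamma >= 1.
  for (gamma in c(0.1, 0.4, 0.8)) {
    for (r in c(1, 3, 6)) {
      v <- expected_cis_fraction_v(r, gamma)
      dia <- expected_cis_fraction_diamond(r, gamma, 1)
      tri <- expected_cis_fraction_triangle(r, gamma, 1)
      expect_lte(tri, dia)
      expect_lte(tri, v)
      if (r * gamma >= 1) expect_lte(dia, v) else expect_gte(dia, v)
    }
  }
})

test_that("motif counting matches hand counts and brute force", {
  ffl <- make_topology(3, from = c(1, 1, 2), to = c(2, 3, 3))
  expect_equal(count_motifs(ffl)$n_ffl, 1)
  expect_equal(count_motifs(ffl)$n_biparallel, 0)

  bip <- make_topology(4, from = c(1, 1, 2, 3), to = c(2, 3, 4, 4))
  expect_equal(count_motifs(bip)$n_ffl, 0)
  expect_equal(count_motifs(bip)$n_biparallel, 1)

  full4 <- make_topology(4, from = c(1, 1, 1, 2, 2, 3),
                         to = c(2, 3, 4, 3, 4, 4))
  expect_equal(count_motifs(full4)$n_ffl, 4)
  expect_equal(count_motifs(full4)$n_biparallel, 1)

  # direct-edge exclusion drops the bi-parallel inside the complete DAG
  expect_equal(count_motifs(full4, exclude_direct = TRUE)$n_biparallel, 0)

  empty <- make_topology(6)
  expect_equal(count_motifs(empty)$n_ffl, 0)

  for (seed in 1:5) {
    topo <- generate_ppm_dag(grn_params(n = 25, k = 1, r = 4), seed)
    got <- count_motifs(topo)
    want <- brute_motifs(topo)
    expect_equal(got$n_ffl, want$n_ffl)
    expect_equal(got$n_biparallel, want$n_biparallel)
  }
})
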