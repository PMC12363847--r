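# Fixtures and independent oracles used across the suite.

# Hand-built topology: genes already in topological order unless `index` given.
make_topology <- function(n, from = integer(0), to = integer(0),
                          groups = rep(1L, n), index = seq_len(n)) {
  grnarch:::new_grn_topology(
    n, index,
    tibble::tibble(from = as.integer(from), to = as.integer(to)),
    groups, max(groups)
  )
}

make_signed <- function(topology, sign, gamma) {
  grnarch:::new_signed_grn(topology, as.integer(sign), gamma)
}

# chain A -> B -> C, all activators
chain_grn <- function(gamma = 0.5, sign = c(1, 1, 1)) {
  make_signed(make_topology(3, from = c(1, 2), to = c(2, 3)), sign, gamma)
}

# feed-forward loop A -> B, B -> C, A -> C
ffl_grn <- function(gamma = 0.5, sign = c(1, 1, 1)) {
  make_signed(make_topology(3, from = c(1, 1, 2), to = c(2, 3, 3)),
              sign, gamma)
}

# Independent oracle for L: explicit path-product series sum_t G^t.
path_sum_L <- function(grn) {
  topo <- grn$topology
  n <- topo$n
  G <- matrix(0, n, n)
  if (nrow(topo$edges) > 0) {
    G[cbind(topo$edges$from, topo$edges$to)] <-
      grn$sign[topo$edges$from] * grn$gamma
  }
  L <- diag(n)
  P <- diag(n)
  for (t in seq_len(n - 1)) {
    P <- P %*% G
    if (all(P == 0)) break
    L <- L + P
  }
  L
}

# Brute-force motif counts by triple/quadruple enumeration.
brute_motifs <- function(topology) {
  e <- topology$edges
  n <- topology$n
  A <- matrix(FALSE, n, n)
  if (nrow(e) > 0) A[cbind(e$from, e$to)] <- TRUE
  ffl <- 0L
  bip <- 0L
  for (a in seq_len(n)) {
    for (c_ in seq_len(n)) {
      if (a == c_) next
      mids <- which(A[a, ] & A[, c_])
      mids <- setdiff(mids, c(a, c_))
      if (A[a, c_]) ffl <- ffl + length(mids)
      bip <- bip + choose(length(mids), 2)
    }
  }
  list(n_ffl = ffl, n_biparallel = bip)
}

# Random signed GRN for property tests.
random_grn <- function(n, r = 3, gamma = 0.4, p_plus = 0.7, seed = 1,
                       k = 1, m = NULL) {
  params <- grn_params(n = n, k = k, r = r, m = m, gamma = gamma,
                       p_plus = p_plus)
  assign_signs(generate_ppm_dag(params, seed), p_plus, gamma, seed)
}
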