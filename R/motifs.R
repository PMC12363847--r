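#' Expected cis fraction for the three canonical local motifs
#'
#' Closed-form ratios of expected cis variance to expected total genetic
#' variance for a focal gene, taking the expectation over random activator /
#' repressor assignments (each regulator is an activator with probability
#' `p_plus`):
#'
#' * V motif (`r + 1` independent direct regulators):
#'   `1 / (1 + (r+1) gamma^2)`. Sign-free.
#' * diamond / bi-parallel (a master feeding the focal gene through `r`
#'   intermediates, no direct edge):
#'   `1 / (1 + r g2 + r g4 + 2 C(r,2) (2p+ - 1)^2 g4)` with `g2 = gamma^2`,
#'   `g4 = gamma^4`.
#' * triangle / feed-forward (master regulates the `r` intermediates and the
#'   focal gene directly):
#'   `1 / (1 + (r+1) g2 + r g4 + 2 C(r,2) (2p+ - 1)^2 g4 +
#'   2 r (2p+ - 1) gamma^3)`.
#'
#' The ratios are ratios of expectations (E\[V_cis\]/E\[V_G\]), the
#' convention verified exactly by [sign_enumeration_oracle()].
#'
#' @param r Number of pre-existing direct regulators (non-negative integer;
#'   the diamond requires `r >= 1`).
#' @param gamma Regulatory effect magnitude.
#' @param p_plus Probability that a gene is an activator.
#' @return The expected cis fraction (scalar in (0, 1]).
#' @name motif_closed_forms
NULL

#' @rdname motif_closed_forms
#' @export
expected_cis_fraction_v <- function(r, gamma) {
  stopifnot(r >= 0, r == as.integer(r), gamma >= 0)
  1 / (1 + (r + 1) * gamma^2)
}

#' @rdname motif_closed_forms
#' @export
expected_cis_fraction_diamond <- function(r, gamma, p_plus) {
  stopifnot(r >= 1, r == as.integer(r), gamma >= 0, p_plus >= 0, p_plus <= 1)
  1 / (1 + r * gamma^2 + r * gamma^4 +
         2 * choose(r, 2) * (2 * p_plus - 1)^2 * gamma^4)
}

#' @rdname motif_closed_forms
#' @export
expected_cis_fraction_triangle <- function(r, gamma, p_plus) {
  stopifnot(r >= 0, r == as.integer(r), gamma >= 0, p_plus >= 0, p_plus <= 1)
  1 / (1 + (r + 1) * gamma^2 + r * gamma^4 +
         2 * choose(r, 2) * (2 * p_plus - 1)^2 * gamma^4 +
         2 * r * (2 * p_plus - 1) * gamma^3)
}

# Explicit motif DAG on [master?, regulators, focal]; gene ids:
#   V:        regulators 1..r+1, focal r+2
#   diamond:  master 1, intermediates 2..r+1, focal r+2
#   triangle: as diamond plus the direct master -> focal edge
motif_topology <- function(motif, r) {
  edges <- switch(
    motif,
    v = tibble::tibble(from = seq_len(r + 1), to = r + 2L),
    diamond = tibble::tibble(from = c(rep(1L, r), 1L + seq_len(r)),
                             to = c(1L + seq_len(r), rep(r + 2L, r))),
    triangle = tibble::tibble(from = c(rep(1L, r), 1L + seq_len(r), 1L),
                              to = c(1L + seq_len(r), rep(r + 2L, r), r + 2L))
  )
  n <- r + 2L
  new_grn_topology(n, seq_len(n), edges, rep(1L, n), 1L)
}

#' Exhaustive sign-enumeration oracle for the motif closed forms
#'
#' Builds the explicit motif DAG, enumerates all sign assignments of the
#' upstream genes (the focal gene's own sign cannot affect its variance, so
#' enumeration is over `2^(r+1)` assignments), computes cis and total genetic
#' variance for the focal gene from the total-effects matrix in each
#' assignment, and returns the ratio of probability-weighted expectations
#' E\[V_cis\] / E\[V_G\] — *not* the expectation of the ratio. This is the
#' brute-force reference the closed forms are checked against.
#'
#' @param motif One of `"v"`, `"diamond"`, `"triangle"`.
#' @param r Number of pre-existing regulators (at most 12; the enumeration is
#'   exponential in `r`).
#' @inheritParams motif_closed_forms
#' @return The expected cis fraction.
#' @export
sign_enumeration_oracle <- function(motif = c("v", "diamond", "triangle"),
                                    r, gamma, p_plus) {
  motif <- match.arg(motif)
  stopifnot(r >= 0, r == as.integer(r), gamma >= 0, p_plus >= 0, p_plus <= 1)
  if (motif == "diamond") stopifnot(r >= 1)
  if (r > 12) stop("enumeration limited to r <= 12.", call. = FALSE)
  topo <- motif_topology(motif, as.integer(r))
  n_up <- topo$n - 1L                       # upstream genes carry signs
  focal <- topo$n
  e_vcis <- 0
  e_vg <- 0
  for (mask in 0:(2^n_up - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n_up)]
    sign <- c(ifelse(bits == 1L, 1L, -1L), 1L)
    prob <- prod(ifelse(bits == 1L, p_plus, 1 - p_plus))
    if (prob == 0) next
    eff <- total_effects(new_signed_grn(topo, sign, gamma), method = "dense")
    vg <- sum(eff$L[, focal]^2)
    e_vcis <- e_vcis + prob * eff$L[focal, focal]^2
    e_vg <- e_vg + prob * vg
  }
  e_vcis / e_vg
}

#' Count feed-forward and bi-parallel motifs in a DAG
#'
#' A feed-forward loop (triangle) is an ordered triple with edges a -> b,
#' b -> c, a -> c. A bi-parallel (diamond) is a master a feeding a target c
#' through two distinct intermediates: counted per unordered intermediate
#' pair, i.e. `choose(#two-step paths a -> c, 2)` summed over (a, c) pairs.
#' By default the presence of the direct a -> c edge does not disqualify a
#' bi-parallel; set `exclude_direct` to require its absence.
#'
#' @param topology A `grn_topology`.
#' @param exclude_direct If `TRUE`, (a, c) pairs connected by a direct edge
#'   contribute no bi-parallel motifs.
#' @return A one-row tibble with integer columns `n_ffl` and `n_biparallel`.
#' @export
count_motifs <- function(topology, exclude_direct = FALSE) {
  stopifnot(inherits(topology, "grn_topology"))
  e <- topology$edges
  n <- topology$n
  if (nrow(e) == 0) {
    return(tibble::tibble(n_ffl = 0, n_biparallel = 0))
  }
  A <- Matrix::sparseMatrix(i = e$from, j = e$to, x = 1, dims = c(n, n))
  P2 <- Matrix::drop0(A %*% A)             # P2[a, c] = # two-step paths a -> c
  n_ffl <- sum(A * P2)
  P2t <- methods::as(P2, "TsparseMatrix")
  paths <- if (exclude_direct) {
    has_edge <- as.logical(A[cbind(P2t@i + 1L, P2t@j + 1L)] > 0)
    P2t@x[!has_edge]
  } else {
    P2t@x
  }
  tibble::tibble(n_ffl = as.numeric(n_ffl),
                 n_biparallel = sum(choose(paths, 2)))
}
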