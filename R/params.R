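#' Generative parameters for one gene regulatory network
#'
#' Bundles the knobs of the two DAG generators and the expression model:
#' `n` genes are split into `k` groups, the typical gene has `r` regulators
#' (in-edges), a fraction `m` of edges fall within groups, each regulator acts
#' with magnitude `gamma` and is an activator with probability `p_plus`, and
#' `sigma2` is the non-genetic noise variance. `d` is the out-degree
#' uniformity of the scale-free generator (small `d` concentrates outgoing
#' regulation in hubs); leave it `NULL` for planted-partition networks.
#'
#' @param n Number of genes (integer, at least 2).
#' @param k Number of groups (integer, between 1 and `n`). `k = 1` recovers
#'   the Erdos-Renyi case, where `m` is meaningless and must be `NULL`.
#' @param r Expected number of regulators (in-edges) per gene (non-negative).
#' @param m Expected fraction of edges within groups. Required when `k > 1`
#'   and must exceed `1/k`: the dissociative regime (`m <= 1/k`) is rejected.
#' @param gamma Magnitude of every regulatory effect (positive).
#' @param p_plus Probability that a gene acts as an activator for all of its
#'   targets, in `[0, 1]`.
#' @param d Out-degree uniformity for the scale-free generator (positive), or
#'   `NULL` for the planted-partition model.
#' @param sigma2 Non-genetic noise variance (non-negative). Enters results
#'   only through [heritability_scaling()].
#'
#' @return An object of class `grn_params` (a validated named list).
#' @seealso [generate_ppm_dag()], [generate_scalefree_dag()], [ppm_edge_probs()]
#' @export
#' @examples
#' grn_params(n = 500, k = 5, r = 4, m = 0.8, gamma = 0.3, p_plus = 0.8)
grn_params <- function(n, k = 1, r = 2, m = NULL, gamma = 0.3, p_plus = 0.5,
                       d = NULL, sigma2 = 0) {
  stopifnot(
    length(n) == 1, n >= 2, n == as.integer(n),
    length(k) == 1, k >= 1, k <= n, k == as.integer(k),
    length(r) == 1, r >= 0, is.finite(r),
    length(gamma) == 1, gamma >= 0, is.finite(gamma),
    length(p_plus) == 1, p_plus >= 0, p_plus <= 1,
    length(sigma2) == 1, sigma2 >= 0, is.finite(sigma2)
  )
  if (k == 1) {
    if (!is.null(m)) {
      stop("`m` is undefined when k = 1 (single-group / Erdos-Renyi case); ",
           "leave it NULL.", call. = FALSE)
    }
  } else {
    if (is.null(m)) stop("`m` is required when k > 1.", call. = FALSE)
    stopifnot(length(m) == 1, is.finite(m))
    if (m <= 1 / k || m > 1) {
      stop("`m` must lie in (1/k, 1]: m <= 1/k is the dissociative regime, ",
           "which is excluded.", call. = FALSE)
    }
  }
  if (!is.null(d)) {
    stopifnot(length(d) == 1, is.finite(d))
    if (d <= 0) stop("`d` must be positive.", call. = FALSE)
  }
  structure(
    list(n = as.integer(n), k = as.integer(k), r = r, m = m, gamma = gamma,
         p_plus = p_plus, d = d, sigma2 = sigma2),
    class = "grn_params"
  )
}

#' @export
print.grn_params <- function(x, ...) {
  cat("<grn_params>\n")
  cat(sprintf("  n = %d genes, k = %d group(s)%s\n", x$n, x$k,
              if (is.null(x$m)) "" else sprintf(", m = %.4g", x$m)))
  cat(sprintf("  r = %.4g regulators/gene, gamma = %.4g, p_plus = %.4g\n",
              x$r, x$gamma, x$p_plus))
  if (!is.null(x$d)) cat(sprintf("  d = %.4g (out-degree uniformity)\n", x$d))
  cat(sprintf("  sigma2 = %.4g (h2 = %.4g)\n", x$sigma2,
              heritability_scaling(x$sigma2)))
  invisible(x)
}

#' Planted-partition edge probabilities from (r, m)
#'
#' Converts the interpretable parameterization (expected regulators per gene
#' `r`, within-group edge fraction `m`) into the classical planted-partition
#' probabilities: `p = 2krm/(n-1)` within groups and
#' `q = 2kr(1-m)/((k-1)(n-1))` between groups. The inverse map is
#' `r = (n-1)(p + q(k-1))/(2k)` and `m = p/(p + q(k-1))`.
#'
#' @param params A [grn_params()] object with `k >= 2`.
#' @return A one-row tibble with columns `p` and `q`.
#' @export
#' @examples
#' ppm_edge_probs(grn_params(n = 5000, k = 10, r = 5, m = 0.5))
ppm_edge_probs <- function(params) {
  stopifnot(inherits(params, "grn_params"))
  if (params$k < 2) {
    stop("ppm_edge_probs() requires k >= 2; use er_edge_prob() for k = 1.",
         call. = FALSE)
  }
  n <- params$n; k <- params$k; r <- params$r; m <- params$m
  p <- 2 * k * r * m / (n - 1)
  q <- 2 * k * r * (1 - m) / ((k - 1) * (n - 1))
  if (p > 1 || q > 1) {
    stop(sprintf(
      "Derived edge probabilities out of range (p = %.4g, q = %.4g): reduce k, r or m.",
      p, q), call. = FALSE)
  }
  tibble::tibble(p = p, q = q)
}

#' Erdos-Renyi edge probability from expected regulators per gene
#'
#' The single-group degeneracy of the planted-partition reparameterization:
#' with `k = 1` the expected in-degree is `r = (n-1)p/2`, so `p = 2r/(n-1)`.
#'
#' @param n Number of genes.
#' @param r Expected regulators per gene.
#' @return The edge probability `p` (scalar).
#' @export
#' @examples
#' er_edge_prob(1001, 5) # 0.01
er_edge_prob <- function(n, r) {
  stopifnot(n >= 2, r >= 0)
  p <- 2 * r / (n - 1)
  if (p > 1) {
    stop(sprintf("Edge probability %.4g exceeds 1: r too large for n.", p),
         call. = FALSE)
  }
  p
}

# Deterministic sub-stream seeds: one root seed per network; group assignment,
# ordering, edges, signs etc. each draw from their own derived stream.
derive_seed <- function(seed, stream) {
  s <- as.double(seed) %% 2147483647
  as.integer((s * 48271 + as.double(stream) * 8191 + 1) %% 2147483647)
}
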