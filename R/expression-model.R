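new_signed_grn <- function(topology, sign, gamma) {
  stopifnot(all(sign %in% c(-1L, 1L)), length(sign) == topology$n, gamma >= 0)
  structure(list(topology = topology, sign = as.integer(sign), gamma = gamma),
            class = "signed_grn")
}

#' @export
print.signed_grn <- function(x, ...) {
  cat(sprintf("<signed_grn> %d genes, %d edges, gamma = %.4g, %d activators\n",
              x$topology$n, nrow(x$topology$edges), x$gamma,
              sum(x$sign == 1L)))
  invisible(x)
}

#' Assign regulatory signs to a topology
#'
#' Each gene is independently declared an activator (sign +1) with probability
#' `p_plus`, else a repressor (-1). A gene acts with the same sign on all of
#' its targets, so the weight of every edge j -> i is `sign(j) * gamma`.
#'
#' @param topology A `grn_topology`.
#' @param p_plus Probability of being an activator.
#' @param gamma Magnitude of every regulatory effect.
#' @param seed Integer seed (deterministic assignment).
#' @return A `signed_grn` object.
#' @export
assign_signs <- function(topology, p_plus, gamma, seed) {
  stopifnot(inherits(topology, "grn_topology"),
            p_plus >= 0, p_plus <= 1, gamma >= 0)
  sign <- withr::with_seed(
    derive_seed(seed, 4L),
    ifelse(stats::runif(topology$n) < p_plus, 1L, -1L)
  )
  new_signed_grn(topology, sign, gamma)
}

#' Total-effects matrix of a signed GRN
#'
#' For the linear structural equation model on a DAG with weighted adjacency
#' `G` (`G[j, i]` = direct effect of gene j on gene i), the total effect of
#' each gene's aggregate cis input on every downstream gene is
#' `L = (I - G)^-1 = sum_t G^t` (a finite sum: `G` is nilpotent on a DAG).
#' `L[j, i]` equals the signed sum over all directed paths j -> i of the
#' product of edge weights; the diagonal is 1. The inverse is obtained by a
#' triangular solve in topological order, never by general dense inversion.
#'
#' @param grn A `signed_grn` from [assign_signs()].
#' @param method `"sparse"` (default: sparse triangular solve) or `"dense"`
#'   (dense backsolve, kept as an independent numerical route). Both give
#'   identical results.
#' @return A `total_effects` object holding `L` (genes x genes, `L[j, i]` the
#'   total effect of j on i) and the originating `grn`.
#' @export
#' @examples
#' topo <- generate_ppm_dag(grn_params(n = 50, k = 1, r = 3), seed = 1)
#' grn <- assign_signs(topo, p_plus = 1, gamma = 0.5, seed = 1)
#' eff <- total_effects(grn)
#' variance_decomposition(eff)
total_effects <- function(grn, method = c("sparse", "dense")) {
  stopifnot(inherits(grn, "signed_grn"))
  method <- match.arg(method)
  topo <- grn$topology
  n <- topo$n
  idx <- topo$index
  e <- topo$edges
  # Work in topological coordinates: A = I - G is unit upper triangular.
  fi <- idx[e$from]
  ti <- idx[e$to]
  w <- grn$sign[e$from] * grn$gamma
  if (method == "dense") {
    A <- diag(n)
    if (nrow(e) > 0) A[cbind(fi, ti)] <- -w
    L_topo <- backsolve(A, diag(n))
  } else {
    A <- Matrix::sparseMatrix(i = c(seq_len(n), fi), j = c(seq_len(n), ti),
                              x = c(rep(1, n), -w), dims = c(n, n))
    L_topo <- Matrix::solve(methods::as(A, "triangularMatrix"))
  }
  inv <- order(idx)                      # inv[pos] = gene at that position
  perm <- idx                            # gene -> position
  L <- L_topo[perm, perm, drop = FALSE]  # L[j, i] in gene coordinates
  structure(list(L = L, grn = grn), class = "total_effects")
}

#' @export
print.total_effects <- function(x, ...) {
  cat(sprintf("<total_effects> %d genes, %d nonzero total effects\n",
              x$grn$topology$n,
              if (inherits(x$L, "sparseMatrix")) Matrix::nnzero(x$L)
              else sum(x$L != 0)))
  invisible(x)
}

col_sq_norms <- function(L) {
  if (inherits(L, "sparseMatrix")) Matrix::colSums(L^2) else colSums(L^2)
}

col_max_offdiag_abs <- function(L) {
  n <- ncol(L)
  if (inherits(L, "sparseMatrix")) {
    out <- numeric(n)
    M <- methods::as(L, "TsparseMatrix")   # 0-based triplet slots
    off <- M@i != M@j
    if (any(off)) {
      mx <- tapply(abs(M@x[off]), M@j[off] + 1L, max)
      out[as.integer(names(mx))] <- as.numeric(mx)
    }
    out
  } else {
    M <- abs(L)
    diag(M) <- 0
    apply(M, 2, max)
  }
}

#' Exact per-gene variance decomposition
#'
#' From the total-effects matrix, each gene's genetic variance is
#' `V_G,i = (L'L)_ii` (with every gene's aggregate cis input normalized to
#' unit variance), the cis fraction is `L_ii^2 / (L'L)_ii = 1/(L'L)_ii`, and
#' the trans contribution of regulator j is `B_ji^2 = L_ji^2 / (L'L)_ii`.
#' The lead trans fraction is the largest single-regulator contribution and
#' the lead ratio `max_j |L_ji| / |L_ii|` is its amplitude counterpart, a
#' proxy for the lead trans/cis eQTL effect-size ratio.
#'
#' @param effects A `total_effects` object.
#' @return A tibble with one row per gene: `gene`, `index` (topological
#'   position), `v_g`, `cis_fraction`, `trans_fraction`,
#'   `lead_trans_fraction`, `lead_ratio`, `lead_trans_scaled`
#'   (`max_j |L_ji| / sqrt(V_G,i)`, the lead trans effect in units of
#'   expression standard deviations), and `n_ancestors` (direct and indirect
#'   regulators).
#' @export
variance_decomposition <- function(effects) {
  stopifnot(inherits(effects, "total_effects"))
  topo <- effects$grn$topology
  v_g <- as.numeric(col_sq_norms(effects$L))
  lead_amp <- as.numeric(col_max_offdiag_abs(effects$L))
  tibble::tibble(
    gene = seq_len(topo$n),
    index = topo$index,
    v_g = v_g,
    cis_fraction = 1 / v_g,
    trans_fraction = 1 - 1 / v_g,
    lead_trans_fraction = lead_amp^2 / v_g,
    lead_ratio = lead_amp,
    lead_trans_scaled = lead_amp / sqrt(v_g),
    n_ancestors = ancestor_counts(topo)$n_ancestors
  )
}

#' Distance-resolved variance decomposition
#'
#' Splits each gene's genetic variance by the unweighted directed
#' shortest-path distance from regulator to target: the fraction at distance
#' `d` for gene i is `sum_{j: d_ji = d} L_ji^2 / (L'L)_ii`, with distance 0
#' the cis term. Fractions for each gene sum to 1 over distances.
#'
#' @param effects A `total_effects` object.
#' @return A long tibble `gene`, `distance`, `fraction` (rows only for
#'   distances with at least one contributing regulator).
#' @export
distance_decomposition <- function(effects) {
  stopifnot(inherits(effects, "total_effects"))
  topo <- effects$grn$topology
  g <- topology_igraph(topo)
  dmat <- igraph::distances(g, mode = "out")   # dmat[j, i] = dist j -> i
  n <- topo$n
  L2 <- as.matrix(effects$L)^2
  v_g <- colSums(L2)
  finite <- is.finite(dmat)
  # column-major over dmat[j, i]: regulator j varies fastest, target i per column
  gene <- rep(seq_len(n), each = n)[finite]
  dist <- as.integer(dmat[finite])
  key <- gene * (n + 1) + dist             # distance <= n - 1 < n + 1
  agg <- rowsum(as.numeric(L2[finite]), key)  # sorted by key: gene, distance
  keys <- as.numeric(rownames(agg))
  out_gene <- as.integer(keys %/% (n + 1))
  tibble::tibble(
    gene = out_gene,
    distance = as.integer(keys %% (n + 1)),
    fraction = as.numeric(agg) / v_g[out_gene]
  )
}

#' Simulate individual-level expression (Monte-Carlo oracle)
#'
#' Draws `q_per_gene` standardized biallelic genotypes per gene (binomial
#' allele counts, minor-allele frequency 0.5, standardized), with equal
#' effects `beta = 1/sqrt(q)` so each gene's aggregate cis input has unit
#' variance, then builds expression gene-by-gene in topological order:
#' `y_i = cis_i + sum_{j in parents(i)} sign_j * gamma * y_j + noise_i`.
#' Empirical variance components converge to [variance_decomposition()] as
#' `n_individuals` grows; this simulator is the package's independent check
#' on the analytic decomposition.
#'
#' @param grn A `signed_grn`.
#' @param n_individuals Number of simulated individuals (>= 2).
#' @param q_per_gene Number of cis variants per gene (>= 1).
#' @param sigma2 Non-genetic noise variance.
#' @param seed Integer seed.
#' @return A list of class `individual_sample` with matrices `y`, `cis`,
#'   `noise` (individuals x genes) and the `grn`.
#' @export
simulate_individuals <- function(grn, n_individuals, q_per_gene = 1,
                                 sigma2 = 0, seed = 1) {
  stopifnot(inherits(grn, "signed_grn"), n_individuals >= 2, q_per_gene >= 1)
  topo <- grn$topology
  n <- topo$n
  withr::with_seed(derive_seed(seed, 5L), {
    beta <- 1 / sqrt(q_per_gene)
    cis <- matrix(0, n_individuals, n)
    for (kk in seq_len(q_per_gene)) {
      x <- matrix(stats::rbinom(n_individuals * n, 2, 0.5),
                  n_individuals, n)
      cis <- cis + beta * (x - 1) / sqrt(0.5)
    }
    noise <- if (sigma2 > 0) {
      matrix(stats::rnorm(n_individuals * n, sd = sqrt(sigma2)),
             n_individuals, n)
    } else {
      matrix(0, n_individuals, n)
    }
    y <- cis + noise
    gene_at <- order(topo$index)
    parents <- split(topo$edges$from, topo$edges$to)
    for (g in gene_at) {
      par <- parents[[as.character(g)]]
      if (is.null(par)) next
      y[, g] <- y[, g] +
        y[, par, drop = FALSE] %*% (grn$sign[par] * grn$gamma)
    }
    structure(list(y = y, cis = cis, noise = noise, grn = grn),
              class = "individual_sample")
  })
}

#' Heritability implied by the noise variance
#'
#' With unit aggregate cis variance per gene, the noise variance scales the
#' ratio of genetic to total variance identically for all genes:
#' `h2 = 1 / (1 + sigma2)`.
#'
#' @param sigma2 Non-genetic noise variance (>= 0).
#' @return The per-gene heritability.
#' @export
#' @examples
#' heritability_scaling(1) # 0.5
heritability_scaling <- function(sigma2) {
  stopifnot(all(sigma2 >= 0))
  1 / (1 + sigma2)
}

#' Serialize a variance decomposition to TSV
#'
#' @param decomp Tibble from [variance_decomposition()].
#' @param path Output TSV path.
#' @param distance Optional long tibble from [distance_decomposition()];
#'   written alongside as `<path>.distance.tsv`.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(decomp, path, distance = NULL) {
  readr::write_tsv(
    decomp[, c("gene", "cis_fraction", "lead_trans_fraction", "lead_ratio",
               "n_ancestors")],
    path
  )
  if (!is.null(distance)) {
    readr::write_tsv(distance, paste0(path, ".distance.tsv"))
  }
  invisible(path)
}
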