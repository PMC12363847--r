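#' @importFrom rlang .data
NULL

new_grn_topology <- function(n, index, edges, groups, k) {
  structure(
    list(n = as.integer(n), index = as.integer(index),
         edges = tibble::as_tibble(edges), groups = as.integer(groups),
         k = as.integer(k)),
    class = "grn_topology"
  )
}

#' @export
print.grn_topology <- function(x, ...) {
  cat(sprintf("<grn_topology> %d genes, %d edges, %d group(s)\n",
              x$n, nrow(x$edges), x$k))
  invisible(x)
}

validate_topology <- function(topology) {
  stopifnot(inherits(topology, "grn_topology"))
  e <- topology$edges
  idx <- topology$index
  if (nrow(e) > 0) {
    stopifnot(
      all(e$from >= 1), all(e$to <= topology$n),
      all(idx[e$from] < idx[e$to]),           # acyclic by construction
      !anyDuplicated(paste(e$from, e$to))
    )
  }
  invisible(topology)
}

#' Generate a random DAG from the reparameterized planted-partition model
#'
#' Assigns `n` genes to `k` groups uniformly at random, draws a random
#' topological ordering, and places an edge between each unordered pair
#' independently with probability `p` (same group) or `q` (different groups),
#' with `(p, q)` derived from `(r, m)` via [ppm_edge_probs()]. Every edge is
#' oriented from the lower to the higher topological index, so the result is
#' acyclic by construction. With `k = 1` the Erdos-Renyi probability
#' [er_edge_prob()] is used and group structure is absent.
#'
#' @param params A [grn_params()] object.
#' @param seed Integer root seed; group assignment, ordering and edge draws
#'   use sub-streams derived deterministically from it, so identical
#'   `(params, seed)` yield identical topologies.
#' @return A `grn_topology`: gene count `n`, per-gene topological `index`,
#'   an `edges` tibble (`from`, `to`), per-gene `groups`, and `k`.
#' @export
#' @examples
#' topo <- generate_ppm_dag(grn_params(n = 100, k = 2, r = 3, m = 0.8), seed = 1)
#' topology_stats(topo)
generate_ppm_dag <- function(params, seed) {
  stopifnot(inherits(params, "grn_params"))
  n <- params$n
  k <- params$k
  groups <- withr::with_seed(derive_seed(seed, 1L),
                             sample.int(k, n, replace = TRUE))
  index <- withr::with_seed(derive_seed(seed, 2L), sample.int(n))
  edges <- withr::with_seed(derive_seed(seed, 3L), {
    if (k == 1) {
      p <- er_edge_prob(n, params$r)
      g <- igraph::sample_gnp(n, p, directed = FALSE)
      el <- igraph::as_edgelist(g, names = FALSE)
      list(u = el[, 1], v = el[, 2])
    } else {
      pq <- ppm_edge_probs(params)
      pref <- matrix(pq$q, k, k)
      diag(pref) <- pq$p
      sizes <- tabulate(groups, nbins = k)
      g <- igraph::sample_sbm(n, pref.matrix = pref, block.sizes = sizes,
                              directed = FALSE)
      # sample_sbm orders vertices by block; map back to gene ids
      gene_of_vertex <- order(groups)
      el <- igraph::as_edgelist(g, names = FALSE)
      list(u = gene_of_vertex[el[, 1]], v = gene_of_vertex[el[, 2]])
    }
  })
  from <- ifelse(index[edges$u] < index[edges$v], edges$u, edges$v)
  to <- ifelse(index[edges$u] < index[edges$v], edges$v, edges$u)
  ord <- order(index[from], index[to])
  topo <- new_grn_topology(
    n, index,
    tibble::tibble(from = as.integer(from[ord]), to = as.integer(to[ord])),
    groups, k
  )
  validate_topology(topo)
}

#' Generate a modular acyclic scale-free DAG
#'
#' Sequential (Bollobas-style) construction with an out-degree uniformity
#' parameter `d`. Genes are assigned to `k` groups uniformly and created in a
#' random topological order; the gene at position `i` draws its parent count
#' from `Binomial(i - 1, 2r/(n - 1))` (the same marginal in-degree profile as
#' the planted-partition model, so the expected in-degree is `r`) and samples
#' parents without replacement from its predecessors with weight
#' `(out-degree + d) * g`, where the within-group boost `g = m(k-1)/(1-m)`
#' calibrates the expected within-group edge fraction to `m`. Small `d` makes
#' early accumulation of out-degree self-reinforcing (hubs, heavy-tailed
#' out-degree); as `d` grows the weights flatten and the generator approaches
#' the planted-partition/ER case.
#'
#' @inheritParams generate_ppm_dag
#' @return A `grn_topology`; see [generate_ppm_dag()].
#' @export
#' @examples
#' p <- grn_params(n = 200, k = 1, r = 4, d = 2)
#' topo <- generate_scalefree_dag(p, seed = 7)
#' topology_stats(topo)
generate_scalefree_dag <- function(params, seed) {
  stopifnot(inherits(params, "grn_params"))
  if (is.null(params$d)) {
    stop("scale-free generation requires `d` in grn_params().", call. = FALSE)
  }
  n <- params$n
  k <- params$k
  p_edge <- er_edge_prob(n, params$r)   # marginal in-degree profile
  groups <- withr::with_seed(derive_seed(seed, 1L),
                             sample.int(k, n, replace = TRUE))
  index <- withr::with_seed(derive_seed(seed, 2L), sample.int(n))
  gene_at <- order(index)               # gene_at[pos] = gene with that index
  boost <- if (k == 1 || is.null(params$m)) {
    1
  } else if (params$m >= 1) {
    Inf
  } else {
    params$m * (k - 1) / (1 - params$m)
  }
  from_l <- withr::with_seed(derive_seed(seed, 3L), {
    outdeg <- numeric(n)                # indexed by position
    fl <- vector("list", n)
    for (i in seq_len(n)[-1]) {
      n_par <- stats::rbinom(1, i - 1L, p_edge)
      if (n_par == 0) next
      pred <- seq_len(i - 1L)
      w <- outdeg[pred] + params$d
      same <- groups[gene_at[pred]] == groups[gene_at[i]]
      if (is.infinite(boost)) {
        pred <- pred[same]
        if (length(pred) == 0) next
        w <- w[same]
      } else {
        w <- w * ifelse(same, boost, 1)
      }
      n_par <- min(n_par, length(pred))
      par <- if (length(pred) == 1) pred else sample(pred, n_par, prob = w)
      outdeg[par] <- outdeg[par] + 1
      fl[[i]] <- par
    }
    fl
  })
  edges_from <- unlist(from_l, use.names = FALSE)
  if (is.null(edges_from)) edges_from <- integer(0)
  edges_to <- rep.int(seq_len(n), vapply(from_l, length, integer(1)))
  topo <- new_grn_topology(
    n, index,
    tibble::tibble(from = as.integer(gene_at[edges_from]),
                   to = as.integer(gene_at[edges_to]))[
                     order(index[gene_at[edges_from]],
                           index[gene_at[edges_to]]), , drop = FALSE],
    groups, k
  )
  validate_topology(topo)
}

#' Realized summary statistics of a topology
#'
#' Diagnostics for the generator contracts: realized mean in-degree, realized
#' within-group edge fraction, edge count, and the out-degree distribution.
#'
#' @param topology A `grn_topology`.
#' @return A one-row tibble with columns `n_genes`, `n_edges`,
#'   `mean_in_degree`, `within_group_fraction` (NA when `k = 1` or no edges),
#'   `out_degree_var`, and a list-column `out_degree` holding the full
#'   per-gene out-degree vector.
#' @export
topology_stats <- function(topology) {
  stopifnot(inherits(topology, "grn_topology"))
  e <- topology$edges
  outdeg <- tabulate(e$from, nbins = topology$n)
  within <- if (nrow(e) == 0 || topology$k == 1) {
    NA_real_
  } else {
    mean(topology$groups[e$from] == topology$groups[e$to])
  }
  tibble::tibble(
    n_genes = topology$n,
    n_edges = nrow(e),
    mean_in_degree = nrow(e) / topology$n,
    within_group_fraction = within,
    out_degree_var = stats::var(outdeg),
    out_degree = list(outdeg)
  )
}

#' Write / read a topology as plain-text TSV
#'
#' The edge list uses 0-based gene indices with header `source<TAB>target`;
#' a companion `<path>.genes.tsv` stores per-gene attributes
#' (`gene<TAB>group<TAB>index`, plus `sign` for signed networks).
#'
#' @param topology A `grn_topology` (or `signed_grn`, whose signs are saved).
#' @param path Output path for the edge-list TSV.
#' @return `path`, invisibly (writer); a `grn_topology` or `signed_grn`
#'   (reader).
#' @export
write_edges <- function(topology, path) {
  signed <- inherits(topology, "signed_grn")
  topo <- if (signed) topology$topology else topology
  stopifnot(inherits(topo, "grn_topology"))
  readr::write_tsv(
    tibble::tibble(source = topo$edges$from - 1L, target = topo$edges$to - 1L),
    path
  )
  nodes <- tibble::tibble(
    gene = seq_len(topo$n) - 1L,
    group = topo$groups,
    index = topo$index - 1L
  )
  if (signed) nodes$sign <- topology$sign
  readr::write_tsv(nodes, paste0(path, ".genes.tsv"))
  invisible(path)
}

#' @rdname write_edges
#' @param gamma Effect magnitude to attach when the node table carries signs.
#' @export
read_edges <- function(path, gamma = NULL) {
  e <- readr::read_tsv(path, col_types = "ii", progress = FALSE)
  nodes <- readr::read_tsv(paste0(path, ".genes.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  topo <- new_grn_topology(
    n = nrow(nodes),
    index = nodes$index + 1L,
    edges = tibble::tibble(from = e$source + 1L, to = e$target + 1L),
    groups = nodes$group,
    k = max(nodes$group)
  )
  validate_topology(topo)
  if ("sign" %in% names(nodes)) {
    if (is.null(gamma)) {
      stop("node table carries signs; supply `gamma` to rebuild the signed GRN.",
           call. = FALSE)
    }
    new_signed_grn(topo, as.integer(nodes$sign), gamma)
  } else {
    topo
  }
}

topology_igraph <- function(topology) {
  igraph::make_graph(
    edges = rbind(topology$edges$from, topology$edges$to),
    n = topology$n, directed = TRUE
  )
}
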