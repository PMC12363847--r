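#' Two-sample Kolmogorov-Smirnov distance
#'
#' The supremum absolute difference between the two empirical CDFs over the
#' pooled support, used purely as a non-parametric distance between a
#' simulated and a reference cis-fraction distribution (no p-value is
#' attached; ties are handled exactly).
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return The statistic D in \[0, 1\]; symmetric in its arguments.
#' @export
#' @examples
#' ks_distance(c(1, 2, 3, 4), c(3, 4, 5, 6)) # 0.5
ks_distance <- function(sample_a, sample_b) {
  sample_a <- sample_a[!is.na(sample_a)]
  sample_b <- sample_b[!is.na(sample_b)]
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    stop("both samples must be non-empty.", call. = FALSE)
  }
  z <- sort(unique(c(sample_a, sample_b)))
  fa <- findInterval(z, sort(sample_a)) / length(sample_a)
  fb <- findInterval(z, sort(sample_b)) / length(sample_b)
  max(abs(fa - fb))
}

#' Select the matched tail of K-S statistics
#'
#' Returns the indices of the `round(tail_fraction * N)` smallest statistics;
#' ties are broken by index order, so the selection is deterministic.
#'
#' @param ks_stats Numeric vector of per-network K-S statistics.
#' @param tail_fraction Fraction of networks to select, in (0, 1).
#' @return Integer vector of selected indices (sorted by statistic, then
#'   index).
#' @export
select_matched <- function(ks_stats, tail_fraction) {
  stopifnot(tail_fraction > 0, tail_fraction < 1, length(ks_stats) >= 1)
  n_sel <- round(tail_fraction * length(ks_stats))
  ord <- order(ks_stats, seq_along(ks_stats))
  ord[seq_len(n_sel)]
}

#' Per-gene count of direct and indirect regulators
#'
#' The number of distinct genes with a directed path into each gene
#' (reachability closure, excluding the gene itself).
#'
#' @param topology A `grn_topology`.
#' @return A tibble `gene`, `n_ancestors`.
#' @export
ancestor_counts <- function(topology) {
  stopifnot(inherits(topology, "grn_topology"))
  g <- topology_igraph(topology)
  dmat <- igraph::distances(g, mode = "out")
  tibble::tibble(
    gene = seq_len(topology$n),
    n_ancestors = as.integer(colSums(is.finite(dmat)) - 1L)
  )
}

#' Cumulative variance fraction within a network distance
#'
#' Per-gene sum of distance-resolved fractions at distances `0..max_distance`
#' (distance 0 is the cis term). Non-decreasing in `max_distance` and equal
#' to 1 at the graph diameter.
#'
#' @param distance_fractions Long tibble from [distance_decomposition()].
#' @param max_distance Hop threshold `d`.
#' @return A tibble `gene`, `cumulative`.
#' @export
cumulative_by_distance <- function(distance_fractions, max_distance) {
  stopifnot(max_distance >= 0)
  distance_fractions |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      cumulative = sum(.data$fraction[.data$distance <= max_distance]),
      .groups = "drop"
    )
}

#' One-row summary of a simulated GRN
#'
#' The per-network summary statistics used throughout the sweep analyses:
#' the median cis fraction (the central summary), the median lead trans/cis
#' amplitude ratio, motif counts, realized topology statistics, the median
#' ancestor count, and the median cumulative variance fraction within two
#' hops.
#'
#' @param decomp Per-gene tibble from [variance_decomposition()].
#' @param topology The `grn_topology` the decomposition came from.
#' @param motifs One-row tibble from [count_motifs()]; computed here when
#'   `NULL`.
#' @param distance_fractions Optional long tibble from
#'   [distance_decomposition()]; when supplied, `median_cum2` (median
#'   cumulative fraction within distance 2) is filled in.
#' @return A one-row tibble.
#' @export
summarize_grn <- function(decomp, topology, motifs = NULL,
                          distance_fractions = NULL) {
  stopifnot(inherits(topology, "grn_topology"))
  if (is.null(motifs)) motifs <- count_motifs(topology)
  stats <- topology_stats(topology)
  median_cum2 <- if (is.null(distance_fractions)) {
    NA_real_
  } else {
    stats::median(cumulative_by_distance(distance_fractions, 2)$cumulative)
  }
  tibble::tibble(
    median_cis_fraction = stats::median(decomp$cis_fraction),
    median_lead_ratio = stats::median(decomp$lead_ratio),
    median_lead_trans_scaled = stats::median(decomp$lead_trans_scaled),
    median_ancestors = stats::median(decomp$n_ancestors),
    median_cum2 = median_cum2,
    n_ffl = motifs$n_ffl,
    n_biparallel = motifs$n_biparallel,
    n_edges = stats$n_edges,
    mean_in_degree = stats$mean_in_degree,
    within_group_fraction = stats$within_group_fraction,
    out_degree_var = stats$out_degree_var
  )
}
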