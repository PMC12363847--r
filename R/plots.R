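#' Empirical CDFs of per-gene cis fractions
#'
#' Overlays the cis-fraction ECDF of one or more decompositions (and,
#' optionally, a reference heritability table) — the standard way to compare
#' simulated networks with observed heritability partitions.
#'
#' @param decomps Named list of tibbles from [variance_decomposition()] (or
#'   any data frame with a `cis_fraction` column).
#' @param reference Optional heritability tibble with `cis_fraction`.
#' @return A ggplot object.
#' @export
plot_cis_fraction_cdf <- function(decomps, reference = NULL) {
  if (is.data.frame(decomps)) decomps <- list(simulated = decomps)
  if (is.null(names(decomps)) || any(names(decomps) == "")) {
    names(decomps) <- paste0("grn", seq_along(decomps))
  }
  df <- purrr::imap_dfr(decomps, function(d, nm) {
    tibble::tibble(source = nm, cis_fraction = d$cis_fraction)
  })
  if (!is.null(reference)) {
    df <- dplyr::bind_rows(
      df,
      tibble::tibble(source = "reference",
                     cis_fraction = reference$cis_fraction[
                       !is.na(reference$cis_fraction)])
    )
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cis_fraction,
                                   colour = .data$source)) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::coord_cartesian(xlim = c(0, 1)) +
    ggplot2::labs(x = "cis fraction of genetic variance",
                  y = "cumulative fraction of genes", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Median cumulative heritability by network distance
#'
#' @param profile The `profile` tibble from [run_exemplar_report()].
#' @return A ggplot object.
#' @export
plot_distance_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$distance,
                               y = .data$median_cumulative,
                               colour = .data$exemplar)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "network distance from regulator to gene",
                  y = "median cumulative fraction of genetic variance",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Matched vs background parameter distributions
#'
#' Faceted density comparison of the generating parameters in the matched
#' tail against the remaining networks.
#'
#' @param object A `grn_match` object.
#' @param params Parameter columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grn_match <- function(object,
                               params = c("r", "gamma", "p_plus", "m", "d"),
                               ...) {
  tbl <- tidy(object)
  params <- intersect(params, names(tbl))
  params <- params[vapply(params, function(p) !all(is.na(tbl[[p]])),
                          logical(1))]
  df <- tidyr::pivot_longer(
    tbl[, c(params, "matched")], dplyr::all_of(params),
    names_to = "parameter", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value,
                                   fill = .data$matched)) +
    ggplot2::geom_density(alpha = 0.5, colour = NA) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = NULL, fill = "matched") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
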