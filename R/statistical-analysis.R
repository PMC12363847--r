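#' Features derived from network parameters
#'
#' `direct_effect_feature()` is the dominant predictor of the median cis
#' fraction, `1 / (1 + r gamma^2)`: the cis fraction a gene would have if all
#' `r` of its regulators were independent. `scaled_group_terms()` are the
#' group-structure features `(2 p_plus - 1) * k` and `(2 p_plus - 1) * m`:
#' group structure only moves trans variance through sign-coherent paths, so
#' its effect scales with the expected regulator sign.
#'
#' @param r Expected regulators per gene.
#' @param gamma Regulatory effect magnitude.
#' @return `direct_effect_feature()`: a numeric vector.
#'   `scaled_group_terms()`: a tibble with columns `k_scaled`, `m_scaled`.
#' @export
#' @examples
#' direct_effect_feature(6, 0.4) # ~0.5102
direct_effect_feature <- function(r, gamma) {
  stopifnot(all(r >= 0), all(gamma >= 0))
  1 / (1 + r * gamma^2)
}

#' @rdname direct_effect_feature
#' @param k Number of groups.
#' @param m Within-group edge fraction.
#' @param p_plus Probability of being an activator.
#' @export
scaled_group_terms <- function(k, m, p_plus) {
  s <- 2 * p_plus - 1
  tibble::tibble(k_scaled = s * k, m_scaled = s * m)
}

#' Ordinary-least-squares residualization
#'
#' Residuals of `response` on the feature columns, with intercept. Residuals
#' are orthogonal to every feature and have mean zero.
#'
#' @param response Numeric vector.
#' @param features Numeric vector, matrix, or data frame of features (rows
#'   matching `response`).
#' @return Numeric vector of residuals.
#' @export
residualize <- function(response, features) {
  X <- cbind(`(Intercept)` = 1, as.matrix(features))
  stopifnot(nrow(X) == length(response), all(is.finite(X)),
            all(is.finite(response)))
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design: drop collinear features.", call. = FALSE)
  }
  as.numeric(stats::lm.fit(X, response)$residuals)
}

r_squared <- function(response, features) {
  tss <- sum((response - mean(response))^2)
  if (tss < 1e-20 * length(response)) return(0) # nothing left to explain
  fit <- stats::lm.fit(cbind(1, as.matrix(features)), response)
  1 - sum(fit$residuals^2) / tss
}

#' Mediation of an exposure's R-squared by candidate mediators
#'
#' Compares the variance in `response` explained by `exposure` before and
#' after residualizing the response on the `mediators` (here, motif counts):
#' `r2_unadjusted` is the R-squared of `response ~ exposure`;
#' `r2_adjusted` that of `resid(response ~ mediators) ~ exposure`. The
#' mediated share is `1 - r2_adjusted / r2_unadjusted` (reported when
#' `r2_unadjusted > 0`). Features are z-scored internally for conditioning;
#' R-squared is invariant to this.
#'
#' @param response,exposure Numeric vectors.
#' @param mediators Numeric vector, matrix, or data frame.
#' @return An object of class `grn_mediation`; see [tidy.grn_mediation()].
#' @export
mediation_r2 <- function(response, exposure, mediators) {
  stopifnot(length(exposure) == length(response))
  if (stats::sd(exposure) == 0) {
    stop("degenerate (constant) exposure.", call. = FALSE)
  }
  zscore <- function(x) {
    x <- as.matrix(x)
    apply(x, 2, function(col) {
      if (stats::sd(col) == 0) col - mean(col) else (col - mean(col)) / stats::sd(col)
    })
  }
  med <- zscore(mediators)
  stopifnot(nrow(med) == length(response))
  r2_un <- r_squared(response, zscore(exposure))
  adj <- residualize(response, med)
  r2_adj <- r_squared(adj, zscore(exposure))
  structure(
    list(r2_unadjusted = r2_un,
         r2_adjusted = r2_adj,
         mediated_share = if (r2_un > 0) 1 - r2_adj / r2_un else NA_real_,
         n = length(response),
         n_mediators = ncol(med)),
    class = "grn_mediation"
  )
}

#' @export
print.grn_mediation <- function(x, ...) {
  cat(sprintf(
    "<grn_mediation> R2 %.4f -> %.4f after %d mediator(s) (mediated share %.2f)\n",
    x$r2_unadjusted, x$r2_adjusted, x$n_mediators, x$mediated_share))
  invisible(x)
}

#' Tidy a mediation result
#'
#' @param x A `grn_mediation` object.
#' @param ... Unused.
#' @return `tidy()`: a two-row tibble (`model`, `r.squared`); `glance()`: a
#'   one-row tibble with `r2_unadjusted`, `r2_adjusted`, `mediated_share`,
#'   `n`, `n_mediators`.
#' @export
tidy.grn_mediation <- function(x, ...) {
  tibble::tibble(model = c("unadjusted", "adjusted"),
                 r.squared = c(x$r2_unadjusted, x$r2_adjusted))
}

#' @rdname tidy.grn_mediation
#' @export
glance.grn_mediation <- function(x, ...) {
  tibble::tibble(r2_unadjusted = x$r2_unadjusted,
                 r2_adjusted = x$r2_adjusted,
                 mediated_share = x$mediated_share,
                 n = x$n, n_mediators = x$n_mediators)
}

#' Structure-heritability analysis of a sweep table
#'
#' Reproduces the residualization-and-mediation workflow on a sweep of
#' simulated networks. The response is the per-network median cis fraction
#' residualized on the direct-effect feature `1/(1 + r gamma^2)`; each term in
#' `terms` is then assessed univariately for its R-squared before and after
#' residualizing the response on the motif-count mediators.
#'
#' @param sweep A sweep tibble from [run_sweep()] (needs columns `r`, `gamma`,
#'   `p_plus`, `median_cis_fraction`, `n_ffl`, `n_biparallel`, plus `k`, `m`
#'   or `d` as required by `terms`).
#' @param terms Character vector of exposures to assess: any of `"k_scaled"`,
#'   `"m_scaled"` (group terms scaled by `2 p_plus - 1`) and `"log_d"`.
#' @param mediator_interactions If `TRUE` (default), the mediator set is the
#'   motif counts together with their `(2 p_plus - 1)` and `(2 p_plus - 1)^2`
#'   interactions — the scaling under which motif-borne covariance enters the
#'   variance decomposition; if `FALSE`, raw counts only.
#' @return A tibble with one row per term: `term`, `r2_unadjusted`,
#'   `r2_adjusted`, `mediated_share`, plus a `direct_r2` column giving the
#'   R-squared of the direct-effect feature itself (same value each row).
#' @export
sweep_mediation <- function(sweep,
                            terms = c("k_scaled", "m_scaled"),
                            mediator_interactions = TRUE) {
  stopifnot(is.data.frame(sweep), nrow(sweep) >= 10)
  direct <- direct_effect_feature(sweep$r, sweep$gamma)
  direct_r2 <- r_squared(sweep$median_cis_fraction, direct)
  response <- residualize(sweep$median_cis_fraction, direct)
  s <- 2 * sweep$p_plus - 1
  mediators <- cbind(ffl = sweep$n_ffl, bip = sweep$n_biparallel)
  if (mediator_interactions) {
    mediators <- cbind(
      mediators,
      ffl_s = sweep$n_ffl * s, bip_s = sweep$n_biparallel * s,
      ffl_s2 = sweep$n_ffl * s^2, bip_s2 = sweep$n_biparallel * s^2
    )
  }
  exposure_of <- function(term) {
    switch(term,
           k_scaled = s * sweep$k,
           m_scaled = s * sweep$m,
           log_d = log(sweep$d),
           stop("unknown term: ", term, call. = FALSE))
  }
  purrr::map_dfr(terms, function(term) {
    med <- mediation_r2(response, exposure_of(term), mediators)
    dplyr::bind_cols(tibble::tibble(term = term), glance(med))
  }) |>
    dplyr::mutate(direct_r2 = direct_r2)
}
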