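#' Configuration of a network sweep
#'
#' Describes how to draw the per-network parameters of a sweep: each of `k`,
#' `m`, `r`, `gamma`, `p_plus`, `d` is either a fixed value or a length-2
#' range. `k` is drawn as a uniform integer over its range; `m` uniformly on
#' `(max(lower, 1/k), upper)` conditional on the drawn `k` (default lower
#' bound `1/k`); `d` log-uniformly; the others uniformly. `d = NULL` with
#' `generator = "ppm"`.
#'
#' @param generator `"ppm"` or `"scalefree"`.
#' @param n_grns Number of networks to simulate.
#' @param n_genes Genes per network.
#' @param k,m,r,gamma,p_plus,d Fixed value or `c(lower, upper)` range. Use
#'   `m = NULL` with `k = 1`, `d = NULL` for the PPM.
#' @param sigma2 Noise variance (fixed; affects only the heritability scale).
#' @param seed Root seed; each network `i` uses a recorded sub-seed derived
#'   from it, so any single network can be regenerated in isolation.
#' @param tail_fraction Default matched-tail fraction for [run_matching()].
#' @return A `sweep_config` object.
#' @seealso [preset_config()] for the shipped experiment presets.
#' @export
sweep_config <- function(generator = c("ppm", "scalefree"),
                         n_grns = 100, n_genes = 500,
                         k = 1, m = NULL, r = c(2, 10),
                         gamma = c(0.2, 0.5), p_plus = c(0, 1),
                         d = NULL, sigma2 = 0, seed = 1,
                         tail_fraction = 0.025) {
  generator <- match.arg(generator)
  stopifnot(n_grns >= 1, n_genes >= 2)
  if (generator == "scalefree" && is.null(d)) {
    stop("scale-free sweeps need `d` (fixed value or range).", call. = FALSE)
  }
  rng_ok <- function(x) is.null(x) || length(x) == 1 ||
    (length(x) == 2 && x[1] <= x[2])
  stopifnot(rng_ok(k), rng_ok(m), rng_ok(r), rng_ok(gamma), rng_ok(p_plus),
            rng_ok(d))
  structure(
    list(generator = generator, n_grns = as.integer(n_grns),
         n_genes = as.integer(n_genes), k = k, m = m, r = r, gamma = gamma,
         p_plus = p_plus, d = d, sigma2 = sigma2, seed = as.integer(seed),
         tail_fraction = tail_fraction),
    class = "sweep_config"
  )
}

#' Shipped experiment presets
#'
#' Three named experiment designs, each at two scales:
#' * `"er50"`: 50 single-group (Erdos-Renyi) networks of 1000 genes with
#'   `r ~ U(4, 8)`, `gamma ~ U(0.1, 0.5)`, `p_plus = 0.5` — the introductory
#'   example of cis-fraction distributions across simple networks.
#' * `"ppm"`: the planted-partition sweep — `k ~ U{2..100}`, `m ~ U(1/k, 1)`,
#'   `r ~ U(2, 10)`, `gamma ~ U(0.2, 0.5)`, `p_plus ~ U(0, 1)`; full scale is
#'   10,000 networks of 5000 genes.
#' * `"scalefree"`: the same parameter ranges plus
#'   `log d ~ U(log 1, log 30)`.
#'
#' The `"desk"` scale replaces (10,000 networks x 5000 genes) with
#' (500 x 500) and restricts `k` to `{2..20}` so the planted-partition edge
#' probabilities stay below 1 at the smaller gene count; it runs in minutes
#' on one core through the identical code path.
#'
#' @param name `"er50"`, `"ppm"`, or `"scalefree"`.
#' @param scale `"desk"` or `"full"`.
#' @param seed Root seed.
#' @return A [sweep_config()].
#' @export
preset_config <- function(name = c("er50", "ppm", "scalefree"),
                          scale = c("desk", "full"), seed = 1) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  desk <- scale == "desk"
  switch(
    name,
    er50 = sweep_config("ppm", n_grns = 50, n_genes = if (desk) 500 else 1000,
                        k = 1, m = NULL, r = c(4, 8), gamma = c(0.1, 0.5),
                        p_plus = 0.5, seed = seed),
    ppm = sweep_config("ppm",
                       n_grns = if (desk) 500 else 10000,
                       n_genes = if (desk) 500 else 5000,
                       k = if (desk) c(2, 20) else c(2, 100),
                       m = NULL, r = c(2, 10), gamma = c(0.2, 0.5),
                       p_plus = c(0, 1), seed = seed),
    scalefree = sweep_config("scalefree",
                             n_grns = if (desk) 500 else 10000,
                             n_genes = if (desk) 500 else 5000,
                             k = if (desk) c(2, 20) else c(2, 100),
                             m = NULL, r = c(2, 10), gamma = c(0.2, 0.5),
                             p_plus = c(0, 1), d = c(1, 30), seed = seed)
  )
}

draw_value <- function(x, how = c("uniform", "int", "log"), default = NULL) {
  how <- match.arg(how)
  if (is.null(x)) return(default)
  if (length(x) == 1) return(x)
  switch(how,
         uniform = stats::runif(1, x[1], x[2]),
         int = sample(seq(x[1], x[2]), 1),
         log = exp(stats::runif(1, log(x[1]), log(x[2]))))
}

draw_params <- function(config) {
  k <- draw_value(config$k, "int")
  m <- if (k == 1) NULL else {
    lo <- if (is.null(config$m)) 1 / k else max(config$m[1], 1 / k)
    hi <- if (is.null(config$m)) 1 else config$m[length(config$m)]
    stats::runif(1, lo, hi)
  }
  grn_params(
    n = config$n_genes, k = k, r = draw_value(config$r), m = m,
    gamma = draw_value(config$gamma), p_plus = draw_value(config$p_plus),
    d = if (config$generator == "scalefree") draw_value(config$d, "log")
        else NULL,
    sigma2 = config$sigma2
  )
}

simulate_one_grn <- function(params, generator, grn_seed,
                             keep_grn = FALSE) {
  topo <- if (generator == "scalefree") {
    generate_scalefree_dag(params, grn_seed)
  } else {
    generate_ppm_dag(params, grn_seed)
  }
  grn <- assign_signs(topo, params$p_plus, params$gamma, grn_seed)
  eff <- total_effects(grn)
  decomp <- variance_decomposition(eff)
  dist <- distance_decomposition(eff)
  summary <- summarize_grn(decomp, topo, count_motifs(topo), dist)
  out <- dplyr::bind_cols(
    tibble::tibble(
      generator = generator, grn_seed = grn_seed,
      n_genes = params$n, k = params$k,
      m = if (is.null(params$m)) NA_real_ else params$m,
      r = params$r, gamma = params$gamma, p_plus = params$p_plus,
      d = if (is.null(params$d)) NA_real_ else params$d,
      sigma2 = params$sigma2
    ),
    summary
  )
  out$cis_fractions <- list(decomp$cis_fraction)
  if (keep_grn) out$grn <- list(grn)
  out
}

#' Run a parameter sweep of simulated networks
#'
#' For each network: draw parameters from the configured distributions,
#' generate the topology, assign signs, decompose variance, count motifs, and
#' summarize. Fully reproducible from the root seed; the per-network sub-seed
#' is recorded in the output so any network can be rebuilt in isolation with
#' [regenerate_grn()].
#'
#' @param config A [sweep_config()] or [preset_config()].
#' @param keep_grns If `TRUE`, keep the `signed_grn` objects in a list-column
#'   (memory permitting).
#' @param progress Print a dot every 50 networks.
#' @return A tibble with one row per network: the drawn parameters, the
#'   summary columns of [summarize_grn()], and a list-column `cis_fractions`
#'   holding each network's per-gene cis-fraction vector. Networks whose
#'   parameter draw violates the edge-probability bounds are skipped with a
#'   warning and counted in the `n_failed` attribute.
#' @export
run_sweep <- function(config, keep_grns = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  rows <- vector("list", config$n_grns)
  failed <- 0L
  for (i in seq_len(config$n_grns)) {
    grn_seed <- derive_seed(config$seed, 100L + i)
    params <- withr::with_seed(derive_seed(grn_seed, 9L),
                               draw_params(config))
    rows[[i]] <- tryCatch(
      simulate_one_grn(params, config$generator, grn_seed,
                       keep_grn = keep_grns),
      error = function(e) {
        warning(sprintf("GRN %d skipped: %s", i, conditionMessage(e)),
                call. = FALSE)
        NULL
      }
    )
    if (is.null(rows[[i]])) failed <- failed + 1L
    if (progress && i %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_cols(tibble::tibble(grn_id = seq_len(nrow(out))), out)
  attr(out, "n_failed") <- failed
  attr(out, "config") <- config
  out
}

#' Rebuild one swept network from its recorded row
#'
#' @param sweep_row A single row of a [run_sweep()] table.
#' @return The `signed_grn` for that row (identical to the one summarized
#'   during the sweep).
#' @export
regenerate_grn <- function(sweep_row) {
  stopifnot(nrow(sweep_row) == 1)
  params <- grn_params(
    n = sweep_row$n_genes, k = sweep_row$k, r = sweep_row$r,
    m = if (is.na(sweep_row$m)) NULL else sweep_row$m,
    gamma = sweep_row$gamma, p_plus = sweep_row$p_plus,
    d = if (is.na(sweep_row$d)) NULL else sweep_row$d,
    sigma2 = sweep_row$sigma2
  )
  topo <- if (sweep_row$generator == "scalefree") {
    generate_scalefree_dag(params, sweep_row$grn_seed)
  } else {
    generate_ppm_dag(params, sweep_row$grn_seed)
  }
  assign_signs(topo, params$p_plus, params$gamma, sweep_row$grn_seed)
}

#' Match swept networks to a reference cis-fraction distribution
#'
#' Computes the two-sample K-S distance between each network's per-gene
#' cis-fraction distribution and the reference (a heritability table or a
#' bare numeric vector of cis fractions), then flags the lowest
#' `tail_fraction` of distances as matched.
#'
#' @param sweep A [run_sweep()] tibble (its `cis_fractions` list-column is
#'   required).
#' @param reference A heritability tibble with a `cis_fraction` column, or a
#'   numeric vector.
#' @param tail_fraction Fraction of networks to flag as matched.
#' @return A `grn_match` object. `tidy()` returns the sweep table with
#'   `ks_stat` and `matched` columns; `glance()` a one-row comparison of
#'   matched vs background networks.
#' @export
run_matching <- function(sweep, reference, tail_fraction = 0.025) {
  stopifnot(is.data.frame(sweep), "cis_fractions" %in% names(sweep))
  ref <- if (is.numeric(reference)) reference else reference$cis_fraction
  ref <- ref[!is.na(ref)]
  if (length(ref) == 0) stop("empty reference distribution.", call. = FALSE)
  ks <- vapply(sweep$cis_fractions, ks_distance, numeric(1), sample_b = ref)
  matched_idx <- select_matched(ks, tail_fraction)
  tbl <- sweep
  tbl$ks_stat <- ks
  tbl$matched <- seq_len(nrow(tbl)) %in% matched_idx
  structure(list(table = tbl, reference = ref,
                 tail_fraction = tail_fraction),
            class = "grn_match")
}

#' @export
print.grn_match <- function(x, ...) {
  cat(sprintf("<grn_match> %d networks, %d matched (tail %.3g), min K-S %.4f\n",
              nrow(x$table), sum(x$table$matched), x$tail_fraction,
              min(x$table$ks_stat)))
  invisible(x)
}

#' Tidy and summarize a matching result
#'
#' @param x A `grn_match` object.
#' @param ... Unused.
#' @return `tidy()`: the per-network tibble with `ks_stat` and `matched`
#'   (list-columns dropped); `glance()`: one row with matched counts, the
#'   matched-set medians of the network summaries and of the drawn
#'   parameters, and their background counterparts.
#' @export
tidy.grn_match <- function(x, ...) {
  dplyr::select(x$table, -dplyr::any_of(c("cis_fractions", "grn")))
}

#' @rdname tidy.grn_match
#' @export
glance.grn_match <- function(x, ...) {
  tbl <- x$table
  med <- function(v, flag) stats::median(v[flag], na.rm = TRUE)
  tibble::tibble(
    n_grns = nrow(tbl),
    n_matched = sum(tbl$matched),
    min_ks = min(tbl$ks_stat),
    median_ks_matched = med(tbl$ks_stat, tbl$matched),
    median_ks_background = med(tbl$ks_stat, !tbl$matched),
    matched_median_cis = med(tbl$median_cis_fraction, tbl$matched),
    matched_lead_ratio = med(tbl$median_lead_ratio, tbl$matched),
    background_lead_ratio = med(tbl$median_lead_ratio, !tbl$matched),
    matched_direct_effect = med(direct_effect_feature(tbl$r, tbl$gamma),
                                tbl$matched),
    matched_p_plus = med(tbl$p_plus, tbl$matched),
    background_p_plus = med(tbl$p_plus, !tbl$matched),
    matched_m = med(tbl$m, tbl$matched),
    matched_d = med(tbl$d, tbl$matched),
    background_d = med(tbl$d, !tbl$matched)
  )
}

#' Per-gene report for exemplar networks
#'
#' For a named list of networks (e.g. the best-matched network and structural
#' comparators), emits the per-gene tables behind the exemplar comparisons:
#' cis fraction, ancestor counts and lead trans effects against topological
#' index, the distance-resolved decomposition, and the median cumulative
#' heritability profile by network distance.
#'
#' @param grns Named list of `signed_grn` objects (names label the
#'   exemplars).
#' @return A list of tibbles: `genes` (per gene), `distance` (per gene and
#'   distance), and `profile` (median cumulative fraction per distance and
#'   exemplar, including `within_two_hops`, the median cumulative fraction at
#'   distance <= 2).
#' @export
run_exemplar_report <- function(grns) {
  stopifnot(is.list(grns), length(grns) >= 1)
  if (is.null(names(grns)) || any(names(grns) == "")) {
    names(grns) <- paste0("grn", seq_along(grns))
  }
  per <- purrr::imap(grns, function(grn, label) {
    stopifnot(inherits(grn, "signed_grn"))
    eff <- total_effects(grn)
    decomp <- variance_decomposition(eff)
    dist <- distance_decomposition(eff)
    max_d <- max(dist$distance)
    profile <- purrr::map_dfr(0:max_d, function(dd) {
      tibble::tibble(
        exemplar = label, distance = dd,
        median_cumulative =
          stats::median(cumulative_by_distance(dist, dd)$cumulative)
      )
    })
    profile$within_two_hops <-
      stats::median(cumulative_by_distance(dist, 2)$cumulative)
    list(
      genes = dplyr::bind_cols(tibble::tibble(exemplar = label), decomp),
      distance = dplyr::bind_cols(tibble::tibble(exemplar = label), dist),
      profile = profile
    )
  })
  list(
    genes = purrr::map_dfr(per, "genes"),
    distance = purrr::map_dfr(per, "distance"),
    profile = purrr::map_dfr(per, "profile")
  )
}
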