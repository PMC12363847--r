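herit_required_cols <- c("gene", "h2_cis", "h2_trans")

add_cis_fraction <- function(tbl) {
  total <- tbl$h2_cis + tbl$h2_trans
  tbl$cis_fraction <- ifelse(total > 0, tbl$h2_cis / total, NA_real_)
  tbl
}

#' Read a per-gene heritability table
#'
#' Expects a TSV with columns `gene`, `h2_cis`, `h2_trans` and (optionally)
#' the 0/1 eQTL detection flags `has_cis_eqtl`, `has_trans_eqtl`. Adds the
#' derived `cis_fraction = h2_cis / (h2_cis + h2_trans)`; genes with zero
#' total genetic variance carry `NA` there (they are retained in the table
#' but excluded from reference CDFs).
#'
#' @param path Path to the TSV file.
#' @return A tibble with the table columns plus `cis_fraction`.
#' @export
read_heritability_table <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    stop("unparseable rows in ", path, " (lines ",
         paste(unique(probs$row), collapse = ", "), ")", call. = FALSE)
  }
  missing <- setdiff(herit_required_cols, names(tbl))
  if (length(missing) > 0) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(tbl$h2_cis) || !is.numeric(tbl$h2_trans)) {
    stop("h2_cis and h2_trans must be numeric.", call. = FALSE)
  }
  bad <- which(tbl$h2_cis < 0 | tbl$h2_trans < 0)
  if (length(bad) > 0) {
    stop("negative heritabilities on data rows ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (flag in c("has_cis_eqtl", "has_trans_eqtl")) {
    if (flag %in% names(tbl)) tbl[[flag]] <- as.integer(tbl[[flag]])
  }
  add_cis_fraction(tibble::as_tibble(tbl))
}

#' @rdname read_heritability_table
#' @param table A heritability tibble.
#' @export
write_heritability_table <- function(table, path) {
  cols <- intersect(
    c("gene", "h2_cis", "h2_trans", "has_cis_eqtl", "has_trans_eqtl"),
    names(table)
  )
  readr::write_tsv(table[, cols], path, na = "")
  invisible(path)
}

#' Subset to genes with both a cis- and a trans-eQTL
#'
#' Keeps genes whose `has_cis_eqtl` and `has_trans_eqtl` flags are both set.
#' Detection probability rises with the underlying variance component, so
#' this filter preferentially removes genes with small h2_cis and shifts the
#' cis-fraction distribution upward; the induced shift in the median is
#' attached as the `median_shift` attribute (median after minus median
#' before, over genes with a defined fraction).
#'
#' @param table A heritability tibble with flag columns.
#' @return The filtered tibble (attribute `median_shift`).
#' @export
filter_eqtl_genes <- function(table) {
  stopifnot(all(c("has_cis_eqtl", "has_trans_eqtl") %in% names(table)))
  keep <- table$has_cis_eqtl == 1 & table$has_trans_eqtl == 1
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warning("no genes carry both eQTL flags; returning an empty table.")
  }
  attr(out, "median_shift") <-
    stats::median(out$cis_fraction, na.rm = TRUE) -
    stats::median(table$cis_fraction, na.rm = TRUE)
  out
}

#' Generate a synthetic per-gene heritability table
#'
#' Stand-in for a twin-study heritability table (synthetic; no real data are
#' involved). Per gene, the cis fraction is drawn from a Beta distribution
#' whose shapes (at fixed concentration `nu`) are solved numerically so the
#' population median equals `target_median_cis_fraction`; total genetic
#' variance is drawn from `Beta(total_shape1, total_shape2)`; `h2_cis` and
#' `h2_trans` split the total by the fraction. eQTL detection flags are
#' Bernoulli with logistic success probability increasing in the respective
#' variance component, so filtering on the flags reproduces the upward shift
#' of the cis-fraction distribution seen when requiring detected eQTLs.
#'
#' @param n_genes Number of genes.
#' @param target_median_cis_fraction Population median of the cis fraction,
#'   in (0, 1). Default 0.28, a typical whole-blood value.
#' @param seed Integer seed (tables are reproducible).
#' @param nu Beta concentration (shape1 + shape2) for the cis fraction.
#' @param total_shape1,total_shape2 Beta shapes for total genetic variance.
#' @param cis_detect,trans_detect Length-2 numeric vectors `(intercept,
#'   slope)` of the logistic detection models on h2_cis and h2_trans.
#' @return A heritability tibble with `cis_fraction` and flag columns.
#' @export
#' @examples
#' tbl <- generate_synthetic_table(2000, 0.28, seed = 1)
#' median(tbl$cis_fraction)
generate_synthetic_table <- function(n_genes,
                                     target_median_cis_fraction = 0.28,
                                     seed = 1,
                                     nu = 2,
                                     total_shape1 = 2, total_shape2 = 2,
                                     cis_detect = c(-2, 30),
                                     trans_detect = c(-1, 8)) {
  stopifnot(n_genes >= 1,
            target_median_cis_fraction > 0, target_median_cis_fraction < 1,
            nu > 0)
  target <- target_median_cis_fraction
  # shape1 a with median(Beta(a, nu - a)) = target
  a <- stats::uniroot(
    function(a) suppressWarnings(stats::qbeta(0.5, a, nu - a)) - target,
    lower = 1e-8, upper = nu - 1e-8, tol = 1e-12
  )$root
  withr::with_seed(derive_seed(seed, 6L), {
    fraction <- stats::rbeta(n_genes, a, nu - a)
    total <- stats::rbeta(n_genes, total_shape1, total_shape2)
    h2_cis <- fraction * total
    h2_trans <- (1 - fraction) * total
    tbl <- tibble::tibble(
      gene = sprintf("g%05d", seq_len(n_genes)),
      h2_cis = h2_cis,
      h2_trans = h2_trans,
      has_cis_eqtl = stats::rbinom(
        n_genes, 1, stats::plogis(cis_detect[1] + cis_detect[2] * h2_cis)),
      has_trans_eqtl = stats::rbinom(
        n_genes, 1, stats::plogis(trans_detect[1] + trans_detect[2] * h2_trans))
    )
    add_cis_fraction(tbl)
  })
}
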