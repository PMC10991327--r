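# Correlation of wave spatial maps with per-gene spatial expression maps,
# and classification of correlation strengths.

#' Correlate a wave map with gene-expression maps
#'
#' Pearson correlation, over the in-mask pixels, between one spatial map
#' (conventionally a wave's amplitude map `rho`; a signed variant
#' `Re(rho exp(i theta))` can be passed instead where the phase should
#' matter) and each gene's expression map. Genes whose maps are constant
#' over the mask have no defined correlation; they are flagged and sorted
#' last.
#'
#' @param wave_map Numeric matrix (`NA` outside the mask).
#' @param genes Named list of numeric matrices on the same grid, or a
#'   3-D array with gene names on the third dimension.
#' @return A tibble sorted by `|r|` descending: `gene_id`, `r`, `defined`.
#' @export
map_gene_correlations <- function(wave_map, genes) {
  stopifnot(is.matrix(wave_map))
  if (is.array(genes) && length(dim(genes)) == 3) {
    genes <- stats::setNames(
      lapply(seq_len(dim(genes)[3]), function(i) genes[, , i]),
      dimnames(genes)[[3]] %||% sprintf("gene_%02d", seq_len(dim(genes)[3])))
  }
  stopifnot(is.list(genes), length(genes) >= 0)
  ids <- names(genes) %||% sprintf("gene_%02d", seq_along(genes))
  if (length(genes) == 0) {
    return(tibble::tibble(gene_id = character(), r = numeric(),
                          defined = logical()))
  }
  mask <- !is.na(wave_map)
  wv <- wave_map[mask]
  if (stats::sd(wv) == 0) stop("wave map is constant over the mask")
  res <- lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    if (!all(dim(g) == dim(wave_map))) {
      stop(sprintf("gene map '%s' is on a different grid", ids[i]))
    }
    gv <- g[mask]
    if (anyNA(gv)) stop(sprintf("gene map '%s' has missing in-mask values", ids[i]))
    if (stats::sd(gv) == 0) {
      tibble::tibble(gene_id = ids[i], r = NA_real_, defined = FALSE)
    } else {
      tibble::tibble(gene_id = ids[i], r = stats::cor(wv, gv), defined = TRUE)
    }
  })
  out <- do.call(rbind, res)
  out[order(!out$defined, -abs(out$r)), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify gene correlations by strength thresholds
#'
#' Buckets each gene by `|r|`: below `low` is negligible, from `low`
#' (inclusive) to below `high` is correlated, and `high` or above is highly
#' correlated. The conventional thresholds are 0.3 and 0.75; both
#' boundaries are inclusive upward.
#'
#' @param table Output of [map_gene_correlations()].
#' @param low,high Thresholds on `|r|`; defaults 0.3 and 0.75.
#' @return The table with a `category` factor column added, plus a `counts`
#'   attribute (named vector over the three categories; undefined
#'   correlations are excluded from the counts).
#' @export
classify_correlations <- function(table, low = 0.3, high = 0.75) {
  if (low >= high) stop("`low` must be below `high`")
  lv <- c("negligible", "correlated", "highly_correlated")
  cat_of <- function(r) {
    if (is.na(r)) return(NA_character_)
    a <- abs(r)
    if (a >= high) "highly_correlated" else if (a >= low) "correlated"
    else "negligible"
  }
  table$category <- factor(vapply(table$r, cat_of, character(1)), levels = lv)
  counts <- tabulate(as.integer(table$category), nbins = length(lv))
  out <- table
  attr(out, "counts") <- stats::setNames(counts, lv)
  out
}
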