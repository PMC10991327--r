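# Group statistics on FC edges: Fisher z, t-tests, Benjamini-Hochberg FDR.

#' Edgewise group tests on FC matrices
#'
#' Fisher-z transforms every upper-triangle edge of every matrix, then tests
#' each edge: a one-sample two-sided t-test of mean z = 0 when only one group
#' is given, or Welch's unequal-variances two-sided t-test between the two
#' groups. P-values are corrected across all tested edges with the
#' Benjamini-Hochberg procedure; edges with `q < alpha` are flagged
#' significant.
#'
#' Correlations at exactly +/-1 are clipped to `1 - 1e-7` before the z
#' transform (flagged in the `clipped` column). An edge with zero variance
#' across replicates and nonzero mean yields an infinite statistic with
#' p = 0, flagged in `degenerate`.
#'
#' @param group_a List of `fc_matrix` objects (>= 3) on a shared node set.
#' @param group_b Optional second group for a between-group comparison.
#' @param alpha FDR threshold; default 0.05.
#' @return A tibble with one row per edge: `i`, `j`, `mean_z_a`,
#'   (`mean_z_b`,) `statistic`, `p`, `q`, `significant`, `clipped`,
#'   `degenerate`.
#' @export
group_fc_tests <- function(group_a, group_b = NULL, alpha = 0.05) {
  za <- fisher_z_stack(group_a)
  zb <- if (!is.null(group_b)) fisher_z_stack(group_b) else NULL
  if (ncol(za$z) < 3) stop("need at least 3 matrices per group")
  if (!is.null(zb)) {
    if (nrow(zb$z) != nrow(za$z)) stop("groups are on different node sets")
    if (ncol(zb$z) < 3) stop("need at least 3 matrices per group")
  }
  n_edges <- nrow(za$z)
  stat <- p <- numeric(n_edges)
  degen <- logical(n_edges)
  for (e in seq_len(n_edges)) {
    xa <- za$z[e, ]
    if (is.null(zb)) {
      if (stats::sd(xa) == 0) {
        degen[e] <- TRUE
        stat[e] <- sign(mean(xa)) * Inf
        p[e] <- if (mean(xa) == 0) 1 else 0
      } else {
        tt <- stats::t.test(xa, mu = 0)
        stat[e] <- unname(tt$statistic); p[e] <- tt$p.value
      }
    } else {
      xb <- zb$z[e, ]
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        degen[e] <- TRUE
        dm <- mean(xa) - mean(xb)
        stat[e] <- sign(dm) * Inf
        p[e] <- if (dm == 0) 1 else 0
      } else {
        tt <- stats::t.test(xa, xb, var.equal = FALSE)
        stat[e] <- unname(tt$statistic); p[e] <- tt$p.value
      }
    }
  }
  q <- stats::p.adjust(p, method = "BH")
  out <- tibble::tibble(
    i = za$idx[, 1], j = za$idx[, 2],
    mean_z_a = rowMeans(za$z),
    statistic = stat, p = p, q = q,
    significant = q < alpha,
    clipped = za$clipped | (if (is.null(zb)) FALSE else zb$clipped),
    degenerate = degen
  )
  if (!is.null(zb)) out$mean_z_b <- rowMeans(zb$z)
  out
}

# Stack the upper-triangle Fisher-z values of a list of FC matrices into an
# edges x replicates matrix.
fisher_z_stack <- function(fcs) {
  stopifnot(is.list(fcs), length(fcs) >= 1)
  dims <- unique(vapply(fcs, nrow, integer(1)))
  if (length(dims) != 1) stop("matrices have mismatched node sets")
  ut <- which(upper.tri(fcs[[1]]), arr.ind = TRUE)
  n_edges <- nrow(ut)
  z <- matrix(vapply(fcs, function(fc) {
    r <- unclass(fc)[upper.tri(fc)]
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    atanh(r)
  }, numeric(n_edges)), nrow = n_edges)
  clip_edge <- rowSums(matrix(vapply(fcs, function(fc) {
    abs(unclass(fc)[upper.tri(fc)]) >= 1
  }, logical(n_edges)), nrow = n_edges)) > 0
  list(z = z, idx = ut, clipped = clip_edge)
}
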