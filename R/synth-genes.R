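# Synthetic spatial gene-expression maps with controlled correlation to a
# reference map: test fixtures for the gene-correlation module.

# Separable Gaussian blur on a matrix (reflect padding via filter support
# truncation/renormalization at borders).
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  blur1d <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- (i - half):(i + half)
      ok <- j >= 1 & j <= n
      out[i] <- sum(v[j[ok]] * k[ok]) / sum(k[ok])
    }
    out
  }
  x <- apply(x, 2, blur1d)
  t(apply(t(x), 2, blur1d))
}

#' Simulate gene-expression maps with target correlations
#'
#' Generates one spatially smooth map per requested correlation, each with
#' Pearson correlation to `reference_map` (over the mask) equal to its
#' target: a smooth Gaussian random field is orthogonalized against the
#' reference and mixed back as `r * z(ref) + sqrt(1 - r^2) * z(resid)`, so
#' the realized in-mask correlation matches the target exactly (up to a
#' degenerate residual field). Targets of +/-1 return the (negated)
#' reference up to affine scaling.
#'
#' @param reference_map Numeric matrix (e.g. a wave amplitude map).
#' @param target_correlations Numeric vector of r values in \[-1, 1\].
#' @param smoothness Gaussian blur sd in pixels for the random fields;
#'   default 2.
#' @param seed Integer seed.
#' @param mask Logical matrix; default all `TRUE`.
#' @return A named list of matrices (`gene_01`, `gene_02`, ...), `NA`
#'   outside the mask, with attribute `targets`.
#' @export
simulate_gene_maps <- function(reference_map, target_correlations,
                               smoothness = 2, seed = 1, mask = NULL) {
  stopifnot(is.matrix(reference_map))
  if (any(abs(target_correlations) > 1)) {
    stop("target correlations must lie in [-1, 1]")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(reference_map), ncol(reference_map))
  ref <- reference_map[mask]
  zref <- (ref - mean(ref)) / stats::sd(ref)
  maps <- with_seed(seed, lapply(seq_along(target_correlations), function(i) {
    r <- target_correlations[i]
    if (abs(r) == 1) {
      vals <- sign(r) * ref
    } else {
      field <- gaussian_blur(matrix(stats::rnorm(length(reference_map)),
                                    nrow(reference_map)), smoothness)[mask]
      resid <- field - mean(field) -
        (sum((field - mean(field)) * zref) / sum(zref^2)) * zref
      if (stats::sd(resid) == 0) stop("degenerate residual field")
      zres <- (resid - mean(resid)) / stats::sd(resid)
      vals <- r * zref + sqrt(1 - r^2) * zres
    }
    out <- matrix(NA_real_, nrow(reference_map), ncol(reference_map))
    out[mask] <- vals
    out
  }))
  names(maps) <- sprintf("gene_%02d", seq_along(maps))
  attr(maps, "targets") <- target_correlations
  maps
}
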