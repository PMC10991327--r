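# Functional connectivity: raw and per-wave correlation matrices, their
# superposition, spatial summaries, hemispheric asymmetry, similarity maps,
# seed-based connectivity.

new_fc_matrix <- function(values, pixel_index, grid_dim, gsr_applied, source) {
  structure(values,
            class = c("fc_matrix", "matrix"),
            pixel_index = pixel_index, grid_dim = grid_dim,
            gsr_applied = gsr_applied, source = source)
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d x %d (source: %s, GSR: %s)\n",
              nrow(x), ncol(x), attr(x, "source"),
              isTRUE(attr(x, "gsr_applied"))))
  invisible(x)
}

#' Functional connectivity matrix
#'
#' Pairwise Pearson correlations between all pixel time series. The
#' `gsr_applied` flag of the input is recorded on the result.
#'
#' @param m A `pixel_matrix` (z-scored or raw; correlation is scale
#'   invariant).
#' @return An `fc_matrix`: a symmetric correlation matrix with unit diagonal,
#'   carrying the pixel index and provenance as attributes.
#' @export
fc_matrix <- function(m) {
  stopifnot(inherits(m, "pixel_matrix"))
  if (nrow(m$values) < 3) stop("need at least 3 time points")
  v <- apply(Re(m$values), 2, stats::var)
  if (any(v == 0)) {
    bad <- which(v == 0)[1]
    stop(sprintf("pixel at grid (%d, %d) has zero variance",
                 m$pixel_index$row[bad], m$pixel_index$col[bad]))
  }
  fc <- stats::cor(Re(m$values))
  new_fc_matrix(fc, m$pixel_index, m$grid_dim,
                gsr_applied = isTRUE(m$flags$gsr), source = "raw")
}

#' Correlation matrix of a single wave
#'
#' Pearson correlations of the real pixel time courses reconstructed from one
#' component alone. Because the reconstructed waveform is the same everywhere
#' up to a time lag, for a long (circularly symmetric) analytic score the
#' entries approach `cos(theta_j - theta_k)`: a pi phase offset between two
#' regions appears as a negative correlation. Pixels with (numerically) zero
#' amplitude have an identically zero reconstruction; their rows and columns
#' are `NA` and flagged in `attr(, "undefined_pixels")`.
#'
#' @param d A `wave_decomposition`.
#' @param k Component index.
#' @return An `fc_matrix` with `source = "wave:k"`.
#' @export
wave_fc <- function(d, k) {
  stopifnot(inherits(d, "wave_decomposition"), length(k) == 1)
  rec <- reconstruct_component(d, k)
  sds <- apply(rec$values, 2, stats::sd)
  ok <- sds > max(sds) * 1e-12
  fc <- matrix(NA_real_, ncol(rec$values), ncol(rec$values))
  fc[ok, ok] <- stats::cor(rec$values[, ok, drop = FALSE])
  diag(fc) <- ifelse(ok, 1, NA_real_)
  out <- new_fc_matrix(fc, d$pixel_index, d$grid_dim,
                       gsr_applied = NA, source = paste0("wave:", k))
  attr(out, "undefined_pixels") <- which(!ok)
  out
}

#' Superposition of per-wave correlation matrices
#'
#' Weighted sum of the first `upto_k` wave correlation matrices, with the
#' weight of wave `t` equal to its variance fraction, renormalized to a unit
#' diagonal. As more waves enter, the superposition approaches the raw FC
#' matrix; the similarity curve (Pearson correlation between vectorized upper
#' triangles, per k) quantifies the approach.
#'
#' @param d A `wave_decomposition`.
#' @param upto_k Number of leading waves to superpose.
#' @param reference Optional reference `fc_matrix` (e.g. the raw FC) for the
#'   similarity curve.
#' @return A list with elements `fc` (the renormalized superposition, an
#'   `fc_matrix`) and `similarity` (a tibble with columns `k`, `r`, or `NULL`
#'   when no reference was given).
#' @export
fc_superposition <- function(d, upto_k = d$n_components, reference = NULL) {
  stopifnot(inherits(d, "wave_decomposition"),
            upto_k >= 1, upto_k <= d$n_components)
  p <- d$n_pixels
  acc <- matrix(0, p, p)
  wacc <- matrix(0, p, p)
  sims <- if (is.null(reference)) NULL else numeric(upto_k)
  sup <- NULL
  for (t in seq_len(upto_k)) {
    ct <- unclass(wave_fc(d, t))
    s_t <- d$variance_fraction[t]
    w <- ifelse(is.na(ct), 0, s_t)
    acc <- acc + ifelse(is.na(ct), 0, ct) * s_t
    wacc <- wacc + w
    sup <- acc / ifelse(wacc == 0, NA_real_, wacc)
    if (!is.null(reference)) sims[t] <- upper_tri_cor(sup, unclass(reference))
  }
  fc <- new_fc_matrix(sup, d$pixel_index, d$grid_dim, gsr_applied = NA,
                      source = paste0("superposition:", upto_k))
  list(fc = fc,
       similarity = if (is.null(sims)) NULL else
         tibble::tibble(k = seq_len(upto_k), r = sims))
}

#' Pixel-averaged FC map
#'
#' For every pixel, the mean (absolute, by default) correlation with all
#' other pixels, displayed on the grid. With `absolute = TRUE` this is the
#' absolute average FC map; the signed variant averages raw correlations.
#'
#' @param fc A pixel-level `fc_matrix`.
#' @param absolute Average `|r|` rather than `r`; default `TRUE`.
#' @return A `height x width` matrix.
#' @export
mean_fc_map <- function(fc, absolute = TRUE) {
  v <- unclass(fc)
  diag(v) <- NA
  if (absolute) v <- abs(v)
  means <- rowMeans(v, na.rm = TRUE)
  map_to_grid(means, attr(fc, "pixel_index"), attr(fc, "grid_dim"))
}

#' Hemispheric difference of the absolute FC
#'
#' For every pixel `p`: the mean absolute correlation with pixels on its own
#' side of the midline minus the mean absolute correlation with pixels on
#' the opposite side (homolateral minus contralateral). Positive values mark
#' pixels more strongly connected within their own hemisphere.
#'
#' @param fc A pixel-level `fc_matrix`.
#' @param midline_column Grid column index of the midline; columns `<=` it
#'   form the left side.
#' @return A `height x width` matrix.
#' @export
hemispheric_difference_map <- function(fc, midline_column) {
  pi_ <- attr(fc, "pixel_index")
  left <- pi_$col <= midline_column
  if (sum(left) < 2 || sum(!left) < 2) {
    stop("each side of the midline needs at least 2 pixels")
  }
  v <- abs(unclass(fc))
  diag(v) <- NA
  same <- ifelse(outer(left, left, "=="), v, NA)
  diff_ <- ifelse(outer(left, left, "!="), v, NA)
  out <- rowMeans(same, na.rm = TRUE) - rowMeans(diff_, na.rm = TRUE)
  map_to_grid(out, pi_, attr(fc, "grid_dim"))
}

#' Per-pixel similarity of two FC matrices
#'
#' For every node `i`, the Pearson correlation between row `i` of the two
#' matrices (diagonal entries excluded): how similar the node's connection
#' map is across the two datasets. Affine rescaling of one matrix leaves the
#' map at 1, which is why a strong FC-to-FC_GSR similarity indicates
#' `FC ~ alpha FC_GSR + beta`.
#'
#' @param fc_a,fc_b Two `fc_matrix` objects on the same node set.
#' @return A `height x width` matrix (or plain vector when no grid is
#'   attached).
#' @export
fc_similarity_map <- function(fc_a, fc_b) {
  if (!identical(dim(fc_a), dim(fc_b)) ||
      !identical(attr(fc_a, "pixel_index"), attr(fc_b, "pixel_index"))) {
    stop("FC matrices are on different node sets")
  }
  a <- unclass(fc_a); b <- unclass(fc_b)
  n <- nrow(a)
  s <- vapply(seq_len(n), function(i) {
    stats::cor(a[i, -i], b[i, -i], use = "complete.obs")
  }, numeric(1))
  pi_ <- attr(fc_a, "pixel_index")
  if (is.null(pi_)) return(s)
  map_to_grid(s, pi_, attr(fc_a, "grid_dim"))
}

#' Seed-to-seed and seed-to-pixel connectivity
#'
#' Pearson correlations between the seed pixels' time series (a `k x k`
#' matrix) plus, for each seed, its full connection map over all pixels.
#'
#' @param m A `pixel_matrix`.
#' @param seeds A `seed_set` from [select_seeds()].
#' @return A list with `fc` (seed-seed `fc_matrix`) and `maps`
#'   (`height x width x k` array of per-seed correlation maps).
#' @export
seed_fc <- function(m, seeds) {
  stopifnot(inherits(m, "pixel_matrix"), inherits(seeds, "seed_set"))
  cols <- match_seed_columns(m, seeds)
  x <- Re(m$values)
  sfc <- stats::cor(x[, cols, drop = FALSE])
  rownames(sfc) <- colnames(sfc) <- seeds$seeds$label
  maps <- array(NA_real_, c(m$grid_dim, length(cols)))
  full <- stats::cor(x[, cols, drop = FALSE], x)
  for (i in seq_along(cols)) {
    maps[, , i] <- map_to_grid(full[i, ], m$pixel_index, m$grid_dim)
  }
  fc <- new_fc_matrix(sfc, NULL, NULL, gsr_applied = isTRUE(m$flags$gsr),
                      source = "seeds")
  attr(fc, "seed_labels") <- seeds$seeds$label
  list(fc = fc, maps = maps)
}

match_seed_columns <- function(m, seeds) {
  cols <- mapply(function(r, c) {
    j <- which(m$pixel_index$row == r & m$pixel_index$col == c)
    if (length(j) != 1) stop(sprintf("seed at (%d, %d) is outside the mask", r, c))
    j
  }, seeds$seeds$row, seeds$seeds$col)
  as.integer(cols)
}

#' Short-range connectivity of each seed
#'
#' Pearson correlation between a seed's time series and the mean time series
#' of its in-mask 8-neighborhood. Seeds on the mask border use only their
#' in-mask neighbors; an isolated seed yields `NA`, flagged via
#' `attr(, "isolated")`.
#'
#' @param m A `pixel_matrix`.
#' @param seeds A `seed_set`.
#' @return A named numeric vector, one value per seed.
#' @export
short_range_fc <- function(m, seeds) {
  stopifnot(inherits(m, "pixel_matrix"), inherits(seeds, "seed_set"))
  cols <- match_seed_columns(m, seeds)
  x <- Re(m$values)
  isolated <- logical(length(cols))
  out <- vapply(seq_along(cols), function(i) {
    r <- seeds$seeds$row[i]; c <- seeds$seeds$col[i]
    nb <- expand.grid(dr = -1:1, dc = -1:1)
    nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
    j <- unlist(mapply(function(dr, dc) {
      which(m$pixel_index$row == r + dr & m$pixel_index$col == c + dc)
    }, nb$dr, nb$dc))
    if (length(j) == 0) {
      isolated[i] <<- TRUE
      return(NA_real_)
    }
    stats::cor(x[, cols[i]], rowMeans(x[, j, drop = FALSE]))
  }, numeric(1))
  names(out) <- seeds$seeds$label
  attr(out, "isolated") <- which(isolated)
  out
}
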