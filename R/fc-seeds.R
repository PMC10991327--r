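# Seed selection by k-means clustering of FC connection maps.

#' Select seed pixels by clustering connection maps
#'
#' Groups pixels by k-means on the rows of the FC matrix (each pixel's
#' connection map), chooses the number of clusters by maximizing the average
#' silhouette width over `k_range`, and picks one seed per cluster: the
#' in-mask pixel whose connection map is nearest (Euclidean) to the cluster
#' centroid. Deterministic given `seed`.
#'
#' A degenerate input (all connection maps identical) cannot be clustered;
#' `k = 2` is returned with a warning and the `degenerate` field set.
#'
#' @param fc A pixel-level `fc_matrix`.
#' @param k_range Candidate cluster counts; default `2:25`.
#' @param replicates Random restarts per k for k-means; default 5.
#' @param seed Integer seed for the clustering.
#' @return An object of class `seed_set`: a list with `seeds` (tibble:
#'   `label`, `cluster`, `row`, `col`), `assignment` (pixel -> cluster id),
#'   `k`, `silhouette` (tibble of mean widths per k), `degenerate`.
#' @export
select_seeds <- function(fc, k_range = 2:25, replicates = 5, seed = 1) {
  v <- unclass(fc)
  pi_ <- attr(fc, "pixel_index")
  n <- nrow(v)
  k_range <- k_range[k_range >= 2 & k_range < n]
  if (length(k_range) == 0) stop("k_range infeasible for the pixel count")
  if (all(abs(v - v[1, 1]) < 1e-12) ||
      max(stats::dist(v[seq_len(min(n, 50)), , drop = FALSE])) < 1e-12) {
    warning("degenerate (constant) connection maps; returning k = 2")
    km <- list(cluster = rep_len(1:2, n))
    return(build_seed_set(v, pi_, attr(fc, "grid_dim"), km$cluster, 2,
                          silhouette = NULL, degenerate = TRUE))
  }
  d <- stats::dist(v)
  with_seed(seed, {
    sil <- vapply(k_range, function(k) {
      km <- stats::kmeans(v, centers = k, nstart = replicates,
                          iter.max = 50)
      mean(cluster::silhouette(km$cluster, d)[, "sil_width"])
    }, numeric(1))
    k_best <- k_range[which.max(sil)]
    km <- stats::kmeans(v, centers = k_best, nstart = replicates,
                        iter.max = 50)
    build_seed_set(v, pi_, attr(fc, "grid_dim"), km$cluster, k_best,
                   silhouette = tibble::tibble(k = k_range, width = sil),
                   degenerate = FALSE, centers = km$centers)
  })
}

build_seed_set <- function(v, pixel_index, grid_dim, cluster, k,
                           silhouette, degenerate, centers = NULL) {
  seeds <- lapply(seq_len(k), function(cl) {
    members <- which(cluster == cl)
    center <- if (is.null(centers)) colMeans(v[members, , drop = FALSE])
              else centers[cl, ]
    d2 <- rowSums(sweep(v[members, , drop = FALSE], 2, center)^2)
    p <- members[which.min(d2)]
    tibble::tibble(label = sprintf("seed_%02d", cl), cluster = cl,
                   row = pixel_index$row[p], col = pixel_index$col[p])
  })
  structure(
    list(seeds = do.call(rbind, seeds), assignment = cluster, k = k,
         silhouette = silhouette, degenerate = degenerate,
         pixel_index = pixel_index, grid_dim = grid_dim),
    class = "seed_set"
  )
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("<seed_set> k = %d%s\n", x$k,
              if (x$degenerate) " (degenerate)" else ""))
  print(x$seeds)
  invisible(x)
}
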