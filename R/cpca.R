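# Complex PCA of the analytic signal: the decomposition of a movie into
# standing and traveling waves.
#
# Conventions. The analytic matrix M (time x pixels) is factored by SVD,
# M = U D V^H. For component k the complex score is t_k = d_k u_k (with
# unit-norm version phi_k = u_k), and the complex loading l_k = v_k encodes
# the wave's spatial amplitude rho = |l_k| and phase theta = Arg(l_k)
# (time lag = theta / (2 pi f)). The real spatiotemporal pattern of wave k is
# Re(t_k conj(l_k)^T) and summing over all components reproduces the real
# input exactly. Variance fractions are d_k^2 / sum_j d_j^2, which is
# invariant to any overall normalization of the singular values.

#' Analytic signal of every pixel time series
#'
#' Computes `x + i H[x]` per column via the frequency-domain construction
#' (doubling positive frequencies, zeroing negative ones), so the analytic
#' signal of `cos(wt)` is `exp(iwt)`. The real part equals the input exactly;
#' the imaginary part (the Hilbert transform) of each column has zero mean.
#'
#' @param m A z-scored `pixel_matrix` (a warning is issued otherwise).
#' @return An object of class `analytic_matrix`: like a `pixel_matrix` but
#'   with complex `values`.
#' @export
analytic_signal <- function(m) {
  stopifnot(inherits(m, "pixel_matrix"))
  if (!isTRUE(m$flags$zscored)) {
    warning("analytic signal of a non-z-scored matrix")
  }
  out <- m
  out$values <- analytic_columns(m$values)
  class(out) <- c("analytic_matrix", "pixel_matrix")
  out
}

# Frequency-domain analytic signal of each column of a real matrix.
analytic_columns <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) stop("need at least 4 time points for the analytic signal")
  ft <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  vals <- stats::mvfft(ft * h, inverse = TRUE) / n
  # force the real part to equal the input exactly (it already does up to
  # rounding; this removes the rounding)
  vals <- complex(real = x, imaginary = Im(vals))
  dim(vals) <- dim(x)
  vals
}

#' @export
print.analytic_matrix <- function(x, ...) {
  cat(sprintf("<analytic_matrix> %d frames x %d pixels @ %g Hz\n",
              nrow(x$values), ncol(x$values), x$sampling_rate))
  invisible(x)
}

# Gauge fixing: rotate component k by a global phase so that the
# amplitude-weighted circular mean of the loading phases is zero. The
# rotation is unique (the argument of the resultant sum(l)), which makes the
# decomposition reproducible across runs and LAPACK builds; when the
# resultant (nearly) cancels -- e.g. a two-lobe pi-offset wave -- the phase
# of the largest-amplitude pixel is used instead.
fix_gauge <- function(loading, score) {
  resultant <- sum(loading)
  total <- sum(Mod(loading))
  if (total == 0) return(list(loading = loading, score = score))
  if (Mod(resultant) / total > 1e-8) {
    alpha <- Arg(resultant)
  } else {
    alpha <- Arg(loading[which.max(Mod(loading))])
  }
  rot <- exp(complex(imaginary = -alpha))
  list(loading = loading * rot, score = score * rot)
}

#' Complex principal component decomposition
#'
#' Singular value decomposition of the analytic matrix. Column means are not
#' removed: columns are z-scored real signals and the Hilbert transform
#' preserves their zero mean. The phase gauge of every component is fixed
#' deterministically (zero amplitude-weighted circular phase mean).
#'
#' @param a An `analytic_matrix`.
#' @param n_components Number of components to retain; default 10.
#' @return An object of class `wave_decomposition` with elements
#'   `loadings` (pixels x k complex, each column unit norm), `scores`
#'   (time x k complex, `t_k = d_k u_k`), `d` (singular values, all of them),
#'   `variance_fraction` (per retained component), `total_sumsq`,
#'   `pixel_index`, `grid_dim`, `sampling_rate`, `n_time`, `n_pixels`.
#' @export
cpca_decompose <- function(a, n_components = 10) {
  stopifnot(inherits(a, "analytic_matrix"))
  M <- a$values
  r <- min(dim(M))
  n_components <- as.integer(n_components)
  if (n_components < 1 || n_components > r) {
    stop(sprintf("n_components must be in 1..%d", r))
  }
  s <- svd(M, nu = n_components, nv = n_components)
  d <- s$d
  tol <- max(dim(M)) * max(d) * .Machine$double.eps
  rank <- sum(d > tol)
  if (rank < n_components) {
    warning(sprintf("input has numerical rank %d < %d requested components",
                    rank, n_components))
  }
  loadings <- s$v
  scores <- sweep(s$u, 2, d[seq_len(n_components)], "*")
  for (k in seq_len(n_components)) {
    g <- fix_gauge(loadings[, k], scores[, k])
    loadings[, k] <- g$loading
    scores[, k] <- g$score
  }
  structure(
    list(
      loadings = loadings, scores = scores, d = d,
      variance_fraction = d[seq_len(n_components)]^2 / sum(d^2),
      total_sumsq = sum(d^2),
      n_components = n_components, rank = rank,
      pixel_index = a$pixel_index, grid_dim = a$grid_dim,
      sampling_rate = a$sampling_rate,
      n_time = nrow(M), n_pixels = ncol(M),
      boundaries = a$boundaries
    ),
    class = "wave_decomposition"
  )
}

#' @export
print.wave_decomposition <- function(x, ...) {
  cat(sprintf("<wave_decomposition> %d components (%d x %d input)\n",
              x$n_components, x$n_time, x$n_pixels))
  cat("  variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}

#' Extract one wave's complex loading as a grid map
#'
#' @param d A `wave_decomposition`.
#' @param k Component index.
#' @return A complex `height x width` matrix (`NA` off-mask); its modulus is
#'   the amplitude map `rho`, its argument the phase map `theta`.
#' @export
loading_map <- function(d, k) {
  stopifnot(inherits(d, "wave_decomposition"), k >= 1, k <= d$n_components)
  map_to_grid(d$loadings[, k], d$pixel_index, d$grid_dim)
}

#' Reconstruct the real spatiotemporal pattern of one wave
#'
#' `S_R^k(t, p) = Re(t_k(t) conj(l_k(p)))`. Summing the reconstructions of
#' all components reproduces the real input matrix exactly.
#'
#' @param d A `wave_decomposition`.
#' @param k Component index (may be a vector; patterns are summed).
#' @return A `pixel_matrix` holding the reconstructed real time courses.
#' @export
reconstruct_component <- function(d, k) {
  stopifnot(inherits(d, "wave_decomposition"), all(k >= 1), all(k <= d$n_components))
  vals <- Re(d$scores[, k, drop = FALSE] %*% Conj(t(d$loadings[, k, drop = FALSE])))
  pixel_matrix(vals, d$pixel_index, d$grid_dim, d$sampling_rate,
               flags = list(filtered = NA, zscored = FALSE, gsr = FALSE,
                            source = paste0("wave:", paste(k, collapse = "+"))))
}

#' Remove one or more waves from a signal
#'
#' Subtracts the reconstructed pattern of components `k` from the matrix the
#' decomposition was computed on. Removing the first (standing, global)
#' component approximates global signal regression.
#'
#' @param m The `pixel_matrix` (or `analytic_matrix`) the decomposition came
#'   from; its real part is used.
#' @param d A `wave_decomposition`.
#' @param k Component indices to remove.
#' @return A `pixel_matrix` of residual time courses.
#' @export
remove_component <- function(m, d, k) {
  stopifnot(inherits(m, "pixel_matrix"))
  rec <- reconstruct_component(d, k)
  out <- m
  out$values <- Re(m$values) - rec$values
  class(out) <- "pixel_matrix"
  out$flags$removed_components <- k
  out
}

#' Spatial maps of one wave over a cycle
#'
#' `map_j(p) = Re(rho(p) exp(i theta(p)) exp(-2 pi i j / n_phases))` for
#' `j = 0 .. n_phases - 1`: the wave's spatial pattern sampled at equal phase
#' steps through one oscillation, frame 0 being the gauge-aligned peak.
#'
#' @param d A `wave_decomposition`.
#' @param k Component index.
#' @param n_phases Number of phase steps (>= 2).
#' @return A `height x width x n_phases` array.
#' @export
cycle_pattern <- function(d, k, n_phases = 8) {
  stopifnot(n_phases >= 2)
  lm <- loading_map(d, k)
  ph <- exp(complex(imaginary = -2 * pi * (0:(n_phases - 1)) / n_phases))
  out <- vapply(ph, function(z) Re(lm * z),
                matrix(0, nrow(lm), ncol(lm)))
  out
}
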