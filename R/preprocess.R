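# Preprocessing: masking/flattening, bandpass filtering, per-pixel z-scoring,
# global signal regression. The pipeline order used throughout the package is
# flatten -> bandpass -> zscore (-> optional GSR).

#' Time-by-pixel matrix
#'
#' The working container for a masked, flattened movie: an `n_time x n_pixels`
#' real matrix whose columns are per-pixel fluorescence time series, together
#' with the map back to the 2-D grid and provenance flags recording which
#' preprocessing steps have been applied.
#'
#' @param values Real matrix, `n_time x n_pixels`.
#' @param pixel_index Data frame with integer columns `row`, `col`: grid
#'   coordinates of each pixel column, in column order.
#' @param grid_dim Integer vector `c(height, width)` of the source grid.
#' @param sampling_rate Sampling rate in Hz.
#' @param flags Named list of provenance flags
#'   (`filtered`, `zscored`, `gsr`).
#' @param boundaries Integer vector of cumulative end frames when the matrix
#'   is a concatenation of experiments (see [concatenate_experiments()]).
#' @return An object of class `pixel_matrix`.
#' @seealso [flatten_movie()] which constructs one from a movie array.
#' @export
pixel_matrix <- function(values, pixel_index, grid_dim, sampling_rate,
                         flags = list(filtered = FALSE, zscored = FALSE,
                                      gsr = FALSE),
                         boundaries = nrow(values)) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("pixel_matrix values must not contain NAs")
  if (nrow(values) < 2) stop("need at least 2 time points")
  if (ncol(values) != nrow(pixel_index)) {
    stop("pixel_index must have one entry per pixel column")
  }
  if (anyDuplicated(pixel_index[c("row", "col")])) {
    stop("pixel_index maps two columns to the same grid location")
  }
  check_scalar(sampling_rate, "sampling_rate", 0, open_lower = TRUE)
  structure(
    list(values = values, pixel_index = pixel_index,
         grid_dim = as.integer(grid_dim),
         sampling_rate = sampling_rate, flags = flags,
         boundaries = boundaries),
    class = "pixel_matrix"
  )
}

#' @export
print.pixel_matrix <- function(x, ...) {
  cat(sprintf(
    "<pixel_matrix> %d frames x %d pixels @ %g Hz (grid %dx%d)\n",
    nrow(x$values), ncol(x$values), x$sampling_rate,
    x$grid_dim[1], x$grid_dim[2]
  ))
  on <- names(Filter(isTRUE, x$flags))
  cat("  applied:", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @export
dim.pixel_matrix <- function(x) dim(x$values)

#' Flatten a movie to a time-by-pixel matrix
#'
#' Extracts the in-mask pixel time series of a `time x height x width` movie
#' into the columns of a [pixel_matrix()]. Columns are ordered row-major over
#' the grid (row index varying slowest), so the layout is reproducible across
#' platforms.
#'
#' @param movie Numeric array `time x height x width`.
#' @param mask Logical `height x width` matrix; `TRUE` marks valid pixels.
#' @param sampling_rate Sampling rate in Hz.
#' @return A `pixel_matrix`.
#' @export
flatten_movie <- function(movie, mask, sampling_rate) {
  stopifnot(length(dim(movie)) == 3)
  if (!is.logical(mask)) stop("mask must be logical")
  if (!all(dim(movie)[2:3] == dim(mask))) {
    stop("mask shape does not match the movie frames")
  }
  if (sum(mask) < 2) stop("mask must contain at least 2 pixels")
  idx <- which(mask, arr.ind = TRUE)
  ord <- order(idx[, 1], idx[, 2])  # row-major
  idx <- idx[ord, , drop = FALSE]
  flat <- matrix(movie, nrow = dim(movie)[1])  # time x (H*W), column-major grid
  lin <- (idx[, 2] - 1L) * dim(mask)[1] + idx[, 1]
  pixel_matrix(
    flat[, lin, drop = FALSE],
    pixel_index = data.frame(row = idx[, 1], col = idx[, 2]),
    grid_dim = dim(mask), sampling_rate = sampling_rate
  )
}

#' Map a time-by-pixel matrix back onto the grid
#'
#' Inverse of [flatten_movie()]: rebuilds the `time x height x width` movie,
#' with `NA` outside the mask. `map_to_grid()` does the same for a single
#' per-pixel vector (one value per column), returning a `height x width` map.
#'
#' @param m A `pixel_matrix`.
#' @return `unflatten_movie()`: a numeric array; `map_to_grid()`: a matrix.
#' @export
unflatten_movie <- function(m) {
  h <- m$grid_dim[1]; w <- m$grid_dim[2]
  out <- array(NA_real_, c(nrow(m$values), h, w))
  lin <- (m$pixel_index$col - 1L) * h + m$pixel_index$row
  flat <- matrix(NA_real_, nrow(m$values), h * w)
  flat[, lin] <- m$values
  array(flat, c(nrow(m$values), h, w))
}

#' @param values Vector with one value per pixel column (real or complex).
#' @param pixel_index,grid_dim As stored in a `pixel_matrix`.
#' @rdname unflatten_movie
#' @export
map_to_grid <- function(values, pixel_index, grid_dim) {
  stopifnot(length(values) == nrow(pixel_index))
  out <- matrix(if (is.complex(values)) NA_complex_ else NA_real_,
                grid_dim[1], grid_dim[2])
  out[cbind(pixel_index$row, pixel_index$col)] <- values
  out
}

#' Zero-phase Chebyshev type II bandpass filter
#'
#' Filters every pixel column with a type II Chebyshev bandpass applied
#' forward and backward ([signal::filtfilt()]), so the output has no group
#' delay. The requested band is treated as the passband; the stopband edges
#' are placed at `low/2` and midway between `high` and the Nyquist frequency,
#' with at least `stopband_db` attenuation beyond them.
#'
#' The first and last `edge_seconds` of the record carry filter transients;
#' they are recorded in the output flags rather than trimmed.
#'
#' @param m A `pixel_matrix`.
#' @param band Numeric `c(low, high)` in Hz; default 0.1-14.5 Hz.
#' @param order Filter order of the analog prototype (the bandpass has twice
#'   this order); default 4.
#' @param stopband_db Minimum stopband attenuation in dB; default 40.
#' @param edge_seconds Length of the transient guard recorded in metadata.
#' @return The filtered `pixel_matrix` with `flags$filtered = TRUE`.
#' @export
bandpass <- function(m, band = c(0.1, 14.5), order = 4, stopband_db = 40,
                     edge_seconds = 5) {
  stopifnot(inherits(m, "pixel_matrix"), length(band) == 2)
  nyq <- m$sampling_rate / 2
  if (!(band[1] >= 0 && band[1] < band[2] && band[2] < nyq)) {
    stop(sprintf("band [%g, %g] Hz is infeasible at %g Hz sampling",
                 band[1], band[2], m$sampling_rate))
  }
  if (nrow(m$values) < 3 * (2 * order)) {
    stop("record too short for filter transients")
  }
  ws <- c(band[1] / 2, band[2] + (nyq - band[2]) / 2) / nyq
  flt <- signal::cheby2(order, stopband_db, ws, type = "pass")
  out <- apply(m$values, 2, function(x) signal::filtfilt(flt, x))
  m$values <- out
  m$flags$filtered <- TRUE
  m$flags$band <- band
  m$flags$edge_seconds <- edge_seconds
  m
}

#' Z-score every pixel time series
#'
#' Centers each pixel column and scales it to unit variance, using the
#' population (1/N) variance convention (recorded in the flags; downstream
#' correlations are invariant to the 1/N vs 1/(N-1) choice).
#'
#' @param m A `pixel_matrix`.
#' @return The z-scored `pixel_matrix` with `flags$zscored = TRUE`.
#' @export
zscore_pixels <- function(m) {
  stopifnot(inherits(m, "pixel_matrix"))
  mu <- colMeans(m$values)
  centered <- sweep(m$values, 2, mu)
  v <- colMeans(centered^2)  # population variance
  if (any(v == 0)) {
    bad <- which(v == 0)[1]
    stop(sprintf("pixel at grid (%d, %d) has zero variance",
                 m$pixel_index$row[bad], m$pixel_index$col[bad]))
  }
  m$values <- sweep(centered, 2, sqrt(v), "/")
  m$flags$zscored <- TRUE
  m$flags$variance_convention <- "population"
  m
}

#' Global signal regression
#'
#' Regresses the pixel-averaged (global) time series out of every pixel by
#' ordinary least squares with an intercept, keeping the residuals. This is
#' the standard functional-imaging definition of GSR; residuals are exactly
#' uncorrelated with the global mean.
#'
#' @param m A z-scored `pixel_matrix`.
#' @return The residual `pixel_matrix` with `flags$gsr = TRUE`.
#' @export
regress_global_signal <- function(m) {
  stopifnot(inherits(m, "pixel_matrix"))
  if (!isTRUE(m$flags$zscored)) {
    warning("global signal regression on a non-z-scored matrix")
  }
  g <- rowMeans(m$values)
  if (all(g == 0)) stop("global mean signal is identically zero")
  gc <- g - mean(g)
  denom <- sum(gc^2)
  if (denom == 0) stop("global mean signal is constant")
  # per-column OLS on [1, g]: residual = x - mean(x) - beta * (g - mean(g))
  beta <- as.vector(crossprod(m$values, gc)) / denom
  m$values <- sweep(m$values, 2, colMeans(m$values)) - outer(gc, beta)
  m$flags$gsr <- TRUE
  m
}

#' Concatenate experiments along time
#'
#' Stacks z-scored recordings that share a pixel grid and sampling rate into
#' one longer matrix for group-level decomposition; longer records raise the
#' effective signal-to-noise ratio of the decomposition. Per-experiment
#' boundaries are kept in `boundaries`.
#'
#' @param ms List of z-scored `pixel_matrix` objects with identical
#'   `pixel_index` and `sampling_rate`.
#' @return A single `pixel_matrix`.
#' @export
concatenate_experiments <- function(ms) {
  if (length(ms) == 0) stop("empty experiment list")
  stopifnot(all(vapply(ms, inherits, logical(1), "pixel_matrix")))
  ref <- ms[[1]]
  for (m in ms[-1]) {
    if (!identical(m$pixel_index, ref$pixel_index)) {
      stop("experiments have mismatched pixel sets")
    }
    if (m$sampling_rate != ref$sampling_rate) {
      stop("experiments have mismatched sampling rates")
    }
  }
  if (!all(vapply(ms, function(m) isTRUE(m$flags$zscored), logical(1)))) {
    warning("concatenating experiments that are not all z-scored")
  }
  out <- ref
  out$values <- do.call(rbind, lapply(ms, `[[`, "values"))
  out$boundaries <- cumsum(vapply(ms, function(m) nrow(m$values), integer(1)))
  out
}
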