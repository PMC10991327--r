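# Wave characterization: autocorrelation-based natural frequency and damping,
# PSNR spatial-map quality, circular variance of phase maps, unit-energy
# power spectra and band-power maps.

#' Sample autocorrelation of a waveform
#'
#' Biased sample autocorrelation (the default of [stats::acf()]), normalized
#' to 1 at lag zero.
#'
#' @param waveform Real time series.
#' @param max_lag Maximum lag in seconds; must be below half the duration.
#' @param rate Sampling rate in Hz.
#' @return An object of class `acf_curve` with fields `lags` (seconds) and
#'   `values`.
#' @export
autocorrelation <- function(waveform, max_lag, rate) {
  waveform <- as.numeric(waveform)
  n <- length(waveform)
  check_scalar(rate, "rate", 0, open_lower = TRUE)
  if (max_lag >= n / rate / 2) stop("max_lag must be below half the duration")
  if (stats::var(waveform) == 0) stop("zero-variance waveform")
  nlag <- floor(max_lag * rate)
  ac <- stats::acf(waveform, lag.max = nlag, plot = FALSE,
                   demean = TRUE, type = "correlation")
  structure(list(lags = (0:nlag) / rate, values = as.vector(ac$acf),
                 rate = rate),
            class = "acf_curve")
}

# The damped second-order-oscillator autocorrelation model:
# R(tau) = A exp(-2 pi f_n xi |tau|) *
#          (cos(2 pi f_d tau) + xi / sqrt(1 - xi^2) * sin(2 pi f_d |tau|)),
# with f_d = f_n sqrt(1 - xi^2) tied to (f_n, xi). A lumps the white-noise
# input level and stiffness, which are not separately identifiable.
oscillator_acf <- function(tau, A, f_n, xi) {
  f_d <- f_n * sqrt(1 - xi^2)
  at <- abs(tau)
  A * exp(-2 * pi * f_n * xi * at) *
    (cos(2 * pi * f_d * tau) + xi / sqrt(1 - xi^2) * sin(2 * pi * f_d * at))
}

# Candidate frequencies for the multi-start fit: the top peaks of the
# spectrum of the ACF itself (Wiener-Khinchin).
acf_peak_freqs <- function(acf, n_peaks = 5) {
  v <- acf$values
  n <- length(v)
  sym <- c(v, rev(v[-c(1, n)]))  # even extension
  p <- Mod(stats::fft(sym))[seq_len(n)]
  freqs <- (seq_len(n) - 1) / (length(sym)) * acf$rate
  ok <- freqs > 0 & freqs < acf$rate / 2
  p <- p[ok]; freqs <- freqs[ok]
  is_peak <- c(FALSE, diff(sign(diff(p))) < 0, FALSE)[seq_along(p)]
  cand <- freqs[is_peak][order(p[is_peak], decreasing = TRUE)]
  cand <- cand[seq_len(min(n_peaks, length(cand)))]
  if (length(cand) == 0) cand <- freqs[which.max(p)]
  cand
}

#' Fit the damped-oscillator model to an autocorrelation curve
#'
#' Nonlinear least squares of the second-order-oscillator autocorrelation
#' model over `(A, f_n, xi)`, with the damped frequency tied to
#' `f_d = f_n sqrt(1 - xi^2)`. The fit proceeds in two stages: a
#' multi-start unweighted fit over the dominant spectral peaks of the
#' curve, followed by a weighted refinement whose weights decay an order
#' of magnitude faster than the fitted envelope
#' (`exp(-10 * 2 pi f_n xi * tau)`). Sample-autocorrelation values at
#' small lags are far less noisy than the tail (whose fluctuations mimic
#' spurious damping), so concentrating the refinement there substantially
#' reduces the variance of the damping estimate while leaving fits on
#' noise-free curves exact. Since the input curve is normalized at lag
#' zero, a fitted `A` far from 1 flags a poor fit.
#'
#' @param acf An `acf_curve` from [autocorrelation()].
#' @param xi_bounds Bounds for the damping ratio; default `c(1e-4, 0.999)`.
#' @param extra_starts Optional extra start frequencies in Hz.
#' @param refine Run the weighted refinement stage; default `TRUE`.
#' @return An object of class `oscillator_fit`: `f_n`, `f_d`, `xi`,
#'   `amplitude`, `rms_residual`, `n_lags`, `converged`.
#' @export
fit_oscillator <- function(acf, xi_bounds = c(1e-4, 0.999),
                           extra_starts = NULL, refine = TRUE) {
  stopifnot(inherits(acf, "acf_curve"))
  tau <- acf$lags; y <- acf$values
  L <- max(tau)
  f_lo <- 1 / L; f_hi <- acf$rate / 2
  starts <- unique(c(acf_peak_freqs(acf), extra_starts))
  starts <- pmin(pmax(starts, f_lo * 1.01), f_hi * 0.99)
  one_fit <- function(tau, y, start, wts = NULL) {
    args <- list(
      y ~ oscillator_acf(tau, A, f_n, xi),
      data = data.frame(tau = tau, y = y),
      start = start,
      lower = c(A = 1e-8, f_n = f_lo, xi = xi_bounds[1]),
      upper = c(A = 10, f_n = f_hi, xi = xi_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    if (!is.null(wts)) args$weights <- wts
    tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) NULL)
  }
  best <- NULL
  for (f0 in starts) {
    for (xi0 in c(0.02, 0.1, 0.3)) {
      fit <- one_fit(tau, y, list(A = 1, f_n = f0, xi = xi0))
      if (is.null(fit)) next
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop("oscillator fit failed to converge from every start")
  }
  cf <- stats::coef(best$fit)
  if (refine) {
    decay <- 2 * pi * cf[["f_n"]] * cf[["xi"]]
    wfit <- one_fit(tau, y,
                    list(A = cf[["A"]], f_n = cf[["f_n"]], xi = cf[["xi"]]),
                    wts = exp(-10 * decay * tau))
    if (!is.null(wfit)) cf <- stats::coef(wfit)
  }
  resid_all <- y - oscillator_acf(tau, cf[["A"]], cf[["f_n"]], cf[["xi"]])
  structure(
    list(f_n = cf[["f_n"]],
         f_d = cf[["f_n"]] * sqrt(1 - cf[["xi"]]^2),
         xi = cf[["xi"]],
         amplitude = cf[["A"]],
         rms_residual = sqrt(mean(resid_all^2)),
         n_lags = length(y), converged = TRUE),
    class = "oscillator_fit"
  )
}

#' @export
print.oscillator_fit <- function(x, ...) {
  cat(sprintf(
    "<oscillator_fit> f_n = %.4g Hz, f_d = %.4g Hz, xi = %.4g (Q = %.3g), rms = %.3g\n",
    x$f_n, x$f_d, x$xi, q_from_damping(x$xi), x$rms_residual))
  invisible(x)
}

#' Convert between damping ratio and Q-factor
#'
#' The damping ratio is half the reciprocal of the Q-factor:
#' `xi = 0.5 / Q` and `Q = 0.5 / xi`.
#'
#' @param q Q-factor (> 0).
#' @return `damping_from_q()`: the damping ratio; `q_from_damping()`: the
#'   Q-factor.
#' @export
damping_from_q <- function(q) {
  check_scalar(q, "q", 0, open_lower = TRUE)
  0.5 / q
}

#' @param xi Damping ratio (> 0).
#' @rdname damping_from_q
#' @export
q_from_damping <- function(xi) {
  check_scalar(xi, "xi", 0, open_lower = TRUE)
  0.5 / xi
}

# Mask-aware median filter with a k x k window. An even kernel has no center
# pixel: the window for pixel (i, j) spans offsets -k/2 .. k/2 - 1 in each
# dimension (the (+0, +0) corner of the 2 x 2 ambiguity). Borders are
# reflect-padded; out-of-mask pixels are excluded from each window.
median_filter_masked <- function(x, kernel = 10) {
  h <- nrow(x); w <- ncol(x)
  lo <- -floor(kernel / 2); hi <- lo + kernel - 1
  reflect <- function(i, n) {
    # reflect indices into 1..n (edge-repeat reflection)
    if (n == 1) return(rep(1L, length(i)))
    i <- abs(i - 1) %% (2 * n - 2)
    as.integer(ifelse(i >= n, 2 * n - 2 - i, i) + 1)
  }
  ri <- vapply(lo:hi, function(o) reflect(seq_len(h) + o, h), integer(h))
  ci <- vapply(lo:hi, function(o) reflect(seq_len(w) + o, w), integer(w))
  out <- matrix(NA_real_, h, w)
  for (i in seq_len(h)) {
    rows <- ri[i, ]
    for (j in seq_len(w)) {
      if (is.na(x[i, j])) next
      win <- x[rows, ci[j, ]]
      out[i, j] <- stats::median(win[!is.na(win)])
    }
  }
  out
}

#' PSNR quality of a wave's spatial map
#'
#' Scores how spatially structured a complex loading map is: the PSNR of its
#' real part plus the PSNR of its imaginary part, each computed as
#' `10 log10(x_max / var(x - median_filter(x)))` where `x_max` is the maximum
#' of that part over the mask and the median filter uses a `kernel x kernel`
#' window. Note `x_max` enters linearly (not squared, not the range), which
#' deviates from the conventional image-PSNR definition; the score is
#' therefore "dB-like" and meaningful as a relative quality index.
#'
#' A part whose residual variance is zero (e.g. a constant map) contributes
#' the documented ceiling value and the result is flagged via
#' `attr(, "capped")`. A part whose mask maximum is not positive contributes
#' `NA` with `attr(, "undefined_part")` set (the printed formula has no value
#' there).
#'
#' @param loading Complex `height x width` matrix, `NA` outside the mask
#'   (see [loading_map()]).
#' @param kernel Median filter window size; default 10.
#' @param ceiling_db Cap used when the residual variance is zero.
#' @return The summed score, with attributes `capped` and `undefined_part`.
#' @export
psnr_quality <- function(loading, kernel = 10, ceiling_db = 300) {
  stopifnot(is.matrix(loading))
  if (nrow(loading) < kernel || ncol(loading) < kernel) {
    stop(sprintf("grid must be at least %d x %d", kernel, kernel))
  }
  part_psnr <- function(x) {
    filt <- median_filter_masked(x, kernel)
    resid <- x - filt
    v <- stats::var(as.vector(resid), na.rm = TRUE)
    xmax <- max(x, na.rm = TRUE)
    if (!is.finite(v) || v == 0) {
      return(structure(ceiling_db, capped = TRUE, undefined = FALSE))
    }
    if (xmax <= 0) {
      return(structure(NA_real_, capped = FALSE, undefined = TRUE))
    }
    structure(10 * log10(xmax / v), capped = FALSE, undefined = FALSE)
  }
  re <- part_psnr(Re(loading))
  im <- part_psnr(Im(loading))
  total <- sum(c(re, im), na.rm = TRUE)
  structure(total,
            capped = attr(re, "capped") || attr(im, "capped"),
            undefined_part = attr(re, "undefined") || attr(im, "undefined"))
}

#' Circular variance of a wave's phase map
#'
#' `1 - |sum_p rho_p exp(i theta_p)| / sum_p rho_p`: one minus the length of
#' the amplitude-weighted phase resultant. Zero for a constant-phase
#' (standing) wave; tends to 1 as phases disperse, and equals 1 exactly for
#' two equal-mass antipodal phase lobes. Weighting by amplitude is the
#' default because low-amplitude pixels carry unreliable phase; the
#' unweighted variant treats every in-mask pixel equally.
#'
#' @param loading Complex map or vector (`NA` entries ignored).
#' @param weighted If `FALSE`, use equal weights over pixels with
#'   nonzero amplitude.
#' @return A value in \[0, 1\].
#' @export
circular_variance <- function(loading, weighted = TRUE) {
  l <- as.vector(loading)
  l <- l[!is.na(l)]
  if (length(l) == 0) stop("empty loading")
  rho <- Mod(l)
  if (sum(rho) == 0) stop("all-zero amplitude map")
  if (weighted) {
    1 - Mod(sum(l)) / sum(rho)
  } else {
    z <- exp(complex(imaginary = Arg(l[rho > 0])))
    1 - Mod(sum(z)) / length(z)
  }
}

#' Unit-energy power spectral density
#'
#' Hann-windowed periodogram of a real series, rescaled so that the PSD
#' integrates (trapezoid rule) to one over frequency. Used for displaying
#' waveform spectra on a common energy scale.
#'
#' @param series Real time series (length >= 16).
#' @param rate Sampling rate in Hz.
#' @return A `data.frame` with columns `freq` (Hz) and `psd` (1/Hz).
#' @export
unit_energy_psd <- function(series, rate) {
  series <- as.numeric(series)
  n <- length(series)
  if (n < 16) stop("series too short (need >= 16 samples)")
  if (stats::var(series) == 0) stop("constant series has no spectrum")
  w <- hann_window(n)
  x <- (series - mean(series)) * w
  p <- Mod(stats::fft(x))^2
  nf <- floor(n / 2) + 1
  freq <- (seq_len(nf) - 1) * rate / n
  psd <- p[seq_len(nf)]
  # fold negative frequencies onto positive ones
  if (n %% 2 == 0) {
    psd[2:(nf - 1)] <- 2 * psd[2:(nf - 1)]
  } else {
    psd[2:nf] <- 2 * psd[2:nf]
  }
  area <- sum(diff(freq) * (psd[-1] + psd[-nf]) / 2)
  data.frame(freq = freq, psd = psd / area)
}

#' Per-pixel spectral power fractions in frequency bands
#'
#' For every pixel, the fraction of its (unit-normalized) spectral energy
#' falling in each band. Bands must be non-overlapping and lie in
#' `(0, Nyquist)`; over a full partition the per-pixel fractions sum to 1.
#' Six logarithmically spaced bands partitioning the 0.1-14.5 Hz passband
#' are the conventional display choice (see [default_bands()]).
#'
#' @param m A `pixel_matrix`.
#' @param bands A list of `c(low, high)` pairs in Hz.
#' @return A `height x width x n_bands` array of energy fractions.
#' @export
band_power_maps <- function(m, bands) {
  stopifnot(inherits(m, "pixel_matrix"), length(bands) >= 1)
  nyq <- m$sampling_rate / 2
  bm <- do.call(rbind, bands)
  if (any(bm[, 1] >= bm[, 2]) || any(bm[, 1] < 0) || any(bm[, 2] > nyq)) {
    stop("each band must satisfy 0 <= low < high <= Nyquist")
  }
  ord <- order(bm[, 1])
  bm <- bm[ord, , drop = FALSE]
  if (nrow(bm) > 1 && any(bm[-1, 1] < bm[-nrow(bm), 2] - 1e-12)) {
    stop("bands overlap")
  }
  n <- nrow(m$values)
  centered <- sweep(m$values, 2, colMeans(m$values))
  p <- Mod(stats::mvfft(centered))^2
  nf <- floor(n / 2) + 1
  freq <- (seq_len(nf) - 1) * m$sampling_rate / n
  p <- p[seq_len(nf), , drop = FALSE]
  pos <- freq > 0
  total <- colSums(p[pos, , drop = FALSE])
  out <- array(NA_real_, c(m$grid_dim, length(bands)))
  for (b in seq_len(nrow(bm))) {
    sel <- pos & freq > bm[b, 1] & freq <= bm[b, 2]
    frac <- colSums(p[sel, , drop = FALSE]) / total
    out[, , ord[b]] <- map_to_grid(frac, m$pixel_index, m$grid_dim)
  }
  out
}

#' Default six-band partition of a passband
#'
#' Six logarithmically spaced, non-overlapping bands partitioning
#' `low`-`high` Hz (0.1-14.5 by default).
#'
#' @param low,high Passband edges in Hz.
#' @param n Number of bands.
#' @return A list of `c(low, high)` pairs.
#' @export
default_bands <- function(low = 0.1, high = 14.5, n = 6) {
  edges <- exp(seq(log(low), log(high), length.out = n + 1))
  lapply(seq_len(n), function(i) c(edges[i], edges[i + 1]))
}
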