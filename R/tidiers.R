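# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a wave decomposition
#'
#' One row per retained component: eigenvalue, variance fraction and
#' circular variance of the phase map.
#'
#' @param x A `wave_decomposition`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy wave_decomposition
#' @export
tidy.wave_decomposition <- function(x, ...) {
  tibble::tibble(
    component = seq_len(x$n_components),
    eigenvalue = x$d[seq_len(x$n_components)],
    variance_fraction = x$variance_fraction,
    circular_variance = vapply(seq_len(x$n_components), function(k) {
      circular_variance(x$loadings[, k])
    }, numeric(1))
  )
}

#' @rdname tidy.wave_decomposition
#' @method glance wave_decomposition
#' @export
glance.wave_decomposition <- function(x, ...) {
  tibble::tibble(
    n_time = x$n_time, n_pixels = x$n_pixels,
    n_components = x$n_components, rank = x$rank,
    variance_retained = sum(x$variance_fraction)
  )
}

#' Tidy an oscillator fit
#'
#' One row per fitted quantity (`f_n`, `f_d`, `xi`, `amplitude`).
#'
#' @param x An `oscillator_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`.
#' @method tidy oscillator_fit
#' @export
tidy.oscillator_fit <- function(x, ...) {
  tibble::tibble(
    term = c("f_n", "f_d", "xi", "amplitude"),
    estimate = c(x$f_n, x$f_d, x$xi, x$amplitude)
  )
}

#' @rdname tidy.oscillator_fit
#' @method glance oscillator_fit
#' @export
glance.oscillator_fit <- function(x, ...) {
  tibble::tibble(rms_residual = x$rms_residual, n_lags = x$n_lags,
                 converged = x$converged)
}

#' Tidy a wave match
#'
#' @param x A `wave_match`.
#' @param ... Unused.
#' @return The assignment tibble (`query`, `reference`, `mse`).
#' @method tidy wave_match
#' @export
tidy.wave_match <- function(x, ...) x$assignment
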