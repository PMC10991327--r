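# Synthetic narrowband waveforms: a stochastically driven second-order
# linear oscillator, discretized at the sampling rate. Its autocorrelation
# follows the damped-oscillator model the metrics module fits, which makes
# the generator and the estimator two sides of the same signal family.

#' Simulate a damped-narrowband analytic waveform
#'
#' Drives a discretized second-order linear oscillator (resonant frequency
#' `freq`, damping ratio `damping`) with Gaussian white noise, discards a
#' burn-in of several decay times, scales the real part to unit variance and
#' returns the analytic (complex) signal. The power concentrates at `freq`
#' with quality factor `Q ~ 1 / (2 damping)`; as `damping -> 0` the
#' autocorrelation envelope decays ever more slowly toward an undamped
#' sinusoid. Identical arguments give identical output.
#'
#' @param freq Oscillation frequency in Hz (0 < freq < rate/2).
#' @param damping Damping ratio in (0, 1).
#' @param duration Duration in seconds.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return A complex vector of length `duration * rate` with attributes
#'   `rate`, `freq`, `damping`. Its real part is the waveform; its argument
#'   the instantaneous phase.
#' @export
simulate_waveform <- function(freq, damping, duration, rate, seed = NULL) {
  check_scalar(rate, "rate", 0, open_lower = TRUE)
  check_scalar(freq, "freq", 0, rate / 2, open_lower = TRUE, open_upper = TRUE)
  check_scalar(damping, "damping", 0, 1, open_lower = TRUE, open_upper = TRUE)
  n <- round(duration * rate)
  if (n < 2) stop("duration * rate must be at least 2")
  with_seed(seed, {
    dt <- 1 / rate
    w_n <- 2 * pi * freq
    w_d <- w_n * sqrt(1 - damping^2)
    r <- exp(-damping * w_n * dt)
    # AR(2) with complex-conjugate poles r exp(+/- i w_d dt): the discrete
    # analog of the continuous oscillator driven by white noise
    a <- c(2 * r * cos(w_d * dt), -r^2)
    # burn-in: ~8 envelope decay times, at least one period
    burn <- ceiling(max(8 / (damping * w_n), 2 * pi / w_n) / dt)
    e <- stats::rnorm(n + burn)
    x <- stats::filter(e, filter = a, method = "recursive")
    x <- as.numeric(x)[(burn + 1):(burn + n)]
    x <- (x - mean(x)) / stats::sd(x)
    z <- as.vector(analytic_columns(x))
    structure(z, rate = rate, freq = freq, damping = damping)
  })
}
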