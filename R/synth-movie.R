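# Synthetic movie generation and ground-truth recovery reporting.

#' Generate a synthetic movie from a ground truth
#'
#' Builds `movie(t, p) = efficiency(p) * sum_k c_k rho_k(p)
#' Re(w_k(t) exp(-i theta_k(p))) + noise(t, p)`: each wave's narrowband
#' analytic waveform is delayed per pixel by a phase rotation (valid for
#' narrowband signals, and exactly the phase model the decomposition
#' assumes), scaled by its amplitude map and a constant `c_k` chosen so the
#' wave carries its specified share of the average pixel variance, summed,
#' multiplied by the expression-efficiency map, and topped with zero-mean
#' Gaussian noise of standard deviation `noise_sigma`.
#'
#' All randomness derives from `truth$seed` (waveform `k` uses
#' `seed + k`, the noise uses `seed + 997`), so the movie is
#' bit-reproducible.
#'
#' @param truth A [synthetic_truth()].
#' @return A list: `movie` (`time x height x width` array), `mask` (logical
#'   matrix, all `TRUE`), `truth`, and `waveforms` (list of the complex
#'   source waveforms).
#' @export
simulate_movie <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  h <- truth$grid_dim[1]; w <- truth$grid_dim[2]
  p <- h * w
  n <- round(truth$duration * truth$sampling_rate)
  signal <- matrix(0, n, p)
  waveforms <- vector("list", length(truth$wave_specs))
  for (k in seq_along(truth$wave_specs)) {
    ws <- truth$wave_specs[[k]]
    wf <- simulate_waveform(ws$waveform_freq, ws$waveform_damping,
                            truth$duration, truth$sampling_rate,
                            seed = truth$seed + k)
    waveforms[[k]] <- wf
    l <- as.vector(ws$amplitude_map * exp(complex(imaginary = ws$phase_map)))
    # scale so the wave's summed pixel variance is share * p (the average
    # pixel variance of the noiseless movie is 1 when shares sum to 1)
    c_k <- sqrt(ws$variance_share * p / sum(Mod(l)^2))
    signal <- signal + Re(as.vector(wf) %o% Conj(c_k * l))
  }
  eff <- as.vector(truth$efficiency_map)
  signal <- sweep(signal, 2, eff, "*")
  if (truth$noise_sigma > 0) {
    noise <- with_seed(truth$seed + 997L,
                       matrix(stats::rnorm(n * p, sd = truth$noise_sigma), n, p))
    signal <- signal + noise
  }
  list(movie = array(signal, c(n, h, w)), mask = matrix(TRUE, h, w),
       truth = truth, waveforms = waveforms)
}

#' Match a decomposition against the generating ground truth
#'
#' Assigns each ground-truth wave to the recovered component whose complex
#' loading it resembles most ([complex_map_similarity()], invariant to the
#' component's global phase), greedily from the best pair down so that no
#' component is used twice. Reports the loading similarity and the error of
#' the recovered variance fraction; extra components appear as unmatched
#' rows, and truth waves are left unmatched (flagged) when the decomposition
#' has fewer components than the truth has waves.
#'
#' @param truth The [synthetic_truth()] the movie came from.
#' @param decomposition A `wave_decomposition` computed from that movie.
#' @return A tibble with one row per truth wave and per unmatched component:
#'   `truth_wave`, `component`, `similarity`, `truth_share`,
#'   `recovered_fraction`, `share_error`, `matched`.
#' @export
recovery_report <- function(truth, decomposition) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(decomposition, "wave_decomposition"))
  if (!all(truth$grid_dim == decomposition$grid_dim)) {
    stop("truth and decomposition are on different grids")
  }
  pi_ <- decomposition$pixel_index
  lin <- cbind(pi_$row, pi_$col)
  truth_maps <- lapply(truth$wave_specs, function(ws) {
    (ws$amplitude_map * exp(complex(imaginary = ws$phase_map)))[lin]
  })
  n_truth <- length(truth_maps)
  n_comp <- decomposition$n_components
  sim <- matrix(0, n_truth, n_comp)
  for (i in seq_len(n_truth)) {
    for (j in seq_len(n_comp)) {
      sim[i, j] <- complex_map_similarity(truth_maps[[i]],
                                          decomposition$loadings[, j])
    }
  }
  assign_comp <- rep(NA_integer_, n_truth)
  s <- sim
  for (step in seq_len(min(n_truth, n_comp))) {
    best <- arrayInd(which.max(s), dim(s))
    assign_comp[best[1]] <- best[2]
    s[best[1], ] <- -Inf
    s[, best[2]] <- -Inf
  }
  shares <- vapply(truth$wave_specs, `[[`, numeric(1), "variance_share")
  rows <- tibble::tibble(
    truth_wave = seq_len(n_truth),
    component = assign_comp,
    similarity = ifelse(is.na(assign_comp), NA_real_,
                        sim[cbind(seq_len(n_truth), assign_comp)]),
    truth_share = shares,
    recovered_fraction = ifelse(
      is.na(assign_comp), NA_real_,
      decomposition$variance_fraction[assign_comp]),
    matched = !is.na(assign_comp)
  )
  rows$share_error <- rows$recovered_fraction - rows$truth_share
  extra <- setdiff(seq_len(n_comp), assign_comp[!is.na(assign_comp)])
  if (length(extra)) {
    rows <- rbind(rows, tibble::tibble(
      truth_wave = NA_integer_, component = extra, similarity = NA_real_,
      truth_share = NA_real_,
      recovered_fraction = decomposition$variance_fraction[extra],
      matched = FALSE, share_error = NA_real_
    ))
  }
  rows
}
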