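# Shared fixtures, built in code. The heavier ones are memoized so several
# test files can reuse them without recomputation.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small, fast ground truth: same three-wave structure as default_truth()
# on a 20 x 20 grid, 50 s.
small_truth <- function(seed = 1, duration = 50) {
  default_truth(seed = seed, duration = duration, grid_dim = c(20, 20))
}

# Small movie -> z-scored pixel matrix -> decomposition, memoized per seed.
small_decomposition <- function(seed = 1, n_components = 6) {
  memo(sprintf("smalldec_%d_%d", seed, n_components), {
    tr <- small_truth(seed)
    sim <- simulate_movie(tr)
    m <- zscore_pixels(flatten_movie(sim$movie, sim$mask, tr$sampling_rate))
    list(truth = tr, m = m,
         dec = cpca_decompose(analytic_signal(m), n_components))
  })
}

# A single-wave movie with a two-lobe pi-offset map: the canonical
# negative-correlation geometry.
two_lobe_fixture <- function(seed = 3, duration = 100, grid_dim = c(12, 12)) {
  memo(sprintf("twolobe_%d_%d_%d", seed, duration, grid_dim[1]), {
    h <- grid_dim[1]; w <- grid_dim[2]
    centers <- rbind(c(h / 2, w * 0.25), c(h / 2, w * 0.75))
    pat <- make_wave_pattern(
      "traveling", grid_dim,
      amplitude = list(type = "blobs", centers = centers, widths = 0.25 * h),
      phase = list(type = "two_lobe", centers = centers, offset = pi)
    )
    tr <- synthetic_truth(
      list(wave_pattern_spec("traveling", pat$amplitude_map, pat$phase_map,
                             0.5, 0.05, 0.9)),
      sampling_rate = 30, duration = duration, seed = seed
    )
    sim <- simulate_movie(tr)
    m <- zscore_pixels(flatten_movie(sim$movie, sim$mask, tr$sampling_rate))
    list(truth = tr, pattern = pat, m = m,
         dec = cpca_decompose(analytic_signal(m), 3))
  })
}

# A movie dominated by a global standing wave (the GSR-equivalence regime):
# standing 60%, two-lobe traveling 20% covering the whole grid, noise 20%.
standing_dominant_fixture <- function(seed = 5, duration = 100,
                                      grid_dim = c(16, 16)) {
  memo(sprintf("standdom_%d_%d_%d", seed, duration, grid_dim[1]), {
    h <- grid_dim[1]; w <- grid_dim[2]
    standing <- make_wave_pattern("standing", grid_dim,
                                  amplitude = list(type = "uniform"))
    centers <- rbind(c(h / 2, w * 0.25), c(h / 2, w * 0.75))
    pat <- make_wave_pattern(
      "traveling", grid_dim,
      amplitude = list(type = "blobs", centers = centers, widths = 0.35 * h),
      phase = list(type = "two_lobe", centers = centers, offset = pi)
    )
    tr <- synthetic_truth(
      list(wave_pattern_spec("standing", standing$amplitude_map,
                             standing$phase_map, 0.3, 0.05, 0.6),
           wave_pattern_spec("traveling", pat$amplitude_map, pat$phase_map,
                             0.7, 0.05, 0.2)),
      sampling_rate = 30, duration = duration, seed = seed
    )
    sim <- simulate_movie(tr)
    m <- zscore_pixels(flatten_movie(sim$movie, sim$mask, tr$sampling_rate))
    list(truth = tr, m = m)
  })
}

# Tiny deterministic pixel_matrix from explicit values.
tiny_pm <- function(values, rate = 30) {
  p <- ncol(values)
  pixel_matrix(values,
               data.frame(row = rep(1L, p), col = seq_len(p)),
               grid_dim = c(1L, p), sampling_rate = rate)
}

# Plain correlation matrix -> fc_matrix on a 1 x n line grid.
tiny_fc <- function(v, gsr = FALSE) {
  n <- nrow(v)
  structure(v, class = c("fc_matrix", "matrix"),
            pixel_index = data.frame(row = rep(1L, n), col = seq_len(n)),
            grid_dim = c(1L, n), gsr_applied = gsr, source = "raw")
}
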