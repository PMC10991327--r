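# Synthetic waveforms, patterns, movies, gene maps, recovery reporting.

test_that("simulate_waveform is deterministic, validated, and narrowband", {
  w1 <- simulate_waveform(0.3, 0.05, 60, 30, seed = 1)
  w2 <- simulate_waveform(0.3, 0.05, 60, 30, seed = 1)
  expect_identical(w1, w2)
  w3 <- simulate_waveform(0.3, 0.05, 60, 30, seed = 2)
  expect_false(identical(as.vector(w1), as.vector(w3)))
  expect_error(simulate_waveform(20, 0.05, 10, 30), "freq")
  expect_error(simulate_waveform(0.3, 1.5, 10, 30), "damping")
  expect_error(simulate_waveform(0.3, 0, 10, 30), "damping")
  # real part is zero mean, unit variance; spectrum peaks near 0.3 Hz
  x <- Re(w1)
  expect_lt(abs(mean(x)), 1e-10)
  expect_equal(sd(x), 1, tolerance = 1e-10)
  psd <- unit_energy_psd(x, 30)
  expect_lt(abs(psd$freq[which.max(psd$psd)] - 0.3), 0.1)
})

test_that("waveform autocorrelation follows the damped-oscillator model", {
  # recovered natural frequency within 10% of truth (median over seeds)
  errs <- vapply(1:7, function(s) {
    w <- simulate_waveform(0.3, 0.05, 180, 30, seed = s)
    fit <- fit_oscillator(autocorrelation(Re(w), 30, 30))
    abs(fit$f_n - 0.3) / 0.3
  }, numeric(1))
  expect_lt(median(errs), 0.10)
  # damping -> 0: the envelope barely decays over many periods
  w <- simulate_waveform(0.5, 0.001, 400, 30, seed = 4)
  ac <- autocorrelation(Re(w), 20, 30)
  peak_at <- function(lag_s) ac$values[which.min(abs(ac$lags - lag_s))]
  expect_gt(peak_at(2), 0.9)    # one period later, still ~1
  expect_gt(peak_at(10), 0.75)  # five periods later
  expect_lt(peak_at(1), -0.75)  # half period: deep anticorrelation
})

test_that("make_wave_pattern produces the requested geometries", {
  st <- make_wave_pattern("standing", c(40, 40),
                          amplitude = list(type = "uniform", value = 1))
  expect_true(all(st$phase_map == 0))
  expect_true(all(st$amplitude_map == 1))
  expect_equal(circular_variance(st$amplitude_map *
                                   exp(complex(imaginary = st$phase_map))), 0)

  lin <- make_wave_pattern("traveling", c(40, 40),
                           phase = list(type = "linear", axis = "col",
                                        range = c(0, pi)))
  expect_true(all(diff(lin$phase_map[1, ]) > 0))      # column-monotone
  expect_equal(max(lin$phase_map) - min(lin$phase_map), pi)
  expect_true(all(lin$phase_map == rep(lin$phase_map[1, ],
                                       each = nrow(lin$phase_map))))

  centers <- rbind(c(20, 10), c(20, 30))
  tl <- make_wave_pattern("traveling", c(40, 40),
                          amplitude = list(type = "blobs", centers = centers,
                                           widths = 6),
                          phase = list(type = "two_lobe", centers = centers))
  expect_setequal(unique(as.vector(tl$phase_map)), c(0, pi))
  expect_error(make_wave_pattern("spinning", c(10, 10)), "arg")
  expect_error(make_wave_pattern("standing", c(10, 10),
                                 phase = list(type = "linear", axis = "col",
                                              range = c(0, 1))), "constant")
})

test_that("simulate_movie composes waves, efficiency and noise as specified", {
  # noiseless single standing wave with unit efficiency: every pixel is a
  # scalar multiple of the source waveform
  pat <- make_wave_pattern("standing", c(5, 5),
                           amplitude = list(type = "blobs",
                                            centers = rbind(c(3, 3)),
                                            widths = 2))
  tr <- synthetic_truth(
    list(wave_pattern_spec("standing", pat$amplitude_map, pat$phase_map,
                           0.4, 0.05, 1)),
    noise_sigma = 0, sampling_rate = 30, duration = 20, seed = 2
  )
  sim <- simulate_movie(tr)
  m <- flatten_movie(sim$movie, sim$mask, 30)
  expect_lt(max(abs(cor(m$values) - 1)), 1e-10)
  # determinism: same truth -> identical movie
  sim2 <- simulate_movie(tr)
  expect_identical(sim$movie, sim2$movie)
  # errors
  expect_error(
    synthetic_truth(list(
      wave_pattern_spec("standing", pat$amplitude_map, pat$phase_map,
                        0.4, 0.05, 0.7),
      wave_pattern_spec("standing", pat$amplitude_map, pat$phase_map,
                        0.6, 0.05, 0.7))),
    "sum")
  pat2 <- make_wave_pattern("standing", c(6, 5))
  expect_error(
    synthetic_truth(list(
      wave_pattern_spec("standing", pat$amplitude_map, pat$phase_map,
                        0.4, 0.05, 0.3),
      wave_pattern_spec("standing", pat2$amplitude_map, pat2$phase_map,
                        0.6, 0.05, 0.3))),
    "grid")
})

test_that("realized variance shares match the specification", {
  tr <- default_truth(seed = 6)
  sim <- simulate_movie(tr)
  n <- dim(sim$movie)[1]
  p <- prod(tr$grid_dim)
  flat <- matrix(sim$movie, nrow = n)
  total_var <- sum(apply(flat, 2, var))
  # rebuild each wave's field from the returned waveforms and measure its
  # share of the total movie variance
  for (k in 1:3) {
    ws <- tr$wave_specs[[k]]
    l <- as.vector(ws$amplitude_map * exp(complex(imaginary = ws$phase_map)))
    c_k <- sqrt(ws$variance_share * p / sum(Mod(l)^2))
    field <- Re(as.vector(sim$waveforms[[k]]) %o% Conj(c_k * l))
    share <- sum(apply(field, 2, var)) / total_var
    expect_lt(abs(share - ws$variance_share), 0.02)
  }
})

test_that("expression-efficiency differences do not change the decomposition", {
  # ~2x expression contrast across the field; additive (post-efficiency)
  # noise makes the invariance approximate, degrading gracefully as the
  # contrast grows
  h <- 20
  eff <- matrix(0.7, h, h) + 0.6 * neurowave:::gaussian_blobs(
    c(h, h), rbind(c(6, 6), c(15, 13)), widths = 5)
  run <- function(em) {
    tr <- default_truth(seed = 8, duration = 100, grid_dim = c(h, h),
                        efficiency_map = em)
    sim <- simulate_movie(tr)
    m <- zscore_pixels(flatten_movie(sim$movie, sim$mask, 30))
    cpca_decompose(analytic_signal(m), 3)
  }
  d_flat <- run(NULL)
  d_eff <- run(eff)
  for (k in 1:3) {
    expect_gt(complex_map_similarity(d_flat$loadings[, k], d_eff$loadings[, k]),
              0.99)
  }
})

test_that("simulate_gene_maps hits its target correlations and stays smooth", {
  ref <- neurowave:::gaussian_blobs(c(30, 30), rbind(c(10, 10), c(22, 20)),
                                    widths = c(4, 7))
  maps <- simulate_gene_maps(ref, c(1, 0.8, 0.4, 0, -0.5), seed = 3)
  expect_length(maps, 5)
  rs <- vapply(maps, function(m) cor(as.vector(m), as.vector(ref)), numeric(1))
  expect_equal(unname(rs), c(1, 0.8, 0.4, 0, -0.5), tolerance = 1e-10)
  # r = 0 across many seeds: mean absolute realized correlation stays small
  r0 <- vapply(1:50, function(s) {
    cor(as.vector(simulate_gene_maps(ref, 0, seed = s)[[1]]), as.vector(ref))
  }, numeric(1))
  expect_lt(mean(abs(r0)), 0.05)
  # smoothness: a blurred field has most of its energy at low spatial
  # frequency -- neighboring pixels correlate strongly
  g <- maps[[4]]
  expect_gt(cor(as.vector(g[-1, ]), as.vector(g[-nrow(g), ])), 0.5)
  expect_error(simulate_gene_maps(ref, 1.2), "\\[-1, 1\\]")
})

test_that("recovery_report matches waves and flags the unmatched", {
  # noiseless two-wave movie on orthogonal maps with spatially uniform
  # total variance: exact recovery
  h <- 8; w <- 8
  l1 <- matrix(1 + 0i, h, w)
  l2 <- matrix(exp(complex(imaginary = 2 * pi * (0:(w - 1)) / w)),
               h, w, byrow = TRUE)
  mk <- function(l, kind, f, share) {
    wave_pattern_spec(kind, Mod(l), Arg(l), f, 0.05, share)
  }
  tr <- synthetic_truth(list(mk(l1, "standing", 0.4, 0.6),
                             mk(l2, "traveling", 1.2, 0.4)),
                        noise_sigma = 0, sampling_rate = 30, duration = 60,
                        seed = 5)
  sim <- simulate_movie(tr)
  m <- zscore_pixels(flatten_movie(sim$movie, sim$mask, 30))
  d <- cpca_decompose(analytic_signal(m), 2)
  rr <- recovery_report(tr, d)
  expect_equal(rr$component[1:2], c(1L, 2L))
  expect_true(all(rr$similarity[1:2] >= 0.99))
  expect_true(all(abs(rr$share_error[1:2]) < 0.01))

  # one truth wave, five components on a 5-pixel grid: the four extra
  # components are unmatched and split the noise share about evenly
  pat <- make_wave_pattern("standing", c(1, 5))
  tr1 <- synthetic_truth(
    list(wave_pattern_spec("standing", pat$amplitude_map, pat$phase_map,
                           0.4, 0.05, 0.6)),
    sampling_rate = 30, duration = 200, seed = 9
  )
  sim1 <- simulate_movie(tr1)
  m1 <- zscore_pixels(flatten_movie(sim1$movie, sim1$mask, 30))
  d5 <- cpca_decompose(analytic_signal(m1), 5)
  rr1 <- recovery_report(tr1, d5)
  expect_equal(nrow(rr1), 5L)
  expect_equal(sum(rr1$matched), 1L)
  unmatched <- rr1$recovered_fraction[!rr1$matched]
  expect_equal(unmatched, rep(0.4 / 4, 4), tolerance = 0.5)

  # fewer components than truth waves: the weakest truth wave is unmatched
  d1 <- cpca_decompose(analytic_signal(m), 1)
  rr2 <- recovery_report(tr, d1)
  expect_true(rr2$matched[1])
  expect_false(rr2$matched[2])
})
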