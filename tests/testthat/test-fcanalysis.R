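# Functional connectivity: matrices, wave FC, superposition, spatial
# summaries, seeds, short-range FC, group statistics.

test_that("fc_matrix computes pairwise Pearson correlations with provenance", {
  set.seed(8)
  n <- 1e4
  x <- rnorm(n)
  vals <- cbind(x, x, -x, rnorm(n), rnorm(n))
  m <- tiny_pm(vals, 30)
  fc <- fc_matrix(m)
  expect_equal(unclass(fc)[1, 2], 1)
  expect_equal(unclass(fc)[1, 3], -1)
  expect_false(attr(fc, "gsr_applied"))
  # independent noise columns: off-diagonals within the sampling bound
  expect_lt(abs(unclass(fc)[4, 5]), 3 / sqrt(n))
  expect_lt(max(abs(fc - t(fc))), 1e-10)
  expect_error(fc_matrix(tiny_pm(cbind(x, rep(1, n)), 30)), "zero variance")
})

test_that("wave_fc follows the cos(delta theta) law", {
  tl <- two_lobe_fixture()
  d <- tl$dec
  # an exactly standing wave: all defined entries 1
  wst <- sin(2 * pi * 0.5 * (1:300) / 30)
  mst <- tiny_pm(outer(wst, c(1, 2, 0.5, 3)), 30)
  mst$flags$zscored <- TRUE
  dst <- cpca_decompose(analytic_signal(mst), 1)
  expect_lt(max(abs(unclass(wave_fc(dst, 1)) - 1)), 1e-6)
  # dominant two-lobe wave: within-lobe +1, cross-lobe -1
  rec <- recovery_report(tl$truth, d)
  k <- rec$component[which(rec$truth_wave == 1)]
  wfc <- wave_fc(d, k)
  theta <- Arg(d$loadings[, k])
  oracle <- cos(outer(theta, theta, "-"))
  expect_lt(max(abs(unclass(wfc) - oracle), na.rm = TRUE), 0.05)
  # truth-phase version: cross-lobe entries are negative
  lobe_phase <- as.vector(tl$truth$wave_specs[[1]]$phase_map)[
    (tl$m$pixel_index$col - 1L) * 12L + tl$m$pixel_index$row]
  rho <- as.vector(tl$truth$wave_specs[[1]]$amplitude_map)[
    (tl$m$pixel_index$col - 1L) * 12L + tl$m$pixel_index$row]
  strong <- rho > 0.5 * max(rho)
  cross <- outer(lobe_phase[strong], lobe_phase[strong], "!=")
  expect_lt(max(unclass(wfc)[strong, strong][cross]), -0.9)
  expect_gt(min(unclass(wfc)[strong, strong][!cross]), 0.9)
})

test_that("fc_superposition approaches the raw FC as waves accumulate", {
  sd1 <- small_decomposition(n_components = 6)
  fc <- fc_matrix(sd1$m)
  sup <- fc_superposition(sd1$dec, reference = fc)
  expect_equal(nrow(sup$similarity), 6L)
  # the trend is increasing overall (small non-monotone wiggles from noise
  # components are tolerated at this scale)
  expect_gt(sup$similarity$r[6], sup$similarity$r[1])
  # completeness at full rank: scalar-weighted superposition of
  # correlation matrices is exact when the wave amplitude maps are flat
  # (correlations strip per-pixel amplitude), so the completeness fixture
  # uses uniform-amplitude waves with orthogonal phase geometries
  h <- 8; w <- 8
  u <- matrix(1, h, w)
  th_r <- matrix(2 * pi * (0:(h - 1)) / h, h, w)
  th_c <- matrix(2 * pi * (0:(w - 1)) / w, h, w, byrow = TRUE)
  trf <- synthetic_truth(list(
    wave_pattern_spec("standing", u, 0 * u, 0.3, 0.05, 0.40),
    wave_pattern_spec("traveling", u, th_r, 0.7, 0.05, 0.30),
    wave_pattern_spec("traveling", u, th_c, 1.5, 0.05, 0.20)),
    sampling_rate = 30, duration = 60, seed = 7)
  simf <- simulate_movie(trf)
  mf <- zscore_pixels(flatten_movie(simf$movie, simf$mask, 30))
  df <- cpca_decompose(analytic_signal(mf), h * w)
  fcf <- fc_matrix(mf)
  supf <- fc_superposition(df, reference = fcf)
  expect_gt(supf$similarity$r[h * w], 0.99)
  # non-decreasing (tiny wiggles deep in the noise tail tolerated)
  expect_true(all(diff(supf$similarity$r) > -1e-4))
  # a standing-wave-dominated signal at k = 1 gives a near-constant
  # all-positive matrix
  sdom <- standing_dominant_fixture()
  dd <- cpca_decompose(analytic_signal(sdom$m), 3)
  s1 <- fc_superposition(dd, upto_k = 1)
  expect_gt(min(unclass(s1$fc), na.rm = TRUE), 0.9)
})

test_that("mean_fc_map averages connection strength per pixel", {
  ones <- tiny_fc(matrix(1, 6, 6))
  expect_true(all(mean_fc_map(ones) == 1))
  # two equal blocks, +1 within and -1 between
  b <- rbind(cbind(matrix(1, 3, 3), matrix(-1, 3, 3)),
             cbind(matrix(-1, 3, 3), matrix(1, 3, 3)))
  fcb <- tiny_fc(b)
  expect_true(all(mean_fc_map(fcb, absolute = TRUE) == 1))
  signed <- mean_fc_map(fcb, absolute = FALSE)
  expect_lt(max(abs(signed - (-1 / 5))), 1e-12)  # 2 within, 3 between, /5
  # standing-dominant movie: the mean FC map tracks the dominant wave's
  # amplitude profile
  sdom <- standing_dominant_fixture()
  fc <- fc_matrix(sdom$m)
  dd <- cpca_decompose(analytic_signal(sdom$m), 2)
  dfc <- mean_fc_map(fc, absolute = FALSE)
  rho0 <- Mod(loading_map(dd, 1))
  expect_gt(cor(as.vector(dfc), as.vector(rho0)), 0.8)
})

test_that("hemispheric difference is zero under mirror symmetry and detects asymmetry", {
  # mirror-symmetric FC on a 1 x 4 line: sides {1,2} and {3,4}
  v <- matrix(0.5, 4, 4); diag(v) <- 1
  fc <- tiny_fc(v)
  hd <- hemispheric_difference_map(fc, midline_column = 2)
  expect_lt(max(abs(hd), na.rm = TRUE), 1e-12)
  expect_error(hemispheric_difference_map(fc, midline_column = 4), "midline")
  # a quarter-cycle lag between the hemispheres: within a hemisphere
  # |cos(dtheta)| = 1, across it |cos(pi/2)| = 0, so homolateral |FC|
  # exceeds contralateral |FC| everywhere (a pure pi offset would make
  # the absolute correlations equal on both sides)
  h <- 10; w <- 10
  theta <- matrix(rep(c(0, pi / 2), each = h * w / 2), h, w)
  l <- exp(complex(imaginary = theta))
  wf <- simulate_waveform(0.5, 0.05, 80, 30, seed = 21)
  vals <- Re(as.vector(wf) %o% Conj(as.vector(l))) +
    0.3 * matrix(rnorm(length(wf) * h * w), length(wf))
  mm <- zscore_pixels(flatten_movie(array(vals, c(length(wf), h, w)),
                                    matrix(TRUE, h, w), 30))
  hd2 <- hemispheric_difference_map(fc_matrix(mm), midline_column = 5)
  expect_true(all(hd2 > 0))
})

test_that("fc_similarity_map is 1 for affine copies and centered for shuffles", {
  set.seed(23)
  n <- 2000
  m <- tiny_pm(matrix(rnorm(n * 8), n, 8) +
                 outer(rnorm(n), rep(1, 8)), 30)
  fc <- fc_matrix(m)
  expect_true(all(abs(fc_similarity_map(fc, fc) - 1) < 1e-12))
  aff <- tiny_fc(0.5 * unclass(fc) + 0.2)
  attr(aff, "pixel_index") <- attr(fc, "pixel_index")
  attr(aff, "grid_dim") <- attr(fc, "grid_dim")
  sim_aff <- fc_similarity_map(fc, aff)
  expect_true(all(abs(sim_aff - 1) < 1e-10))
  # row-shuffled: similarities scatter around zero
  sh <- unclass(fc)
  set.seed(1)
  perm <- sample(8)
  sh <- sh[perm, perm]
  shf <- tiny_fc(sh)
  attr(shf, "pixel_index") <- attr(fc, "pixel_index")
  attr(shf, "grid_dim") <- attr(fc, "grid_dim")
  expect_lt(abs(mean(fc_similarity_map(fc, shf))), 0.35)
  bad <- tiny_fc(matrix(0.1, 5, 5))
  expect_error(fc_similarity_map(fc, bad), "node")
})

test_that("select_seeds clusters connection maps and is deterministic", {
  # two-block FC forces k = 2 with one seed per block
  n <- 20
  b <- rbind(cbind(matrix(0.9, n / 2, n / 2), matrix(-0.9, n / 2, n / 2)),
             cbind(matrix(-0.9, n / 2, n / 2), matrix(0.9, n / 2, n / 2)))
  diag(b) <- 1
  b <- b + 0.01 * matrix(rnorm(n * n), n, n)
  b <- (b + t(b)) / 2; diag(b) <- 1
  fc <- tiny_fc(b)
  ss <- select_seeds(fc, k_range = 2:6, seed = 2)
  expect_equal(ss$k, 2L)
  blocks <- (seq_len(n) > n / 2) + 1L
  expect_equal(length(unique(ss$assignment[blocks == 1])), 1L)
  expect_equal(length(unique(ss$assignment[blocks == 2])), 1L)
  expect_equal(nrow(ss$seeds), 2L)
  seed_cols <- ss$seeds$col
  expect_true(any(seed_cols <= n / 2) && any(seed_cols > n / 2))
  # determinism
  ss2 <- select_seeds(fc, k_range = 2:6, seed = 2)
  expect_identical(ss$seeds, ss2$seeds)
  # degenerate constant FC
  cst <- tiny_fc(matrix(1, 10, 10))
  expect_warning(ssd <- select_seeds(cst, k_range = 2:4), "degenerate")
  expect_equal(ssd$k, 2L)
})

test_that("seed_fc and short_range_fc use the seed geometry", {
  # 3 x 3 grid; all pixels share one series except a contrary corner
  set.seed(31)
  n <- 400
  base <- rnorm(n)
  vals <- matrix(rep(base, 9), n, 9)
  vals[, 9] <- rnorm(n)
  movie <- array(vals, c(n, 3, 3))
  m <- flatten_movie(movie, matrix(TRUE, 3, 3), 30)
  seeds <- structure(list(
    seeds = tibble::tibble(label = c("a", "b"), cluster = 1:2,
                           row = c(1L, 2L), col = c(1L, 2L)),
    assignment = rep(1L, 9), k = 2L, degenerate = FALSE,
    pixel_index = m$pixel_index, grid_dim = c(3L, 3L)),
    class = "seed_set")
  sf <- seed_fc(m, seeds)
  expect_equal(dim(sf$fc), c(2L, 2L))
  expect_equal(unclass(sf$fc)[1, 2], 1)
  expect_equal(dim(sf$maps), c(3L, 3L, 2L))
  expect_equal(sf$maps[1, 2, 1], 1)
  # short-range: the center seed's 8-neighborhood includes the contrary
  # corner, the corner seed has identical neighbors
  sr <- short_range_fc(m, seeds)
  expect_gt(sr[["a"]], 0.99)  # corner seed: 3 in-mask neighbors, all = base
  expect_lt(sr[["b"]], 1)     # center seed: neighborhood diluted
  # k = 1: a 1 x 1 matrix
  one <- seeds; one$seeds <- one$seeds[1, ]; one$k <- 1L
  expect_equal(dim(seed_fc(m, one)$fc), c(1L, 1L))
  # seed outside the mask errors
  mask <- matrix(TRUE, 3, 3); mask[1, 1] <- FALSE
  m2 <- flatten_movie(movie, mask, 30)
  expect_error(seed_fc(m2, seeds), "outside")
})

test_that("group_fc_tests controls error rates and flags degeneracies", {
  # identical matrices with nonzero edges: degenerate, all significant
  fc <- tiny_fc(matrix(c(1, .5, .5, 1), 2))
  res <- group_fc_tests(list(fc, fc, fc))
  expect_true(all(res$degenerate))
  expect_true(all(res$significant))
  expect_equal(res$p, 0)
  # a real signal is detected: one edge strongly positive across replicates
  set.seed(41)
  mats <- lapply(1:6, function(i) {
    v <- diag(3)
    v[1, 2] <- v[2, 1] <- 0.7 + 0.05 * rnorm(1)
    v[1, 3] <- v[3, 1] <- 0.02 * rnorm(1)
    v[2, 3] <- v[3, 2] <- 0.02 * rnorm(1)
    tiny_fc(v)
  })
  res2 <- group_fc_tests(mats)
  sig_edge <- res2[res2$i == 1 & res2$j == 2, ]
  expect_true(sig_edge$significant)
  # Welch comparison between groups differing in one wave's strength
  mk_group <- function(share2, seeds) {
    lapply(seeds, function(s) {
      h <- 8
      centers <- rbind(c(4, 2), c(4, 6))
      pat <- make_wave_pattern("traveling", c(h, h),
        amplitude = list(type = "blobs", centers = centers, widths = 2),
        phase = list(type = "two_lobe", centers = centers))
      st <- make_wave_pattern("standing", c(h, h))
      tr <- synthetic_truth(list(
        wave_pattern_spec("standing", st$amplitude_map, st$phase_map,
                          0.3, 0.05, 0.75 - share2),
        wave_pattern_spec("traveling", pat$amplitude_map, pat$phase_map,
                          0.8, 0.05, share2)),
        sampling_rate = 30, duration = 30, seed = s)
      sim <- simulate_movie(tr)
      fc_matrix(zscore_pixels(flatten_movie(sim$movie, sim$mask, 30)))
    })
  }
  weak <- mk_group(0.05, 1:5)
  strong <- mk_group(0.55, 11:15)
  res3 <- group_fc_tests(weak, strong)
  expect_true(any(res3$significant))
  # significant differences concentrate where the changed wave connects:
  # its own two-lobe C_Phi has the largest |cos(dtheta)| everywhere, so
  # check the top edges involve the lobe pixels
  expect_gt(mean(abs(res3$statistic[res3$significant]), na.rm = TRUE),
            mean(abs(res3$statistic[!res3$significant]), na.rm = TRUE))
  expect_error(group_fc_tests(list(fc, fc)), "at least 3")
})
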