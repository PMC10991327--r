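# End-to-end pipeline: preprocess -> decompose -> characterize -> FC
# (-> matching / gene correlation), driven by a single configuration.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with the conventional defaults:
#' 0.1-14.5 Hz passband, 10 retained components, k-means seed selection over
#' 2-25 clusters, gene-correlation thresholds 0.3/0.75, a 10 x 10 median
#' filter for wave quality, and one root seed from which all randomness
#' flows.
#'
#' @param band Bandpass edges in Hz.
#' @param bandpass_filter Apply the bandpass at all (synthetic movies are
#'   already band-limited); default `TRUE`.
#' @param gsr Also compute the GSR branch; default `TRUE`.
#' @param n_components Number of retained components.
#' @param k_range Candidate cluster counts for seed selection.
#' @param select_seeds Run seed selection (the silhouette sweep is the most
#'   expensive stage on large grids); default `TRUE`.
#' @param gene_low,gene_high Gene-correlation thresholds.
#' @param median_kernel PSNR median-filter kernel.
#' @param acf_lag Autocorrelation fitting window in seconds.
#' @param midline_column Grid column splitting the hemispheres, or `NULL`
#'   to use the grid middle.
#' @param seed Root seed.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(band = c(0.1, 14.5), bandpass_filter = TRUE,
                            gsr = TRUE, n_components = 10,
                            k_range = 2:25, select_seeds = TRUE,
                            gene_low = 0.3, gene_high = 0.75,
                            median_kernel = 10, acf_lag = 30,
                            midline_column = NULL, seed = 1) {
  structure(
    list(band = band, bandpass_filter = bandpass_filter, gsr = gsr,
         n_components = n_components, k_range = k_range,
         select_seeds = select_seeds,
         gene_low = gene_low, gene_high = gene_high,
         median_kernel = median_kernel, acf_lag = acf_lag,
         midline_column = midline_column, seed = seed),
    class = "pipeline_config"
  )
}

#' Run the full wave-decomposition pipeline
#'
#' Flattens and preprocesses the movie (bandpass, z-score, optional GSR
#' branch), decomposes the analytic signal into standing/traveling waves,
#' characterizes every wave (oscillator fit, PSNR quality, circular
#' variance, variance fraction), computes raw and GSR functional
#' connectivity with the per-wave superposition, selects seeds and seed
#' connectivity, and — when given — matches the waves against a reference
#' decomposition and correlates wave amplitude maps with gene maps.
#'
#' @param movie `time x height x width` numeric array.
#' @param mask Logical matrix.
#' @param sampling_rate Hz.
#' @param config A [pipeline_config()].
#' @param gene_maps Optional named list of gene-expression matrices.
#' @param reference_waves Optional `wave_decomposition` to match against.
#' @return A list of class `wave_pipeline` with elements `preprocessed`,
#'   `decomposition`, `metrics` (per-wave tibble), `fc`, `fc_gsr`,
#'   `superposition`, `seeds`, `seed_fc`, `short_range`, `match`,
#'   `gene_correlations`, `config`.
#' @export
run_pipeline <- function(movie, mask, sampling_rate, config = pipeline_config(),
                         gene_maps = NULL, reference_waves = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  m <- flatten_movie(movie, mask, sampling_rate)
  if (config$bandpass_filter) m <- bandpass(m, config$band)
  m <- zscore_pixels(m)
  a <- analytic_signal(m)
  dec <- cpca_decompose(a, n_components = config$n_components)
  metrics <- wave_metrics_table(dec, acf_lag = config$acf_lag,
                                kernel = config$median_kernel)
  fc <- fc_matrix(m)
  sup <- fc_superposition(dec, reference = fc)
  fc_gsr <- NULL
  if (config$gsr) fc_gsr <- fc_matrix(regress_global_signal(m))
  seeds <- seedfc <- short <- NULL
  if (config$select_seeds) {
    fc_for_seeds <- if (is.null(fc_gsr)) fc else fc_gsr
    seeds <- select_seeds(fc_for_seeds, k_range = config$k_range,
                          seed = config$seed)
    seedfc <- seed_fc(m, seeds)
    short <- short_range_fc(m, seeds)
  }
  match <- if (!is.null(reference_waves)) match_waves(dec, reference_waves)
  genes <- NULL
  if (!is.null(gene_maps)) {
    rho0 <- Mod(loading_map(dec, which_traveling(dec)[1]))
    tbl <- map_gene_correlations(rho0, gene_maps)
    genes <- classify_correlations(tbl, config$gene_low, config$gene_high)
  }
  structure(
    list(preprocessed = m, decomposition = dec, metrics = metrics,
         fc = fc, fc_gsr = fc_gsr, superposition = sup,
         seeds = seeds, seed_fc = seedfc, short_range = short,
         match = match, gene_correlations = genes, config = config),
    class = "wave_pipeline"
  )
}

# Index of the traveling (phase-dispersed) components, by circular variance.
which_traveling <- function(dec, threshold = 0.1) {
  cv <- vapply(seq_len(dec$n_components), function(k) {
    circular_variance(dec$loadings[, k])
  }, numeric(1))
  out <- which(cv > threshold)
  if (length(out) == 0) out <- seq_len(dec$n_components)
  out
}

#' Per-wave metrics table
#'
#' One row per retained component: eigenvalue, variance fraction, circular
#' variance of the phase map, PSNR map quality, and the oscillator fit of
#' the score waveform (natural and damped frequency, damping ratio, Q,
#' residual).
#'
#' @param dec A `wave_decomposition`.
#' @param acf_lag Autocorrelation window in seconds.
#' @param kernel PSNR median-filter kernel.
#' @return A tibble.
#' @export
wave_metrics_table <- function(dec, acf_lag = 30, kernel = 10) {
  stopifnot(inherits(dec, "wave_decomposition"))
  acf_lag <- min(acf_lag, 0.45 * dec$n_time / dec$sampling_rate)
  rows <- lapply(seq_len(dec$n_components), function(k) {
    wf <- Re(dec$scores[, k])
    fit <- tryCatch({
      ac <- autocorrelation(wf, max_lag = acf_lag, rate = dec$sampling_rate)
      fit_oscillator(ac)
    }, error = function(e) NULL)
    lm <- loading_map(dec, k)
    q <- tryCatch(as.numeric(psnr_quality(lm, kernel = kernel)),
                  error = function(e) NA_real_)
    tibble::tibble(
      component = k,
      eigenvalue = dec$d[k],
      variance_fraction = dec$variance_fraction[k],
      circular_variance = circular_variance(dec$loadings[, k]),
      psnr = q,
      f_n = if (is.null(fit)) NA_real_ else fit$f_n,
      f_d = if (is.null(fit)) NA_real_ else fit$f_d,
      xi = if (is.null(fit)) NA_real_ else fit$xi,
      fit_rms = if (is.null(fit)) NA_real_ else fit$rms_residual
    )
  })
  do.call(rbind, rows)
}

#' @export
print.wave_pipeline <- function(x, ...) {
  cat("<wave_pipeline>\n")
  print(x$decomposition)
  cat("\nPer-wave metrics:\n")
  print(x$metrics)
  invisible(x)
}
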