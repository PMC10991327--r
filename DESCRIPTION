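Package: neurowave
Title: Standing and Traveling Wave Decomposition of Widefield Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes pixel-resolved fluorescence movies of spontaneous
    cortical activity into standing and traveling waves by complex principal
    component analysis of the Hilbert-transformed (analytic) signal.
    Characterizes each wave by its natural frequency and damping ratio
    (damped-oscillator autocorrelation fit), spatial-map quality (PSNR against
    a median-filtered map) and phase uniformity (circular variance); expresses
    functional connectivity as a weighted superposition of per-wave
    correlation matrices, with global signal regression, hemispheric
    asymmetry maps, k-means seed selection and Fisher-z group statistics;
    matches waves across conditions by the mean squared error of their
    correlation matrices; and correlates wave amplitude maps with spatial
    gene-expression maps. Includes a synthetic-movie generator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    signal,
    minpack.lm,
    cluster,
    tibble,
    generics,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
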