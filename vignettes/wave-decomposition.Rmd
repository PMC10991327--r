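---
title: "Standing and traveling waves in widefield calcium imaging: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standing and traveling waves in widefield calcium imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the model the package implements, the parameters
that matter, the design decisions taken where the method leaves room, and
what the synthetic validation does and does not establish.

## The signal model

The package assumes a pixel-resolved fluorescence movie records a linear
superposition of a small number of spatiotemporal waves plus noise. Wave
$k$ is a narrowband temporal waveform $t_k(t)$ broadcast across the field
with a per-pixel intensity $\rho_k(p)$ and time lag expressed as a phase
$\theta_k(p)$ (lag $= \theta / 2\pi f$). A *standing* wave has constant
$\theta$ — the whole field rises and falls together; a *traveling* wave
has a spatial phase gradient — the oscillation sweeps across the field.

The decomposition works on the analytic signal. Each pixel series is
bandpass filtered, z-scored, and extended to
$C_p(t) = N_p(t) + i\,H[N_p](t)$ with $H$ the Hilbert transform
(frequency-domain construction; the analytic signal of $\cos\omega t$ is
$e^{i\omega t}$). Complex PCA is the SVD of the time-by-pixel matrix
$M = U D V^H$: loadings $l_k = v_k$ (stored as $\rho_k e^{i\theta_k}$),
scores $t_k = d_k u_k$, and variance fractions $d_k^2 / \sum_j d_j^2$.
Column means are not removed before the SVD: the columns are z-scored real
signals and the Hilbert transform preserves their zero mean. The
reconstruction $\mathrm{Re}(t_k \overline{l_k}^{\,T})$ of all components
sums to the real input exactly, and the complex covariance satisfies
$M^H M = \sum_k d_k^2\, l_k l_k^H$ — both identities are asserted to
$10^{-8}$ in the test suite.

**Assumptions worth keeping in mind.** The analytic-phase representation
of a time lag is a narrowband approximation; it is accurate for waves with
quality factors of a few or more, which is also the regime where "a wave"
is a meaningful description. Components are orthogonal by construction, so
the decomposition can only recover ground-truth waves whose complex maps
are near-orthogonal; strongly overlapping mixtures are not identifiable by
this (or any orthogonal) decomposition, and the number of waves is not
determined by the method — components must be screened by variance
fraction, map quality and phase structure.

## Phase gauge

Each component is defined only up to a global phase $e^{i\alpha}$
(rotating the loading and score together leaves the reconstruction
unchanged). Every reported quantity — $\rho$, phase *differences*,
variance fractions, wave correlation matrices — is gauge invariant, but
for reproducible output the gauge is fixed: each component is rotated so
the amplitude-weighted circular mean of its phase map is zero, i.e.
$\alpha = \arg \sum_p l_k(p)$. This makes standing waves display
$\theta \approx 0$ and is unique whenever the phase resultant is nonzero.
When the resultant (nearly) cancels — e.g. a two-lobe anti-phase map —
the phase of the largest-amplitude pixel is used instead. Both rules are
deterministic, so repeated runs and different LAPACK builds give identical
output; no further sign convention is needed.

## Preprocessing choices

- **Bandpass** (default 0.1–14.5 Hz): Chebyshev type II, analog-prototype
  order 4, ≥ 40 dB stopband, applied forward–backward (zero phase). The
  nominal band is treated as the passband; stopband edges sit at half the
  low corner and midway between the high corner and Nyquist. With the
  stopband edges placed *on* the band corners, a 0.3 Hz tone — well inside
  the band of interest — loses ~3% amplitude; the chosen placement keeps
  it within 0.1% while still rejecting slow drift by > 80 dB after the
  forward–backward pass. The first and last 5 s carry filter transients
  and are flagged in metadata, not trimmed.
- **Z-scoring** uses the population (1/N) variance convention, recorded in
  the output; downstream correlations are invariant to the 1/N vs 1/(N−1)
  choice. Filtering precedes z-scoring, so the unit-variance property
  holds for the matrix the decomposition actually sees.
- **GSR** is per-pixel ordinary least squares on the spatial-mean trace
  with an intercept (the standard functional-imaging definition), not
  plain subtraction; residuals are exactly uncorrelated with the global
  mean. On movies dominated by a global standing wave, removing the first
  component from the signal reproduces GSR almost exactly — the package
  tests both `corr(FC, FC_GSR)` ≥ 0.9 and the remove-first-component
  equivalence ≥ 0.95 on such a fixture.

## Wave metrics

- **Oscillator fit.** The natural frequency and damping ratio come from a
  nonlinear LS fit of the damped-oscillator autocorrelation model with
  $f_d$ tied to $f_n\sqrt{1-\xi^2}$, multi-started over the curve's
  spectral peaks (via the even-extension FFT of the ACF), with bounds
  $\xi \in (10^{-4}, 0.999)$, $f_n \in (1/L, \text{Nyquist})$. A second,
  weighted pass uses weights $e^{-10 \cdot 2\pi f_n \xi \tau}$ — an order
  of magnitude steeper than the fitted envelope. The rationale is
  statistical: sample-ACF values at early lags have far lower variance
  than the tail, whose fluctuations mimic spurious damping; on noise-free
  curves the refinement changes nothing (fits stay exact to $10^{-4}$
  relative), while on 180 s simulated waveforms at $f_n = 0.3$ Hz,
  $\xi = 0.05$ it roughly halves the median damping error. The curve is
  normalized at lag zero but the amplitude $A$ is left free, so
  $A \approx 1$ doubles as a fit sanity check. The default lag window is
  30 s.
- **PSNR map quality** follows the printed definition literally:
  $10\log_{10}(x_{\max} / \mathrm{var}(x - x_{\text{filtered}}))$ per
  part, real and imaginary parts summed, with $x_{\max}$ the *maximum*
  (not its square, not the range) — a deliberate fidelity to the source
  formula that makes the score "dB-like" rather than a standard image
  PSNR; it is documented as a relative quality index. The 10×10 median
  filter has no center pixel: the window spans offsets $-5..+4$ (one fixed
  corner of the 2×2 ambiguity), borders reflect, and out-of-mask pixels
  are excluded per window. Degenerate inputs are capped (zero residual
  variance) or flagged (non-positive part maximum) rather than erroring.
  Because the real/imaginary split is gauge dependent, PSNR is computed on
  gauge-fixed loadings.
- **Circular variance** is amplitude-weighted by default
  ($1 - |\sum_p \rho_p e^{i\theta_p}| / \sum_p \rho_p$): low-amplitude
  pixels carry unreliable phase. An unweighted variant is available.
- **Spectra**: Hann-windowed periodograms normalized to unit trapezoid
  area; band-power maps default to six logarithmically spaced bands
  partitioning 0.1–14.5 Hz (the band edges are a display convention, not
  printed anywhere authoritative, and are configurable).

## FC decomposition and statistics

Wave correlation matrices $C_{\Phi_k}$ are Pearson correlations of the
single-component reconstructions; for long proper scores they equal
$\cos(\theta_j - \theta_k)$ — this is how anti-phase (π-offset) regions
generate *negative* connections, and the identity is asserted within 0.05
on 3000-frame fixtures. Pixels with numerically zero amplitude have an
identically zero reconstruction; their rows are `NA` and flagged.

The superposition $\sum_{t \le k} s_t C_{\Phi_t}$ uses the variance
fractions as weights with unit-diagonal renormalization. Note that
correlation matrices discard amplitude: the superposition is exactly
complete only when the wave amplitude maps are flat, because the true FC
weighs each wave by $\rho_t(j)\rho_t(k)$ per entry while the scalar
weighting cannot. The completeness check therefore uses flat-amplitude
waves (similarity > 0.99 at full rank); on blob-shaped waves the
similarity saturates below 1, which is a property of the superposition
definition, not an implementation error.

Seed selection clusters FC rows by k-means; the number of clusters is
chosen automatically by mean silhouette width over `k_range` (default
2–25) — the field practice of manual selection is replaced by an
automated criterion, with the manual override available by passing a
single-value `k_range`. Group tests Fisher-z transform the upper-triangle
edges (clipping |r| at $1 - 10^{-7}$), use one-sample t-tests within a
group or Welch t-tests between groups, and control FDR by
Benjamini–Hochberg at 0.05; zero-variance edges yield flagged infinite
statistics rather than errors. Hemispheric difference maps use the
homolateral-minus-contralateral sign convention with the midline supplied
as a mask column (no atlas logic).

Wave matching across conditions uses the mean squared error between
$C_{\Phi}$ matrices over the strict upper triangle (the full-matrix and
upper-triangle versions differ by a constant factor and never change a
ranking), with per-query argmin assignment; collisions are flagged and a
minimum-total-MSE one-to-one variant is available (exhaustive up to 8
components, greedy beyond). MSE is gauge invariant since $C_\Phi$ depends
only on phase differences. Grids are assumed pre-aligned; no resampling.

Gene correlations compare a wave's *intensity* map $\rho$ (the displayed
quantity) against expression maps by Pearson correlation over the mask; a
signed variant $\mathrm{Re}(\rho e^{i\theta})$ can be passed where phase
should matter. Classification uses $|r|$ with inclusive thresholds at 0.3
(correlated) and 0.75 (highly correlated).

## The synthetic generator: what it emulates, what it does not

`simulate_movie()` builds
$\text{eff}(p) \sum_k c_k \rho_k(p)\,\mathrm{Re}(w_k(t) e^{-i\theta_k(p)})
+ \varepsilon$: independent narrowband source waveforms (stochastically
driven second-order oscillators — an AR(2) whose autocorrelation is
exactly the damped-oscillator model being fitted), per-pixel phase
rotation of the analytic waveform (the same narrowband lag model the
decomposition assumes), an expression-efficiency map, and additive white
Gaussian noise. Scales $c_k$ are set so wave $k$ carries its specified
share of the average pixel variance; shares sum to ≤ 1 with the remainder
assigned to noise. All randomness flows from explicit seeds; identical
truths give bit-identical movies.

The reference conditions are a 40×40 grid, 3000 frames at 30 Hz: a global
standing wave at a 35% variance share, a two-lobe π-offset traveling wave
at 25%, a linear-gradient traveling wave at 20%, and 20% noise, with
natural frequencies 0.3 / 0.7 / 1.5 Hz and damping ratio 0.05 (Q = 10) —
values chosen once as representative of the low-frequency, high-Q regime
of slow cortical calcium dynamics, with bands separated enough that the
sources are spectrally distinct. The three geometry classes mirror the
canonical wave types: global zero-lag, anti-phase two-lobe (the
negative-connection generator), and a directional sweep.

Two deliberate design points:

- **Identifiability of the validation fixture.** The three complex maps
  are Gram–Schmidt orthogonalized (second against first, third against
  both). This barely changes their appearance but places the fixture in
  the regime where an orthogonal decomposition *can* recover the truth;
  without it, recovery scores bound the mixture's overlap, not the
  implementation's correctness. Blob widths were likewise chosen so that
  the variance fractions remain separated *after* per-pixel z-scoring —
  z-scoring redistributes variance across space, and near-degenerate
  eigenvalues mix components regardless of implementation.
- **Efficiency invariance is approximate.** Noise is added after the
  efficiency scaling, so per-pixel SNR varies with expression efficiency
  and z-scoring cannot cancel it exactly. At a realistic ~2× expression
  contrast the loadings agree to ≥ 0.99 across different efficiency maps;
  the agreement degrades gracefully as the contrast grows. (If the noise
  scaled with brightness — shot-noise-like — the invariance would be
  exact.)

What the generator does **not** emulate: indicator kinetics and
nonlinearity, photobleaching, hemodynamic contamination, vascular
artifacts, motion, spatially correlated noise, and 1/f background. Passing
the synthetic tests therefore establishes that the chain correctly inverts
its own forward model at realistic SNR — not that real recordings satisfy
that model. Gene-map fixtures are synthetic random fields with exactly
controlled correlation to a reference map; they stand in for expression
atlases only in the format sense.

## Numerical conventions and degenerate inputs

- Singular values below `max(dim) * max(d) * eps` are treated as numerical
  rank loss (warning, not error). Near-equal singular values make the
  subspace split arbitrary; ordering follows LAPACK's descending values.
- Flattening is row-major over in-mask pixels; the round trip through
  `unflatten_movie()` is exact.
- Zero-variance pixels error with their grid location; constant series
  error in spectra and autocorrelation; empty masks, mismatched grids and
  infeasible bands error before any heavy computation.
- `correlation_mse` skips entries undefined in either matrix; degenerate
  (constant-map) clustering returns k = 2 with a warning.

## Problem sizes

The test suite validates on 40×40 × 3000-frame movies for the reference
recovery experiment and 8×8 to 20×20 grids (30–150 s) for the remaining
properties; the oscillator recovery experiment uses 20 waveforms of 180 s
at 30 Hz, and the FDR null uses 200 Monte-Carlo repetitions of 20
replicate 10-pixel recordings. These sizes were chosen to make the full
suite run in about a minute while keeping every statistical check in the
regime where its stated tolerance is meaningful.

## Known limitations

- CPCA cannot determine the number of waves; variance fractions, PSNR and
  circular variance assist screening but the cut is the analyst's.
- The scalar-weighted FC superposition is exact only for flat-amplitude
  waves (above); treat per-wave FC matrices, not the superposition, as
  the quantitative decomposition.
- The narrowband phase-lag model blurs for broadband or strongly damped
  waves (ξ approaching 1).
- k-means on FC rows uses Euclidean distance, which conflates pattern and
  strength differences; the silhouette-chosen k inherits this.
- Cross-condition matching assumes pre-aligned grids and is sensitive to
  phase noise in regions where no wave has amplitude support (the MSE is
  computed on amplitude-free correlation matrices).
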