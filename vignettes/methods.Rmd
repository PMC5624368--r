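---
title: "Methods: models, conventions and design choices in colorgamut"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in colorgamut}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colorgamut)
```

# The model

## Homomorphic pipeline

The package treats channel intensities in the open unit interval as sigmoid
images of unbounded physical quantities. The forward map is
$\Omega(x) = (1+\tanh x)/2$ and its inverse $\Omega^{-1}(y) =
\operatorname{atanh}(2y-1)$. Two modelling facts motivate this:
multiplicative physical parameters with no preferred scale (the
absorption-to-scattering ratio $K/S$ of Kubelka–Munk reflectance theory is
the canonical example, implemented in `km_reflectance()`/`km_xi()`) are
naturally represented on a logarithmic axis, where scale-free priors are
uniform; and imaging itself maps log radiance through a sigmoid (exposure
and contrast being its location and width). Any sigmoid would serve; the
tanh pair is fixed because it is fast, exactly self-inverse, and its
particular shape is immaterial to the covariance structure the package
studies — a point made quantitative by `distortion_experiment()`.
Consequences of the choice that matter downstream: a normal distribution in
the physical domain pushes forward to unimodal-skewed or bimodal
reflectance histograms depending on its width (`km_histogram()`), matching
the shapes seen in empirical reflectance data.

In the physical domain, triples $(\rho,\chi,\beta)$ are rotated to opponent
coordinates by the fixed matrix `opponent_T()`: the channel mean $\Lambda$,
the half-difference $\Theta=(\rho-\beta)/2$ of the outer bands, and the
second difference $\Xi=(-\rho+2\chi-\beta)/4$. These are the discrete
zeroth, first and second wavelength-derivatives of a three-point spectrum,
which is why they diagonalize covariances whose entries fall off with
spectral separation. `opponent_T_inv()` is the exact matrix inverse of
`opponent_T()` (the transform is not orthogonal, so the inverse is not the
transpose — a fact with consequences discussed under the alien preset).

## Band covariance, eigenstructure and Z

For three spectral bins of a translation-invariant articulation process the
correlation matrix is modelled as unit diagonal with off-diagonals
$1-\varepsilon_i$, $\varepsilon$ increasing with spectral separation
(`model_covariance()`). In the symmetric case
$(\varepsilon, 2\varepsilon, \varepsilon)$, $(1,0,-1)/\sqrt2$ is an exact
eigenvector with eigenvalue exactly $2\varepsilon$; the other two
eigenvectors mix the achromatic direction and $(-1,2,-1)/\sqrt6$ at order
$\varepsilon$. As $\varepsilon \to 0$ the eigenvalues approach the ratios
$1 : 2\varepsilon/3 : 2\varepsilon/9$, so $\lambda_2/\lambda_3 \to 3$ and
the dominance statistic $Z = \lambda_1/(\lambda_2+\lambda_3)$ approaches
$9/(8\varepsilon)$. `model_eigen()` exposes the exact numeric
decomposition; the tests assert the exact eigenpair to $10^{-12}$
*absolute* (the identity is algebraic; at $\varepsilon=10^{-6}$ a relative
bound would demand more of LAPACK than double precision provides).

`summarize_triples()` computes unbiased covariance, descending eigenpairs,
and Z for any sample of triples. By default the package computes Z from
physical-domain triples: the physical domain is where the marginals are
near-normal and where the band model lives; raw-RGB covariance is exposed
through the same function for comparison (the command-line `analyze` has a
`--domain` flag). Quoted covariance matrices are conventionally normalized
to a largest entry of 100 (RGB and physical domains) or 1000 (opponent
domain), recorded in `cov_normalized`/`normalize_to`.

Eigendirections are axes, defined only up to sign. Two conventions are
fixed: eigenvector columns are flipped so their largest-magnitude component
is positive, and `stereographic_frame()` — which projects the
eigendirections from the antipode of the white point $(1,1,1)/\sqrt3$ onto
the equatorial plane, pole to the origin, equator to the unit circle —
flips polar-ish directions (|dot with pole| > 0.5) into the pole-facing
hemisphere and near-equatorial ones to lexicographically non-negative
coordinates along the reference axes $(1,0,-1)/\sqrt2$ and
$(-1,2,-1)/\sqrt6$, with a $10^{-9}$ numerical-zero band on the first
coordinate. Either member of an antipodal pair represents the same axis;
the convention only makes plots and tests deterministic.

## Colorimetry: the parts-of-daylight basis

The object colors of an illuminant — tristimulus values of all its 0–1
spectral attenuations — form a zonotope generated by the per-interval
tristimulus increments of the illuminant (`color_solid_generators()`), and
`zonotope_volume()` evaluates the standard $\sum_{i<j<k}|\det|$ formula.
Splitting the spectrum at two cut wavelengths gives three band tristimulus
vectors (`band_tristimulus()`); `optimize_cuts()` searches for the pair of
cuts maximizing the volume of the spanned parallelepiped, equivalently its
fraction of the color-solid volume, since volume ratios are invariant under
any nonsingular linear recoding of color space (`volume_fraction()`, and a
100-recoding invariance test).

Numerical conventions, chosen for exactness and bit-reproducibility:

* Integration is trapezoidal on the working grid; a cut falling between
  grid points splits the straddling interval linearly, which is exact for
  the piecewise-linear integrand and resolves cut positions well below the
  grid step. The three band vectors therefore sum to the full-range
  tristimulus to machine precision, always.
* The coarse search is exhaustive over all cut pairs on a configurable
  grid (default 1 nm); ties — possible only in degenerate synthetic
  cases — keep the lexicographically smallest pair. Refinement is
  deterministic coordinate-wise golden-section iterated to 0.01 nm. No
  stochastic optimizer is involved; re-runs are bit-identical.
* The vendored CIE tables (illuminant D65, normalized to 100 at 560 nm,
  and the CIE 1964 10° observer) are classic 10-nm tabulations stored as
  plain CSV. `load_spectral_table()` resamples them to the working grid
  (default 380–700 nm at 1 nm). The default interpolation is a cubic FMM
  spline clamped at zero: with 10-nm tables, linear interpolation biases
  the low cut by about 0.4 nm, while the spline reproduces the known cut
  loci for daylight (482.65, 565.43 nm) to a few hundredths of a
  nanometre. Linear interpolation remains available for finely tabulated
  inputs, where the distinction is immaterial.
* The zonotope volume is cubic in the number of generators; on a 1-nm grid
  (320 generators, ~5.4M determinants) it is computed directly, and a
  `coarsen` stride that merges consecutive generators is available (and
  off by default) for repeated evaluation. Coarsening changes the solid's
  volume only at the scale of the merged wiggles; the volume *fraction*
  shifts in the third decimal at stride 5.

The matching functions re-expressed in the optimal basis
(`rgb_matching_functions()`) integrate to the identity over the three bands
by construction, and are predominantly non-negative: on the vendored
tables, their negative lobes carry a measured 11.3% of the total absolute
area — recorded as a regression value in the tests, not a tuned target.

## The gamut generator and its presets

`sample_gamut()` draws independent normal deviates
$(\lambda,\theta,\xi) \sim N(\mu_i,\sigma_i)$, applies the inverse opponent
rotation and squashes through $\Omega$. Six parameters — the gamut
signature — thus parameterize a gamut; `gamut_signature()` estimates them
back from any RGB field, and the pair is consistent: for continuous fields
the estimator recovers generator parameters within normal-theory standard
errors (see the clamp note below).

`sublunar_preset()` fixes $(\sigma_\Lambda,\sigma_\Theta,\sigma_\Xi) =
(1.07, 0.47, 0.13)$, the median spreads reported across natural-image
corpora, with zero locations (automatic cameras white-balance the locations
away). An analytic consequence worth recording: with independent opponent
deviates the physical-domain correlation between the outer channels is
$(\sigma_\Lambda^2-\sigma_\Theta^2+\tfrac49\sigma_\Xi^2) /
(\sigma_\Lambda^2+\sigma_\Theta^2+\tfrac49\sigma_\Xi^2)$, which is 0.68 for
these medians. Single homogeneous images are typically much more
concentrated (opponent variance ratios of order 1000:39:4, implying outer
correlation ≈ 0.93), so corpus-median and single-image gamuts are
deliberately different regimes; the tests assert the analytic values for
the preset rather than a nominal "high correlation" figure.

`alien_preset()` targets the opposite of the terrestrial pattern: flat RGB
histograms and a covariance proportional to the identity. Because the
inverse opponent transform is not orthogonal, *equal* opponent widths do
not achieve this — they leave an 18% red–blue physical correlation and
channel widths 1.6 times the opponent width. Requiring the physical
channels to be exactly independent with equal variance forces the width
ratios $(1, \sqrt{3/2}, 3/(2\sqrt2))$, and matching the common channel
variance to the logistic distribution of scale $\tfrac12$ (variance
$\pi^2/12$) that underlies $\Omega$ fixes the scale:
$(\sigma_\Lambda,\sigma_\Theta,\sigma_\Xi) = (\pi/6, \pi\sqrt6/12,
\pi\sqrt2/8) \approx (0.524, 0.641, 0.555)$. The channels are then
independent by construction (not merely uncorrelated), and the
variance-matched normal-through-logistic-CDF push-forward is flat to a
max/min 10-bin ratio of about 1.3.

## Distortion robustness

`distortion_experiment()` operationalizes the question "does uncalibrated
display processing destroy the covariance structure?". True RGB values are
$\Omega$-images of Gaussian physical triples with a given covariance
(default input in the acceptance script: the physical-domain covariance of
a typical terrestrial image, quoted normalized to 100 and rescaled to unit
peak variance, zero means). Each distortion draw applies independent
per-channel gain $A$ and exponent $\gamma$, $v \mapsto (Av)^\gamma$,
both uniform on (0.5, 1.5) by default — a wide band for realistic
"corrections" — followed by the same clamp used at ingestion. The statistic
is the per-channel Pearson correlation between distorted and true values,
pooled over channels (three correlations per draw), summarized by median
and quartiles. Pooling the correlations rather than concatenating the
channel values is deliberate: concatenation mixes the three channels'
different distortion-induced offsets into one scatter and measures mostly
those offsets (median ≈ 0.92 in that variant), not the within-channel
association the question is about. Any purely monotone distortion leaves
rank correlations at exactly 1; the Pearson median quantifies how little
the *linear* structure suffers.

## The toy spectral model

`sample_spectra()` realizes random reflectance spectra as
$\Omega(\text{shift} + \text{scale}\cdot g(\lambda))$ where $g$ is a
stationary, standardized Gaussian articulation process with Lorentzian
power spectrum $S(f) \propto 1/(f^2+f_c^2)$, $f_c = 1/(2\pi\tau)$, $\tau$
the correlation length in units of the visible-range width. Synthesis is
spectral: random phases under the amplitude filter on a periodic domain
eight times the visible window (so the window is a proper excerpt of a
stationary process rather than one forced period — synthesizing on the bare
window anticorrelates the bands through the zero-mean constraint), inverse
FFT, crop, and division by the theoretical standard deviation (per-spectrum
empirical standardization would distort the marginals). The grid is 96
wavelength samples (divisible by 3; fine enough to resolve $\tau$ a third
of the window, cheap enough for $10^4$-spectrum ensembles), and
`bin_rgb()` averages equal thirds — unweighted, since these spectra are
articulation envelopes with no illuminant attached. With $\tau$ equal to
the bin width the binned ensemble reproduces the band covariance pattern
($\varepsilon_1 \approx \varepsilon_3 < \varepsilon_2$, achromatic
dominance, opponent-aligned minor eigenvectors), which is the model-level
account of why the pattern is universal in terrestrial images.

### The telegraph-wave limit

At large amplitude the spectra degenerate to two-state, telegraph-wave-like
profiles, and their binned colors concentrate on six edges of the RGB cube
— the boundary colors produced by a single spectral light–dark transition
(black–red, red–yellow, yellow–white, white–cyan, cyan–blue, blue–black;
Goethe's edge colors), never the six green/magenta edges, which no
single-transition spectrum can reach. `telegraph_limit_check()` simulates
this limit directly as a two-state Markov process with Poisson switching at
rate $1/(2\tau)$, which has exactly the model's Lorentzian $1/f^2$ power
spectrum. It does *not* simply binarize the Gaussian process: a Gaussian
process with an $f^{-2}$ spectrum has a white-noise derivative, so its
zero crossings cluster in bursts at all resolved scales, and the binarized
process never cleanly degenerates to single transitions (the near-edge
fraction saturates around two thirds for any amplitude and correlation
length). The two processes share second-order statistics and differ in
phase statistics — precisely the distinction the telegraph limit is about.
The default demonstration uses $\tau = 1$ (correlation length equal to the
visible window): the expected number of transitions per window is then
$1/2$, so the fraction of spectra with at most one transition is
$e^{-1/2}(1 + 1/2) \approx 0.91$ a priori, and samples concentrate on the
Goethe edges while the green/magenta edges stay essentially empty. At
$\tau$ equal to the bin width (1.5 expected transitions) the Goethe edges
still dominate but only about two thirds of samples lie within tolerance
of an edge; the edge-color claim is a statement about the long-correlation
limit, not about every parameter setting.

# Ingestion conventions and the clamp

8-bit levels map to $(v+0.5)/256$ (16-bit analogously), so stored 0 and 255
become $1/512$ and $511/512$ and the endpoints of the unit interval —
which $\Omega^{-1}$ sends to infinity — can never occur in ingested
images. Synthetic or distorted data are clamped to
$[\delta, 1-\delta]$, $\delta = 1/512$, half an 8-bit quantization step.
One subtlety is documented rather than hidden: applied to *continuous*
generator output, the $1/512$ clamp truncates physical-domain Gaussian
tails beyond $\operatorname{atanh}(1 - 1/256) \approx 3.12$ and thereby
biases recovered spreads low by up to about 1% at terrestrial parameter
settings — several standard errors at $n = 10^5$. For continuous fields
the clamp has no protective role beyond excluding exact endpoints, so
parameter-recovery tests pass $\delta = 10^{-9}$; every image-based path
keeps $\delta = 1/512$. No color management or EXIF gamma handling is
applied anywhere: the package's own distortion analysis is the argument
that monotone transforms leave the structure of interest intact.

# What the synthetic fixtures do and do not emulate

`make_fixture()` writes PNG corpora with known statistics: per-image gamut
samples (optionally a two-region layout stacking a "sky" band with its own
signature over a "ground" band, mirroring the top/bottom row splits used
for landscape corpora), optional Gaussian blur applied in the physical
domain before squashing (preserving the marginal families approximately),
8-bit quantization, and a JSON manifest from which the images regenerate
bit-identically. The fixtures reproduce what the analysis pipeline
measures: marginal signatures, channel covariance, region contrasts.

They deliberately do not reproduce: spatial structure beyond optional
isotropic blur (no textures, edges, or scale hierarchy), heavy-tailed or
bimodal opponent distributions (generator marginals are exactly normal in
the physical domain, whereas small real samples often show heavy tails in
$\Theta$, $\Xi$), JPEG artifacts, chromatic aberration, or saturated /
underexposed pixel masses. Tests passing on fixtures therefore validate
the estimator–generator loop and the pipeline's conventions, not claims
about any external image corpus; analyses of real corpora remain the
user's empirical work.

# Problem sizes and determinism

Every stochastic operation takes a seed and restores the caller's RNG
state; fixed seeds make ensembles bit-reproducible. The test suite uses
$10^5$–$10^6$ samples where normal-theory error bounds are asserted,
$10^4$ spectra for ensemble structure, 1000 distortion draws of $10^4$
samples for the robustness experiment, and 5-nm grids for repeated
zonotope evaluations (the 1-nm volume is asserted once); these sizes put
Monte-Carlo error comfortably below every asserted tolerance while keeping
the suite around half a minute. The zonotope implementation is checked
against frozen convex-hull volumes of brute-force Minkowski sums computed
once with an independent implementation for generator sets of size 4–10.

# Known limitations

* The psi regression (`psi_regression()`) reports both the log-log fit
  ($\Psi = e^{\text{intercept}}$, `power` the slope) and the
  through-origin linear slope (`psi_linear`), because the two
  parametrizations of "the proportionality constant between opponent
  spreads" coincide only at power exactly 1. With fewer than ~10
  signatures, neither is well determined.
* The cut optimization assumes a single illuminant table; observers other
  than those supplied as tables, full chromaticity machinery, and
  color-appearance models are out of scope.
* The Kubelka–Munk pair covers the infinitely thick layer only; finite
  thickness and backing are out of scope.
* The spectral model is intentionally minimal: Lorentzian articulation
  spectrum, logistic squashing, equal-thirds binning; its constants
  (96-point grid, 8× synthesis padding, $f_c = 1/(2\pi\tau)$) are package
  choices, stated here and in the code, not fits to hyperspectral data.
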