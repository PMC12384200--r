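---
title: "Models and methods behind speckleflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind speckleflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speckleflow)
```

# The measurement this package models

Diffuse speckle contrast analysis (DSCA, also called SCOS or SVS) infers
deep-tissue blood flow from the *spatial statistics* of laser speckle. A
long-coherence laser is coupled into tissue through a source fiber; a
detection fiber at separation $\rho$ on the surface relays the diffusely
scattered light onto a camera. Moving red blood cells decorrelate the
field, and a camera exposure of duration $T$ integrates over that
decorrelation, blurring the speckle: the faster the flow, the lower the
spatial contrast

$$\kappa^2(\rho, T) = \frac{\sigma_I^2(\rho, T)}{\langle I(\rho, T)\rangle^2},$$

computed across an ensemble of pixels within one frame. `speckleflow`
implements the full computational chain around this statistic for a
photon-counting SPAD array with $128 \times 128$ macropixels: a forward
model mapping tissue optics and flow to $\kappa^2$, a timing model of the
photon-counting acquisition, a synthetic frame generator with known ground
truth, the noise-corrected contrast-to-flow pipeline, and the downstream
time-series analyses.

# Forward model

## Field autocorrelation

For a point source on a semi-infinite homogeneous medium with absorption
$\mu_a$, reduced scattering $\mu_s'$ and Brownian scatterer dynamics
$\langle \Delta r^2(\tau)\rangle = 6 \alpha D_b \tau$, the unnormalized
field autocorrelation is the extrapolated-boundary Green's function

$$G_1(\rho, \tau) \propto \frac{e^{-K(\tau) r_1}}{r_1} -
  \frac{e^{-K(\tau) r_b}}{r_b}, \qquad
  K(\tau) = \sqrt{3\mu_a\mu_s' + 6\mu_s'^2 k_0^2\, \alpha D_b\, \tau},$$

with $k_0 = 2\pi n/\lambda$, the effective source at depth $z_0 = 1/\mu_s'$,
its negative image at height $z_0 + 2z_b$, and
$r_1, r_b$ the corresponding distances to the detector.
`g1_semi_infinite()` returns $g_1 = G_1(\rho,\tau)/G_1(\rho,0)$, which is 1
at zero lag by construction and decays monotonically.

The extrapolated-boundary distance is
$z_b = \tfrac{2}{3}(1+R_\mathrm{eff})/((1-R_\mathrm{eff})\mu_s')$.
For $R_\mathrm{eff}$ we evaluate the flux-weighted hemispherical average of
the unpolarized internal Fresnel reflectance numerically
(`effective_reflection()`), which is exactly zero for a matched boundary
and agrees with the cubic polynomial fit in $n$ familiar from the
diffuse-optics literature to about $5\times10^{-4}$ over physiological
indices; the polynomial is provided as an alternative method. Shear-induced
diffusion variants of the mean-square displacement are out of scope: the
Brownian model is the one the contrast-to-flow mapping assumes.

## Exposure-integrated contrast

Contrast accumulates over the exposure via

$$\kappa^2(\rho, T) = \frac{2\beta}{T}\int_0^T
  \left(1 - \frac{\tau}{T}\right) g_1(\rho, \tau)^2\, d\tau,$$

where $\beta \in (0, 1]$ is the coherence factor of the collection optics
(speckle-to-pixel sampling, polarization); it bounds $\kappa^2$ from above
and is the value $\kappa^2$ attains as $T \to 0$ or for a static medium.
Squaring $g_1$ inside the integral is the Siegert relation for the
intensity correlation; no separate intensity-correlation machinery is
kept. For simulation studies $\beta$ defaults to 1 (ideal collection);
measured systems typically sit below 0.5, and every function takes
$\beta$ explicitly.

Numerically, the integral is evaluated with adaptive quadrature at a
relative tolerance of $10^{-8}$ (`contrast_integral()`). When flow is fast
or the exposure long, $g_1$ collapses at lags orders of magnitude below
$T$ and the integrand is stiff; the lag at which $g_1^2$ drops below
$10^{-12}$ is located by bisection and the interval is split there, so the
quadrature resolves both the decaying head and the flat tail. The same
routine accepts any decorrelation kernel, which is how the test suite
checks it: for $g_1 = e^{-\tau/\tau_c}$ the integral has the closed form
$\beta\,(e^{-2x} - 1 + 2x)/(2x^2)$ with $x = T/\tau_c$, and the quadrature
matches it to better than $10^{-9}$ across $x \in \{0.01, 1, 100\}$.

One analytic point is worth recording: the contrast deficit
$\beta - \kappa^2$ vanishes only *linearly* in $T$ (the integrand's
departure from 1 is first-order in $\tau$), so at $T = 1$ ns with typical
tissue parameters at $\rho = 20$ mm the deficit is still about
$2\times10^{-5}$. Tests of the short-exposure limit assert this linear
approach rather than an arbitrarily tight agreement at a fixed small $T$.

The blood-flow surrogate rests on the near-linearity of $1/\kappa^2$ in
$\alpha D_b$: `contrast_vs_flow_curve()` sweeps the flow index and
`fit_flow_linearity()` quantifies the relationship (the default
two-decade sweep at $T = 2$ ms, $\rho = 20$ mm yields $R^2 > 0.9999$).

# Acquisition timing

In photon-counting mode the camera exposes for
`tint_tbin_iterations × tbin_clk_periods / clock_frequency` seconds (the
accumulation registers), then reads the array out in a fixed
`readout_time`; the frame rate is the reciprocal of their sum. The readout
time is a stored constant (default 1.1264 ms at a 20 MHz clock) rather
than a quantity derived from row-level timing, which the register map does
not expose. `timing_table()` reproduces the instrument's published
operating points, from 849.2 fps at 32 iterations (51.2 µs exposure) down
to 9.4 fps at the 16-bit register ceiling of 65,535. Displayed frame rates
round half-up to one decimal, matching how they are quoted.

# Synthetic frames: what is emulated, and what is not

`generate_speckle_frames()` is the package's digital twin of the
acquisition. Fully developed speckle integrated over an exposure has
gamma-distributed intensity with shape $M = 1/\kappa^2$ (the effective
number of speckle modes averaged by a pixel during $T$); photon detection
is Poisson given that intensity. Each pixel of each frame therefore draws

$$I \sim \mathrm{Gamma}(M, \text{mean} = \bar n), \qquad
  c \sim \mathrm{Poisson}(I),$$

so by the law of total variance
$\mathrm{Var}(c) = \bar n + \bar n^2/M$: the ensemble statistic
$(\widehat{\mathrm{Var}} - \hat{\bar n})/\hat{\bar n}^2$ has expectation
$\kappa^2$, which makes shot noise and speckle contrast separable exactly
as the correction pipeline assumes, with $\kappa^2$ known by construction.
Dark counts are Poisson with a per-pixel rate map in which a configurable
minority of "hot" pixels (default 1% at 50× the base rate) stand out; the
hot placement is pinned by the dark model's own seed because hotness is a
property of the detector, so calibration stacks and measurement stacks
generated from the same model share the same hot pixels — exactly the
situation the 3σ screening stage faces on real hardware.

Deliberate simplifications, which bound what passing tests demonstrate:

* **Pixels are statistically independent.** The processing chain computes
  one ensemble contrast over the whole array, so inter-pixel speckle
  correlation is not needed to exercise any stage; spatially correlated
  speckle grains, fiber-speckle structure and polarization effects are not
  reproduced.
* **Each frame is an independent speckle realisation** (frame spacing
  assumed much longer than the decorrelation time). Frame-to-frame
  correlation at extreme frame rates is not modelled.
* **No read noise, quantization, or dead-time pile-up.** Photon-counting
  SPAD output is digital, so the first two are genuinely absent; dead-time
  nonlinearity at extreme count rates is a real effect we do not model.

Passing recovery tests therefore show the estimator chain is correct under
the stated statistical model of the detector — not that the generator is
distributionally faithful to any particular instrument's raw data.

`generate_scenario_stack()` drives the generator with a time-varying flow
profile, converting $\alpha D_b(t)$ to $\kappa^2(t)$ through the forward
model frame by frame and emitting the ground-truth series alongside the
stack. Two protocols are built in: an arterial cuff occlusion (3.5 s
baseline, 7 s occlusion at 10% of baseline flow, 4 s recovery with a 3×
hyperemic overshoot decaying with a 2 s time constant) and a
cognitive-task block (8 s rest, 30 s task at +8% flow, 10 s recovery).
The occlusion timeline follows the standard cuff protocol for wrist
measurements; the overshoot factor and decay are a plausible reactive
hyperemia, chosen once for the simulations, not fitted to any subject.

# The processing pipeline

Raw frames are corrected in the order a real acquisition requires:

1. **Dark statistics** (`estimate_dark_statistics()`): per-pixel temporal
   mean and unbiased variance over a laser-off stack (1000 frames is the
   conventional calibration length; tests use 200 to stay desk-scale).
2. **Bad-pixel screening** (`flag_bad_pixels()`): pixels deviating more
   than 3 standard deviations from the mean of a reference image are
   excluded from every downstream statistic. The default reference is the
   *dark mean map*, since hot pixels are defined by their dark counts; the
   same function applied to an intensity frame gives the literal
   frame-data variant. The rule is applied once, not iterated — iterative
   sigma-clipping would change the flagged count.
3. **Noise-corrected contrast** (`corrected_contrast_sq()`): with
   $I_c = I - \bar I_D$ per pixel over valid pixels,
   $$\kappa_m^2 = \frac{\mathrm{Var}(I_c)}{\langle I_c\rangle^2},\qquad
     \kappa_c^2 = \frac{\mathrm{Var}(I_c) - \bar\sigma_D^2 -
     \langle I_c\rangle}{\langle I_c\rangle^2},$$
   i.e. dark variance and Poisson shot variance (equal to the mean, in
   count units — a photon-counting array has unit gain) are subtracted;
   read-noise and quantization terms are identically zero. The ensemble is
   the full valid array, not a local window. Sample (not population)
   variance is used; at $128^2$ pixels the distinction is negligible. The
   dark variance is the per-pixel variance map averaged over valid pixels.
   A negative $\kappa_c^2$ (over-subtraction at low signal) is kept in the
   series for diagnostics but maps to a missing BFi rather than a negative
   flow.
4. **Flow index**: $\mathrm{BFi} = 1/\kappa_c^2$, relative flow
   $\mathrm{rBFi} = \mathrm{BFi}/\overline{\mathrm{BFi}}_\mathrm{baseline}$
   (`normalize_bfi()`, baseline mean exactly 1 by construction), and a
   centered 20-sample moving average (`smooth_series()`; windows shrink at
   the edges, missing values are excluded per window).

The decomposition $\kappa_m^2 - \kappa_c^2 = 1/\langle I_c\rangle +
\bar\sigma_D^2/\langle I_c\rangle^2$ holds exactly on every frame and is
asserted as an identity in the tests.

# Downstream analyses

**Welch PSD** (`welch_psd()`): overlapping segments (default 256 samples,
50% overlap), per-segment mean removal, a periodic Hann taper, averaged
periodograms scaled as a one-sided density so the PSD integrates to the
series variance. No installed R package provides the averaged-periodogram
estimator, so it is implemented here directly on `stats::fft()`; the
variance-integral identity and tone-location tests pin its calibration.

**SNR**: `snr_db()` computes $20\log_{10}(S/N)$; for flow traces the
operational reading `series_snr_db()` takes $S$ = mean and $N$ = standard
deviation over a stationary segment. The raw-count reading (signal vs
dark counts) is available by passing those estimates directly. Published
SNR figures for in vivo recordings are not reproduced — they depend on
instrument data this package does not model.

**Envelope trend** (`envelope_trend()`): local maxima/minima separated by
at least `window` samples (larger extremum wins inside a conflict),
spline-interpolated, endpoints pinned to the series values to avoid
extrapolation blow-up; the trend is the envelope midline. The default
window of 250 samples corresponds to ~0.7 s at the 361.7 fps operating
point; simulations sampled at 50 fps use a 35-sample window to cover the
same data span. **Percent change** (`percent_change()`) references the
trend to its mean over an initial baseline window (default 8 s).

# Problem sizes and reproducibility

All stochastic results in the tests and the acceptance script run at
desk scale, chosen once: full $128\times128$ arrays with 200-frame stacks
for estimator recovery, 200-frame dark calibrations, and scenario stacks
sampled at 50 fps (725 frames for the occlusion protocol, 2400 for the
task protocol) with 50 mean photons per pixel — between the count levels
reported at moderate and large fiber separations on real systems. Every
generator takes an explicit integer seed and identical seeds give
byte-identical stacks; `run_pipeline()` threads one seed through the whole
simulate–process–analyze chain and stamps outputs with the configuration,
seed and package version.

# Known limitations

* The forward model is homogeneous semi-infinite; layered media, pulsatile
  flow waveforms and time-gated (pathlength-resolved) contrast are not
  modelled.
* BFi is a flow *index*: no absolute calibration to volumetric perfusion
  is attempted.
* The generator's independence assumptions (pixels, frames) mean spatially
  or temporally correlated artifacts — motion, fiber speckle drift —
  cannot be studied with it.
* $\kappa_r^2$ and $\kappa_q^2$ estimation for analog cameras is out of
  scope; the pipeline targets photon-counting detectors where both vanish.
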