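# speckleflow

Diffuse speckle contrast analysis (DSCA/SCOS) turns the *spatial
statistics* of diffusely scattered laser speckle into a deep-tissue blood
flow measurement: a camera exposure of duration *T* integrates over the
speckle decorrelation caused by moving red blood cells, so the squared
spatial contrast across a pixel ensemble,

κ²(ρ, T) = σ²_I / ⟨I⟩²,

falls as flow rises. `speckleflow` is for researchers building or
validating fiber-based DSCA systems on photon-counting SPAD cameras. It
provides, as a single tested chain:

- **Forward model** — the semi-infinite correlation-diffusion field
  autocorrelation g₁(ρ, τ) with Brownian dynamics ⟨Δr²⟩ = 6αD_b·τ and the
  exposure-integrated contrast
  κ²(ρ, T) = (2β/T) ∫₀ᵀ (1 − τ/T) g₁(ρ, τ)² dτ,
  evaluated by adaptive quadrature (relative tolerance 1e-8).
- **Acquisition timing** — the photon-counting-mode register model:
  exposure = iterations × clock-periods-per-bin / clock, frame rate =
  1 / (exposure + readout).
- **Synthetic frames** — gamma–Poisson speckle stacks (latent intensity
  gamma with shape M = 1/κ², Poisson photon detection) with per-pixel dark
  counts and a plantable hot-pixel population, plus cuff-occlusion and
  cognitive-task flow scenarios with exact ground truth.
- **Processing pipeline** — dark subtraction, 3σ bad-pixel screening,
  noise-corrected ensemble contrast
  κ_c² = (Var(I_c) − σ_D² − ⟨I_c⟩) / ⟨I_c⟩²,
  blood flow index BFi = 1/κ_c², baseline-relative rBFi, moving-average
  smoothing.
- **Signal analysis** — Welch power spectral density, SNR in dB,
  peak-envelope trends and baseline-relative percent change.

Everything is tibble-in/tibble-out and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and result tables have `autoplot()` methods.

## Worked example

Forward model at typical tissue optics (λ = 785 nm, μ_a = 0.01 mm⁻¹,
μ_s′ = 1 mm⁻¹, n = 1.33), ρ = 20 mm, αD_b = 1e-6 mm²/s, T = 2 ms:

```r
library(speckleflow)

op   <- optical_properties(mua = 0.01, musp = 1, n = 1.33, wavelength_nm = 785)
geom <- semi_infinite_geometry(rho = 20, op)
geom
#> <semi_infinite_geometry> rho = 20 mm, z0 = 1, zb = 1.85834, r1 = 20.025,
#>   rb = 20.5487, Reff = 0.4719

speckle_contrast_sq(op, flow_params(alpha_db = 1e-6, beta = 1), geom,
                    T_exp = 2e-3)
#> [1] 0.01817295        # kappa^2; BFi = 1/kappa^2 = 55.0
```

`Reff = 0.4719` is the effective internal reflection at the tissue–air
boundary; it sets the extrapolated-boundary distance `zb`. The κ² of
0.018 says a 2 ms exposure at this separation averages ~55 effective
speckle modes — the reciprocal is the blood flow index.

Inverse contrast is linear in the flow index (the basis of the method):

```r
curve <- contrast_vs_flow_curve(op, geom, T_exp = 2e-3, beta = 1,
                                alpha_db_grid = 10^seq(-7, -5, length.out = 25))
glance(fit_flow_linearity(curve))
#> # A tibble: 1 × 4
#>   r.squared adj.r.squared  sigma  nobs
#> 1     1.000         1.000 0.0152    25
```

Timing of the photon-counting mode at a 20 MHz clock:

```r
timing_config(tint_tbin_iterations = 1024)
#> <timing_config> clock 20 MHz, 32 periods/bin, 1024 iterations, readout 0.0011264 s
#>   exposure 0.0016384 s, frame time 0.0027648 s, 361.7 fps
```

Simulate a photon-counting stack with known contrast and recover it:

```r
st <- generate_speckle_frames(kappa_sq_target = 0.25, mean_photons = 10,
                              n_frames = 200, shape = c(128, 128), seed = 42)
series <- process_frames(st)
round(colMeans(series[, c("kappa_m_sq", "kappa_c_sq", "bfi")]), 4)
#> kappa_m_sq kappa_c_sq        bfi
#>     0.3498     0.2498      4.004
```

The measured contrast (0.350) carries the shot-noise floor 1/⟨I⟩ = 0.1 on
top of the true speckle contrast; the corrected estimate recovers the
planted 0.25 and BFi its reciprocal. A full scenario (occlusion or task
activation, dark counts and hot pixels included) runs through
`run_pipeline()` from a single seed; see the methods vignette
(`vignettes/speckleflow-methods.Rmd`) for the models and their
assumptions.

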