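# sifsvd

SVD-based retrieval of sun-induced chlorophyll fluorescence (SIF) from
ultra-high-resolution top-of-atmosphere radiance spectra.

Vegetation re-emits a small fraction of absorbed sunlight as chlorophyll
fluorescence (650–800 nm, far-red peak near 740 nm).  From space this signal
is three orders of magnitude weaker than reflected sunlight, but inside
narrow solar Fraunhofer lines the reflected radiance is suppressed while the
additive fluorescence is not, so fluorescence "fills in" the lines and
becomes separable.  `sifsvd` implements a data-driven retrieval for
carbon-observatory-class grating spectrometers sampling the O₂-A band
region at ~0.044 nm, working in a broad (~7 nm) Fraunhofer-only window
without assuming the fluorescence is spectrally constant.

## Model

A training set of non-fluorescent spectra (soil/water scenes) is decomposed
by SVD into orthonormal spectral patterns v₁, v₂, … (singular vectors).  A
measured spectrum L(λ) in the retrieval window is then fit as

    L(λ) = v₁(λ) · Σᵢ aᵢ λ̂ⁱ  +  Σⱼ₌₂ ωⱼ vⱼ(λ)  +  Fs · hF(λ),
    hF(λ) = φ · exp( −(λ − 740)² / (2σ²) ),

where the polynomial (order nP = 1 by default, λ̂ a normalized wavelength
coordinate) carries the smooth reflectance/atmosphere continuum on top of
the dominant spectral shape v₁, the remaining singular vectors carry
high-frequency non-fluorescent variability, and Fs — the coefficient of the
Gaussian far-red emission shape hF (σ = 30 nm, peak at 740 nm) — is the
retrieved fluorescence amplitude.  The fit is weighted least squares with
weights ϖ(λ) = SNR(λ)/L(λ), the reciprocal radiance uncertainty.  The number
of singular vectors nv is chosen per sounding by the Bayesian Information
Criterion,

    BIC = n_λ ln(RSS/n_λ) + k ln(n_λ),   RSS = Σ_λ (ϖ_λ (L_λ − L̃_λ))²,

with k = (nP+1) + (nv−1) + 1 fitted coefficients.  Results report Fs (the
740 nm amplitude), SIF at a reference wavelength (775 nm by default,
Fs·hF(775)), a 1σ uncertainty from the fit covariance, and per-candidate BIC
diagnostics.

A bundled simulator generates Fraunhofer-line scenes with known truth —
smooth effective reflectance, per-scene solar geometry and spectral
calibration/line-width perturbations, additive Gaussian fluorescence,
optional unmodelled O₂-like absorption and SNR-scaled noise — so the whole
pipeline is testable end to end without satellite data.  Performance against
truth is scored with R², bias and RMSE, and sensitivity sweeps over the
emission width σ, the number of singular vectors, and the spectral window
mirror the standard validation analyses.

## Worked example

```r
library(sifsvd)

wl  <- spectralGrid()                                  # 758–778 nm, 0.044 nm
sun <- solarModel()                                    # Fraunhofer-analogue solar model
training <- makeTrainingSet(wl, sun, nScenes = 400, seed = 1)
basis    <- computeSVs(training, nKeep = 8)
basis
#> SingularBasis: 8 vectors over 455 channels (758.000-777.976 nm)
#>   explained variance: 0.9837 0.01571 0.0005851 2.597e-06 4.748e-07 2.278e-07 ...

scene <- simulateScenes(1, wl, sun, fsTrue = 0.8, seed = 2)   # truth: Fs = 0.8
res <- retrieveSif(radianceValues(scene)[, 1], basis,
                   retrievalConfig(), snr = snrModel(300))
res
#> RetrievalResult: Fs = 0.8872 +/- 0.17, SIF(ref) = 0.4492, nv = 4, RSS = 145
round(res@bicByNv, 1)
#>    2    3    4    5    6    7    8
#> 48.9 30.8 15.8 20.8 20.4 24.3 29.3
```

The retrieved amplitude 0.89 ± 0.17 (radiance units at the 740 nm emission
peak) recovers the simulated truth of 0.8 within its 1σ uncertainty; the
noise-limited precision at SNR 300 in a 7 nm window is ~0.2.  `SIF(ref)` is
the same retrieval expressed at 775 nm (Fs·e^(−35²/1800) ≈ 0.51·Fs).  BIC
selected nv = 4 singular vectors for this sounding (minimum of the table);
the weighted RSS ≈ 145 over 159 channels is consistent with noise.  Batch
processing (`retrieveBatch`), sweep analyses (`sweepSigma`, `sweepNsv`,
`sweepWindow`) and comparison scoring (`comparisonStats`) build on the same
primitives, and `inst/scripts/sifsvd` exposes them as the
`simulate | train | retrieve | sweep | stats` command-line pipeline.

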