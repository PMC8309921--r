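---
title: "Retrieving sun-induced fluorescence from Fraunhofer-line spectra: model and methods"
author: "sifsvd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrieving sun-induced fluorescence from Fraunhofer-line spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sifsvd)
```

## The retrieval problem

Sun-induced chlorophyll fluorescence (SIF) adds a faint, spectrally smooth
emission (far-red peak near 740 nm) on top of reflected sunlight that is
roughly a thousand times stronger.  Narrow solar Fraunhofer lines break this
degeneracy: reflected radiance is suppressed inside the lines in proportion
to the local continuum, while the additive emission is not, so fluorescence
partially "fills in" every line.  A spectrometer with ~0.044 nm sampling
resolves this in-filling across many lines in a window such as 771–778 nm,
which contains only Fraunhofer lines and is essentially free of telluric
absorption.

For a Lambertian scene the top-of-atmosphere radiance is

$$ L(\lambda) \;=\; \frac{\rho(\lambda)}{\pi}\, I_{sc}(\lambda)\, \mu_0
   \;+\; F_s\, h_F(\lambda), $$

with $\rho$ an effective surface-plus-atmosphere reflectance, $I_{sc}$ the
solar irradiance, $\mu_0$ the cosine of the solar zenith angle, and $F_s$
the fluorescence amplitude with normalized emission shape
$h_F(\lambda) = \varphi\, e^{-(\lambda-740)^2 / 2\sigma^2}$.
Ground-to-sensor transmittance is taken as unity, which is the defining
assumption of a Fraunhofer-only window; the simulator can deliberately break
it (below).

## The linear model and its estimation

The non-fluorescent part of the spectrum is represented by singular vectors
of a training matrix of non-fluorescent scenes (rows = scenes, columns =
channels, raw radiance units, no centering).  The fitted model over the
window is

$$ L(\lambda) \;=\; v_1(\lambda) \sum_{i=0}^{n_P} a_i \hat\lambda^i
   \;+\; \sum_{j=2}^{n_v} \omega_j v_j(\lambda) \;+\; F_s h_F(\lambda), $$

estimated by weighted least squares with weights
$\varpi(\lambda) = \mathrm{SNR}(\lambda)/L(\lambda)$, the reciprocal
radiance uncertainty.  The number of vectors $n_v$ (counted inclusive of
$v_1$, so $n_v = 1$ means no free singular-vector block) is selected per
sounding by minimizing
$\mathrm{BIC} = n_\lambda \ln(\mathrm{RSS}/n_\lambda) + k \ln n_\lambda$
over a candidate set, with
$\mathrm{RSS} = \sum_\lambda (\varpi_\lambda (L_\lambda -
\tilde L_\lambda))^2$ and $k = (n_P+1) + (n_v-1) + 1$.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| window | 771–778 nm | retrieval window, half-open on channel centers |
| `nP` | 1 | polynomial order modulating $v_1$; first order suffices for a 7 nm window |
| `nvCandidates` | 2–8 | candidate numbers of singular vectors for BIC |
| `sigma` | 30 nm | Gaussian emission width; 30 nm best matches the far-red wing |
| `phi` | 1 | emission peak height (with $\varphi = 1$, $F_s$ is the 740 nm amplitude) |
| `center` | 740 nm | emission peak; configurable because some processors use other shapes |
| `lambdaRef` | 775 nm | reporting wavelength, $\mathrm{SIF}(\lambda_{ref}) = F_s h_F(\lambda_{ref})$ |
| `weighting` | on | SNR weighting; an unweighted mode exists for spectra without SNR |

Reporting at 775 nm matters: the window only constrains the emission
*locally*, so the in-window value is robust to a mis-specified width, while
the extrapolated 740 nm amplitude scales with
$1/h_{F}(\text{window})$ and inherits any shape error.

## Design decisions

**No mean-centering before SVD.**  $v_1$ itself is the multiplicative
carrier of the spectrum shape in the model; centering would replace it with
a deviation pattern and break that role.  Each vector's sign is fixed by
requiring a non-negative inner product with the mean training spectrum
(ties resolved by making the largest-magnitude element positive), so bases
are reproducible across linear-algebra backends.

**Normalized polynomial coordinate.**  The polynomial uses
$\hat\lambda = (\lambda - \lambda_{mid})/(\lambda_{max}-\lambda_{min})$.
With raw wavelengths near 775 nm, the order-0 and order-1 columns would be
collinear to ~1 part in 10³; the affine reparametrization changes the
$a_i$ but not the fitted $F_s$.

**RSS convention.**  The weighted residual enters as
$\sum (\varpi r)^2$ — the dimensionless chi-square when $\varpi$ is the
reciprocal uncertainty — with the alternative $\sum \varpi r^2$ available
via `rssForm = "linear"`.

**Ties and degenerate fits.**  Equal BIC values resolve to the smallest
$n_v$ (parsimony).  A numerically perfect fit has no defined BIC
(`computeBic` refuses RSS = 0); the selector treats it as $-\infty$, so
noiseless in-span spectra still select the smallest sufficient model.  The
selected candidate's fit is reused as the final fit; refitting would
reproduce it exactly.

**Masked channels.**  Channels with non-positive radiance get weight zero:
they stay in the vectors (alignment is preserved) but drop out of the fit
and the RSS.  Negative retrieved $F_s$ is reported, never clipped —
clipping would bias ensemble means.

**Uncertainty.**  `fsUncertainty` is the square root of the $h_F$
coefficient's variance from the weighted least-squares covariance with
residual-based rescaling $\hat s^2 = \mathrm{RSS}/(n-k)$.  This calibrates
the *fit* uncertainty; BIC model selection adds spread on top of it that
the per-fit covariance cannot see (ordinary post-selection inference), so
ensemble scatter under free selection runs some tens of percent above the
mean reported uncertainty, while at fixed $n_v$ the two agree closely.

## The synthetic-spectrum simulator

The simulator exists so that every claim about the retrieval can be tested
as parameter recovery.  It emulates:

* a smooth solar continuum (~1200 mW m⁻² nm⁻¹ at 760 nm) with fifteen
  Gaussian absorption lines of depth 0.2–0.6 and width 0.05–0.08 nm, nine
  of them inside 771–778 nm — Fraunhofer analogues with the instrument line
  shape folded into the width;
* a smooth effective reflectance: a degree-2 polynomial with intercept
  uniform in 0.15–0.55 and slope/curvature scales 0.08/0.03, resampled to
  stay within (0.02, 0.95).  Path reflectance and spherical-albedo coupling
  are deliberately absorbed into this single smooth term: in a
  Fraunhofer-only window they are spectrally smooth and not separately
  identifiable, so simulating them separately would add parameters the
  retrieval cannot distinguish;
* per-scene solar geometry ($\mu_0$ uniform in 0.5–0.9);
* per-scene spectral-calibration residuals: a wavelength offset
  (sd 0.001 nm ≈ 1/44 channel), a dispersion stretch (sd 0.00075 nm at the
  band edges) and a line-width factor (sd 0.005).  These are what give a
  real training archive its high-frequency singular vectors;
* additive fluorescence $F_s h_F$ and Gaussian noise of standard deviation
  $L/\mathrm{SNR}$, with constant SNR 300 as the default noise model (the
  actual instrument SNR model is not public; the choice is configurable and
  an affine-in-radiance model is provided);
* optionally, an O₂-like absorption band: a cluster of strong lines at
  769.1–770.8 nm multiplying both the reflected and emitted terms, standing
  in for ground-to-sensor transmittance.  It is intentionally *not* in the
  forward model, so windows that include it degrade — the mechanism behind
  the window-selection analysis.

Two simulator findings shaped its design and are worth recording.  First,
per-scene variation of *line depths* makes fluorescence unidentifiable: a
basis whose patterns can deepen or shallow lines can mimic line in-filling
exactly, and retrieved amplitudes become arbitrary at near-zero residual.
This is the mirror image of why the method works at all — solar line depths
are stable, and the retrieval lives off that stability — so the simulator
varies only the wavelength registration and width of the line pattern,
whose signatures (antisymmetric or flank-localized at each line) are nearly
orthogonal to the symmetric core-filling fluorescence signature.  Second,
calibration residuals induce a genuine pseudo-fluorescence at second order
(a shift δ raises line cores by $\tfrac{\delta^2}{2} I''$), which is why
the default residuals are set small enough that this leak stays below the
shot-noise floor at SNR 300 — the same requirement a real mission puts on
its Level-1 calibration.

What the simulator does **not** emulate: real solar line shapes and
blended-line crowding, telluric water-vapour lines, explicit instrument
line-shape convolution (folded into line widths instead, since the
retrieval never inverts the ISRF), non-Lambertian surfaces, aerosol
scattering structure, and realistic canopy emission spectra (the Gaussian
$h_F$ stands in for a radiative-transfer fluorescence spectrum).  Passing
parameter-recovery tests here therefore demonstrates the estimator's
correctness and conditioning, not mission-level accuracy on real granules.

## Validation experiments

The test suite and `scripts/acceptance.R` run the package end to end at
desk scale: a 400-scene training set on the 455-channel grid (a real
archive would use thousands of scenes; 400 keeps the basis estimate stable
at this variability budget), Monte-Carlo sizes of 200–500 replicates, and
the 159-channel default window.

* **Exact recovery.**  A noiseless scene whose non-fluorescent part lies in
  the basis span returns $F_s$ to floating-point accuracy — the
  identifiability baseline.
* **Unbiasedness.**  500 noisy replicates at SNR 300 for
  $F_s \in \{0, 0.4, 0.8\}$; mean error is required within 3 Monte-Carlo
  standard errors of zero.
* **Solver cross-check.**  Every weighted fit is compared against an
  independently coded normal-equations solve.  At $n_v = 7$–8 the
  $v_1\hat\lambda$ and $v_2$ columns are nearly collinear and those two
  coefficients are individually ill-determined (they blow up in
  magnitude and cancel); the fitted spectrum and $F_s$ remain stable, and
  the QR and normal-equations solutions agree within the comparison
  tolerance while attaining identical residuals.
* **Selection consistency.**  Scenes built from the first five singular
  vectors plus noise; BIC must pick $n_v = 5$ in at least 90% of
  replicates.  The construction (`effectivePatternSpectrum`) places each
  pattern at its training RMS amplitude or, where that would be
  undetectable, at the amplitude giving marginal detection significance 8
  over the nested model — realizing "five *effective* patterns": a pattern
  below the noise floor is not effective, and no amplitude can make a
  pattern effective whose window content the $v_1$-polynomial block already
  absorbs (the pure continuum slope $v_2$ is such a pattern).
* **Emission-width sweep.**  Retrievals of the same scene set (truth
  σ = 30) under σ ∈ {20, 25, 30, 35, 40}.  The RMSE against truth is
  minimized at the true width: a mis-specified width mis-scales the
  740 nm amplitude by the in-window shape ratio (≈ 2.3× at σ = 20).
  R² is a much weaker probe in this comparison: it is invariant to any
  per-σ linear rescaling, so the mis-scaling that drives the RMSE leaves
  it untouched, and the residual σ-dependence of R² (a few 10⁻³) is
  dominated by noise-geometry and calibration-leak terms rather than by
  shape alignment.  This is a known limitation of scoring against truth
  with a scale-free statistic.
* **Window contamination.**  With the O₂-like band injected (depth 0.3)
  and unmodelled, the clean 771–778 nm window scores far higher R² against
  truth than 769.5–776 or 769.5–778 nm — the windows overlapping the band
  collapse, reproducing the qualitative window-selection result.
* **Batch recovery and calibration.**  Regression of retrieved on true
  amplitudes over a 100-sounding batch has near-unit slope at SNR 300, and
  the empirical spread at fixed $n_v$ matches the mean reported
  uncertainty within 25%.

## Known limitations

* The Gaussian $h_F$ is a stand-in; real far-red emission is asymmetric.
  Within a 7 nm window this matters mainly through the amplitude scale, so
  window-local reporting (`sif_at_ref`) is the robust quantity.
* Windows containing real telluric absorption require transmittance
  modelling that is out of scope here; the package only demonstrates the
  degradation, not its correction.
* Training and scene spectra share a simulator; selection rates and sweep
  orderings quantify self-consistency under the stated variability budget,
  not archive-scale generality.
* Coefficients of near-collinear columns at large $n_v$ are individually
  ill-conditioned (see the solver cross-check above); interpret $\omega_j$
  diagnostically, not physically.
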