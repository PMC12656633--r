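---
title: "Methods: NIR calibration, aquagrams and treatment statistics for purslane oxalate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NIR calibration, aquagrams and treatment statistics for purslane oxalate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(purslaneNIR)
```

## The problem

Purslane (*Portulaca oleracea* L.) accumulates oxalates — up to tens of
g/100 g on a dry-matter basis — which bind calcium, magnesium and iron and
limit their bioavailability. Blanching leaches soluble oxalates and
pickling extracts insoluble ones, so quantifying total oxalate across
treatments matters for food use. Wet-tissue NIR spectra (900–1700 nm,
512-channel InGaAs array) carry that information in weak C=O and O–H
overtone bands superimposed on a dominant water background, which is why
the analysis needs multivariate calibration rather than single-band
regression. This package provides that analysis chain and a synthetic
data generator that reproduces its statistical structure.

## Spectral preprocessing

**Savitzky–Golay second derivative.** A local polynomial of degree
`polyorder` (default 2) is least-squares fitted in a sliding window
(default 15 points) and differentiated twice at the window center. The
filter is exact on polynomials up to the fit degree, so baseline offset
and slope are annihilated and overlapping bands separate. Defaults were
chosen as common practice for 512-channel spectra of wet plant tissue: a
15-point window spans ≈22 nm on the default grid, wide enough to suppress
channel noise and narrower than the ≈40–100 nm water features of
interest. Edge channels where the window does not fit are **trimmed**
(7 on each side at the default), and the grid is trimmed with them;
polynomial extrapolation at the edges would fabricate values that then
enter the calibration. The derivative requires a uniform grid (checked to
1e-6 relative spacing); units are absorbance·nm⁻².

**Multiplicative scatter correction.** Particle-size and surface effects
multiply and offset wet-tissue reflectance spectra. MSC fits each
spectrum to a reference by OLS over all channels, `x ≈ a + b·ref`, and
returns `(x − a)/b`. The reference defaults to the mean spectrum of the
set being corrected — also the convention the aquagram definition uses.
Two numerical facts the tests rely on: with a *fixed* reference MSC is
exactly idempotent (the residual is orthogonal to the reference, so the
refit returns slope 1, intercept 0); with the corrected set's *own mean*
as the new reference it is idempotent only to second order in the
residual scatter, so the near-idempotence check uses near-affine spectra.
A fit with |b| < 1e-12 (a spectrum carrying no trace of the reference
shape) is an error naming the sample, not a silent pass-through.

## PLS1 calibration and validation

`fit_pls()` implements NIPALS PLS1 on mean-centered data: each factor's
weight vector is `X'y` normalized (maximizing covariance between scores
and the analyte), followed by deflation of both `X` and `y`. The factors
collapse into a single regression vector `b = W(P'W)⁻¹q`, so prediction
is `ŷ = ȳ + (x − x̄)·b`; the collapsed and sequential forms agree to
1e-10 by construction and the test suite checks score orthogonality and
the PLS→OLS limit at full rank. A weight-vector norm below 1e-12 during
extraction raises a rank error naming the factor — continuing would
divide by a numerically zero norm.

**Validation.** Leave-one-out cross-validation refits the model n times,
predicting each held-out sample from the remaining n−1. Mean-centering
is always recomputed inside the fold. The MSC reference is a
data-dependent statistic too: by default (`msc_per_fold = TRUE`) it is
recomputed from the training fold, so no information from the held-out
spectrum leaks into its own preprocessing; `msc_per_fold = FALSE`
reproduces the laxer whole-set convention of desktop chemometrics
packages whose internals are not documented. The derivative is
per-sample and carries no fold statistics, so it is applied identically
either way. The factor count is chosen as the argmin of SECV over
`k = 1..k_max` (ties to the smaller k, for parsimony).

**Reported statistics and their conventions.** The literature rarely
states degrees of freedom, so they are explicit here and an RMSE variant
is reported alongside for auditability:

- `SEC = sqrt(RSS_cal / (n − 1 − k))` — the classical NIRS convention
  charging one df per factor plus the intercept;
- `SECV = sqrt(RSS_cv / n)` — plain 1/n, as cross-validation residuals
  are out-of-sample;
- `r_cal`, `r_cval` — Pearson correlation between reference and
  predicted values ("multiple correlation coefficient" reduces to
  Pearson r for a single response);
- `RPD = SD(y)/SECV`, with the n−1 sample standard deviation, so
  `RPD·SECV = SD(y)` is an exact identity the tests assert.

A perfect fit (SECV = 0) makes RPD undefined and is raised as an error
rather than reported as infinity.

## Aquagrams

The aquagram standardizes MSC-corrected absorbance per wavelength over
the analyzed sample set, `Aq_λ = (A_λ − μ_λ)/σ_λ`, and reads it at
water-matrix coordinates — conserved bands of free water (~1348–1410 nm),
water dimers (1441 nm), solvation shells (1447, 1454 nm), water with
two/three/four hydrogen bonds (1465/1478/1485 nm) and strongly bound or
structural water (1503, 1521–1559 nm). The default coordinate list is
the 13 wavelengths discussed for this matrix; published 19-coordinate
sets can be supplied as a custom `water_matrix_coordinates()` — the
package deliberately does not hard-code literature values it cannot cite
in data form. Requested coordinates map to the **nearest grid channel**
(a 512-channel grid does not hit integer nanometers), and the actual
channel wavelength is recorded in the output. Aquagrams are defined on
raw (MSC-corrected) absorbance; derivative spectra are rejected. By
construction each coordinate has mean 0 and SD 1 over the defining set,
group means are size-weighted to zero, and adding a common gain and
offset to every spectrum changes nothing (MSC removes it).

## Treatment statistics from summary tables

Raw replicate values are rarely printed; group means, SDs and sizes are.
One-way ANOVA is fully recoverable from them:
`SSB = Σ nᵢ(x̄ᵢ − grand mean)²` (grand mean weighted by nᵢ),
`SSW = Σ (nᵢ−1)sᵢ²`, `F = (SSB/df_b)/(SSW/df_w)` and
`η² = SSB/(SSB+SSW)`, which equals the one-factor linear model R² that
SPSS-style univariate output reports. The tests verify the identity by
reconstructing raw datasets with exactly the prescribed moments. Percent
change versus the fresh control is computed on unrounded means and
rounded to two decimals only for display; because published tables print
rounded means, recomputed percentages can differ from printed ones by a
few hundredths of a percentage point (observed: −83.05 vs −83.06,
−47.87 vs −47.86, −47.08 vs −47.07), which is flagged as rounding, not
corrected. Dry-matter ↔ fresh-weight conversion is
`fw = dm·(100 − moisture)/100` with its exact inverse. Normality and
variance-homogeneity tests and post-hoc multiple comparisons need raw
replicates and are out of scope; standard R routines apply when raw data
exist.

## The synthetic study generator

`synth_config()` encodes the study conditions as defaults, set once:

- **Grid**: 512 channels, 900–1700 nm.
- **Water background**: Gaussian bands near 970, 1190 and 1450 nm
  (amplitudes 0.4/0.5/1.0), scaled by the sample's moisture fraction.
- **Oxalate absorption**: bands of 0.002 absorbance per g/100 g at 980,
  1162, 1408, 1425, 1448 and 1470 nm (σ = 15 nm) — the wavelengths where
  second-derivative spectra of fresh samples differ by oxalate content.
- **Water-structure coupling**: oxalate shifts weight from a free-water
  band (1375 nm, σ = 30) to a bound-water band (1460 nm, σ = 40), ±0.008
  per g/100 g. Centers and widths were chosen so that, *after* MSC and
  standardization, coordinate–oxalate correlations come out positive at
  1429–1504 nm and negative at 1348–1410 nm — the construction goal. A
  narrower first attempt left the 1429 nm sign indeterminate because the
  MSC gain fit partially absorbs signal near the 1450 nm water peak;
  widths are part of the construction, not a fitted spectroscopic model.
- **Scatter and noise**: per-sample multiplicative gain
  `exp(N(0, 0.05))`, additive offset `N(0, 0.01)`, and i.i.d. channel
  noise with SD equal to the SD of the analyte signal contribution
  divided by a signal-to-noise ratio of 20 — the high-SNR regime in which
  a usable wet-tissue calibration operates.
- **Design**: dry-matter oxalate drawn per series × treatment group from
  the published group means and SDs (truncated at zero by resampling,
  count recorded), 4 population replicates per group, moisture uniform in
  the treatment-specific range (fresh 88.4–92.4 %, blanched 87.8–93.7 %,
  pickled 75.7–83.8 %), fresh-weight concentration via the moisture
  conversion — 36 composite samples, fresh-weight oxalate spanning
  roughly 0.7–8 g/100 g.

All randomness flows through one locally seeded generator that restores
the global RNG state, so generation is reproducible and side-effect
free.

**What the generator does and does not emulate.** It reproduces the
linear analyte–absorbance structure, water dominance, scatter, noise and
the design counts — enough to test that the calibration machinery
recovers known truth (r_cval ≥ 0.97, RPD > 3 at n = 36 under the default
SNR). It does **not** emulate treatment-specific matrix effects: all
treatments share one concentration→spectrum map, so pooling treatments
only adds training data and the pooled calibration cross-validates
*better* than the per-treatment subsets here, whereas on real samples the
per-treatment equations are the more accurate ones (different water
status and matrix per treatment). Passing tests therefore demonstrate
correctness of the machinery, not instrument-grade realism. Two further
honest limits: with n = 4 per group, a single simulated study's η² is a
noisy estimate of the generating effect size (per-seed deviations up to
≈0.35 were observed), so the recovery test checks the median over 20
seeds; and Series 3's fresh and blanched generating means differ by only
0.24 g/100 g, so individual draws can invert their order, exactly as the
real September series barely responded to blanching.

## Numerical choices and degenerate inputs

- Ties in factor selection go to the smaller k.
- Constant response, zero-variance reference values, SECV = 0, MSC
  |b| < 1e-12, aquagram σ_λ < 1e-12, rank exhaustion in NIPALS and empty
  aquagram groups are all explicit errors naming the offending sample,
  factor or wavelength; nothing degenerates silently.
- Replicate averaging is an explicit pre-step (`average_replicates()`),
  never implicit.
- Spectra are exchanged as wide CSV at full float precision; read∘write
  is the identity to ≤1e-12.
- Problem sizes in the test suite (n = 8–36 samples, 40–512 channels,
  20-seed ensembles) were chosen as the smallest sizes at which each
  property is non-trivial; the full suite runs in well under a minute.

## Pipeline

`run_calibration()` orchestrates input (files or simulation), optional
treatment subsetting, the preprocessing chain, factor selection, final
fit and report, writing `report.csv`, `cv_predictions.csv`,
`predicted_vs_reference.csv` and a log that echoes the configuration, the
seed and a configuration hash stamped into every output file (the output
directory is excluded from the hash so relocated reruns stay
byte-identical). Any stage failure aborts with a stage-labeled message
and removes partial outputs. The per-treatment and pooled calibrations
are first-class so the four standard report rows (fresh, blanched,
pickled, all) can be produced directly.
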