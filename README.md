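# purslaneNIR

NIR chemometrics for the non-destructive assessment of total oxalate,
ascorbic acid and total organic acids in purslane (*Portulaca oleracea* L.).

Purslane is a nutritious leafy vegetable whose high oxalate content limits
mineral bioavailability; blanching and pickling reduce oxalates, and
near-infrared (NIR) spectroscopy of the wet tissue (900–1700 nm) can
quantify them without wet chemistry. This package implements the full
analysis chain a spectroscopist needs for that problem:

- **Spectral I/O** — wide-CSV spectral matrices bound to an explicit
  wavelength grid, long-CSV sample metadata (population, monthly series,
  treatment, moisture, reference analyte values per basis), strict
  alignment checks.
- **Preprocessing** — Savitzky–Golay second derivative
  (`second_derivative()`, edges trimmed, exact on polynomials) and
  multiplicative scatter correction (`msc()`: per-spectrum OLS fit
  `x ≈ a + b·ref`, corrected spectrum `(x − a)/b`).
- **PLS1 calibration** — from-scratch NIPALS partial least squares
  (`fit_pls()`), leave-one-out cross-validation (`loocv()`), factor
  selection by minimal SECV (`select_factors()`), and the standard NIRS
  report (`calibration_stats()`):

  - `SEC = sqrt( Σ(yᵢ − ŷ_cal,ᵢ)² / (n − 1 − k) )`
  - `SECV = sqrt( Σ(yᵢ − ŷ_cv,ᵢ)² / n )`
  - `r_cal`, `r_cval` — Pearson correlation of reference vs predicted
  - `RPD = SD(y) / SECV` (RPD > 3 indicates a reliable calibration)

- **Aquaphotomics** — aquagram values `Aq_λ = (A_λ − μ_λ)/σ_λ` of
  MSC-corrected absorbance at water-matrix coordinates (`aquagram()`),
  group-mean radar profiles and per-coordinate analyte correlations.
- **Treatment statistics** — percent oxalate reduction versus the fresh
  control, one-way ANOVA F and η² recovered from group means/SDs/n alone
  (`anova_from_summaries()`), and dry-matter ↔ fresh-weight conversion
  via moisture (`dm_to_fw()`).
- **Synthetic study generator** — seeded Beer–Lambert-style spectra with
  water-dominated absorbance, oxalate bands, an oxalate-dependent
  free→bound water shift, scatter and noise, reproducing the study design
  (4 populations × 3 series × 3 treatments = 36 composite samples), so
  every stage is testable without instrument data.

## Worked example

```r
library(purslaneNIR)

# treatment effects from published-style group summaries (n = 4 per group)
summaries <- data.frame(
  series    = rep(1:3, each = 3),
  treatment = rep(c("fresh", "blanched", "pickled"), 3),
  mean = c(61.84, 19.07, 10.48, 33.38, 22.29, 17.40, 34.60, 34.36, 18.31),
  sd   = c(17.99,  7.90,  3.46,  3.85,  6.00,  5.44,  4.91,  1.88,  4.65),
  n = 4)
reduction_table(summaries)
#> treatment-effect report (mean ± SD, % change vs fresh)
#>  series treatment               display
#>       1     fresh         61.84 ± 17.99
#>       1  blanched 19.07 ± 7.90 (-69.16)
#>       1   pickled 10.48 ± 3.46 (-83.05)
#>       2     fresh          33.38 ± 3.85
#>       2  blanched 22.29 ± 6.00 (-33.22)
#>       2   pickled 17.40 ± 5.44 (-47.87)
#>       3     fresh          34.60 ± 4.91
#>       3  blanched  34.36 ± 1.88 (-0.69)
#>       3   pickled 18.31 ± 4.65 (-47.08)
#> per-series one-way ANOVA:
#>  series        F      p_value eta_squared
#>       1 22.81740 0.0002988677       0.835
#>       2 10.00448 0.0051605582       0.690
#>       3 21.23309 0.0003910590       0.825
```

Blanching removes 69 % of total oxalate in the July series but under 1 %
in September (insoluble oxalates resist leaching); pickling removes
47–83 %. The η² row says 69–84 % of the oxalate variation within a series
is explained by the treatment.

```r
# end-to-end PLS calibration on the simulated study (36 wet-tissue spectra)
res <- run_calibration(run_config(sim = synth_config(), seed = 17, k_max = 8))
res$report
#> calibration_report (n = 36, k = 3)
#>   SEC  = 0.04818  r_cal  = 0.9993
#>   SECV = 0.2294  r_cval = 0.9843
#>   RPD  = 5.547
```

Three latent factors predict fresh-weight oxalate (g/100 g) with a
cross-validated error of 0.23 g/100 g and RPD well above 3 — the accuracy
regime a usable NIRS screening calibration must reach.

```r
# aquagram: which water-matrix coordinates track oxalate in fresh samples?
study <- simulate_study(seed = 17)
fresh <- study$dataset$design$treatment == "fresh"
sp <- spectra_set(study$spectra$grid,
                  study$spectra$absorbance[fresh, ],
                  study$spectra$sample_ids[fresh])
coordinate_correlations(aquagram(sp),
                        reference_values(study$dataset, "oxalate", "fw")[fresh])
#> 1348nm 1360nm 1410nm 1429nm 1441nm 1447nm 1454nm 1465nm 1478nm 1485nm 1503nm
#>  -1.00  -1.00  -0.98   0.98   1.00   0.99   0.99   1.00   0.99   0.99   0.93
#> 1521nm 1559nm
#>   0.88   0.94
```

Correlations are positive at the bound-water coordinates (1429–1503 nm)
and negative at the free-water coordinates (1348–1410 nm): more oxalate
means less free water and more hydrogen-bonded water structures.

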