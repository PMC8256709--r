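# fibrilsaxs

Quantitative analysis of scanning SAXS/WAXS microscopy data from type 1
collagen tissues, of the kind used to monitor how sugar glycation (a model
for diabetes and ageing) remodels the collagen nanostructure.

Type 1 collagen fibrils are built from triple-helix molecules packed in a
staggered, axially periodic arrangement: each period *D* ≈ 63–67 nm divides
into an **overlap** region of extent σ*D* (higher packing density) and a
**gap** region of extent (1 − σ)*D* (lower density), with σ ≈ 0.46 in
hydrated tissue. A scanning beamline raster-scans a tissue sample (81 × 51
= 4131 frames at a 50 µm step is typical) and each frame is azimuthally
folded into a 1D profile *I(q)*. This package turns such per-sample stacks
of 1D profiles into structural parameters.

## What the package computes

**Step-density forward model.** The meridional SAXS intensity of a
two-level periodic axial electron density is

    I(q) ∝ 4 ρ_Ave² / q²                                        (monotone decay)
         + Dmp(q; w, c) · [Δρ²/q² · |2 e^{iqσD} − 1 − e^{iqD}|² / 4]
                        · sin²(N q D / 2) / sin²(q D / 2)        (damped Bragg series)

where *N* periods interfere, Δρ is the half-contrast between overlap and
gap densities, and `Dmp(q) = c + (1 − c)/(1 + (q w / 2π)²)` is a Lorentzian
damping with floor *c* accounting for the finite interface sharpness. At
the Bragg condition *q = 2πn/D* the peak weight is ∝ sin²(πnσ)/n², so even
orders vanish for a symmetric density (σ = 0.5).

**Staged coordinate-descent fit** (`fit_profile`): *D* initialised from the
higher-order Bragg peak positions, *N* from their FWHM, σ = 0.46, then the
least squares is minimised by alternating line searches in Δρ (steps of
0.001), the damping parameters *w* (0.1 nm) and *c* (0.01), followed by
refinement of *D* (0.1 nm) and σ (0.001), repeated for at most ten outer
iterations. R² is reported as one minus the ratio of residual variance to
data variance.

**Even/odd asymmetry value** (`asymmetry_value`): the sum of integrated
even-order peak intensities (n ≥ 4) over the sum of odd-order intensities
(n ≥ 3), computed on the per-sample average profile. Near zero for
hydrated, hardly glycated collagen; grows as glycation skews the axial
density.

**Gap-fraction error landscape** (`sigma_landscape`): RMSE as a function of
1 − σ with all other parameters frozen, exposing the Babinet-degenerate
minimum pair.

**Per-frame peak maps and histograms** (`fit_single_peak`, `scan_peaks`,
`summarize_histogram`): Gaussian on a `A·q⁻ⁿ + floor` background in four
windows — the ~1.5 nm lateral triple-helix spacing, the ~0.286 nm axial
residue rise, the ninth order of the axial period (~7.3 nm) and the
100–150 nm fibril diameter — condensed per sample into a Gaussian-mixture
histogram summary (component count by BIC, position and FWHM weighted by
component area).

**Segmentation and quality control** (`segment_scan`,
`flag_outlier_samples`): normalisation → PCA (3 components) → seeded
k-means (4 subsets by default) with medoid representative profiles and
spatial abundance maps; per-sample correlation-distance screening against
a control profile.

**Synthetic beamline emulator** (`ground_truth`, `scan_spec`,
`generate_scan`): ground-truth-labelled SAXS/WAXS profiles and raster
scans with Poisson counting noise, smooth parameter maps and planted
outlier regions, so the entire pipeline is testable without beamline data.

## Worked example

```r
library(fibrilsaxs)

demo <- demo_scan(seed = 1, n_rows = 12, n_cols = 12)  # paired SAXS/WAXS scan
avg  <- average_profile(demo$saxs)

fit <- fit_profile(avg)
fit
#> <step_fit> R^2 = 1.0000, RMSE = 483, 2 iteration(s)
#> <step_params> D = 65.51 nm, N = 10, sigma = 0.460 (gap 0.540), rho_ave = 1,
#>               delta_rho = 0.078, w = 7.40 nm, c = 0.000

asymmetry_value(index_orders(avg, D_init = fit$params$D))
#> <asymmetry_result> value = 0.2248 (even orders 4,6,8 / odd orders 3,5,7,9),
#>                    D_est = 65.506 nm

landscape_minimum(sigma_landscape(avg, fit))
#> [1] 0.54

summarize_histogram(scan_peaks(demo$waxs, peak_window("waxs_equatorial")))
#> <histogram_summary> 144 values, 1 component(s); weighted position 3.9989 nm^-1
#>                     (d = 1.5712 nm), weighted FWHM 0.0052
```

The demo scan is generated from a ground truth with *D* = 65.5 nm, *N* =
10, σ = 0.46, Δρ = 0.08 and WAXS peaks at 4.0 and 22.0 nm⁻¹: the fit
recovers the period to 0.01 nm and the overlap fraction exactly; the
asymmetry value ≈ 0.22 reflects the even-order intensity that survives at
σ = 0.46; the landscape minimum sits at gap fraction 0.54 = 1 − σ; and the
per-frame equatorial peak histogram lands on the ~1.57 nm (q ≈ 4 nm⁻¹)
lateral spacing.

A command-line surface over the same functions is installed at
`exec/fibrilsaxs.R` (subcommands `simulate`, `fit-profile`, `landscape`,
`scan-peaks`, `histogram`, `asymmetry`, `segment`, `run-sample`).

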