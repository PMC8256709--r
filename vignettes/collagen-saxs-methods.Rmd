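---
title: "Modelling scanning SAXS/WAXS data from collagen tissue"
author: "fibrilsaxs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling scanning SAXS/WAXS data from collagen tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilsaxs)
```

# The physical picture

Type 1 collagen fibrils are staggered assemblies of ~300 nm triple-helix
molecules. The stagger produces a one-dimensional axial density wave of
period $D \simeq 63\text{--}67$ nm: within one period, an *overlap* region
of extent $\sigma D$ packs more molecular mass than the complementary
*gap* region of extent $(1-\sigma)D$; $\sigma \approx 0.46$ in hydrated
tissue. Meridional small-angle scattering from this lattice shows Bragg
peaks at $q_n = 2\pi n / D$. Wide-angle scattering probes the molecular
scale: the ~1.5 nm lateral spacing between triple helices (equatorial,
$q \approx 4\ \mathrm{nm^{-1}}$) and the ~0.286 nm axial rise per residue
(meridional, $q \approx 22\ \mathrm{nm^{-1}}$, one third of the 0.86 nm
helix unit height). Glycation — the non-enzymatic reaction of reducing
sugars with the protein — deposits mass preferentially in one of the two
axial regions and crosslinks the lattice, so its structural fingerprints
are: a changed electron-density contrast between overlap and gap, a
drifting $D$ period, re-appearance of the normally suppressed even Bragg
orders, and shifts of the WAXS spacings. Each module of this package
quantifies one of those fingerprints.

Throughout, length scales use the inter-planar convention $d = 2\pi/q$
with $q$ in $\mathrm{nm^{-1}}$.

# The two-level step-density model

The axial density over one period is approximated by two constant levels:
$\rho_1 = \rho_{\mathrm{Ave}} + \Delta\rho$ over $\sigma D$ and
$\rho_2 = \rho_{\mathrm{Ave}} - \Delta\rho$ over $(1-\sigma)D$, measured
relative to the embedding matrix. In kinematic approximation the
meridional intensity of $N$ coherently interfering periods factorises into
a monotone mean-density term and a damped Bragg series:

$$
I(q) \;\propto\; \frac{4\rho_{\mathrm{Ave}}^2}{q^2}
\;+\; \mathcal{D}(q; w, c)\,
\underbrace{\frac{\Delta\rho^2}{q^2}\,
\frac{\bigl|2e^{iq\sigma D} - 1 - e^{iqD}\bigr|^2}{4}}_{\text{single-period fluctuation}}
\;\cdot\;
\underbrace{\frac{\sin^2(NqD/2)}{\sin^2(qD/2)}}_{\text{interference}}
$$

At $q_n = 2\pi n/D$ the interference factor reaches its removable-limit
value $N^2$ and the fluctuation term reduces to
$4\Delta\rho^2\sin^2(\pi n\sigma)/q_n^2$: even orders vanish exactly when
$\sigma = 1/2$, which is why a hydrated, hardly glycated fibril shows
almost only odd orders, and why the even/odd intensity ratio is a
sensitive reporter of density redistribution. `interference_term()`,
`diffraction_term()` and `damping()` expose the three factors separately
so each can be checked against independent oracles (the test suite
reconciles them against a geometric-sum evaluation and a brute-force FFT
of the explicitly sampled step density).

The damping factor
$\mathcal{D}(q) = c + (1-c)/\bigl(1 + (qw/2\pi)^2\bigr)$ is a Lorentzian
with a high-$q$ floor: the real density does not jump discontinuously
between gap and overlap, and disorder plus multiple scattering further
attenuate high orders. The additive-floor form was chosen over a clipped
`max(Lorentzian, c)` because it is smooth (a clipped form would create
kinks in the error surface of the fit); with this parameterisation $w$
carries nm units and converges to 8–10 nm on collagen-like profiles, with
$c$ around 0.04–0.07. Since the two forms agree at $q \to 0$ and in the
high-$q$ limit, the choice only affects the crossover region.

Because profiles are in arbitrary counts, an overall scale $K$ multiplies
the model. $K$ is a linear parameter and is solved in closed form
($K = \sum I m / \sum m^2$, clamped at zero) at every error evaluation
rather than being descended on.

# The staged fit

`fit_profile()` reproduces a deliberately simple staged descent rather
than a generic optimiser, because the staging itself regularises a
strongly correlated parameter set ($\Delta\rho$, $w$, $c$ and $K$ trade
off against each other):

1. **Initialisation.** Bragg peaks are detected on the $q^2$-weighted,
   baseline-subtracted profile (see below); $D$ comes from a least-squares
   line through the origin of peak position versus assigned integer order;
   $N$ from the peak FWHM via the finite-grating main-lobe width
   $\mathrm{FWHM}_q = 0.886\,\frac{2\pi}{ND}$ (the 0.886 factor is the
   exact sinc² constant — omitting it would systematically overestimate
   $N$ by ~13%); $\sigma = 0.46$, $\rho_{\mathrm{Ave}} = 1$,
   $\Delta\rho = 0$, $w = c = 0$.
2. **Contrast:** $\Delta\rho$ is line-searched in steps of 0.001.
3. **Damping:** $w$ (steps of 0.1 nm) and $c$ (steps of 0.01) are
   line-searched alternately until stable.
4. Steps 2–3 alternate until no improvement.
5. **Refinement:** $D$ (steps of 0.1 nm) and $\sigma$ (steps of 0.001).
6. The whole cycle repeats until the error stops decreasing, for at most
   ten outer iterations. Ties in a line search keep the
   smaller-magnitude change, biasing toward the initialisation.

$N$ deserves a note. The FWHM estimate is adequate on noiseless curves
but counting noise biases measured widths low (apexes of noisy peaks are
selected for upward fluctuations), which drags $N$ up and $\Delta\rho$
with it. The error function itself is far more sensitive to peak width
than any direct FWHM measurement, so by default the integer $N$ is chosen
by the best *full* fit among neighbours of the initial estimate
(`refine_N = TRUE`), walking up or down while the residual improves. On
the synthetic study conditions this recovers $N = 10$ essentially always,
where the raw FWHM estimate scatters over 9–12.

The goodness of fit is reported as $R^2$, with $1 - R^2$ defined as the
residual variance over the variance of the data about its mean, computed
over the fit range only; data before the first scattering peak are
excluded from the fit range, since the beamstop region and the strong
low-$q$ upturn are outside the model's scope.

## Peak detection and order indexing

Peak detection multiplies the profile by $q^2$ (flattening the monotone
term), smooths with a 5-point moving average, subtracts a running-median
baseline, and keeps local maxima above a threshold that is the larger of
0.5% of the tallest structure and eight times the point-to-point noise.
Three artefact classes are removed explicitly: finite-grating sidelobes
(secondary maxima within ~1.5 peak widths of a stronger peak), apexes of
peaks cut by the window edge, and sub-resolution spikes (narrower than two
grid steps). Positions are refined by a parabola through the
baseline-subtracted *intensity* (not the $q^2$-weighted signal, whose
envelope would bias the apex); widths are half-height crossings with the
smoother's boxcar broadening removed in quadrature.

Order assignment (`index_orders()`) scores candidate fundamental spacings
— pairwise peak differences divided by small integers, restricted to
periods of 50–80 nm — by how many strong peaks land on the lattice
$q = ns$ within 4% of $s$, preferring more inliers, then the larger
spacing on ties (a sub-harmonic of the true spacing fits every peak too).
All detected peaks are then filtered for lattice consistency, duplicate
orders keep the stronger peak, and $D = 2\pi/\text{slope}$ is refit on
the retained set. This survives both missing even orders (at
$\sigma \to 0.5$ only odd orders exist) and spurious noise peaks.

## The asymmetry value

`asymmetry_value()` implements the even/odd statistic: the sum of
integrated, locally background-subtracted peak areas of even orders
$n \ge 4$ divided by the same sum over odd orders $n \ge 3$, with
`max_order = 9` by default (orders 1–2 are excluded by the definition and
are beamstop-prone; the ninth order is the highest the data resolve).
Both sums use areas — a ratio of like quantities is dimensionless and
scale-invariant — with an `odd_heights` switch for the variant that
divides by peak heights. Integration runs over ±1.5 FWHM with a linear
background from flanking bands at 1.5–3 FWHM. No damping or Lorentz
correction is applied before integrating. The statistic is computed on
the per-sample average profile, not per pixel, where single-frame even
orders would often be below noise.

## The gap-fraction landscape and the Babinet ambiguity

`sigma_landscape()` freezes every fitted parameter except $\sigma$ and
maps the RMSE over a $\sigma$ grid, reported against the gap fraction
$1-\sigma$. The two-level density and its complement scatter identically
($\sigma \leftrightarrow 1-\sigma$ leaves the model invariant, exactly,
for all $q$), so the landscape is symmetric and its global minimum is a
degenerate pair. `landscape_minimum()` therefore breaks exact ties toward
gap fractions above one half, the physical convention for hydrated
collagen (gap 0.54, overlap 0.46); the ambiguity itself cannot be resolved
from meridional intensities alone and is surfaced, not hidden.

# Per-frame peak analysis and histogram condensation

`fit_single_peak()` fits
$a\,e^{-(q-q_0)^2/2s^2} + A q^{-n} + \mathrm{floor}$ inside a named
window by Levenberg–Marquardt (`minpack.lm::nls.lm` on the explicit
residual, which proved more robust than the formula interface on
noiseless and near-degenerate windows). The constant floor extends the
plain power law to accommodate a detector/dark level. Start values are
data-driven: the background slope from averaged window edges, the peak
position and width from the residual against a running-median baseline. A
fit is *successful* when the amplitude exceeds three times the residual
RMSE (and a negligible-amplitude cut of $10^{-6}$ of the window maximum),
and $q_0$ lies strictly inside the window. Default windows:

| window | $q$ range (nm⁻¹) | length scale |
|---|---|---|
| `waxs_equatorial` | 2.5–6.0 | ~1.5 nm lateral spacing |
| `waxs_meridional` | 19–25 | ~0.286 nm residue rise |
| `saxs_meridional_9th` | 0.80–0.95 | ninth order, d = 7.16–7.3 nm |
| `saxs_equatorial_fibril` | 0.03–0.08 | 100–150 nm fibril diameter |

`summarize_histogram()` condenses the per-pixel positions of one window
into a per-sample summary: a 1D Gaussian mixture (1–3 components, chosen
by BIC via `mclust`) fitted to the position population, with the sample's
characteristic position and FWHM computed as component means/FWHMs
weighted by component area, and the weighted FWHM serving as the
uncertainty of the length-scale estimate. Fitting the sample directly by
maximum likelihood is statistically equivalent to fitting Gaussians to
the histogram but avoids a binning choice; Freedman–Diaconis bin edges
are still returned for plotting. Histograms are built over $q$ with $d$
derived, and both are reported. A degenerate population (all values
equal) short-circuits to a single component whose FWHM is one bin width.

# Segmentation and outlier screening

`segment_scan()` is a deliberately simple stand-in for published
signal-classification pipelines, sufficient for the quality-control role
it plays here: profiles are normalised to unit total intensity
(log-transformed first for SAXS, whose dynamic range spans decades;
linear for WAXS — both switchable), centred, projected on the first three
principal components, and clustered by seeded k-means (k = 4, 20
restarts). Each subset is represented by its medoid — an actual member
profile nearest the subset centre in score space — and subset abundances
and per-pixel PC scores support spatial maps. Duplicate profiles are
legal: a perfectly homogeneous scan yields one populated subset, empty
clusters and duplicated representatives rather than an error (the error
is reserved for k exceeding the pixel count).

`flag_outlier_samples()` screens per-sample representative profiles
against a control by correlation distance $1 - \mathrm{cor}$, flagging
samples beyond median + 5 MAD (or a fixed threshold); this mirrors the
practice of excluding anomalously prepared or dried samples before
population-level conclusions.

# The synthetic-data generator

`generate_saxs_profile()` evaluates the forward model on a default grid
of 0.05–1.2 nm⁻¹ (1000 points: orders 1–12 of a 65 nm period, ≥10 points
per peak FWHM at $N = 10$), scales it so the third-order peak carries
`count_scale` expected counts, adds a constant floor, and draws Poisson
counts. `generate_waxs_profile()` sums Gaussian peaks (defaults at 4.0
and 22.0 nm⁻¹) on an $Aq^{-n}$ + floor background over 2–28 nm⁻¹.
`generate_scan()` assembles raster grids (defaults 81 × 51 pixels at
50 µm, the full-sample geometry) with per-pixel noise streams derived
deterministically from (seed, row, col), so identical seeds give
bit-identical scans. Lateral structure is injected only deliberately:
smooth parameter maps for gradients, and rectangular `outlier_regions`
that swap in an alternative ground truth — matching the laterally
homogeneous character of decellularised pericardium.

Chosen conditions, and why:

* `count_scale = 1e4` at the third-order peak for recovery studies — high
  enough that the staged fit is shot-noise-limited rather than
  failure-prone, low enough that noise effects are visible. No beamline
  count statistics are published for this kind of scan, so this is a
  fixture choice, not a calibration.
* `demo_scan()` uses `count_scale = 1e6`: at $10^4$ the ninth-order
  reflection carries only ~35 counts on a ~750-count background in a
  single frame and honestly fails the 3×RMSE significance gate, which is
  physics, not a defect; the demo exists to exercise every stage of the
  per-frame workflow, so it uses a brighter exposure (well within reach
  of the real instrument's flux).
* Default truth $D = 65.5$ nm, $N = 10$, $\sigma = 0.46$,
  $\Delta\rho = 0.08$, $w = 9$ nm, $c = 0.05$ — central values of the
  ranges the model targets.

What the generator does **not** emulate: 2D detector frames (no geometry,
polarisation or flat-field effects — `fold_azimuthal()` regroups plain 2D
arrays but no detector model stands behind it), beam damage, sample
drift, the equatorial fibril-diameter peak in SAXS (the generator is
purely meridional, so the `saxs_equatorial_fibril` window has nothing to
find in synthetic scans and its per-frame stage records a failure — by
design), inter-pixel correlation of noise, and any chemistry linking
sugar dose to parameter drift. Passing tests therefore demonstrate that
the algorithms recover what the model family can express under Poisson
counting noise; they cannot certify behaviour on effects outside that
family (e.g. strongly asymmetric real peak shapes or diffuse scattering).

# Numerical choices and degenerate inputs

* Error metric: unweighted least squares (no published indication of
  uncertainty weighting); "mean square-root error" in landscape contexts
  is interpreted as root-mean-square error.
* The interference term's removable singularity is evaluated by its limit
  $N^2$ whenever $|\sin(qD/2)| < 10^{-9}$.
* Line searches stop on the first non-improving step (relative tolerance
  $10^{-12}$); the outer loop stops at a relative improvement below
  $10^{-8}$ or ten iterations, whichever first.
* Profiles with fewer than two detectable Bragg peaks are rejected with
  an "insufficient orders" error unless an explicit initialisation is
  supplied (a structureless $1/q^2$ profile then fits with
  $\Delta\rho \le 0.005$ and a flat landscape).
* Poisson mean-convergence is asserted as ≥99% of q-bins within three
  standard errors over 1000 replicates — with ~50 bins, demanding *every*
  bin within 3 SE would fail a substantial fraction of honest runs.
* Problem sizes in tests and the acceptance script: 25 Poisson replicates
  for fit recovery, a 2×2×2–3×3×3 truth grid, 50 histogram replicates of
  4131 draws, 6×6 segmentation fixtures, 8×8–12×12 demo scans, one
  81 × 51 geometry check on a coarse grid; together they run in well
  under a minute of compute apart from the test-suite total of ~30 s.

# Known limitations

* The Babinet ambiguity is intrinsic: $\sigma$ and $1-\sigma$ are
  indistinguishable from meridional intensities, and the package reports
  the conventional branch.
* $\Delta\rho$, $w$, $c$ and the scale are correlated; the staged descent
  resolves the degeneracy the same way the original procedure does, which
  can leave the damping parameters a little off their generating values
  even when $D$, $\sigma$ and $\Delta\rho$ are recovered well.
* The two-level density is a low-resolution approximation; on real data
  the unexplained variance (published fits reach $R^2$ of 0.74–0.8) mixes
  measurement error with model error, and no attempt is made to separate
  them here.
* The segmentation module targets the screening workflow, not
  bit-compatibility with any published classification implementation.
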