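---
title: "Models and numerical methods in adipotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in adipotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipotrace)
```

adipotrace collects the quantitative procedures of a diet-induced-obesity
phenotyping workflow — image-based translocation scoring, clamp and
radiotracer flux arithmetic, mass-spectrometric identity checks, dose
translation and small QC statistics — as composable, individually tested
functions. This vignette explains each model, the tunable parameters and
why their defaults are what they are, the synthetic generators the tests
rely on, and the numerical conventions.

## Nuclear-translocation scoring

**Model.** Insulin-sensitizing stimuli can drive ERK1/2 (or another
target protein) from the cytosol into the nucleus. On a two-channel
micrograph — nuclear stain plus immunostained target — each cell is
scored by the ratio of the mean target intensity inside its nucleus to
the mean in a thin perinuclear ring standing in for the cytosol. A cell
is *nuclear-positive* when that ratio strictly exceeds 4 (configurable,
`ring_geometry(positivity_threshold = )`), and an image is summarized by
the percentage of positive cells.

**Pipeline.** `segment_nuclei()` smooths the nuclear channel with a
Gaussian (`smoothing_sigma = 2` px), applies a global Otsu threshold,
labels connected components, optionally splits touching nuclei by
distance-transform watershed, and discards border-touching labels (their
rings would be truncated). `filter_nuclei()` retains labels with area in
[80, 2000] px² and circularity `4πA/P² ≥ 0.7`. `cell_mask()` thresholds
the *log* of the target channel — fluorescence histograms are dominated
by background with a long bright tail, and raw-scale Otsu tends to split
dim cells from bright nuclei rather than background from cells —
followed by hole filling. `measure_cells()` then takes, per nucleus, the
mean over the nucleus eroded by 1 px and over the ring obtained by
dilating it 1 + 3 steps, removing the 1-step dilation of *every* nucleus
(so rings never touch any nuclear pixel, own or neighbouring) and
intersecting with the cell mask.

**Conventions and edge cases.** "Pixel distance" is realized as
iterations of a 4-connected diamond structuring element, so the
"3-px-wide ring starting 1 px out" means dilation steps, not Euclidean
distance; the alternative is equally defensible but must be fixed once.
Perimeters use the crack-edge count multiplied by π/4 to correct the
city-block overestimate of digitized boundaries — with this estimator
digital disks score circularities between 0.75 (r = 3) and ~0.94
(r = 15), which is why the default cutoff is 0.7 rather than the 0.8+
one would pick for ideal geometry. Cells whose eroded core or masked
ring is empty, or whose ring mean is non-positive, are dropped and
reported (never imputed). On a spatially constant target field every
ratio is exactly 1; ratios are invariant to rescaling the target channel.

**Size/circularity cutoffs, smoothing and threshold rule are declared
choices**: they were tuned on the synthetic generator, are fully exposed
in `segmentation_params()`, and are echoed in every result object for
provenance. No claim is made that they reconstruct any particular
instrument's original settings.

## Synthetic plate images

`simulate_cell_image()` renders cells as filled nuclear disks (radius
6–9 px by default) with a 6-px cytosolic annulus, placed without nuclear
overlap by rejection sampling (hard attempt cap; infeasible packings
fail loudly rather than truncating). Exactly
`round(translocated_fraction × n_cells)` cells get nuclear target signal
at the positive level (default 5000 over a background of 100, i.e. 5:1
against the cytosol's 1000); the rest sit at parity. Gaussian read noise
(`noise_sd = 30`) is added last; with `noise_sd = 0` the image is
exactly its deterministic model, and a fixed seed gives bit-identical
output. Disks were chosen because the circularity of a digital disk is
predictable, which makes the filter testable; an elliptical option is
deliberately absent.

What the generator does *not* emulate: optics (PSF, illumination
gradients), chromatic crosstalk, out-of-focus cells, irregular nuclear
shapes, confluent monolayers and debris. Passing recovery tests
therefore demonstrate that the measurement logic is correct, not that
segmentation is robust on arbitrary real micrographs.

## Clamp and tracer arithmetic

**Steady state.** `detect_steady_state()` scans backwards from the end
of the trace for the latest window spanning ≥ 15 min in which the GIR
coefficient of variation is ≤ 0.05 and mean glycemia is within 0.5 mM of
the 6 mM target — a formalization of "GIR constant with only minor
deviations for 15–20 min". The thresholds are declared defaults; the CV
bound is dimensionless so it scales across GIR magnitudes.

**Turnover and EGP.** At isotopic steady state `Ra = F/SA` (infusion
rate over plasma specific activity); `EGP = Ra − GIR`, which reduces to
`EGP = Ra` at basal. Negative EGP is returned with a warning, not
clipped — a negative value is diagnostic, not a number to hide.

**Tissue uptake.** After a 2-DG bolus at steady state,
`Rg = C*_tissue / ∫₀ᵀ SA(t) dt`, with `SA(t)` the plasma tracer
concentration over plasma glucose and the integral taken by trapezoid on
the observed sampling grid (0, 2, 15, 25, 35 min). No curve is fitted and
no lumped constant applied by default (a user-supplied constant is
accepted); the estimate is therefore in 2-DG-equivalent units, which is
how between-group comparisons are made. Trapezoid integration of a
convex decay overestimates the integral and hence underestimates Rg; the
generator quantifies this bias directly (about 3% at the default
kinetics), which is well inside the 5% recovery band the tests enforce.

**Generator.** `simulate_tracer_curve()` draws plasma DPM from
`A₁e^(−k₁t) + A₂e^(−k₂t)` with defaults A₁ = 2×10⁵, k₁ = 0.2 min⁻¹
(fast mixing), A₂ = 6×10⁵, k₂ = 0.03 min⁻¹ (slow clearance) and 2%
multiplicative observation noise; tissue counts equal
`true_rg × ∫ SA dt` computed on a 0.005-min grid of the *noiseless*
curve (the fine-grid integral agrees with the analytic biexponential
integral to < 0.1%). `simulate_clamp_trace()` uses an exponential
approach of GIR to its plateau (`approach_rate = Inf` gives a constant
trace) with glycemia relaxing from 8.5 to 6 mM at the same rate. Default
plateau 36.3 mg/kg/min, matching the scale of insulin-resistant
high-fat-diet animals.

**AOC.** `aoc()` is the signed trapezoidal integral of the excursion
from each subject's own t = 0 value. The sign is retained (positive for
glucose-tolerance excursions, negative for insulin-tolerance drops),
and the statistic is invariant to adding a constant to curve and
baseline alike. Baselining per subject, not per group, was chosen
because it is the interpretation under which the statistic is a pure
within-subject excursion.

**ECAR metrics.** From a glycolytic stress test (glucose → oligomycin →
2-DG injections, three measurements per phase): glycolysis is
max(post-glucose) − last(baseline); capacity is max(post-oligomycin) −
last(baseline); reserve is their difference. Missing phases are an
error, not a zero.

## Mass and quantification arithmetic

Monoisotopic atomic masses are pinned constants (C exactly 12,
H 1.0078250319, O 15.9949146221, N 14.0030740052, S 31.97207069,
P 30.97376151 Da), so every mass is bit-stable. The formula grammar is
plain Hill strings — no isotopes, charges or parentheses — which covers
every formula the package targets.

The adduct convention mirrors how HRESIMS tables are printed: the
formula given *is the ion composition*, and the negative-mode m/z is its
plain mass (no electron correction) while the positive mode subtracts
one electron mass (0.000549 Da). This asymmetry is not physically
motivated but is what the printed calculated values encode; a
`physical = TRUE` flag applies the electron correction in both modes.
Rounding is half-up at 4 decimals for m/z and half-away-from-zero at
1 decimal for ppm (base R's `round()` is round-half-even and disagrees
at printed precision). Δppm is computed from 4-dp values because the
published arithmetic evidently rounds before dividing; published tables
are not always self-consistent on this point, so only self-consistent
anchors are asserted in tests.

External-standard quantification is ordinary least squares of peak area
on standard concentration (four standards spanning 50–400 µg/mL in the
motivating assay), inverted at the sample's area and expressed as % w/w
of the injected sample concentration; areas mapping outside the
calibrated range are flagged as extrapolated rather than refused.

## Dose translation

The human-equivalent-dose formula uses FDA body-surface-area Km factors
(human 37, mouse 3): a 10.5 mg/kg/day human intake maps to 129.5, and —
at the 10 mg/kg working granularity used for extract-level dosing — to
130 mg/kg/day in the mouse. Diet admixture is
`dose × body_weight / daily_intake` (a 30 g mouse eating 3 g/day needs
1.3 mg of compound per g of diet for 130 mg/kg/day). Fraction and
compound doses chain multiplicatively through their stated percentages
of the parent (extract → fraction → constituent); the stated
percentages are treated as given inputs, since the underlying
fractionation yields are not part of this package's scope.

## QC statistics

The Grubbs test is single-pass and two-sided by default:
`G = max|xᵢ − x̄|/s` against
`((n−1)/√n)·√(t²/(n−2+t²))`, `t` the upper `α/(2n)` t-quantile on n − 2
degrees of freedom. The critical values are verified against an
independent quantile routine (root-finding on the t CDF) to 1e−6 for
n = 3…30. Iterative removal is available behind a flag but warns that it
inflates the type-I error; whether to apply the screen per group or
pooled is the caller's decision — per-group, single-pass is the
documented default. ΔΔCt uses a single reference gene; passing the mean
Ct of several references gives the geometric-mean behaviour on the
expression scale. Omnibus tests (ANOVA and post-hocs) are deliberately
left to base R.

## Problem sizes and runtime

The test-suite and acceptance configurations use 20 synthetic plate
images of 200 cells (600×600 px) for translocation recovery, 50 seeded
tracer fixtures for Rg recovery, and 120-min clamp traces at 2.5-min
sampling — sizes chosen to match the motivating experiments (about
200–330 cells per field; 5 plasma samples over 35 min) while keeping a
full check runnable on a laptop in a couple of minutes.

## Known limitations

- Segmentation is classical (threshold + watershed); densely confluent
  or dim nuclei will need tuned parameters or a different segmenter, and
  no illumination correction is provided.
- Rg carries no lumped-constant correction by default, so absolute
  uptake rates are 2-DG-equivalents, comparable within but not across
  protocols.
- The steady-state detector assumes the trace ends while clamped; it
  scans from the end backwards.
- The Grubbs screen assumes approximate normality within a group and at
  most one outlier per pass.
- Formula parsing rejects isotopic labels and charge annotations by
  design.
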