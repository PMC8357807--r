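---
title: "Methods: colorimetric electron-uptake screening and electrochemical validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colorimetric electron-uptake screening and electrochemical validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macroscreen)
```

## The problem

*Shewanella oneidensis* can take up electrons from external donors
(extracellular electron uptake, EEU) as well as deposit them on
external acceptors. A genome-wide screen for EEU genes uses the redox
dye AHDS~red~ as a proxy electron donor: the reduced form is orange,
the oxidized form (AQDS~ox~) is clear, so a well of an arrayed mutant
library that oxidizes the dye fades from orange to clear over the
assay. Plates are photographed repeatedly; each photograph carries a
Code 128 barcode with two registration-mark discs so images can be
sorted by plate and every well associated with its mutant through the
collection catalog. Mutants that slow or eliminate dye oxidation with
either fumarate or nitrate as the terminal electron acceptor are the
screen's hits; a shortlist of hits with no satisfying functional
annotation is validated on electrodes by chronoamperometry (CA) and
cyclic voltammetry (CV).

This package implements that computational machinery end to end, plus
a synthetic-data generator that stands in for the laboratory's raw
images and potentiostat exports, which are not publicly deposited.
Every stage is therefore testable against planted ground truth.

## The yellow-intensity score

Well color is reduced to one number by projecting the RGB color
$\vec{C}$ onto the axis from the white reference
$\vec{W}_0 = (255, 255, 255)$ (a clear well) to the saturated yellow
reference $\vec{Y}_0 = (225, 153, 0)$:

$$y = \frac{(\vec{C} - \vec{W}_0) \cdot (\vec{Y}_0 - \vec{W}_0)}
           {|\vec{Y}_0 - \vec{W}_0|^2},$$

so $y = 1$ for a fully yellow well and $y = 0$ for a clear one. With
$\vec{Y}_0 - \vec{W}_0 = (-30, -102, -255)$ the blue channel carries
most of the signal (coefficient $255/76329$ per unit versus $30/76329$
for red), which matches the observation that nearly all information
about the dye's redox state sits in the blue channel. The score is
deliberately *not* clipped to $[0, 1]$: off-axis colors (stains,
condensation) can push it slightly outside, and clipping would hide
that as a QC signal.

```{r}
yellow_intensity(c(225, 153, 0))   # saturated yellow
yellow_intensity(c(255, 255, 255)) # clear
yellow_intensity(c(240, 204, 128)) # an intermediate color
```

The affine inverse `display_color()` reconstructs the well color for a
given intensity, which is how the 0–4 h colored-circle summary strips
are drawn and how synthetic wells are rendered; the two functions
round-trip to machine precision.

## Plate ingestion

`decode_plate()` scans image rows for a Code 128 pattern (set B, with
checksum) and retries after a 180° rotation if the upright pass fails,
so upside-down photographs are handled. The two registration marks are
localized by intensity-weighted center-of-mass in windows placed from
the decoded barcode span; the pair of mark centroids defines a
two-point similarity transform (rotation, scale, translation) from the
nominal plate frame to pixels, from which the 96 well centers are
predicted. `sample_wells()` then averages RGB over a disc at each
center. The disc radius defaults to 30% of the well pitch — the mean
well-center color is specified, but no radius, so the choice keeps the
disc well inside the rendered well while averaging over a hundred or
more pixels. Images whose barcode cannot be read are skipped and
logged, never interpolated: absence of data must not fabricate a
phenotype. Mirrored input (imaging through a 45° mirror) is not
corrected; input is assumed upright and unmirrored.

Timestamps come from a sidecar acquisition log (CSV of path and hours
since assay start) rather than image metadata, so synthetic fixtures
need no EXIF forgery.

## Growth-plate QC

Storage plates are imaged once to catch cross-contamination and growth
failures by comparison with the collection catalog. Turbidity is
scored as the Euclidean RGB distance from a blank-media reference.
When a plate has at least three catalogued-empty wells, the reference
color and threshold (blank mean + 3 SD, the conventional screening
default) are estimated from those wells; the estimate is bounded below
by 10 RGB units (blank wells are photometrically tight, so 3 SD alone
can fall under one count) and above by an absolute fallback of 60 (a
planted contamination inflates the blank SD, and the cap stops gross
growth from being hidden). Fully occupied plates use the configured
blank reference and the fallback threshold directly. Growth in a
catalogued-empty well is a `contamination` event; no growth in a
catalogued-occupied well is a `growth_failure` event, and such wells
are excluded from hit calling.

## Hit calling

For each mutant the replicate-mean intensity trace yields a
half-oxidation time t50: the first crossing of half its own dynamic
range, linearly interpolated between observations. The null comes from
the run's quasi-wild-type controls (transposon mutants carrying the
resistance cassette but no oxidation phenotype): a mutant is `slowed`
when its t50 exceeds the control mean by more than 3 control SDs,
`eliminated` when it never crosses within the observation window
(long-duration imaging, ≈40 h, makes this robust to late-time noise —
deliberately not a rate cutoff), and `normal` otherwise. Traces whose
dynamic range stays under 0.1 intensity units count as never declining.
No numeric slow/failed criterion is inherited from the assay itself;
control-referenced thresholds are the screening standard, and the
threshold multiplier, window and minimum-range are all exposed in the
configuration. Calls use replicate-mean behavior; per-replicate calls
are diagnostics only. At least eight control traces are required, or
calling refuses to run.

Hits from the fumarate and nitrate assays are partitioned by set
algebra into fumarate-only, nitrate-only and both; the three sets are
pairwise disjoint and their sizes sum to the distinct-hit total.
`triage_categories()` counts hits per annotated functional category,
with unannotated mutants flowing to the `unknown` bucket that forms
the electrochemical validation shortlist.

## Electrochemistry

**Chronoamperometry.** The steady-state current of a segment is the
arithmetic mean of its final 100 samples. The biological current is
the pre-inhibitor steady state minus the post-inhibitor steady state
(Antimycin A blocks the respiratory chain, leaving the abiotic
residual); with cathodic currents negative, cathode-active strains
give negative biological currents. A 60 s settling margin is excluded
on *both* sides of the addition — the stated convention excludes the
margin after the addition, but the pre-segment's final-100 window
would otherwise overlap the onset of the transition, so the symmetric
margin is applied to keep both windows at true steady state.

**Cyclic voltammetry.** Each scan is split into a forward
(+222 → −322 mV vs SHE) and reverse (−322 → +222 mV) branch inside the
analysis bounds (the full hardware scan is wider; the analysis window
is chosen to contain the wave and both are configurable). Per branch,
current vs potential is smoothed with a cubic smoothing spline —
`stats::smooth.spline` with `spar = 0.70`, the exact parameterization
named by the procedure — evaluated on a 1 mV grid, differentiated by
centered finite differences, and the potential of maximum derivative
magnitude taken as the branch inflection. The text's "maximum current
… from this approximate derivative" is read as the derivative-
magnitude maximum (the wave inflection): the raw-current maximum of a
sigmoidal wave always sits at a scan boundary and cannot yield a
midpoint. The midpoint potential is the mean of the two branch
inflections, which cancels symmetric forward/reverse hysteresis by
construction. A derivative peak within 5 mV of a bound flags
`edge_inflection` (truncated or absent wave) and no midpoint is
reported.

**Strain statistics.** Replicate biological currents (≥3 replicates
per strain, fewer are excluded with a warning) enter a one-factor
linear model; `car::Anova` supplies the type-II F test and
`stats::TukeyHSD` the honestly-significant-difference comparisons, of
which the contrasts against the reference (wild-type) strain are
reported. A strain is flagged as a reduced-uptake phenotype when its
adjusted p < 0.05 *and* its mean current magnitude is below the
reference. The model is fitted on the microampere scale — F and p are
scale-invariant, and ampere-scale residual sums of squares underflow
the fitting machinery's degeneracy checks.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
tested; it emulates:

- **Assay plates** (`render_plate_image()`): well discs colored
  `display_color(y(t))` under single-exponential kinetics
  `y(t) = y0 · exp(−k · max(0, t − lag))` — the simplest forward model
  producing the observed orange→clear trajectories, with a closed form
  for oracles. Defaults: normal and quasi-wild-type mutants
  k = 1.0 h⁻¹, planted slowed mutants k = 0.2 h⁻¹, eliminated and
  no-cell blanks k = 0, y0 = 1, lag = 0. Noise is i.i.d. Gaussian:
  per-well on the intensity scale (default sd 0.02) before color
  rendering, and per-pixel per-channel (default sd 2 counts, clipped
  to 0–255). Each plate carries a Code 128 barcode and two black
  registration discs; the whole plate is translated by a small random
  jitter so grid localization is genuinely exercised.
- **Growth plates** (`render_growth_plate()`): turbid vs clear wells
  with planted contamination/failure sets.
- **CA traces** (`simulate_ca_trace()`): exact baseline plateau, a
  half-cosine transition of width 6 × `step_sharpness` centered on the
  inhibitor time, exact abiotic plateau, additive Gaussian noise. The
  plateaus are exact by construction so the noiseless biological
  current is exactly baseline − abiotic.
- **CV scans** (`simulate_cv_scan()`): logistic sigmoid wave (default
  width 30 mV, comparable to a one-electron wave at room temperature)
  on a constant capacitive offset; with hysteresis h the forward
  inflection sits at E° − h/2 and the reverse at E° + h/2, so the
  branch mean recovers E° exactly. Default scan −322 to +222 mV in
  2 mV steps, noise 2% of the 5 µA amplitude in the noisy regime.
- **Screens** (`simulate_screen()`): 4 plates per acceptor, 4
  quasi-wild-type controls and 2 blanks per plate, 90 test mutants per
  plate, 16 planted hits (10 slowed + 6 eliminated), hourly imaging
  for 40 h, intensity noise 0.02. This draws intensity traces
  directly from the kinetic model; the image chain
  (render → decode → locate → sample → score) is validated separately
  by round-trip tests, so screen-scale recovery experiments do not pay
  for thousands of image renders.
- **Strain currents** (`simulate_strain_currents()`): Gaussian
  replicates around true strain means (default wild type −8 µA,
  mutants −0.5 to −2 µA, sd 0.5 µA, n = 4).

What the generator does *not* emulate — and what passing tests
therefore do not establish about real data — includes photographic
nonidealities (vignetting, exposure drift, specular highlights, white-
balance error; illumination is assumed ideal and constant since no
photographic calibration is specified), lens distortion, mirrored
optics, electrochemical double-layer physics, drifting capacitive
baselines, and non-exponential dye kinetics.

## Numerical choices and degenerate inputs

- t50 interpolation is linear between bracketing observations; ties
  (flat segment at the crossing) return the later endpoint.
- The oxidation-rate window is the [20%, 80%] band of the
  replicate-mean curve's own dynamic range; if a steep curve leaves
  fewer than two points in the band, the two points bracketing the
  half-range crossing are used instead. Flat traces (range < 0.1)
  report rate 0 with a `no_decline` flag rather than an error.
- `smooth.spline` requires ≥20 branch points inside the analysis
  bounds; non-monotone branch grids are a data error.
- The ANOVA/Tukey stage refuses fewer than two strains; identical
  groups give F = 0 and no flags.
- Determinism: every stochastic function takes a `seed` argument;
  identical spec + seed gives bit-identical output. The pipeline
  derives per-stage seeds from its master seed by a fixed affine map
  below 2³¹.

## Problem sizes used in the test suite

The suite runs planted-truth recovery at 4 plates × 20 seeds
(sensitivity/specificity of hit calling, pooled over seeds), 200 noisy
CV scans for midpoint RMSE, 500 noisy CA traces for biological-current
calibration, 1000 null simulations for the Tukey family-wise flag
rate, and image round-trips on single plates with randomized plate
identifiers and planted QC events. These sizes give stable Monte-Carlo
estimates (binomial SE under 1% at the asserted rates) while keeping
the suite fast.

## Known limitations

- Barcode decoding assumes horizontal barcodes (upright or rotated
  180°); arbitrary rotation would need a rectification step that the
  macroscope's fixed plate holder makes unnecessary.
- The growth/assay classifier is a color-distance threshold, not a
  segmentation; severe lighting gradients would need flat-field
  correction upstream.
- The two assay runs of a screen are assumed to share the collection's
  mutant identifiers; mutants present in only one assay are counted
  there with a warning.
- The 109-vs-108 discrepancy in explained-hit counts reported for the
  original screen is treated as data-dependent output; category counts
  here are whatever the annotation table yields.
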