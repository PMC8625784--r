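---
title: "Quantitative densitometry of photographed SDS-PAGE gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative densitometry of photographed SDS-PAGE gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelquant)
```

## The measurement problem

Polyacrylamide gel electrophoresis is usually read qualitatively: a band is
present or absent, darker or fainter. Yet Coomassie staining intensity is,
to good approximation, proportional to the amount of protein in a band, so
a photographed gel carries quantitative information — provided the
photograph is converted into something that can be integrated like a
chromatogram. gelquant implements that conversion and the downstream
quantitative analysis:

1. a photograph (PNG/TIFF/JPEG, 8- or 16-bit) is inverted into an
   optical-signal matrix (dark bands become large values),
2. illumination and background-staining gradients are flattened,
3. lanes are located and each lane becomes a **densitogram** — signal
   versus migration distance,
4. densitograms are baseline-corrected and band peaks are integrated to
   areas $S$ (arbitrary units $\times$ rows),
5. serial-dilution lanes on the *same gel* calibrate the
   quadratic-through-origin curve
   $$Q = a S^2 + b S,$$
   mapping area to protein mass $Q$ (µg),
6. a marker-ladder lane maps relative mobility $R_f$ to molecular weight
   through $\log_{10}(\mathrm{MW})$,
7. treated/control lane pairs yield the degradation degree
   $$\alpha = \frac{S_0 - S_t}{S_0} \times 100\,\%.$$

Every step is exposed as a plain function returning an S3 object, so the
pipeline can be run whole (`run_quantify()`, driven by a YAML config) or
piecewise.

## The calibration model

The calibration is a weighted least-squares fit of $Q = aS^2 + bS$ with no
intercept: zero area must mean zero protein. The quadratic term absorbs
the mild saturation of dye binding at high loads; for dilute lanes the
curve is effectively linear with slope $b$.

The weighting choice matters more than it may look. A twofold serial
dilution spans a 16-fold mass range; with unit weights the most
concentrated lane dominates the fit, and the relative error of the
faintest lanes can be large. The default `inverse_Q2` weighting minimises
*relative* residuals, giving every dilution level equal say. All three
schemes (`none`, `inverse_Q`, `inverse_Q2`) are available and the one used
is recorded in the model and the run log.

Calibration quality is summarised as `relative_deviation_pct`, defined
here as the mean absolute relative residual in percent (a `max` variant is
available). The solver uses QR on the weighted design matrix; the test
suite cross-checks it against an independently written normal-equations
solve.

Calibration and unknowns must come from one gel: background staining and
gel-concentration differences then cancel. `run_quantify()` refuses an
externally supplied calibration unless `allow_cross_gel: true` is set
explicitly.

```{r calibration-example}
pts <- data.frame(S = c(1288, 934, 763, 525, 348),
                  Q = c(2.0, 1.0, 0.5, 0.25, 0.125))
fit <- fit_calibration(pts)
fit
```

## Molecular weights

Band mobility is normalised as $R_f = \text{apex row} / \text{front row}$,
with the reference front (dye front or gel end) declared by the user — the
package deliberately does not guess it. Two ladder models are offered:
`loglinear` fits $\log_{10}(\mathrm{MW}) = \beta_0 + \beta_1 R_f$ globally;
`piecewise` (the default for reporting) interpolates $\log_{10}(\mathrm{MW})$
linearly between neighbouring anchors and reproduces every anchor exactly,
which is preferable because real ladders are only locally log-linear.
Queries outside the anchor range extend the end segment and are flagged
`extrapolated` in reports.

## Degradation degree

$\alpha$ compares the *native-protein band* before and after treatment.
Being a ratio of areas it is unit-free — any common rescaling of the two
areas cancels — so it can be compared across gels even though areas
themselves cannot. In the pipeline, $S_t$ is integrated over the control
lane's native-band row interval, because after aggressive treatment the
native band may no longer be detectable on its own; diffuse degradation
products are quantified only through explicitly declared integration
regions (`regions:` in the config), never by automatic peak picking,
which is unreliable on smears. `St > S0` gives a negative $\alpha$ with a
warning (apparent gain), not an error.

## Numerical choices

**Inversion.** `signal = white_reference − luminance`, clipped at zero,
with the modal luminance (the unstained background) as the default white
reference. The linear difference — not optical density — is the default
because the quantification premise is direct proportionality between
staining intensity and protein mass; an OD mode (`mode = "od"`) is
provided. Colour collapses to Rec. 601 luma. Note one corner case: under
a strong illumination gradient the modal reference clips background
brighter than the mode, so for such photographs pass a white reference at
the brightest background level. Similarly, with a synthetic background
exactly at the white reference, sensor noise clips asymmetrically and
lifts the off-band background by about $1.3\sigma_{\text{noise}}$; on
real gels nonzero background staining hides this.

**Background flattening** is a per-column moving low-quantile filter
(default: 10th percentile, window 25% of the gel height). A centred
moving quantile of a trending background is biased by
$(q-0.5)\cdot\text{window}\cdot\text{slope}$, which at the default window
is ~10% of the gradient range — far too much. Instead each window
contributes a knot at the *actual row* of its low order statistic; on any
monotone background that knot lies exactly on the background curve.
Band rows are first masked against a rolling-minimum floor so that a
window whose low-value end happens to align with a band flank cannot
absorb the flank into its quantile. The result removes smooth gradients
essentially exactly while preserving band integrals.

**Lane detection** thresholds at 20% of the 95th percentile of the
column-mean profile — after subtracting the profile's robust floor and
log-compressing it. The compression is what makes a *fixed relative*
threshold work on a 16-fold dilution series, where the faintest lane is
~6% of the brightest on the raw scale. Run edges are refined on the raw
profile (smoothing otherwise spills lane intervals into background
columns, diluting the width-averaged densitogram), runs much narrower
than the widest are discarded as noise blips, and touching lanes are
split at an interior minimum only if it dips below 70% of the lower
flanking maximum. Explicit lane geometry in the run config always
overrides detection.

**Baseline correction.** `valley_chords` is the classical chromatographic
valley-to-valley baseline: straight chords between local minima of a
lightly smoothed profile (knot levels taken from the smoothed profile, so
chords are not pinned to noise minima). `smooth_floor` iteratively clips
the profile to a local-linear smooth of itself and then bridges detected
band supports by interpolation; it is the more robust choice for crowded
lanes whose valleys never return to the floor.

**Peak detection and integration.** Local maxima qualify by height *and*
topographic prominence (both at 5% of the profile maximum by default);
prominence suppresses noise ripple on band flanks. Bounds are
valley-to-valley: the deepest minimum between adjacent peaks, or on outer
flanks the first local minimum after the profile falls below 5% of peak
height. Plateau apexes take the earliest row. Areas are trapezoidal
integrals of the piecewise-linear interpolant over half-open `[start,
end)` row intervals — exact for piecewise-linear profiles and exactly
additive over partitions. Minimum peak width is 3 rows. Peaks whose
support contains more than 1% saturated source pixels are flagged
`saturated` and never silently quantified. Indices are 1-based
throughout, the R convention.

## The synthetic gel generator

All validation runs on synthetic gels with exact ground truth, generated
by `make_calibration_gel()` / `make_degradation_gel()` /
`render_gel()`. Bands are Gaussian along migration and uniform across the
lane width, so each band deposits exactly `mass_ug * response` units of
densitogram area before noise; centres follow the mobility law
$R_f = \beta_0 + \beta_1 \log_{10}(\mathrm{MW})$; the image gets a planar
illumination gradient, additive Gaussian sensor noise (applied before
quantisation), inversion to dark-bands-on-light, and 8- or 16-bit
quantisation. Rendering is bit-exact reproducible for a fixed seed.

Defaults emulate the study conditions of the underlying workflow: a
twofold serial dilution from 0.2 mg/mL × 10 µL (masses 2.0 … 0.125 µg),
a 14.4–116 kDa unstained marker lane (the intermediate masses 85, 66.2,
45, 35, 25, 18.4 kDa are a conventional ladder composition and are
configurable), band sharpness σ = 4 rows on a 420-row gel, and a
degradation series that retains a fraction of the native band and
redistributes the remainder into a broad (σ = 45 rows) smear of smaller
fragments, conserving each lane's deposited mass exactly. The
degradation gel's noise is parameterised by SNR — native control-band
amplitude over noise sd — with default 50.

What the generator does *not* emulate: perspective/keystone distortion,
gel texture and cracks, lane curvature ("smiling"), Poisson shot noise,
and cross-lane smearing. Passing tests therefore demonstrate correctness
of the mathematics and robustness to noise, gradients and dilution range
— not robustness to a badly photographed or physically distorted gel;
inputs are assumed approximately rectified.

## Validation scale

The test suite and acceptance checks run on 420×~320 synthetic gels
(five to ten lanes), 25 seeds for the end-to-end degradation recovery
(fractions 0.8/0.5/0.2/0.08 at SNR 50, median $\alpha$ error within ±3
percentage points) and 100 seeds for the noisy single-peak area
recovery (median within 3% at SNR 50) — sizes chosen as representative
of a typical gel photograph's useful resolution along the migration
axis.

## Known limitations

- Overlapping peaks are split at the valley; no Gaussian deconvolution.
- No uncertainty propagation from calibration-point scatter into
  confidence intervals on predicted masses.
- No 2-D gel support, no western-blot chemiluminescence model.
- The quadratic calibration is monotone only for $a, b \ge 0$; fits on
  pathological data can return a negative quadratic term, which the
  inversion refuses.

## A complete run

```{r pipeline, eval = FALSE}
spec <- make_calibration_gel(noise_sd = 0.002, seed = 3,
                             unknown_mass_ug = 0.7)
render_gel(spec, path = "gel.tif")

config <- list(
  image = "gel.tif",
  lanes = lapply(seq_len(nrow(spec$lanes)), function(i) {
    l <- as.list(spec$lanes[i, ])
    if (l$role == "calibration")
      l$mass_ug <- spec$bands$mass_ug[spec$bands$lane_id == l$lane_id][1]
    l
  }),
  marker_mws = c(116, 85, 66.2, 45, 35, 25, 18.4, 14.4),
  front_row = spec$front_row)

res <- run_quantify(config, output_dir = "reports")
res$report
```
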