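---
title: "Measuring stem density, diameter and biovolume from post-harvest imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring stem density, diameter and biovolume from post-harvest imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

At harvest, the combine leaves cereal stems cut a few centimetres above the
ground. Seen from directly above at submillimetric ground resolution, each
stem tip is a bright annulus: the stem wall reflects strongly, while the
hollow lumen and the surrounding soil are darker. Because nearly every stem
at maturity bears an ear, counting these cross sections per unit ground area
estimates ear density; measuring their diameters gives access to basal area
and, combined with plant height, to biovolume — a structural proxy for
above-ground biomass (AGB).

`stemscan` implements everything from "boxes in an image" to "plot traits
and their evaluation". The detector itself is deliberately replaceable: the
trained CNN weights used in large field campaigns are not a reproducible
desk-scale object, but every computation around them is. The package
therefore accepts external detections through a CSV/JSON interface and ships
a classical matched-filter ring detector with the same output contract.

## Detection post-processing

Images are tiled into `patch_size` × `patch_size` patches (default 1000 px)
with 50% overlap, so stems cut by one patch border lie in the interior of a
neighbour. Anchors advance by `stride = patch_size (1 − overlap)`; a final
anchor is clamped to the image edge rather than padding, so no synthetic
border content is ever created.

Overlapping patches detect border stems twice. Two boxes are considered the
same stem when their *overlap fraction* — intersection area over the
**smaller** of the two areas — reaches 0.75. The min-area denominator is
chosen so that a detection nested inside another (the typical cross-patch
duplicate geometry) scores exactly 1 regardless of the size difference; IOU
would dilute that signal by the size ratio. Elimination is greedy in
score-descending order, keeping the higher-score member of every conflicting
pair (ties broken lexicographically on position, which makes the operation
deterministic and idempotent). Finally, boxes with confidence below 0.80 are
discarded; the threshold is inclusive (`score >= 0.80` survives) because the
operating convention discards scores *smaller than* the cut. Whether the
score cut runs before or after duplicate elimination is in principle open;
the package merges first (the default), because a high-scoring duplicate
should suppress its low-scoring twin before that twin is dropped silently —
but the order is a flag (`filter_first`) for users who want the alternative.

## The reference ring detector

Stems are identified by relative brightness, not colour, so detection
operates on the luma channel. The detector correlates the image with
zero-mean annulus templates (a radial Gaussian ridge of width
`ring_sigma = 1.5` px at radius `R`) over a geometric grid of radii spanning
`radius_min`–`radius_max` (defaults 2.5–12 px, ratio 1.22 between
consecutive radii, so the best-matching template is always within ~10% of
the true ring radius). Zero-mean normalized cross-correlation (ZNCC) makes
the response invariant to global gain and offset; the FFT computes the
numerator and integral images the local moments, so a 1000 × 1000 patch
costs a handful of FFTs per radius. Local 3 × 3 correlation maxima above a
floor become candidates; each is emitted as a square box of side
`2 R (1 + margin)` (margin 25%, so the diameter profiles see background on
both sides of the wall), with score `(correlation + 1)/2`, and candidates
are reduced by greedy non-maximum suppression at IOU 0.2.

The default score floor is 0.7 (correlation 0.4). Partial-arc responses —
small templates locking onto a segment of a larger ring — peak near
correlation 0.25, while genuine rings exceed 0.6 even under heavy noise, so
0.7 separates the two regimes while still emitting sub-0.80 candidates for
score-distribution studies. The final 0.80 pipeline cut is a separate,
downstream decision.

## Diameter from gray-value profiles

Gray conversion uses the fixed linear combination
`V = 0.2989 R + 0.5870 G + 0.1140 B`, unrounded. Profiles are sampled by
bilinear interpolation every 0.5 px along the four compass directions (0°,
45°, 90°, 135°) through the box center, clipped to the box. The stem wall
produces one intensity maximum on each side of the center; the diameter is
their separation. Design details that matter in practice:

* **Side-split maxima.** The two borders are found as the per-side maxima,
  not the two global maxima of the profile: under clutter the two largest
  values can fall on the same side, which would produce a nonsense
  "diameter". Ties within a side are broken toward the center.
* **Invalidity as a return state.** A direction is invalid when its maximum
  sits at a profile endpoint (the border was truncated by the box) or when a
  side is flat (no border at all). A stem measurement is valid when at least
  two directions survive and the mean lies strictly inside `(0, box
  diagonal)`. Averaging over however many of the four directions survive is
  the package's choice; requiring all four would discard every stem near a
  patch border.
* **Sub-sample refinement.** The discrete peak is refined by a parabola
  through the three samples around it (offset clamped to ±½ step). On
  rendered annuli this brings the per-direction error well under half a
  pixel.
* **No smoothing by default.** Profile smoothing (Gaussian, sigma in
  samples) is exposed for noisy imagery but off by default: smoothing
  slightly biases peak separation inward, and the matched-filter detector
  already rejects most noise-born candidates.

The synthetic truth for a diameter is the *ring-center* diameter — the
distance between the intensity maxima of the rendered wall — not the outer
edge of the stem. Users calibrating against callipers should expect the
profile method to track the mid-wall circle for the same reason.

## Plot traits

Stem density is count over sampled area; the sampled area of the standard
field protocol is `n_samples × rows_per_sample × row_spacing × length`
(three samples of two 1.0 m rows at 0.17 m spacing give 1.02 m²). Basal
area is the **mean of per-stem section areas** times density — not the
section area of the mean diameter — so the spread of the diameter
distribution contributes (by Jensen's inequality the distinction is never
negative). Biovolume is basal area times height; heights are accepted in
metres. All traits are computed in SI units (m²/m², m³/m²) from diameters
in mm; the unit conversions commute to < 1e-12 relative error, which the
tests assert.

Per-plot diameters are fitted by maximum likelihood to both a gamma and a
normal law (`fitdistrplus`). The goodness-of-fit p-value of each family
comes from a one-sample Kolmogorov–Smirnov test against the fitted law —
the same procedure for both families, so the comparison is like-for-like
and the well-known optimism of KS with estimated parameters cancels in the
comparison; the family with the larger p-value is selected. Diameters are
fitted in millimetres. Fits require at least 10 positive finite values; a
constant vector is a degenerate error, not a fit.

## Evaluation statistics

Matching uses greedy score-descending assignment: each detection claims the
unmatched labeled box of highest IOU, provided IOU is **strictly** greater
than the 0.5 threshold (ties broken by larger IOU). Greedy matching can in
principle fall below the optimal assignment; the tests compare it against
an exhaustive oracle on small scenes and require agreement on the vast
majority of random instances.

The bias statistic is implemented as `1 − recall/precision`. The
alternative `1 − precision/recall` form is available behind
`convention = "inverse"`; the default is the form consistent with the
published operating points this statistic is meant to summarize (precision
0.95 / recall 0.97 giving −0.02), and its sign is interpretable: negative
exactly when recall exceeds precision, i.e. when the detector over-reports.

Agreement metrics regress the reference on the estimate by OLS (slope,
intercept, R²); RMSE is the root mean squared difference of the two series
and RRMSE divides by the mean of the *reference* values, in percent. R² is
taken from the OLS fit rather than as a squared correlation; on these data
the two are numerically close, and the OLS form pairs naturally with the
reported slope and intercept.

Leave-one-out cross-validation refits the linear model n times, predicting
each held-out plot. Since single-observation folds have no per-fold R², all
metrics are computed over the pooled out-of-fold predictions: R² from OLS
of observed on predicted, RMSE of the predictions, RRMSE against the mean
observed response. This is the natural reading of "averaged
cross-validation metrics" when every fold holds one plot.

Broad-sense heritability uses the one-way random-effects decomposition:
`Ve` is the within-genotype mean square, `Vg = (MS_between − MS_within)/r̄`
clipped at zero, with `r̄` the harmonic mean of the replicate counts — the
standard divisor under unbalanced replication (here 6–15 replicates per
genotype). `H² = Vg/(Vg+Ve)` is then the repeatability of a single-plot
observation. The estimator is invariant to shifting the trait by a constant
and to rescaling, which the tests assert. A REML mixed-model estimate is a
deliberate non-goal; for a single-site, single-factor design the ANOVA
estimator is transparent and adequate.

## What the synthetic generator does and does not emulate

`render_scene()` emulates the acquisition the package targets: ground
resolution 0.12–0.18 mm/px (default 0.18), rows 0.17 m apart, stem
diameters gamma(shape 6, scale 0.35) mm — mean 2.1 mm — and densities of a
few hundred stems/m². The scene footprint (default 1000 × 950 px ≈
0.031 m²) is sized so that one crop row crosses the default image and the
stem count per scene stays in the tens; the per-row linear density
`density × row_spacing` then reproduces the specified areal density
exactly, and the rendered count is `round(density × area)` by
construction. The diameter law is truncated below 1.0 mm (the sub-millimetre
tail, ~0.4% of draws, is resampled): cut cereal stems that thin do not
occur, and at ~0.2 mm/px such an object would span two pixels — below any
meaningful resolution limit.

Rings are drawn as a radial Gaussian ridge
(`background + contrast · exp(−(r−R)²/2σ²)`) with the lumen lifted slightly
above the background, matching the observed profile shape (bright wall,
darker lumen and soil). Straw clutter is rendered as bright line segments;
occluded stems are buried under wide streaks and flagged in the truth
table. Scenes are bit-identical per seed, and generation restores the
global RNG stream.

The generator does **not** emulate: inclined or deformed stems (profiles of
an elliptical section are measured, but no deprojection is attempted),
lodging, variable illumination across a scene, JPEG artefacts, or
photorealistic soil texture. Passing the synthetic suites therefore
demonstrates the correctness of the geometry, measurement and statistics —
not field-grade detector robustness, which belongs to whatever detector the
user brings.

`generate_trial()` draws plot trait values as `mean + g_i + e` with
genotypic and residual variances set by the designed heritability (default
0.8, 16 genotypes, 6–15 replicates), builds basal area and biovolume from
the traits, sets AGB proportional to biovolume with 6% multiplicative noise
(`beta_agb = 8.5e5` g/m² per m³/m², placing AGB near 1000 g/m²), and adds a
small zero-mean discrepancy between ear and stem density.

## Numerical choices and degenerate inputs

* Boxes are 0-based, half-open, origin top-left — the dominant imaging
  convention; degenerate (zero-area) boxes are rejected everywhere with an
  error rather than propagating NaN ratios.
* Pixel (i, j) has its center at (i + 0.5, j + 0.5); bilinear samples are
  clamped to the outermost pixel centers.
* ZNCC returns 0 where the local window variance is below 1e-8 (flat
  regions carry no evidence either way), and −Inf outside the valid region
  so border artefacts cannot become candidates.
* `fitdistrplus::fitdist` performs the gamma MLE (moment-based starts);
  KS p-values are taken as computed, ties warnings suppressed.
* Precision/recall with an empty denominator is an error naming the empty
  side, not a silent 0/0.

## Problem sizes used by the test suite

The suites run on sizes chosen to make every statistical check sharp yet
quick on a single CPU: 20 rendered scenes per noise condition (~15 stems
each) for end-to-end recovery, 500 single annuli spanning radii 5–15 px for
diameter accuracy, 100 plots of 300 stems for family selection, 200
simulated trials for heritability recovery, and 1000 random box pairs plus
exhaustive matching oracles on ≤ 8-box scenes for the geometry. The whole
suite completes in a few minutes.

## Known limitations

* The profile method measures the mid-wall diameter; systematic offsets to
  calliper measurements of the outer diameter are expected and must be
  calibrated by the user.
* Greedy duplicate elimination and greedy matching are order-dependent by
  design; both are deterministic, but neither is guaranteed optimal on
  pathological overlap chains.
* Heritability assumes a single-site, one-factor random-effects design;
  spatial field trends and genotype × environment structure are out of
  scope.
* The ring detector assumes approximately circular, unoccluded cross
  sections on a darker background. It is a reference implementation for
  validating the pipeline, not a replacement for a trained detector on real
  field imagery.
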