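---
title: "Methods: models, parameters and design choices in strokeflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in strokeflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokeflow)
```

strokeflow implements the quantitative readouts of a mouse
stroke-microcirculation experiment: laser speckle contrast imaging (LSCI)
flowmetry, rule-based detection of pericyte-associated capillary
constrictions with stereological densities, peri-microvascular stain
densitometry, edema-corrected infarct volumetry, tail-cuff systolic blood
pressure extraction, and the nonparametric statistics that accompany such
studies. Every input the pipeline consumes can be produced by a seeded
synthetic generator with known ground truth, so each stage is testable
against planted truth rather than against unavailable tissue data. This
vignette documents the models, the tunable parameters, and the design
choices made where the underlying procedures left the details open.

## Laser speckle flowmetry

### Forward model

A time-integrated speckle pattern recorded with camera exposure time $T$
over a field decorrelating with correlation time $\tau_c$ has spatial
contrast $K = \sigma / \mu$ over a small window, with

$$K^2(x) = \beta \, \frac{e^{-2x} - 1 + 2x}{2 x^2}, \qquad x = T/\tau_c,$$

where $\beta \in (0, 1]$ is the optical coherence factor. $K$ falls
monotonically from $\sqrt{\beta}$ (static scatterers) toward $0$ (fast
flow), and for $x \ge 100$ the model is within 2% of the asymptote
$K^2 \approx \beta / x$. The inverse correlation time ICT $= 1/\tau_c =
x/T$ is taken as proportional to blood flow speed, so flow is always
reported relative to a baseline, never in absolute perfusion units.

`contrast_to_ict()` inverts the full nonlinear model (grid-seeded Newton
iteration; round-trip relative error below $10^{-6}$ across
$x \in [10^{-3}, 10^{3}]$, asserted in the tests) rather than the crude
$1/(T K^2)$ approximation; the approximation is contained in the model as
its large-$x$ limit. Contrast at or above $\sqrt\beta$ — static tissue, or
noise pushing past the model ceiling — is clamped to ICT $0$ and counted.

### Pipeline and parameters

* `spatial_contrast(stack, window)` — $K$ per pixel per frame.
  **window** (px, odd): default **7**, common LSCI practice; the
  procedure's source left it unstated. $\sigma$ uses the population form
  (denominator $N$); borders use the truncated window; zero-mean pixels
  are invalid (`NA`).
* `contrast_to_ict(contrast, exposure, beta)` — **exposure** 5 ms (the
  study's camera setting); **beta** defaults to **1** because the
  original optical train is uncharacterized; it is configurable
  everywhere.
* `baseline_map(series, start, n = 10)` — mean of the 10 frames
  immediately preceding ischemia onset, matching the study's baseline
  construction.
* `relative_cbf_series()`, `epoch_mean_change()` — each ICT frame is
  divided by the baseline image first, then ratios are averaged over the
  epoch (division before temporal averaging; the original order is
  unstated, and for the step-flow scenes used here the two orders agree).
  Percent change is $100(\bar r - 1)$, bounded below by $-100$ for
  non-negative flow.
* `roi_mean_change()` — ROI mean and standard error (sd with $n-1$ over
  $\sqrt n$) over valid pixels; pixels with zero baseline ICT are
  excluded rather than treated as $-100\%$, and fully invalid ROIs are
  flagged, never silently zeroed.
* `pseudocolor_map()` — symmetric diverging map, white at 0, clipped at
  $\pm$`clip` percent (default 100, matching the figure convention of 0
  to $\pm 100\%$); invalid pixels render dark gray.

No motion or z-drift registration is implemented: drift is acknowledged
in the experimental description but no correction is specified, so none
is invented.

### What the speckle generator emulates

`gen_speckle_stack()` draws frames $\mu (1 + K \cdot Z)$, where $K$ is the
forward-model contrast at each pixel's epoch-scaled true ICT and $Z$ is a
zero-mean, unit-variance noise texture built as a random permutation of
the standardized exponential quantile multiset, tiled with period equal to
the analysis window and a random toroidal shift. Because every window of
that size contains exactly one full period, the window statistics are
exact: the measured contrast equals the target at every interior pixel,
and the ICT round-trip is limited only by border effects. This is a
variance-matched statistical emulation chosen because the pipeline
consumes only contrast statistics; it is **not** coherent speckle. Real
speckle adds spatially correlated grain, camera noise, vessel-vs-
parenchyma texture and drift, so passing these tests validates the
algebra and the inversion, not robustness to those artifacts. An earlier
construction (pointwise local standardization of i.i.d. gamma noise) was
rejected because iterating it inflates window variance and the inversion's
nonlinearity turns residual contrast noise into a percent-level ICT bias.

Problem sizes: flowmetry tests use 96–110 px square scenes with 14
frames (10 baseline + 4 occlusion at flow factor 0.3), giving ROIs of
more than 500 valid pixels and interior fields of more than $10^4$ pixels
for the round-trip checks.

## Vessel morphometry and constriction detection

### Geometry conventions

Images are 2-D projections standing in for the study's 40-µm z-stacks;
z-collapse is a documented simplification. Pixel centers sit at
$(i - 0.5) \cdot \text{pixel\_size}$ µm so that raster masks, skeleton
points and truth records share one coordinate frame.

### Segmentation

`segment_vessels()` thresholds the background-subtracted vessel channel.
Tubes are rendered (and assumed) with a Gaussian cross-section whose full
width at half maximum equals the nominal diameter, so the default
threshold is background + half the background-corrected peak: half-
maximum thresholding is what makes the mask width equal the FWHM
diameter. A `mean + k sd` mode (default $k = 2$) is kept for images
without a defined amplitude, but it lands far from the half maximum on
Gaussian tubes and inflates diameters, so it is not the default.
Connected components under 10 px are removed. With `supersample = 2` the
intensity image is bilinearly upsampled before thresholding; the mask
boundary then resolves below the acquisition pixel, which halves the
quantization step of the diameter estimator — the noise-robustness
figures below use this setting.

### Skeleton graph and diameters

`build_vessel_graph()` thins the mask to a 1-px skeleton (Zhang–Suen;
implemented here because no installed package provides 2-D
skeletonization), annotates every skeleton pixel with the local diameter
from the Euclidean distance transform, and traces edges between endpoint
and junction nodes. Two numerical choices matter:

* **Diameter** $= (2\,\mathrm{EDT} - 0.5) \cdot \text{pixel\_size}$. At
  the centerline of a $w$-px tube the EDT is $(w+1)/2$ for odd $w$ and
  $w/2$ for even $w$; the half-pixel term centers the estimator's bias at
  $\pm 0.5$ px instead of the one-sided $0..+1$ px of the raw $2\,
  \mathrm{EDT}$. Measured bias on noiseless 3–12 µm tubes is 0.25 µm or
  less.
* **Junction clustering**: thinning can split one anatomical branch point
  into several nearby branch pixels inside a wide lumen, so branch pixels
  within one local vessel radius merge into a single junction node, and
  short connector chains inside a merged junction are not emitted as
  edges.

### The constriction rule

`detect_constrictions()` implements the counting rule: an event is a
focal narrowing of **more than 20%** relative to the flanking vessel
segment, counted on capillaries of diameter **below 9 µm**, optionally
associated with a mural-cell (pericyte) soma within **10 µm**
(`associate_constrictions()`). Open details were resolved as follows:

* The diameter profile along each edge is median-smoothed over 3 µm;
  local minima are candidates.
* The reference diameter is the **larger** of the median diameters over
  the two flanking windows 5–15 µm away from the minimum; "upstream
  and/or downstream" is read as OR, so the event fires if the narrowing
  exceeds the threshold against either flank.
* The 9-µm capillary gate applies to the **reference** (parent-segment)
  diameter, not the constricted minimum: the rule describes the vessel,
  not the dip.
* Minima closer than 10 µm merge, keeping the deepest; edges shorter than
  the flanking geometry are skipped and counted.
* The source procedure contains a contradictory sentence about excluding
  constrictions near somata; association is therefore an *annotation*,
  and `disector_density(associated_only = )` selects the counted subset
  (default `TRUE`, matching pericyte-associated counts).
* Soma distance is centroid-to-event (boundary-to-event is unstated).

For noisy images (the benchmark uses additive Gaussian noise at SNR 10),
Gaussian pre-smoothing with $\sigma = 3$ px before segmentation is the
recommended and benchmark-default setting: the diameter profile minimum is
an extreme-value statistic, so unsmoothed boundary noise systematically
deepens measured narrowings; $\sigma = 3$ px suppresses that inflation
while a planted 30% narrowing remains well above threshold. The
15%-narrowing false-positive specification is the binding constraint
here, and this setting was selected on seed blocks disjoint from the ones
the test suite and acceptance script use.

### Stereology

`disector_frames()` builds the 240 × 160 µm (0.0384 mm²) counting
frames, 40 µm deep; 100 frames give the 3.84 mm² evaluated area per
hemisphere, and a 5 mm anteroposterior extent cut at 50 µm yields 100
serial sections. Counting uses the unbiased-frame edge rule (left/top
edges count, right/bottom do not — the source states no forbidden lines),
which makes densities invariant to tiling a frame into adjacent halves.
Densities are counts per mm² of evaluated frame area, independent of the
total area sampled. `marker_coverage()` scores a skeleton point
marker-positive when thresholded marker signal occupies at least half of
the vessel-mask pixels within one local diameter of the point; the
mask-restriction keeps tube ends and partial-coverage boundaries
unbiased.

The vessel-scene generator plants straight horizontal tubes (5–7 µm
baseline diameter unless specified), Gaussian focal dips of given
fractions (3 µm axial sigma), and soma blobs adjacent to constrictions
(4 µm perpendicular offset) or far from them; it does not emulate
tortuosity, crossings, depth attenuation, or labeling heterogeneity, so
the detection benchmark validates the rule logic and noise robustness,
not performance on real confocal stacks.

## Peri-microvascular stain quantification

`intensity_fold()` proportions the mean brightfield intensity over the
vessel region to the mean background intensity. Defaults: the measurement
region is the vessel mask itself (ring width 0 — intensity is measured
"over the vessels"; a positive ring is available for halo analyses), and
the background is the image outside a 10 µm guard dilation of all
vessels. Chromogenic stains usually darken the brightfield, so polarity
is an explicit flag, never inferred: under `"decrease"` the fold is
background over region, so a fold above 1 always means more stain. The
fold is invariant to global illumination scaling by construction.
`semiquant_scale()` bins folds onto the study-style scales (0–6 by 1, or
0–1 by 0.2) by nearest multiple with half-up ties — the scale itself is
prescribed, the assignment rule is this package's choice.

## Infarct volumetry

Edema-corrected (Swanson) infarct area is contralateral hemisphere area
minus non-infarcted ipsilateral area; because vasogenic edema swells the
infarcted tissue, not the surviving tissue, the subtraction cancels the
edema term exactly — the generator plants the inflation only in the
infarcted compartment and the invariance is asserted noiselessly. Volume
is the sum of adjusted areas times the 0.5 mm inter-section spacing. The
source text multiplies by "the total distance of 5 mm", which is
dimensionally inconsistent for 10 sections; for the study's uniform
sampling the two rules coincide (mean area × 5 mm), and the per-spacing
sum is implemented as the evident intent. The ellipsoid-lesion generator
samples a parabolic area profile at slab midpoints, for which the
midpoint-rule volume error is $1/(2n^2)$ — about 0.5% at 10 sections,
comfortably within the 10% recovery check. Infarct delineation from
images is out of scope: areas enter as tables.

## Tail-cuff systolic pressure

`gen_cuff_trace()` produces one inflation–deflation cycle (default: 5 s
baseline, 5 mmHg/s ramps to 150 mmHg, 20 Hz sampling) with flow collapsing
to 2% of baseline while cuff pressure is at or above the true systolic
value, plus Gaussian flow noise. `systolic_from_trace()` smooths flow
with a 0.5 s moving average, takes "interrupted" as flow below 10% of the
pre-inflation baseline (both configurable; the source does not define
interruption), and reports the pressure at the first suppressed up-ramp
sample, the pressure at the last suppressed down-ramp sample, and their
mean as systolic. The smoothing delays both crossings in the same
direction along time — later on the rising ramp (reading high), later on
the falling ramp (reading low) — so the mean cancels the smoothing bias
to first order; the residual bias is under 1 mmHg at the default settings
and the cutoff-as-fraction rule makes everything invariant to flow-scale
changes. A session helper averages repeated cycles, as in the study's
two-measurements protocol.

## Statistics

All group comparisons are nonparametric, as in the source workflow; a
Shapiro–Wilk gate (`normality_gate()`) documents the routing decision but
no parametric branch is provided. Two-sided p values throughout; no
multiple-testing correction is applied (none was in the source) — apply
`p.adjust()` externally if desired.

* `mwu_test()` — exact mode enumerates all $\binom{m+n}{m}$ group
  assignments (valid under ties; $m + n \le 12$) and doubles the smaller
  tail, capped at 1; asymptotic mode uses the tie-corrected normal
  approximation without continuity correction. Because the exact null is
  discrete, the attainable size at $\alpha = 0.05$ for $n = 5$ vs 5 is
  $8/252 \approx 0.032$ (rejection iff $U \le 2$), not 0.05 — the test
  suite asserts the simulated null rejection rate against this enumerated
  value.
* `wilcoxon_signed()` — zero differences removed; exact enumeration of
  the $2^n$ sign patterns of the observed midranks for $n \le 12$.
* `kruskal_wallis()` — tie-corrected $H$ with $\chi^2_{k-1}$ p value;
  for `[1,2], [3,4], [5,6]` the rank formula gives $H = 32/7 = 4.5714$,
  cross-checked against `kruskal.test()`.
* `pearson_regression()` — product–moment $R$, $R^2$, OLS line, t-based
  p; the identity $R^2 = R \cdot R$ holds to machine precision.
* `superplot_summary()` — group median and Q1–Q3 using type-7 (linear
  interpolation) quantiles — stated because quartile values depend on the
  convention — plus per-animal medians so animal-level replicates remain
  distinguishable from section-level measurements; the unit of analysis
  is the caller's choice.

Published two-group comparisons at $n = 3$ per group reporting
$U = 0, p = 0.025$ are not reproducible by exact enumeration (the minimum
two-sided p for 3 vs 3 is 0.1); this package reproduces the procedures,
not those printed p values.

## Known limitations

* 2-D projections, straight synthetic vessels, and statistical (not
  coherent) speckle: results on real stacks will degrade in ways these
  fixtures cannot reveal.
* Diameters come from binary masks via the EDT; sub-resolution vessels
  (under ~3 px after supersampling) quantize visibly.
* The tail-cuff extractor assumes a single clean inflation–deflation
  cycle with an estimable pre-inflation baseline.
* Exact tests are limited to small samples by enumeration cost; larger
  samples switch to tie-corrected normal approximations.
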