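---
title: "Methods: apical tone-mapping enhancement and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: apical tone-mapping enhancement and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvtdm)
```

## The problem and the model

Left ventricular thrombus typically forms at an akinetic apex. On B-mode
echocardiography a fresh thrombus is a low-to-mid echogenic mass sitting in
a nearly anechoic (black) blood pool; when the apical window is poor, the
few gray levels separating the two are easily lost in clutter, and the
clinical fallback is contrast injection. The enhancement implemented here
attacks the display side of that problem: it re-maps intensities so that
the darkest part of the range — where the cavity/thrombus distinction
lives — occupies more of the output scale.

The transform is a one-parameter generalization of the Reinhard
tone-mapping operator. With frame intensities normalized to $[0,1]$,

$$I_{out} = \frac{I_{in}}{I_{in} + A}, \qquad A > 0,$$

which is strictly increasing, concave, bounded by $1/(1+A)$, and has slope
$1/A$ at the origin. $A=1$ is the classical curve; $A<1$ steepens the
dark-to-mid response ("higher contrast"), $A>1$ flattens it. The parameter
is deliberately left to the operator: image quality varies between
machines and patients, and the method's intended use is interactive
adjustment per study, with $A=1$ as the default starting point. `A` is
global per video — every frame of a loop is mapped identically, so the
enhancement never introduces temporal flicker.

### Display rescale

The raw curve maps $[0,1]$ into $[0,1/(1+A)]$: quantized directly, output
at $A=1$ would peak at gray level 128 and look dark. The package therefore
multiplies the mapped intensities by $1+A$ by default, so the attainable
maximum uses the full range. This is a pure linear gain — it changes
brightness, not the shape of the tone curve, and every contrast ratio
discussed below is invariant to it. The `rescale_display` flag disables
it for workflows that prefer the raw operator output (e.g. display
hardware with its own range mapping).

### Region of interest and blending

The enhancement is applied selectively. The apical region of interest is
user-specified geometry (rectangle, ellipse, or polygon) in normalized
coordinates; the default is the upper 40% of the frame, where the apex is
displayed in standard apical views. There is no automatic apex detection —
ROI placement is an expert decision, like probe placement.

Hard ROI edges would leave a visible seam, so the rasterized mask is
feathered: weights ramp linearly from 0 at the boundary to 1 at
`feather_px` (default 8 px) inside it, using a Euclidean distance
transform. Outside the ROI the frame receives a mild Gaussian smoothing
(default $\sigma = 1$ px, configurable to 0), implemented as an explicit,
uniform filter; per-frame output is

$$\mathrm{out} = w \cdot T(\mathrm{frame}) + (1-w) \cdot S(\mathrm{frame}),$$

clamped to $[0,1]$. All blending happens in floating point on normalized
intensities; quantization back to 8 bits (round half away from zero,
clamp) happens exactly once at the end of the pipeline, so no intermediate
rounding error accumulates. With $\sigma = 0$, pixels with $w = 0$ are
bit-identical to the input — the enhancement is strictly local. The
operation is deliberately *not* idempotent (the tone curve composes with
itself into a different curve), which is why the tool operates on original
recordings, not previously enhanced output.

## Rater-study statistics

The evaluation module reproduces the statistics of a 29-patient
two-observer reader study in which enhanced loops were read blind and
compared with contrast echocardiography as the reference standard.

* **Confusion counts** per rater (nondiagnostic calls excluded pairwise;
  none occur in the packaged fixture).
* **Diagnostic metrics** kept as exact fractions — sensitivity
  $TP/(TP+FN)$, specificity $TN/(TN+FP)$, PPV, NPV, accuracy — and
  reported as whole percentages, matching the precision such studies
  print. Zero-denominator metrics are flagged undefined, never zeroed.
* **Single-operating-point ROC area.** A binary rater yields one operating
  point; the ROC polyline through $(0,0)$, $(1-Sp, Se)$, $(1,1)$ has
  trapezoidal area $(Se+Sp)/2$. Reported to 3 decimals.
* **Tie-corrected Friedman test** across the $k$ related rating columns:
  mid-ranks within each patient row, $\chi^2_u = 12\sum_j R_j^2 / (nk(k+1))
  - 3n(k+1)$, divided by the tie correction
  $C = 1 - \sum (t^3 - t) / (nk(k^2-1))$. Binary ratings are heavily tied,
  so the correction is essential: on the study table $C \approx 0.155$,
  and without it the statistic would be an order of magnitude smaller.
  With every row fully tied $C = 0$ and the test is reported as degenerate
  (statistic 0, $p = 1$) rather than dividing by zero. The p-value is the
  $\chi^2_{k-1}$ upper tail, which for $k = 3$ has the closed form
  $e^{-x/2}$ used as a test oracle.

### Reconstructing the study table from its margins

The study's published counts fix each column margin (14, 15 and 11
positives out of 29) and the structural fact that neither observer missed
a reference positive. They do not fix the joint distribution of the two
observers' false positives; the number $a$ of reference-negative patients
overcalled by *both* observers remains free, $a \in \{0,\dots,3\}$.
Two useful facts, both verified by enumeration in the tests:

* the Friedman **rank sums depend only on the margins** (they are
  59 / 60.5 / 54.5, i.e. mean ranks 2.03 / 2.09 / 1.88, for every $a$);
* the **tie-corrected statistic does depend on $a$**, and exactly one
  value, $a = 1$, reproduces the published 4.333. The packaged fixture
  (`study_fixture_path()`) uses that table.

`evaluate_ratings()` on the fixture reproduces every published figure:
Se 100% / Sp 83% / PPV 79% / NPV 100% / accuracy 90% (observer 1), AUCs
0.917 and 0.889, $\chi^2 = 4.333$, df 2, $p = 0.115$. The study's three
pairwise comparison p-values are not computed: the procedure that produced
them is not identifiable from the published material, and no standard
candidate reproduces them.

## The synthetic phantom

`generate_phantom()` renders what the pipeline needs from a validation
input and nothing more: a sector-scan geometry (75° wedge), a dark
elliptical cavity (mean reflectivity 0.03) inside a bright myocardial band
(0.75) over moderate background tissue (0.45), and an optional apical
thrombus ellipse (0.35) — ordered cavity < thrombus < myocardium as in
B-mode imaging, where blood is nearly anechoic and fresh thrombus is less
echogenic than muscle. Each frame multiplies that template by fully
developed speckle: the squared magnitude of a unit-variance circular
Gaussian field (an exponential variate of mean 1), given lateral
correlation by a small $3\times3$ point-spread kernel. A sinusoidal inward
wall displacement of 2% of frame height across the 16-frame loop (30 fps)
emulates systolic motion. Frames are quantized to 8 bits; generation is
bit-exact under a fixed seed and leaves the caller's RNG stream untouched.

The defaults — 256×256 px, 16 frames — were chosen as a realistic but
compact emulation of a stored cine loop; they keep a full 10-seed
validation run cheap while leaving every region hundreds of pixels.

Ground-truth masks are drawn on the zero-displacement (end-diastolic)
geometry, one set per loop — the way a reader annotates a representative
still frame. Consequently cavity-mask pixels adjacent to the moving wall
contain myocardium during part of the cycle. This is intentional: it is
precisely the near-wall clutter that plagues real apical windows, and it
is what makes contrast-to-noise behave realistically (below).

**What the phantom does not model:** acoustic wave propagation,
beamforming, attenuation, depth-dependent resolution, trabeculation,
reverberation artifacts, probe motion. Passing phantom tests demonstrates
that the processing pipeline behaves as designed on speckle-statistics
imagery; it is not evidence of clinical diagnostic performance.

## The mechanistic enhancement property

The quantitative proxy for "improved thrombus visualization" is the
contrast-to-noise ratio between thrombus and cavity inside the apical ROI,

$$\mathrm{CNR} = \frac{|\mu_{thr} - \mu_{cav}|}{\sigma_{cav}},$$

pooled over all frames. A subtlety worth recording: for a *pure*
multiplicative-noise cavity, a concave tone curve can never raise this
CNR — the cavity sits where the curve is steepest, so its noise is
amplified at least as much as the thrombus-cavity separation (the mean
slope of a concave function over $[\mu_{cav}, \mu_{thr}]$ is below its
slope at $\mu_{cav}$). What the curve *does* improve is the separation of
the dark range relative to clutter spread: in the end-diastolic cavity
mask, the dominant noise term is bright near-wall clutter spanning up to
myocardial intensity, and the curve compresses that bright spread while
expanding the dark-range separation. On the default phantom with
$A = 0.6$ the ROI CNR rises in 10 of 10 seeds (ratio ≈ 1.37); the test
suite asserts at least 8 of 10, and the property holds throughout
$A \le 1$. This mirrors the clinical reading that enhancement helps most
exactly where clutter, not electronics, limits interpretation.

## Cine I/O and numerical choices

* **DICOM**: multi-frame 8-bit, implicit/explicit little-endian written
  with a deterministic SOP instance UID derived from the pixel content, so
  identical inputs give byte-identical files; RLE (PackBits) supported in
  both directions. `MONOCHROME1` input is inverted to the `MONOCHROME2`
  convention; RGB input is reduced to Rec. 601 luminance. Vendor and
  JPEG-family codecs are rejected with a clear message.
* **AVI**: uncompressed bottom-up 8-bit DIB with a grayscale palette —
  lossless and deterministic; 24-bit DIB accepted on read. Compressed
  FourCC streams and MP4 are out of scope; the ROI mechanism makes
  cropping of burned-in overlays unnecessary for processing.
* **PNG sequences** for frame-level interchange, via the `png` package.
* Quantization everywhere is round-half-away-from-zero then clamp;
  normalize → quantize round-trips 8-bit data exactly.
* Gaussian smoothing uses replicated edges (a black frame border should
  not bleed inward); the mask feather uses a Euclidean distance transform
  (EBImage) so the ramp is isotropic for any geometry.
* Degenerate inputs fail loudly and specifically: zero-area ROI (empty
  mask + warning), frame-size drift mid-video (error naming the frame),
  constant CNR reference region (`NA` + warning), fully tied Friedman
  tables (degeneracy flag).

## Validation strategy

Every closed-form value in the test suite was either computed by hand from
the defining formula or cross-checked against an independent oracle
implemented separately from the package code: a first-principles Friedman
ranking oracle (pairwise-comparison mid-ranks, centered statistic) run
exhaustively over all 3-category tables with $n \le 3, k = 3$ and on 100
random larger tables; `stats::friedman.test` as the no-ties cross-check;
and a direct-convolution oracle for the Gaussian smoothing path. The
reader-study figures are reproduced end to end from the packaged fixture,
and `scripts/acceptance.R` recomputes the Friedman statistic and mean
ranks from the margins alone at run time.
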