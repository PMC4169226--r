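---
title: "Sweep-volume diastology: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sweep-volume diastology: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(masweep)
```

## The measurement

During diastole the mitral annulus recoils from its end-systolic position
toward the left atrium in two waves: a rapid early-diastolic (E) recoil
driven by ventricular relaxation and a late (A) displacement driven by
atrial contraction. Tissue Doppler quantifies this as the e′ and a′
annular velocities at single sites; their reversal (e′/a′ < 1) is a
hallmark of diastolic dysfunction. `masweep` derives an analogous — but
global and volumetric — measurement from standard cine CMR long-axis
views: the volume swept by the moving annular disk, accumulated from
end-diastole, normalized by its end-systolic maximum (ESSV), and
differentiated in time.

The pipeline has four stages, each exposed as package functions and each
validated against an independent oracle in the test suite.

### 1. Tracking (`ncc_match`, `track_point`, `correct_and_retrack`)

Template matching by zero-mean normalized cross-correlation: the
correlation coefficient of a template patch with every fully contained
placement inside a larger search region. Window sizes default to 21 px
(template) and 41 px (search) — odd, centered realizations of the 20/40
pixel squares known to work well for junction tracking, which is
insensitive to the precise size. The argmax placement gives the new point;
the chain template-(phase n) → search-(phase n+1) runs once through the
cycle without wrapping.

Numerical choices:

* Ties in the correlation map break to the first occurrence in row-major
  order (deterministic).
* Placements with zero intensity variance get coefficient −∞ and can
  never win; a zero-variance *template* is an error ("untrackable
  feature").
* At image borders the windows are clamped and placements without full
  template support are excluded.
* Localization is pixel-level by default; a 3-point parabolic subpixel
  refinement is available (`track_config(subpixel = TRUE)`) but off by
  default, since the underlying workflow tracks at pixel resolution.
* Phases whose peak correlation falls below `min_corr` (default 0.5) are
  flagged — the batch stand-in for interactive visual QC. Corrections
  enter as a JSON file of `{view, point, phase, row, col}` records and
  re-run tracking downstream of the corrected phase, exactly like the
  interactive workflow.

A property worth knowing: chained matching rounds each *relative*
per-step displacement, so with subpixel true motion the rounding residuals
accumulate as a bounded walk. On the noiseless default phantom the error
is ≈ 0.6 px RMS (≤ 2 px worst case) over a full cycle; this, not the
spline or the quadrature, is the accuracy floor of the whole measurement
at 1.4 mm pixels.

### 2. Geometry (`pixel_to_patient`, `order_annulus_points`, `interpolate_annulus`, `annulus_area_centroid`)

Pixels are 0-based `(row, col)` pairs addressing pixel centers and map to
DICOM LPS patient coordinates by the standard plane equation
`origin + row·Δr·col_dir + col·Δc·row_dir`. The six per-phase 3D points
are ordered circumferentially (angle sort about the centroid in the
least-squares plane, starting at the four-chamber septal point) and
interpolated by a *closed periodic cubic spline*, chord-length
parameterized, sampled at 120 points (doubling the sampling changes areas
by < 0.1 %, a self-check in the tests).

The annulus is saddle-shaped, so "area" needs a definition: we use the
triangle fan about the sample centroid with each triangle's signed area
taken along the best-fit plane normal — i.e. the area of the projection
onto the best-fit plane. This reduces exactly to the polygon area in the
planar limit and is convergent and deterministic. It differs from the
slant surface area by O((saddle/R)²): about 1 % at a 2 mm saddle on a
20 mm ring, which is irrelevant for the normalized indices (area enters
numerator and denominator alike).

### 3. Sweep volume (`sweep_volume`)

With `A_n` the annular area and `d_n` the displacement of the annular
centroid between phases projected on a **fixed** apex-directed long axis,
the incremental volume is the swept-slab (frustum) approximation
`V_n = (A_{n-1}+A_n)/2 · d_n`, and the curve is the running sum from
end-diastole. Design choices, made where the construction was genuinely
open:

* **Long axis**: the end-diastolic best-fit plane normal, sign-oriented so
  the systolic excursion is positive. A fixed axis prevents sign flips
  from frame-to-frame normal jitter; only the quadrature, not the axis,
  varies with phase.
* **Quadrature**: the trapezoid of areas (mean of adjacent areas). It is
  second-order accurate and matches the swept-slab picture; the exact
  historical choice (area at `t_n`, `t_{n-1}`, or their mean) is not
  recoverable, so it is isolated in one function.
* **Wrap handling**: the increment closing the last phase back to phase 0
  is computed and reported as `closure_mm3` but *not* added to the curve.
  A nonzero closure residual is a tracking-drift diagnostic.
* A curve that never rises (no systolic excursion) is an error, not a
  degenerate result.

### 4. Diastology (`sweep_rate`, `segment_intervals`, `compute_parameters`)

The recovery rate is the central difference of the normalized curve on
the periodic phase grid (spacing RR/P), sign-flipped so recovery is
positive; the signed derivative is kept alongside. Central differencing
attenuates narrow waves slightly and smears each pulse edge by about one
sample — hence interval boundaries are trusted to two phase spacings, and
E and A waves of equal width suffer the same attenuation, leaving their
ratio nearly unbiased.

Automatic segmentation realizes the manual "slope transition" division:
end-systole is the curve maximum (last sample of a tied run, since
pixel-quantized curves can plateau); within diastole, rate maxima with
prominence ≥ 10 % of the diastolic rate maximum are the E (first) and A
(last) waves; ED ends at the first rate minimum after E, AS starts at the
last rate minimum before A (non-strict minima, so an exactly flat
diastasis yields its entry and exit). Fewer than two qualifying waves
raises an "E/A fusion" error instead of guessing — the cue for a manual
division, which can replace any subset of boundaries (or all five, in
which case no automatic detection runs).

Parameters follow directly: peak and interval-mean rates; recovery
percentages from the normalized curve's interval endpoints (the value at
cycle end includes the closure residual, so ED + MD + AS recovery ≈
100 %); `AT_SV` from ED onset to the E rate peak; `DT_SV` by a
least-squares line through the monotone descending rate samples from the
E peak to the next minimum, extrapolated to zero — a tangent-style
extrapolation is unstable at 25 phases, the LS line is deterministic;
`DSVRT_50` as the linearly interpolated first crossing of 0.5 after
end-systole, as % of RR (the 50 % threshold is the configurable
`recovery_threshold`; 50 % is the default because it discriminates best).
If the sampled curve never falls through the threshold the index is `NA`
with an `incomplete_recovery` QC flag — fabricating a crossing in the
unsampled wrap segment would hide exactly the failures the flag exists
for.

## The phantom: what it emulates, and what it does not

`phantom_spec()` defines the study conditions; `render_views()` draws
them. The geometry is three long-axis planes 0°/60°/120° apart through a
common long axis, 25 phases over RR = 857 ms (70 bpm), 128 px images at
1.4 mm — typical clinical cine parameters. The motion model is:

* systole: half-cosine descent of `systolic_descent_mm` (default 12 mm);
* E and A recoveries: raised-cosine (Hann) velocity pulses. Hann pulses
  are infinitely differentiable with trivial integrals and analytic peak
  rates, so every ground-truth parameter is available in closed or
  near-closed form. Their areas split the descent `e_fraction :
  1 − e_fraction` (default 0.7, a normal early-recovery fraction); by
  default each pulse fills its interval and the peak-rate ratio follows
  as `fE/(1−fE)·T_AS/T_ED` (2.33 at the default timing 0.35/0.20/0.25/
  0.20 of RR). A prescribed `ea_peak_ratio` is honoured by narrowing the
  wave with surplus velocity; a pulse narrower than two phase spacings is
  refused as unresolvable. When sweeping the prescribed ratio (e.g. 0.5
  to 3) the natural companion is `e_fraction = ratio/(1+ratio)`, the
  physiologic covariation of peak ratio and recovered fraction, which
  keeps both waves resolvable;
* first-harmonic tilt (`tilt_mm`, default 2 mm) and transverse sway
  (`sway_mm`, default 2 mm), both scaling with the instantaneous descent.
  Both have zero azimuthal mean, so the analytic centroid motion — and
  hence the truth curve `A·z(t)` — is unaffected, while septal and
  lateral excursions differ as they do in vivo. Without them every
  tracked point would quantize identically and the phantom would be
  unrealistically degenerate. Sway can carry a point up to 2 mm off a
  view plane; as in 6 mm-thick cine slices, the point is rendered at its
  in-plane projection;
* each view's raster is offset by a sub-pixel amount (independently
  prescribed slices share no pixel grid);
* the junction points carry analytic broadband texture blobs whose
  appearance is identical at any subpixel location, with amplitude chosen
  so the image never saturates (clipping would flatten the blob core and
  bias the tracker). Gaussian noise and blur are applied only after the
  ground-truth pixel locations are recorded.

What the phantom does **not** emulate: SSFP tissue contrast and banding,
through-plane motion, respiratory drift, arrhythmia, and the appearance
of real junction anatomy. Passing the phantom tests therefore
demonstrates the correctness of the geometry, tracking chain, quadrature
and parameter definitions under known motion — not clinical robustness to
image-quality failure modes, which the correlation floor/manual
correction path is designed to absorb.

Known quantization facts, measured on the defaults and asserted in the
tests: recovered `PSR_E/PSR_A` is within 10 % of analytic truth (typical
−7 %), `DSVRT_50` within 3 points of RR, ED recovery within 5 points, and
DT within two phase spacings; mild image noise can *reduce* parameter
error (it dithers the pixel rounding), so graceful degradation is
asserted on the deterministic channels — peak correlation and RMS pixel
error — rather than on parameter error.

## Cohort statistics

The reporting utilities implement exactly the estimators conventional for
this validation design: Spearman rank correlation (average ranks,
large-sample t approximation), ROC analysis with AUC by the trapezoidal
rule and the cutoff that maximizes classification *accuracy* (ties broken
toward higher specificity; reported as a `score < cutoff` or
`score > cutoff` rule), Bland–Altman bias with 1.96·SD limits, and
ICC(A,1) — two-way, absolute agreement, single measures, with the F-based
95 % CI. The ICC form is a documented choice (the conventional model for
two fixed raters); other forms exist and give slightly different values
on the same data. A labeling helper applies the guideline rule (septal
e′ < 8 cm/s, lateral e′ < 10 cm/s, or LA volume index ≥ 34 mL/m²) so
synthetic cohorts can be auto-labeled.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run phantoms at 25 phases and
128 px (the clinical geometry), cohorts of 16 subjects, 10 reader pairs,
and a 2000-point null simulation for the ROC — sizes chosen so the whole
validation completes in about a minute on one CPU while every assertion
still has its intended power. All randomness (textures, noise, cohort
draws) flows from a single integer seed; two runs with the same seed are
byte-identical end to end.

## Limitations

* Six points is a coarse annulus sampling; regional annular dynamics are
  out of scope.
* The sweep volume is a swept-slab approximation, not a meshed surface
  volume; rapid area change between phases is only second-order
  corrected.
* Pixel-level tracking bounds accuracy at ≈ 0.5–1 px per point; the
  six-point centroid averages this down, but absolute volumes inherit a
  few percent of uncertainty at clinical pixel sizes.
* The DICOM reader covers uncompressed little-endian single-frame series
  only — the common export for cine research data; compressed transfer
  syntaxes must be converted upstream.
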