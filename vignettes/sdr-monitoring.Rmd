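---
title: "Monitoring transducer uniformity with SDR curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring transducer uniformity with SDR curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrwatch)
```

## The model and its assumptions

A defective part of a linear array — a dead element, a broken cable
conductor, a delaminated patch — attenuates both transmission and
reception, so every image produced through it is slightly darker in the
affected columns. The anatomical content of clinical images varies from
frame to frame; the systematic darkening does not. A pixel-wise median over
enough frames therefore cancels anatomy and preserves the defect. The
method rests on three assumptions:

1. **Column-to-element correspondence.** After extracting the B-mode
   rectangle and resizing its width to the element count, column $j$ of
   every image is produced by element $j$. This is why laterally zoomed
   images must be rejected (the physical width check), and why the method
   as implemented applies to linear arrays driven without lateral zoom.
2. **Superficial visibility.** Attenuation from a defective element is
   strongest directly under the transducer face, so only a superficial row
   band (defaults: rows 1–19 of 500, about 4% of depth) enters the
   statistics.
3. **Stationarity over one stack.** A defect present in most of the
   `n_stack` frames of the analysis window is detectable; one that flickers
   on a timescale short relative to the stack turnover is attenuated in
   the median and may be missed.

## The three detection paths

Every frame first has each row's mean subtracted, centring rows at zero so
column statistics compare lateral positions rather than absolute
brightness; the signed frames feed all three paths.

The **green path** targets narrow streaks at a fixed lateral position.
`n_rep` times, `n_select` frames are drawn without replacement and their
pixel-wise median is taken; the column-wise mean (CWM) of the superficial
band is inverted (negated — valid because row-centred values are signed,
a 255-complement would be wrong here) and an order-`o_poly_green`
polynomial is subtracted as baseline. Peaks of the residual are detected;
peaks recurring across repetitions are clustered by position and clusters
whose mean height exceeds `t_green` are rendered into the detection curve
as Gaussians

$$f(x) = \sum_{k=1}^{n} \mathrm{height}_k \,
  e^{-\left((x - \mathrm{pos}_k) / (\mathrm{width}_k / 2)\right)^2},$$

so each detection drops to $\mathrm{height}_k\,e^{-1}$ one half-width from
its centre. Subsampling plus medianing makes this path sensitive to faults
present in most frames while single-frame anatomy is rejected twice (by
the median and by the recurrence requirement).

The **red path** targets broader, more diffuse darkening: the inverted CWM
of the median of *all* `n_stack` frames has an order-`o_poly_red` baseline
subtracted, and residuals above `t_red` are kept.

Both polynomial fits adapt to the curve's endpoints, so endpoint darkening
is invisible to them. The **blue path** therefore thresholds the *raw*
inverted CWM at `t_blue` within the outer `p_include` percent of columns.

The SDR curve is the pointwise maximum of the three paths with the outer
`p_exclude` percent of columns zeroed (border streaks appear even on
healthy systems). The scalar indicator is the trapezoidal area under the
curve divided by the element count; since all thresholds are strictly
positive, a clean stack gives an exactly zero curve and zero area.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `n_stack` | 150 | images | analysis window; larger = fewer false positives, slower response |
| `n_select` | 15 | images | frames per green-path median |
| `n_rep` | 100 | — | green-path repetitions |
| `r_upper`, `r_lower` | 1, 19 | rows | superficial band (≈ 4% of the 500-row depth) |
| `o_poly_green`, `o_poly_red` | 6, 6 | — | baseline polynomial orders |
| `t_green`, `t_red`, `t_blue` | 2, 5, 10 | gray levels | path thresholds |
| `p_include` | 25 | % of columns | endpoint zone eligible for the blue path |
| `p_exclude` | 2 | % of columns | columns zeroed at each end of the SDR curve |
| `seed` | 1 | — | green-path subset sampling |

These defaults are the method's published operating point; they were tuned
empirically against known-defective systems rather than optimized, and
`sdr_params()` accepts deviations (also via a YAML file, `read_params()`).
The notification level default 0.75 sits inside the 0.5–1 interval that
flagged the studied defect cases early; it is a policy choice, not a fitted
constant. One consequence of tracking clinical images is that scanner
settings (dynamic range, compounding, depth) vary across frames, so the
area is an *indicator* calling for a controlled check, not a calibrated
severity measure.

## What the synthetic generator emulates — and what it does not

No statistical description of real clinical backgrounds accompanies the
method, so the generator is a deliberate stand-in with controllable
statistics. Each frame is a mean gray level plus `blob_count` smooth random
radial structures (anatomical variability that differs per frame but has a
laterally flat expectation) times a unit-mean Rayleigh speckle factor
blended by `speckle_sigma` (fully developed speckle has a Rayleigh
envelope). Defects subtract `strength` gray levels over a column band,
decaying linearly with depth (`depth_decay`), and are absent in an i.i.d.
fraction `intermittency` of frames — the simplest model of intermittent
cable/connector faults. Frame `i` of a stack is generated under a seed
derived from (`seed`, `i`), so stacks are bit-reproducible and the
background realization is identical with and without defects, which is what
makes ground-truth scoring exact.

The generator does **not** emulate: spatially correlated speckle, depth-
dependent gain and focal banding, vendor post-processing (spatial
compounding in particular, which blurs defect streaks laterally), color
Doppler overlays, or burned-in annotation that moves between frames.
Passing tests on synthetic stacks therefore demonstrate the algorithm's
contract — soundness on clean input, recovery and localization of injected
column-band defects, monotonicity in defect strength — not clinical
sensitivity or specificity, which depend on scanner settings and usage
patterns and require archive-scale evaluation.

## Numerical and design choices

- **Corner finding.** The largest *8-connected* component of nonzero
  pixels is kept (connectivity is a choice; 8 matches the common default of
  raster tooling). Top/bottom are the first/last rows containing component
  pixels; left/right are taken within the top 5% of the component's rows,
  so displays narrowing with depth are extracted at the width of their most
  superficial part. Coordinates are 1-based inclusive; the physical width
  is `n_columns × PhysicalDeltaX`, with the tag's cm-per-pixel convention
  converted to mm (overridable per scanner).
- **Accepted width interval is closed** at both ends (49.5 and 51.5 mm are
  both accepted); "inside the range" is ambiguous and the closed reading
  is the permissive one.
- **Bicubic resize** is separable Keys cubic convolution (a = −0.5) with
  clamped edges, applied as two weight-matrix products; weights sum to one
  for every output pixel, so constant images are preserved exactly.
- **Median with an even count** is the mean of the two middle values
  (the defaults use odd `n_select = 15`, but the primitive accepts any
  count).
- **Polynomial baselines** are least-squares fits on an abscissa rescaled
  to [−1, 1]; mathematically the same fit, numerically stable at order 6
  on hundreds of points.
- **Peak detection** reports samples strictly greater than both neighbours
  (first sample of a plateau); height is the raw residual value (not the
  prominence), and width is the full width at half prominence with linear
  interpolation at the crossings. Endpoints are never peaks.
- **Cross-repetition grouping** on the green path is single-linkage
  clustering of peak positions with a one-column gap tolerance; a
  cluster's height and width are averaged over the repetitions in which it
  appears (not over all `n_rep`). The grouping rule is underdetermined by
  the method's description; this is the most literal reading that still
  absorbs one-column jitter.
- **Percent-to-columns conversions** (`p_include`, `p_exclude`) use
  `floor`.
- **Degenerate inputs** error early and explicitly: empty stacks,
  all-zero frames (no region), sub-2-pixel extracts, bands outside the
  image, `n_select` exceeding the stack.
- **Determinism.** The only stochastic step is the green path's subset
  sampling, driven by `params$seed` through a state-restoring RNG scope;
  red and blue paths are order-free (median), so reordering frames changes
  only which indices the green sampler picks. Equal seeds give
  bit-identical curves, stacks and fixtures.

## Problem sizes in the shipped tests

Unit and property tests run on small geometries (e.g. 64 × 60-pixel
frames, 30-frame stacks, 20 repetitions) chosen so the whole suite
exercises every code path in a couple of minutes; the end-to-end checks of
the published operating point use full-size 336 × 500 stacks of 150 frames
(20 seeded runs for the false-positive rate, a five-point strength grid for
monotonicity). The acceptance script reruns the full-size computations from
scratch under a caller-supplied seed.

## Known limitations

- Vertical (axial) nonuniformities are undetectable by construction: depth
  is resized and mixed across images with different depth settings.
- Logotypes, scales and measurement readouts that touch the B-mode region
  become part of the extracted image and can masquerade as lateral
  darkening; the generic connected-component rule carries no vendor-
  specific masking.
- The monitor assumes a transducer stays attached to one scanner; DICOM
  tags carry no serial number, so swapped transducers alias into one
  series.
- Intermittent defects active for periods short relative to the stack
  turnover are attenuated by the median and may stay below threshold.
- Curved and virtually-convex arrays are extracted by the rectangle rule
  only; no rescan-geometry correction is attempted.
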