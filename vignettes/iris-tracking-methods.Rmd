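---
title: "Methods: visible-light iris tracking with iristrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visible-light iris tracking with iristrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iristrack)
```

## The problem

Video-oculography with a consumer camera records the eye in visible light,
where the pupil/iris boundary is weak but the whole iris reads as a dark
disc against the sclera. The tracking task is to localise the iris centre
in every sampled frame of an eye-region crop, despite eyelid occlusion,
eyelashes, specular glints and sensor noise, and to score the result
against manual annotations. `iristrack` implements two trackers over a
shared preprocessing front end:

* **CHT_ACM** - every frame independently: morphological cleanup, an
  active-contour fit that narrows the crop to the eye, histogram
  binarisation, a Circular Hough Transform (CHT), and a white-pixel
  acceptance rule that picks the mostly-dark circle.
* **CHT_TM** - CHT_ACM on the first frame only, producing an iris
  template; every later frame is localised by masked template matching
  with darkest-region selection. One detection plus cheap correlation
  sweeps is what makes this tracker several times faster per frame.

All coordinates are 0-based pixels relative to the top-left corner of the
eye crop, x rightward and y downward; centres are kept as floats.

## Circle detection

Edges are Sobel-gradient pixels with magnitude at or above `canny_high`
(default 180 on the 0-255 intensity scale). Because the target is a dark
disc, the boundary gradient points radially outward, and each edge pixel
votes only towards its darker side, at every radius in the search window
(defaults 15-50 px, centre spacing `min_dist = 40`, vote threshold
`accumulator_threshold = 10`). Cells clearing the vote threshold are
ranked on a 3x3 box-smoothed accumulator - direction quantisation spreads
a peak over neighbouring cells - and suppressed within `min_dist` of a
stronger peak.

Each surviving peak is refined by an iterated least-squares (Kåsa) circle
fit to its supporting edge pixels, gated two ways: the distance to the
current centre must lie within a band around the windowed modal ring
distance (band shrinking 2 to 1 px over four rounds), and the pixel's
gradient must be radially outward (cosine above 0.7). The alignment gate
is what keeps eyelash strokes and the eyelid arc - both of which can sit
at ring distance - out of the fit; without it the centre can bias by
2-3 px on unlucky lash layouts. A fit that drifts more than 5 px from the
vote peak is treated as degenerate and the peak retained with the ring
mean as radius.

## Eye-region refinement and circle acceptance

The active contour is a morphological active-contour-without-edges: the
region boundary is reassigned pixelwise to the inside/outside class whose
mean intensity it matches better, followed by sup-inf/inf-sup smoothing
with four line structuring elements. The scheme needs no step sizes, is
expansive from inside a contrasting region (so no explicit balloon force),
and stops when the boundary moves less than `acm_tol = 0.1` px per
iteration for three consecutive iterations (cap 200). It is initialised
from the best raw CHT candidate, falling back to a circle at the frame
centre with radius 0.4 x the smaller frame side. The contour's padded
bounding box (kept at least twice the maximal radius wide) becomes the
refined crop.

The crop is binarised at Otsu's between-class-variance threshold; a fixed
threshold can be supplied. A frame whose two classes are separated by less
than 25 intensity units - a closed lid, a constant patch - is flagged
degenerate and fails detection rather than producing an arbitrary mask.
Candidates from the CHT on the crop are then scored by the fraction of
binarised-white pixels inside the discrete disc; a circle is accepted only
if that fraction is below 0.60. We read the 60% rule as a fraction of the
circle area rather than an absolute sum, because absolute sums are
image-scale-dependent; ties resolve to the lowest white fraction, then
the most votes, then the smaller centre y. If no candidate passes, the
frame is marked invalid - there is no mid-video fallback, mirroring the
flow in which failed frames are simply excluded.

## Template matching

The template is a square patch of side `2(round(r) + margin) + 1`
(margin 4 px) centred on the first-frame iris, with an inscribed circular
mask of the iris radius. The default similarity is zero-mean normalised
cross-correlation (NCC) computed only under the mask; a raw product-sum
score (`match_method = "ccorr"`) is retained for fidelity runs. Candidate
placements are local maxima of the similarity map within 98% of the
per-frame maximum; each implies a centre via the stored offset, and the
one whose circular region is darkest wins (ties to higher similarity).
No sub-pixel interpolation is applied to match locations, consistent with
manual annotation at half-pixel precision being the reference.

A frame whose best masked NCC falls below 0.5 is declared invalid; this
automates blink exclusion (a closed lid correlates poorly with an iris
template) where the original workflow excluded blinks manually. Invalid
frames stay in the trajectory with a flag - they are never dropped.

Two observations from the synthetic experiments are worth recording.
First, with raw cross-correlation the mask matters for exactly the
documented reason: the score is dominated by bright regions, so under
deep lid occlusion unmasked matching drifts towards the exposed lower
half of the eye (y-MAE 5.6 px unmasked vs 4.0 px masked at 0.25 coverage
in our harness). Second, zero-mean NCC removes that bias at the source:
both masked and unmasked NCC track at ~0.5-0.7 px under the same
occlusion, and the mask then yields no further gain. The package defaults
to masked NCC - the robust combination - and demonstrates the masking
mechanism in the raw-correlation regime where it belongs.

## Validation metrics

Per axis, over frames valid in both the trajectory and the truth
(intersection pairing, so blinks and failures are excluded pairwise):

* `MAE = mean(|a - m|)` pixels,
* `MPE = mean(|a - m| / (a + eps)) * 100` percent, with `eps = 1e-6`
  guarding division by zero. The denominator is the raw pixel coordinate,
  which makes MPE depend on where the crop origin sits; we replicate that
  convention deliberately and flag the caveat here,
* `RMSE = sqrt(mean((a - m)^2))` pixels,
* Pearson `r`, with `t = r * sqrt((n - 2) / (1 - r^2))` and the
  two-tailed p-value from the Student-t survival function on `n - 2`
  degrees of freedom. Perfectly linear series report `r = +/-1`, `t =
  +/-Inf`, `p = 0` rather than dividing by zero; constant series raise an
  error from `pearson_cc()` and are reported as `NA` by
  `evaluate_trajectory()`, since a fixation task has a constant truth
  coordinate and its error metrics remain meaningful.

`evaluate_videos()` offers the two aggregations that can be meant by "the
average over all videos": pooling all co-valid frames before computing
metrics (the default, and what the grouped tables here use), or averaging
per-video metric values. `compare_groups()` lays evaluations out in long
format with best-per-metric flags within a row family.

## The synthetic generator

No recordings ship with the package, so the generator is the test
surface. It renders what the study's crops contain: a light sclera
(intensity 220), an iris disc (brown 60 / green 110 / gray 140 - darker
irises give the easiest contrast, matching the reported ordering across
subjects), a darker pupil (0.4 x iris radius, intensity 30), elliptical
eyelids (skin 190), up to two specular glints riding the iris, eyelash
strokes hanging from the upper lid, and clipped Gaussian noise (sd 3).
The default crop is 240 x 160 px with iris radius 30 - inside the
detector's 15-50 px radius window - and 30 fps.

Two lid-modelling choices matter:

* **Lids are anchored to the face, not the eyeball.** They follow a
  vertical gaze shift with gain `lid_follow = 0.9` - the upper lid
  physiologically tracks vertical gaze almost completely - so an upward
  excursion buries a few extra pixels of iris under the lid. This is the
  mechanism behind the larger y-axis errors in real recordings; a gain
  much lower than 0.9 produces occlusion excursions (and tracking errors)
  an order of magnitude beyond anything the pixel-level accuracies of
  visible-light studies allow, which is how the default was fixed.
* **The palpebral aperture fluctuates.** Each frame past the first
  deepens the top coverage by a seeded uniform draw on
  `[0, coverage_jitter]` (default 0.10 of the iris height), emulating lid
  sag and partial closure, so later frames are never pixel-for-pixel
  translations of the template.

Tasks reproduce the four stimuli: linear out-and-back (one triangular
cycle; the apex is attained up to one frame step), one full revolution at
constant angular speed, and fixation, each over 1 s or 5 s at the
configured fps, amplitude 35 px by default with a 5 px border margin.
Blink frames render fully closed lids. All randomness derives from the
scene seed (per-frame streams are keyed by seed and frame index), so
identical configurations are bit-identical; ground truth records the
exact float centre per frame plus the blink flag, and the rendered disc's
pixel centroid stays within 0.5 px of it.

What the generator does not emulate: head motion, perspective
foreshortening of the iris into an ellipse, iris texture, shadows and
illumination gradients, motion blur, and camera compression artifacts.
Passing recovery tests here therefore demonstrates correctness of the
algorithms under controlled conditions, not field accuracy on real
smartphone video.

## Problem sizes and runtime choices

The test-suite conditions are sized for a single CPU: recovery runs use
5 s videos at 30 fps sampled every 10 frames (15 frames each, four tasks,
three seeds), the runtime-ordering comparison uses one 100-frame video,
the disc-recovery sweep uses 50 frames across the full radius window, and
oracle comparisons use 100 random series pairs and 24 x 24 / 8 x 8
matching instances. The full suite completes in roughly two minutes; the
acceptance script in about one and a half. The matcher's inner loops are
compiled (Rcpp) with the mask decomposed into per-column runs so the hot
loop streams over memory; everything else is vectorised R.

## Known limitations

* Circles only: lateral gaze makes the iris elliptical, and the CHT will
  fit the best circle through it; the refinement fit inherits that bias.
* The dark-disc prior (single-sided voting, outward-alignment gating) is
  deliberate: the detector is not a general circle finder for bright
  objects on dark fields.
* The first frame must yield an intact iris - CHT_TM aborts otherwise,
  by design, since no template is obtainable.
* The template is never re-acquired; a long occlusion or appearance
  change degrades all subsequent frames.
* MPE inherits the origin-dependence of the published definition.
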