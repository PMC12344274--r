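---
title: "Colour-threshold flower detection and monocular georeferencing in oblique UAV imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colour-threshold flower detection and monocular georeferencing in oblique UAV imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satt)
```

## The problem

Himalayan balsam (*Impatiens glandulifera*) invades riparian corridors,
forming tall monocultures whose pink-purple flowers are the one feature a
camera can pick out reliably from a distance.  Riverbanks are hard to walk
and often canopy-covered, so surveys fly a small UAV low along the bank,
capturing *oblique* (side-facing, roughly 45-degree) frames.  `satt`
implements a semi-automatic detection and mapping workflow for such
imagery: a colour-threshold detector with a morphological shape prior, a
monocular georeferencing step that turns each frame's detections into map
coordinates, standard detection-evaluation metrics, and GIS vector export.
Because the method is colour-plus-shape rather than learned, it needs no
training data and its few parameters are interpretable by a field
ecologist.

## The detection model

Each frame is processed independently through a fixed chain
(`detect_flowers()`):

1. **HSV conversion** (`to_hsv()`).  Hue separates the flower's chroma
   from brightness, which varies hugely across oblique scenes.  Hue is
   stored on a *full-byte* scale, 0-360 degrees mapped to 0-255; the tuned
   thresholds that ship with the package (hue up to 230) are expressed in
   this dialect.  Convert from the half-byte OpenCV dialect by doubling,
   and from degrees by multiplying with 255/360.
2. **Colour thresholding** (`threshold_mask()`).  A pixel is foreground
   when hue and saturation lie within inclusive bounds.  A value channel
   with bounds (0, 0) is treated as *unconstrained*: brightness varies
   with sun angle, and the tuned parameter sets deliberately leave it
   free.  A literal `[0, 0]` value window would match nothing.
3. **Gaussian smoothing with 50% re-binarisation.**  The binary chromatic
   mask is smoothed with a 15-px separable Gaussian (sigma from the usual
   size relation, here 2.6; reflect padding) and re-binarised at one half.
   A blurred step edge crosses one half exactly at the original edge, so
   object boundaries stay put, while an isolated speckle pixel's smoothed
   response peaks near 0.02 and vanishes.  We binarise the smoothed
   *mask* rather than re-thresholding the smoothed colour image: blurring
   flower colour into black background preserves hue and saturation while
   only scaling value, so with the value channel free a colour re-threshold
   would keep the entire blur halo and inflate every object by roughly the
   blur radius, corrupting the size-based distance estimate below.
4. **Elliptical shape search** (`shape_search()`).  Morphological opening
   with an elliptical structuring element: only regions that can contain
   the kernel footprint survive.  This is the shape prior -- the balsam
   flower is ellipsoidal face-on -- and it is what suppresses thin
   stem-like structures narrower than the kernel.  Cross and rectangle
   elements are available for other flower geometries.  Elliptical
   elements use semi-axes width/2 and height/2, so the smallest (3x3)
   ellipse is the full block; this is the convention under which a solid
   block is preserved by the small noise opening while 1-px diagonals and
   specks are removed.
5. **Noise opening** (`noise_opening()`), a second opening with a fixed
   3x3 element, removing residual pixel clusters.
6. **Component reconstruction.**  Components of the *original* threshold
   mask that intersect the surviving morphology output are restored at
   their full chromatic extent.  Opening erodes high-curvature tips, and
   the smoothing step can shave the single-pixel extremities of an
   ellipse; reconstruction makes the reported box the hull of the
   chromatic object itself, which is the quantity the distance model
   needs.
7. **Contours and boxes** (`extract_contours()`,
   `boxes_from_contours()`).  One outer contour per 4-connected
   component (holes recorded as child contours), an axis-aligned hull per
   outer contour, and an inclusive minimum-size filter in both axes.
   Each box carries a fill-ratio pseudo-score, area / (w x h), in (0, 1]:
   the detector itself is thresholded and scoreless, but average
   precision needs a ranking, and fill ratio prefers compact elliptical
   blobs (a clean ellipse scores about pi/4 = 0.79; straggly or partial
   shapes score lower), matching the workflow's shape prior.

Pixel coordinates are 0-based with the origin at the top-left; boxes are
`(x, y, w, h)`.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `hsv` lower/upper | 117/9/0 -- 230/200/0 | full-byte HSV gamut of the flower colour; value free |
| `blur_size` | 15 px | Gaussian kernel width; larger kills more speckle but can bridge close flowers |
| `kernel` | ellipse 9 x 7 px | shape-search footprint; should be just below the smallest flower of interest |
| `min_size` | 15 x 15 px | inclusive minimum box extents; the noise floor of the detector |
| `reference_height_mm` | 43.2 | field-measured mean flower height used for ranging |

The three tuned parameter sets used for the original riverbank image
sets ship as YAML under
`system.file("extdata", package = "satt")` and load with
`read_params_yaml()`.

## Monocular georeferencing

With one camera and a known object size, range follows from the pinhole
model (`object_distance_mm()`):

    distance = f * real_height * image_height / (object_height_px * sensor_height)

with `f = sensor_height = 8.8` mm for the survey camera and a reference
flower height of 43.2 mm (a field-measured mean; its ~2% natural spread
is an irreducible ranging error floor).  A 38-px box at the 3648-px
frame height gives 4147.2 mm.  Each image's detections are summarised by
their mean distance; the image-side bearings are gimbal yaw -+ FOV/2
(73.7 degrees for this camera); and each bearing/distance pair is pushed
through the spherical destination-point formula (earth radius
6378.1 km, `destination_point()`) to get the footprint line endpoints.
The footprint's haversine length converts a flower count into *flowers
per metre*, the density weight used for heatmaps.  Flowers-per-metre is
count divided by length; the attribute name states the unit.

Deliberate simplifications, mirroring the workflow this package
re-implements: the slant range is used directly as ground distance (no
correction for the ~45-degree pitch), no DEM intersection, no lens
distortion model.  These bias absolute placement but preserve the
relative density structure along the bank, which is what hotspot mapping
consumes.  Frames with no detections have no mean distance and are
skipped for geolocation (their camera point is still exported).

## Evaluation metrics

`match_detections()` performs greedy one-to-one matching, descending
score order, each detection claiming the highest-IoU unmatched truth at
IoU >= 0.5 (tunable).  A detection spanning a bunch of flowers counts
one true positive and leaves the rest as misses, reproducing how bunching
depresses recall.  Precision, recall and F1 follow the count formulas,
with degenerate denominators returning 0 with a warning.
`pr_curve()` sweeps the score threshold over all distinct detection
scores and pools counts over the image set; `eleven_point_ap()` averages
the interpolated precision max{p(r') : r' >= r} over
r in {0, 0.1, ..., 1}; `mean_ap()` averages per-class APs (with the
single flower class, mAP = AP).

## The synthetic scene generator

Real UAV surveys cannot ship with a package, so validation runs on
generated scenes (`render_scene()`, `generate_survey()`) whose ground
truth is exact by construction:

* background pixels sample a vegetation-like HSV range (greens, byte hue
  70-100) strictly outside the detector gamut;
* flowers are filled axis-aligned ellipses in in-gamut colour, rasterised
  with a strict-interior midpoint rule so a flower specified as w x h
  spans exactly w x h pixels (even extents sit on half-integer centres);
  truth boxes are recorded from the pixels actually drawn;
* distractors reproduce the field failure modes: thick "stem" strokes in
  flower hue (the dominant false-positive source in sunlit conditions)
  and near-white low-saturation flowers (missed by design, as the manual
  tuning protocol preferred under-classification to false positives);
* speckle noise flips a configurable fraction of pixels to flower colour;
* the survey generator walks a bank polyline (default: a ~200 m reach at
  riverbank coordinates in North Wales), one pose per frame at a 5 m
  standoff with yaw facing the bank, and draws per-frame flower counts
  from a Poisson whose mean is a baseline (2) plus one Gaussian hotspot
  (amplitude 22, width 18% of the transect) -- the single-hotspot
  structure that density mapping is meant to recover.  Per-flower pixel
  sizes come from inverting the pinhole model at ranges drawn in
  standoff x [0.8, 1.2].

The survey camera is a reduced-resolution variant (608 x 456 px,
1.73 mm sensor height, same 8.8 mm focal length and 73.7-degree FOV) so
that a 43.2 mm flower at 4-6 m projects to a detectable 17-27 px while
thirty frames render and process in well under a minute; the pinhole
geometry is exact at this scale, only the pixel count differs from the
full-size survey camera.

What the generator does *not* emulate: photometric texture within a
flower, shadows and specular water reflections, perspective footprint
trapezoids, motion blur, and lighting drift across a flight.  Passing
the clean-scene suite therefore demonstrates correctness of the
algorithmic chain (colour gate, morphology, measurement, geometry), not
field-condition robustness; the degradation suite (speckle, sub-size
flowers, stem distractors) probes the failure directions seen in real
imagery but at controlled severities.

## Numerical and design choices

* Deterministic throughout: every stochastic fixture owns one integer
  seed; reruns are bit-identical, and detection itself has no
  randomness.
* Morphology is exact set morphology (vectorised shifts) with off-image
  treated as background; opening is idempotent and is validated against
  a per-pixel brute-force oracle.
* Blur borders use reflect padding, so constant images are fixed points
  and frame edges gain no artificial gradients.
* Minimum-size comparison is inclusive (a 15 x 15 box passes a 15 x 15
  threshold).  Exactly duplicated boxes are deduplicated; distinct
  contours sharing a hull are all kept.
* Distance recovery through the full detector is limited by pixel
  quantisation: a flower h pixels tall carries a relative range error of
  up to 0.5/h from rounding alone (2.9% at 17 px, 1.3% at 38 px), which
  is the accuracy floor reported by the acceptance script.
* GeoJSON (RFC 7946, lon-lat order) is the canonical lossless output;
  the ESRI Shapefile writer is a best-effort dialect (point and polyline
  records, field names truncated to 10 characters with a JSON rename
  manifest alongside).  Coordinates are WGS84 only; reprojection is left
  to the consuming GIS.
* Camera poses are ingested from a sidecar table
  (`image_id, lat, lon, alt_m, yaw_deg`); `dms_to_decimal()` covers the
  degree-minute-second conversion used by EXIF GPS tags.  Binary EXIF
  parsing is out of scope, and the sidecar is authoritative when both
  exist.
* The tuning command automates the manual protocol: a seeded 10-image
  subsample, every candidate parameter set run per image, the per-image
  winner being the candidate with the most detections (or, when ground
  truth is available, most true positives with zero false positives),
  and the element-wise mean of the winners' bounds adopted for the full
  run.

## Problem sizes used in the shipped validation

The test-suite and acceptance-script workloads are sized for a single
CPU: 50 clean scenes of 400 x 400 px with 1-20 flowers each, 10-scene
degradation batches per condition, 200 random masks (up to 64 x 64)
for the morphology oracle, 1000 geodesic round trips, 100 random scored
detection sets for the AP oracle, and one 30-frame survey.  Larger
scenes and surveys scale linearly through the same code paths.

## Known limitations

Colour thresholding cannot separate co-flowering species of similar hue;
bunched flowers merge into single detections; side-on (bell-shaped)
flowers and white morphs are missed by design; sunlit stems sharing the
flower hue are the dominant false-positive source when wider than the
search kernel; and absolute geolocation inherits GNSS error plus the
uncorrected slant-range bias.  The package reports what the workflow
computes -- it does not attempt radiometric calibration or learned
detection.
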