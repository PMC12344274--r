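# satt — semi-automatic thresholding tool for flower detection in oblique UAV imagery

`satt` detects conspicuously coloured flowers in side-facing UAV
photographs and maps them.  The motivating target is Himalayan balsam
(*Impatiens glandulifera*), an invasive annual whose pink-purple,
ellipsoidal flowers mark riparian monocultures that are hard to survey on
foot.  The package is aimed at ecologists and land managers who want a
tunable, training-data-free detector whose every parameter has a field
meaning — a colour gamut, a flower size, a camera spec — plus the
evaluation and GIS plumbing around it.

## What it computes

**Detection** is colour thresholding with a morphological shape prior.
A frame is converted to HSV (hue on a full-byte 0–255 scale for 0–360°),
thresholded to the flower gamut (value channel optionally free), smoothed
with a 15-px Gaussian and re-binarised at the 50% level, opened with an
elliptical structuring element (only regions that can contain the kernel
survive — the ellipse is the flower's face-on shape), noise-opened,
reconstructed to full chromatic extent, and reduced to bounding boxes with
an inclusive minimum-size filter.  Each box carries a fill-ratio
pseudo-score in (0, 1] used to rank detections.

**Georeferencing** is monocular, from a known reference flower height
(field-measured mean 43.2 mm) through the pinhole model:

    distance = f · real_height · image_height / (object_height_px · sensor_height)

with f = sensor height = 8.8 mm for the DJI Phantom 4 Advanced camera.
Image-side bearings are gimbal yaw ± FOV/2 (FOV 73.7°); each
bearing/distance pair goes through the spherical destination-point
formula (earth radius 6378.1 km) to build the frame's field-of-view
footprint line, whose length turns the flower count into **flowers per
metre** — the density weight for GIS heatmaps.

**Evaluation** implements greedy one-to-one IoU matching, precision,
recall, F1, the 11-point interpolated average precision
AP = mean over r ∈ {0, 0.1, …, 1} of max{p(r′) : r′ ≥ r}, and mAP.

**Synthetic scenes** stand in for flight imagery: seeded generators
render in-gamut elliptical flowers on out-of-gamut vegetation-like
backgrounds, with optional speckle, stem distractors and near-white
flowers, plus whole riverbank surveys with a density hotspot, exact
ground truth and a camera-pose sidecar.

## Worked example

```r
library(satt)

spec  <- random_scene_spec(6, seed = 42, image_id = "frame042")
sc    <- render_scene(spec)                       # image + exact truth
boxes <- detect_flowers(sc$image, detection_params())
df    <- boxes_to_df(boxes, "frame042")
df$distance_mm <- object_distance_mm(
  df$h, 43.2, camera_model(8.8, 1.73, 73.7, 608L, 456L))
print(df, digits = 4)
#>   image_id   x   y  w  h  score distance_mm
#> 1 frame042  46 181 15 20 0.7867        5010
#> 2 frame042  81 344 16 19 0.7895        5274
#> 3 frame042 148 256 20 25 0.7920        4008
#> 4 frame042 343 169 20 24 0.7917        4175
#> 5 frame042 359  99 15 16 0.8000        6263
#> 6 frame042 379 363 15 16 0.8000        6263

evaluate_detections(df, sc$truth)
#> Detection evaluation: 6 TP, 0 FP, 0 FN
#>   precision 1.000  recall 1.000  F1 1.000  AP(11-pt) 1.000  mAP 1.000
```

All six planted flowers are found at their exact pixel hulls (fill
ratios near π/4 ≈ 0.79, as a clean ellipse should score), and each box
height yields a pinhole range — a 20–25 px flower on this small-sensor
survey camera sits 4–6 m away.  The geometry pieces compose the same
way on their own:

```r
object_distance_mm(38)                      # 43.2 mm flower, 38 px tall, stock camera
#> [1] 4147.2                                # mm
side_bearings(135, 73.7)
#>   left  right
#>  98.15 171.85
destination_point(53.28, -3.44, 135, 4.1472e-3)   # 4.15 m along the view
#>       lat       lon
#> 53.279974 -3.439956
```

The tuned parameter sets for the three original riverbank image sets are
included:

```r
read_params_yaml(system.file("extdata", "imageset2_params.yaml", package = "satt"))
```

## Command line

```sh
satt detect   --input imgs/ --out run/ [--config cfg.yaml --hsv-lower 117,9,0 \
              --hsv-upper 230,200,0 --min-size 15,15 --kernel ellipse:9x7]
satt tune     --input imgs/ --subsample-n 10 --seed 0 [--truth truth.csv]
satt eval     --detections run/detections.csv --truth truth.csv --iou-min 0.5 --out report/
satt georef   --detections run/detections.csv --poses poses.csv --out gis/ \
              --format geojson --fov-deg 73.7 --focal-mm 8.8 --sensor-mm 8.8
satt simulate --out fixtures/ --seed 1 --n-images 30
```

`detect` writes `detections.csv` (image_id, x, y, w, h, score,
distance_mm) and an annotation JSON; `georef` writes three vector layers
(camera points, FOV lines, flower-density points) as GeoJSON or
Shapefile; all subcommands are deterministic given their inputs and
`--seed`.

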