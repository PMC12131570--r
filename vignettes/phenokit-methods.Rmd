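---
title: "phenokit: methods, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phenokit: methods, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenokit)
```

phenokit measures plant traits from images the way a field technician
captures them: seeds or fruit photographed top-down on a dark background
with a reference coin, a wheat ear photographed side-on between black
cards, a canopy from above, a maize ear from the side, a field plot marked
with a white rectangle. This vignette explains the measurement models, the
tunable parameters and their defaults, what the synthetic scenes do and do
not emulate, and the numerical choices a maintainer would want to know
about.

## Coordinate conventions

Images are numeric arrays `[row, col, channel]` in `[0, 1]`; masks and
label maps are `[row, col]` matrices. Pixel coordinates are 1-based
`(row, col)` — the native R indexing convention, used consistently in every
function, test and oracle. Geometry functions on abstract point sets use
`(x, y)` columns with `x = col`, `y = row` (so angles read naturally in
screen coordinates).

## Scale calibration

A reference coin is found by Otsu-binarizing the luminance channel
(Rec. 601 luma), labeling connected components, and scoring each by
circularity $4\pi A / P^2$. The most circular component with circularity
$\ge$ `circularity_min` (default 0.85) and radius $\ge$ `min_radius_px`
(default 20) wins; ties go to the larger radius. The physical diameter is
user configuration (`coin_diameter_mm`, default 25 mm — the coin type is
the user's choice), and `mm_per_px = D / 2r`. Lengths convert linearly,
areas quadratically, and count densities per px² convert to per m² via
$(mm\_per\_px/1000)^{-2}$.

Field plots use a white rectangular marker instead. Near-white pixels (all
channels $\ge$ `whiteness_threshold`, default 200/255) form the candidate
region; its convex hull's minimum-area rotated rectangle is snapped to the
nearest hull vertices to get four corners, which are verified to form a
convex quadrilateral with interior angles within `marker_angle_tol_deg`
(default 15°) of 90°. Rectification estimates the 4-point homography from
the detected corners to an axis-aligned rectangle whose aspect equals the
marker's physical aspect and whose area equals the detected quadrilateral
area (area preservation makes re-rectification the identity, which the
tests assert to sub-pixel accuracy). The scale comes from the rectified
marker width. The marker's physical size is configuration
(`marker_width_m`, `marker_height_m`); verification-by-right-angles is this
package's concrete reading of what "checking" a marker should mean, since
there is no canonical procedure.

## Segmentation

`otsu_threshold()` is the exact argmax of the between-class variance
$\omega_0(t)\,\omega_1(t)\,(\mu_0(t)-\mu_1(t))^2$ over all 256 levels, ties
to the lowest level; the suite checks it against a literal exhaustive
search. `hsv_in_range()` implements bounded-HSV masking with hue in degrees
and wrap-around bands (a red band `[340°, 20°]` is written with
`lower_h > upper_h`). Cleanup removes components below `min_area_px`
(default 25 px²); a disc opening is available (`opening_radius`) but
defaults to 0 because even a radius-1 opening erodes the tips of elongated
seeds and biases length low by several percent — the area filter alone
removes noise specks at realistic noise levels.

Connected components are 8-connected by default (4-connectivity fragments
anti-aliased borders; it remains available). Labels are renumbered in
first-pixel order so results are deterministic.

### Splitting touching objects

Touching seeds, fruit or spikelets appear as one component. Every instance
whose *solidity* — pixel count over the number of pixel centers inside the
convex hull of the instance's pixel centers — falls below
`solidity_threshold` is re-segmented:

1. Euclidean distance transform of the instance mask.
2. Peak detection: local maxima under a square max filter of half
   `peak_min_distance`, suppression of duplicates closer than
   `peak_min_distance` (larger distance value wins), then a saddle test:
   two peaks are merged when the minimum of the distance transform along
   the straight path between them stays above 90% of the lower peak —
   the flat ridge of a single elongated object has no saddle, while two
   fused objects always have a neck.
3. Marker-controlled watershed growth from the surviving peaks
   (`EBImage::propagate` on the distance transform), which partitions the
   instance exactly, so the union of foreground pixels is conserved and
   the count never decreases.

The rasterized-hull solidity is deliberate: for any convex rendered shape
it is *exactly* 1 (every pixel center inside the hull of foreground centers
is itself foreground), so single convex objects can never be gated into the
splitter. Measured on touching ellipse pairs, solidity ranges from about
0.94 to 0.98 — hence the default gate of 0.985, chosen from the geometry
of the two populations rather than tuned per dataset. A polygon-area
solidity (the textbook formula) blurs this separation, because the hull
polygon of pixel centers systematically under-covers the pixel footprint.

`peak_min_distance` should be about half the expected object minor axis
(default 8 px for seed-scale objects; the fruit pipelines pass larger
values through config).

## Morphometry

Per instance: area is the pixel count; the boundary is traced as a closed
8-connected chain; length and width are the side extents of the
minimum-area rotated rectangle (rotating calipers over the convex hull)
plus one pixel of footprint, with length the longer side; aspect ratio,
compactness $4\pi A/P^2$, equivalent diameter $2\sqrt{A/\pi}$ and the
centroid follow. The rotated-rectangle convention (not ellipse fits or
Feret diameters) is robust for angular seeds and kernels and is recorded
in the output so users can compare conventions.

Perimeter uses Kulpa-corrected chain weights — 0.948 per axial step, 1.343
per diagonal step — rather than raw $(1, \sqrt 2)$ weights. Raw weights
overestimate digitized smooth boundaries by about 5.5%, which pushes a
perfect disc's compactness down to ~0.90; the corrected weights are
unbiased for digitized circles, putting disc compactness at ~1.0 while
preserving the strict ordering disc > 2:1 ellipse > 5:1 rectangle that the
tests assert. The cost is a ~5% underestimate on perfectly axis-aligned
straight edges, which affects no ordering or equivariance property.

The canopy green ratio is the fraction of mask pixels inside the green HSV
band (default hue 60–180°, saturation ≥ 0.15, value ≥ 0.1).

## Geometry

* **RANSAC major axis** (`ransac_major_axis`): 200 two-point hypotheses by
  default, inliers within 2 px, total-least-squares refit on the best
  inlier set; deterministic given its seed, which is recorded in the
  output. On a filled ellipse the inlier band concentrates along the major
  axis, recovering orientation within ~3° at 2.5:1 elongation.
* **Ear axis** (`fit_ear_axis`): centers are rotated so their principal
  direction is the independent axis, then a degree-3 polynomial (the
  degree is configurable; 3 captures the gentle S-curves of real ears
  without chasing noise) is least-squares fitted. Because spikelets
  attach *alternately* left and right of the rachis, their midpoints
  zigzag about the axis; the spikelet pipeline therefore fits the
  polynomial to midpoints of consecutive centers ordered along the ear,
  which cancels the alternation exactly and keeps end tangents honest
  (raw zigzag fitting tilts the end tangents by up to ~10°). The fitted
  domain is stored; evaluating beyond it is flagged as extrapolation.
* **Zhang–Suen thinning**: the classical two-subpass iteration to a fixed
  point, vectorized over the foreground bounding box. The skeleton is a
  subset of the input and thinning is idempotent by construction (the
  suite also checks 1-px thickness on bars and topology preservation on an
  annulus).
* **Angles**: `angle_at_vertex` is the arccosine of the normalized dot
  product, checked against an independent atan2 formulation to 1e-9°.
  The flag-leaf angle needs a leaf-direction reference beyond the three
  organ keypoints (stem base A, spike tip B, leaf node C), so a fourth
  point L (leaf bounding-box center or tip) is an explicit input. Two
  modes are provided because the measurement convention is genuinely
  ambiguous: `node_stem_leaf` (default) measures at the node between C→B
  and C→L; `stem_axis_leaf` measures between the whole stem axis A→B and
  C→L. Neither is asserted as the one true protocol. Spikelet angles are
  folded to `[0, 90]` — chirality is not distinguished.

## Maize row features

Kernel centroids (from a detector, a CSV, or the classical yellow-blob
backend) are centered and rotated so the first principal component — the
ear's long axis — is horizontal. Rows are positions *across* that axis, so
1-D K-means on the cross-axis coordinate cannot split a long row
lengthwise, which 2-D clustering happily does. For each candidate row
count `k` in `[k_min, k_max]` (default 4–24, covering commercial maize),
K-means runs with a deterministic farthest-point initialization plus 9
seeded random restarts; the `k` maximizing mean silhouette width wins.
Counts per row are reported in cross-axis order and always sum to the
input point count. Only the visible face is reported; a documented
`row_multiplier` exists because single-view "row count" semantics are
ambiguous, and no hidden doubling is applied.

The PCA alignment rests on a geometric assumption: the point cloud's
extent *along* the ear (kernels per row times column pitch) must exceed
its extent *across* the rows. Real maize ears satisfy this comfortably —
a visible face carries roughly 25–40 kernels per row against 8–20 rows,
and the ear is several times longer than it is wide — and the synthetic
lattices are drawn in that regime (25+ columns). A lattice wider than it
is long would make the first principal component the cross-row axis and
row clustering would then run along the wrong coordinate.

## Wheat-head density and yield

After marker rectification, head-like blobs inside the marker interior are
found by Otsu thresholding of the non-white pixels, with a contrast guard:
when foreground and background means separate by fewer than 20 grey
levels — a noise-only plot — the pipeline reports zero heads rather than
shattering noise into spurious objects. Density is count over the marker's
physical area. Yield is reported **only** when the user supplies a
per-head grain weight (`head_weight_g`); the chain is
`kg/ha = density × head_weight_g × 10`, and both the weight factor and the
area unit are deliberately explicit configuration because no universal
convention exists.

## The synthetic scenes

Each generator is a pure function of its parameters and seed: integer
rasterization by pixel-center membership, no anti-aliasing, additive
Gaussian noise (default sd 5/255) on background pixels only. Ground truth
records the generative parameters — centers, semi-axes, orientations,
counts, scale, row labels, homographies, green fractions — so tests
compare measurements to exact truth. Defaults describe realistic captures:
a 640² tray with 20–80 seeds of 8–14 px semi-major axis and a 60 px coin;
ears of 12–24 spikelets at a fixed angle to a gentle cubic rachis; maize
lattices of 8–18 rows with jitter up to 15% of pitch; 1 m² markers at
~0.42 px/mm under mild projective warps. Pair overlap is parameterized as
`1 − d/(a₁+a₂)` (0 = tangent), so test difficulty is explicit.

What the scenes do *not* emulate: anti-aliased or motion-blurred edges,
uneven illumination and shadows, color casts, lens distortion, occlusion
by debris, and the long-tailed shape variation of real seed lots. Passing
the suite therefore demonstrates that the *measurement* stages are correct
and stable under controlled degradation — not that the classical detection
front-ends match a trained detector on field imagery. The
detection-backend contract exists precisely so a stronger detector can be
swapped in without touching the measurement code.

The soundness harness (`soundness_scores()`) varies the generative
parameters scene-by-scene (counts 20–80, size scale ±25%, angles 20–50°,
green fractions 0.2–0.9, densities 30–90 /m², rows 8–18) and reports
predicted-versus-truth $R^2$ per pipeline; the suite requires ≥ 0.95 for
counts and ≥ 0.90 for continuous traits over 100 scenes per pipeline. The
test suite uses 100-scene batches for counting, splitting, and row
recovery, 50 for calibration, 8 ears and 20 axis fits for spikelet
geometry — sizes chosen to estimate the rates tightly while keeping the
suite comfortably re-runnable.

## Degenerate inputs and error signalling

Errors are classed conditions (`pheno_coin_not_found`,
`pheno_marker_not_found`, `pheno_degenerate`, `pheno_insufficient_data`,
`pheno_out_of_domain`, ...), so pipelines can downgrade gracefully: a
missing coin yields pixel units, a missing marker yields uncalibrated
counts without density, fewer spikelets than the polynomial needs yields a
count without an axis, an empty foreground is a zero-count result rather
than an error. Degenerate geometry (coincident points, collinear marker
corners, zero reference variance in $R^2$) is always a typed error, never
a silent NaN.

## Known limitations

* Deeply fused pairs whose smaller member's half-width is below the neck
  width have no distance-transform catchment of their own; no
  marker-based watershed can separate them. They are rare under the
  documented overlap range (the splitting rate on disc pairs is ≥ 95%).
* The classical coin detector assumes the coin is the most circular large
  bright object; the fruit pipelines suppress fruit pixels before the
  coin check, but a perfectly circular bright distractor of coin size
  would win.
* Perimeter bias: Kulpa weights are tuned for smooth boundaries; long
  exactly-axis-aligned edges are measured ~5% short.
* PNG (and in-memory arrays) are the supported raster inputs.
* The whole-image homography warp uses nearest-neighbour sampling — exact
  for masks and counting, but not intended for photometric resampling.
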