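---
title: "Methods: lumen segmentation and quantification in endoscopic OCT pullbacks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lumen segmentation and quantification in endoscopic OCT pullbacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octlumen)
```

## Data model and conventions

A pullback stack is an ordered list of polar B-scans: numeric matrices
in [0, 1] whose rows are depth samples along an A-line (index `j`,
0-based, increasing away from the probe) and whose columns are angular
A-line positions (index `i`, 0-based). All public depth and A-line
indices in the package are 0-based, because the physical mapping is
anchored at index 0:

> radius(j) = `probe_offset_radius` + j × `radial_pixel_pitch` (mm)

with depth index 0 at the outer sheath surface. The inter-frame spacing
is `pullback_speed / frame_rate`; for a 5 mm/s pullback at 25 frames/s
(one frame per revolution at 1,500 rpm) that is 0.2 mm, so 150 frames
span 3 cm of airway. Intensities are normalized to [0, 1] at load time
(by the integer dtype maximum, or by the stack maximum for float input)
so that thresholds are independent of acquisition bit depth.

A boundary is one depth index per A-line with `|Δj| ≤ 1` between
neighbouring A-lines; the lumen mask of a frame marks every pixel with
`j < boundary(i)`, so mask column sums equal the boundary indices
exactly.

## The segmentation model

The pipeline assumes a single, roughly star-convex inner surface per
frame: each A-line crosses the lumen once and then enters tissue. Under
that assumption the inner surface is a function `j(i)` and can be found
as a minimum-cost left-to-right path. Airways with secondary ("false")
lumens from detached tissue layers violate the assumption; the masking
stage is designed so the tracer stays on the *innermost* surface, and
mapping secondary lumens is out of scope.

### De-noising

* **Median filter** (`median_kernel`, default 5 px): speckle is
  impulsive under coherent imaging, and a small median window removes
  it without displacing the wall edge. Padding is *reflected* in depth
  but *wrapped* across columns, because the angular direction is
  circular. The filtering itself is delegated to EBImage's
  constant-time median filter; its internal 16-bit quantization can
  perturb values by about 1.5 × 10⁻⁵, so the output is clipped to the
  input's [min, max] range, restoring the defining property that a
  median never leaves the input range.
* **A-line normalization** (`normalize_alines`, default on): each
  column is rescaled so its intensity sum equals the frame's mean
  column sum. This damps A-lines dominated by the specular sheath
  reflection while preserving overall brightness (a target of 1.0 would
  shift every binarization threshold). Zero-sum columns are left
  unscaled and reported rather than divided by zero. The operation is
  idempotent, and the order — median first, then normalization —
  follows the processing sequence of the de-noising stage. The frame is
  finally rescaled by its maximum to span [0, 1].

### Feature extraction

* **Binarization**: Otsu's threshold by default, because lumen/tissue
  histograms are strongly bimodal; a fixed threshold in (0, 1) can be
  substituted. The threshold is estimated below the sheath guard band,
  and a constant frame yields all-background with a warning rather than
  an error, so one blank frame cannot abort a pullback run.
* **Sheath guard band** (`sheath_exclusion_depth`, default 10 px): the
  transparent sheath produces bright rings at fixed shallow depth. The
  guard band forces those rows out of the binary image *and* out of the
  masked frame handed to the gradient, which matters in practice:
  with rings two rows apart, the middle ring survives a 5 × 5 median
  (15 of 25 window pixels are bright) and would otherwise offer the
  tracer a perfectly straight spurious edge. Small-object removal
  (`min_object_area`, default 200 px) additionally removes any residual
  ring fragments; both mechanisms are deliberate redundancy.
* **Connectivity**: components are 8-connected and the first/last
  columns are treated as adjacent (wrap-around), so a wall segment
  crossing the angular seam is one object, not two small ones.
* **Top-surface masking** (`surface_margin`, default 30 px): for each
  A-line, intensities deeper than `surface + margin` are set to zero
  ("zeroed" is the strongest reading of de-emphasizing sub-surface
  pixels, and makes the tracer provably blind to deeper surfaces).
  A-lines with no detected surface pass through unchanged and are
  reported, since zeroing them would fabricate an edge at row 0.
* **Depth gradient**: forward difference along depth, negative values
  clipped (the inner surface is a dark-to-bright transition moving away
  from the probe; falling edges belong to the far side of the wall),
  rescaled by the maximum. The response to a step sits on the
  lumen-side pixel of the transition, so traced boundaries carry a
  systematic −1 px offset relative to the first tissue pixel. At the
  default phantom geometry (5 µm radial pitch, 1–1.2 mm lumen radius)
  this is a −0.5 % radius (−1 % area) bias; it is the dominant term in
  the pipeline's volume error and the reason the phantom samples depth
  at the probe's axial-resolution scale (see below).

### Boundary tracing

Pixel transition weight: `w(a, b) = 2·max(I) − a − b`, where `max(I)`
is the gradient-image maximum — zero for the brightest possible
transition, always non-negative. Accumulated costs:

* Column 0 is seeded with `Cost(0, j) = w(I(0,j), I(0,j)) =
  2(max(I) − I(0, j))`, which favours starting on bright pixels without
  preferring any row a priori.
* For `i ≥ 1`, `Cost(i, j)` minimizes over predecessors
  `j′ ∈ {j−1, j, j+1}` with the weight scaled by `alpha` for diagonal
  moves. `alpha = sqrt(2)` by default — the geometric length ratio of a
  diagonal step — and is exposed because larger values visibly smooth
  the boundary. Out-of-range predecessors are simply excluded, so
  boundaries may run along `j = 0` or `j = depth − 1`.
* Ties break straight, then up, then down: determinism plus a
  preference for smooth boundaries.
* Traceback starts at the global minimum of the last column (smallest
  row on ties) and follows stored backpointers. This "global minimum"
  start is an interpretation — a fixed-row start would be the
  alternative — and is the natural reading of following minimum costs
  from the right-most column.
* **Circular closure**: the gradient image is duplicated and
  concatenated at both ends (`[G|G|G]`), the path is traced across the
  triple width, and the middle copy is returned. A step placed exactly
  at the seam is then crossed by a ±1 ramp rather than a discontinuity.
  The boundary is flagged closed when first and last columns are within
  one row; an open boundary warns but does not fail.

The recursion is validated against an independent oracle — exhaustive,
vectorized enumeration of *all* ±1-step paths — on hundreds of random
images up to 8 × 12 (the largest size at which 3¹¹ move sequences are
still cheap to enumerate), and the traced path is checked to realize the
enumerated minimum and to have minimum-cost prefixes.

### Quantification

Areas use the shoelace formula on the boundary polygon rather than
counting mask pixels: exact for polygonal data and independent of
rasterization. Radii are measured from the rotation axis, so the
probe/sheath cross-section is counted as lumen space — it occupies the
airway during the scan, and subtracting it would be a constant offset
either way. Volume uses the rectangle rule `Σ area × Δz`, matching the
voxel semantics of the exported binary mask stack (a trapezoid rule
would disagree with the masks it ships alongside). Mean/SD use the
sample (n − 1) denominator. Frames whose segmentation fails are
recorded as missing and excluded from mean, SD and volume — explicit
exclusion over silent interpolation — and a run aborts only when more
than 20 % of frames fail. The default regional split at 0.5 contrasts
the proximal and distal halves of the pullback.

### Agreement analysis

Bland–Altman on frame-aligned area series: bias = mean difference,
limits of agreement = bias ± 1.96 SD of the differences. The 1.96
normal-theory multiplier is used without a small-sample t correction; at
the 150-frame scale of a full pullback the correction is negligible.
Percent bias is defined as 100 × bias / (grand mean of the per-frame
means) — the conventional normalization of a Bland–Altman bias to the
measurement scale; other definitions exist, so the package documents
this one explicitly rather than asserting it as canonical.

## The phantom generator

`generate_phantom()` renders what the pipeline needs to see to be
testable: a dark lumen whose radius profile is known analytically, a
bright wall band with exponential depth attenuation, sheath rings near
the probe, mean-1 multiplicative gamma speckle, and additive Gaussian
background noise, all seeded and bit-reproducible. Ground truth stores
the rendered boundary rows, the *analytic* polar areas
`0.5 ∮ r(θ)² dθ` (computed by 4096-point quadrature on the radius
function, independent of the angular rasterization) and their volume —
an oracle that shares no code with the segmentation path.

Default conditions mirror a small-animal tracheal pullback: 150 frames
at 0.2 mm spacing (3 cm at 5 mm/s and 25 fps), lumen radius 1.2 mm
(2.4 mm diameter, at the lower end of the healthy rat trachea's
~2.4–2.8 mm so that injured-airway presets remain in the field of
view), wall band 0.3 mm at reflectivity 0.9 with attenuation 2 mm⁻¹,
180 A-lines (2°/A-line) and 360 depth samples at 5 µm/px. The 5 µm
radial pitch is chosen to match the probe's stated 6.8 µm axial
resolution — sampling at the resolution scale — and keeps the
one-pixel gradient-edge offset at a −1 % area bias; generic I/O
fixtures elsewhere in the package use a coarser 10 µm default pitch.
Morphology presets: `cylinder`, `ellipse` (polar ellipse, area πab),
`stenosis` (raised-cosine circumferential narrowing along the pullback;
halving the radius quarters the area at the stenosis centre), and
`flap` (raised-cosine radial bite over an angular sector, emulating
detached tissue protruding into the lumen).

What the phantom does *not* emulate — and what passing tests therefore
do not demonstrate on real data: non-uniform rotational distortion,
motion artifacts from breathing or pulsation, the OCT point-spread
function and sensitivity roll-off, intraluminal debris/fluid, and
multi-layer or false-lumen wall architecture. Noise levels (gamma shape
4, additive SD 0.02) describe a moderately noisy scan; heavier speckle
degrades the boundary RMSE before it degrades volume, because area
errors average out around the circumference.

## Numerical choices and degenerate inputs

* Constant frames: Otsu is undefined → all-background plus warning.
* All-background binary: masking is skipped with a warning; the
  gradient of the unmasked frame still feeds the tracer.
* Zero gradient images (max 0): left as zeros; the DP then returns the
  row-0 path by tie-break, and the closed flag still reports sanity.
* A-line normalization skips zero-sum columns; the final rescale by the
  frame maximum preserves column-sum equality exactly, and the
  coefficient of variation of column sums after normalization is below
  10⁻⁹ by construction.
* Boundary validity is enforced at construction (`|Δj| ≤ 1`, in-range),
  so malformed paths fail fast rather than producing silently wrong
  polygons.
* All pipeline stages are deterministic; run outputs (CSV/JSON/TIFF)
  are byte-identical across repeated runs on the same stack.

## Problem sizes in the test suite

Unit tests run the full chain on scaled-down phantoms (1–10 frames) and
validate the DP against enumeration on random images up to 8 × 12; the
end-to-end validation uses the full study conditions — 150-frame
phantoms, clean and noisy (three seeds), plus a noisy stenosis pullback
for the agreement property — chosen as the package's reference
workload: recovery within 2 % (noise-free) and 5 % (noisy) of the
analytic cylinder volume, boundary RMSE within 2 px, and Bland–Altman
percent bias within 5 % on the stenosis stack.

## Known limitations

* One boundary row per A-line: vertical or overhanging wall sections
  cannot be followed; this is inherent to the 3-predecessor recursion.
* The −1 px edge localization bias is geometry-dependent: at coarse
  radial pitch or small lumens it grows proportionally
  (2 × pitch / radius in area).
* The traceback-start and percent-bias definitions are documented
  interpretations (see above), not the only possible ones.
* Areas include the probe/sheath cross-section; subtract
  `π × probe_offset_radius²` per frame if the open-air lumen is wanted.
* No cross-frame regularization: each B-scan is segmented
  independently, so frame-to-frame jitter in very noisy stacks is not
  smoothed.
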