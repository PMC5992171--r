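# octlumen

Automated segmentation and structural quantification of the inner airway
lumen in endoscopic optical coherence tomography (OCT) pullback scans.

## The problem

Rotational endoscopic OCT probes image the airway from the inside: each
B-scan is a polar image (rows = depth along an A-line, columns = angular
position) acquired during one probe revolution, and a constant-speed
pullback stacks B-scans along the airway axis. Quantifying airway
obstruction — e.g. after toxic-gas inhalation injury in small-animal
models — requires tracing the inner luminal surface in every frame,
converting the traces to cross-sectional areas, and integrating a lumen
volume. Manual tracing of hundreds of frames is slow and reader-dependent;
`octlumen` automates it for researchers running such pullback studies.

## The method

Each frame passes through three stages:

1. **De-noising** — a square median filter (reflect padding in depth,
   wrap padding across the circular angular direction) suppresses
   speckle, and each A-line's summed intensity is normalized to reduce
   the bright sheath reflection.
2. **Feature extraction** — Otsu binarization exposes the wall, small
   connected components (8-connected, wrap-aware) are removed, pixels
   beneath the innermost tissue surface are masked out, and the depth
   gradient (forward difference, rising edges only) highlights the
   lumen-to-tissue transition.
3. **Edge detection** — the boundary is the minimum-cost left-to-right
   path through the gradient image *G* under the dynamic program

   ```
   Cost(i, j) = min { alpha * w(G(i-1, j+1), G(i, j)) + Cost(i-1, j+1)
                ,            w(G(i-1, j  ), G(i, j)) + Cost(i-1, j  )
                ,     alpha * w(G(i-1, j-1), G(i, j)) + Cost(i-1, j-1) }

   w(a, b) = 2 * max(G) - a - b
   ```

   with `alpha >= 1` penalizing diagonal moves (default `sqrt(2)`).
   Costs accumulate from the left edge; the trace follows backpointers
   from the minimum-cost pixel of the right-most column. Because the
   angular direction is circular, the image is duplicated and
   concatenated at both ends before tracing and the middle copy's path
   is returned, keeping the boundary connected across the seam.

A-line *i* of *W* at boundary depth *j* maps to the Cartesian vertex at
angle `2*pi*i/W` and radius `probe_offset_radius + j * radial_pixel_pitch`;
per-frame area is the shoelace polygon area, and total volume is
`sum(area) * frame_spacing` with `frame_spacing = pullback_speed /
frame_rate`. Agreement between two segmentations (e.g. automated vs
manual) is summarized with Bland–Altman bias and 95% limits of agreement.

Because no real pullback data ship with the package, a seeded phantom
generator (`generate_phantom()`) renders OCT-like stacks — tissue band
with depth attenuation, sheath reflection rings, multiplicative gamma
speckle, additive noise, and cylinder / ellipse / stenosis / flap
morphology — together with analytic ground truth (boundary rows, polar
areas `0.5 * integral r(theta)^2 dtheta`, volume).

## Worked example

A noisy cylindrical pullback (radius 1 mm, 150 frames at 0.2 mm spacing,
speckle shape 4, additive noise SD 0.02), segmented with the defaults:

```r
library(octlumen)

ph <- generate_phantom(phantom_spec(
  n_frames = 150, lumen_radius_fn = radius_cylinder(1.0),
  speckle_shape = 4, background_noise_sd = 0.02, seed = 1))
res <- run_pipeline(ph$stack, pipeline_config())
res$report
#> Lumen quantification over 150 frames (0 missing)
#>   mean area   : 3.111 +/- 0.001 mm^2
#>   total volume: 93.33 mm^3 (frame spacing 0.200 mm)
#>   region frame_lo frame_hi  n mean_area     sd_area
#>    0-50%        1       75 75  3.110895 0.001191054
#>  50-100%       76      150 75  3.110790 0.001047332

bland_altman(res$report$per_frame_area, ph$truth$area_mm2)
#> Bland-Altman: bias -0.0308 mm^2 (-0.98%), 95% LoA [-0.0329, -0.0286]
```

The analytic volume of this phantom is `pi * 30 = 94.25` mm³; the
pipeline recovers 93.33 mm³ (−1.0%), the small deficit coming from the
one-pixel lumen-side localization of the gradient edge. The regional
summary contrasts the proximal and distal halves of the pullback — for a
stenosis phantom the 50–100% rows drop accordingly.

A shell entry point wrapping the same functions lives at
`inst/cli/octlumen.R`:

```sh
Rscript inst/cli/octlumen.R phantom --preset stenosis --noisy --seed 7 \
    --out phantom.tiff --truth truth.json
Rscript inst/cli/octlumen.R run --input phantom.tiff --config cfg.yaml --out results/
Rscript inst/cli/octlumen.R compare --a results/areas.csv --b manual.csv \
    --out bland_altman.json --png bland_altman.png
```

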