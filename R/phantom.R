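#' Lumen radius profile presets
#'
#' Construct radius functions `r(angle_frac, z_frac)` (mm) for the
#' phantom generator. `angle_frac` is the angular position in \[0, 1)
#' and `z_frac` the pullback position in \[0, 1\]; both are vectorized
#' over angle.
#'
#' * `radius_cylinder(r)`: constant radius.
#' * `radius_ellipse(a, b)`: elliptical cross-section with semi-axes
#'   `a`, `b` centred on the probe, `r(theta) = a*b /
#'   sqrt((b*cos(theta))^2 + (a*sin(theta))^2)` (area `pi*a*b`).
#' * `radius_stenosis(r, depth_of_narrowing, z_center, z_width)`: a
#'   raised-cosine circumferential narrowing along the pullback; at
#'   `z_center` the radius is `r * (1 - depth_of_narrowing)`, recovering
#'   to `r` outside `z_center +/- z_width/2` (fractions of the pullback).
#' * `radius_flap(r, angular_extent, lift)`: a raised-cosine bite of
#'   depth `lift` mm over an angular fraction `angular_extent` centred
#'   at angle 0 — tissue detached from the wall hanging into the lumen.
#'
#' @param r,a,b Radii / semi-axes in mm.
#' @param depth_of_narrowing Fractional radius reduction at the stenosis
#'   centre, in \[0, 1).
#' @param z_center,z_width Centre and full width of the stenosis as
#'   fractions of the pullback length.
#' @param angular_extent Angular fraction (of the full turn) covered by
#'   the flap.
#' @param lift Maximum radial protrusion of the flap into the lumen, mm.
#' @return A function `(angle_frac, z_frac) -> radius (mm)`.
#' @name radius_presets
NULL

#' @rdname radius_presets
#' @export
radius_cylinder <- function(r = 1.2) {
  force(r)
  function(angle_frac, z_frac) rep(r, length(angle_frac))
}

#' @rdname radius_presets
#' @export
radius_ellipse <- function(a = 1.4, b = 1.0) {
  force(a); force(b)
  function(angle_frac, z_frac) {
    th <- 2 * pi * angle_frac
    a * b / sqrt((b * cos(th))^2 + (a * sin(th))^2)
  }
}

#' @rdname radius_presets
#' @export
radius_stenosis <- function(r = 1.2, depth_of_narrowing = 0.5,
                            z_center = 0.5, z_width = 1 / 3) {
  force(r); force(depth_of_narrowing); force(z_center); force(z_width)
  function(angle_frac, z_frac) {
    u <- (z_frac - z_center) / z_width
    w <- if (abs(u) <= 0.5) 0.5 * (1 + cos(2 * pi * u)) else 0
    rep(r * (1 - depth_of_narrowing * w), length(angle_frac))
  }
}

#' @rdname radius_presets
#' @export
radius_flap <- function(r = 1.2, angular_extent = 0.25, lift = 0.5) {
  force(r); force(angular_extent); force(lift)
  function(angle_frac, z_frac) {
    # signed angular distance from the flap centre at angle 0
    d <- angle_frac - round(angle_frac)
    u <- d / angular_extent
    w <- ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
    r - lift * w
  }
}

#' Specification of a synthetic OCT pullback phantom
#'
#' Defines an airway-like pullback stack with known ground truth: a
#' lumen of prescribed radius profile, a bright tissue band of given
#' thickness and reflectivity decaying with depth, bright sheath
#' reflection rings near the probe, multiplicative gamma speckle and
#' additive background noise. The defaults mirror a rat-trachea scan:
#' 150 frames at 0.2 mm spacing (3 cm pullback, 5 mm/s at 25 fps), a
#' 2.4 mm diameter lumen, 0.3 mm wall band, with depth sampled at
#' 5 um/px (the probe's axial resolution scale).
#'
#' @param n_frames Number of B-scans in the pullback.
#' @param n_alines Angular A-lines per frame (columns).
#' @param n_depth Depth samples per A-line (rows).
#' @param geometry An [acquisition_geometry()].
#' @param lumen_radius_fn Radius function from [radius_presets], or any
#'   `function(angle_frac, z_frac) -> mm`.
#' @param tissue_thickness Wall band thickness, mm.
#' @param tissue_reflectivity Peak tissue intensity in (0, 1].
#' @param attenuation Intensity attenuation with depth inside tissue,
#'   1/mm.
#' @param speckle_shape Shape of the multiplicative mean-1 gamma speckle
#'   field; `NULL` disables speckle. Smaller shape = heavier speckle
#'   (shape 4 is a moderately noisy scan).
#' @param sheath_ring_rows 0-based depth rows carrying bright sheath
#'   reflection rings.
#' @param sheath_ring_intensity Intensity of the sheath rings.
#' @param background_noise_sd SD of additive Gaussian background noise.
#' @param seed Integer RNG seed; the same spec and seed reproduce the
#'   stack bit-identically.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_frames = 150,
                         n_alines = 180,
                         n_depth = 360,
                         geometry = acquisition_geometry(
                           radial_pixel_pitch = 0.005,
                           probe_offset_radius = 0.3,
                           pullback_speed = 5, frame_rate = 25),
                         lumen_radius_fn = radius_cylinder(1.2),
                         tissue_thickness = 0.3,
                         tissue_reflectivity = 0.9,
                         attenuation = 2,
                         speckle_shape = NULL,
                         sheath_ring_rows = c(2, 4, 6),
                         sheath_ring_intensity = 0.8,
                         background_noise_sd = 0,
                         seed = 1) {
  stopifnot(n_frames >= 1, n_alines >= 8, n_depth >= 8,
            inherits(geometry, "acq_geometry"),
            is.function(lumen_radius_fn),
            tissue_thickness > 0,
            tissue_reflectivity > 0, tissue_reflectivity <= 1,
            attenuation >= 0, background_noise_sd >= 0)
  if (!is.null(speckle_shape) && speckle_shape <= 0)
    stop("speckle_shape must be positive")
  structure(list(n_frames = as.integer(n_frames),
                 n_alines = as.integer(n_alines),
                 n_depth = as.integer(n_depth),
                 geometry = geometry,
                 lumen_radius_fn = lumen_radius_fn,
                 tissue_thickness = tissue_thickness,
                 tissue_reflectivity = tissue_reflectivity,
                 attenuation = attenuation,
                 speckle_shape = speckle_shape,
                 sheath_ring_rows = as.integer(sheath_ring_rows),
                 sheath_ring_intensity = sheath_ring_intensity,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# analytic polar area 0.5 * integral r(theta)^2 dtheta, independent of
# the angular rasterization
analytic_polar_area <- function(radius_fn, z_frac, n_theta = 4096) {
  af <- (seq_len(n_theta) - 1) / n_theta
  r <- radius_fn(af, z_frac)
  if (length(r) == 1) r <- rep(r, n_theta)
  0.5 * sum(r^2) * (2 * pi / n_theta)
}

#' Generate a synthetic OCT pullback stack with ground truth
#'
#' Renders each frame from the radius profile: intensity 0 inside the
#' lumen, `tissue_reflectivity * exp(-attenuation * depth_into_tissue)`
#' across the wall band, 0 beyond; sheath rings are overlaid near the
#' probe; then multiplicative gamma speckle (mean 1) and additive
#' Gaussian noise are applied and the frame is clipped to \[0, 1\].
#'
#' @param spec A [phantom_spec()].
#' @return A list with `stack` (a [bscan_stack()]) and `truth`, an
#'   object of class `phantom_truth` holding `boundary_rows` (n_frames x
#'   n_alines matrix of 0-based first-tissue depth rows), `area_mm2`
#'   (per-frame analytic polar areas), `volume_mm3` (their rectangle-rule
#'   integral), `thickness_px` and the spec.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$geometry
  pitch <- g$radial_pixel_pitch
  nr <- spec$n_depth; W <- spec$n_alines; nf <- spec$n_frames
  thick_px <- max(1L, as.integer(round(spec$tissue_thickness / pitch)))
  af <- (seq_len(W) - 1) / W
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)
  frames <- vector("list", nf)
  boundary_rows <- matrix(NA_integer_, nf, W)
  areas <- numeric(nf)
  rows0 <- matrix(seq_len(nr) - 1L, nr, W)
  for (f in seq_len(nf)) {
    zf <- if (nf == 1) 0 else (f - 1) / (nf - 1)
    r <- spec$lumen_radius_fn(af, zf)
    if (length(r) == 1) r <- rep(r, W)
    if (any(r < g$probe_offset_radius))
      stop("lumen radius below the probe offset radius")
    jstar <- as.integer(round((r - g$probe_offset_radius) / pitch))
    if (any(jstar + thick_px > nr))
      stop("lumen outside field of view")
    boundary_rows[f, ] <- jstar
    areas[f] <- analytic_polar_area(spec$lumen_radius_fn, zf)
    jmat <- matrix(jstar, nr, W, byrow = TRUE)
    depth_in <- (rows0 - jmat) * pitch
    frame <- ifelse(rows0 >= jmat & rows0 < jmat + thick_px,
                    spec$tissue_reflectivity *
                      exp(-spec$attenuation * depth_in),
                    0)
    if (length(spec$sheath_ring_rows) > 0) {
      rr <- spec$sheath_ring_rows[spec$sheath_ring_rows < nr] + 1L
      frame[rr, ] <- pmax(frame[rr, ], spec$sheath_ring_intensity)
    }
    if (!is.null(spec$speckle_shape))
      frame <- frame * matrix(stats::rgamma(nr * W, shape = spec$speckle_shape,
                                            rate = spec$speckle_shape), nr, W)
    if (spec$background_noise_sd > 0)
      frame <- frame + matrix(stats::rnorm(nr * W, 0,
                                           spec$background_noise_sd), nr, W)
    frames[[f]] <- pmin(pmax(frame, 0), 1)
  }
  truth <- structure(list(boundary_rows = boundary_rows,
                          area_mm2 = areas,
                          volume_mm3 = sum(areas) *
                            (if (is.null(g$frame_spacing)) NA_real_
                             else g$frame_spacing),
                          thickness_px = thick_px,
                          spec = spec),
                     class = "phantom_truth")
  list(stack = bscan_stack(frames, g), truth = truth)
}

#' Ground-truth tissue mask of one phantom frame
#'
#' @param truth A `phantom_truth` from [generate_phantom()].
#' @param frame 1-based frame number.
#' @return Logical matrix: `TRUE` inside the rendered tissue band.
#' @export
tissue_mask <- function(truth, frame = 1) {
  stopifnot(inherits(truth, "phantom_truth"))
  nr <- truth$spec$n_depth; W <- truth$spec$n_alines
  rows0 <- matrix(seq_len(nr) - 1L, nr, W)
  jmat <- matrix(truth$boundary_rows[frame, ], nr, W, byrow = TRUE)
  rows0 >= jmat & rows0 < jmat + truth$thickness_px
}

#' Quantification report from phantom ground truth
#'
#' Builds a [stack_quantify()]-style report directly from the analytic
#' per-frame polar areas — no segmentation involved — for use as an
#' independent oracle against pipeline output.
#'
#' @param truth A `phantom_truth` from [generate_phantom()].
#' @param geometry An [acquisition_geometry()] with positive
#'   `frame_spacing`.
#' @param region_splits Passed through to the regional summary.
#' @return A `quant_report`.
#' @export
ground_truth_report <- function(truth, geometry = truth$spec$geometry,
                                region_splits = 0.5) {
  stopifnot(inherits(truth, "phantom_truth"))
  spacing <- geometry$frame_spacing
  if (is.null(spacing) || spacing <= 0)
    stop("frame_spacing must be > 0")
  areas <- truth$area_mm2
  n <- length(areas)
  structure(list(
    per_frame_area = areas,
    z_mm = (seq_len(n) - 1) * spacing,
    total_volume = sum(areas) * spacing,
    mean_area = mean(areas),
    sd_area = if (n >= 2) stats::sd(areas) else NA_real_,
    n_frames = n,
    n_missing = 0L,
    region_summaries = region_table(areas, region_splits),
    frame_spacing = spacing),
    class = "quant_report")
}
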