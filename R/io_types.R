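#' octlumen: automated lumen segmentation for endoscopic OCT pullbacks
#'
#' Tools to segment the inner airway lumen in polar-coordinate endoscopic
#' OCT B-scan stacks, quantify per-frame cross-sectional area and total
#' lumen volume, compare segmentations with Bland-Altman statistics, and
#' generate synthetic phantom pullbacks with analytic ground truth.
#'
#' Conventions used throughout: a B-scan is a numeric matrix with rows =
#' depth samples along an A-line (index j, 0-based, increasing away from
#' the probe) and columns = angular A-line positions (index i, 0-based,
#' increasing with rotation angle); intensities lie in \[0, 1\]. The radius
#' of depth index j is `probe_offset_radius + j * radial_pixel_pitch`.
#'
#' @keywords internal
"_PACKAGE"

#' Acquisition geometry of a rotational OCT pullback
#'
#' Describes how pixel indices of a polar B-scan stack map to physical
#' millimetres: the radial sampling pitch, the radial offset of depth
#' index 0 from the rotation axis (the sheath surface where imaging
#' starts), and the longitudinal spacing between consecutive frames.
#'
#' `frame_spacing` is derived as `pullback_speed / frame_rate` when both
#' are given; if supplied explicitly alongside both rates it must agree
#' with that ratio. If `rotation_speed` (rpm) is given together with
#' `frame_rate`, one frame per revolution is assumed and a mismatch with
#' `rotation_speed / 60` raises a warning. A `frame_spacing` of zero is
#' accepted at construction (e.g. a stationary probe) but rejected by
#' [stack_quantify()], which needs a positive spacing to integrate volume.
#'
#' @param radial_pixel_pitch Length per depth pixel, mm/px. Must be > 0.
#' @param probe_offset_radius Radial distance from the rotation axis to
#'   depth index 0, mm. Must be >= 0.
#' @param pullback_speed Pullback translation speed, mm/s (optional).
#' @param frame_rate Frame acquisition rate, frames/s (optional).
#' @param rotation_speed Probe rotation speed, rev/min (optional,
#'   informational; one frame per revolution).
#' @param frame_spacing Longitudinal distance between frames, mm. Derived
#'   from `pullback_speed / frame_rate` when omitted.
#' @return An object of class `acq_geometry`: a list with the fields above.
#' @examples
#' acquisition_geometry(pullback_speed = 5, frame_rate = 25)$frame_spacing # 0.2
#' @seealso [derive_geometry()]
#' @export
acquisition_geometry <- function(radial_pixel_pitch = 0.01,
                                 probe_offset_radius = 0.3,
                                 pullback_speed = NULL,
                                 frame_rate = NULL,
                                 rotation_speed = NULL,
                                 frame_spacing = NULL) {
  stopifnot(is.numeric(radial_pixel_pitch), length(radial_pixel_pitch) == 1,
            radial_pixel_pitch > 0)
  stopifnot(is.numeric(probe_offset_radius), length(probe_offset_radius) == 1,
            probe_offset_radius >= 0)
  if (!is.null(frame_rate) && frame_rate <= 0)
    stop("frame_rate must be > 0")
  if (!is.null(rotation_speed) && !is.null(frame_rate)) {
    if (abs(rotation_speed / 60 - frame_rate) > 1e-9 * max(1, frame_rate))
      warning("rotation_speed/60 (", rotation_speed / 60,
              " fps) does not match frame_rate (", frame_rate, " fps)")
  }
  if (is.null(frame_rate) && !is.null(rotation_speed)) {
    if (rotation_speed <= 0) stop("rotation_speed must be > 0")
    frame_rate <- rotation_speed / 60
  }
  derived <- if (!is.null(pullback_speed) && !is.null(frame_rate))
    pullback_speed / frame_rate else NULL
  if (is.null(frame_spacing)) {
    frame_spacing <- derived
  } else if (!is.null(derived) &&
             abs(frame_spacing - derived) > 1e-9 * max(1, derived)) {
    stop("frame_spacing (", frame_spacing, ") inconsistent with ",
         "pullback_speed / frame_rate (", derived, ")")
  }
  if (!is.null(frame_spacing) && frame_spacing < 0)
    stop("frame_spacing must be >= 0")
  if (!is.null(pullback_speed) && pullback_speed < 0)
    stop("pullback_speed must be >= 0")
  structure(list(radial_pixel_pitch = radial_pixel_pitch,
                 probe_offset_radius = probe_offset_radius,
                 pullback_speed = pullback_speed,
                 frame_rate = frame_rate,
                 rotation_speed = rotation_speed,
                 frame_spacing = frame_spacing),
            class = "acq_geometry")
}

#' Derive acquisition geometry from scan-motor settings
#'
#' Computes the inter-frame spacing from the pullback speed and frame
#' rate. When the frame rate is omitted it is taken as one frame per
#' probe revolution, `rotation_speed / 60`.
#'
#' @inheritParams acquisition_geometry
#' @param ... Further arguments passed to [acquisition_geometry()]
#'   (e.g. `radial_pixel_pitch`, `probe_offset_radius`).
#' @return An `acq_geometry` object with `frame_spacing` filled in.
#' @examples
#' derive_geometry(5, 25)$frame_spacing              # 0.2 mm
#' derive_geometry(5, rotation_speed = 1500)$frame_rate  # 25 fps
#' @export
derive_geometry <- function(pullback_speed, frame_rate = NULL,
                            rotation_speed = NULL, ...) {
  if (is.null(frame_rate) && is.null(rotation_speed))
    stop("one of frame_rate or rotation_speed is required")
  acquisition_geometry(pullback_speed = pullback_speed,
                       frame_rate = frame_rate,
                       rotation_speed = rotation_speed, ...)
}

#' @export
print.acq_geometry <- function(x, ...) {
  cat("Acquisition geometry\n")
  cat("  radial pixel pitch : ", x$radial_pixel_pitch, " mm/px\n", sep = "")
  cat("  probe offset radius: ", x$probe_offset_radius, " mm\n", sep = "")
  if (!is.null(x$pullback_speed))
    cat("  pullback speed     : ", x$pullback_speed, " mm/s\n", sep = "")
  if (!is.null(x$frame_rate))
    cat("  frame rate         : ", x$frame_rate, " fps\n", sep = "")
  if (!is.null(x$frame_spacing))
    cat("  frame spacing      : ", x$frame_spacing, " mm\n", sep = "")
  invisible(x)
}

validate_frame <- function(frame, min_dim = 1L) {
  if (!is.matrix(frame) || !is.numeric(frame))
    stop("frame must be a numeric matrix")
  if (nrow(frame) < min_dim || ncol(frame) < min_dim)
    stop("frame must be at least ", min_dim, "x", min_dim)
  if (anyNA(frame) || min(frame) < 0 || max(frame) > 1)
    stop("frame intensities must lie in [0, 1]")
  invisible(frame)
}

#' Assemble a B-scan stack
#'
#' Bundles an ordered list of polar B-scan frames (numeric matrices in
#' \[0, 1\], rows = depth, columns = A-lines) with the acquisition
#' geometry. All frames must share one shape of at least 8 x 8.
#'
#' @param frames List of numeric matrices, one per pullback position.
#' @param geometry An [acquisition_geometry()] object.
#' @return An object of class `bscan_stack` with elements `frames` and
#'   `geometry`.
#' @export
bscan_stack <- function(frames, geometry) {
  if (!inherits(geometry, "acq_geometry"))
    stop("geometry must be an acq_geometry object")
  if (!is.list(frames) || length(frames) == 0)
    stop("no frames")
  dims <- vapply(frames, function(f) dim(f), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shape mismatch: frames differ in size")
  for (f in frames) validate_frame(f, min_dim = 8L)
  structure(list(frames = frames, geometry = geometry),
            class = "bscan_stack")
}

#' @export
print.bscan_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat("B-scan stack: ", length(x$frames), " frames of ",
      d[1], " depth px x ", d[2], " A-lines\n", sep = "")
  print(x$geometry)
  invisible(x)
}

read_one_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path, all = FALSE),
    "png" = png::readPNG(path),
    stop("unsupported image format: ", path))
  if (length(dim(img)) == 3) img <- img[, , 1]  # drop channels if present
  img
}

#' Load a pullback stack from disk
#'
#' Reads a multi-page TIFF, or a directory of single-frame TIFF/PNG
#' images taken in lexicographic filename order. Integer images are
#' scaled to \[0, 1\] by their dtype maximum (the behaviour of the tiff
#' and png readers); floating-point TIFF data with values above 1 are
#' scaled by the stack maximum.
#'
#' @param path Path to a multi-page TIFF file or a directory of frames.
#' @param geometry An [acquisition_geometry()] object.
#' @return A [bscan_stack()].
#' @export
load_bscan_stack <- function(path, geometry) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(tiff?|png)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no frames in directory ", path)
    frames <- lapply(files, read_one_frame)
  } else {
    if (!file.exists(path)) stop("cannot read ", path)
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    frames <- lapply(frames, function(img) {
      if (length(dim(img)) == 3) img[, , 1] else img
    })
  }
  if (length(frames) == 0) stop("no frames")
  mx <- max(vapply(frames, max, numeric(1)))
  if (mx > 1) frames <- lapply(frames, function(f) f / mx)
  bscan_stack(frames, geometry)
}

#' Write a stack of frames to a multi-page TIFF
#'
#' @param stack A [bscan_stack()] or a plain list of numeric matrices in
#'   \[0, 1\].
#' @param path Output TIFF path.
#' @param bits_per_sample 8 or 16; integer quantization of the output.
#' @return `path`, invisibly.
#' @export
write_bscan_stack <- function(stack, path, bits_per_sample = 16) {
  frames <- if (inherits(stack, "bscan_stack")) stack$frames else stack
  tiff::writeTIFF(frames, path, bits.per.sample = bits_per_sample)
  invisible(path)
}
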