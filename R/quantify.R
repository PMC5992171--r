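#' Convert a traced boundary to a Cartesian cross-section polygon
#'
#' A-line i (0-based, of W) sits at angle `theta_i = 2*pi*i/W`; its
#' boundary depth index j maps to radius
#' `r_i = probe_offset_radius + j * radial_pixel_pitch` (mm, measured
#' from the rotation axis, so the probe/sheath cross-section is counted
#' as lumen space). Vertices are `(r_i cos theta_i, r_i sin theta_i)`.
#'
#' @param boundary A [lumen_boundary()]. A warning is raised when it is
#'   not closed.
#' @param geometry An [acquisition_geometry()].
#' @return An object of class `lumen_polygon`: an n x 2 matrix of (x, y)
#'   vertices in mm, implicitly closed.
#' @export
boundary_to_polygon <- function(boundary, geometry) {
  stopifnot(inherits(boundary, "lumen_boundary"),
            inherits(geometry, "acq_geometry"))
  if (!boundary$closed)
    warning("boundary is not closed; polygon may self-intersect at the seam")
  W <- boundary$n_alines
  theta <- 2 * pi * (seq_len(W) - 1) / W
  r <- geometry$probe_offset_radius +
    boundary$depth_index * geometry$radial_pixel_pitch
  structure(cbind(x = r * cos(theta), y = r * sin(theta)),
            class = c("lumen_polygon", "matrix"))
}

#' Polygon area by the shoelace formula
#'
#' @param polygon An n x 2 matrix of ordered (x, y) vertices in mm,
#'   closed implicitly; at least 3 vertices.
#' @return Cross-sectional area in mm^2 (absolute value).
#' @export
cross_section_area <- function(polygon) {
  if (nrow(polygon) < 3) stop("polygon must have at least 3 vertices")
  x <- polygon[, 1]; y <- polygon[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Rasterize the intraluminal space of one frame
#'
#' Builds the polar binary mask used for 3D stack export: pixel (j, i)
#' is lumen iff `j < depth_index[i]` (0-based), i.e. everything between
#' the probe and the traced surface. Column sums of the mask equal the
#' boundary depth indices exactly.
#'
#' @param boundary A [lumen_boundary()].
#' @param frame_shape Integer vector `c(rows, cols)` of the source frame.
#' @return Logical matrix of that shape.
#' @export
lumen_mask <- function(boundary, frame_shape) {
  stopifnot(inherits(boundary, "lumen_boundary"),
            length(frame_shape) == 2,
            boundary$n_alines == frame_shape[2])
  rows0 <- matrix(seq_len(frame_shape[1]) - 1L, frame_shape[1], frame_shape[2])
  jmat <- matrix(boundary$depth_index, frame_shape[1], frame_shape[2],
                 byrow = TRUE)
  rows0 < jmat
}

region_table <- function(areas, region_splits) {
  n <- length(areas)
  cuts <- unique(c(0, pmin(pmax(region_splits, 0), 1), 1))
  cuts <- sort(cuts)
  idx <- round(cuts * n)
  out <- data.frame(region = character(0), frame_lo = integer(0),
                    frame_hi = integer(0), n = integer(0),
                    mean_area = numeric(0), sd_area = numeric(0))
  for (k in seq_len(length(idx) - 1)) {
    lo <- idx[k] + 1L; hi <- idx[k + 1]
    if (hi < lo) next
    a <- areas[lo:hi]
    out <- rbind(out, data.frame(
      region = sprintf("%.0f-%.0f%%", 100 * cuts[k], 100 * cuts[k + 1]),
      frame_lo = lo, frame_hi = hi, n = sum(!is.na(a)),
      mean_area = mean(a, na.rm = TRUE),
      sd_area = stats::sd(a, na.rm = TRUE)))
  }
  out
}

#' Quantify a stack of traced boundaries
#'
#' Converts each boundary to a Cartesian polygon, computes per-frame
#' cross-sectional areas (shoelace formula) and integrates total lumen
#' volume by the rectangle rule, `sum(area) * frame_spacing`, matching
#' the voxel semantics of a binary mask stack. Frames whose boundary is
#' `NA` (failed detection) are excluded from the mean, SD and volume;
#' their count is reported. Mean/SD use the n-1 (sample) denominator.
#'
#' @param boundaries List of [lumen_boundary()] objects; entries may be
#'   `NA` for frames where detection failed.
#' @param geometry An [acquisition_geometry()] with `frame_spacing > 0`.
#' @param region_splits Fractions of the pullback at which to cut
#'   contiguous frame regions for regional summaries; the default `0.5`
#'   contrasts the proximal and distal halves.
#' @return An object of class `quant_report`: list with `per_frame_area`
#'   (mm^2, `NA` where detection failed), `z_mm`, `total_volume` (mm^3),
#'   `mean_area`, `sd_area`, `n_frames`, `n_missing`, `region_summaries`
#'   (data.frame) and `frame_spacing`.
#' @export
stack_quantify <- function(boundaries, geometry, region_splits = 0.5) {
  stopifnot(inherits(geometry, "acq_geometry"))
  if (length(boundaries) < 1) stop("no frames")
  spacing <- geometry$frame_spacing
  if (is.null(spacing) || spacing <= 0)
    stop("frame_spacing must be > 0 to quantify a stack")
  areas <- vapply(boundaries, function(b) {
    if (inherits(b, "lumen_boundary"))
      cross_section_area(boundary_to_polygon(b, geometry))
    else NA_real_
  }, numeric(1))
  n <- length(areas)
  detected <- sum(!is.na(areas))
  structure(list(
    per_frame_area = areas,
    z_mm = (seq_len(n) - 1) * spacing,
    total_volume = sum(areas, na.rm = TRUE) * spacing,
    mean_area = mean(areas, na.rm = TRUE),
    sd_area = if (detected >= 2) stats::sd(areas, na.rm = TRUE) else NA_real_,
    n_frames = n,
    n_missing = n - detected,
    region_summaries = region_table(areas, region_splits),
    frame_spacing = spacing),
    class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat("Lumen quantification over ", x$n_frames, " frames (",
      x$n_missing, " missing)\n", sep = "")
  cat(sprintf("  mean area   : %.3f +/- %.3f mm^2\n", x$mean_area, x$sd_area))
  cat(sprintf("  total volume: %.2f mm^3 (frame spacing %.3f mm)\n",
              x$total_volume, x$frame_spacing))
  print(x$region_summaries, row.names = FALSE)
  invisible(x)
}

#' Write per-frame areas to CSV
#'
#' One row per frame: 0-based frame index, pullback position z (mm) and
#' cross-sectional area (mm^2).
#'
#' @param report A [stack_quantify()] report.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_areas_csv <- function(report, path) {
  df <- data.frame(frame = seq_along(report$per_frame_area) - 1L,
                   z_mm = report$z_mm,
                   area_mm2 = report$per_frame_area)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a quantification report as JSON
#'
#' @param report A [stack_quantify()] report (or any serializable list).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns", na = "null")
  invisible(path)
}
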