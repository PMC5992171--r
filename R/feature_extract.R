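#' Feature-extraction parameters
#'
#' @param threshold_method `"otsu"` or a fixed threshold in (0, 1).
#' @param min_object_area Minimum connected-component size (pixels) kept
#'   by [remove_small_objects()]; separates tissue from small artifacts
#'   such as residual sheath reflections.
#' @param surface_margin Pixels retained below the detected top surface
#'   in [top_surface_mask()]; everything deeper is zeroed so only the
#'   innermost luminal surface remains for edge detection.
#' @param sheath_exclusion_depth Rows at the top of every A-line forced
#'   to background during binarization — a guard band over the sheath
#'   reflection rings right at the probe.
#' @return An object of class `feature_params`.
#' @export
feature_params <- function(threshold_method = "otsu",
                           min_object_area = 200,
                           surface_margin = 30,
                           sheath_exclusion_depth = 10) {
  if (!identical(threshold_method, "otsu")) {
    if (!is.numeric(threshold_method) || threshold_method <= 0 ||
        threshold_method >= 1)
      stop("threshold_method must be \"otsu\" or a number in (0, 1)")
  }
  if (min_object_area < 1) stop("min_object_area must be >= 1")
  if (surface_margin < 1) stop("surface_margin must be >= 1")
  if (sheath_exclusion_depth < 0) stop("sheath_exclusion_depth must be >= 0")
  structure(list(threshold_method = threshold_method,
                 min_object_area = as.integer(min_object_area),
                 surface_margin = as.integer(surface_margin),
                 sheath_exclusion_depth = as.integer(sheath_exclusion_depth)),
            class = "feature_params")
}

#' Binarize a de-noised B-scan
#'
#' Thresholds the frame to expose the general shape of the airway wall.
#' The threshold is Otsu's (computed below the sheath guard band) or a
#' fixed value; pixels at or above it are foreground. The top
#' `sheath_exclusion_depth` rows are always background. A constant frame
#' (Otsu undefined) yields an all-background mask with a warning.
#'
#' @param frame De-noised numeric matrix in \[0, 1\].
#' @param params A [feature_params()] object.
#' @return Logical matrix, `TRUE` = tissue foreground.
#' @export
binarize <- function(frame, params = feature_params()) {
  validate_frame(frame)
  guard <- min(params$sheath_exclusion_depth, nrow(frame))
  body <- if (guard > 0) frame[-seq_len(guard), , drop = FALSE] else frame
  if (nrow(body) == 0 || diff(range(body)) == 0) {
    warning("constant frame: threshold undefined, returning all background")
    return(matrix(FALSE, nrow(frame), ncol(frame)))
  }
  th <- if (identical(params$threshold_method, "otsu"))
    EBImage::otsu(EBImage::Image(body)) else params$threshold_method
  fg <- frame >= th
  if (guard > 0) fg[seq_len(guard), ] <- FALSE
  fg
}

# 8-connected component labels with angular wrap-around. EBImage::bwlabel
# is 4-connected, so diagonal and seam adjacencies are merged afterwards
# through a label graph.
label_components_polar <- function(binary) {
  nr <- nrow(binary); nc <- ncol(binary)
  lab <- EBImage::bwlabel(EBImage::Image(binary * 1))
  lab <- matrix(as.integer(lab), nr, nc)
  nlab <- max(lab)
  if (nlab == 0) return(lab)
  pair <- function(a, b) {
    keep <- a > 0 & b > 0 & a != b
    cbind(a[keep], b[keep])
  }
  edges <- rbind(
    # diagonals within the frame
    pair(lab[-nr, -nc], lab[-1, -1]),
    pair(lab[-nr, -1], lab[-1, -nc]),
    # wrap seam: last column adjacent to first (horizontal + diagonals)
    pair(lab[, nc], lab[, 1]),
    pair(lab[-nr, nc], lab[-1, 1]),
    pair(lab[-1, nc], lab[-nr, 1]))
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, nlab - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    lab[lab > 0] <- comp[lab[lab > 0]]
  }
  lab
}

#' Remove small connected components from a binary image
#'
#' Foreground components are 8-connected with wrap-around across the
#' angular (column) seam, as the B-scan is cylindrical. Components
#' smaller than `min_object_area` pixels are removed; components of
#' exactly that size are kept.
#'
#' @param binary Logical (or 0/1) matrix.
#' @param min_object_area Minimum component size in pixels.
#' @return Logical matrix.
#' @export
remove_small_objects <- function(binary, min_object_area = 200) {
  binary <- binary > 0
  lab <- label_components_polar(binary)
  if (max(lab) == 0) return(binary)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_object_area)
  matrix(lab %in% keep, nrow(binary), ncol(binary))
}

#' Mask pixels beneath the innermost tissue surface
#'
#' For every A-line, finds the shallowest foreground pixel in `binary`
#' and zeroes all intensities deeper than `surface_margin` pixels below
#' it, so that only the most inner surface of the luminal wall is left
#' for edge detection (deeper surfaces from detached tissue would
#' otherwise attract the tracer). A-lines with no foreground are left
#' unchanged; their 0-based indices are attached as attribute
#' `"skipped_alines"`.
#'
#' @param frame De-noised numeric matrix.
#' @param binary Cleaned binary tissue mask derived from `frame`.
#' @param params A [feature_params()] object (uses `surface_margin`).
#' @return Masked matrix, same shape, with attribute `"skipped_alines"`.
#' @export
top_surface_mask <- function(frame, binary, params = feature_params()) {
  stopifnot(all(dim(frame) == dim(binary)))
  nr <- nrow(frame)
  surface <- apply(binary, 2, function(col) {
    w <- which(col)
    if (length(w) == 0) NA_integer_ else w[1]
  })
  skipped <- which(is.na(surface))
  if (length(skipped) == ncol(frame)) {
    warning("no foreground in any A-line; frame returned unchanged")
    attr(frame, "skipped_alines") <- skipped - 1L
    return(frame)
  }
  out <- frame
  for (i in which(!is.na(surface))) {
    cutoff <- surface[i] + params$surface_margin  # 1-based row of last kept px
    if (cutoff < nr) out[(cutoff + 1):nr, i] <- 0
  }
  attr(out, "skipped_alines") <- skipped - 1L
  out
}

#' Depth-gradient feature image
#'
#' First derivative of pixel intensity along depth, computed as a
#' forward difference (the last row duplicates the second-to-last).
#' Negative values are clipped to zero so only rising (lumen-to-tissue)
#' edges remain, and the result is rescaled by its maximum to \[0, 1\].
#' The response to a dark-to-bright step sits on the lumen-side pixel of
#' the transition.
#'
#' @param frame Masked numeric matrix (rows = depth).
#' @return Numeric matrix in \[0, 1\], same shape.
#' @export
depth_gradient <- function(frame) {
  nr <- nrow(frame)
  if (nr < 2) stop("frame must have at least 2 rows")
  g <- frame[-1, , drop = FALSE] - frame[-nr, , drop = FALSE]
  g <- rbind(g, g[nr - 1, , drop = FALSE])
  g[g < 0] <- 0
  mx <- max(g)
  if (mx > 0) g <- g / mx
  g
}
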