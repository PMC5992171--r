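#' Dynamic-programming tracer parameters
#'
#' @param alpha Scale factor applied to the transition weight of
#'   diagonal (row-changing) moves. The default `sqrt(2)` is the
#'   geometric length ratio of a diagonal to a straight step; values
#'   above 1 favour smooth boundaries.
#' @param pad_mode `"full-duplicate"`: duplicate the image at both ends
#'   (three copies side by side) before tracing, so the path stays
#'   connected across the angular seam; `"none"`: trace the image as-is.
#' @return An object of class `dp_params`.
#' @export
dp_params <- function(alpha = sqrt(2),
                      pad_mode = c("full-duplicate", "none")) {
  if (!is.numeric(alpha) || alpha < 1) stop("alpha must be >= 1")
  structure(list(alpha = alpha, pad_mode = match.arg(pad_mode)),
            class = "dp_params")
}

#' Transition weight between two gradient pixels
#'
#' The cost of stepping between pixels of gradient intensity `a` and
#' `b` in an image whose maximum intensity is `max_I`:
#' `w(a, b) = 2 * max_I - a - b`. Bright transitions are cheap; the
#' brightest possible transition costs zero.
#'
#' @param a,b Gradient intensities, each `<= max_I`.
#' @param max_I Maximum intensity of the gradient image.
#' @return Non-negative numeric weight (vectorized).
#' @export
pixel_cost <- function(a, b, max_I) {
  2 * max_I - a - b
}

#' Accumulated-cost matrix of the boundary dynamic program
#'
#' Sweeps the gradient image left to right, assigning each pixel the
#' minimum accumulated cost of any depth-monotone-by-at-most-one path
#' reaching it from the first column:
#' `Cost(i, j) = min over j' in {j-1, j, j+1} of
#'   m * w(I(i-1, j'), I(i, j)) + Cost(i-1, j')`,
#' with `m = alpha` for diagonal moves (`j' != j`) and `m = 1` for
#' straight moves, and `w` as in [pixel_cost()]. The first column is
#' seeded with `Cost(0, j) = w(I(0, j), I(0, j)) = 2 * (max_I - I(0, j))`,
#' which favours starting on bright pixels without biasing any row.
#' Out-of-range predecessors are excluded; ties are broken straight,
#' then up, then down.
#'
#' @param gradient Numeric matrix in \[0, 1\] (rows = depth, cols =
#'   A-lines), at least 2 columns.
#' @param params A [dp_params()] object.
#' @return An object of class `cost_matrix`: list with `cost` (numeric
#'   matrix), `backpointer` (integer matrix of predecessor row offsets
#'   in -1/0/+1, `NA` in column 1) and `max_I`.
#' @export
compute_cost_matrix <- function(gradient, params = dp_params()) {
  validate_frame(gradient)
  nr <- nrow(gradient); nc <- ncol(gradient)
  if (nc < 2) stop("gradient must have at least 2 columns")
  alpha <- params$alpha
  max_I <- max(gradient)
  cost <- matrix(NA_real_, nr, nc)
  bp <- matrix(NA_integer_, nr, nc)
  cost[, 1] <- 2 * (max_I - gradient[, 1])
  for (i in 2:nc) {
    a <- gradient[, i - 1]   # predecessor-column intensities
    b <- gradient[, i]       # current-column intensities
    prev <- cost[, i - 1]
    cand_s <- (2 * max_I - a - b) + prev
    # predecessor one row up (j - 1): undefined for the top row
    cand_u <- c(Inf, alpha * (2 * max_I - a[-nr] - b[-1]) + prev[-nr])
    # predecessor one row down (j + 1): undefined for the bottom row
    cand_d <- c(alpha * (2 * max_I - a[-1] - b[-nr]) + prev[-1], Inf)
    best <- cand_s
    move <- integer(nr)            # 0 = straight
    up <- cand_u < best
    best[up] <- cand_u[up]; move[up] <- -1L
    dn <- cand_d < best
    best[dn] <- cand_d[dn]; move[dn] <- 1L
    cost[, i] <- best
    bp[, i] <- move
  }
  structure(list(cost = cost, backpointer = bp, max_I = max_I),
            class = "cost_matrix")
}

#' Construct a lumen boundary object
#'
#' @param depth_index Integer vector of 0-based boundary depth indices,
#'   one per A-line; consecutive entries may differ by at most 1.
#' @param n_depth Number of depth rows of the source image (for range
#'   checking); optional.
#' @param closed Whether the boundary closes across the angular seam
#'   (first and last entries within one row).
#' @return An object of class `lumen_boundary`.
#' @export
lumen_boundary <- function(depth_index, n_depth = NULL, closed = NULL) {
  depth_index <- as.integer(depth_index)
  if (length(depth_index) < 1 || anyNA(depth_index))
    stop("depth_index must be a non-empty integer vector")
  if (any(depth_index < 0)) stop("depth indices must be >= 0")
  if (!is.null(n_depth) && any(depth_index >= n_depth))
    stop("depth indices must be < n_depth")
  if (length(depth_index) > 1 && any(abs(diff(depth_index)) > 1))
    stop("boundary violates the one-row-per-step connectivity invariant")
  if (is.null(closed))
    closed <- abs(depth_index[1] - depth_index[length(depth_index)]) <= 1
  structure(list(depth_index = depth_index,
                 n_alines = length(depth_index),
                 closed = isTRUE(closed)),
            class = "lumen_boundary")
}

#' @export
print.lumen_boundary <- function(x, ...) {
  cat("Lumen boundary: ", x$n_alines, " A-lines, depth range [",
      min(x$depth_index), ", ", max(x$depth_index), "], ",
      if (x$closed) "closed" else "NOT closed", "\n", sep = "")
  invisible(x)
}

#' Trace the minimum-cost boundary through a cost matrix
#'
#' Starts at the row with the minimum accumulated cost in the right-most
#' column (ties: smallest row index) and follows backpointers to the
#' first column.
#'
#' @param costs A `cost_matrix` from [compute_cost_matrix()].
#' @return A [lumen_boundary()] with one 0-based depth index per column.
#' @export
trace_min_cost_path <- function(costs) {
  stopifnot(inherits(costs, "cost_matrix"))
  cm <- costs$cost; bp <- costs$backpointer
  nc <- ncol(cm)
  path <- integer(nc)
  path[nc] <- which.min(cm[, nc])       # smallest row on ties
  if (nc > 1) for (i in nc:2) {
    path[i - 1] <- path[i] + bp[path[i], i]
  }
  lumen_boundary(path - 1L, n_depth = nrow(cm))
}

#' Detect the lumen boundary with circular padding
#'
#' The angular direction of a B-scan is circular, but the dynamic
#' program sweeps a flat image. With `pad_mode = "full-duplicate"` the
#' gradient image is duplicated and concatenated at both ends, the
#' minimum-cost path is traced across the triple-width image, and the
#' middle copy's columns are returned — so the path remains connected
#' across the seam. The boundary is flagged `closed` when its first and
#' last columns lie within one row of each other; a warning is raised
#' otherwise.
#'
#' @param gradient Numeric gradient matrix in \[0, 1\], width >= 8.
#' @param params A [dp_params()] object.
#' @return A [lumen_boundary()].
#' @export
detect_boundary_circular <- function(gradient, params = dp_params()) {
  W <- ncol(gradient)
  if (W < 8) stop("gradient must have at least 8 columns")
  if (params$pad_mode == "full-duplicate") {
    g3 <- cbind(gradient, gradient, gradient)
    full <- trace_min_cost_path(compute_cost_matrix(g3, params))
    d <- full$depth_index[(W + 1):(2 * W)]
  } else {
    d <- trace_min_cost_path(compute_cost_matrix(gradient, params))$depth_index
  }
  b <- lumen_boundary(d, n_depth = nrow(gradient))
  if (!b$closed)
    warning("boundary does not close across the angular seam")
  b
}
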