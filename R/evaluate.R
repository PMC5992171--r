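#' Mean and sample standard deviation of per-frame areas
#'
#' @param areas Numeric vector of per-frame areas (mm^2), length >= 2.
#' @return Named numeric vector `c(mean = ..., sd = ...)` (n-1
#'   denominator).
#' @export
summarize_areas <- function(areas) {
  if (length(areas) < 2) stop("at least 2 areas are required")
  c(mean = mean(areas), sd = stats::sd(areas))
}

#' Bland-Altman agreement between two segmentations
#'
#' Computes per-frame differences `A - B` and means `(A + B) / 2`, the
#' bias (mean difference), the 95% limits of agreement
#' `bias -/+ 1.96 * SD(diff)` (normal-theory multiplier, no small-sample
#' correction), and the percent bias, `100 * bias / mean(per-frame
#' means)` — the conventional normalization of the bias to the overall
#' measurement scale.
#'
#' @param areas_a,areas_b Frame-aligned numeric vectors of per-frame
#'   areas (mm^2), equal length >= 2.
#' @return An object of class `bland_altman`: list with
#'   `per_frame_diff`, `per_frame_mean`, `bias`, `loa_low`, `loa_high`,
#'   `percent_bias`.
#' @export
bland_altman <- function(areas_a, areas_b) {
  if (length(areas_a) != length(areas_b))
    stop("length mismatch between the two area series")
  if (length(areas_a) < 2) stop("at least 2 paired frames are required")
  d <- areas_a - areas_b
  m <- (areas_a + areas_b) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  grand <- mean(m)
  structure(list(per_frame_diff = d,
                 per_frame_mean = m,
                 bias = bias,
                 loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s,
                 percent_bias = if (bias == 0) 0 else 100 * bias / grand),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f mm^2 (%.2f%%), 95%% LoA [%.4f, %.4f]\n",
              x$bias, x$percent_bias, x$loa_low, x$loa_high))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Per-frame differences against per-frame means, with dashed lines at
#' the bias and the 95% limits of agreement.
#'
#' @param x A [bland_altman()] result.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$per_frame_mean, x$per_frame_diff,
                 xlab = "Mean of the two areas (mm^2)",
                 ylab = "Difference A - B (mm^2)",
                 pch = 16, col = "grey30", ...)
  graphics::abline(h = c(x$loa_low, x$bias, x$loa_high), lty = 2)
  invisible(x)
}

#' Load a reference (e.g. manual) segmentation area table
#'
#' Reads a CSV with columns `frame` and `area_mm2` (additional columns
#' ignored), orders rows by frame index and checks that frame indices
#' are contiguous.
#'
#' @param path CSV path.
#' @return Numeric vector of per-frame areas in frame order.
#' @export
load_reference_segmentation <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("frame", "area_mm2") %in% names(df)))
    stop("reference CSV must have columns 'frame' and 'area_mm2'")
  if (!is.numeric(df$area_mm2))
    stop("area_mm2 column is not numeric")
  df <- df[order(df$frame), , drop = FALSE]
  if (nrow(df) > 1 && any(diff(df$frame) != 1))
    stop("non-contiguous frames in reference CSV")
  df$area_mm2
}
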