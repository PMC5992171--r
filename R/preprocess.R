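#' De-noising parameters
#'
#' @param median_kernel Odd square median-filter window size in pixels.
#'   The default 5 px spans roughly the probe's lateral resolution at
#'   the fixture geometry, enough to reject isolated speckle spikes
#'   without blunting the lumen-wall edge.
#' @param normalize_alines Normalize each A-line's summed intensity so
#'   the bright sheath reflection does not dominate a subset of A-lines.
#' @param target_aline_sum Target column sum after normalization: a
#'   positive number, or `"stack-mean"` to use the frame's mean column
#'   sum (preserves overall brightness).
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(median_kernel = 5,
                              normalize_alines = TRUE,
                              target_aline_sum = "stack-mean") {
  median_kernel <- as.integer(median_kernel)
  if (median_kernel < 1 || median_kernel %% 2 == 0)
    stop("median_kernel must be odd and >= 1")
  if (is.numeric(target_aline_sum) && target_aline_sum <= 0)
    stop("target_aline_sum must be positive")
  structure(list(median_kernel = median_kernel,
                 normalize_alines = isTRUE(normalize_alines),
                 target_aline_sum = target_aline_sum),
            class = "preprocess_params")
}

# Median filter with reflect padding in depth and wrap padding across
# A-lines (the angular direction is circular). Delegates the filtering
# itself to EBImage's constant-time median; its 16-bit internal
# quantization is neutralized by clipping to the input range.
median_filter_polar <- function(frame, kernel) {
  if (kernel == 1) return(frame)
  k2 <- (kernel - 1L) %/% 2L
  nr <- nrow(frame); nc <- ncol(frame)
  if (nr < kernel || nc < kernel) stop("frame too small for median kernel")
  rows <- c(k2:1, seq_len(nr), nr:(nr - k2 + 1))          # reflect
  cols <- c(nc - k2 + seq_len(k2), seq_len(nc), seq_len(k2))  # wrap
  padded <- frame[rows, cols, drop = FALSE]
  filt <- EBImage::medianFilter(padded, size = k2)
  out <- filt[k2 + seq_len(nr), k2 + seq_len(nc), drop = FALSE]
  pmin(pmax(out, min(frame)), max(frame))
}

#' Normalize per-A-line summed intensity
#'
#' Scales every column so its pixel-intensity sum equals `target`
#' (default: the frame's mean column sum). Columns whose sum is zero are
#' left unscaled; their 0-based indices are attached as attribute
#' `"zero_sum_alines"`. Applying the normalization twice is identical to
#' applying it once.
#'
#' @param frame Numeric matrix in \[0, 1\].
#' @param target Positive scalar, or `"stack-mean"` for the mean column sum.
#' @return The rescaled matrix (not yet re-clipped to \[0, 1\]).
#' @export
normalize_alines <- function(frame, target = "stack-mean") {
  sums <- colSums(frame)
  if (identical(target, "stack-mean")) target <- mean(sums)
  zero <- sums == 0
  scale <- ifelse(zero, 1, target / sums)
  out <- sweep(frame, 2, scale, `*`)
  attr(out, "zero_sum_alines") <- which(zero) - 1L
  out
}

#' De-noise a polar B-scan
#'
#' The de-noising stage of the segmentation pipeline: a square median
#' filter suppresses speckle (reflect padding in depth, wrap padding
#' across the circular angular direction), then, optionally, each
#' A-line's summed intensity is normalized to reduce the strong sheath
#' reflection. The result is divided by its maximum so the output again
#' spans \[0, 1\].
#'
#' @param frame Numeric matrix in \[0, 1\]; rows = depth, cols = A-lines.
#' @param params A [preprocess_params()] object.
#' @return De-noised matrix in \[0, 1\], same shape. 0-based indices of
#'   zero-sum A-lines (left unscaled) are carried in attribute
#'   `"zero_sum_alines"`.
#' @export
denoise <- function(frame, params = preprocess_params()) {
  validate_frame(frame)
  if (nrow(frame) < params$median_kernel || ncol(frame) < params$median_kernel)
    stop("frame too small")
  out <- median_filter_polar(frame, params$median_kernel)
  zero_cols <- integer(0)
  if (params$normalize_alines) {
    out <- normalize_alines(out, params$target_aline_sum)
    zero_cols <- attr(out, "zero_sum_alines")
  }
  mx <- max(out)
  if (mx > 0) out <- out / mx
  out <- pmin(pmax(out, 0), 1)
  attr(out, "zero_sum_alines") <- zero_cols
  out
}
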