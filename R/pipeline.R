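#' Assemble a pipeline configuration
#'
#' Aggregates the per-stage parameter objects, the regional split
#' fractions and an optional output directory into one configuration
#' carried through [run_pipeline()].
#'
#' @param geometry An [acquisition_geometry()], or `NULL` to use the
#'   stack's own geometry.
#' @param preprocess A [preprocess_params()].
#' @param features A [feature_params()].
#' @param dp A [dp_params()].
#' @param region_splits Pullback fractions for regional area summaries.
#' @param output_dir Directory for `areas.csv`, `report.json` and
#'   `masks.tiff`; `NULL` writes nothing.
#' @param seed Optional integer recorded in the report for provenance
#'   (the pipeline itself is deterministic).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(geometry = NULL,
                            preprocess = preprocess_params(),
                            features = feature_params(),
                            dp = dp_params(),
                            region_splits = 0.5,
                            output_dir = NULL,
                            seed = NULL) {
  stopifnot(inherits(preprocess, "preprocess_params"),
            inherits(features, "feature_params"),
            inherits(dp, "dp_params"))
  structure(list(geometry = geometry, preprocess = preprocess,
                 features = features, dp = dp,
                 region_splits = region_splits,
                 output_dir = output_dir, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may carry any subset of the sections `geometry`,
#' `preprocess`, `features`, `dp`, plus `region_splits`, `output_dir`
#' and `seed`; omitted entries fall back to package defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON configuration file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  geometry <- if (!is.null(cfg$geometry))
    do.call(acquisition_geometry, cfg$geometry) else NULL
  pipeline_config(
    geometry = geometry,
    preprocess = do.call(preprocess_params,
                         as.list(cfg$preprocess %||% list())),
    features = do.call(feature_params, as.list(cfg$features %||% list())),
    dp = do.call(dp_params, as.list(cfg$dp %||% list())),
    region_splits = cfg$region_splits %||% 0.5,
    output_dir = cfg$output_dir,
    seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Segment one polar B-scan
#'
#' Runs the full per-frame chain: de-noising, binarization,
#' small-object removal, top-surface masking, depth gradient and
#' circular dynamic-programming boundary tracing. The sheath guard band
#' (`sheath_exclusion_depth` rows at the top of every A-line) is zeroed
#' in the masked frame before the gradient, so residual sheath
#' reflection rings cannot offer the tracer a spurious edge near the
#' probe.
#'
#' @param frame Numeric matrix in \[0, 1\], rows = depth.
#' @param config A [pipeline_config()].
#' @return A [lumen_boundary()].
#' @export
segment_frame <- function(frame, config = pipeline_config()) {
  den <- denoise(frame, config$preprocess)
  bin <- binarize(den, config$features)
  bin <- remove_small_objects(bin, config$features$min_object_area)
  masked <- top_surface_mask(den, bin, config$features)
  guard <- min(config$features$sheath_exclusion_depth, nrow(masked))
  if (guard > 0) masked[seq_len(guard), ] <- 0
  grad <- depth_gradient(masked)
  detect_boundary_circular(grad, config$dp)
}

#' Run the full segmentation and quantification pipeline
#'
#' Processes every frame of the stack independently with
#' [segment_frame()], then quantifies areas and volume with
#' [stack_quantify()]. A frame whose segmentation raises an error is
#' flagged and its area recorded as missing; the run aborts only when
#' more than 20% of frames fail. When `config$output_dir` is set, the
#' per-frame area table (`areas.csv`), the quantification report
#' (`report.json`) and the binary lumen mask stack (`masks.tiff`,
#' 8-bit, 255 = lumen) are written there.
#'
#' @param stack A [bscan_stack()].
#' @param config A [pipeline_config()].
#' @return A list with `boundaries` (per frame; `NA` where detection
#'   failed), `report` (a `quant_report`), `failed_frames` (1-based
#'   indices) and `open_boundaries` (frames whose boundary did not close
#'   across the seam).
#' @export
run_pipeline <- function(stack, config = pipeline_config()) {
  stopifnot(inherits(stack, "bscan_stack"))
  if (length(stack$frames) == 0) stop("no frames")
  geometry <- config$geometry %||% stack$geometry
  n <- length(stack$frames)
  boundaries <- vector("list", n)
  failed <- integer(0)
  open <- integer(0)
  for (f in seq_len(n)) {
    b <- tryCatch(
      withCallingHandlers(
        segment_frame(stack$frames[[f]], config),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NA)
    if (inherits(b, "lumen_boundary")) {
      if (!b$closed) open <- c(open, f)
    } else {
      failed <- c(failed, f)
    }
    boundaries[[f]] <- b
  }
  if (length(failed) > 0.2 * n)
    stop("boundary detection failed on ", length(failed), " of ", n,
         " frames (> 20%)")
  report <- stack_quantify(boundaries, geometry, config$region_splits)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_areas_csv(report, file.path(config$output_dir, "areas.csv"))
    write_report_json(report, file.path(config$output_dir, "report.json"))
    shape <- dim(stack$frames[[1]])
    masks <- lapply(boundaries, function(b) {
      if (inherits(b, "lumen_boundary")) lumen_mask(b, shape) * 1
      else matrix(0, shape[1], shape[2])
    })
    write_bscan_stack(masks, file.path(config$output_dir, "masks.tiff"),
                      bits_per_sample = 8)
  }
  list(boundaries = boundaries, report = report,
       failed_frames = failed, open_boundaries = open)
}
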