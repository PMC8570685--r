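# One-call analysis pipeline: video -> motion trace -> immobility track ->
# bout summary + block summary, with an output bundle (CSVs, plots, run log)
# mirroring the per-second output-file convention.

#' Analysis run configuration
#'
#' Collects every knob of the pipeline. When `threshold` is `NULL` the
#' calibrated default for `test_type` is applied ([default_threshold()]:
#' 2.5861 for FST, 0.7808 for TST) and recorded in the run log.
#'
#' @param test_type `"FST"` or `"TST"`; selects the default threshold.
#' @param window An [analysis_window()], or `NULL` for the whole video.
#' @param roi A [region_of_interest()], or `NULL` for the full frame.
#' @param segmentation A [segmentation_config()].
#' @param metric_mode `"area"` (default), `"length"` or `"variation"`.
#' @param threshold Delta-area % cut-point, or `NULL` for the test-type
#'   default.
#' @param block_length_s Block size for block-wise immobility, seconds.
#' @param out_dir Output directory for the bundle, or `NULL` to skip
#'   writing.
#' @param seed Integer seed recorded in the log (the analysis itself is
#'   deterministic).
#' @return A `run_config` list with the resolved threshold.
#' @export
run_config <- function(test_type = c("FST", "TST"),
                       window = NULL,
                       roi = NULL,
                       segmentation = segmentation_config(),
                       metric_mode = c("area", "length", "variation"),
                       threshold = NULL,
                       block_length_s = 60,
                       out_dir = NULL,
                       seed = 1) {
  test_type <- match.arg(toupper(test_type), c("FST", "TST"))
  metric_mode <- match.arg(metric_mode)
  threshold <- threshold %||% default_threshold(test_type)
  if (threshold <= 0) {
    stop_immobilitr("threshold must be positive",
      class = "immobilitr_error_bad_threshold"
    )
  }
  structure(
    list(
      test_type = test_type, window = window, roi = roi,
      segmentation = segmentation, metric_mode = metric_mode,
      threshold = threshold, block_length_s = block_length_s,
      out_dir = out_dir, seed = seed
    ),
    class = "run_config"
  )
}

#' Analyze one video end to end
#'
#' Segments every frame in the analysis window, computes the per-second
#' delta-area motion trace, classifies each second against the threshold and
#' derives the bout and block summaries. When `config$out_dir` is set the
#' full output bundle is written: `trace.csv`, `labels.csv`, `summary.csv`,
#' `blocks.csv`, `raster.png`, `trace.png` and `run_log.json` (the resolved
#' configuration, including the threshold actually applied and the grayscale
#' conversion weights).
#'
#' @param video Path to a video (see [open_video()]) or a `video_meta`.
#' @param config A [run_config()].
#' @param fps Frame rate override passed to [open_video()].
#' @param background Optional [estimate_background()] model.
#' @return An `immobility_analysis` list: `trace`, `track`, `summary`,
#'   `blocks`, `config`, `meta`, `out_dir`.
#' @export
analyze_video <- function(video, config = run_config(), fps = NULL,
                          background = NULL) {
  stopifnot(inherits(config, "run_config"))
  meta <- if (inherits(video, "video_meta")) video else open_video(video, fps = fps)
  frames <- frame_stream(meta, window = config$window, roi = config$roi)
  feats <- segment_frames(
    frames, config$segmentation,
    background = background,
    measure_length = config$metric_mode == "length",
    keep_masks = config$metric_mode == "variation"
  )
  per_frame <- frame_percent_change(feats, mode = config$metric_mode)
  window <- config$window %||% analysis_window(0, meta$duration_s)
  n_seconds <- floor(window$end_s - window$start_s)
  trace <- per_second_average(per_frame, meta$fps,
    n_seconds = n_seconds,
    metric_mode = config$metric_mode
  )
  track <- classify_immobility(trace, config$threshold)
  result <- structure(
    list(
      trace = trace,
      track = track,
      summary = bout_summary(track),
      blocks = block_immobility(track, config$block_length_s),
      config = config,
      meta = meta,
      out_dir = config$out_dir
    ),
    class = "immobility_analysis"
  )
  if (!is.null(config$out_dir)) {
    write_analysis_bundle(result, config$out_dir)
  }
  result
}

#' @export
print.immobility_analysis <- function(x, ...) {
  cat(sprintf(
    "<immobility_analysis> %s [%s, threshold %.4f %%]\n",
    x$meta$path, x$config$test_type, x$config$threshold
  ))
  print(x$summary)
  invisible(x)
}

#' @rdname analyze_video
#' @param x An `immobility_analysis`.
#' @param ... Unused.
#' @export
tidy.immobility_analysis <- function(x, ...) {
  dplyr::left_join(
    as_tibble(x$trace),
    as_tibble(x$track)[, c("second", "label", "imputed")],
    by = "second"
  )
}

#' @rdname analyze_video
#' @export
glance.immobility_analysis <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$summary),
    tibble(
      test_type = x$config$test_type,
      threshold = x$config$threshold,
      metric_mode = x$config$metric_mode,
      fps = x$meta$fps
    )
  )
}

# Serializable view of the resolved configuration; this is the run log, and
# the threshold recorded here is the one the classification used.
resolved_config <- function(result) {
  cfg <- result$config
  window <- cfg$window %||% analysis_window(0, result$meta$duration_s)
  list(
    video = result$meta$path,
    test_type = cfg$test_type,
    threshold = cfg$threshold,
    metric_mode = cfg$metric_mode,
    window = list(start_s = window$start_s, end_s = window$end_s),
    roi = if (!is.null(cfg$roi)) as.data.frame(cfg$roi$vertices),
    segmentation = unclass(cfg$segmentation),
    block_length_s = cfg$block_length_s,
    fps = result$meta$fps,
    n_seconds = nrow(result$trace),
    gray_weights = as.list(GRAY_WEIGHTS),
    seed = cfg$seed
  )
}

write_analysis_bundle <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_per_second_csv(result$trace, file.path(out_dir, "trace.csv"))
  write_per_second_csv(result$track, file.path(out_dir, "labels.csv"))
  g <- glance(result$summary)
  # the CSV writes an empty cell, not 0, when no immobility occurred
  readr::write_csv(g, file.path(out_dir, "summary.csv"), na = "")
  readr::write_csv(result$blocks, file.path(out_dir, "blocks.csv"))
  jsonlite::write_json(resolved_config(result),
    file.path(out_dir, "run_log.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA
  )
  save_plot(autoplot(result$track), file.path(out_dir, "raster.png"), height = 2)
  save_plot(
    autoplot(result$trace, threshold = result$config$threshold),
    file.path(out_dir, "trace.png")
  )
  invisible(out_dir)
}

save_plot <- function(p, path, width = 7, height = 4) {
  grDevices::png(path, width = width * 100, height = height * 100, res = 100)
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  invisible(path)
}
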