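# The delta-area motion statistic: per-frame percentage change in the
# binarized animal area (or object length, or frame-by-frame pixel
# variation), averaged within each second, then thresholded into
# mobile/immobile states.

#' Per-frame percentage change of a feature series
#'
#' For frames `t = 1..N-1` (0-based), the unsigned change in the feature
#' relative to the previous frame, as a percentage:
#' `100 * |A(t) - A(t-1)| / A(t-1)` for the area and length modes, and
#' `100 * XOR(mask_t, mask_{t-1}) / A(t-1)` for the variation mode. The
#' unsigned difference is used because signed changes would cancel within a
#' second and the statistic is a motion magnitude.
#'
#' Frames whose previous-frame feature is zero (empty mask) get `NA` with
#' `valid = FALSE`; they are skipped, not silently zeroed, by
#' [per_second_average()].
#'
#' @param features Per-frame feature tibble from [segment_frames()], or a
#'   numeric vector of per-frame feature values.
#' @param mode `"area"` (default, the validated metric), `"length"`, or
#'   `"variation"`.
#' @param masks List of `binary_mask` objects (consecutive pairs are XORed);
#'   required for `mode = "variation"`. Taken from `attr(features, "masks")`
#'   if present.
#' @return A tibble with columns `frame` (0-based index `t`, starting at 1),
#'   `pct`, `valid`.
#' @export
frame_percent_change <- function(features, mode = c("area", "length", "variation"),
                                 masks = NULL) {
  mode <- match.arg(mode)
  if (is.data.frame(features)) {
    masks <- masks %||% attr(features, "masks")
    values <- switch(mode,
      area = features$area_px,
      length = features$major_axis_px,
      variation = features$area_px
    )
  } else {
    values <- as.numeric(features)
  }
  n <- length(values)
  if (n < 2) {
    stop_immobilitr("need at least 2 frames to compute frame-to-frame change",
      class = "immobilitr_error_too_short"
    )
  }
  if (all(values == 0 | is.na(values))) {
    stop_immobilitr("all frames have empty masks; nothing to measure",
      class = "immobilitr_error_all_empty"
    )
  }
  prev <- values[-n]
  if (mode == "variation") {
    if (is.null(masks)) {
      stop_immobilitr("variation mode needs the binary masks (keep_masks = TRUE)",
        class = "immobilitr_error_bad_config"
      )
    }
    num <- vapply(seq_len(n - 1), function(i) {
      sum(xor(masks[[i + 1]]$pixels, masks[[i]]$pixels))
    }, numeric(1))
  } else {
    num <- abs(values[-1] - prev)
  }
  pct <- ifelse(prev > 0, 100 * num / prev, NA_real_)
  tibble(
    frame = seq_len(n - 1),
    pct = pct,
    valid = prev > 0 & !is.na(values[-1]) & !is.na(prev)
  )
}

#' Average per-frame changes within each second
#'
#' Second `s` (0-based) covers frames with index in `[s*fps, (s+1)*fps)`
#' relative to the window start, half-open. Frame 0 has no predecessor and is
#' skipped, as are frames flagged invalid. A second with no valid frames is
#' marked invalid (`NA` value).
#'
#' @param per_frame Tibble from [frame_percent_change()].
#' @param fps Frames per second.
#' @param n_seconds Number of whole analyzed seconds; defaults to
#'   `floor(n_frames / fps)`.
#' @param metric_mode Recorded on the result.
#' @return A `motion_trace` tibble with columns `second` (0-based), `value`
#'   (mean delta %), `valid`; attributes `fps`, `metric_mode`.
#' @export
per_second_average <- function(per_frame, fps, n_seconds = NULL,
                               metric_mode = "area") {
  stopifnot(fps > 0)
  n_frames <- max(per_frame$frame) + 1L
  n_seconds <- n_seconds %||% floor(n_frames / fps)
  if (is.null(n_seconds) || n_seconds < 1) {
    stop_immobilitr("n_seconds must be >= 1", class = "immobilitr_error_bad_window")
  }
  sec <- floor(per_frame$frame / fps)
  keep <- sec < n_seconds & per_frame$valid
  vals <- rep(NA_real_, n_seconds)
  agg <- tapply(per_frame$pct[keep], sec[keep], mean)
  vals[as.integer(names(agg)) + 1L] <- as.numeric(agg)
  new_motion_trace(
    tibble(second = seq_len(n_seconds) - 1L, value = vals, valid = !is.na(vals)),
    fps = fps, metric_mode = metric_mode
  )
}

new_motion_trace <- function(df, fps, metric_mode = "area", threshold_used = NULL) {
  structure(
    df,
    fps = fps, metric_mode = metric_mode, threshold_used = threshold_used,
    class = c("motion_trace", class(tibble()))
  )
}

#' Classify each second as mobile or immobile
#'
#' A second is immobile (label 1) when its motion statistic is strictly
#' below the threshold `c`; ties classify as mobile. Invalid seconds inherit
#' the previous second's label (a leading invalid second is scored mobile)
#' and are flagged `imputed`.
#'
#' @param trace A `motion_trace` from [per_second_average()].
#' @param threshold Positive delta-area % cut-point. The calibrated defaults
#'   are available from [default_threshold()].
#' @return An `immobility_track` tibble with columns `second`, `label`
#'   (integer 0/1, 1 = immobile), `imputed`; attributes `source =
#'   "automatic"` and `threshold`.
#' @export
classify_immobility <- function(trace, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop_immobilitr("threshold must be a single positive number",
      class = "immobilitr_error_bad_threshold"
    )
  }
  lab <- as.integer(trace$value < threshold)
  imputed <- !trace$valid
  for (i in seq_along(lab)) {
    if (imputed[i]) lab[i] <- if (i == 1) 0L else lab[i - 1]
  }
  new_immobility_track(
    tibble(second = trace$second, label = lab, imputed = imputed),
    source = "automatic", threshold = threshold
  )
}

new_immobility_track <- function(df, source, threshold = NULL) {
  structure(
    df,
    source = source, threshold = threshold,
    class = c("immobility_track", class(tibble()))
  )
}

#' Wrap manual per-second labels as an immobility track
#'
#' @param labels Integer 0/1 vector, 1 = immobile, one entry per second.
#' @return An `immobility_track` with `source = "manual"`.
#' @export
manual_track <- function(labels) {
  labels <- check_binary_labels(labels)
  new_immobility_track(
    tibble(second = seq_along(labels) - 1L, label = labels, imputed = FALSE),
    source = "manual"
  )
}

check_binary_labels <- function(labels) {
  labels <- as.integer(labels)
  if (length(labels) == 0 || anyNA(labels) || !all(labels %in% c(0L, 1L))) {
    stop_immobilitr("labels must be 0/1, one per second",
      class = "immobilitr_error_nonbinary"
    )
  }
  labels
}

# Accept either an immobility_track tibble or a bare 0/1 vector.
as_track_labels <- function(track) {
  if (is.data.frame(track)) {
    check_binary_labels(track$label)
  } else {
    check_binary_labels(track)
  }
}

#' Write a motion trace or immobility track to CSV
#'
#' Matches the per-second output-file convention: one row per second.
#'
#' @param x A `motion_trace` or `immobility_track`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_per_second_csv <- function(x, path) {
  if (inherits(x, "motion_trace")) {
    readr::write_csv(tibble(second_index = x$second, value = x$value), path)
  } else if (inherits(x, "immobility_track")) {
    readr::write_csv(tibble(second_index = x$second, label = x$label), path)
  } else {
    stop_immobilitr("x must be a motion_trace or immobility_track",
      class = "immobilitr_error_bad_input"
    )
  }
  invisible(path)
}
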