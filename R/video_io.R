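# Frame-stack video I/O.
#
# Videos are read either as multi-frame grayscale/RGB TIFF stacks or as a
# directory of numbered PNG/TIFF frames. Frame rate is not stored by these
# containers, so it comes from an `fps` argument or a JSON sidecar
# ("<stack>.meta.json", or "meta.json" inside a frame directory) of the form
# {"fps": 15}. The synthetic renderer (render_video) writes both pieces.

# Rec. 709 luminance weights used for RGB -> gray conversion; recorded in the
# analysis run log so runs are reproducible.
GRAY_WEIGHTS <- c(r = 0.2126, g = 0.7152, b = 0.0722)

# round-half-up; base round() is half-to-even which would make the frame
# count of a window disagree with round(duration * fps) at x.5 boundaries
round_half_up <- function(x) floor(x + 0.5)

#' Open a video and read its metadata
#'
#' Validates the container and returns frame-rate, frame count and frame
#' dimensions without loading pixel data. Supported containers are multi-frame
#' TIFF stacks (`.tif`/`.tiff`) and directories of numbered `.png`/`.tif`
#' frames.
#'
#' @param path Path to a TIFF stack or a frame directory.
#' @param fps Frames per second. If `NULL`, read from the JSON sidecar
#'   (`<path>.meta.json` for a stack, `meta.json` inside a directory).
#' @return A `video_meta` object: a list with `path`, `kind`
#'   (`"tiff_stack"` or `"frame_dir"`), `fps`, `n_frames`, `width`, `height`,
#'   `duration_s` and, for directories, the ordered frame file list.
#' @examples
#' vid <- render_video(alternating_schedule(4, bout_s = 2),
#'   fps = 5, seed = 1, out_path = tempfile(fileext = ".tif")
#' )
#' open_video(vid$path)
#' @export
open_video <- function(path, fps = NULL) {
  if (!file.exists(path)) {
    stop_immobilitr(
      paste0("video not found: ", path),
      class = "immobilitr_error_missing_file"
    )
  }
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", full.names = TRUE)
    files <- sort(files)
    if (length(files) == 0) {
      stop_immobilitr(
        paste0("no frames (*.png, *.tif) found in directory: ", path),
        class = "immobilitr_error_empty_video"
      )
    }
    frame1 <- read_frame_file(files[[1]])
    fps <- fps %||% sidecar_fps(file.path(path, "meta.json"))
    meta <- new_video_meta(
      path = path, kind = "frame_dir", fps = fps, n_frames = length(files),
      width = ncol(frame1), height = nrow(frame1), files = files
    )
    return(meta)
  }
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("tif", "tiff")) {
    stop_immobilitr(
      paste0(
        "cannot decode container '.", ext, "'; supported containers are ",
        "multi-frame TIFF stacks and PNG/TIFF frame directories"
      ),
      class = "immobilitr_error_undecodable"
    )
  }
  info <- tryCatch(
    tiff::readTIFF(path, all = TRUE, payload = FALSE),
    error = function(e) {
      stop_immobilitr(
        paste0("failed to decode TIFF stack: ", conditionMessage(e)),
        class = "immobilitr_error_undecodable"
      )
    }
  )
  info <- as.data.frame(info)
  if (nrow(info) == 0) {
    stop_immobilitr("TIFF stack contains zero frames",
      class = "immobilitr_error_empty_video"
    )
  }
  fps <- fps %||% sidecar_fps(paste0(path, ".meta.json"))
  new_video_meta(
    path = path, kind = "tiff_stack", fps = fps, n_frames = nrow(info),
    width = info$width[1], height = info$length[1]
  )
}

new_video_meta <- function(path, kind, fps, n_frames, width, height,
                           files = NULL) {
  if (is.null(fps)) {
    stop_immobilitr(
      "frame rate unknown: supply `fps` or provide a JSON sidecar with {\"fps\": ...}",
      class = "immobilitr_error_no_fps"
    )
  }
  fps <- as.numeric(fps)
  stopifnot(is.finite(fps), fps > 0, n_frames >= 1)
  structure(
    list(
      path = path, kind = kind, fps = fps, n_frames = as.integer(n_frames),
      width = as.integer(width), height = as.integer(height),
      duration_s = n_frames / fps, files = files
    ),
    class = "video_meta"
  )
}

sidecar_fps <- function(sidecar) {
  if (!file.exists(sidecar)) {
    return(NULL)
  }
  meta <- jsonlite::read_json(sidecar)
  meta$fps
}

#' @export
print.video_meta <- function(x, ...) {
  cat(
    sprintf(
      "<video_meta> %s (%s)\n  %d frames, %dx%d px, %.6g fps, %.6g s\n",
      x$path, x$kind, x$n_frames, x$width, x$height, x$fps, x$duration_s
    )
  )
  invisible(x)
}

#' Analysis time window
#'
#' The part of the video to analyze, in seconds from the start of the video.
#' The analyzed duration in whole seconds is `floor(end_s - start_s)`.
#'
#' @param start_s Start, seconds (>= 0).
#' @param end_s End, seconds (> `start_s`).
#' @return An `analysis_window` object.
#' @export
analysis_window <- function(start_s, end_s) {
  if (!is.numeric(start_s) || !is.numeric(end_s) ||
    start_s < 0 || end_s <= start_s) {
    stop_immobilitr(
      "invalid analysis window: need 0 <= start_s < end_s",
      class = "immobilitr_error_bad_window"
    )
  }
  structure(list(start_s = start_s, end_s = end_s), class = "analysis_window")
}

#' Region of interest
#'
#' A polygonal multi-point selection around the area in which the animal
#' stays for the whole test. Analysis crops to the minimal axis-aligned
#' rectangle containing all vertices (the polygon itself is not used as a
#' mask).
#'
#' @param vertices A two-column matrix or data frame of (x, y) pixel
#'   coordinates, at least 3 points, 1-based.
#' @return A `region_of_interest` object.
#' @export
region_of_interest <- function(vertices) {
  v <- as.matrix(as.data.frame(vertices))
  if (ncol(v) != 2 || nrow(v) < 3 || !is.numeric(v)) {
    stop_immobilitr(
      "region of interest needs >= 3 numeric (x, y) vertices",
      class = "immobilitr_error_bad_roi"
    )
  }
  colnames(v) <- c("x", "y")
  structure(list(vertices = v), class = "region_of_interest")
}

# Minimal axis-aligned integer rectangle containing the ROI vertices,
# clipped to the frame; errors if degenerate (< 2 px on a side) after
# clipping.
roi_bounding_rect <- function(roi, width, height) {
  v <- roi$vertices
  x0 <- max(1L, floor(min(v[, "x"])))
  x1 <- min(as.integer(width), ceiling(max(v[, "x"])))
  y0 <- max(1L, floor(min(v[, "y"])))
  y1 <- min(as.integer(height), ceiling(max(v[, "y"])))
  if (x1 - x0 + 1 < 2 || y1 - y0 + 1 < 2) {
    stop_immobilitr(
      "region of interest is degenerate after clipping to frame bounds",
      class = "immobilitr_error_bad_roi"
    )
  }
  list(x0 = x0, x1 = x1, y0 = y0, y1 = y1)
}

to_grayscale <- function(frame) {
  if (length(dim(frame)) == 2) {
    return(frame)
  }
  nch <- dim(frame)[3]
  if (nch >= 3) {
    frame[, , 1] * GRAY_WEIGHTS[["r"]] +
      frame[, , 2] * GRAY_WEIGHTS[["g"]] +
      frame[, , 3] * GRAY_WEIGHTS[["b"]]
  } else {
    frame[, , 1]
  }
}

read_frame_file <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- if (ext == "png") png::readPNG(file) else tiff::readTIFF(file)
  to_grayscale(img)
}

#' Extract grayscale, cropped frames for an analysis window
#'
#' Yields the frames with 0-based indices in
#' `[round(start_s * fps), round(end_s * fps))`, each converted to
#' single-channel grayscale (Rec. 709 luminance) and cropped to the ROI's
#' bounding rectangle. Intensities are in `[0, 1]`.
#'
#' @param meta A `video_meta` from [open_video()].
#' @param window An [analysis_window()], or `NULL` for the full video.
#' @param roi A [region_of_interest()], or `NULL` for the full frame.
#' @return A list of numeric matrices (rows = y, cols = x), one per frame,
#'   with attributes `fps` and `frame_index0` (0-based source indices).
#' @export
frame_stream <- function(meta, window = NULL, roi = NULL) {
  stopifnot(inherits(meta, "video_meta"))
  window <- window %||% analysis_window(0, meta$duration_s)
  if (window$end_s > meta$duration_s + 1e-9 || window$start_s >= meta$duration_s) {
    stop_immobilitr(
      sprintf(
        "analysis window [%g, %g) s outside video duration %g s",
        window$start_s, window$end_s, meta$duration_s
      ),
      class = "immobilitr_error_bad_window"
    )
  }
  i0 <- round_half_up(window$start_s * meta$fps) # 0-based, inclusive
  i1 <- round_half_up(min(window$end_s, meta$duration_s) * meta$fps) # exclusive
  idx <- seq.int(i0, i1 - 1L)
  rect <- if (!is.null(roi)) roi_bounding_rect(roi, meta$width, meta$height)

  frames <- if (meta$kind == "tiff_stack") {
    raw <- tiff::readTIFF(meta$path, all = idx + 1L)
    if (!is.list(raw)) raw <- list(raw)
    lapply(raw, to_grayscale)
  } else {
    lapply(meta$files[idx + 1L], read_frame_file)
  }
  if (!is.null(rect)) {
    frames <- lapply(frames, function(f) f[rect$y0:rect$y1, rect$x0:rect$x1])
  }
  structure(frames, fps = meta$fps, frame_index0 = idx)
}
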