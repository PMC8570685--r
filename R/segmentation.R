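# Per-frame animal segmentation: optional background subtraction, Gaussian
# smoothing, global thresholding (Otsu or user-set), small-component
# rejection, largest-connected-component selection.

#' Segmentation configuration
#'
#' @param blur_sigma Gaussian smoothing scale in pixels (>= 0; 0 disables
#'   smoothing). Default 2.
#' @param threshold_mode `"automatic"` (Otsu's method per frame) or
#'   `"manual"`.
#' @param manual_threshold Grayscale level in `[0, 1]`; required when
#'   `threshold_mode = "manual"`.
#' @param polarity `"animal-dark"` (dark animal on a bright background, the
#'   validated acquisition setup) or `"animal-light"`. Ignored when a
#'   background model is used: the absolute difference image is always bright
#'   where the animal is, which is what makes the method work for black and
#'   white animals alike.
#' @param min_component_px Connected components smaller than this many pixels
#'   are discarded before the largest one is kept; rejects glare and ripple
#'   speckle. Default 50.
#' @param use_background If `TRUE`, frames are segmented as
#'   `|frame - background|` against a [estimate_background()] model.
#' @return A `segmentation_config` list.
#' @export
segmentation_config <- function(blur_sigma = 2,
                                threshold_mode = c("automatic", "manual"),
                                manual_threshold = NULL,
                                polarity = c("animal-dark", "animal-light"),
                                min_component_px = 50,
                                use_background = FALSE) {
  threshold_mode <- match.arg(threshold_mode)
  polarity <- match.arg(polarity)
  stopifnot(blur_sigma >= 0, min_component_px >= 1)
  if (threshold_mode == "manual") {
    if (is.null(manual_threshold) || manual_threshold < 0 || manual_threshold > 1) {
      stop_immobilitr(
        "manual_threshold must be supplied in [0, 1] when threshold_mode = \"manual\"",
        class = "immobilitr_error_bad_config"
      )
    }
  }
  structure(
    list(
      blur_sigma = blur_sigma, threshold_mode = threshold_mode,
      manual_threshold = manual_threshold, polarity = polarity,
      min_component_px = as.integer(min_component_px),
      use_background = isTRUE(use_background)
    ),
    class = "segmentation_config"
  )
}

# Even-odd point-in-polygon test, vectorized over query points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polygon_mask <- function(polygon, height, width) {
  v <- region_of_interest(polygon)$vertices
  grid <- expand.grid(y = seq_len(height), x = seq_len(width))
  matrix(points_in_polygon(grid$x, grid$y, v[, "x"], v[, "y"]),
    nrow = height, ncol = width
  )
}

#' Estimate the background behind the animal
#'
#' Given a reference frame and a polygon marking the animal's outer boundary,
#' replaces the pixels inside the polygon with the median intensity of a
#' 3-px ring of pixels just outside it, producing an animal-free background
#' image for background-subtracted segmentation.
#'
#' @param reference_frame Grayscale matrix, intensities in `[0, 1]`.
#' @param animal_polygon >= 3 (x, y) vertices inside the frame.
#' @return A `background_model`: list with `image` (the filled frame) and
#'   `fill_polygon`.
#' @export
estimate_background <- function(reference_frame, animal_polygon) {
  stopifnot(is.matrix(reference_frame))
  h <- nrow(reference_frame)
  w <- ncol(reference_frame)
  inside <- polygon_mask(animal_polygon, h, w)
  ring <- EBImage::dilate(
    EBImage::Image(inside * 1),
    EBImage::makeBrush(7, shape = "disc")
  ) > 0.5
  ring <- as.matrix(ring) & !inside
  if (!any(ring)) {
    stop_immobilitr(
      "animal polygon covers the whole frame; no background ring available",
      class = "immobilitr_error_no_ring"
    )
  }
  filled <- reference_frame
  filled[inside] <- median(reference_frame[ring])
  structure(
    list(image = filled, fill_polygon = animal_polygon),
    class = "background_model"
  )
}

#' Binarize one frame into an animal mask
#'
#' Pipeline: optional absolute difference against a background model, then
#' Gaussian smoothing (`blur_sigma`), then a global threshold (Otsu when
#' automatic, the user's level otherwise, with `polarity` picking the
#' foreground side), then rejection of components below `min_component_px`,
#' then retention of the largest remaining connected component.
#'
#' An empty result (e.g. a blank frame) is not an error: the mask comes back
#' with `empty = TRUE` and zero area.
#'
#' @param frame Grayscale matrix, intensities in `[0, 1]`.
#' @param config A [segmentation_config()].
#' @param background Optional [estimate_background()] model; used when
#'   `config$use_background` is `TRUE`.
#' @return A `binary_mask`: list with `pixels` (logical matrix), `area_px`,
#'   `empty` flag and the `threshold` actually applied.
#' @export
binarize_frame <- function(frame, config = segmentation_config(),
                           background = NULL) {
  stopifnot(is.matrix(frame), inherits(config, "segmentation_config"))
  x <- frame
  polarity <- config$polarity
  if (config$use_background && !is.null(background)) {
    x <- abs(x - background$image)
    polarity <- "animal-light" # difference image is bright at the animal
  }
  if (config$blur_sigma > 0) {
    x <- as.matrix(EBImage::gblur(EBImage::Image(x), sigma = config$blur_sigma))
  }
  if (config$threshold_mode == "automatic") {
    if (diff(range(x)) < 1e-6) {
      # blank frame: no bimodality, nothing to segment
      return(new_binary_mask(matrix(FALSE, nrow(x), ncol(x)), threshold = NA_real_))
    }
    th <- EBImage::otsu(EBImage::Image(x), range = range(x))
  } else {
    th <- config$manual_threshold
  }
  fg <- if (polarity == "animal-dark") x < th else x > th
  lab <- EBImage::bwlabel(EBImage::Image(fg * 1))
  lab <- as.matrix(EBImage::imageData(lab))
  sizes <- tabulate(lab)
  keep <- which(sizes >= config$min_component_px)
  if (length(keep) == 0) {
    return(new_binary_mask(matrix(FALSE, nrow(x), ncol(x)), threshold = th))
  }
  largest <- keep[which.max(sizes[keep])]
  new_binary_mask(lab == largest, threshold = th)
}

new_binary_mask <- function(pixels, threshold = NA_real_) {
  structure(
    list(
      pixels = pixels, area_px = sum(pixels), empty = !any(pixels),
      threshold = threshold
    ),
    class = "binary_mask"
  )
}

#' Measure a binary mask
#'
#' @param mask A `binary_mask` from [binarize_frame()].
#' @return A named numeric vector `c(area_px, major_axis_px)`; the major axis
#'   is the major-axis length of the best-fit ellipse of the component
#'   (0 for an empty mask).
#' @export
measure_mask <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask$empty) {
    return(c(area_px = 0, major_axis_px = 0))
  }
  # EBImage moments expect an x-by-y labelled image; transpose our row=y
  # matrices.
  m <- EBImage::computeFeatures.moment(t(mask$pixels) * 1L)
  c(area_px = mask$area_px, major_axis_px = unname(m[1, "m.majoraxis"]))
}

#' Segment a frame sequence
#'
#' Applies [binarize_frame()] to every frame and tabulates per-frame
#' features.
#'
#' @param frames A list of grayscale matrices (e.g. from [frame_stream()]).
#' @param config A [segmentation_config()].
#' @param background Optional background model.
#' @param measure_length If `TRUE`, also computes the per-frame major-axis
#'   length (needed for the object-length metric; skipped otherwise for
#'   speed).
#' @param keep_masks If `TRUE`, the masks are returned in an attribute
#'   `masks` (needed for the frame-by-frame variation metric).
#' @return A tibble with columns `frame` (0-based), `area_px`,
#'   `major_axis_px` (NA unless `measure_length`), `empty`.
#' @export
segment_frames <- function(frames, config = segmentation_config(),
                           background = NULL, measure_length = FALSE,
                           keep_masks = FALSE) {
  masks <- lapply(frames, binarize_frame, config = config, background = background)
  res <- tibble(
    frame = seq_along(masks) - 1L,
    area_px = vapply(masks, function(m) as.numeric(m$area_px), numeric(1)),
    major_axis_px = if (measure_length) {
      vapply(masks, function(m) measure_mask(m)[["major_axis_px"]], numeric(1))
    } else {
      NA_real_
    },
    empty = vapply(masks, function(m) m$empty, logical(1))
  )
  if (keep_masks) attr(res, "masks") <- masks
  res
}
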