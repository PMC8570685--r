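# ROC-based threshold calibration against manual per-second scores.
#
# Human scorers take 1-3 s to react to a behavioral state change, so the
# seconds nearest each manual-label transition are unreliable; they are
# masked out (transition exclusion, k seconds on each side of every
# boundary) before the ROC is built. The optimum cut-point maximizes
# Sensitivity(c) * Specificity(c).

#' Calibrated default delta-area thresholds
#'
#' The recommended per-second delta-area % thresholds shipped with the
#' package, from the reference calibration on mouse videos (transition
#' exclusion k = 3): 2.5861 for FST, 0.7808 for TST.
#'
#' @param test_type `"FST"` or `"TST"`.
#' @return The threshold, a single number.
#' @examples
#' default_threshold("FST")
#' default_threshold("TST")
#' @export
default_threshold <- function(test_type = c("FST", "TST")) {
  test_type <- match.arg(toupper(test_type), c("FST", "TST"))
  c(FST = 2.5861, TST = 0.7808)[[test_type]]
}

#' Split videos into calibration and validation sets
#'
#' Deterministic seeded shuffle; the calibration set gets
#' `round(fraction * n)` videos.
#'
#' @param videos A vector or list of video identifiers (>= 2).
#' @param fraction Calibration fraction, in (0, 1). Default 0.60.
#' @param seed Integer seed; the same seed always yields the same split.
#' @return A list with elements `calibration` and `validation`, a disjoint
#'   partition of `videos`.
#' @export
split_calibration <- function(videos, fraction = 0.60, seed) {
  n <- length(videos)
  if (n < 2) {
    stop_immobilitr("need at least 2 videos to split",
      class = "immobilitr_error_too_few_videos"
    )
  }
  if (fraction <= 0 || fraction >= 1) {
    stop_immobilitr("fraction must be in (0, 1)",
      class = "immobilitr_error_bad_fraction"
    )
  }
  perm <- with_local_seed(seed, sample.int(n))
  n_cal <- round(fraction * n)
  list(
    calibration = videos[sort(perm[seq_len(n_cal)])],
    validation = videos[sort(perm[setdiff(seq_len(n), seq_len(n_cal))])]
  )
}

#' Mask out seconds around manual-label transitions
#'
#' A boundary exists between seconds `t-1` and `t` whenever the labels
#' differ; the `k` seconds on each side of every boundary (seconds
#' `t-k..t-1` and `t..t+k-1`, clipped to range) are excluded. `k = 0` keeps
#' everything.
#'
#' @param labels 0/1 manual labels, one per second.
#' @param k Exclusion half-window in seconds (>= 0). Default 3, matching the
#'   shipped calibration.
#' @return A logical vector, `TRUE` where the second is kept.
#' @export
exclude_transitions <- function(labels, k = 3) {
  labels <- check_binary_labels(labels)
  stopifnot(k >= 0)
  n <- length(labels)
  kept <- rep(TRUE, n)
  if (k == 0 || n < 2) {
    return(kept)
  }
  boundaries <- which(labels[-1] != labels[-n]) # boundary before second t (0-based t)
  for (t in boundaries) {
    lo <- max(1L, t - k + 1L) # 1-based index of second t-k
    hi <- min(n, t + k) # 1-based index of second t+k-1
    kept[lo:hi] <- FALSE
  }
  kept
}

#' Pair per-second trace values with manual labels
#'
#' @param trace A `motion_trace` or numeric vector of per-second delta-area
#'   % values.
#' @param labels 0/1 manual labels (1 = immobile), same length.
#' @param k Transition-exclusion half-window, passed to
#'   [exclude_transitions()].
#' @return A `labeled_seconds` tibble with columns `second`, `value`,
#'   `label`, `kept`; attribute `exclusion_k`.
#' @export
labeled_seconds <- function(trace, labels, k = 3) {
  values <- if (is.data.frame(trace)) trace$value else as.numeric(trace)
  labels <- check_binary_labels(labels)
  if (length(values) != length(labels)) {
    stop_immobilitr("trace and labels must have the same length",
      class = "immobilitr_error_length_mismatch"
    )
  }
  structure(
    tibble(
      second = seq_along(values) - 1L,
      value = values,
      label = labels,
      kept = exclude_transitions(labels, k) & !is.na(values)
    ),
    exclusion_k = k,
    class = c("labeled_seconds", class(tibble()))
  )
}

#' ROC curve for immobility classification
#'
#' The positive class is immobile; a second is predicted positive when its
#' trace value is strictly below the cut-point `c`. The threshold grid is
#' every distinct kept trace value plus one sentinel below the minimum and
#' one above the maximum, which makes the trapezoidal AUC exactly the
#' Mann-Whitney pair-ordering probability (ties counted 1/2) and the
#' optimum cut-point grid-independent.
#'
#' @param data A `labeled_seconds` tibble (rows with `kept = FALSE` are
#'   ignored).
#' @return A `roc_curve` tibble with columns `threshold`, `sensitivity`,
#'   `specificity`; attributes `auc` and `exclusion_k`.
#' @export
roc_curve <- function(data) {
  d <- data[data$kept, ]
  pos <- d$value[d$label == 1L]
  neg <- d$value[d$label == 0L]
  if (length(pos) == 0 || length(neg) == 0) {
    stop_immobilitr(
      "kept seconds must contain both classes (immobile and mobile)",
      class = "immobilitr_error_single_class"
    )
  }
  v <- sort(unique(d$value))
  grid <- c(v[1] - 1, v, v[length(v)] + 1)
  sens <- vapply(grid, function(c) mean(pos < c), numeric(1))
  spec <- vapply(grid, function(c) mean(neg >= c), numeric(1))
  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)
  structure(
    tibble(threshold = grid, sensitivity = sens, specificity = spec),
    auc = auc,
    exclusion_k = attr(data, "exclusion_k"),
    class = c("roc_curve", class(tibble()))
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf(
    "<roc_curve> %d thresholds, AUC = %.4f\n", nrow(x), attr(x, "auc")
  ))
  NextMethod()
}

#' Optimum classification cut-point from an ROC curve
#'
#' `c* = argmax Sensitivity(c) * Specificity(c)` over the threshold grid;
#' ties break toward the smaller cut-point.
#'
#' @param roc A `roc_curve`.
#' @param metric_mode Recorded on the result.
#' @return A `calibration_result`: list with `optimum_threshold`, `auc`,
#'   `exclusion_k`, `metric_mode`, `product` (the maximized
#'   sensitivity-specificity product) and the `roc` curve itself.
#' @export
optimum_cutpoint <- function(roc, metric_mode = "area") {
  stopifnot(inherits(roc, "roc_curve"), nrow(roc) > 0)
  prod <- roc$sensitivity * roc$specificity
  best <- which.max(prod) # which.max returns the first (smallest c) on ties
  structure(
    list(
      optimum_threshold = roc$threshold[best],
      auc = attr(roc, "auc"),
      exclusion_k = attr(roc, "exclusion_k"),
      metric_mode = metric_mode,
      product = prod[best],
      roc = roc
    ),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<calibration_result>\n",
      "  optimum threshold (delta-area %%): %.4f\n",
      "  AUC:                               %.4f\n",
      "  sens x spec at optimum:            %.4f\n",
      "  transition exclusion k:            %s s\n"
    ),
    x$optimum_threshold, x$auc, x$product,
    ifelse(is.null(x$exclusion_k), "?", as.character(x$exclusion_k))
  ))
  invisible(x)
}

#' @rdname optimum_cutpoint
#' @param x A `calibration_result`.
#' @param ... Unused.
#' @export
tidy.calibration_result <- function(x, ...) {
  as_tibble(x$roc)
}

#' @rdname optimum_cutpoint
#' @export
glance.calibration_result <- function(x, ...) {
  tibble(
    optimum_threshold = x$optimum_threshold,
    auc = x$auc,
    product = x$product,
    exclusion_k = as.numeric(x$exclusion_k %||% NA_real_),
    metric_mode = x$metric_mode
  )
}

#' Calibrate the immobility threshold against manual scores
#'
#' Pools the kept seconds from every supplied video into one ROC and picks
#' the optimum cut-point. Each element of `videos` pairs a per-second motion
#' trace with manual labels for the same seconds.
#'
#' @param videos A list whose elements are lists with components `trace`
#'   (a `motion_trace` or numeric vector) and `labels` (0/1 per second).
#' @param k Transition-exclusion half-window in seconds. Default 3.
#' @param metric_mode Recorded on the result.
#' @return A `calibration_result`.
#' @export
calibrate_threshold <- function(videos, k = 3, metric_mode = "area") {
  pooled <- bind_rows(lapply(videos, function(v) {
    labeled_seconds(v$trace, v$labels, k = k)
  }))
  attr(pooled, "exclusion_k") <- k
  optimum_cutpoint(roc_curve(pooled), metric_mode = metric_mode)
}

#' Load manual per-second labels from CSV
#'
#' Expects columns `second_index` (contiguous from 0) and `label` (0/1,
#' 1 = immobile) — the per-second manual-scoring output convention.
#'
#' @param path CSV path.
#' @return Integer 0/1 vector.
#' @export
load_manual_labels <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("second_index", "label") %in% names(df))) {
    stop_immobilitr("label CSV needs columns second_index, label",
      class = "immobilitr_error_bad_labels"
    )
  }
  if (anyDuplicated(df$second_index)) {
    stop_immobilitr("duplicate second_index in label CSV",
      class = "immobilitr_error_duplicate_seconds"
    )
  }
  expected <- seq_len(nrow(df)) - 1L
  if (!identical(as.integer(sort(df$second_index)), expected)) {
    stop_immobilitr("label CSV seconds must be contiguous from 0",
      class = "immobilitr_error_gap"
    )
  }
  df <- df[order(df$second_index), ]
  if (!all(df$label %in% c(0, 1))) {
    stop_immobilitr("labels must be 0 or 1",
      class = "immobilitr_error_nonbinary"
    )
  }
  as.integer(df$label)
}
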