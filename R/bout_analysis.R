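# Bout analytics on a per-second immobility track: percent time immobile,
# latency to first immobility, longest bouts, block-wise immobility, raster
# intervals. A bout is any maximal run of >= 1 s in one state; no
# minimum-bout smoothing is applied.

#' Summarize immobility behavior
#'
#' @param track An `immobility_track` (from [classify_immobility()] or
#'   [manual_track()]) or a bare 0/1 vector, 1 = immobile.
#' @return A `bout_summary` object: list with `percent_immobile`,
#'   `latency_first_immobility_s` (`NA` when the track has no immobile
#'   second — never 0 or the track length), `longest_immobility_bout_s`,
#'   `longest_mobility_bout_s`, `n_seconds`, and `bouts`, a tibble of
#'   alternating maximal runs (`state`, `start_s`, `length_s`).
#' @examples
#' bout_summary(c(0, 0, 1, 1, 1, 0, 1))
#' @export
bout_summary <- function(track) {
  labels <- as_track_labels(track)
  n <- length(labels)
  runs <- rle(labels)
  starts <- cumsum(c(0L, runs$lengths[-length(runs$lengths)]))
  bouts <- tibble(
    state = ifelse(runs$values == 1L, "immobile", "mobile"),
    start_s = starts,
    length_s = runs$lengths
  )
  imm_lengths <- runs$lengths[runs$values == 1L]
  mob_lengths <- runs$lengths[runs$values == 0L]
  structure(
    list(
      percent_immobile = 100 * sum(labels) / n,
      latency_first_immobility_s =
        if (any(labels == 1L)) which.max(labels == 1L) - 1L else NA_integer_,
      longest_immobility_bout_s = if (length(imm_lengths)) max(imm_lengths) else 0L,
      longest_mobility_bout_s = if (length(mob_lengths)) max(mob_lengths) else 0L,
      n_seconds = n,
      bouts = bouts
    ),
    class = "bout_summary"
  )
}

#' @export
print.bout_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<bout_summary> %d s analyzed\n",
      "  %% time immobile:          %.2f\n",
      "  latency to immobility:    %s s\n",
      "  longest immobility bout:  %d s\n",
      "  longest mobility bout:    %d s\n",
      "  bouts:                    %d\n"
    ),
    x$n_seconds, x$percent_immobile,
    ifelse(is.na(x$latency_first_immobility_s), "--",
      as.character(x$latency_first_immobility_s)
    ),
    x$longest_immobility_bout_s, x$longest_mobility_bout_s, nrow(x$bouts)
  ))
  invisible(x)
}

#' @rdname bout_summary
#' @param x A `bout_summary`.
#' @param ... Unused.
#' @export
tidy.bout_summary <- function(x, ...) {
  x$bouts
}

#' @rdname bout_summary
#' @export
glance.bout_summary <- function(x, ...) {
  tibble(
    percent_immobile = x$percent_immobile,
    latency_first_immobility_s = as.numeric(x$latency_first_immobility_s),
    longest_immobility_bout_s = as.numeric(x$longest_immobility_bout_s),
    longest_mobility_bout_s = as.numeric(x$longest_mobility_bout_s),
    n_seconds = x$n_seconds
  )
}

#' Immobile seconds per analysis block
#'
#' Splits the track into consecutive non-overlapping blocks starting at
#' second 0 (the last block may be shorter) and counts the immobile seconds
#' in each.
#'
#' @inheritParams bout_summary
#' @param block_length_s Block size in seconds (>= 1).
#' @return A tibble with columns `block` (0-based), `start_s`, `length_s`,
#'   `immobile_s`.
#' @export
block_immobility <- function(track, block_length_s) {
  if (!is.numeric(block_length_s) || block_length_s < 1) {
    stop_immobilitr("block_length_s must be >= 1",
      class = "immobilitr_error_bad_block"
    )
  }
  block_length_s <- as.integer(block_length_s)
  labels <- as_track_labels(track)
  blk <- (seq_along(labels) - 1L) %/% block_length_s
  tibble(
    block = unique(blk),
    start_s = unique(blk) * block_length_s,
    length_s = as.integer(tabulate(blk + 1L)),
    immobile_s = as.integer(tapply(labels, blk, sum))
  )
}

#' Immobile intervals for raster plotting
#'
#' @inheritParams bout_summary
#' @return A tibble of half-open `(start_s, end_s)` intervals, disjoint and
#'   sorted, whose union covers exactly the immobile seconds.
#' @export
raster_intervals <- function(track) {
  s <- bout_summary(track)
  b <- s$bouts[s$bouts$state == "immobile", ]
  tibble(start_s = b$start_s, end_s = b$start_s + b$length_s)
}
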