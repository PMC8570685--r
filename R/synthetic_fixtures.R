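# Ground-truthed synthetic fixtures: rendered videos of a dark elliptical
# blob on a bright background following a known per-second
# mobility/immobility schedule, plus simulated human-scorer labels with
# reaction lag. These stand in for real FST/TST recordings in tests and
# examples; they emulate the contrast structure the method assumes, not
# water, ripples, reflections or tail-climbing artifacts.

#' Alternating mobility schedule
#'
#' @param total_s Total duration in seconds. Default 300 (the standard
#'   5-minute test).
#' @param bout_s Bout length of each state in seconds. Default 20.
#' @param start_state First state, `"mobile"` or `"immobile"`.
#' @return A character vector of per-second states.
#' @export
alternating_schedule <- function(total_s = 300, bout_s = 20,
                                 start_state = c("mobile", "immobile")) {
  start_state <- match.arg(start_state)
  states <- c(start_state, setdiff(c("mobile", "immobile"), start_state))
  rep(rep(states, length.out = ceiling(total_s / bout_s)), each = bout_s)[seq_len(total_s)]
}

#' Synthetic mobility schedule
#'
#' The per-second plan a fixture video follows, together with the motion
#' parameters of the rendered blob. During mobile seconds the blob takes an
#' integer-pixel random-walk step of up to `mobile_jitter_px` per frame and
#' its area oscillates sinusoidally by `deform_frac` (peak fractional area
#' change, period `deform_period_frames` frames) — translation alone
#' preserves area, so the deformation is what drives the delta-area
#' statistic, as limb and body movement does in a real recording. Immobile
#' seconds allow only residual micro-motion of `immobile_jitter_px` and no
#' deformation.
#'
#' @param states Character vector of `"mobile"`/`"immobile"`, one per
#'   second, e.g. from [alternating_schedule()].
#' @param mobile_jitter_px Per-frame displacement amplitude during mobile
#'   seconds (integer pixels). Default 2.
#' @param immobile_jitter_px Residual micro-motion during immobile seconds;
#'   must be smaller than `mobile_jitter_px`. Default 0.
#' @param deform_frac Peak fractional area fluctuation during mobile
#'   seconds. Default 0.15, which puts the mean mobile delta-area % near 6 —
#'   comfortably above both shipped thresholds — while immobile seconds stay
#'   near 0.
#' @param deform_period_frames Period of the area oscillation, frames.
#' @return A `synthetic_schedule` object.
#' @export
synthetic_schedule <- function(states,
                               mobile_jitter_px = 2,
                               immobile_jitter_px = 0,
                               deform_frac = 0.15,
                               deform_period_frames = 10) {
  if (!is.character(states) || !all(states %in% c("mobile", "immobile"))) {
    stop_immobilitr("states must be \"mobile\"/\"immobile\", one per second",
      class = "immobilitr_error_bad_schedule"
    )
  }
  stopifnot(
    length(states) >= 1,
    mobile_jitter_px >= 0, immobile_jitter_px >= 0,
    immobile_jitter_px < mobile_jitter_px || mobile_jitter_px == 0,
    deform_frac >= 0, deform_period_frames >= 2
  )
  structure(
    list(
      states = states,
      mobile_jitter_px = as.integer(mobile_jitter_px),
      immobile_jitter_px = as.integer(immobile_jitter_px),
      deform_frac = deform_frac,
      deform_period_frames = deform_period_frames
    ),
    class = "synthetic_schedule"
  )
}

as_synthetic_schedule <- function(schedule) {
  if (inherits(schedule, "synthetic_schedule")) schedule else synthetic_schedule(schedule)
}

# Ground-truth immobility labels (1 = immobile) for a schedule.
#' @rdname synthetic_schedule
#' @param schedule A `synthetic_schedule` or character state vector.
#' @export
schedule_truth <- function(schedule) {
  as.integer(as_synthetic_schedule(schedule)$states == "immobile")
}

#' Render a synthetic fixture video
#'
#' Draws a dark ellipse on a bright noisy background, frame by frame, moving
#' and deforming according to the schedule, and (optionally) writes it as an
#' 8-bit multi-frame TIFF stack together with an fps JSON sidecar and the
#' ground-truth per-second label CSV. Fully deterministic given `seed`.
#'
#' @param schedule A [synthetic_schedule()] or character state vector.
#' @param fps Frames per second. Default 15, the validated reference rate.
#' @param frame_size `c(height, width)` in pixels.
#' @param animal List: `semi_axes = c(a, b)` ellipse semi-axes in px,
#'   `intensity` 0-255.
#' @param background List: `intensity` 0-255, `noise_sd` Gaussian pixel
#'   noise SD on the 0-255 scale.
#' @param seed Integer seed.
#' @param out_path Output `.tif` path, or `NULL` to keep frames in memory
#'   only.
#' @return A `synthetic_video` list: `path` (or NULL), `frames` (list of
#'   matrices in `[0, 1]`, quantized to 8 bits exactly as written),
#'   `truth` (tibble `second_index`, `label`), `fps`, `schedule`.
#' @export
render_video <- function(schedule,
                         fps = 15,
                         frame_size = c(96, 128),
                         animal = list(semi_axes = c(12, 7), intensity = 40),
                         background = list(intensity = 220, noise_sd = 5),
                         seed = 1,
                         out_path = NULL) {
  schedule <- as_synthetic_schedule(schedule)
  stopifnot(fps > 0, length(frame_size) == 2)
  h <- as.integer(frame_size[1])
  w <- as.integer(frame_size[2])
  a0 <- animal$semi_axes[1]
  b0 <- animal$semi_axes[2]
  smax <- sqrt(1 + schedule$deform_frac)
  margin <- 2 + schedule$mobile_jitter_px
  if (a0 * smax + margin >= w / 2 || b0 * smax + margin >= h / 2) {
    stop_immobilitr("animal does not fit in the frame with its jitter margin",
      class = "immobilitr_error_blob_exits_frame"
    )
  }

  n_seconds <- length(schedule$states)
  n_frames <- round_half_up(n_seconds * fps)
  frame_second <- pmin(floor((seq_len(n_frames) - 1) / fps), n_seconds - 1) + 1
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  bg <- background$intensity / 255
  fg <- animal$intensity / 255
  nsd <- background$noise_sd / 255

  frames <- with_local_seed(seed, {
    cx <- w / 2
    cy <- h / 2
    phase <- runif(1, 0, 2 * pi)
    out <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      mobile <- schedule$states[frame_second[f]] == "mobile"
      jit <- if (mobile) schedule$mobile_jitter_px else schedule$immobile_jitter_px
      if (jit > 0) {
        cx <- cx + sample(-jit:jit, 1)
        cy <- cy + sample(-jit:jit, 1)
      }
      if (mobile) phase <- phase + 2 * pi / schedule$deform_period_frames
      s <- if (mobile) 1 + schedule$deform_frac * sin(phase) else 1
      # clamp the walk so the blob (with deformation) stays inside the frame
      amax <- a0 * sqrt(max(s, 1)) + 1
      bmax <- b0 * sqrt(max(s, 1)) + 1
      cx <- min(max(cx, amax + 1), w - amax)
      cy <- min(max(cy, bmax + 1), h - bmax)
      blob <- ((xx - cx) / (a0 * sqrt(s)))^2 + ((yy - cy) / (b0 * sqrt(s)))^2 <= 1
      img <- matrix(bg, h, w)
      img[blob] <- fg
      if (nsd > 0) img <- img + matrix(rnorm(h * w, 0, nsd), h, w)
      # quantize to 8 bits so in-memory frames equal what readTIFF returns
      out[[f]] <- round(pmin(pmax(img, 0), 1) * 255) / 255
    }
    out
  })

  truth <- tibble(
    second_index = seq_len(n_seconds) - 1L,
    label = schedule_truth(schedule)
  )
  if (!is.null(out_path)) {
    tiff::writeTIFF(frames, out_path, bits.per.sample = 8L, compression = "deflate")
    jsonlite::write_json(list(fps = fps), paste0(out_path, ".meta.json"),
      auto_unbox = TRUE
    )
    readr::write_csv(truth, paste0(out_path, ".truth.csv"))
  }
  structure(
    list(
      path = out_path, frames = frames, truth = truth, fps = fps,
      schedule = schedule, seed = seed
    ),
    class = "synthetic_video"
  )
}

#' Simulate human-scorer labels with reaction lag
#'
#' Human scorers take roughly 1-3 s to register a behavioral state change
#' with a key press, so each ground-truth transition is delayed by an
#' independently drawn integer lag. Overlapping delayed transitions are
#' applied in chronological order of their delayed times.
#'
#' @param truth 0/1 ground-truth labels, one per second.
#' @param lag_range Integer `c(min, max)` lag in seconds, drawn uniformly
#'   per transition. Default `c(1, 3)`. Use `c(0, 0)` for a perfect scorer.
#' @param seed Integer seed.
#' @return Lagged 0/1 label vector, same length as `truth`.
#' @export
simulate_human_labels <- function(truth, lag_range = c(1, 3), seed = 1) {
  truth <- check_binary_labels(truth)
  stopifnot(length(lag_range) == 2, lag_range[1] >= 0, lag_range[2] >= lag_range[1])
  n <- length(truth)
  trans <- which(truth[-1] != truth[-n]) # 0-based transition second = trans
  if (length(trans) == 0) {
    return(truth)
  }
  choices <- seq.int(lag_range[1], lag_range[2])
  lags <- with_local_seed(
    seed,
    choices[sample.int(length(choices), length(trans), replace = TRUE)]
  )
  delayed <- trans + lags # 0-based second at which the new state registers
  ord <- order(delayed)
  out <- rep(truth[1], n)
  for (i in ord) {
    t0 <- delayed[i]
    if (t0 < n) out[(t0 + 1):n] <- truth[trans[i] + 1]
  }
  out
}

#' Simulate a per-second motion trace for a schedule
#'
#' Desk-scale surrogate for the full render-and-segment path: draws each
#' second's delta-area % directly from a per-state lognormal distribution
#' (mobile seconds high, immobile seconds low), calibrated to match what the
#' renderer's default motion parameters produce. Used for studying the
#' calibration procedure across many replicates without rendering video.
#'
#' @param truth 0/1 labels (1 = immobile), a character schedule, or a
#'   `synthetic_schedule`.
#' @param mobile_meanlog,immobile_meanlog,sdlog Lognormal parameters of the
#'   per-second delta-area % in each state.
#' @param seed Integer seed.
#' @return A `motion_trace` tibble.
#' @export
simulate_motion_trace <- function(truth,
                                  mobile_meanlog = log(6),
                                  immobile_meanlog = log(0.35),
                                  sdlog = 0.45,
                                  seed = 1) {
  if (is.character(truth) || inherits(truth, "synthetic_schedule")) {
    truth <- schedule_truth(truth)
  }
  truth <- check_binary_labels(truth)
  vals <- with_local_seed(seed, {
    meanlog <- ifelse(truth == 1L, immobile_meanlog, mobile_meanlog)
    stats::rlnorm(length(truth), meanlog = meanlog, sdlog = sdlog)
  })
  new_motion_trace(
    tibble(second = seq_along(truth) - 1L, value = vals, valid = TRUE),
    fps = NA_real_, metric_mode = "area"
  )
}
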