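# Independent oracles and tiny in-code fixtures shared across tests.

# Scan-based bout summary: a deliberately naive single-pass loop, kept
# independent of the rle-based implementation it checks.
scan_bout_summary <- function(labels) {
  n <- length(labels)
  n_imm <- 0L
  latency <- NA_integer_
  longest_imm <- 0L
  longest_mob <- 0L
  run_len <- 0L
  run_state <- NA_integer_
  for (i in seq_len(n)) {
    x <- labels[i]
    if (x == 1L) {
      n_imm <- n_imm + 1L
      if (is.na(latency)) latency <- i - 1L
    }
    if (!is.na(run_state) && x == run_state) {
      run_len <- run_len + 1L
    } else {
      if (!is.na(run_state)) {
        if (run_state == 1L) longest_imm <- max(longest_imm, run_len)
        if (run_state == 0L) longest_mob <- max(longest_mob, run_len)
      }
      run_state <- x
      run_len <- 1L
    }
  }
  if (run_state == 1L) longest_imm <- max(longest_imm, run_len)
  if (run_state == 0L) longest_mob <- max(longest_mob, run_len)
  list(
    percent_immobile = 100 * n_imm / n,
    latency_first_immobility_s = latency,
    longest_immobility_bout_s = longest_imm,
    longest_mobility_bout_s = longest_mob
  )
}

# Brute-force Mann-Whitney pair-ordering probability: for the immobile-low
# convention, a correctly ordered pair has the immobile value below the
# mobile value; ties count 1/2.
mw_auc <- function(immobile_values, mobile_values) {
  total <- 0
  for (p in immobile_values) {
    for (q in mobile_values) {
      total <- total + if (p < q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(immobile_values) * length(mobile_values))
}

# Draw an axis-aligned ellipse of the given intensity on a uniform
# background; returns the frame and the exact rendered pixel mask.
ellipse_frame <- function(h = 60, w = 80, cx = 40, cy = 30, a = 12, b = 7,
                          fg = 40 / 255, bg = 200 / 255) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  blob <- ((xx - cx) / a)^2 + ((yy - cy) / b)^2 <= 1
  frame <- matrix(bg, h, w)
  frame[blob] <- fg
  list(frame = frame, mask = blob)
}

# A short rendered fixture shared by several files (4 s, 2 s bouts, 5 fps).
tiny_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                         seconds = 4, bout_s = 2, fps = 5, seed = 11) {
  render_video(
    alternating_schedule(seconds, bout_s = bout_s),
    fps = fps, seed = seed,
    out_path = file.path(dir, sprintf("fix_%ds_%gfps_%d.tif", seconds, fps, seed))
  )
}
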