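test_that("per-frame percentage change follows the delta-area formula", {
  pf <- frame_percent_change(c(100, 110, 110))
  expect_equal(pf$pct, c(10, 0))
  expect_equal(pf$frame, c(1L, 2L))
  expect_true(all(pf$valid))

  # unsigned: a decrease counts the same as an increase
  expect_equal(frame_percent_change(c(100, 90))$pct, 10)

  # previous-frame feature of zero flags the value instead of zeroing it
  pf0 <- frame_percent_change(c(100, 0, 50))
  expect_true(is.na(pf0$pct[2]))
  expect_false(pf0$valid[2])

  expect_error(frame_percent_change(c(5)), class = "immobilitr_error_too_short")
  expect_error(frame_percent_change(c(0, 0, 0)), class = "immobilitr_error_all_empty")
})

test_that("variation mode measures the XOR pixel count", {
  m1 <- matrix(FALSE, 10, 10)
  m1[2:5, 2:5] <- TRUE # 16 px
  m2 <- m1 # identical
  m3 <- matrix(FALSE, 10, 10)
  m3[6:9, 6:9] <- TRUE # disjoint, equal area
  masks <- lapply(list(m1, m2, m3), function(p) {
    structure(list(pixels = p, area_px = sum(p), empty = FALSE),
      class = "binary_mask"
    )
  })
  pf <- frame_percent_change(c(16, 16, 16), mode = "variation", masks = masks)
  expect_equal(pf$pct, c(0, 200)) # identical -> 0; disjoint -> 2A/A
})

test_that("per-second averaging uses half-open frame bins and skips frame 0", {
  # fps = 3, per-frame deltas for frames 1..5
  pf <- tibble::tibble(frame = 1:5, pct = c(2, 4, 6, 8, 10), valid = TRUE)
  trace <- per_second_average(pf, fps = 3, n_seconds = 2)
  expect_equal(trace$value, c(mean(c(2, 4)), mean(c(6, 8, 10))))

  # constant per-frame value appears unchanged in every second
  pfc <- tibble::tibble(frame = 1:29, pct = 7, valid = TRUE)
  expect_true(all(per_second_average(pfc, fps = 10, n_seconds = 2)$value == 7))

  # trace length equals the whole-second count
  pf15 <- tibble::tibble(frame = 1:4499, pct = 1, valid = TRUE)
  expect_equal(nrow(per_second_average(pf15, fps = 15)), 300L)

  # a second with no valid frames is marked invalid
  pfi <- tibble::tibble(frame = 1:5, pct = c(2, 4, NA, NA, NA),
                        valid = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  tr <- per_second_average(pfi, fps = 3, n_seconds = 2)
  expect_false(tr$valid[2])
  expect_true(is.na(tr$value[2]))
})

make_trace <- function(values) {
  structure(
    tibble::tibble(
      second = seq_along(values) - 1L, value = values, valid = !is.na(values)
    ),
    fps = 1, metric_mode = "area",
    class = c("motion_trace", class(tibble::tibble()))
  )
}

test_that("classification is strictly-below with mobile ties", {
  track <- classify_immobility(make_trace(c(0.5, 3.0, 0.7)), 0.7808)
  expect_equal(track$label, c(1L, 0L, 1L))

  # a value exactly at the cut-point classifies mobile
  expect_equal(
    classify_immobility(make_trace(c(0.7808, 0.7808)), 0.7808)$label,
    c(0L, 0L)
  )
  trace <- make_trace(c(0.5, 3.0, 0.7))

  expect_error(classify_immobility(trace, 0), class = "immobilitr_error_bad_threshold")
  expect_error(classify_immobility(trace, -1), class = "immobilitr_error_bad_threshold")
})

test_that("invalid seconds inherit the previous label and are flagged", {
  trace <- structure(
    tibble::tibble(
      second = 0:3, value = c(NA, 0.1, NA, 9),
      valid = c(FALSE, TRUE, FALSE, TRUE)
    ),
    fps = 1, metric_mode = "area",
    class = c("motion_trace", class(tibble::tibble()))
  )
  track <- classify_immobility(trace, 1)
  expect_equal(track$label, c(0L, 1L, 1L, 0L)) # first invalid -> mobile
  expect_equal(track$imputed, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("a static mask sequence is 100% immobile at any positive threshold", {
  pf <- frame_percent_change(rep(250, 31))
  trace <- per_second_average(pf, fps = 10, n_seconds = 3)
  expect_true(all(trace$value == 0))
  for (c in c(0.01, 0.7808, 2.5861, 50)) {
    expect_true(all(classify_immobility(trace, c)$label == 1L))
  }
})

test_that("raising the threshold never decreases immobile seconds", {
  set.seed(5)
  pf <- tibble::tibble(frame = 1:100, pct = rlnorm(100, 0, 1), valid = TRUE)
  trace <- per_second_average(pf, fps = 10, n_seconds = 10)
  counts <- sapply(
    seq(0.1, 10, length.out = 25),
    function(c) sum(classify_immobility(trace, c)$label)
  )
  expect_true(all(diff(counts) >= 0))
})

test_that("the area metric is invariant to uniform area rescaling", {
  areas <- c(200, 210, 195, 230, 230, 180)
  t1 <- per_second_average(frame_percent_change(areas), fps = 5, n_seconds = 1)
  t2 <- per_second_average(frame_percent_change(areas * 7.3), fps = 5, n_seconds = 1)
  expect_equal(t1$value, t2$value)
})

test_that("per-second CSV export matches the output-file convention", {
  dir <- withr::local_tempdir()
  trace <- per_second_average(
    tibble::tibble(frame = 1:4, pct = c(1, 2, 3, 4), valid = TRUE),
    fps = 2, n_seconds = 2
  )
  p <- write_per_second_csv(trace, file.path(dir, "trace.csv"))
  df <- readr::read_csv(p, show_col_types = FALSE)
  expect_equal(names(df), c("second_index", "value"))
  expect_equal(nrow(df), 2L)

  track <- classify_immobility(trace, 2)
  write_per_second_csv(track, file.path(dir, "labels.csv"))
  lab <- readr::read_csv(file.path(dir, "labels.csv"), show_col_types = FALSE)
  expect_equal(names(lab), c("second_index", "label"))
  expect_equal(load_manual_labels(file.path(dir, "labels.csv")), track$label)
})
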