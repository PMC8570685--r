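test_that("calibration split sizes and determinism", {
  vids <- sprintf("video%02d", 1:20)
  sp <- split_calibration(vids, fraction = 0.60, seed = 42)
  expect_length(sp$calibration, 12L)
  expect_length(sp$validation, 8L)
  expect_setequal(c(sp$calibration, sp$validation), vids)
  expect_length(intersect(sp$calibration, sp$validation), 0L)

  sp2 <- split_calibration(vids, fraction = 0.60, seed = 42)
  expect_identical(sp, sp2)
  sp3 <- split_calibration(vids, fraction = 0.60, seed = 43)
  expect_false(identical(sp$calibration, sp3$calibration))

  half <- split_calibration(1:10, fraction = 0.5, seed = 1)
  expect_length(half$calibration, 5L)

  expect_error(split_calibration("one", seed = 1),
    class = "immobilitr_error_too_few_videos"
  )
  expect_error(split_calibration(1:5, fraction = 1.2, seed = 1),
    class = "immobilitr_error_bad_fraction"
  )
})

test_that("transition exclusion masks k seconds on each side of boundaries", {
  labels <- c(0, 0, 0, 1, 1, 1, 0, 0)
  kept <- exclude_transitions(labels, k = 1)
  expect_equal(which(kept) - 1L, c(0L, 1L, 4L, 7L))

  expect_true(all(exclude_transitions(labels, k = 0)))
  expect_true(all(exclude_transitions(rep(1L, 10), k = 3)))

  # increasing k never decreases the excluded set
  set.seed(9)
  for (i in 1:20) {
    lab <- rbinom(40, 1, 0.5)
    excluded <- sapply(0:4, function(k) sum(!exclude_transitions(lab, k)))
    expect_true(all(diff(excluded) >= 0))
    # nesting: everything excluded at k stays excluded at k+1
    for (k in 0:3) {
      expect_true(all(exclude_transitions(lab, k + 1) <= exclude_transitions(lab, k)))
    }
  }
})

test_that("ROC construction on separable, tied and interleaved data", {
  # perfectly separated: AUC 1 and some threshold attains sens = spec = 1
  d <- labeled_seconds(c(0.1, 0.2, 0.5, 0.9), c(1, 1, 0, 0), k = 0)
  roc <- roc_curve(d)
  expect_equal(attr(roc, "auc"), 1.0)
  expect_true(any(roc$sensitivity == 1 & roc$specificity == 1))
  expect_true(all(diff(roc$sensitivity) >= 0)) # higher c labels more immobile

  # ties only: chance performance
  tie <- labeled_seconds(rep(2.2, 6), c(1, 0, 1, 0, 1, 0), k = 0)
  expect_equal(attr(roc_curve(tie), "auc"), 0.5)

  # interleaved: 3 of 4 (immobile, mobile) pairs ordered correctly
  mix <- labeled_seconds(c(1, 3, 2, 4), c(1, 1, 0, 0), k = 0)
  expect_equal(attr(roc_curve(mix), "auc"), 0.75)

  expect_error(
    roc_curve(labeled_seconds(c(1, 2), c(1, 1), k = 0)),
    class = "immobilitr_error_single_class"
  )
})

test_that("trapezoidal AUC equals the Mann-Whitney pair-ordering probability", {
  set.seed(7)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5)) # guarantee both classes
    values <- round(rlnorm(n, 0, 1), sample(0:3, 1)) # rounding induces ties
    d <- labeled_seconds(values, labels, k = 0)
    auc <- attr(roc_curve(d), "auc")
    expect_equal(auc, mw_auc(values[labels == 1], values[labels == 0]),
      tolerance = 1e-12
    )
  }
})

test_that("our AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(21)
  labels <- rep(c(1, 0), 25)
  values <- rlnorm(50, ifelse(labels == 1, -1, 1), 0.8)
  auc <- attr(roc_curve(labeled_seconds(values, labels, k = 0)), "auc")
  ref <- suppressMessages(
    pROC::auc(pROC::roc(labels, values, direction = ">", quiet = TRUE))
  )
  expect_equal(auc, as.numeric(ref), tolerance = 1e-12)
})

test_that("optimum cut-point maximizes sensitivity x specificity", {
  d <- labeled_seconds(c(0.1, 0.2, 0.5, 0.9), c(1, 1, 0, 0), k = 0)
  cal <- optimum_cutpoint(roc_curve(d))
  expect_s3_class(cal, "calibration_result")
  expect_equal(cal$product, 1.0) # separable: the upper bound is attained
  expect_true(cal$optimum_threshold > 0.2 && cal$optimum_threshold <= 0.5)
  expect_true(cal$optimum_threshold %in% cal$roc$threshold)

  # exhaustive-search oracle on random instances
  set.seed(13)
  for (i in 1:20) {
    labels <- c(0, 1, rbinom(28, 1, 0.5))
    values <- round(rlnorm(30, 0, 1), 2)
    roc <- roc_curve(labeled_seconds(values, labels, k = 0))
    cal <- optimum_cutpoint(roc)
    prods <- roc$sensitivity * roc$specificity
    expect_equal(cal$product, max(prods))
    expect_equal(cal$optimum_threshold, roc$threshold[which.max(prods)])
  }

  # constructed tie: interleaved classes give two cut-points with the same
  # sensitivity-specificity product; the smaller one must be returned
  tie <- labeled_seconds(c(1, 3, 2, 4), c(1, 1, 0, 0), k = 0)
  roc_tie <- roc_curve(tie)
  prods <- roc_tie$sensitivity * roc_tie$specificity
  tied_at <- roc_tie$threshold[prods == max(prods)]
  expect_gt(length(tied_at), 1)
  expect_equal(optimum_cutpoint(roc_tie)$optimum_threshold, min(tied_at))
})

test_that("pooled calibration recovers a separating threshold", {
  videos <- lapply(1:4, function(i) {
    truth <- schedule_truth(alternating_schedule(60, bout_s = 10))
    list(
      trace = simulate_motion_trace(truth, seed = i),
      labels = truth
    )
  })
  cal <- calibrate_threshold(videos, k = 0)
  expect_gt(cal$auc, 0.95)
  expect_gt(cal$optimum_threshold, 0.35)
  expect_lt(cal$optimum_threshold, 6)
  g <- glance(cal)
  expect_equal(g$exclusion_k, 0)
  expect_equal(g$optimum_threshold, cal$optimum_threshold)
})

test_that("manual label CSVs are validated", {
  dir <- withr::local_tempdir()
  ok <- file.path(dir, "ok.csv")
  readr::write_csv(
    tibble::tibble(second_index = 0:2, label = c(1, 1, 0)), ok
  )
  expect_equal(load_manual_labels(ok), c(1L, 1L, 0L))

  gap <- file.path(dir, "gap.csv")
  readr::write_csv(tibble::tibble(second_index = c(0, 2), label = c(1, 0)), gap)
  expect_error(load_manual_labels(gap), class = "immobilitr_error_gap")

  dup <- file.path(dir, "dup.csv")
  readr::write_csv(tibble::tibble(second_index = c(0, 1, 1), label = c(1, 0, 0)), dup)
  expect_error(load_manual_labels(dup), class = "immobilitr_error_duplicate_seconds")

  bad <- file.path(dir, "bad.csv")
  readr::write_csv(tibble::tibble(second_index = 0:1, label = c(1, 2)), bad)
  expect_error(load_manual_labels(bad), class = "immobilitr_error_nonbinary")
})
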