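test_that("response-time exclusions use strict bounds", {
  tr <- tibble::tibble(subject_id = "S01",
                       response_time = c(0.3, 1.0, 16.0))
  kept <- apply_exclusions(tr)
  expect_equal(nrow(kept), 1L)
  expect_equal(exclusion_report(kept)$pct_excluded, 100 * 2 / 3)

  # boundary values are retained: only strictly < 0.5 or > 15 is excluded
  edge <- tibble::tibble(subject_id = "S01", response_time = c(0.5, 15))
  expect_equal(nrow(apply_exclusions(edge)), 2L)

  clean <- tibble::tibble(subject_id = "S01", response_time = c(0.6, 2, 14.9))
  expect_equal(exclusion_report(apply_exclusions(clean))$pct_excluded, 0)

  bad <- tibble::tibble(subject_id = "S01", response_time = c(-1, 2))
  expect_error(apply_exclusions(bad), "negative")
})

test_that("degenerate same-location responders are flagged by modal share", {
  # 19 of 36 trials (52.8%) at one location -> flagged at threshold 0.50
  sticky <- tibble::tibble(
    subject_id = "S01",
    rated_position = c(rep(40L, 19), sample(c(1:39, 41:72), 17)))
  flags <- flag_degenerate_subjects(sticky, threshold = 0.5)
  expect_true(flags$flagged)
  expect_equal(flags$modal_position, 40L)
  expect_equal(flags$modal_share, 19 / 36)

  distinct <- tibble::tibble(subject_id = "S02", rated_position = 1:36)
  expect_false(flag_degenerate_subjects(distinct)$flagged)

  constant <- tibble::tibble(subject_id = "S03", rated_position = rep(7L, 10))
  expect_true(flag_degenerate_subjects(constant, threshold = 1)$flagged)
})

test_that("trial metrics define accuracy and bias correctly", {
  tr <- tibble::tibble(
    subject_id = "S01", condition = "sham",
    actual_position = c(15L, 20L, 1L),
    rated_position = c(10L, 20L, 72L),
    within_context_position = c(1L, 3L, 1L))
  m <- compute_metrics(tr)
  expect_equal(m$accuracy, c(5, 0, 71))
  expect_equal(m$bias, c(-5, 0, 71))
  expect_equal(m$position_class, c("boundary", "non_boundary", "boundary"))
  expect_equal(m$accuracy, abs(m$bias))

  out_of_range <- dplyr::mutate(tr, rated_position = c(10L, 73L, 72L))
  expect_error(compute_metrics(out_of_range), "1\\.\\.72")
})

test_that("aggregation weights positions equally and supports trimming", {
  # per-position means 10, 12, 14 at positions 3/5/7 -> non-boundary 12
  tr <- tidyr::expand_grid(subject_id = "S01", condition = "sham",
                           within_context_position = c(1L, 3L, 5L, 7L),
                           rep = 1:2) |>
    dplyr::mutate(
      actual_position = 30L,
      rated_position = 30L + dplyr::case_when(
        within_context_position == 1L ~ 5L,
        within_context_position == 3L ~ 10L,
        within_context_position == 5L ~ 12L,
        within_context_position == 7L ~ 14L))
  cells <- aggregate_cells(compute_metrics(tr))
  expect_equal(cells$mean_accuracy[cells$position_class == "non_boundary"], 12)
  expect_equal(cells$mean_accuracy[cells$position_class == "boundary"], 5)

  # unequal trial counts must not re-weight positions
  uneq <- dplyr::bind_rows(
    tr,
    tr |> dplyr::filter(within_context_position == 3L))  # extra pos-3 trials
  cells_uneq <- aggregate_cells(compute_metrics(uneq))
  expect_equal(
    cells_uneq$mean_accuracy[cells_uneq$position_class == "non_boundary"], 12)

  # trimmed mean drops one value per tail: {1,2,3,4,100} -> 3
  tm <- tidyr::expand_grid(subject_id = "S01", condition = "sham",
                           within_context_position = 3L, rep = 1:5) |>
    dplyr::mutate(actual_position = 30L,
                  rated_position = 30L + c(1L, 2L, 3L, 4L, 40L))
  robust <- aggregate_cells(compute_metrics(tm), estimator = "trimmed_mean",
                            trim = 0.2)
  expect_equal(robust$mean_accuracy[robust$position_class == "non_boundary"], 3)

  # single-trial cells return the trial value under either estimator
  single <- compute_metrics(tm[1, ])
  expect_equal(aggregate_cells(single)$mean_accuracy, 1)
  expect_equal(aggregate_cells(single, estimator = "trimmed_mean")$mean_accuracy, 1)
})

test_that("two-class non-boundary equals the mean of per-position cells", {
  tl <- simulate_timeline(probe_grid(6), behavioral_params(), seed = 21)
  m <- compute_metrics(tl)
  two <- aggregate_cells(m, granularity = "two_class")
  four <- aggregate_cells(m, granularity = "four_position")
  merged <- four |>
    dplyr::filter(position_class != "p1") |>
    dplyr::group_by(subject_id, condition) |>
    dplyr::summarise(nb = mean(mean_accuracy), .groups = "drop") |>
    dplyr::left_join(two |> dplyr::filter(position_class == "non_boundary"),
                     by = c("subject_id", "condition"))
  expect_equal(merged$nb, merged$mean_accuracy)
})

test_that("aggregated cells satisfy the triangle inequality", {
  tl <- simulate_timeline(probe_grid(24), behavioral_params(), seed = 31)
  cells <- aggregate_cells(compute_metrics(tl))
  expect_true(all(cells$mean_accuracy >= abs(cells$mean_bias) - 1e-12))
})

test_that("empty cells are recorded as missing with a warning", {
  tl <- simulate_timeline(probe_grid(3), behavioral_params(), seed = 41)
  tl <- tl[!(tl$subject_id == "S002" & tl$condition == "sham"), ]
  expect_warning(cells <- aggregate_cells(compute_metrics(tl)), "S002/sham")
  expect_true(any(is.na(cells$mean_accuracy[cells$subject_id == "S002"])))
})

test_that("exclusion rate on an outlier-calibrated cohort is near 2.2%", {
  probes <- probe_grid(48)
  tl <- simulate_timeline(probes, behavioral_params(outlier_rt_rate = 0.022),
                          seed = 51)
  rate <- exclusion_report(apply_exclusions(tl))$pct_excluded / 100
  n <- nrow(tl)
  # outliers are always out of range; lognormal tails add ~0.07%
  expected <- 0.022 + (1 - 0.022) * 0.0007
  expect_lt(abs(rate - expected), 3 * sqrt(expected * (1 - expected) / n))
})
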