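#' Apply response-time exclusion rules to timeline trials
#'
#' Excludes trials with overly fast or slow responses. The bounds are strict:
#' a trial is excluded only if `response_time < min_rt` or
#' `response_time > max_rt`, so trials at exactly 0.5 s or 15 s are retained.
#'
#' @param trials Timeline trials with a `response_time` column (seconds).
#' @param min_rt,max_rt Exclusion bounds in seconds (defaults 0.5 and 15).
#'
#' @return The retained trials, with an `exclusion_report` attribute holding
#'   overall and per-subject exclusion percentages (see
#'   [exclusion_report()]).
#' @export
#' @examples
#' tr <- tibble::tibble(subject_id = "S01", response_time = c(0.3, 1, 16))
#' nrow(apply_exclusions(tr))  # 1
apply_exclusions <- function(trials, min_rt = 0.5, max_rt = 15) {
  assert_columns(trials, c("subject_id", "response_time"), "`trials`")
  if (any(trials$response_time < 0, na.rm = TRUE)) {
    abort("Malformed data: negative response times present.")
  }
  keep <- trials$response_time >= min_rt & trials$response_time <= max_rt
  per_subject <- trials |>
    mutate(.excluded = !keep) |>
    group_by(.data$subject_id) |>
    summarise(n_trials = n(),
              n_excluded = sum(.data$.excluded),
              pct_excluded = 100 * mean(.data$.excluded),
              .groups = "drop")
  report <- list(
    n_trials = nrow(trials),
    n_excluded = sum(!keep),
    pct_excluded = 100 * mean(!keep),
    min_rt = min_rt,
    max_rt = max_rt,
    per_subject = per_subject
  )
  retained <- trials[keep, , drop = FALSE]
  attr(retained, "exclusion_report") <- report
  retained
}

#' @rdname apply_exclusions
#' @param x A tibble returned by [apply_exclusions()].
#' @export
exclusion_report <- function(x) {
  rep <- attr(x, "exclusion_report")
  if (is.null(rep)) abort("`x` carries no exclusion report; run apply_exclusions() first.")
  rep
}

#' Flag degenerate same-location responders
#'
#' Flags subjects whose modal rated position accounts for at least
#' `threshold` of their trials, the signature of a responder who parks the
#' slider at one location rather than performing the task.
#'
#' @param trials Timeline trials with `subject_id` and `rated_position`.
#' @param threshold Minimal modal share to flag (default 0.50).
#'
#' @return A tibble per subject: `n_trials`, `modal_position`, `modal_share`,
#'   `flagged`.
#' @export
flag_degenerate_subjects <- function(trials, threshold = 0.5) {
  assert_columns(trials, c("subject_id", "rated_position"), "`trials`")
  if (threshold < 0 || threshold > 1) abort("`threshold` must lie in [0, 1].")
  out <- trials |>
    group_by(.data$subject_id) |>
    summarise(
      n_trials = n(),
      modal_position = as.integer(names(which.max(table(.data$rated_position)))),
      modal_share = max(table(.data$rated_position)) / n(),
      .groups = "drop"
    ) |>
    mutate(flagged = .data$modal_share >= threshold)
  few <- out$subject_id[out$n_trials < 2L]
  if (length(few) > 0L) {
    warn(sprintf("Subject(s) with fewer than 2 trials: %s.",
                 paste(few, collapse = ", ")))
  }
  out
}

#' Compute trial-level temporal-memory metrics
#'
#' Adds the two dependent variables of the timeline analysis: temporal
#' accuracy, the absolute placement error `|rated - actual|`, and temporal
#' bias, the signed error `rated - actual` (negative = placed earlier than
#' actual). Trials are classed as boundary (within-context position 1) or
#' non-boundary.
#'
#' @param trials Timeline trials with `actual_position`, `rated_position`,
#'   `within_context_position`.
#' @param n_positions Timeline length (default 72).
#'
#' @return The input tibble plus `accuracy`, `bias`, `position_class`.
#' @export
compute_metrics <- function(trials, n_positions = 72) {
  assert_columns(trials, c("actual_position", "rated_position",
                           "within_context_position"), "`trials`")
  rng <- range(c(trials$actual_position, trials$rated_position))
  if (rng[1] < 1 || rng[2] > n_positions) {
    abort(sprintf("Positions must lie in 1..%d (found %g..%g).",
                  n_positions, rng[1], rng[2]))
  }
  trials |>
    mutate(
      bias = .data$rated_position - .data$actual_position,
      accuracy = abs(.data$bias),
      position_class = if_else(.data$within_context_position == 1L,
                               "boundary", "non_boundary")
    ) |>
    as_tibble()
}

trimmed_mean <- function(x, trim) mean(x, trim = trim)

#' Aggregate trial metrics into subject cells
#'
#' Averages trial-level accuracy and bias into one cell per subject,
#' condition, and position class. Per-position means are computed first;
#' under `granularity = "two_class"` the non-boundary cell is the unweighted
#' average of the per-position means (positions 3, 5, 7 under the default
#' design), so unequal trial exclusions cannot re-weight positions. Under
#' `"four_position"` every tested within-context position keeps its own cell
#' (labelled `"p1"`, `"p3"`, ...). The robust estimator is a two-sided
#' trimmed mean applied at the trial level within each position.
#'
#' @param metrics Trial metrics from [compute_metrics()].
#' @param granularity `"two_class"` (boundary vs non-boundary) or
#'   `"four_position"`.
#' @param estimator `"mean"` or `"trimmed_mean"`.
#' @param trim Trim fraction per tail for the trimmed mean (default 0.2).
#'
#' @return A tibble per subject cell: `subject_id`, `condition`,
#'   `position_class`, `mean_accuracy`, `mean_bias`, `n_trials_retained`.
#'   Cells absent from the data are recorded as `NA` with a warning.
#' @export
aggregate_cells <- function(metrics,
                            granularity = c("two_class", "four_position"),
                            estimator = c("mean", "trimmed_mean"),
                            trim = 0.2) {
  granularity <- match.arg(granularity)
  estimator <- match.arg(estimator)
  assert_columns(metrics, c("subject_id", "condition",
                            "within_context_position", "accuracy", "bias"),
                 "`metrics`")
  est <- if (estimator == "mean") mean else function(x) trimmed_mean(x, trim)

  per_position <- metrics |>
    group_by(.data$subject_id, .data$condition, .data$within_context_position) |>
    summarise(mean_accuracy = est(.data$accuracy),
              mean_bias = est(.data$bias),
              n_trials_retained = n(),
              .groups = "drop")

  cells <- if (granularity == "four_position") {
    per_position |>
      mutate(position_class = sprintf("p%d", .data$within_context_position)) |>
      select("subject_id", "condition", "position_class",
             "mean_accuracy", "mean_bias", "n_trials_retained")
  } else {
    per_position |>
      mutate(position_class = if_else(.data$within_context_position == 1L,
                                      "boundary", "non_boundary")) |>
      group_by(.data$subject_id, .data$condition, .data$position_class) |>
      summarise(mean_accuracy = mean(.data$mean_accuracy),
                mean_bias = mean(.data$mean_bias),
                n_trials_retained = sum(.data$n_trials_retained),
                .groups = "drop")
  }

  complete <- cells |>
    tidyr::complete(.data$subject_id, .data$condition, .data$position_class)
  missing <- complete |>
    filter(is.na(.data$mean_accuracy))
  if (nrow(missing) > 0L) {
    warn(sprintf("Empty subject cell(s) recorded as missing: %s.",
                 paste(paste(missing$subject_id, missing$condition,
                             missing$position_class, sep = "/"),
                       collapse = ", ")))
  }
  arrange(complete, .data$subject_id, .data$condition, .data$position_class)
}
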