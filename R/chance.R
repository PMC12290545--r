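new_chance_curves <- function(curve, method, n_series = NA_integer_, seed = NULL) {
  n <- nrow(curve)
  structure(
    curve,
    class = c("chance_curves", class(curve)),
    n_positions = n,
    method = method,
    n_series = n_series,
    seed = seed,
    grand_abs_mean = mean(curve$abs_error),
    grand_signed_mean = mean(curve$signed_error)
  )
}

#' Monte-Carlo chance-level curves for timeline placement error
#'
#' Simulates chance-level timeline performance: each simulated response
#' series is a uniformly random permutation of the position indexes
#' `1..n_positions`, i.e. a responder who uses every position exactly once
#' but in random order. Per position, the absolute and signed differences
#' between simulated response and actual position are averaged across
#' series, giving a U-shaped absolute-error curve (smaller errors for middle
#' positions) and a signed-error curve that decreases linearly across
#' positions. Because every permutation preserves the multiset of positions,
#' the grand signed mean is exactly zero for every series.
#'
#' @param n_series Number of shuffled series (default 10000).
#' @param n_positions Timeline length (default 72).
#' @param seed Integer seed.
#'
#' @return A `chance_curves` tibble with columns `position`, `abs_error`,
#'   `signed_error`, `abs_se` (Monte-Carlo standard error of `abs_error`),
#'   and attributes `grand_abs_mean`, `grand_signed_mean`, `method`,
#'   `n_series`. Use [glance()] for the grand means.
#' @export
#' @examples
#' cc <- simulate_chance(1000, seed = 1)
#' round(attr(cc, "grand_abs_mean"))
simulate_chance <- function(n_series = 10000, n_positions = 72, seed = NULL) {
  n_series <- assert_count(n_series, "n_series")
  n_positions <- assert_count(n_positions, "n_positions", min = 2L)
  maybe_set_seed(seed)
  idx <- seq_len(n_positions)
  abs_sum <- numeric(n_positions)
  abs_sq <- numeric(n_positions)
  signed_sum <- numeric(n_positions)
  for (i in seq_len(n_series)) {
    d <- sample.int(n_positions) - idx
    a <- abs(d)
    abs_sum <- abs_sum + a
    abs_sq <- abs_sq + a * a
    signed_sum <- signed_sum + d
  }
  abs_mean <- abs_sum / n_series
  abs_var <- (abs_sq - n_series * abs_mean^2) / (n_series - 1)
  curve <- tibble(
    position = idx,
    abs_error = abs_mean,
    signed_error = signed_sum / n_series,
    abs_se = sqrt(abs_var / n_series)
  )
  new_chance_curves(curve, method = "monte_carlo", n_series = n_series,
                    seed = seed)
}

#' Exact chance-level curves
#'
#' Closed-form counterpart of [simulate_chance()]: the marginal distribution
#' of a uniform random permutation at any slot is uniform on
#' `1..n_positions`, so the expected absolute error at position `p` is
#' `(p(p-1)/2 + (N-p)(N-p+1)/2) / N`, the expected signed error is
#' `(N+1)/2 - p`, and the grand mean absolute error is `(N^2 - 1) / (3N)`.
#'
#' @param n_positions Timeline length (>= 2).
#' @return A `chance_curves` tibble (see [simulate_chance()]).
#' @export
#' @examples
#' ec <- exact_chance(72)
#' ec$abs_error[c(1, 36)]        # 35.5, 18
#' attr(ec, "grand_abs_mean")    # 5183/216
exact_chance <- function(n_positions = 72) {
  n_positions <- assert_count(n_positions, "n_positions", min = 2L)
  p <- seq_len(n_positions)
  N <- n_positions
  curve <- tibble(
    position = p,
    abs_error = (p * (p - 1) / 2 + (N - p) * (N - p + 1) / 2) / N,
    signed_error = (N + 1) / 2 - p,
    abs_se = 0
  )
  new_chance_curves(curve, method = "exact")
}

#' @export
print.chance_curves <- function(x, ...) {
  cat(sprintf("<chance_curves: %s, %d positions%s>\n",
              attr(x, "method"), attr(x, "n_positions"),
              if (attr(x, "method") == "monte_carlo")
                sprintf(", %d series", attr(x, "n_series")) else ""))
  cat(sprintf("  grand mean |error| = %.4f, grand mean signed error = %.4g\n",
              attr(x, "grand_abs_mean"), attr(x, "grand_signed_mean")))
  NextMethod()
}

#' @rdname glance.chance_curves
#' @method tidy chance_curves
#' @export
tidy.chance_curves <- function(x, ...) {
  as_tibble(x)
}

#' Summarize chance curves
#'
#' `glance()` returns the grand means and method metadata; `tidy()` returns
#' the per-position curve as a plain tibble.
#'
#' @param x A `chance_curves` object.
#' @param ... Unused.
#' @return A one-row tibble (`glance`) or the per-position tibble (`tidy`).
#' @method glance chance_curves
#' @export
glance.chance_curves <- function(x, ...) {
  tibble(
    n_positions = attr(x, "n_positions"),
    method = attr(x, "method"),
    n_series = attr(x, "n_series"),
    grand_abs_mean = attr(x, "grand_abs_mean"),
    grand_signed_mean = attr(x, "grand_signed_mean")
  )
}

#' Compare empirical timeline performance to the chance-level null
#'
#' Per subject and condition, averages over retained trials the difference
#' between the chance curve and the empirical error at each probed position
#' (for accuracy: `chance |error| - empirical |error|`, so positive means
#' better than chance; for bias: `empirical bias - chance signed error`, so
#' negative means stronger underestimation than chance), then runs a
#' one-sample t-test of the subject means against zero per condition.
#'
#' @param trials Timeline trials with `subject_id`, `condition`,
#'   `actual_position`, `rated_position` (exclusions should be applied
#'   first).
#' @param curves A `chance_curves` object whose length matches the task.
#' @param alpha Nominal alpha before correction.
#' @param m Number of comparisons Bonferroni-corrected for (default: number
#'   of conditions).
#'
#' @return A tibble with one row per condition and metric (`accuracy`,
#'   `bias`): `n_subjects`, `mean_diff`, `statistic` (t), `df`, `p.value`,
#'   `alpha_corrected`, `degenerate` (`TRUE` when all subject means are zero
#'   and t is reported as 0).
#' @export
compare_to_chance <- function(trials, curves, alpha = 0.05, m = NULL) {
  assert_columns(trials, c("subject_id", "condition", "actual_position",
                           "rated_position"), "`trials`")
  stopifnot(inherits(curves, "chance_curves"))
  n_pos <- attr(curves, "n_positions")
  if (max(trials$actual_position) > n_pos) {
    abort("`curves` cover fewer positions than the trials reference.")
  }
  m <- m %||% length(unique(trials$condition))

  full <- tidyr::expand_grid(subject_id = unique(trials$subject_id),
                             condition = unique(trials$condition))
  per_subject <- trials |>
    mutate(
      chance_abs = curves$abs_error[.data$actual_position],
      chance_signed = curves$signed_error[.data$actual_position],
      emp_abs = abs(.data$rated_position - .data$actual_position),
      emp_signed = .data$rated_position - .data$actual_position
    ) |>
    group_by(.data$subject_id, .data$condition) |>
    summarise(
      accuracy = mean(.data$chance_abs - .data$emp_abs),
      bias = mean(.data$emp_signed - .data$chance_signed),
      n_trials = n(),
      .groups = "drop"
    )
  dropped <- anti_join(full, per_subject, by = c("subject_id", "condition"))
  if (nrow(dropped) > 0L) {
    warn(sprintf("Excluding %d subject-condition cell(s) with zero retained trials: %s.",
                 nrow(dropped),
                 paste(paste(dropped$subject_id, dropped$condition, sep = "/"),
                       collapse = ", ")))
  }

  one_sample <- function(x) {
    n <- length(x)
    if (n < 2L) return(tibble(statistic = NA_real_, df = n - 1, p.value = NA_real_,
                              degenerate = TRUE))
    if (sd(x) == 0) {
      return(tibble(statistic = 0, df = n - 1,
                    p.value = if (mean(x) == 0) 1 else 0,
                    degenerate = TRUE))
    }
    tt <- t.test(x)
    tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
           p.value = tt$p.value, degenerate = FALSE)
  }

  per_subject |>
    tidyr::pivot_longer(c("accuracy", "bias"), names_to = "metric",
                        values_to = "value") |>
    group_by(.data$condition, .data$metric) |>
    summarise(
      n_subjects = n(),
      mean_diff = mean(.data$value),
      one_sample(.data$value),
      .groups = "drop"
    ) |>
    mutate(alpha_corrected = alpha / m)
}
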