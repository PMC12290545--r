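#' Parameters of the generative behavioral model
#'
#' Collects the parameters of the phenomenological generator that stands in
#' for human behavior in the boundary-segmented timeline task. Rated
#' positions follow a linear compression model: per condition, the rated
#' position is the actual position plus a subject random intercept, a
#' condition-specific bias intercept, a condition-specific slope in the
#' within-context distance from the boundary (negative slope = compression
#' growing away from the boundary), and Gaussian noise; the sum is clipped to
#' the scale and rounded to a whole position. Encoding response times carry a
#' boundary slowing effect; timeline response times are lognormal with a
#' small rate of out-of-range outliers; a configurable fraction of subjects
#' are degenerate same-location responders who tend to repeat their previous
#' rating.
#'
#' Per-condition parameters are named numeric vectors keyed by condition
#' label; scalars are recycled to all conditions.
#'
#' The default bias and noise values are calibrated so that default
#' 24-subject cohorts land near the canonical group-level cell means of the
#' task (pooled accuracy about 17 under sham and 15 under slow-theta; pooled
#' bias about -2.9 under sham and -0.7 under fast-theta), after accounting
#' for the attenuation that scale clipping and rounding impose on the raw
#' linear-model parameters. Analyses assert recovery of configured
#' parameters, never these landing points.
#'
#' @param bias_intercept Bias intercept per condition, in positions.
#' @param bias_slope Bias change per unit within-context distance from the
#'   boundary, per condition, in positions.
#' @param noise_sd Trial noise SD per condition, in positions (> 0).
#' @param subject_sd_intercept SD of the subject random intercept, positions.
#' @param rt_base Baseline encoding response time, seconds.
#' @param rt_boundary_effect Added encoding RT at boundary items, seconds.
#' @param rt_sd Encoding RT noise SD, seconds.
#' @param rt_subject_sd SD of the subject random intercept on encoding RT.
#' @param encoding_miss_rate Probability an encoding trial has no response
#'   within the 2.5 s window.
#' @param timeline_rt_meanlog,timeline_rt_sdlog Lognormal parameters of
#'   timeline response times (log-seconds).
#' @param outlier_rt_rate Probability a timeline RT is replaced by an
#'   out-of-range draw (uniform on \[0.1, 0.5) or (15, 30\] s).
#' @param degenerate_rate Expected fraction of subjects that are
#'   same-location responders; `round(rate * n_subjects)` subjects are
#'   flagged.
#' @param degenerate_stick_prob Probability a degenerate subject repeats the
#'   previous rated position.
#' @param sham_identification_rate Probability a simulated subject correctly
#'   identifies the sham session (used for the covariate analyses; default is
#'   the 1/3 chance level).
#' @param conditions Condition labels the per-condition vectors are keyed by.
#'
#' @return A `behavioral_params` object (a validated list).
#' @export
#' @examples
#' behavioral_params()
#' behavioral_params(noise_sd = 5)  # recycled to all conditions
behavioral_params <- function(bias_intercept = c(sham = -2.35, slow_3hz = -1.3, fast_8hz = -1.0),
                              bias_slope = c(sham = -1.3, slow_3hz = -0.9, fast_8hz = -0.25),
                              noise_sd = c(sham = 28, slow_3hz = 23.5, fast_8hz = 27.5),
                              subject_sd_intercept = 2,
                              rt_base = 1.1,
                              rt_boundary_effect = 0.15,
                              rt_sd = 0.2,
                              rt_subject_sd = 0.1,
                              encoding_miss_rate = 0.01,
                              timeline_rt_meanlog = 1.0,
                              timeline_rt_sdlog = 0.5,
                              outlier_rt_rate = 0.02,
                              degenerate_rate = 0,
                              degenerate_stick_prob = 0.53,
                              sham_identification_rate = 1 / 3,
                              conditions = c("sham", "slow_3hz", "fast_8hz")) {
  conditions <- as.character(conditions)
  per_cond <- function(x, name) {
    if (length(x) == 1L && is.null(names(x))) {
      x <- setNames(rep(as.numeric(x), length(conditions)), conditions)
    }
    if (is.null(names(x)) || !setequal(names(x), conditions)) {
      abort(sprintf("`%s` must be named by condition (%s) or a single scalar.",
                    name, paste(conditions, collapse = ", ")))
    }
    x[conditions]
  }
  probs <- c(encoding_miss_rate = encoding_miss_rate,
             outlier_rt_rate = outlier_rt_rate,
             degenerate_rate = degenerate_rate,
             degenerate_stick_prob = degenerate_stick_prob,
             sham_identification_rate = sham_identification_rate)
  if (any(probs < 0 | probs > 1)) {
    abort("All rate/probability parameters must lie in [0, 1].")
  }
  noise_sd <- per_cond(noise_sd, "noise_sd")
  if (any(noise_sd < 0)) abort("`noise_sd` must be non-negative.")
  structure(
    list(
      bias_intercept = per_cond(bias_intercept, "bias_intercept"),
      bias_slope = per_cond(bias_slope, "bias_slope"),
      noise_sd = noise_sd,
      subject_sd_intercept = subject_sd_intercept,
      rt_base = rt_base,
      rt_boundary_effect = rt_boundary_effect,
      rt_sd = rt_sd,
      rt_subject_sd = rt_subject_sd,
      encoding_miss_rate = encoding_miss_rate,
      timeline_rt_meanlog = timeline_rt_meanlog,
      timeline_rt_sdlog = timeline_rt_sdlog,
      outlier_rt_rate = outlier_rt_rate,
      degenerate_rate = degenerate_rate,
      degenerate_stick_prob = degenerate_stick_prob,
      sham_identification_rate = sham_identification_rate,
      conditions = conditions
    ),
    class = "behavioral_params"
  )
}

#' Identity (noise-free) generator parameters
#'
#' Convenience wrapper: all bias, noise, and RT-effect parameters are zero,
#' so rated positions equal actual positions and all encoding RTs are equal.
#' Useful as an end-to-end null.
#'
#' @param ... Overrides passed on to [behavioral_params()].
#' @return A `behavioral_params` object.
#' @export
identity_params <- function(...) {
  defaults <- list(bias_intercept = 0, bias_slope = 0, noise_sd = 0,
                   subject_sd_intercept = 0, rt_boundary_effect = 0,
                   rt_sd = 0, rt_subject_sd = 0, encoding_miss_rate = 0,
                   outlier_rt_rate = 0, degenerate_rate = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(behavioral_params, args)
}

draw_timeline_rt <- function(n, params) {
  rt <- rlnorm(n, params$timeline_rt_meanlog, params$timeline_rt_sdlog)
  is_out <- runif(n) < params$outlier_rt_rate
  n_out <- sum(is_out)
  if (n_out > 0L) {
    # uniform on [0.1, 0.5) U (15, 30], weighted by interval length
    low <- runif(n_out) < 0.4 / (0.4 + 15)
    out <- numeric(n_out)
    out[low] <- runif(sum(low), 0.1, 0.5)
    out[!low] <- runif(sum(!low), 15, 30)
    rt[is_out] <- out
  }
  rt
}

#' Simulate timeline-task responses
#'
#' Draws rated positions and response times for a table of timeline probes
#' under the linear compression model (see [behavioral_params()]):
#' `rated = round(clip(actual + b_subj + intercept[c] + slope[c] * (wcp - 1)
#' + noise, 1, n_positions))`. Degenerate subjects repeat their previous
#' rated position with probability `degenerate_stick_prob`.
#'
#' @param probes Probe table with columns `subject_id`, `condition`,
#'   `actual_position`, `within_context_position`, `is_boundary` (typically
#'   from [select_test_items()]); a `probe_order` column, if present, defines
#'   the trial sequence used for degenerate sticking.
#' @param params A [behavioral_params()] object.
#' @param seed Integer seed.
#' @param n_positions Length of the timeline scale (default 72).
#' @param subject_effects Optional named numeric vector of subject random
#'   intercepts; drawn from `N(0, subject_sd_intercept)` if `NULL`.
#' @param degenerate_subjects Optional character vector naming the
#'   same-location responders; if `NULL`, `round(degenerate_rate * n)`
#'   subjects are sampled.
#'
#' @return The probe tibble plus `rated_position` (integer in
#'   `1..n_positions`) and `response_time` (seconds).
#' @export
simulate_timeline <- function(probes, params = behavioral_params(), seed = NULL,
                              n_positions = 72, subject_effects = NULL,
                              degenerate_subjects = NULL) {
  assert_columns(probes, c("subject_id", "condition", "actual_position",
                           "within_context_position"), "`probes`")
  if (any(probes$actual_position < 1L | probes$actual_position > n_positions)) {
    abort(sprintf("`actual_position` must lie in 1..%d.", n_positions))
  }
  if (!all(probes$condition %in% params$conditions)) {
    abort("`probes$condition` contains labels absent from `params$conditions`.")
  }
  maybe_set_seed(seed)
  subjects <- unique(probes$subject_id)
  if (is.null(subject_effects)) {
    subject_effects <- setNames(
      rnorm(length(subjects), 0, params$subject_sd_intercept), subjects)
  }
  if (is.null(degenerate_subjects)) {
    n_deg <- round(params$degenerate_rate * length(subjects))
    degenerate_subjects <- if (n_deg > 0L) sample(subjects, n_deg) else character(0)
  }

  sort_cols <- intersect(c("subject_id", "session_order", "condition", "probe_order"),
                         names(probes))
  out <- probes |> arrange(across(all_of(sort_cols)))

  cond <- out$condition
  mu <- out$actual_position +
    unname(subject_effects[out$subject_id]) +
    unname(params$bias_intercept[cond]) +
    unname(params$bias_slope[cond]) * (out$within_context_position - 1)
  eps <- rnorm(nrow(out), 0, unname(params$noise_sd[cond]))
  rated <- as.integer(round(pmin(pmax(mu + eps, 1), n_positions)))

  if (length(degenerate_subjects) > 0L && params$degenerate_stick_prob > 0) {
    stick <- runif(nrow(out)) < params$degenerate_stick_prob
    grp <- interaction(out$subject_id, out$condition, drop = TRUE)
    for (g in levels(grp)) {
      idx <- which(grp == g)
      if (!(out$subject_id[idx[1]] %in% degenerate_subjects)) next
      for (j in seq_along(idx)[-1]) {
        if (stick[idx[j]]) rated[idx[j]] <- rated[idx[j - 1]]
      }
    }
  }

  out$rated_position <- rated
  out$response_time <- draw_timeline_rt(nrow(out), params)
  as_tibble(out)
}

#' Simulate encoding-task responses
#'
#' Adds pleasantness ratings and response times to an encoding design.
#' Response time is `rt_base + rt_boundary_effect * is_boundary + subject
#' effect + N(0, rt_sd)`, truncated to the (0, 2.5] response window; with
#' probability `encoding_miss_rate` no response is given within the window
#' and both rating and RT are `NA`. Ratings are uniform on 1..4.
#'
#' @param design Encoding trials from [generate_design()].
#' @param params A [behavioral_params()] object.
#' @param seed Integer seed.
#' @param subject_effects Optional named vector of subject RT intercepts.
#'
#' @return The design tibble plus `rating` and `response_time`.
#' @export
simulate_encoding <- function(design, params = behavioral_params(), seed = NULL,
                              subject_effects = NULL) {
  assert_columns(design, c("subject_id", "is_boundary"), "`design`")
  maybe_set_seed(seed)
  subjects <- unique(design$subject_id)
  if (is.null(subject_effects)) {
    subject_effects <- setNames(
      rnorm(length(subjects), 0, params$rt_subject_sd), subjects)
  }
  n <- nrow(design)
  rt <- params$rt_base + params$rt_boundary_effect * design$is_boundary +
    unname(subject_effects[design$subject_id]) + rnorm(n, 0, params$rt_sd)
  rt <- pmin(pmax(rt, 1e-3), 2.5)
  rating <- sample.int(4L, n, replace = TRUE)
  missing <- runif(n) < params$encoding_miss_rate
  rt[missing] <- NA_real_
  rating[missing] <- NA_integer_
  design |>
    mutate(rating = rating, response_time = rt) |>
    as_tibble()
}

#' Simulate a full synthetic cohort
#'
#' Runs the whole generative pipeline: counterbalanced encoding designs for
#' every participant, encoding responses, timeline probes for every session,
#' and timeline responses, all reproducible from one seed (child seeds are
#' derived deterministically per stage).
#'
#' @param spec A [design_spec()].
#' @param params A [behavioral_params()].
#' @param seed Integer master seed.
#'
#' @return A `tl_cohort`: a list with tibbles `encoding`, `timeline`, and
#'   `subjects` (per-subject order id, order, degenerate flag, simulated
#'   sham-identification outcome, and the latent subject bias intercept).
#' @export
#' @examples
#' cohort <- simulate_cohort(design_spec(n_participants = 6), seed = 1)
#' nrow(cohort$timeline)  # 6 x 3 x 36
simulate_cohort <- function(spec = design_spec(), params = behavioral_params(),
                            seed = NULL) {
  stopifnot(inherits(spec, "design_spec"), inherits(params, "behavioral_params"))
  if (!setequal(spec$conditions, params$conditions)) {
    abort("`spec$conditions` and `params$conditions` must agree.")
  }
  seeds <- derive_seeds(seed, 5L)
  design <- generate_design(spec, seed = seeds[[1]])
  encoding <- simulate_encoding(design, params, seed = seeds[[2]])

  maybe_set_seed(seeds[[3]])
  probes <- design |>
    filter(.data$within_context_position %in% spec$tested_within_positions) |>
    transmute(.data$subject_id, .data$condition, .data$session_order,
              actual_position = .data$serial_position,
              context_index = .data$context_index,
              within_context_position = .data$within_context_position,
              is_boundary = .data$is_boundary) |>
    group_by(.data$subject_id, .data$session_order) |>
    slice_sample(prop = 1) |>
    mutate(probe_order = row_number()) |>
    ungroup()

  subjects <- unique(design$subject_id)
  maybe_set_seed(seeds[[4]])
  b_subj <- setNames(rnorm(length(subjects), 0, params$subject_sd_intercept),
                     subjects)
  n_deg <- round(params$degenerate_rate * length(subjects))
  deg <- if (n_deg > 0L) sample(subjects, n_deg) else character(0)
  sham_id <- setNames(runif(length(subjects)) < params$sham_identification_rate,
                      subjects)

  timeline <- simulate_timeline(probes, params, seed = seeds[[5]],
                                subject_effects = b_subj,
                                degenerate_subjects = deg)

  orders <- design |>
    distinct(.data$subject_id, .data$session_order, .data$condition) |>
    arrange(.data$subject_id, .data$session_order) |>
    group_by(.data$subject_id) |>
    summarise(order = paste(.data$condition, collapse = ">"), .groups = "drop")

  subject_tbl <- orders |>
    mutate(
      tacs_order_id = match(.data$order, sort(unique(.data$order))),
      degenerate = .data$subject_id %in% deg,
      sham_identified = unname(sham_id[.data$subject_id]),
      subject_effect = unname(b_subj[.data$subject_id])
    )

  structure(
    list(encoding = encoding, timeline = timeline, subjects = subject_tbl,
         spec = spec, params = params, seed = seed),
    class = "tl_cohort"
  )
}

#' @export
print.tl_cohort <- function(x, ...) {
  cat("<tl_cohort>\n")
  cat(sprintf("  %d subjects x %d conditions; %d encoding trials, %d timeline trials\n",
              nrow(x$subjects), length(x$spec$conditions),
              nrow(x$encoding), nrow(x$timeline)))
  if (any(x$subjects$degenerate)) {
    cat(sprintf("  degenerate responders: %s\n",
                paste(x$subjects$subject_id[x$subjects$degenerate], collapse = ", ")))
  }
  invisible(x)
}

#' Recover generative bias parameters by per-subject least squares
#'
#' Fits, per subject and condition, an ordinary least-squares regression of
#' trial bias (`rated - actual`) on within-context distance from the boundary
#' (`within_context_position - 1`), then averages intercepts and slopes
#' across subjects per condition. Restricting to interior serial positions
#' (the default keeps 17..56) avoids the scale-edge clipping region where the
#' linear generative model is censored.
#'
#' @param timeline Timeline trials with `subject_id`, `condition`,
#'   `actual_position`, `within_context_position`, `rated_position`.
#' @param positions Serial positions retained for the fit.
#'
#' @return A tibble per condition: `n_subjects`, `intercept`, `intercept_se`,
#'   `slope`, `slope_se` (standard errors of the across-subject means).
#' @export
recover_bias_params <- function(timeline, positions = 17:56) {
  assert_columns(timeline, c("subject_id", "condition", "actual_position",
                             "within_context_position", "rated_position"),
                 "`timeline`")
  fits <- timeline |>
    filter(.data$actual_position %in% positions) |>
    mutate(bias = .data$rated_position - .data$actual_position,
           dist = .data$within_context_position - 1) |>
    group_by(.data$subject_id, .data$condition) |>
    group_modify(function(d, key) {
      co <- coef(lm(bias ~ dist, data = d))
      tibble(intercept = co[[1]], slope = co[[2]])
    }) |>
    ungroup()
  fits |>
    group_by(.data$condition) |>
    summarise(
      n_subjects = n(),
      intercept_se = sd(.data$intercept) / sqrt(n()),
      intercept = mean(.data$intercept),
      slope_se = sd(.data$slope) / sqrt(n()),
      slope = mean(.data$slope),
      .groups = "drop"
    ) |>
    select("condition", "n_subjects", "intercept", "intercept_se",
           "slope", "slope_se")
}
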