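orthonormal_contrasts <- function(k) {
  H <- stats::contr.helmert(k)
  t(H) / sqrt(colSums(H^2))
}

gg_epsilon <- function(M, C) {
  A <- C %*% cov(M) %*% t(C)
  d <- nrow(C)
  sum(diag(A))^2 / (d * sum(A^2))
}

extract_aov_table <- function(fit, n_subjects) {
  sm <- summary(fit)
  rows <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    resid <- which(terms == "Residuals")
    if (length(resid) == 0L) next
    df_den <- tab$Df[resid]
    ss_den <- tab$`Sum Sq`[resid]
    for (i in setdiff(seq_along(terms), resid)) {
      rows[[length(rows) + 1L]] <- tibble(
        term = terms[i],
        df_num = tab$Df[i],
        df_den = df_den,
        ss_num = tab$`Sum Sq`[i],
        ss_den = ss_den
      )
    }
  }
  bind_rows(rows)
}

finalize_anova_table <- function(tab) {
  tol <- 1e-10 * max(c(tab$ss_num, tab$ss_den, 1))
  tab |>
    mutate(
      statistic = case_when(
        .data$ss_num <= tol ~ 0,
        .data$ss_den <= tol ~ Inf,
        TRUE ~ (.data$ss_num / .data$df_num) / (.data$ss_den / .data$df_den)
      ),
      p.value = case_when(
        .data$ss_num <= tol ~ 1,
        .data$ss_den <= tol ~ 0,
        TRUE ~ pf((.data$ss_num / .data$df_num) / (.data$ss_den / .data$df_den),
                  .data$df_num * .data$epsilon, .data$df_den * .data$epsilon,
                  lower.tail = FALSE)
      ),
      partial_eta_sq = if_else(.data$ss_num + .data$ss_den <= tol, 0,
                               .data$ss_num / (.data$ss_num + .data$ss_den))
    )
}

check_rm_layout <- function(data, dv, within, subject) {
  assert_columns(data, c(dv, within, subject), "`data`")
  if (any(is.na(data[[dv]]))) {
    abort(sprintf("`%s` contains missing values; resolve empty cells first.", dv))
  }
  counts <- data |>
    count(across(all_of(c(subject, within))))
  if (any(counts$n != 1L)) {
    abort("Each subject x cell combination must appear exactly once; aggregate trials to cells first.")
  }
  cells <- data |>
    distinct(across(all_of(within)))
  per_subject <- data |>
    count(across(all_of(subject)))
  bad <- per_subject[[subject]][per_subject$n != nrow(cells)]
  if (length(bad) > 0L) {
    abort(sprintf("Incomplete crossed design for subject(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  n_subjects <- nrow(per_subject)
  if (n_subjects < 2L) abort("At least 2 subjects are required.")
  n_subjects
}

#' Univariate repeated-measures ANOVA
#'
#' Fits the univariate (subject-stratified) within-subject ANOVA on a
#' subject-cell table: sums of squares are partitioned per subject x factor
#' stratum, so each within effect is tested against its own subject-by-effect
#' interaction. For `n` subjects and a factor with `k` levels the main-effect
#' denominator df is `(n-1)(k-1)`; a 3x2 design with 24 subjects reports
#' df (2, 46) for the 3-level factor and (1, 23) for the 2-level factor.
#' Partial eta squared is `SS_effect / (SS_effect + SS_error)`. Effects with
#' zero effect variance are reported as F = 0, p = 1.
#'
#' Sphericity is assumed by default (matching the conventional reporting for
#' these designs); `sphericity_correction = "greenhouse_geisser"` rescales
#' the dfs of each within effect by the Box/Greenhouse-Geisser epsilon
#' estimated from the subject-cell covariance.
#'
#' @param data Subject-cell table (one row per subject x cell), e.g. from
#'   [aggregate_cells()].
#' @param dv Name of the dependent-variable column.
#' @param within Character vector of one or two within-subject factor
#'   columns.
#' @param subject Name of the subject identifier column.
#' @param sphericity_correction `"none"` or `"greenhouse_geisser"`.
#'
#' @return A `tl_anova` object; [tidy()] returns the effect table (`term`,
#'   `df_num`, `df_den`, `statistic`, `p.value`, `partial_eta_sq`,
#'   `epsilon`), [glance()] the fit metadata.
#' @export
#' @examples
#' cells <- simulate_cohort(design_spec(n_participants = 6), seed = 1)$timeline |>
#'   apply_exclusions() |>
#'   compute_metrics() |>
#'   aggregate_cells()
#' rm_anova(cells, dv = "mean_accuracy")
rm_anova <- function(data, dv = "mean_accuracy",
                     within = c("condition", "position_class"),
                     subject = "subject_id",
                     sphericity_correction = c("none", "greenhouse_geisser")) {
  sphericity_correction <- match.arg(sphericity_correction)
  if (!length(within) %in% 1:2) abort("`within` must name one or two factors.")
  n_subjects <- check_rm_layout(data, dv, within, subject)

  d <- data.frame(
    y = data[[dv]],
    S = factor(data[[subject]])
  )
  for (i in seq_along(within)) d[[paste0("W", i)]] <- factor(data[[within[i]]])

  form <- if (length(within) == 2L) {
    y ~ W1 * W2 + Error(S / (W1 * W2))
  } else {
    y ~ W1 + Error(S / W1)
  }
  fit <- aov(form, data = d)
  tab <- extract_aov_table(fit, n_subjects)

  # map internal names back to user-facing factor names
  rename_term <- function(term) {
    for (i in seq_along(within)) {
      term <- gsub(paste0("\\bW", i, "\\b"), within[i], term)
    }
    term
  }
  tab$term <- vapply(tab$term, rename_term, character(1))

  tab$epsilon <- 1
  if (sphericity_correction == "greenhouse_geisser") {
    wide_means <- function(cols) {
      data |>
        group_by(across(all_of(c(subject, cols)))) |>
        summarise(y = mean(.data[[dv]]), .groups = "drop") |>
        tidyr::pivot_wider(names_from = all_of(cols), values_from = "y") |>
        select(-all_of(subject)) |>
        as.matrix()
    }
    eff_cols <- list()
    for (i in seq_along(within)) eff_cols[[within[i]]] <- within[i]
    if (length(within) == 2L) {
      eff_cols[[paste(within, collapse = ":")]] <- within
    }
    for (term in names(eff_cols)) {
      cols <- eff_cols[[term]]
      M <- wide_means(cols)
      if (ncol(M) < 2L) next
      C <- if (length(cols) == 1L) {
        orthonormal_contrasts(ncol(M))
      } else {
        k1 <- length(unique(data[[cols[1]]]))
        k2 <- length(unique(data[[cols[2]]]))
        kronecker(orthonormal_contrasts(k1), orthonormal_contrasts(k2))
      }
      eps <- gg_epsilon(M, C)
      tab$epsilon[tab$term == term] <- max(eps, 1 / nrow(C))
    }
  }

  tab <- finalize_anova_table(tab) |>
    select("term", "df_num", "df_den", "statistic", "p.value",
           "partial_eta_sq", "epsilon")

  structure(
    list(table = tab, n_subjects = n_subjects, dv = dv, within = within,
         correction = sphericity_correction, covariate = NULL),
    class = "tl_anova"
  )
}

#' Repeated-measures ANOVA with a between-subject covariate
#'
#' Expands [rm_anova()] with one mean-centered between-subject covariate
#' (e.g. whether a subject identified the sham session, or the stimulation
#' order coded 1..6 as a linear term). The covariate main effect is tested in
#' the between-subject stratum; its interactions with the within factors are
#' tested in the corresponding within strata.
#'
#' @inheritParams rm_anova
#' @param covariate Name of the covariate column (one value per subject;
#'   logical covariates are coded 0/1).
#' @param center Mean-center the covariate (default `TRUE`).
#' @return A `tl_anova` object including covariate terms.
#' @export
covariate_anova <- function(data, dv = "mean_accuracy", covariate,
                            within = c("condition", "position_class"),
                            subject = "subject_id", center = TRUE) {
  if (!length(within) %in% 1:2) abort("`within` must name one or two factors.")
  assert_columns(data, covariate, "`data`")
  n_subjects <- check_rm_layout(data, dv, within, subject)

  per_subj <- data |>
    distinct(across(all_of(c(subject, covariate))))
  if (nrow(per_subj) != n_subjects) {
    abort(sprintf("`%s` must be constant within subject.", covariate))
  }
  cov_vals <- as.numeric(per_subj[[covariate]])
  if (sd(cov_vals) == 0) {
    abort(sprintf("Covariate `%s` is constant across subjects.", covariate))
  }

  d <- data.frame(
    y = data[[dv]],
    S = factor(data[[subject]]),
    X = as.numeric(data[[covariate]])
  )
  if (center) d$X <- d$X - mean(cov_vals)
  for (i in seq_along(within)) d[[paste0("W", i)]] <- factor(data[[within[i]]])

  form <- if (length(within) == 2L) {
    y ~ (W1 * W2) * X + Error(S / (W1 * W2))
  } else {
    y ~ W1 * X + Error(S / W1)
  }
  fit <- aov(form, data = d)
  tab <- extract_aov_table(fit, n_subjects)
  rename_term <- function(term) {
    for (i in seq_along(within)) {
      term <- gsub(paste0("\\bW", i, "\\b"), within[i], term)
    }
    gsub("\\bX\\b", covariate, term)
  }
  tab$term <- vapply(tab$term, rename_term, character(1))
  tab$epsilon <- 1
  tab <- finalize_anova_table(tab) |>
    select("term", "df_num", "df_den", "statistic", "p.value",
           "partial_eta_sq", "epsilon")

  structure(
    list(table = tab, n_subjects = n_subjects, dv = dv, within = within,
         correction = "none", covariate = covariate),
    class = "tl_anova"
  )
}

#' @export
print.tl_anova <- function(x, ...) {
  cat(sprintf("<tl_anova: %s on %d subjects%s>\n", x$dv, x$n_subjects,
              if (!is.null(x$covariate))
                sprintf(", covariate %s", x$covariate) else ""))
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Tidy a repeated-measures ANOVA
#'
#' @param x A `tl_anova` object.
#' @param ... Unused.
#' @return `tidy()` gives the effect table; `glance()` one row of metadata.
#' @method tidy tl_anova
#' @export
tidy.tl_anova <- function(x, ...) x$table

#' @rdname tidy.tl_anova
#' @method glance tl_anova
#' @export
glance.tl_anova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects, dv = x$dv,
         within = paste(x$within, collapse = " x "),
         covariate = x$covariate %||% NA_character_,
         sphericity_correction = x$correction)
}

# Unweighted pooling of cells to one value per subject x factor level.
pool_subject_values <- function(data, dv, factor, subject, pool_over) {
  data |>
    group_by(across(all_of(c(subject, factor)))) |>
    summarise(..value = mean(.data[[dv]]), .groups = "drop")
}

#' Bonferroni-corrected paired posthoc tests
#'
#' Paired t-tests for every pair of factor levels on subject-level values
#' (cells are pooled over `pool_over` by unweighted averaging first), with
#' Cohen's d for paired differences (`mean(diff) / sd(diff)`, sample sd) and
#' the Bonferroni-corrected alpha `alpha / m`. Zero-variance difference
#' vectors are reported as degenerate (t = 0, d = 0 when all differences are
#' zero).
#'
#' @param data Subject-cell table.
#' @param dv Dependent-variable column.
#' @param factor Column whose levels are compared (default `"condition"`).
#' @param subject Subject identifier column.
#' @param alpha Nominal alpha (default 0.05).
#' @param m Number of comparisons corrected for; defaults to the number of
#'   level pairs.
#' @param pool_over Column averaged over before pairing (default
#'   `"position_class"`).
#'
#' @return A tibble per contrast: `contrast`, `estimate` (mean difference),
#'   `statistic` (t), `df`, `p.value`, `cohens_d`, `alpha_corrected`,
#'   `significant`, `degenerate`.
#' @export
pairwise_posthoc <- function(data, dv = "mean_accuracy", factor = "condition",
                             subject = "subject_id", alpha = 0.05, m = NULL,
                             pool_over = "position_class") {
  assert_columns(data, c(dv, factor, subject), "`data`")
  pooled <- pool_subject_values(data, dv, factor, subject, pool_over)
  levels <- unique(pooled[[factor]])
  pairs <- combn(as.character(levels), 2, simplify = FALSE)
  m <- m %||% length(pairs)
  alpha_corr <- alpha / m

  wide <- pooled |>
    tidyr::pivot_wider(names_from = all_of(factor), values_from = "..value")

  res <- purrr::map_dfr(pairs, function(pr) {
    diffs <- wide[[pr[1]]] - wide[[pr[2]]]
    diffs <- diffs[!is.na(diffs)]
    n <- length(diffs)
    if (n < 2L) abort(sprintf("Fewer than 2 paired observations for %s vs %s.",
                              pr[1], pr[2]))
    s <- sd(diffs)
    if (s == 0) {
      est <- mean(diffs)
      tibble(contrast = paste(pr, collapse = " - "), estimate = est,
             statistic = if (est == 0) 0 else sign(est) * Inf,
             df = n - 1,
             p.value = if (est == 0) 1 else 0,
             cohens_d = if (est == 0) 0 else sign(est) * Inf,
             degenerate = TRUE)
    } else {
      tt <- t.test(diffs)
      tibble(contrast = paste(pr, collapse = " - "),
             estimate = mean(diffs),
             statistic = unname(tt$statistic),
             df = n - 1,
             p.value = tt$p.value,
             cohens_d = mean(diffs) / s,
             degenerate = FALSE)
    }
  })
  res |>
    mutate(alpha_corrected = alpha_corr,
           significant = .data$p.value < alpha_corr)
}

#' Correlate stimulation-induced changes in accuracy and bias
#'
#' For one active condition, computes per subject the change relative to
#' sham in pooled temporal accuracy and in pooled temporal bias, then the
#' Pearson correlation between the two difference scores (t-based p, df
#' `n - 2`).
#'
#' @param data Subject-cell table with accuracy and bias columns.
#' @param condition Active condition label (e.g. `"slow_3hz"`).
#' @param reference Reference condition label (default `"sham"`).
#' @param accuracy_col,bias_col Cell columns holding the two metrics.
#' @param subject Subject identifier column.
#' @param pool_over Column averaged over before differencing.
#'
#' @return A one-row tibble: `condition`, `n`, `r`, `statistic`, `df`,
#'   `p.value`, `degenerate`.
#' @export
diff_correlation <- function(data, condition, reference = "sham",
                             accuracy_col = "mean_accuracy",
                             bias_col = "mean_bias",
                             subject = "subject_id",
                             pool_over = "position_class") {
  deltas <- condition_deltas(data, condition, reference, accuracy_col,
                             bias_col, subject, pool_over)
  n <- nrow(deltas)
  if (sd(deltas$d_accuracy) == 0 || sd(deltas$d_bias) == 0) {
    warn("Constant difference vector; correlation undefined.")
    return(tibble(condition = condition, n = n, r = NA_real_,
                  statistic = NA_real_, df = n - 2, p.value = NA_real_,
                  degenerate = TRUE))
  }
  ct <- cor.test(deltas$d_accuracy, deltas$d_bias)
  tibble(condition = condition, n = n, r = unname(ct$estimate),
         statistic = unname(ct$statistic), df = unname(ct$parameter),
         p.value = ct$p.value, degenerate = FALSE)
}

condition_deltas <- function(data, condition, reference = "sham",
                             accuracy_col = "mean_accuracy",
                             bias_col = "mean_bias",
                             subject = "subject_id",
                             pool_over = "position_class") {
  assert_columns(data, c("condition", accuracy_col, bias_col, subject),
                 "`data`")
  if (!all(c(condition, reference) %in% data$condition)) {
    abort("Both `condition` and `reference` must be present in the data.")
  }
  pooled <- data |>
    filter(.data$condition %in% c(!!condition, !!reference)) |>
    group_by(across(all_of(c(subject, "condition")))) |>
    summarise(acc = mean(.data[[accuracy_col]]),
              bias = mean(.data[[bias_col]]), .groups = "drop")
  wide <- pooled |>
    tidyr::pivot_wider(names_from = "condition", values_from = c("acc", "bias"))
  missing <- !stats::complete.cases(wide)
  if (any(missing)) {
    abort(sprintf("Subject(s) missing in one condition: %s.",
                  paste(wide[[subject]][missing], collapse = ", ")))
  }
  tibble(
    subject_id = wide[[subject]],
    d_accuracy = wide[[paste0("acc_", condition)]] - wide[[paste0("acc_", reference)]],
    d_bias = wide[[paste0("bias_", condition)]] - wide[[paste0("bias_", reference)]]
  )
}

#' z-test comparing two dependent, non-overlapping correlations
#'
#' Compares two correlations measured on the same subjects but between
#' different variable pairs (variables 1,2 for `r12`; variables 3,4 for
#' `r34`), using the Fisher-transformed difference scaled by the
#' Pearson-Filon covariance term estimated from the six pairwise
#' correlations. When the four cross-correlations (`r13`, `r14`, `r23`,
#' `r24`) are not supplied, the statistic falls back to the
#' independent-samples Fisher z with a warning.
#'
#' @param r12,r34 The two correlations being compared (|r| < 1).
#' @param n Sample size (>= 4).
#' @param r13,r14,r23,r24 Cross-correlations among the four variables.
#'
#' @return A one-row tibble: `r1`, `r2`, `n`, `z`, `p.value`, `method`.
#' @export
#' @examples
#' compare_dependent_correlations(0.5, 0, n = 24,
#'                                r13 = 0, r14 = 0, r23 = 0, r24 = 0)
compare_dependent_correlations <- function(r12, r34, n,
                                           r13 = NULL, r14 = NULL,
                                           r23 = NULL, r24 = NULL) {
  if (!is.finite(r12) || !is.finite(r34)) {
    warn("Non-finite correlation input; comparison reported as degenerate.")
    return(tibble(r1 = r12, r2 = r34, n = n, z = NA_real_,
                  p.value = NA_real_, method = "degenerate"))
  }
  if (abs(r12) >= 1 || abs(r34) >= 1) abort("|r| must be < 1.")
  if (n < 4) abort("`n` must be at least 4.")
  z1 <- atanh(r12)
  z2 <- atanh(r34)
  cross <- list(r13 = r13, r14 = r14, r23 = r23, r24 = r24)
  if (any(vapply(cross, is.null, logical(1)))) {
    warn("Cross-correlations not supplied; using the independent-samples Fisher z.")
    z <- (z1 - z2) / sqrt(2 / (n - 3))
    method <- "independent_fisher_z"
  } else {
    psi <- 0.5 * r12 * r34 * (r13^2 + r14^2 + r23^2 + r24^2) +
      r13 * r24 + r14 * r23 -
      (r12 * r13 * r14 + r12 * r23 * r24 + r34 * r13 * r23 + r34 * r14 * r24)
    k <- psi / ((1 - r12^2) * (1 - r34^2))
    z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * k))
    method <- "pearson_filon_fisher_z"
  }
  tibble(r1 = r12, r2 = r34, n = n, z = z,
         p.value = 2 * pnorm(-abs(z)), method = method)
}

#' Compare accuracy-bias coupling between two active conditions
#'
#' High-level wrapper around [compare_dependent_correlations()]: builds the
#' four per-subject difference scores (accuracy and bias changes of each
#' active condition relative to the reference), computes the two
#' within-condition correlations and the four cross-correlations, and runs
#' the dependent-correlation z-test.
#'
#' @param data Subject-cell table.
#' @param conditions Two active condition labels.
#' @param reference Reference condition (default `"sham"`).
#' @inheritParams diff_correlation
#' @return A one-row tibble as in [compare_dependent_correlations()].
#' @export
compare_condition_correlations <- function(data,
                                           conditions = c("slow_3hz", "fast_8hz"),
                                           reference = "sham",
                                           accuracy_col = "mean_accuracy",
                                           bias_col = "mean_bias",
                                           subject = "subject_id",
                                           pool_over = "position_class") {
  stopifnot(length(conditions) == 2L)
  d1 <- condition_deltas(data, conditions[1], reference, accuracy_col,
                         bias_col, subject, pool_over)
  d2 <- condition_deltas(data, conditions[2], reference, accuracy_col,
                         bias_col, subject, pool_over)
  merged <- inner_join(d1, d2, by = "subject_id", suffix = c("_1", "_2"))
  X <- cbind(a1 = merged$d_accuracy_1, b1 = merged$d_bias_1,
             a2 = merged$d_accuracy_2, b2 = merged$d_bias_2)
  R <- stats::cor(X)
  compare_dependent_correlations(
    r12 = R["a1", "b1"], r34 = R["a2", "b2"], n = nrow(merged),
    r13 = R["a1", "a2"], r14 = R["a1", "b2"],
    r23 = R["b1", "a2"], r24 = R["b1", "b2"]
  )
}

#' Exact binomial test for sham identification
#'
#' Tests whether the number of participants correctly identifying the sham
#' session exceeds a chance level `p0` (default 1/3 for three sessions),
#' using the exact binomial tail `P(X >= k)` and the two-sided exact test.
#'
#' @param k_correct Number of correct identifications.
#' @param n Number of participants.
#' @param p0 Chance probability (default 1/3).
#' @return A one-row tibble: `k_correct`, `n`, `p0`, `proportion`,
#'   `p_one_sided`, `p_two_sided`, `method`.
#' @export
#' @examples
#' sham_identification_test(12, 24)
sham_identification_test <- function(k_correct, n, p0 = 1 / 3) {
  k_correct <- assert_count(k_correct, "k_correct", min = 0L)
  n <- assert_count(n, "n")
  if (k_correct > n) abort("`k_correct` cannot exceed `n`.")
  tibble(
    k_correct = k_correct,
    n = n,
    p0 = p0,
    proportion = k_correct / n,
    p_one_sided = pbinom(k_correct - 1L, n, p0, lower.tail = FALSE),
    p_two_sided = binom.test(k_correct, n, p0)$p.value,
    method = "exact_binomial"
  )
}

#' A priori power for a one-factor within-subject ANOVA
#'
#' Returns the smallest number of subjects at which the noncentral-F tail
#' beyond the central-F critical value reaches the target power, for a
#' one-way repeated-measures design with `m` levels. Follows the G*Power
#' convention for within designs: numerator df `(m-1) * epsilon`,
#' denominator df `(n-1)(m-1) * epsilon`, noncentrality
#' `f^2 * n * m * epsilon / (1 - rho)` where `rho` is the assumed
#' correlation among repeated measures and `epsilon` the nonsphericity
#' correction.
#'
#' @param f Cohen's f effect size (> 0).
#' @param alpha Type-I error rate.
#' @param target_power Desired power.
#' @param m Number of repeated measurements (factor levels, >= 2).
#' @param rho Assumed correlation among repeated measures (default 0.5).
#' @param epsilon Nonsphericity correction in (0, 1] (default 1).
#' @param n_max Search bound (error if power is unattainable below it).
#'
#' @return A one-row tibble: `n`, `power` (achieved), and the inputs.
#' @export
#' @examples
#' power_rm_anova(f = 0.30, m = 3)
power_rm_anova <- function(f, alpha = 0.05, target_power = 0.80, m,
                           rho = 0.5, epsilon = 1, n_max = 1e6) {
  if (!is.numeric(f) || f <= 0) abort("`f` must be positive.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  if (target_power <= 0 || target_power >= 1) abort("`target_power` must lie in (0, 1).")
  m <- assert_count(m, "m", min = 2L)
  if (epsilon <= 0 || epsilon > 1) abort("`epsilon` must lie in (0, 1].")
  if (rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1).")

  power_at <- function(n) {
    df1 <- (m - 1) * epsilon
    df2 <- (n - 1) * (m - 1) * epsilon
    lambda <- f^2 * n * m * epsilon / (1 - rho)
    crit <- qf(1 - alpha, df1, df2)
    pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
  }
  n <- 2L
  while (n <= n_max) {
    pw <- power_at(n)
    if (pw >= target_power) {
      return(tibble(n = n, power = pw, f = f, alpha = alpha,
                    target_power = target_power, m = m, rho = rho,
                    epsilon = epsilon))
    }
    n <- n + 1L
  }
  abort(sprintf("Target power %.2f unattainable with n <= %g.", target_power, n_max))
}

#' Subject-cell table for the encoding response-time analysis
#'
#' Averages encoding response times (missing responses dropped) into one
#' cell per subject, condition, and within-context encoding position,
#' ready for a 3 x 8 [rm_anova()] with `dv = "mean_rt"`.
#'
#' @param encoding Encoding trials with responses (see
#'   [simulate_encoding()]).
#' @return A tibble: `subject_id`, `condition`, `within_context_position`,
#'   `mean_rt`, `n_trials`.
#' @export
encoding_rt_cells <- function(encoding) {
  assert_columns(encoding, c("subject_id", "condition",
                             "within_context_position", "response_time"),
                 "`encoding`")
  encoding |>
    filter(!is.na(.data$response_time)) |>
    group_by(.data$subject_id, .data$condition, .data$within_context_position) |>
    summarise(mean_rt = mean(.data$response_time), n_trials = n(),
              .groups = "drop")
}
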