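# Shared fixtures, built in code.

# Probe table for direct timeline simulation (skips full design generation).
probe_grid <- function(n_subjects = 24,
                       conditions = c("sham", "slow_3hz", "fast_8hz"),
                       n_contexts = 9, context_length = 8,
                       tested = c(1L, 3L, 5L, 7L)) {
  tidyr::expand_grid(
    subject_id = sprintf("S%03d", seq_len(n_subjects)),
    condition = conditions,
    context_index = seq_len(n_contexts),
    within_context_position = tested
  ) |>
    dplyr::mutate(
      actual_position = (context_index - 1L) * context_length +
        within_context_position,
      is_boundary = within_context_position == 1L,
      probe_order = dplyr::row_number(),
      .by = c(subject_id, condition)
    )
}

# All condition parameters equal: a null generator for calibration checks.
null_params <- function(noise = 20, ...) {
  behavioral_params(bias_intercept = -1, bias_slope = -0.7, noise_sd = noise,
                    ...)
}

# Independent hand-computed sums-of-squares decomposition for a balanced
# two-factor within-subject design; returns F per effect from explicit
# marginal means, with no shared code with rm_anova().
manual_rm_ss <- function(cells, dv = "mean_accuracy") {
  y <- cells[[dv]]
  S <- factor(cells$subject_id)
  A <- factor(cells$condition)
  B <- factor(cells$position_class)
  g <- mean(y)
  a <- nlevels(A); b <- nlevels(B); n <- nlevels(S)
  m_s <- tapply(y, S, mean); m_a <- tapply(y, A, mean); m_b <- tapply(y, B, mean)
  m_sa <- tapply(y, list(S, A), mean); m_sb <- tapply(y, list(S, B), mean)
  m_ab <- tapply(y, list(A, B), mean)
  ss_a <- n * b * sum((m_a - g)^2)
  ss_b <- n * a * sum((m_b - g)^2)
  ss_s <- a * b * sum((m_s - g)^2)
  ss_sa <- b * sum((m_sa - outer(m_s, m_a, "+") + g)^2)
  ss_sb <- a * sum((m_sb - outer(m_s, m_b, "+") + g)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, m_b, "+") + g)^2)
  ss_tot <- sum((y - g)^2)
  ss_res <- ss_tot - ss_a - ss_b - ss_s - ss_sa - ss_sb - ss_ab
  list(
    condition = (ss_a / (a - 1)) / (ss_sa / ((n - 1) * (a - 1))),
    position_class = (ss_b / (b - 1)) / (ss_sb / ((n - 1) * (b - 1))),
    interaction = (ss_ab / ((a - 1) * (b - 1))) /
      (ss_res / ((n - 1) * (a - 1) * (b - 1))),
    df = list(condition = c(a - 1, (n - 1) * (a - 1)),
              position_class = c(b - 1, (n - 1) * (b - 1)),
              interaction = c((a - 1) * (b - 1), (n - 1) * (a - 1) * (b - 1)))
  )
}
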