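make_cells <- function(n_subjects = 24, seed = 1,
                       params = behavioral_params()) {
  tl <- simulate_timeline(probe_grid(n_subjects), params, seed = seed)
  aggregate_cells(compute_metrics(tl))
}

test_that("rm_anova matches the hand-computed SS decomposition on the toy table", {
  toy <- toy_cell_table()
  fit <- rm_anova(toy, dv = "mean_accuracy")
  oracle <- manual_rm_ss(toy, dv = "mean_accuracy")
  tab <- tidy(fit)

  expect_equal(tab$statistic[tab$term == "condition"], oracle$condition)
  expect_equal(tab$statistic[tab$term == "position_class"],
               oracle$position_class)
  expect_equal(tab$statistic[tab$term == "condition:position_class"],
               oracle$interaction)
  expect_equal(c(tab$df_num[tab$term == "condition"],
                 tab$df_den[tab$term == "condition"]),
               oracle$df$condition)
  # partial eta squared identity with F and the dfs
  expect_equal(tab$partial_eta_sq,
               tab$statistic * tab$df_num /
                 (tab$statistic * tab$df_num + tab$df_den))
})

test_that("toy table shipped as extdata matches the in-code constants", {
  path <- system.file("extdata", "toy_cells.csv", package = "timelinr")
  expect_true(nzchar(path))
  shipped <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(shipped), as.data.frame(toy_cell_table()))
})

test_that("a 24-subject 3x2 design reports the conventional dfs", {
  cells <- make_cells(24, seed = 3)
  tab <- tidy(rm_anova(cells, dv = "mean_accuracy"))
  expect_equal(tab$df_num[tab$term == "condition"], 2)
  expect_equal(tab$df_den[tab$term == "condition"], 46)
  expect_equal(tab$df_num[tab$term == "position_class"], 1)
  expect_equal(tab$df_den[tab$term == "position_class"], 23)
  expect_true(all(tab$partial_eta_sq >= 0 & tab$partial_eta_sq <= 1))
})

test_that("zero effect variance yields F = 0, and layout errors are caught", {
  cells <- make_cells(4, seed = 5) |>
    dplyr::mutate(mean_accuracy = 7)  # identical in every cell
  tab <- tidy(rm_anova(cells, dv = "mean_accuracy"))
  expect_true(all(tab$statistic == 0))
  expect_true(all(tab$p.value == 1))

  incomplete <- make_cells(4, seed = 5)
  incomplete <- incomplete[-1, ]
  expect_error(rm_anova(incomplete, dv = "mean_accuracy"), "S001")

  lone <- make_cells(4, seed = 5) |> dplyr::filter(subject_id == "S001")
  expect_error(rm_anova(lone, dv = "mean_accuracy"), "2 subjects")
})

test_that("F equals the squared paired t on 2-level sub-designs", {
  cells <- make_cells(12, seed = 7)
  pooled <- cells |>
    dplyr::filter(condition %in% c("sham", "slow_3hz")) |>
    dplyr::group_by(subject_id, condition) |>
    dplyr::summarise(value = mean(mean_accuracy), .groups = "drop")
  f <- tidy(rm_anova(pooled, dv = "value", within = "condition"))
  wide <- tidyr::pivot_wider(pooled, names_from = condition,
                             values_from = value)
  tt <- t.test(wide$sham - wide$slow_3hz)
  expect_equal(f$statistic[f$term == "condition"],
               unname(tt$statistic)^2)
  expect_equal(f$p.value[f$term == "condition"], tt$p.value)
})

test_that("Greenhouse-Geisser correction behaves sensibly", {
  cells <- make_cells(12, seed = 9)
  gg <- tidy(rm_anova(cells, dv = "mean_accuracy",
                      sphericity_correction = "greenhouse_geisser"))
  none <- tidy(rm_anova(cells, dv = "mean_accuracy"))
  # 2-level factor: epsilon is identically 1, p unchanged
  expect_equal(gg$epsilon[gg$term == "position_class"], 1)
  expect_equal(gg$p.value[gg$term == "position_class"],
               none$p.value[none$term == "position_class"])
  # epsilon bounded by (1/df, 1]; F itself is never rescaled
  expect_true(all(gg$epsilon <= 1 + 1e-12))
  expect_true(all(gg$epsilon >= 1 / gg$df_num - 1e-12))
  expect_equal(gg$statistic, none$statistic)
})

test_that("paired posthocs match hand-computed t and Cohen's d", {
  # paired differences (1, 2, 3): mean 2, sd 1, t = 2*sqrt(3), d = 2
  cells <- tibble::tibble(
    subject_id = rep(c("a", "b", "c"), each = 2),
    condition = rep(c("A", "B"), 3),
    position_class = "pooled",
    mean_accuracy = c(11, 10, 14, 12, 16, 13))
  res <- pairwise_posthoc(cells, alpha = 0.05, m = 3)
  expect_equal(res$estimate, 2)
  expect_equal(res$statistic, 2 * sqrt(3))
  expect_equal(res$cohens_d, 2)
  expect_equal(res$df, 2)
  expect_equal(res$alpha_corrected, 0.05 / 3)
  # Bonferroni identity: corrected alpha times m is alpha, exactly
  expect_identical(res$alpha_corrected * 3, 0.05)

  # all-zero differences are degenerate with t = 0, d = 0
  flat <- dplyr::mutate(cells, mean_accuracy = rep(c(5, 5), 3))
  res0 <- pairwise_posthoc(flat)
  expect_true(res0$degenerate)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$cohens_d, 0)
})

test_that("difference correlations recover exact and null structure", {
  # construct cells where the bias change is minus the accuracy change
  base <- tidyr::expand_grid(subject_id = sprintf("S%02d", 1:24),
                             condition = c("sham", "slow_3hz"),
                             position_class = c("boundary", "non_boundary"))
  set.seed(11)
  d <- rnorm(24)
  cells <- base |>
    dplyr::mutate(
      mean_accuracy = ifelse(condition == "sham", 10, 10 + d[match(
        subject_id, sprintf("S%02d", 1:24))]),
      mean_bias = -mean_accuracy)
  res <- diff_correlation(cells, "slow_3hz")
  expect_equal(res$r, -1)
  expect_equal(res$df, 22)  # Pearson df n - 2

  # independent standard-normal difference pairs: mean r near 0
  rs <- vapply(seq_len(1000), function(i) {
    set.seed(3000 + i)
    nn <- 200
    cc <- tidyr::expand_grid(subject_id = sprintf("S%03d", 1:nn),
                             condition = c("sham", "slow_3hz")) |>
      dplyr::mutate(position_class = "pooled",
                    mean_accuracy = ifelse(condition == "sham", 0, rnorm(nn)),
                    mean_bias = ifelse(condition == "sham", 0, rnorm(nn)))
    diff_correlation(cc, "slow_3hz")$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)) + 0.005)

  # constant difference vector is degenerate
  flat <- dplyr::mutate(base, mean_accuracy = 1, mean_bias = 2)
  expect_warning(resf <- diff_correlation(flat, "slow_3hz"), "Constant")
  expect_true(resf$degenerate)
})

test_that("dependent-correlation z-test matches its closed forms", {
  # equal correlations with symmetric dependency -> z = 0
  res_eq <- compare_dependent_correlations(0.4, 0.4, 24, r13 = 0.2,
                                           r14 = 0.1, r23 = 0.1, r24 = 0.2)
  expect_equal(res_eq$z, 0)
  expect_equal(res_eq$p.value, 1)

  # zero cross-correlations reduce to the independent-case closed form
  res <- compare_dependent_correlations(0.5, 0, 24,
                                        r13 = 0, r14 = 0, r23 = 0, r24 = 0)
  expect_equal(res$z, atanh(0.5) / sqrt(2 / (24 - 3)))
  expect_equal(res$z, 1.78, tolerance = 0.005)

  # antisymmetry: swapping the correlations flips the sign of z
  a <- compare_dependent_correlations(0.6, 0.1, 30, r13 = 0.3, r14 = 0.2,
                                      r23 = 0.2, r24 = 0.3)
  b <- compare_dependent_correlations(0.1, 0.6, 30, r13 = 0.3, r14 = 0.2,
                                      r23 = 0.2, r24 = 0.3)
  expect_equal(a$z, -b$z)

  # missing dependency inputs fall back to the independent-samples form
  expect_warning(ind <- compare_dependent_correlations(0.5, 0, 24),
                 "independent")
  expect_equal(ind$method, "independent_fisher_z")
  expect_equal(ind$z, atanh(0.5) / sqrt(2 / 21))

  # end-to-end wrapper agrees with the core on its own correlation matrix
  cells <- make_cells(24, seed = 13)
  whole <- compare_condition_correlations(cells)
  expect_true(is.finite(whole$z))
  expect_equal(whole$method, "pearson_filon_fisher_z")
})

test_that("covariate ANOVA handles coding, orthogonality, and errors", {
  cells <- make_cells(12, seed = 15)
  cov_tbl <- tibble::tibble(subject_id = sprintf("S%03d", 1:12),
                            tacs_order_id = rep(1:6, 2))
  with_cov <- dplyr::left_join(cells, cov_tbl, by = "subject_id")
  fit <- covariate_anova(with_cov, "mean_accuracy", covariate = "tacs_order_id")
  tab <- tidy(fit)
  # linear covariate spends 1 between-subject df
  expect_equal(tab$df_num[tab$term == "tacs_order_id"], 1)
  expect_equal(tab$df_den[tab$term == "tacs_order_id"], 10)
  expect_true(all(c("condition:tacs_order_id",
                    "position_class:tacs_order_id") %in% tab$term))

  # constant covariate is rejected
  const <- dplyr::mutate(cells, grp = 1)
  expect_error(covariate_anova(const, "mean_accuracy", covariate = "grp"),
               "constant")

  # duplicate-subject construction makes the covariate exactly orthogonal:
  # the within-effect sum of squares is untouched, so F changes only by the
  # error-df ratio
  half <- make_cells(2, seed = 17) |>
    dplyr::mutate(subject_id = paste0(subject_id, "x"))
  dup <- dplyr::bind_rows(
    make_cells(2, seed = 17),
    half)
  x <- tibble::tibble(subject_id = unique(dup$subject_id)) |>
    dplyr::mutate(x = ifelse(grepl("x$", subject_id), 1, -1))
  dup <- dplyr::left_join(dup, x, by = "subject_id")
  plain <- tidy(rm_anova(dup, "mean_accuracy"))
  withx <- tidy(covariate_anova(dup, "mean_accuracy", covariate = "x"))
  for (term in c("condition", "position_class")) {
    f0 <- plain[plain$term == term, ]
    f1 <- withx[withx$term == term, ]
    expect_equal(f1$statistic, f0$statistic * f1$df_den / f0$df_den)
  }
  # and the covariate terms themselves carry no variance
  expect_equal(withx$statistic[withx$term == "x"], 0)
})

test_that("null covariates reject at the nominal rate", {
  probes <- probe_grid(12)
  params <- null_params()
  cov_tbl <- tibble::tibble(subject_id = sprintf("S%03d", 1:12))
  hits <- vapply(seq_len(1000), function(i) {
    set.seed(5000 + i)
    tl <- simulate_timeline(probes, params)
    cells <- aggregate_cells(compute_metrics(tl))
    cells <- dplyr::left_join(cells, dplyr::mutate(cov_tbl, x = rnorm(12)),
                              by = "subject_id")
    tab <- tidy(covariate_anova(cells, "mean_accuracy", covariate = "x"))
    tab$p.value[tab$term == "x"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(hits) - 0.05), 0.02)
})

test_that("sham identification uses the exact binomial tail", {
  # k at the chance expectation: one-sided p above one half
  expect_gt(sham_identification_test(8, 24)$p_one_sided, 0.5)
  # extreme tail
  expect_equal(sham_identification_test(24, 24)$p_one_sided, (1 / 3)^24)
  # brute-force tail sum as the oracle
  oracle <- sum(dbinom(12:24, 24, 1 / 3))
  expect_equal(sham_identification_test(12, 24)$p_one_sided, oracle)
})

test_that("power analysis matches a brute-force noncentral-F search", {
  # independent grid search over n with the same distributional primitives
  brute_n <- function(f, alpha, power, m, rho) {
    for (n in 2:1000) {
      df1 <- m - 1
      df2 <- (n - 1) * (m - 1)
      lam <- f^2 * n * m / (1 - rho)
      if (pf(qf(1 - alpha, df1, df2), df1, df2, ncp = lam,
             lower.tail = FALSE) >= power) return(n)
    }
  }
  res <- power_rm_anova(f = 0.30, alpha = 0.05, target_power = 0.8, m = 3,
                        rho = 0.5)
  expect_equal(res$n, brute_n(0.30, 0.05, 0.8, 3, 0.5))
  expect_gte(res$power, 0.8)

  # monotonicity: larger effects never need more subjects
  expect_lte(power_rm_anova(f = 0.60, m = 3)$n, res$n)
  # vanishing power target returns the minimum feasible n
  expect_equal(power_rm_anova(f = 0.30, m = 3, target_power = 1e-9)$n, 2)
  expect_error(power_rm_anova(f = 1e-4, m = 3, n_max = 100), "unattainable")
})

test_that("default condition effects are detectable and signed correctly", {
  probes <- probe_grid(24)
  params <- behavioral_params()
  res <- vapply(seq_len(500), function(i) {
    tl <- simulate_timeline(probes, params, seed = 40000 + i)
    cells <- aggregate_cells(compute_metrics(tl))
    ph_acc <- pairwise_posthoc(cells, dv = "mean_accuracy")
    ph_bias <- pairwise_posthoc(cells, dv = "mean_bias")
    slow <- ph_acc[ph_acc$contrast == "sham - slow_3hz", ]
    fast <- ph_bias[ph_bias$contrast == "fast_8hz - sham", ]
    c(sig = slow$p.value < slow$alpha_corrected,
      sign_ok = fast$estimate > 0)
  }, c(sig = FALSE, sign_ok = FALSE))
  # slow-theta accuracy benefit detected in a majority of cohorts
  expect_gt(mean(res["sig", ]), 0.5)
  # fast-theta bias reduction has the generating sign almost always
  expect_gte(mean(res["sign_ok", ]), 0.95)
})

test_that("trim fraction zero reproduces the raw-mean inference exactly", {
  tl <- simulate_timeline(probe_grid(12),
                          behavioral_params(outlier_rt_rate = 0), seed = 19)
  m <- compute_metrics(apply_exclusions(tl))
  raw <- aggregate_cells(m)
  robust0 <- aggregate_cells(m, estimator = "trimmed_mean", trim = 0)
  f_raw <- tidy(rm_anova(raw, "mean_accuracy"))
  f_rob <- tidy(rm_anova(robust0, "mean_accuracy"))
  expect_equal(f_rob$statistic, f_raw$statistic, tolerance = 1e-12)
})
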