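#' Configuration for a full pipeline run
#'
#' Bundles everything a reproducible run needs: the master seed (fanned out
#' deterministically into per-stage child seeds), the design specification,
#' the generative parameters, and the analysis options. A saved
#' configuration reproduces a run exactly.
#'
#' @param seed Master integer seed.
#' @param spec A [design_spec()].
#' @param params A [behavioral_params()].
#' @param granularity Cell granularity for the main analyses
#'   (`"two_class"` or `"four_position"`).
#' @param trim Trim fraction for the robust re-analysis (default 0.2).
#' @param alpha Nominal alpha (default 0.05).
#' @param n_series Monte-Carlo series for the chance null (default 10000).
#' @param drop_degenerate Drop flagged same-location responders before
#'   analysis (default `TRUE`).
#' @param degenerate_threshold Modal-share threshold for flagging.
#' @param out_dir Output directory (`NULL` = no files written).
#' @param quiet Suppress stage logging.
#'
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1L,
                       spec = design_spec(),
                       params = behavioral_params(),
                       granularity = "two_class",
                       trim = 0.2,
                       alpha = 0.05,
                       n_series = 10000,
                       drop_degenerate = TRUE,
                       degenerate_threshold = 0.5,
                       out_dir = NULL,
                       quiet = FALSE) {
  stopifnot(inherits(spec, "design_spec"), inherits(params, "behavioral_params"))
  structure(
    list(seed = as.integer(seed), spec = spec, params = params,
         granularity = granularity, trim = trim, alpha = alpha,
         n_series = n_series, drop_degenerate = drop_degenerate,
         degenerate_threshold = degenerate_threshold,
         out_dir = out_dir, quiet = quiet),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [run_config()] arguments; nested `spec:` and
#' `params:` blocks are passed to [design_spec()] and
#' [behavioral_params()]. Arguments supplied via `...` override file values.
#'
#' @param path Path to a YAML file.
#' @param ... Overrides for any [run_config()] argument.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$spec)) args$spec <- do.call(design_spec, raw$spec)
  if (!is.null(raw$params)) args$params <- do.call(behavioral_params, raw$params)
  for (key in setdiff(names(raw), c("spec", "params"))) args[[key]] <- raw[[key]]
  overrides <- list(...)
  for (key in names(overrides)) args[[key]] <- overrides[[key]]
  do.call(run_config, args)
}

log_stage <- function(quiet, fmt, ...) {
  if (!quiet) {
    inform(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
  }
}

run_stage <- function(name, quiet, expr) {
  log_stage(quiet, "stage '%s' ...", name)
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

fmt_num <- function(x, digits = 3) {
  ifelse(is.na(x), "NA",
         ifelse(abs(x) >= 1e4 | (abs(x) < 1e-3 & x != 0),
                formatC(x, format = "e", digits = digits),
                formatC(x, format = "f", digits = digits)))
}

md_table <- function(df) {
  df <- as.data.frame(df)
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !all(df[[col]] == round(df[[col]]), na.rm = TRUE)) {
      df[[col]] <- fmt_num(df[[col]])
    }
  }
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, body), collapse = "\n")
}

#' Run the full design-simulate-chance-analyze pipeline
#'
#' Executes every stage of the analysis on a synthetic cohort: cohort
#' simulation, Monte-Carlo chance null, exclusions and degenerate-responder
#' screening, subject-cell aggregation (raw and trimmed), the
#' accuracy/bias/encoding-RT repeated-measures ANOVAs with posthocs, the
#' chance comparisons, the accuracy-bias correlation contrasts, the sham
#' identification test and covariate ANOVAs, and the stimulation-order
#' covariate ANOVAs. When `config$out_dir` is set, dataset CSVs, result
#' JSON, and a Markdown report are written; outputs of completed stages are
#' preserved if a later stage fails.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with the cohort, chance curves, cell tables,
#'   and all result tables, plus the report text.
#' @export
#' @examples
#' \donttest{
#' bundle <- run_pipeline(run_config(
#'   seed = 1, spec = design_spec(n_participants = 6),
#'   n_series = 1000, quiet = TRUE))
#' bundle$anova_accuracy
#' }
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  quiet <- config$quiet
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  seeds <- derive_seeds(config$seed, 2L)
  bundle <- list(config = config)

  cohort <- run_stage("simulate", quiet, {
    simulate_cohort(config$spec, config$params, seed = seeds[[1]])
  })
  bundle$cohort <- cohort
  log_stage(quiet, "simulated %d encoding and %d timeline trials (seed %d)",
            nrow(cohort$encoding), nrow(cohort$timeline), config$seed)
  if (!is.null(out_dir)) {
    write_encoding_csv(cohort$encoding, file.path(out_dir, "encoding.csv"))
    write_timeline_csv(cohort$timeline, file.path(out_dir, "timeline.csv"))
    readr::write_csv(cohort$subjects, file.path(out_dir, "subjects.csv"))
  }

  n_positions <- config$spec$n_items_per_session
  chance <- run_stage("chance", quiet, {
    simulate_chance(config$n_series, n_positions, seed = seeds[[2]])
  })
  bundle$chance <- chance
  if (!is.null(out_dir)) {
    write_chance_csv(chance, file.path(out_dir, "chance_curve.csv"))
  }

  prep <- run_stage("prepare", quiet, {
    retained <- apply_exclusions(cohort$timeline)
    excl <- exclusion_report(retained)
    flags <- flag_degenerate_subjects(retained,
                                      threshold = config$degenerate_threshold)
    dropped <- character(0)
    if (config$drop_degenerate && any(flags$flagged)) {
      dropped <- flags$subject_id[flags$flagged]
      retained <- retained |> filter(!.data$subject_id %in% dropped)
    }
    metrics <- compute_metrics(retained, n_positions = n_positions)
    list(metrics = metrics, exclusions = excl, flags = flags, dropped = dropped)
  })
  bundle$exclusions <- prep$exclusions
  bundle$degenerate_flags <- prep$flags
  log_stage(quiet, "excluded %.2f%% of timeline trials; %d subject(s) dropped as degenerate",
            prep$exclusions$pct_excluded, length(prep$dropped))

  analysis <- run_stage("analyze", quiet, {
    cells <- aggregate_cells(prep$metrics, granularity = config$granularity)
    cells_robust <- aggregate_cells(prep$metrics, granularity = config$granularity,
                                    estimator = "trimmed_mean", trim = config$trim)
    rt_cells <- encoding_rt_cells(
      cohort$encoding |> filter(!.data$subject_id %in% prep$dropped))
    conds <- config$spec$conditions
    active <- setdiff(conds, "sham")
    subj <- cohort$subjects |> filter(!.data$subject_id %in% prep$dropped)

    cells_cov <- cells |>
      left_join(subj |> select("subject_id", "sham_identified", "tacs_order_id"),
                by = "subject_id")

    corr <- bind_rows(lapply(active, function(cc) diff_correlation(cells, cc)))
    corr_cmp <- if (length(active) == 2L) {
      tryCatch(compare_condition_correlations(cells, active),
               warning = function(w) {
                 warn(conditionMessage(w))
                 NULL
               })
    } else NULL

    list(
      cells = cells,
      cells_robust = cells_robust,
      anova_encoding_rt = rm_anova(rt_cells, dv = "mean_rt",
                                   within = c("condition", "within_context_position")),
      chance_tests = compare_to_chance(prep$metrics, chance,
                                       alpha = config$alpha, m = length(conds)),
      anova_accuracy = rm_anova(cells, dv = "mean_accuracy"),
      anova_bias = rm_anova(cells, dv = "mean_bias"),
      posthoc_accuracy = pairwise_posthoc(cells, dv = "mean_accuracy",
                                          alpha = config$alpha),
      posthoc_bias = pairwise_posthoc(cells, dv = "mean_bias",
                                      alpha = config$alpha),
      anova_accuracy_robust = rm_anova(cells_robust, dv = "mean_accuracy"),
      anova_bias_robust = rm_anova(cells_robust, dv = "mean_bias"),
      correlations = corr,
      correlation_comparison = corr_cmp,
      identification = sham_identification_test(sum(subj$sham_identified),
                                                nrow(subj)),
      covariate_sham_accuracy = try_covariate(cells_cov, "mean_accuracy",
                                              "sham_identified"),
      covariate_sham_bias = try_covariate(cells_cov, "mean_bias",
                                          "sham_identified"),
      covariate_order_accuracy = try_covariate(cells_cov, "mean_accuracy",
                                               "tacs_order_id"),
      covariate_order_bias = try_covariate(cells_cov, "mean_bias",
                                           "tacs_order_id")
    )
  })
  bundle <- c(bundle, analysis)

  report <- run_stage("report", quiet, build_report(bundle))
  bundle$report <- report

  if (!is.null(out_dir)) {
    run_stage("write", quiet, {
      readr::write_csv(analysis$cells, file.path(out_dir, "cells.csv"))
      readr::write_csv(analysis$cells_robust, file.path(out_dir, "cells_robust.csv"))
      jsonlite::write_json(
        list(
          exclusions = bundle$exclusions[c("n_trials", "n_excluded", "pct_excluded")],
          degenerate_subjects = prep$dropped,
          chance = as.list(glance(chance)),
          chance_tests = analysis$chance_tests,
          anova_accuracy = tidy(analysis$anova_accuracy),
          anova_bias = tidy(analysis$anova_bias),
          anova_encoding_rt = tidy(analysis$anova_encoding_rt),
          posthoc_accuracy = analysis$posthoc_accuracy,
          posthoc_bias = analysis$posthoc_bias,
          anova_accuracy_robust = tidy(analysis$anova_accuracy_robust),
          anova_bias_robust = tidy(analysis$anova_bias_robust),
          correlations = analysis$correlations,
          correlation_comparison = analysis$correlation_comparison,
          identification = analysis$identification
        ),
        file.path(out_dir, "results.json"),
        auto_unbox = TRUE, digits = NA, na = "null"
      )
      writeLines(report, file.path(out_dir, "report.md"))
    })
    log_stage(quiet, "outputs written to %s", out_dir)
  }
  invisible(bundle)
}

# A constant covariate (e.g. no subject identified sham) is reported as
# not estimable rather than aborting the whole analysis stage.
try_covariate <- function(cells_cov, dv, covariate) {
  tryCatch(covariate_anova(cells_cov, dv, covariate = covariate),
           error = function(e) {
             warn(sprintf("covariate ANOVA (%s on %s) not estimable: %s",
                          covariate, dv, conditionMessage(e)))
             NULL
           })
}

build_report <- function(bundle) {
  g <- glance(bundle$chance)
  anova_md <- function(x) {
    if (is.null(x)) "Not estimable (constant covariate)." else md_table(tidy(x))
  }
  sections <- c(
    "# Timeline memory analysis report",
    "",
    sprintf("Seed %d; %d subjects; granularity %s.",
            bundle$config$seed, bundle$cohort$spec$n_participants,
            bundle$config$granularity),
    sprintf("Timeline exclusions: %.2f%% of %d trials.",
            bundle$exclusions$pct_excluded, bundle$exclusions$n_trials),
    "",
    "## Encoding response time",
    "",
    anova_md(bundle$anova_encoding_rt),
    "",
    "## Chance-level performance",
    "",
    sprintf("Monte-Carlo chance null (%d series): grand mean absolute error %.3f (rounds to %d), grand mean signed error %.3g.",
            g$n_series, g$grand_abs_mean, round(g$grand_abs_mean),
            g$grand_signed_mean),
    "",
    md_table(bundle$chance_tests),
    "",
    "## Temporal accuracy",
    "",
    anova_md(bundle$anova_accuracy),
    "",
    md_table(bundle$posthoc_accuracy),
    "",
    "## Temporal bias",
    "",
    anova_md(bundle$anova_bias),
    "",
    md_table(bundle$posthoc_bias),
    "",
    "## Robust re-analysis",
    "",
    sprintf("Trimmed means (trim fraction %.2f per tail).", bundle$config$trim),
    "",
    anova_md(bundle$anova_accuracy_robust),
    "",
    anova_md(bundle$anova_bias_robust),
    "",
    "## Accuracy-bias correlations",
    "",
    md_table(bundle$correlations),
    "",
    if (!is.null(bundle$correlation_comparison)) {
      md_table(bundle$correlation_comparison)
    } else {
      "Dependent-correlation comparison unavailable (degenerate input)."
    },
    "",
    "## Sham identification",
    "",
    md_table(bundle$identification),
    "",
    anova_md(bundle$covariate_sham_accuracy),
    "",
    anova_md(bundle$covariate_sham_bias),
    "",
    "## Stimulation order",
    "",
    anova_md(bundle$covariate_order_accuracy),
    "",
    anova_md(bundle$covariate_order_bias),
    ""
  )
  paste(sections, collapse = "\n")
}

#' Hand-checkable 3-subject toy cell table
#'
#' A fixed subject-cell table (3 subjects x 3 conditions x 2 position
#' classes) with small integer accuracy values, used as the target of the
#' hand-computed sums-of-squares oracle for [rm_anova()]. The same constants
#' are shipped as `inst/extdata/toy_cells.csv`.
#'
#' @return A tibble of 18 subject cells.
#' @export
toy_cell_table <- function() {
  tidyr::expand_grid(
    subject_id = c("T1", "T2", "T3"),
    condition = c("sham", "slow_3hz", "fast_8hz"),
    position_class = c("boundary", "non_boundary")
  ) |>
    mutate(
      mean_accuracy = c(
        10, 14, 8, 11, 9, 13,   # T1: sham b/nb, slow b/nb, fast b/nb
        12, 16, 9, 12, 11, 14,  # T2
        11, 18, 10, 13, 10, 15  # T3
      ),
      mean_bias = c(
        -2, -6, -1, -4, -1, -3,
        -3, -7, -2, -5, -2, -4,
        -2, -8, -2, -5, -1, -5
      ),
      n_trials_retained = 9L
    )
}

#' Write small packaged test datasets
#'
#' Emits a 6-subject miniature synthetic cohort (encoding, timeline, and
#' subject tables) and the hand-written 3-subject toy cell table into a
#' directory, all as CSV.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed for the miniature cohort.
#' @return (Invisibly) the paths written.
#' @export
make_fixtures <- function(dir, seed = 42) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- simulate_cohort(design_spec(n_participants = 6), seed = seed)
  paths <- c(
    encoding = file.path(dir, "mini_encoding.csv"),
    timeline = file.path(dir, "mini_timeline.csv"),
    subjects = file.path(dir, "mini_subjects.csv"),
    toy = file.path(dir, "toy_cells.csv")
  )
  write_encoding_csv(cohort$encoding, paths["encoding"])
  write_timeline_csv(cohort$timeline, paths["timeline"])
  readr::write_csv(cohort$subjects, paths["subjects"])
  readr::write_csv(toy_cell_table(), paths["toy"])
  invisible(paths)
}
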