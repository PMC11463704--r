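#' Run a full simulated study end to end
#'
#' Orchestrates the pipeline: draw an observer population, simulate the
#' trial table, summarize per participant, flag individually
#' significant participants against the design's error baseline,
#' estimate population prevalence (overall and per condition level),
#' and compute the group-level statistics (Welch t of illusion vs error
#' rates; OLS of subject-by-level rates on the condition value; for
#' block designs, one-way ANOVA over blocks plus a BIC-approximate
#' Bayes factor).
#'
#' When `out_dir` is given, every stage writes a CSV
#' (`trials.csv`, `subject_summaries.csv`, `significance.csv`,
#' `prevalence.csv`, `prevalence_curves.csv`, `group_stats.csv`) plus a
#' YAML provenance sidecar (`run.yaml`) recording the seed, the
#' configuration hash and the package version; re-running with the same
#' configuration reproduces the files byte for byte.
#'
#' @param design A [study_design] or a design id string.
#' @param model A [population_model()].
#' @param baseline A [baseline_spec()]; defaults to the design's
#'   baseline kind with alpha 0.05.
#' @param prev_model Prevalence model (see [prevalence_posterior()]).
#' @param alpha_fp Per-test false-positive rate assumed by the
#'   test-calibrated prevalence model; defaults to the baseline alpha.
#' @param hpdi_mass HPDI probability (default 0.96).
#' @param seed Integer seed controlling both the population draw and
#'   the trial simulation.
#' @param out_dir Optional output directory.
#' @return A `study_run` list: `design`, `model`, `baseline`, `seed`,
#'   `profiles`, `trials`, `summaries`, `significance`, `prevalence`
#'   (overall `prevalence_estimate`), `prevalence_by_level` (tibble),
#'   `group_stats` (tibble), `headline` (named list of the headline
#'   numbers), `files` (paths written, if any).
#' @export
run_study <- function(design,
                      model = population_model(),
                      baseline = NULL,
                      prev_model = c("test_calibrated", "simple_beta"),
                      alpha_fp = NULL,
                      hpdi_mass = 0.96,
                      seed = 1L,
                      out_dir = NULL) {
  if (is.character(design)) design <- builtin_design(design)
  stopifnot(inherits(design, "study_design"))
  prev_model <- match.arg(prev_model)
  if (is.null(baseline)) baseline <- baseline_spec(design$baseline_kind)
  if (is.null(alpha_fp)) alpha_fp <- baseline$alpha
  seed <- as.integer(seed)

  profiles <- draw_population(model, design, seed = seed)
  trials <- simulate_trials(profiles, design, seed = seed + 1L,
                            two_dot_commission = model$two_dot_commission,
                            flash_above_prob = model$flash_above_prob)
  summaries <- summarize_subjects(trials, design)
  sig <- flag_significant(summaries, baseline, per_level = TRUE)
  counts <- significance_counts(sig)
  prev_tab <- prevalence_curve(counts, model = prev_model,
                               alpha_fp = alpha_fp, mass = hpdi_mass)
  overall_est <- prevalence_estimate(sig$k_sig, sig$n, model = prev_model,
                                     alpha_fp = alpha_fp, mass = hpdi_mass)
  group <- group_stats_table(sig$summaries, design, baseline)

  ov <- sig$summaries[sig$summaries$level == "overall", ]
  err_rate <- if (baseline$kind == "commission") ov$pct_commission else
    ov$pct_omission
  headline <- list(
    design_id = design$design_id, seed = seed,
    illusion_rate_mean = mean(ov$pct_report2),
    illusion_rate_sd = stats::sd(ov$pct_report2),
    error_rate_mean = mean(err_rate),
    error_rate_sd = stats::sd(err_rate),
    baseline_p0 = sig$p0,
    k_sig = sig$k_sig, n = sig$n,
    map = overall_est$map,
    hpdi_low = overall_est$hpdi_low,
    hpdi_high = overall_est$hpdi_high,
    true_prevalence = model$gamma,
    true_perceiver_count = sum(profiles$is_perceiver))

  run <- structure(
    list(design = design, model = model, baseline = baseline,
         prev_model = prev_model, alpha_fp = alpha_fp,
         hpdi_mass = hpdi_mass, seed = seed,
         profiles = profiles, trials = trials,
         summaries = sig$summaries, significance = sig,
         prevalence = overall_est, prevalence_by_level = prev_tab,
         group_stats = group, headline = headline, files = NULL),
    class = "study_run")
  if (!is.null(out_dir)) run$files <- write_study_run(run, out_dir)
  run
}

# group-level statistics assembled into one tidy table
group_stats_table <- function(summaries, design, baseline) {
  ov <- summaries[summaries$level == "overall", ]
  per_level <- summaries[summaries$level != "overall", ]
  rows <- list()
  add <- function(statistic, value, df1 = NA_real_, df2 = NA_real_,
                  p = NA_real_, note = "") {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      statistic = statistic, value = value, df1 = df1, df2 = df2,
      p = p, note = note)
  }

  contrast <- if (baseline$kind == "commission")
    "report2_vs_commission" else "report2_vs_omission"
  wt <- welch_t_from_summaries(summaries, contrast)
  add(paste0("welch_t_", contrast), wt$t, df1 = wt$df, p = wt$p,
      note = "illusion rate vs error rate, per-subject percentages")

  # subject x condition-value means (collapse blocks where present)
  reg_pts <- per_level |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(
      pct = 100 * sum(.data$n_report2) / sum(.data$n_experimental),
      .groups = "drop")
  reg <- simple_regression(reg_pts$condition, reg_pts$pct)
  add("regression_slope", reg$slope,
      note = paste0("per ", design$factor_unit))
  add("regression_r_squared", reg$r_squared)
  add("regression_f", reg$f, df1 = reg$df_num, df2 = reg$df_den, p = reg$p)
  bf_reg <- approx_bayes_factor(reg_pts$pct, reg_pts$condition)
  add("bf10_condition", bf_reg$bf10, note = bf_reg$method)

  if (any(!is.na(per_level$block))) {
    blk_pts <- per_level |>
      dplyr::group_by(.data$participant_id, .data$block) |>
      dplyr::summarise(
        pct = 100 * sum(.data$n_report2) / sum(.data$n_experimental),
        .groups = "drop")
    groups <- split(blk_pts$pct, blk_pts$block)
    av <- one_way_anova(groups)
    add("anova_block_f", av$f, df1 = av$df_between, df2 = av$df_within,
        p = av$p, note = "one-way over attention blocks")
    bf_blk <- approx_bayes_factor(blk_pts$pct, blk_pts$block)
    add("bf10_block", bf_blk$bf10, note = bf_blk$method)
  }
  dplyr::bind_rows(rows)
}

write_study_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(name) file.path(out_dir, name)
  readr::write_csv(run$trials, f("trials.csv"))
  readr::write_csv(run$summaries, f("subject_summaries.csv"))
  sig_tab <- run$summaries[run$summaries$level == "overall",
                           c("participant_id", "n_experimental",
                             "n_report2", "p_value", "significant")]
  readr::write_csv(sig_tab, f("significance.csv"))
  readr::write_csv(run$prevalence_by_level, f("prevalence.csv"))
  curves <- dplyr::bind_rows(lapply(
    seq_len(nrow(run$prevalence_by_level)), function(i) {
      row <- run$prevalence_by_level[i, ]
      g <- posterior_grid(prevalence_posterior(
        row$k_sig, row$n, run$prev_model, run$alpha_fp), 501)
      g$level <- row$level
      g[, c("level", "gamma", "density")]
    }))
  readr::write_csv(curves, f("prevalence_curves.csv"))
  readr::write_csv(run$group_stats, f("group_stats.csv"))
  config <- list(design_id = run$design$design_id,
                 model = unclass(run$model),
                 baseline = unclass(run$baseline),
                 prev_model = run$prev_model, alpha_fp = run$alpha_fp,
                 hpdi_mass = run$hpdi_mass, seed = run$seed)
  yaml::write_yaml(
    list(seed = run$seed,
         config_hash = rlang::hash(config),
         package_version = as.character(utils::packageVersion("splitprev")),
         config = config,
         headline = lapply(run$headline, unname)),
    f("run.yaml"))
  stats::setNames(
    f(c("trials.csv", "subject_summaries.csv", "significance.csv",
        "prevalence.csv", "prevalence_curves.csv", "group_stats.csv",
        "run.yaml")),
    c("trials", "subject_summaries", "significance", "prevalence",
      "prevalence_curves", "group_stats", "provenance"))
}

#' @export
print.study_run <- function(x, ...) {
  h <- x$headline
  cat("Simulated study '", h$design_id, "' (seed ", h$seed, ")\n", sep = "")
  cat(sprintf("  illusion rate: M = %.2f%%, SD = %.2f%%\n",
              h$illusion_rate_mean, h$illusion_rate_sd))
  cat(sprintf("  %s error rate: M = %.2f%%, SD = %.2f%% (pooled p0 = %.4f)\n",
              x$baseline$kind, h$error_rate_mean, h$error_rate_sd,
              h$baseline_p0))
  cat(sprintf("  significant participants: %d of %d\n", h$k_sig, h$n))
  cat(sprintf("  prevalence MAP = %.2f (%.0f%% HPDI = [%.2f, %.2f]); true gamma = %.2f (%d perceivers drawn)\n",
              h$map, 100 * x$hpdi_mass, h$hpdi_low, h$hpdi_high,
              h$true_prevalence, h$true_perceiver_count))
  invisible(x)
}
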