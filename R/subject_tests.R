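#' Per-participant summaries of a trial table
#'
#' Counts, per participant and per condition level plus an overall row:
#' experimental trials, illusion reports (response 2 on an experimental
#' trial), catch trials, commission errors (response >= 1 on a catch
#' trial; response-2-only counted separately), and omission errors
#' (response 0 on an experimental trial), with the corresponding
#' percentage rates.
#'
#' @param trials Trial tibble (see [simulate_trials()] /
#'   [read_trials()]).
#' @param design The [study_design] the trials conform to.
#' @return Tibble with one row per (participant, level) and one
#'   `level = "overall"` row per participant; columns `participant_id`,
#'   `level`, `condition`, `block`, `n_experimental`, `n_report2`,
#'   `pct_report2`, `n_catch`, `n_commission`, `n_commission_two`,
#'   `pct_commission`, `n_omission`, `pct_omission`. Percentages are
#'   `NA` where the denominator is zero.
#' @export
summarize_subjects <- function(trials, design) {
  stopifnot(inherits(design, "study_design"))
  validate_trials(trials)
  n_exp_tot <- tapply(trials$trial_type == "experimental",
                      trials$participant_id, sum)
  if (any(n_exp_tot == 0)) {
    stop("participant(s) with zero experimental trials: ",
         paste(names(n_exp_tot)[n_exp_tot == 0], collapse = ", "))
  }
  is_exp <- trials$trial_type == "experimental"
  counts <- trials |>
    dplyr::group_by(.data$participant_id, .data$level) |>
    dplyr::summarise(
      condition = .data$condition[1],
      block = .data$block[1],
      n_experimental = sum(.data$trial_type == "experimental"),
      n_report2 = sum(.data$trial_type == "experimental" &
                        .data$response == 2L),
      n_catch = sum(.data$trial_type == "catch"),
      n_commission = sum(.data$trial_type == "catch" &
                           .data$response >= 1L),
      n_commission_two = sum(.data$trial_type == "catch" &
                               .data$response == 2L),
      n_omission = sum(.data$trial_type == "experimental" &
                         .data$response == 0L),
      .groups = "drop")
  overall <- counts |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      level = "overall", condition = NA_real_, block = NA_character_,
      dplyr::across(dplyr::starts_with("n_"), sum),
      .groups = "drop")
  out <- dplyr::bind_rows(overall, counts) |>
    dplyr::mutate(
      pct_report2 = 100 * .data$n_report2 / .data$n_experimental,
      pct_commission = ifelse(.data$n_catch > 0,
                              100 * .data$n_commission / .data$n_catch,
                              NA_real_),
      pct_omission = 100 * .data$n_omission / .data$n_experimental) |>
    dplyr::arrange(.data$participant_id, .data$level != "overall",
                   .data$level)
  out
}

#' Baseline specification for per-subject significance tests
#'
#' @param kind `"commission"` (catch-trial error rate; Experiment 1
#'   designs) or `"omission"` (rate of reporting zero when one target
#'   was shown; Experiment 2 designs).
#' @param pooling `"pooled"` — the baseline proportion is total errors
#'   over total baseline trials across participants (the default
#'   reading of an "overall average error rate") — or
#'   `"mean_of_rates"`, the unweighted mean of per-subject rates.
#' @param alpha Per-test significance level (default 0.05).
#' @param commission_strict If `TRUE`, only response-2 catch trials
#'   count as commission errors; by default any nonzero report does.
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(kind = c("commission", "omission"),
                          pooling = c("pooled", "mean_of_rates"),
                          alpha = 0.05, commission_strict = FALSE) {
  kind <- match.arg(kind)
  pooling <- match.arg(pooling)
  stopifnot(is.numeric(alpha), alpha > 0, alpha < 1)
  structure(list(kind = kind, pooling = pooling, alpha = alpha,
                 commission_strict = commission_strict),
            class = "baseline_spec")
}

#' Exact one-sided (upper-tail) binomial test
#'
#' Returns `P(X >= k)` for `X ~ Binomial(n, p0)` — the exact upper-tail
#' p-value for the alternative "greater". Vectorized over `k`, `n`,
#' `p0`. With `p0 = 0` and `k > 0` the tail probability is exactly 0
#' (reported with a warning, since it arises when an omission baseline
#' happens to be error-free).
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability in \[0, 1\].
#' @return Upper-tail p-value(s) in \[0, 1\].
#' @examples
#' binom_test_upper(5, 10, 0.5)   # 0.623046875
#' @export
binom_test_upper <- function(k, n, p0) {
  if (any(!is.finite(k)) || any(k < 0) || any(k != floor(k))) {
    stop("k must be a non-negative integer")
  }
  if (any(!is.finite(n)) || any(n < 1) || any(n != floor(n))) {
    stop("n must be a positive integer")
  }
  if (any(k > n)) stop("k must not exceed n")
  if (any(!is.finite(p0)) || any(p0 < 0) || any(p0 > 1)) {
    stop("p0 must lie in [0, 1]")
  }
  if (any(p0 == 0 & k > 0)) {
    warning("baseline rate p0 = 0 with k > 0: p-value is exactly 0")
  }
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Flag participants reporting the illusion above the error baseline
#'
#' Computes the group error baseline per the [baseline_spec()], tests
#' each participant's overall illusion-report count against it with the
#' exact one-sided binomial test ([binom_test_upper()]), and counts the
#' significant participants — the `(k_sig, n)` input of the prevalence
#' analysis. With `per_level = TRUE` the same test is also run within
#' each condition level, reusing the overall pooled baseline, to feed
#' per-condition prevalence curves.
#'
#' @param summaries Output of [summarize_subjects()].
#' @param baseline A [baseline_spec()].
#' @param per_level Also test each (participant, level) row?
#' @return A `significance_result` list: `summaries` (input with
#'   `p_value` and `significant` columns added), `k_sig`, `n`, `p0`
#'   (baseline proportion used), and `baseline`.
#' @export
flag_significant <- function(summaries, baseline = baseline_spec(),
                             per_level = FALSE) {
  stopifnot(inherits(baseline, "baseline_spec"))
  ov <- summaries[summaries$level == "overall", ]
  if (baseline$kind == "commission") {
    err <- if (baseline$commission_strict) ov$n_commission_two else
      ov$n_commission
    den <- ov$n_catch
    if (sum(den) == 0) {
      stop("commission baseline requested but the design has no catch trials")
    }
  } else {
    err <- ov$n_omission
    den <- ov$n_experimental
  }
  p0 <- if (baseline$pooling == "pooled") {
    sum(err) / sum(den)
  } else {
    mean(err / den)
  }
  test_rows <- if (per_level) rep(TRUE, nrow(summaries)) else
    summaries$level == "overall"
  p_value <- rep(NA_real_, nrow(summaries))
  p_value[test_rows] <- binom_test_upper(summaries$n_report2[test_rows],
                                         summaries$n_experimental[test_rows],
                                         p0)
  summaries$p_value <- p_value
  summaries$significant <- summaries$p_value < baseline$alpha
  ov_flag <- summaries$significant[summaries$level == "overall"]
  structure(
    list(summaries = summaries,
         k_sig = sum(ov_flag),
         n = length(ov_flag),
         p0 = p0,
         baseline = baseline),
    class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat("Per-subject significance (", x$baseline$kind, " baseline, alpha = ",
      x$baseline$alpha, ")\n", sep = "")
  cat("  pooled baseline proportion p0 = ", signif(x$p0, 4), "\n", sep = "")
  cat("  significant participants: ", x$k_sig, " of ", x$n, "\n", sep = "")
  invisible(x)
}

#' Per-level significance counts
#'
#' Convenience extractor: the `(k_sig, n)` pair within each condition
#' level (plus overall), in the form [prevalence_curve()] consumes.
#'
#' @param res A `significance_result` computed with `per_level = TRUE`.
#' @return Tibble with columns `level`, `k_sig`, `n`.
#' @export
significance_counts <- function(res) {
  stopifnot(inherits(res, "significance_result"))
  s <- res$summaries
  if (anyNA(s$p_value)) {
    stop("per-level counts require flag_significant(per_level = TRUE)")
  }
  s |>
    dplyr::group_by(.data$level) |>
    dplyr::summarise(k_sig = sum(.data$significant),
                     n = dplyr::n(), .groups = "drop")
}
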