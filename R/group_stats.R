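#' Sample moments
#'
#' Bundles a group's mean, sample standard deviation (denominator
#' n - 1) and size — the inputs the Welch test needs, and the form in
#' which group-level results are reported (M, SD, n).
#'
#' @param mean,sd,n Moments, or pass a numeric vector as `x`.
#' @param x Optional raw data vector; overrides `mean`/`sd`/`n`.
#' @return A `sample_moments` list.
#' @export
sample_moments <- function(mean = NULL, sd = NULL, n = NULL, x = NULL) {
  if (!is.null(x)) {
    stopifnot(is.numeric(x), length(x) >= 2)
    mean <- base::mean(x); sd <- stats::sd(x); n <- length(x)
  }
  stopifnot(is.numeric(mean), is.numeric(sd), sd >= 0,
            is.numeric(n), n >= 2)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "sample_moments")
}

as_moments <- function(g) {
  if (inherits(g, "sample_moments")) g else sample_moments(x = g)
}

#' Welch two-sample t-test from moments or data
#'
#' The unequal-variance t-test computed directly from group moments:
#' `t = (m_a - m_b) / sqrt(s_a^2/n_a + s_b^2/n_b)` with
#' Welch–Satterthwaite degrees of freedom and a two-sided p-value from
#' the t distribution. Accepts [sample_moments()] objects or raw
#' numeric vectors, so it applies equally to published (M, SD, n)
#' summaries and to per-subject rate vectors.
#'
#' @param a,b Each a [sample_moments()] or a numeric vector.
#' @return A `welch_result` list: `t`, `df`, `p`, `mean_diff`.
#' @examples
#' welch_t(sample_moments(10.39, 10.07, 45),
#'         sample_moments(3.27, 4.49, 45))   # t(60.83) = 4.33
#' @export
welch_t <- function(a, b) {
  a <- as_moments(a); b <- as_moments(b)
  if (a$sd == 0 && b$sd == 0) {
    stop("both groups have zero variance; Welch t is undefined")
  }
  va <- a$sd^2 / a$n
  vb <- b$sd^2 / b$n
  se <- sqrt(va + vb)
  t <- (a$mean - b$mean) / se
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(list(t = t, df = df, p = p, mean_diff = a$mean - b$mean),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("Welch t(%.2f) = %.2f, p = %.4g\n", x$df, x$t, x$p))
  invisible(x)
}

#' Welch t-test between per-subject rates in a summary table
#'
#' Builds the two per-subject percentage vectors named by the contrast
#' from the overall rows of a [summarize_subjects()] table and
#' delegates to [welch_t()]. `"report2_vs_commission"` compares
#' illusion-report rates with catch-trial error rates;
#' `"report2_vs_omission"` with omission-error rates.
#'
#' @param summaries A subject-summary tibble.
#' @param contrast Which rate pair to compare.
#' @return A `welch_result`.
#' @export
welch_t_from_summaries <- function(summaries,
                                   contrast = c("report2_vs_commission",
                                                "report2_vs_omission")) {
  contrast <- match.arg(contrast)
  ov <- summaries[summaries$level == "overall", ]
  if (nrow(ov) < 2) stop("need at least 2 participants per side")
  other <- if (contrast == "report2_vs_commission") ov$pct_commission else
    ov$pct_omission
  if (anyNA(other)) stop("contrast rate undefined (no catch trials?)")
  welch_t(ov$pct_report2, other)
}

#' Simple linear regression with R-squared and F
#'
#' Ordinary least squares of a response on a single predictor — in this
#' workflow, per-subject-per-level mean percentages on the condition
#' value, pooling subject-by-level points (the unit of analysis that
#' reproduces the published error degrees of freedom). Fitting is
#' delegated to [stats::lm()]; the returned summary carries slope,
#' intercept, R-squared, and the F test with df (1, N - 2).
#'
#' @param x Predictor (condition values), not constant.
#' @param y Response (mean percentages), same length.
#' @return A `regression_result` list: `slope`, `intercept`,
#'   `r_squared`, `f`, `df_num` (1), `df_den`, `p`, `n`.
#' @export
simple_regression <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 points")
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0) {
    stop("x is constant; slope is undefined")
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  f <- unname(sm$fstatistic)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared,
         f = f[1], df_num = as.integer(f[2]), df_den = as.integer(f[3]),
         p = stats::pf(f[1], f[2], f[3], lower.tail = FALSE),
         n = length(x)),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS: slope = %.4g, R^2 = %.3f, F(%d, %d) = %.2f, p = %.4g\n",
              x$slope, x$r_squared, x$df_num, x$df_den, x$f, x$p))
  invisible(x)
}

#' One-way analysis of variance
#'
#' Between/within decomposition over two or more groups, fitted with
#' [stats::lm()]/[stats::anova()]. In this workflow the observations
#' are per-subject per-block mean percentages.
#'
#' @param groups A list of numeric vectors (one per group), each with
#'   at least 2 values.
#' @return An `anova_result` list: `f`, `df_between`, `df_within`, `p`,
#'   `ss_between`, `ss_within`, `ss_total`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 values (group ",
         paste(which(sizes < 2), collapse = ", "), " too small)")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  tab <- stats::anova(stats::lm(y ~ g))
  structure(
    list(f = tab$`F value`[1],
         df_between = tab$Df[1], df_within = tab$Df[2],
         p = tab$`Pr(>F)`[1],
         ss_between = tab$`Sum Sq`[1], ss_within = tab$`Sum Sq`[2],
         ss_total = sum(tab$`Sum Sq`)),
    class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.4g\n",
              x$df_between, x$df_within, x$f, x$p))
  invisible(x)
}

#' Approximate Bayes factor (BIC approximation)
#'
#' Evidence for an effect of a single predictor, computed as
#' `BF10 = exp((BIC_null - BIC_alt) / 2)` from the two nested linear
#' models `y ~ 1` and `y ~ x`. This is the standard unit-information
#' BIC approximation; it is labelled as such in the result because
#' Bayes factors are sensitive to the (here implicit) prior on the
#' effect, and BIC-based values can differ substantially from other
#' conventions. `BF10 < 1` favours the null.
#'
#' @param y Response values.
#' @param x Predictor: a factor/character (ANOVA-style) or numeric
#'   (regression-style) of the same length.
#' @return A `bayes_factor_result` list: `bf10`, `bic_null`,
#'   `bic_alt`, `method` (`"BIC approximation"`).
#' @export
approx_bayes_factor <- function(y, x) {
  stopifnot(is.numeric(y), length(y) == length(x))
  if (is.character(x)) x <- factor(x)
  fit0 <- stats::lm(y ~ 1)
  fit1 <- stats::lm(y ~ x)
  b0 <- stats::BIC(fit0)
  b1 <- stats::BIC(fit1)
  structure(list(bf10 = exp((b0 - b1) / 2), bic_null = b0, bic_alt = b1,
                 method = "BIC approximation"),
            class = "bayes_factor_result")
}

#' @export
print.bayes_factor_result <- function(x, ...) {
  cat(sprintf("BF10 = %.4g (%s)\n", x$bf10, x$method))
  invisible(x)
}
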