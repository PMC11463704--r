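#' Posterior distribution of population prevalence
#'
#' Given that `k_sig` of `n` participants individually reached
#' significance, two posteriors over the population prevalence
#' `gamma` (the fraction of the population in whom the effect is
#' genuinely present) are available:
#'
#' * `"simple_beta"` — the descriptive recipe of adding one to each
#'   count: `Beta(1 + k_sig, 1 + n - k_sig)`.
#' * `"test_calibrated"` (default) — accounts for the per-subject
#'   test's false-positive rate `alpha_fp`: a subject's test is
#'   significant with probability `theta = alpha_fp +
#'   (1 - alpha_fp) * gamma` (a genuine perceiver is assumed detected
#'   with probability ~1; a non-perceiver triggers a false positive
#'   with probability `alpha_fp`). With a uniform prior on `gamma` the
#'   posterior density is proportional to
#'   `theta^k (1 - theta)^(n - k)` on `gamma` in \[0, 1\] — a beta
#'   density in `theta` truncated to `theta >= alpha_fp` and mapped
#'   linearly back to the `gamma` scale.
#'
#' The two models coincide when `alpha_fp = 0`.
#'
#' @param k_sig Number of individually significant participants.
#' @param n Number of participants tested (`n >= 1`).
#' @param model `"test_calibrated"` or `"simple_beta"`.
#' @param alpha_fp Per-test false-positive rate in \[0, 1);
#'   ignored by `"simple_beta"`.
#' @return A `prevalence_posterior` object with elements `k_sig`, `n`,
#'   `model`, `alpha_fp`, `shape1`, `shape2` (beta shapes on the
#'   `theta` scale), and `density` (vectorized density function of
#'   `gamma`, normalized on \[0, 1\]).
#' @examples
#' post <- prevalence_posterior(24, 45)
#' map_estimate(post)           # 0.509
#' hpdi(post, 0.96)             # c(0.352, 0.661)
#' @export
prevalence_posterior <- function(k_sig, n,
                                 model = c("test_calibrated", "simple_beta"),
                                 alpha_fp = 0.05) {
  model <- match.arg(model)
  stopifnot(length(k_sig) == 1L, length(n) == 1L,
            k_sig == floor(k_sig), n == floor(n), k_sig >= 0)
  if (n < 1) stop("n must be at least 1 (no participants, no posterior)")
  if (k_sig > n) stop("k_sig (", k_sig, ") must not exceed n (", n, ")")
  if (alpha_fp < 0 || alpha_fp >= 1) stop("alpha_fp must lie in [0, 1)")
  if (model == "simple_beta") alpha_fp <- 0
  s1 <- k_sig + 1
  s2 <- n - k_sig + 1
  a <- alpha_fp
  # P(theta > alpha_fp) under Beta(s1, s2): normalizer of the truncation
  tail_mass <- stats::pbeta(a, s1, s2, lower.tail = FALSE)
  density <- function(gamma) {
    out <- numeric(length(gamma))
    ok <- gamma >= 0 & gamma <= 1
    th <- a + (1 - a) * gamma[ok]
    out[ok] <- stats::dbeta(th, s1, s2) * (1 - a) / tail_mass
    out
  }
  cdf <- function(gamma) {
    th <- a + (1 - a) * pmin(pmax(gamma, 0), 1)
    (stats::pbeta(th, s1, s2) - stats::pbeta(a, s1, s2)) / tail_mass
  }
  structure(
    list(k_sig = as.integer(k_sig), n = as.integer(n), model = model,
         alpha_fp = alpha_fp, shape1 = s1, shape2 = s2,
         density = density, cdf = cdf),
    class = "prevalence_posterior")
}

#' @export
print.prevalence_posterior <- function(x, ...) {
  cat("Prevalence posterior (", x$model, "): k_sig = ", x$k_sig,
      ", n = ", x$n, sep = "")
  if (x$model == "test_calibrated") cat(", alpha_fp = ", x$alpha_fp, sep = "")
  cat("\n  Beta(", x$shape1, ", ", x$shape2, ") on theta",
      if (x$alpha_fp > 0) paste0(", truncated to theta >= ", x$alpha_fp),
      "\n", sep = "")
  cat("  MAP = ", round(map_estimate(x), 4),
      ", posterior mean = ", round(posterior_mean(x), 4), "\n", sep = "")
  invisible(x)
}

#' Maximum a posteriori prevalence
#'
#' Closed-form mode of the prevalence posterior. For `simple_beta`,
#' the usual beta mode `(shape1 - 1) / (shape1 + shape2 - 2)` (boundary
#' modes 0 and 1 when a shape equals 1; for the flat `Beta(1, 1)` case
#' `n = 0` is rejected at construction). For `test_calibrated`,
#' `max(0, (k_sig/n - alpha_fp) / (1 - alpha_fp))`: the mode on the
#' `theta` scale is `k_sig/n`, mapped back to `gamma` and clamped at 0
#' when the observed significance rate is below the false-positive
#' rate.
#'
#' @param p A [prevalence_posterior()].
#' @return The posterior mode in \[0, 1\].
#' @export
map_estimate <- function(p) {
  stopifnot(inherits(p, "prevalence_posterior"))
  theta_mode <- p$k_sig / p$n
  max(0, (theta_mode - p$alpha_fp) / (1 - p$alpha_fp))
}

#' Posterior mean prevalence
#'
#' The mean of the prevalence posterior, by numerical quadrature for
#' the truncated (test-calibrated) model and in closed form
#' `shape1 / (shape1 + shape2)` for the simple beta. Reported alongside
#' the MAP because for boundary cases (no significant participants:
#' `Beta(1, n + 1)`) the mode is 0 while the mean `1/(n + 2)` is the
#' small nonzero summary sometimes quoted.
#'
#' @param p A [prevalence_posterior()].
#' @return Posterior mean in \[0, 1\].
#' @export
posterior_mean <- function(p) {
  stopifnot(inherits(p, "prevalence_posterior"))
  if (p$alpha_fp == 0) return(p$shape1 / (p$shape1 + p$shape2))
  stats::integrate(function(g) g * p$density(g), 0, 1,
                   rel.tol = 1e-10)$value
}

#' Highest posterior density interval
#'
#' The shortest interval containing `mass` of the posterior: a
#' horizontal threshold on the density is bisected until the enclosed
#' probability matches `mass`, with the interval endpoints located by
#' root-finding on each side of the mode. When the density is monotone
#' near a boundary (all-or-none significance counts) the corresponding
#' endpoint clamps to 0 or 1. Interval probabilities use the posterior's
#' closed-form CDF, so the mass constraint is satisfied to root-finding
#' tolerance rather than quadrature error.
#'
#' @param p A [prevalence_posterior()].
#' @param mass Interval probability in (0, 1); 0.96 by convention for
#'   prevalence reporting.
#' @return Numeric vector `c(low, high)`.
#' @export
hpdi <- function(p, mass = 0.96) {
  stopifnot(inherits(p, "prevalence_posterior"),
            is.numeric(mass), mass > 0, mass < 1)
  mode <- map_estimate(p)
  peak <- p$density(mode)
  if (!is.finite(peak) || peak <= 0) stop("degenerate posterior density")
  ends_at <- function(h) {
    lo <- if (mode <= 0 || p$density(0) >= h) 0 else
      stats::uniroot(function(g) p$density(g) - h, c(0, mode),
                     tol = 1e-12)$root
    hi <- if (mode >= 1 || p$density(1) >= h) 1 else
      stats::uniroot(function(g) p$density(g) - h, c(mode, 1),
                     tol = 1e-12)$root
    c(lo, hi)
  }
  excess <- function(h) {
    e <- ends_at(h)
    (p$cdf(e[2]) - p$cdf(e[1])) - mass
  }
  h <- stats::uniroot(excess, c(peak * 1e-12, peak * (1 - 1e-12)),
                      tol = 1e-13)$root
  ends_at(h)
}

#' Point estimate with uncertainty for population prevalence
#'
#' Bundles the MAP and the highest-posterior-density interval for one
#' significance count.
#'
#' @inheritParams prevalence_posterior
#' @param mass HPDI probability (default 0.96).
#' @return A `prevalence_estimate` list: `map`, `hpdi_low`,
#'   `hpdi_high`, `hpdi_mass`, `posterior`.
#' @examples
#' prevalence_estimate(24, 45)   # MAP 0.51, 96% HPDI [0.35, 0.66]
#' @export
prevalence_estimate <- function(k_sig, n,
                                model = c("test_calibrated", "simple_beta"),
                                alpha_fp = 0.05, mass = 0.96) {
  post <- prevalence_posterior(k_sig, n, model, alpha_fp)
  ci <- hpdi(post, mass)
  structure(
    list(map = map_estimate(post), hpdi_low = ci[1], hpdi_high = ci[2],
         hpdi_mass = mass, posterior = post),
    class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat("Population prevalence: MAP = ", sprintf("%.2f", x$map),
      " (", x$hpdi_mass * 100, "% HPDI = [",
      sprintf("%.2f", x$hpdi_low), ", ",
      sprintf("%.2f", x$hpdi_high), "])\n", sep = "")
  cat("  full precision: map ", format(x$map, digits = 10), ", hpdi [",
      format(x$hpdi_low, digits = 10), ", ",
      format(x$hpdi_high, digits = 10), "]  (",
      x$posterior$model, ", k = ", x$posterior$k_sig, ", n = ",
      x$posterior$n, ")\n", sep = "")
  invisible(x)
}

#' Prevalence estimates across condition levels
#'
#' One prevalence estimate per condition level plus the overall count —
#' the per-manipulation posterior summary used to compare prevalence
#' across frame speeds or flash opacities.
#'
#' @param counts Tibble with columns `level`, `k_sig`, `n` (e.g. from
#'   [significance_counts()]).
#' @inheritParams prevalence_estimate
#' @return Tibble with columns `level`, `k_sig`, `n`, `model`, `map`,
#'   `hpdi_low`, `hpdi_high`, `hpdi_mass`.
#' @export
prevalence_curve <- function(counts,
                             model = c("test_calibrated", "simple_beta"),
                             alpha_fp = 0.05, mass = 0.96) {
  model <- match.arg(model)
  stopifnot(all(c("level", "k_sig", "n") %in% names(counts)))
  est <- lapply(seq_len(nrow(counts)), function(i) {
    e <- prevalence_estimate(counts$k_sig[i], counts$n[i], model,
                             alpha_fp, mass)
    tibble::tibble(level = counts$level[i], k_sig = counts$k_sig[i],
                   n = counts$n[i], model = model, map = e$map,
                   hpdi_low = e$hpdi_low, hpdi_high = e$hpdi_high,
                   hpdi_mass = mass)
  })
  dplyr::bind_rows(est)
}

#' Posterior density on a prevalence grid
#'
#' Evaluates the posterior density on an equally spaced `gamma` grid,
#' for export and plotting of prevalence curves.
#'
#' @param p A [prevalence_posterior()].
#' @param n_grid Number of grid points (default 1001).
#' @return Tibble with columns `gamma`, `density`.
#' @export
posterior_grid <- function(p, n_grid = 1001) {
  stopifnot(inherits(p, "prevalence_posterior"), n_grid >= 2)
  gamma <- seq(0, 1, length.out = n_grid)
  tibble::tibble(gamma = gamma, density = p$density(gamma))
}
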