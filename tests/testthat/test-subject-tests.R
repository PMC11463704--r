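test_that("subject summaries reproduce hand-computed counts and rates", {
  trials <- dplyr::bind_rows(
    hand_trials("P1", n2 = 30, n0 = 8, n1 = 250, catch_hit = 0,
                catch_miss = 72),
    hand_trials("P2", n2 = 5, n0 = 0, n1 = 283, catch_hit = 6,
                catch_miss = 66),
    hand_trials("P3", n2 = 0, n0 = 2, n1 = 286, catch_hit = 1,
                catch_miss = 71))
  d <- study_design(
    design_id = "fix", n_participants = 3L,
    factor_name = "frame_speed", factor_unit = "deg/s",
    baseline_kind = "commission",
    levels = tibble::tibble(condition = 5, n_experimental = 288L,
                            n_catch = 72L))
  s <- summarize_subjects(trials, d)
  ov <- s[s$level == "overall", ]
  expect_equal(ov$n_experimental, rep(288L, 3))
  expect_equal(ov$n_report2, c(30L, 5L, 0L))
  expect_equal(ov$pct_report2, 100 * c(30, 5, 0) / 288)
  expect_equal(round(ov$pct_report2[1], 2), 10.42)
  expect_equal(ov$pct_commission, 100 * c(0, 6, 1) / 72)
  expect_equal(ov$n_omission, c(8L, 0L, 2L))
  # per-level rows exist and agree with the overall for a 1-level design
  lv <- s[s$level != "overall", ]
  expect_equal(lv$n_report2, ov$n_report2)
})

test_that("a participant with zero experimental trials is named in the error", {
  d <- tiny_design(n_participants = 1L)
  bad <- hand_trials("P9", n2 = 0, n0 = 0, n1 = 0, catch_hit = 1,
                     catch_miss = 4)
  expect_error(summarize_subjects(bad, d), "P9")
})

test_that("upper-tail binomial p-values match frozen and boundary values", {
  expect_identical(binom_test_upper(0, 45, 0.05), 1)
  expect_equal(binom_test_upper(45, 45, 0.05), 0.05^45)
  # brute-force pmf sum of Binomial(10, 0.5) from 5 to 10 = 0.623046875
  expect_equal(binom_test_upper(5, 10, 0.5), 0.623046875)
  expect_equal(binom_test_upper(5, 10, 0.5), brute_tail(5, 10, 0.5))
  expect_error(binom_test_upper(5, 4, 0.1), "exceed")
  expect_error(binom_test_upper(-1, 4, 0.1), "non-negative")
  expect_error(binom_test_upper(1, 4, 1.1), "\\[0, 1\\]")
})

test_that("exact tails agree with the brute-force oracle up to n = 1000", {
  set.seed(4)
  for (n in c(1, 7, 45, 288, 600, 1000)) {
    ks <- unique(c(0, 1, n, sort(sample.int(n, min(n, 12)))))
    for (p0 in c(0.0327, 0.05, 0.5, 0.93)) {
      expect_equal(binom_test_upper(ks, n, p0),
                   vapply(ks, brute_tail, numeric(1), n = n, p0 = p0),
                   tolerance = 1e-12)
    }
  }
})

test_that("p-values are monotone in k and in p0", {
  n <- 288
  p <- binom_test_upper(0:n, n, 0.0327)
  expect_true(all(diff(p) <= 0))
  p0s <- seq(0.01, 0.99, by = 0.01)
  pk <- binom_test_upper(30, n, p0s)
  expect_true(all(diff(pk) >= 0))
})

test_that("pooled baseline weights by trials, not by subject rates", {
  trials <- dplyr::bind_rows(
    hand_trials("P1", n2 = 60, n0 = 0, n1 = 228, catch_hit = 0,
                catch_miss = 72),
    hand_trials("P2", n2 = 0, n0 = 0, n1 = 288, catch_hit = 7,
                catch_miss = 65))
  d <- study_design(
    design_id = "fix", n_participants = 2L,
    factor_name = "frame_speed", factor_unit = "deg/s",
    baseline_kind = "commission",
    levels = tibble::tibble(condition = 5, n_experimental = 288L,
                            n_catch = 72L))
  s <- summarize_subjects(trials, d)
  res <- flag_significant(s, baseline_spec("commission"))
  expect_equal(res$p0, 7 / 144)           # total errors / total catch
  res2 <- flag_significant(s, baseline_spec("commission",
                                            pooling = "mean_of_rates"))
  expect_equal(res2$p0, mean(c(0, 7 / 72)))
  # 60/288 ~ 20.8% against ~4.9% baseline: clearly significant
  ovp <- res$summaries$p_value[res$summaries$level == "overall"]
  expect_lt(ovp[1], 0.05)
  expect_identical(res$k_sig, 1L)
  expect_identical(res$n, 2L)
})

test_that("a subject at 60/288 against p0 = 0.0327 is flagged significant", {
  p <- binom_test_upper(60, 288, 0.0327)
  expect_lt(p, 0.05)
  expect_equal(p, brute_tail(60, 288, 0.0327), tolerance = 1e-12)
})

test_that("all-zero report counts give k_sig = 0", {
  trials <- dplyr::bind_rows(lapply(c("P1", "P2", "P3"), function(id) {
    hand_trials(id, n2 = 0, n0 = 1, n1 = 9, catch_hit = 1, catch_miss = 4)
  }))
  d <- tiny_design(n_participants = 3L)
  d$levels <- d$levels[1, ]
  s <- summarize_subjects(trials, d)
  res <- flag_significant(s, baseline_spec("commission"))
  expect_identical(res$k_sig, 0L)
})

test_that("a zero baseline with nonzero reports warns and flags", {
  trials <- dplyr::bind_rows(
    hand_trials("P1", n2 = 3, n0 = 0, n1 = 7, catch_hit = 0,
                catch_miss = 5),
    hand_trials("P2", n2 = 0, n0 = 0, n1 = 10, catch_hit = 0,
                catch_miss = 5))
  d <- tiny_design(n_participants = 2L)
  d$levels <- d$levels[1, ]
  s <- summarize_subjects(trials, d)
  expect_warning(res <- flag_significant(s, baseline_spec("commission")),
                 "p0 = 0")
  expect_identical(res$k_sig, 1L)
})

test_that("omission baselines and strict commission counting are honoured", {
  trials <- dplyr::bind_rows(
    hand_trials("P1", n2 = 4, n0 = 2, n1 = 14),
    hand_trials("P2", n2 = 0, n0 = 3, n1 = 17))
  d <- study_design(
    design_id = "fix2", n_participants = 2L,
    factor_name = "frame_speed", factor_unit = "deg/s",
    baseline_kind = "omission",
    levels = tibble::tibble(condition = 5, n_experimental = 20L,
                            n_catch = 0L))
  s <- summarize_subjects(trials, d)
  res <- flag_significant(s, baseline_spec("omission"))
  expect_equal(res$p0, 5 / 40)
  expect_error(flag_significant(s, baseline_spec("commission")),
               "no catch trials")
})

test_that("per-level testing reuses the overall pooled baseline", {
  d <- tiny_design(n_participants = 4L, n_exp = 30L, n_catch = 10L)
  pr <- draw_population(population_model(gamma = 0.5), d, seed = 8)
  tr <- simulate_trials(pr, d, seed = 9)
  s <- summarize_subjects(tr, d)
  res <- flag_significant(s, baseline_spec("commission"), per_level = TRUE)
  expect_false(anyNA(res$summaries$p_value))
  # per-level p-values recompute from counts with the shared p0
  lv <- res$summaries[res$summaries$level != "overall", ]
  expect_equal(lv$p_value,
               binom_test_upper(lv$n_report2, lv$n_experimental, res$p0))
  counts <- significance_counts(res)
  expect_identical(sort(unique(counts$level)),
                   sort(unique(res$summaries$level)))
  expect_true(all(counts$n == 4L))
})
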