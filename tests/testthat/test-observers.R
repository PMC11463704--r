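test_that("degenerate prevalence yields all-or-none perceiver populations", {
  d <- tiny_design(n_participants = 20L)
  p0 <- draw_population(population_model(gamma = 0), d, seed = 1)
  expect_false(any(p0$is_perceiver))
  # non-perceivers report two at their own commission-style rate
  expect_equal(vapply(seq_len(nrow(p0)),
                      function(i) unname(p0$p_report2[[i]][1]),
                      numeric(1)),
               p0$p_commission)
  expect_true(all(vapply(p0$p_report2,
                         function(p) length(unique(p)) == 1L, logical(1))))
  p1 <- draw_population(population_model(gamma = 1), d, seed = 1)
  expect_true(all(p1$is_perceiver))
})

test_that("perceiver counts follow binomial moments across seeds", {
  d <- tiny_design(n_participants = 45L)
  m <- population_model(gamma = 0.5)
  counts <- vapply(1:1000, function(s) {
    sum(draw_population(m, d, seed = s)$is_perceiver)
  }, numeric(1))
  se <- sqrt(45 * 0.5 * 0.5 / 1000)
  expect_lt(abs(mean(counts) - 22.5), 3 * se)
})

test_that("probabilities respect their bounds and joint constraint", {
  d <- builtin_design("exp1a")
  pr <- draw_population(population_model(), d, seed = 3)
  all_p2 <- unlist(pr$p_report2)
  expect_true(all(all_p2 >= 0 & all_p2 <= 1))
  expect_true(all(pr$p_commission >= 0 & pr$p_commission <= 1))
  expect_true(all(pr$p_omission >= 0 & pr$p_omission <= 1))
  maxp2 <- vapply(pr$p_report2, max, numeric(1))
  expect_true(all(maxp2 + pr$p_omission <= 1))
  expect_error(population_model(gamma = 1.2), "\\[0, 1\\]")
  expect_error(population_model(commission_spread = -1), "non-negative")
})

test_that("trial counts match the design exactly for every participant", {
  for (id in c("exp1a", "exp2a")) {
    d <- builtin_design(id)
    pr <- draw_population(population_model(), d, seed = 5)
    tr <- simulate_trials(pr, d, seed = 6)
    expect_identical(nrow(tr), d$n_participants *
                       sum(d$levels$n_experimental + d$levels$n_catch))
    got <- tr |>
      dplyr::count(.data$participant_id, .data$level, .data$trial_type) |>
      tidyr::pivot_wider(names_from = "trial_type", values_from = "n",
                         values_fill = 0L)
    if (!"catch" %in% names(got)) got$catch <- 0L
    want <- d$levels[match(got$level, d$levels$level), ]
    expect_equal(got$experimental, want$n_experimental,
                 ignore_attr = TRUE)
    expect_equal(got$catch, want$n_catch, ignore_attr = TRUE)
  }
})

test_that("simulation is reproducible from the seed and varies across seeds", {
  d <- tiny_design()
  pr <- draw_population(population_model(), d, seed = 11)
  t1 <- simulate_trials(pr, d, seed = 12)
  t2 <- simulate_trials(pr, d, seed = 12)
  expect_identical(t1, t2)
  t3 <- simulate_trials(pr, d, seed = 13)
  expect_false(identical(t1$response, t3$response))
  # byte-identical CSV round trip
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trials(t1, f1); write_trials(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(read_trials(f1), t1)
})

test_that("deterministic observer profiles produce deterministic responses", {
  d <- tiny_design(n_participants = 1L)
  pr <- draw_population(population_model(gamma = 1, p_report2 = 1,
                                         commission_mean = 0,
                                         commission_spread = 0,
                                         omission_mean = 0,
                                         omission_spread = 0),
                        d, seed = 1)
  tr <- simulate_trials(pr, d, seed = 2)
  expect_true(all(tr$response[tr$trial_type == "experimental"] == 2L))
  expect_true(all(tr$response[tr$trial_type == "catch"] == 0L))

  pr0 <- draw_population(population_model(gamma = 1, p_report2 = 0,
                                          commission_mean = 0,
                                          commission_spread = 0,
                                          omission_mean = 0,
                                          omission_spread = 0),
                         d, seed = 1)
  tr0 <- simulate_trials(pr0, d, seed = 2)
  expect_true(all(tr0$response[tr0$trial_type == "experimental"] == 1L))

  # commission errors default to a one-dot report; the two-dot split is a
  # model parameter
  prc <- draw_population(population_model(gamma = 0, commission_mean = 0.999,
                                          commission_spread = 0,
                                          nonperceiver_report2 = 0,
                                          omission_mean = 0,
                                          omission_spread = 0),
                         d, seed = 1)
  trc <- simulate_trials(prc, d, seed = 2)
  expect_true(all(trc$response[trc$trial_type == "catch"] == 1L))
  trc2 <- simulate_trials(prc, d, seed = 2, two_dot_commission = 1)
  expect_true(all(trc2$response[trc2$trial_type == "catch"] == 2L))
})

test_that("report-two counts follow binomial moments at a fixed level", {
  d <- study_design(
    design_id = "one_level", n_participants = 1L,
    factor_name = "frame_speed", factor_unit = "deg/s",
    baseline_kind = "commission",
    levels = tibble::tibble(condition = 10, n_experimental = 32L,
                            n_catch = 0L))
  pr <- draw_population(population_model(gamma = 1, p_report2 = 0.3,
                                         omission_mean = 0,
                                         omission_spread = 0),
                        d, seed = 1)
  counts <- vapply(1:2000, function(s) {
    tr <- simulate_trials(pr, d, seed = s)
    sum(tr$response == 2L)
  }, numeric(1))
  se <- sqrt(32 * 0.3 * 0.7 / 2000)
  expect_lt(abs(mean(counts) - 9.6), 3 * se)
})

test_that("profile/design mismatch and malformed tables are rejected", {
  d1 <- tiny_design(); d2 <- builtin_design("exp1a")
  pr <- draw_population(population_model(), d1, seed = 1)
  expect_error(simulate_trials(pr, d2, seed = 1), "drawn for design")

  tr <- simulate_trials(pr, d1, seed = 1)
  tr$response[4] <- 3L
  expect_error(validate_trials(tr), "row 4")
  tr$response[4] <- 1L
  tr$n_presented[7] <- 1L  # catch trial with a target
  if (tr$trial_type[7] != "catch") tr$trial_type[7] <- "catch"
  expect_error(validate_trials(tr), "catch trial")
})
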