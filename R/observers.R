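#' Population model for the perceiver / non-perceiver mixture
#'
#' The simulator assumes the statistical structure the prevalence
#' analysis is built to detect: a fraction `gamma` of the population
#' ("perceivers") report the illusion (two targets) above their own
#' error baseline, while the remaining subjects report two targets only
#' at their commission-style error rate. Per-subject error rates are
#' drawn from beta distributions reparameterized by mean and spread
#' (standard deviation), which keeps them bounded in \[0, 1\] with
#' direct moment control.
#'
#' A perceiver's probability of reporting two targets follows a
#' logistic (saturating) link in the condition value,
#' `plogis(link_intercept + link_slope * condition)`, increasing in
#' frame speed and in flash opacity by default. Passing `p_report2`
#' overrides the link with a constant probability (useful for power and
#' recovery studies). The default link coefficients are illustrative —
#' chosen to give perceiver report rates of roughly 8–25% across each
#' design's condition range, the order of magnitude seen in group
#' summaries of this paradigm — not estimates.
#'
#' @param gamma True population prevalence of perceivers, in \[0, 1\].
#' @param link_intercept,link_slope Logistic-link coefficients on the
#'   condition scale; `NULL` selects a per-factor default
#'   (frame_speed: -2.6 + 0.04 v; flash_opacity: -3.4 + 0.02 v).
#' @param p_report2 Optional constant report-two probability for
#'   perceivers, overriding the link.
#' @param nonperceiver_report2 Optional constant report-two probability
#'   for non-perceivers; by default each non-perceiver reports two at
#'   their own commission-style error rate.
#' @param commission_mean,commission_spread Mean and SD of the
#'   between-subject distribution of the catch-trial commission rate
#'   (reporting at least one target when none was shown).
#' @param omission_mean,omission_spread Likewise for the omission rate
#'   (reporting zero targets when one was shown).
#' @param two_dot_commission Probability that a commission error on a
#'   catch trial is reported as *two* targets rather than one. Defaults
#'   to 0: subjects in this paradigm describe defaulting to "one dot"
#'   when discrimination is hard.
#' @param flash_above_prob For designs with randomized flash location,
#'   probability the flash appears above fixation (default 0.5).
#' @return A `population_model` list.
#' @export
population_model <- function(gamma = 0.5,
                             link_intercept = NULL, link_slope = NULL,
                             p_report2 = NULL,
                             nonperceiver_report2 = NULL,
                             commission_mean = 0.033,
                             commission_spread = 0.04,
                             omission_mean = 0.03,
                             omission_spread = 0.03,
                             two_dot_commission = 0,
                             flash_above_prob = 0.5) {
  m <- structure(
    list(gamma = gamma,
         link_intercept = link_intercept, link_slope = link_slope,
         p_report2 = p_report2,
         nonperceiver_report2 = nonperceiver_report2,
         commission_mean = commission_mean,
         commission_spread = commission_spread,
         omission_mean = omission_mean,
         omission_spread = omission_spread,
         two_dot_commission = two_dot_commission,
         flash_above_prob = flash_above_prob),
    class = "population_model")
  validate_population_model(m)
  m
}

validate_population_model <- function(m, design = NULL) {
  chk01 <- function(x, nm) {
    if (!is.null(x) && (!is.numeric(x) || any(x < 0 | x > 1))) {
      stop("population_model: ", nm, " must lie in [0, 1]")
    }
  }
  chk01(m$gamma, "gamma")
  chk01(m$p_report2, "p_report2")
  chk01(m$nonperceiver_report2, "nonperceiver_report2")
  chk01(m$commission_mean, "commission_mean")
  chk01(m$omission_mean, "omission_mean")
  chk01(m$two_dot_commission, "two_dot_commission")
  chk01(m$flash_above_prob, "flash_above_prob")
  if (m$commission_spread < 0 || m$omission_spread < 0) {
    stop("population_model: spreads must be non-negative")
  }
  if (!is.null(design)) {
    p2 <- perceiver_link_probs(m, design)
    if (any(p2 < 0 | p2 > 1)) {  # plogis guarantees this; guard anyway
      stop("population_model: implied p_report2 outside [0, 1] for design ",
           design$design_id)
    }
  }
  invisible(m)
}

# default logistic link by manipulated factor
default_link <- function(factor_name) {
  switch(factor_name,
    frame_speed   = c(intercept = -2.6, slope = 0.04),
    flash_opacity = c(intercept = -3.4, slope = 0.02),
    c(intercept = -2.6, slope = 0))
}

perceiver_link_probs <- function(model, design) {
  if (!is.null(model$p_report2)) {
    return(rep(model$p_report2, nrow(design$levels)))
  }
  def <- default_link(design$factor_name)
  a <- model$link_intercept %||% def[["intercept"]]
  b <- model$link_slope %||% def[["slope"]]
  stats::plogis(a + b * design$levels$condition)
}

# beta draw parameterized by mean and standard deviation; spread 0 is
# degenerate at the mean, and s^2 >= m(1-m) is rejected (no valid beta)
rbeta_ms <- function(n, mean, spread) {
  if (spread == 0 || mean %in% c(0, 1)) return(rep(mean, n))
  v <- spread^2
  if (v >= mean * (1 - mean)) {
    stop("spread ", spread, " too large for a beta with mean ", mean)
  }
  kappa <- mean * (1 - mean) / v - 1
  stats::rbeta(n, mean * kappa, (1 - mean) * kappa)
}

#' Draw a population of simulated observers
#'
#' Each of the design's participants is independently a perceiver with
#' probability `model$gamma`. Perceivers get level-wise report-two
#' probabilities from the model's link; non-perceivers report two at
#' their own commission-style error rate (constant across levels).
#' Per-subject commission and omission rates are drawn from the model's
#' beta distributions; the omission rate is truncated so that
#' `p_report2 + p_omission <= 1` holds at every level.
#'
#' @param model A [population_model()].
#' @param design A [study_design].
#' @param seed Integer seed; the draw is fully reproducible from it.
#' @return A tibble of class `observer_profiles` with one row per
#'   participant: `participant_id`, `is_perceiver`, `p_commission`,
#'   `p_omission`, and `p_report2` (list-column, one probability per
#'   design level, named by level).
#' @export
draw_population <- function(model, design, seed) {
  stopifnot(inherits(model, "population_model"),
            inherits(design, "study_design"))
  validate_population_model(model, design)
  set.seed(as.integer(seed))
  n <- design$n_participants
  is_perceiver <- stats::runif(n) < model$gamma
  p_comm <- rbeta_ms(n, model$commission_mean, model$commission_spread)
  p_omit <- rbeta_ms(n, model$omission_mean, model$omission_spread)
  link_p <- perceiver_link_probs(model, design)
  p2 <- lapply(seq_len(n), function(i) {
    p <- if (is_perceiver[i]) {
      link_p
    } else {
      rep(model$nonperceiver_report2 %||% p_comm[i], nrow(design$levels))
    }
    stats::setNames(p, design$levels$level)
  })
  p_omit <- pmin(p_omit, 1 - vapply(p2, max, numeric(1)))
  out <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    is_perceiver = is_perceiver,
    p_commission = p_comm,
    p_omission = p_omit,
    p_report2 = p2)
  attr(out, "design_id") <- design$design_id
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("observer_profiles", class(out))
  out
}

#' Simulate a trial table from observer profiles
#'
#' Generates, per participant, exactly the design's experimental and
#' catch trial counts at every condition level, in an order randomized
#' within participant. On experimental trials (one target shown) the
#' response is 2 with the profile's level-wise `p_report2`, 0 with
#' `p_omission`, else 1. On catch trials (no target) the response is
#' nonzero with `p_commission`; a nonzero commission is 2 with the
#' model-level `two_dot_commission` probability carried in
#' `two_dot_commission`, else 1. Responses are independent across
#' trials.
#'
#' @param profiles An `observer_profiles` tibble from
#'   [draw_population()].
#' @param design The same [study_design] the profiles were drawn for.
#' @param seed Integer seed; the table is byte-identical across runs
#'   with the same inputs.
#' @param two_dot_commission Probability a catch-trial commission error
#'   reports two targets (default 0).
#' @param flash_above_prob For designs without catch trials (randomized
#'   flash location), probability the flash is above fixation.
#' @return Tibble with one row per trial: `participant_id`,
#'   `design_id`, `level`, `condition`, `block`, `trial_type`
#'   (`"experimental"`/`"catch"`), `n_presented` (0 or 1),
#'   `response` (0/1/2), `flash_position`, `trial_index`.
#' @export
simulate_trials <- function(profiles, design, seed,
                            two_dot_commission = 0,
                            flash_above_prob = 0.5) {
  stopifnot(inherits(profiles, "observer_profiles"),
            inherits(design, "study_design"))
  if (!identical(attr(profiles, "design_id"), design$design_id)) {
    stop("profiles were drawn for design '", attr(profiles, "design_id"),
         "', not '", design$design_id, "'")
  }
  set.seed(as.integer(seed))
  lv <- design$levels
  # one participant's trial skeleton, reused for all
  skel <- tibble::tibble(
    level = rep(lv$level, lv$n_experimental + lv$n_catch),
    condition = rep(lv$condition, lv$n_experimental + lv$n_catch),
    block = rep(lv$block, lv$n_experimental + lv$n_catch),
    trial_type = unlist(lapply(seq_len(nrow(lv)), function(i) {
      rep(c("experimental", "catch"), c(lv$n_experimental[i], lv$n_catch[i]))
    })))
  n_per <- nrow(skel)
  n_sub <- nrow(profiles)
  trials <- skel[rep(seq_len(n_per), n_sub), ]
  trials$participant_id <- rep(profiles$participant_id, each = n_per)
  trials$design_id <- design$design_id
  trials$n_presented <- ifelse(trials$trial_type == "experimental", 1L, 0L)

  # level-wise report-two probability for each trial's participant
  p2_mat <- do.call(rbind, profiles$p_report2)      # n_sub x n_levels
  lev_idx <- match(trials$level, lv$level)
  sub_idx <- rep(seq_len(n_sub), each = n_per)
  p2 <- p2_mat[cbind(sub_idx, lev_idx)]
  pom <- profiles$p_omission[sub_idx]
  pcm <- profiles$p_commission[sub_idx]

  u <- stats::runif(nrow(trials))
  exp_resp <- ifelse(u < p2, 2L, ifelse(u < p2 + pom, 0L, 1L))
  u2 <- stats::runif(nrow(trials))
  catch_resp <- ifelse(u < pcm,
                       ifelse(u2 < two_dot_commission, 2L, 1L), 0L)
  trials$response <- ifelse(trials$trial_type == "experimental",
                            exp_resp, catch_resp)
  trials$flash_position <- ifelse(
    trials$trial_type == "experimental",
    ifelse(stats::runif(nrow(trials)) < flash_above_prob,
           "above", "below"),
    NA_character_)
  # randomized presentation order within participant
  ord <- unlist(lapply(seq_len(n_sub), function(i) sample.int(n_per)))
  trials$trial_index <- ord
  trials <- trials[order(trials$participant_id, trials$trial_index), ]
  trials <- trials[, c("participant_id", "design_id", "level", "condition",
                       "block", "trial_type", "n_presented", "response",
                       "flash_position", "trial_index")]
  tibble::as_tibble(trials)
}

#' Write / read a trial table as CSV
#'
#' The comma-separated trial table (header row, one row per trial) is
#' the interchange format between simulation and analysis.
#' `read_trials()` validates the schema and fails with the offending
#' row numbers when responses fall outside \{0, 1, 2\}, trial types are
#' unknown, or presented-target counts are inconsistent with the trial
#' type.
#'
#' @param trials Trial tibble as produced by [simulate_trials()].
#' @param path CSV file path.
#' @return `read_trials()` returns the validated tibble;
#'   `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              participant_id = "c", design_id = "c",
                              level = "c", condition = "d", block = "c",
                              trial_type = "c", n_presented = "i",
                              response = "i", flash_position = "c",
                              trial_index = "i"))
  validate_trials(trials)
  trials
}

#' Validate a trial table's schema
#'
#' @param trials A trial tibble.
#' @return The tibble, invisibly; errors list offending rows.
#' @export
validate_trials <- function(trials) {
  required <- c("participant_id", "design_id", "level", "condition",
                "trial_type", "n_presented", "response", "trial_index")
  missing <- setdiff(required, names(trials))
  if (length(missing) > 0L) {
    stop("trial table is missing columns: ", paste(missing, collapse = ", "))
  }
  complain <- function(bad, what) {
    if (any(bad)) {
      rows <- which(bad)
      shown <- utils::head(rows, 5L)
      stop("trial table schema violation (", what, ") in row",
           if (length(rows) > 1L) "s" else "", " ",
           paste(shown, collapse = ", "),
           if (length(rows) > length(shown))
             paste0(" and ", length(rows) - length(shown), " more") else "")
    }
  }
  complain(!trials$response %in% 0:2, "response not in {0, 1, 2}")
  complain(!trials$trial_type %in% c("experimental", "catch"),
           "unknown trial_type")
  complain(trials$trial_type == "catch" & trials$n_presented != 0L,
           "catch trial with a presented target")
  complain(trials$trial_type == "experimental" & trials$n_presented != 1L,
           "experimental trial without exactly one presented target")
  invisible(trials)
}
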