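#' Study designs for the split-stimulus experiments
#'
#' A `study_design` object declares, per condition level, how many
#' experimental and catch trials each participant completes, which error
#' baseline the per-subject significance tests use, and the admissible
#' response values. Both the simulator ([simulate_trials()]) and the
#' analysis functions ([summarize_subjects()], [flag_significant()])
#' consume the same object, so the trial bookkeeping is defined in one
#' place.
#'
#' Four designs are built in:
#'
#' * `exp1a` — 45 participants; nine frame speeds uniformly spaced on
#'   3.9–35 deg/s, 40 trials per speed (32 experimental + 8 catch;
#'   catch trials are 20% of the 360-trial total, evenly divided over
#'   speeds). Baseline: commission errors on catch trials.
#' * `exp1b` — 45 participants; six flash opacities uniformly spaced on
#'   50–100%, 32 experimental + 8 catch per opacity (240 trials total).
#'   Baseline: commission.
#' * `exp2a` — 85 participants; three attention blocks (above-cued and
#'   below-cued, 150 trials each; uncued, 300 trials) crossed with three
#'   frame speeds 19.5/27.3/35 deg/s allocated equally within block
#'   (600 trials total, no catch trials). Baseline: omission errors
#'   (reporting 0 when one target was shown).
#' * `exp2b` — 85 participants; motion-onset trials at the same three
#'   speeds, 100 each (300 trials, no catch). Baseline: omission.
#'
#' @param design_id One of `"exp1a"`, `"exp1b"`, `"exp2a"`, `"exp2b"`.
#' @return A `study_design` list with elements `design_id`,
#'   `n_participants`, `factor_name`, `factor_unit`, `baseline_kind`,
#'   `response_alphabet`, and `levels` (a tibble with columns `level`,
#'   `condition`, `block`, `n_experimental`, `n_catch`).
#' @examples
#' d <- builtin_design("exp1a")
#' sum(d$levels$n_experimental + d$levels$n_catch)  # 360
#' @export
builtin_design <- function(design_id) {
  ids <- c("exp1a", "exp1b", "exp2a", "exp2b")
  if (length(design_id) != 1L || !design_id %in% ids) {
    stop("unknown design_id ", deparse(design_id),
         "; valid choices are: ", paste(ids, collapse = ", "))
  }
  d <- switch(design_id,
    exp1a = study_design(
      design_id = "exp1a", n_participants = 45L,
      factor_name = "frame_speed", factor_unit = "deg/s",
      baseline_kind = "commission",
      levels = tibble::tibble(
        condition = seq(3.9, 35, length.out = 9),
        block = NA_character_,
        n_experimental = 32L, n_catch = 8L)),
    exp1b = study_design(
      design_id = "exp1b", n_participants = 45L,
      factor_name = "flash_opacity", factor_unit = "%",
      baseline_kind = "commission",
      levels = tibble::tibble(
        condition = seq(50, 100, length.out = 6),
        block = NA_character_,
        n_experimental = 32L, n_catch = 8L)),
    exp2a = study_design(
      design_id = "exp2a", n_participants = 85L,
      factor_name = "frame_speed", factor_unit = "deg/s",
      baseline_kind = "omission",
      levels = tidyr::crossing(
        block = c("above_cued", "below_cued", "uncued"),
        condition = c(19.5, 27.3, 35)) |>
        dplyr::mutate(
          n_experimental = ifelse(.data$block == "uncued", 100L, 50L),
          n_catch = 0L)),
    exp2b = study_design(
      design_id = "exp2b", n_participants = 85L,
      factor_name = "frame_speed", factor_unit = "deg/s",
      baseline_kind = "omission",
      levels = tibble::tibble(
        condition = c(19.5, 27.3, 35),
        block = NA_character_,
        n_experimental = 100L, n_catch = 0L)))
  d
}

#' Construct a study design
#'
#' Low-level constructor; most users want [builtin_design()]. The object
#' is validated on construction ([validate_design()]) and construction
#' fails on any violation.
#'
#' @param design_id Character identifier.
#' @param n_participants Positive integer.
#' @param factor_name Name of the manipulated factor
#'   (e.g. `"frame_speed"`).
#' @param factor_unit Unit label for the factor values.
#' @param baseline_kind `"commission"` (catch-trial errors) or
#'   `"omission"` (reporting zero targets on experimental trials).
#' @param levels Tibble with columns `condition` (numeric factor value),
#'   `block` (character or `NA`), `n_experimental`, `n_catch`.
#' @param response_alphabet Admissible report values; defaults to 0:2
#'   (saw zero, one, or two targets).
#' @return A validated `study_design` object.
#' @export
study_design <- function(design_id, n_participants, factor_name,
                         factor_unit, baseline_kind, levels,
                         response_alphabet = 0:2) {
  levels <- tibble::as_tibble(levels)
  if (!"block" %in% names(levels)) levels$block <- NA_character_
  levels$level <- ifelse(is.na(levels$block),
                         format_level(levels$condition),
                         paste(levels$block, format_level(levels$condition),
                               sep = "/"))
  levels <- levels[, c("level", "condition", "block",
                       "n_experimental", "n_catch")]
  d <- structure(
    list(design_id = design_id,
         n_participants = as.integer(n_participants),
         factor_name = factor_name, factor_unit = factor_unit,
         baseline_kind = baseline_kind,
         response_alphabet = as.integer(response_alphabet),
         levels = levels),
    class = "study_design")
  viol <- validate_design(d)
  if (length(viol) > 0L) {
    stop("invalid study design:\n  ", paste(viol, collapse = "\n  "))
  }
  d
}

format_level <- function(x) trimws(formatC(x, format = "fg", digits = 6))

#' Validate a study design
#'
#' Checks the structural invariants of a `study_design` and returns the
#' violations as data rather than raising: an empty character vector
#' means the design is valid. Checked rules: positive participant count;
#' non-negative trial counts; positive speeds / opacities in (0, 100];
#' response alphabet \{0, 1, 2\}; for the built-in identifiers, the
#' printed per-participant totals (exp1a 360, exp1b 240, exp2a 600,
#' exp2b 300), the 20%-catch-evenly-divided rule for Experiment 1
#' designs, and zero catch trials with an omission baseline for
#' Experiment 2 designs.
#'
#' @param d A `study_design` (or a modified copy of one).
#' @return Character vector of violation messages (empty if valid).
#' @export
validate_design <- function(d) {
  v <- character()
  say <- function(...) v <<- c(v, paste0(...))
  lv <- d$levels
  if (!is.numeric(d$n_participants) || d$n_participants < 1) {
    say("n_participants: must be a positive integer")
  }
  bad <- which(lv$n_experimental < 0)
  for (i in bad) say("level ", lv$level[i], ": n_experimental is negative")
  bad <- which(lv$n_catch < 0)
  for (i in bad) say("level ", lv$level[i], ": n_catch is negative")
  if (identical(d$factor_name, "frame_speed") && any(lv$condition <= 0)) {
    say("frame_speed: all speeds must be positive")
  }
  if (identical(d$factor_name, "flash_opacity") &&
      any(lv$condition <= 0 | lv$condition > 100)) {
    say("flash_opacity: opacities must lie in (0, 100]")
  }
  if (!identical(sort(unique(d$response_alphabet)), 0:2)) {
    say("response_alphabet: must be {0, 1, 2}")
  }
  if (!d$baseline_kind %in% c("commission", "omission")) {
    say("baseline_kind: must be 'commission' or 'omission'")
  }
  printed_totals <- c(exp1a = 360L, exp1b = 240L, exp2a = 600L, exp2b = 300L)
  if (d$design_id %in% names(printed_totals)) {
    total <- sum(lv$n_experimental + lv$n_catch)
    if (total != printed_totals[[d$design_id]]) {
      say("total trials per participant: ", total, " != printed total ",
          printed_totals[[d$design_id]], " for ", d$design_id)
    }
    if (d$design_id %in% c("exp1a", "exp1b")) {
      if (length(unique(lv$n_catch)) != 1L) {
        say("n_catch: catch trials must be evenly divided over levels")
      }
      if (sum(lv$n_catch) * 5L != total) {
        say("n_catch: catch trials must be 20% of the total")
      }
    } else {
      if (any(lv$n_catch != 0L)) say("n_catch: ", d$design_id,
                                     " has no catch trials")
      if (!identical(d$baseline_kind, "omission")) {
        say("baseline_kind: ", d$design_id, " uses the omission baseline")
      }
    }
  }
  v
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design '", x$design_id, "': ", x$n_participants,
      " participants, ", nrow(x$levels), " condition levels (",
      x$factor_name, ", ", x$factor_unit, ")\n", sep = "")
  cat("  trials/participant: ",
      sum(x$levels$n_experimental + x$levels$n_catch),
      " (", sum(x$levels$n_catch), " catch); baseline: ",
      x$baseline_kind, "\n", sep = "")
  print(x$levels, n = nrow(x$levels))
  invisible(x)
}

#' Write / read a study design as a plain-text config
#'
#' Designs serialize to YAML (key–value with a nested list of levels) so
#' that custom designs can be edited by hand and round-trip exactly.
#'
#' @param d A `study_design`.
#' @param path File path.
#' @return `read_design()` returns the validated `study_design`;
#'   `write_design()` returns `path` invisibly.
#' @export
write_design <- function(d, path) {
  stopifnot(inherits(d, "study_design"))
  lv <- d$levels[, c("condition", "block", "n_experimental", "n_catch")]
  yaml::write_yaml(
    list(design_id = d$design_id,
         n_participants = d$n_participants,
         factor_name = d$factor_name,
         factor_unit = d$factor_unit,
         baseline_kind = d$baseline_kind,
         response_alphabet = d$response_alphabet,
         levels = lapply(seq_len(nrow(lv)), function(i) {
           row <- as.list(lv[i, ])
           if (is.na(row$block)) row$block <- NULL
           row
         })),
    path, precision = 15)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  lv <- dplyr::bind_rows(lapply(y$levels, function(row) {
    tibble::tibble(condition = as.numeric(row$condition),
                   block = row$block %||% NA_character_,
                   n_experimental = as.integer(row$n_experimental),
                   n_catch = as.integer(row$n_catch))
  }))
  study_design(design_id = y$design_id,
               n_participants = y$n_participants,
               factor_name = y$factor_name,
               factor_unit = y$factor_unit,
               baseline_kind = y$baseline_kind,
               levels = lv,
               response_alphabet = as.integer(y$response_alphabet))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
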