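# shared fixtures built in code

# a two-level miniature design (not a builtin id, so printed-total rules
# do not apply) for fast unit tests
tiny_design <- function(n_participants = 3L, n_exp = 10L, n_catch = 5L) {
  study_design(
    design_id = "tiny", n_participants = n_participants,
    factor_name = "frame_speed", factor_unit = "deg/s",
    baseline_kind = "commission",
    levels = tibble::tibble(condition = c(5, 10),
                            n_experimental = n_exp, n_catch = n_catch))
}

# hand-built trial table with known counts: one participant, one level
hand_trials <- function(participant, n2, n0, n1, catch_hit = 0L,
                        catch_miss = 0L, level = "5", condition = 5,
                        design_id = "tiny") {
  resp <- c(rep(2L, n2), rep(0L, n0), rep(1L, n1),
            rep(1L, catch_hit), rep(0L, catch_miss))
  type <- c(rep("experimental", n2 + n0 + n1),
            rep("catch", catch_hit + catch_miss))
  tibble::tibble(
    participant_id = participant, design_id = design_id,
    level = level, condition = condition, block = NA_character_,
    trial_type = type,
    n_presented = ifelse(type == "experimental", 1L, 0L),
    response = resp,
    flash_position = NA_character_,
    trial_index = seq_along(resp))
}

# independent brute-force oracle for the upper binomial tail, via
# log-scale pmf summation (no pbinom)
brute_tail <- function(k, n, p0) {
  if (k == 0) return(1)
  if (p0 == 0) return(0)
  if (p0 == 1) return(1)
  ks <- k:n
  sum(exp(lchoose(n, ks) + ks * log(p0) + (n - ks) * log1p(-p0)))
}

# grid argmax oracle for the prevalence posterior mode: coarse global
# grid then a fine local grid at 1e-5 spacing (equivalent to a full
# 100001-point grid for these unimodal densities)
grid_argmax <- function(post) {
  g <- seq(0, 1, length.out = 2001)
  d <- post$density(g)
  g0 <- g[which.max(d)]
  fine <- seq(max(0, g0 - 0.001), min(1, g0 + 0.001), by = 1e-5)
  fine[which.max(post$density(fine))]
}
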