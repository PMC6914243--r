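# Shared fixtures: everything is generated in code at test time.

# small, fast generator config
small_config <- function(seed = 42, ...) {
  generator_config(n_per_arm = c(12L, 10L), seed = seed, ...)
}

# config with all noise switched off (degenerate, fully deterministic given
# the baseline draw); integer effects so integer rounding is exact
noiseless_config <- function(seed = 1, time_effect = c(-7, -14, -21),
                             group_effect = 0, baseline_sd = 0) {
  generator_config(
    n_per_arm = c(6L, 6L),
    baseline_ids_mean_sd = list(blended = c(45, baseline_sd),
                                standard = c(40, baseline_sd)),
    time_effect = time_effect,
    group_effect = group_effect,
    random_intercept_sd = 0,
    residual_sd = 0,
    utility_link = list(intercept = 0.9, slope = 0.01, noise_sd = 0),
    seed = seed)
}

# a hand-built tiny panel: 2 patients x 4 weeks, known numbers
tiny_panel <- function() {
  data.frame(
    patient_id = rep(c("A", "B"), each = 4),
    arm = factor(rep(c("blended", "standard"), each = 4),
                 levels = c("standard", "blended")),
    age = 40, employed = TRUE,
    week = rep(c(0L, 10L, 20L, 30L), 2),
    ids_sr = c(45, 30, 25, 12, 40, 40, 35, 30),
    utility = c(0.4, 0.5, 0.6, 0.8, 0.5, 0.5, 0.6, 0.6),
    episode = c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE),
    ru_gp_visit = 1, ru_specialist_visit = 2, ru_medication_item = 1,
    ru_psych_inpatient_day = 0, ru_hospital_day = 0,
    ru_informal_care_hour = 3, ru_productivity_hour = 10,
    n_f2f_sessions = rep(c(10L, 14L), each = 4),
    n_online_sessions = rep(c(9L, 0L), each = 4),
    n_feedback_messages = rep(c(8L, 0L), each = 4),
    stringsAsFactors = FALSE)
}

# deterministic synthetic pair set for plane/CEAC counting oracles
fixed_pairs <- function(dc, de) {
  structure(data.frame(delta_cost = dc, delta_effect = de),
            perspective = "societal", effect_kind = "response",
            method = "parametric", seed = 0L, n_draws = length(dc),
            dropped = 0L,
            point = list(dc = mean(dc), de = mean(de),
                         dc_se = stats::sd(dc), de_se = stats::sd(de),
                         dc_ci_wald = range(dc), de_ci_wald = range(de)),
            class = c("ce_pairs", "data.frame"))
}

# brute-force CEAC oracle: per-draw counting, independent of ceac()
ceac_oracle <- function(pairs, wtp) {
  vapply(wtp, function(l) {
    n_ce <- 0L
    for (i in seq_len(nrow(pairs)))
      if (l * pairs$delta_effect[i] - pairs$delta_cost[i] > 0)
        n_ce <- n_ce + 1L
    n_ce / nrow(pairs)
  }, numeric(1))
}
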