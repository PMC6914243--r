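test_that("generate_trial produces the forced panel structure", {
  d <- generate_trial(generator_config(n_per_arm = c(53L, 49L), seed = 1))
  expect_s3_class(d, "trial_data")
  expect_equal(nrow(d), 102 * 4)
  expect_equal(length(unique(d$patient_id)), 102)
  counts <- table(d$arm[!duplicated(d$patient_id)])
  expect_equal(unname(counts[c("blended", "standard")]),
               c(53L, 49L), ignore_attr = TRUE)
  expect_true(all(table(d$patient_id, d$week) == 1))
  expect_true(all(d$ids_sr >= 0 & d$ids_sr <= 84))
  expect_true(all(d$utility >= -0.33 & d$utility <= 1))
  std <- d$arm == "standard"
  expect_true(all(d$n_online_sessions[std] == 0))
  expect_true(all(d$n_feedback_messages[std] == 0))
  expect_true(all(d[, grep("^ru_", names(d))] >= 0))
})

test_that("same seed gives bit-identical datasets, different seed differs", {
  cfg <- small_config(seed = 11)
  expect_identical(generate_trial(cfg), generate_trial(cfg))
  cfg2 <- small_config(seed = 12)
  expect_false(identical(generate_trial(cfg)$ids_sr,
                         generate_trial(cfg2)$ids_sr))
})

test_that("invalid configs are rejected with the offending field named", {
  expect_error(generator_config(n_per_arm = c(0L, 10L)), "n_per_arm")
  expect_error(generator_config(assessment_weeks = c(0, 20, 10)),
               "assessment_weeks")
  expect_error(generator_config(assessment_weeks = c(5, 10)),
               "assessment_weeks")
  expect_error(generator_config(residual_sd = -1), "residual_sd")
  expect_error(
    generator_config(cost_params = list(
      direct_medical = c(shape = -1, scale = 1),
      direct_nonmedical = c(shape = 1, scale = 1),
      indirect_nonmedical = c(shape = 1, scale = 1),
      inpatient_prob = 0.1, inpatient_cost = 100)),
    "cost_params")
  expect_error(generator_config(time_effect = c(-1, -2)), "time_effect")
})

test_that("degenerate noise gives follow-ups = baseline + cumulative effects", {
  d <- generate_trial(noiseless_config(time_effect = c(-7, -14, -21),
                                       group_effect = 3))
  for (pid in unique(d$patient_id)) {
    p <- d[d$patient_id == pid, ]
    p <- p[order(p$week), ]
    g <- if (p$arm[1] == "blended") 3 else 0
    expect_equal(p$ids_sr[-1], p$ids_sr[1] + c(-7, -14, -21) + g)
  }
  # non-integer per-step effect: exact up to integer rounding of the scale
  d2 <- generate_trial(noiseless_config(time_effect = -7.13))
  p <- d2[d2$patient_id == d2$patient_id[1], ]
  expect_true(all(abs(p$ids_sr[-1] -
                        (p$ids_sr[1] + (1:3) * -7.13)) <= 0.5))
})

test_that("scalar time_effect accumulates per step", {
  cfg <- noiseless_config(time_effect = -5)
  d <- generate_trial(cfg)
  p <- d[d$patient_id == d$patient_id[1], ]
  expect_equal(p$ids_sr[-1], p$ids_sr[1] + c(-5, -10, -15))
})

test_that("baseline moments converge to configured values", {
  cfg <- generator_config(n_per_arm = c(4000L, 4000L), seed = 202)
  d <- generate_trial(cfg)
  b <- d[d$week == 0, ]
  expect_lt(abs(mean(b$ids_sr[b$arm == "blended"]) - 45.2), 0.5)
  expect_lt(abs(mean(b$ids_sr[b$arm == "standard"]) - 41.5), 0.5)
  expect_lt(abs(sd(b$ids_sr[b$arm == "blended"]) - 12.1), 0.6)
  # window-cost means: costing the generated counts with the same table
  # must reproduce the configured gamma means (to Monte-Carlo error)
  uc <- default_unit_costs()
  cp <- cfg$cost_params
  wc <- t(apply(b[, paste0("ru_", resource_items())], 1, function(r) {
    names(r) <- resource_items()
    window_costs(r, uc)
  }))
  # each empirical category mean within 3.5 theoretical MC standard errors
  n <- nrow(b)
  gmean <- function(p) unname(p["shape"] * p["scale"])
  gsd <- function(p) unname(sqrt(p["shape"]) * p["scale"])
  expect_lt(abs(mean(wc[, "direct_medical"]) -
                  (gmean(cp$direct_medical) +
                     cp$inpatient_prob * cp$inpatient_cost)),
            3.5 * sqrt(gsd(cp$direct_medical)^2 +
                         cp$inpatient_prob * (1 - cp$inpatient_prob) *
                           cp$inpatient_cost^2) / sqrt(n))
  expect_lt(abs(mean(wc[, "direct_nonmedical"]) -
                  gmean(cp$direct_nonmedical)),
            3.5 * gsd(cp$direct_nonmedical) / sqrt(n))
  expect_lt(abs(mean(wc[, "indirect_nonmedical"]) -
                  gmean(cp$indirect_nonmedical)),
            3.5 * gsd(cp$indirect_nonmedical) / sqrt(n))
  # utility mean tracks the link prediction (clamping allows small bias)
  pred <- cfg$utility_link$intercept -
    cfg$utility_link$slope * mean(b$ids_sr)
  expect_lt(abs(mean(b$utility) - pred), 0.05)
})

test_that("MCAR missingness hits the configured marginal rate", {
  cfg <- generator_config(
    n_per_arm = c(1500L, 1500L), seed = 5,
    dropout_model = list(intercept = qlogis(0.25), age = 0, employed = 0))
  d <- apply_missingness(generate_trial(cfg), cfg)
  fup <- d[d$week > 0, ]
  expect_equal(mean(is.na(fup$ids_sr)), 0.25, tolerance = 0.05)
  expect_false(anyNA(d$ids_sr[d$week == 0]))
})

test_that("probability-zero dropout returns the dataset unchanged", {
  cfg <- small_config(
    dropout_model = list(intercept = -Inf, age = -0.04, employed = -0.7))
  d <- generate_trial(cfg)
  expect_identical(apply_missingness(d, cfg), d)
})

test_that("negative age coefficient makes patients with missing data younger", {
  cfg <- generator_config(
    n_per_arm = c(1000L, 1000L), seed = 9,
    dropout_model = list(intercept = qlogis(0.3), age = -0.08,
                         employed = 0))
  d <- apply_missingness(generate_trial(cfg), cfg)
  has_miss <- tapply(is.na(d$ids_sr) & d$week > 0, d$patient_id, any)
  age <- d$age[!duplicated(d$patient_id)]
  names(age) <- d$patient_id[!duplicated(d$patient_id)]
  age <- age[names(has_miss)]
  expect_lt(mean(age[has_miss]), mean(age[!has_miss]))
})

test_that("logistic regression recovers the configured dropout coefficients", {
  dm <- list(intercept = qlogis(0.3), age = -0.06, employed = -0.8)
  cfg <- generator_config(n_per_arm = c(3000L, 3000L), seed = 17,
                          dropout_model = dm)
  d <- apply_missingness(generate_trial(cfg), cfg)
  fup <- d[d$week > 0, ]
  fit <- glm(is.na(ids_sr) ~ I(age - 40) + employed, data = fup,
             family = binomial())
  expect_lt(abs(unname(coef(fit)["I(age - 40)"]) - dm$age), 0.02)
  expect_lt(abs(unname(coef(fit)["employedTRUE"]) - dm$employed), 0.2)
})

test_that("monotone mode censors everything after the first missing visit", {
  cfg <- small_config(seed = 3,
                      dropout_model = list(intercept = qlogis(0.4),
                                           age = 0, employed = 0))
  d <- apply_missingness(generate_trial(cfg), cfg, monotone = TRUE)
  for (pid in unique(d$patient_id)) {
    p <- d[d$patient_id == pid & d$week > 0, ]
    p <- p[order(p$week), ]
    miss <- is.na(p$ids_sr)
    if (any(miss))
      expect_true(all(miss[seq(min(which(miss)), length(miss))]))
  }
})

test_that("trial CSV round-trips with seed metadata", {
  d <- generate_trial(small_config(seed = 21))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(d, path)
  d2 <- read_trial_csv(path)
  expect_equal(attr(d2, "seed"), 21L)
  expect_equal(d2$ids_sr, d$ids_sr)
  expect_equal(levels(d2$arm), levels(d$arm))
})
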