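test_that("icer reproduces hand arithmetic with quadrant labels", {
  r <- icer(1183, 0.03)
  expect_equal(r$icer, 1183 / 0.03)
  expect_equal(r$quadrant, "NE")
  r <- icer(-176, 0.03)
  expect_equal(r$icer, -176 / 0.03)
  expect_equal(r$quadrant, "SE")
  expect_equal(r$dominance_label, "dominant")
  expect_equal(icer(0, 0.05)$icer, 0)
  expect_equal(icer(100, -0.05)$quadrant, "NW")
  expect_equal(icer(100, -0.05)$dominance_label, "dominated")
  expect_equal(icer(-100, -0.05)$quadrant, "SW")
})

test_that("zero incremental effect yields an undefined ICER, not Inf", {
  r <- icer(500, 0)
  expect_true(is.na(r$icer))
  expect_equal(r$dominance_label, "undefined")
})

test_that("plane proportions partition and follow the boundary convention", {
  p <- fixed_pairs(rep(1000, 5), rep(0.1, 5))
  pd <- plane_distribution(p)
  expect_equal(unname(pd$proportions["NE"]), 1)
  expect_equal(sum(pd$proportions), 1)
  # boundary: dE = 0 counts west, dC = 0 counts south
  p <- fixed_pairs(c(1, 1, -1, -1, 0, 0), c(1, 0, 1, 0, 1, -1))
  pd <- plane_distribution(p)
  expect_equal(unname(pd$proportions), c(1, 1, 2, 2) / 6,
               ignore_attr = TRUE)  # NE, NW, SE, SW
  expect_equal(sum(pd$proportions), 1)
})

test_that("symmetric clouds split evenly across quadrants", {
  set.seed(4)
  n <- 40000
  p <- fixed_pairs(rnorm(n), rnorm(n))
  pd <- plane_distribution(p)
  # brute-force counting oracle
  oracle <- c(NE = 0, NW = 0, SE = 0, SW = 0)
  for (i in seq_len(n)) {
    q <- if (p$delta_effect[i] > 0) {
      if (p$delta_cost[i] > 0) "NE" else "SE"
    } else {
      if (p$delta_cost[i] > 0) "NW" else "SW"
    }
    oracle[q] <- oracle[q] + 1
  }
  expect_equal(pd$proportions, oracle / n)
  expect_true(all(abs(pd$proportions - 0.25) < 0.01))
})

test_that("ceac equals brute-force per-draw counting at every ceiling", {
  set.seed(12)
  p <- fixed_pairs(rnorm(50, 500, 800), rnorm(50, 0.04, 0.05))
  wtp <- seq(0, 60000, by = 2500)
  curve <- ceac(p, wtp)
  expect_identical(curve$probability, ceac_oracle(p, wtp))
  expect_true(all(curve$probability >= 0 & curve$probability <= 1))
})

test_that("ceac at 0 is P(dC < 0) and equals SW+SE for continuous draws", {
  set.seed(21)
  p <- fixed_pairs(rnorm(400, 100, 500), rnorm(400, 0.02, 0.08))
  c0 <- ceac(p, c(0, 1000))$probability[1]
  expect_equal(c0, mean(p$delta_cost < 0))
  pd <- plane_distribution(p)
  expect_equal(c0, unname(pd$proportions["SE"] + pd$proportions["SW"]))
})

test_that("ceac is non-decreasing when every draw has positive effect", {
  set.seed(31)
  p <- fixed_pairs(rnorm(300, 500, 1000), runif(300, 0.01, 0.2))
  curve <- ceac(p, seq(0, 80000, 1000))
  expect_true(all(diff(curve$probability) >= 0))
  # limit: large ceilings approach probability 1
  expect_equal(ceac(p, c(0, 1e9))$probability[2], 1)
})

test_that("ties count as not cost-effective (strict net benefit)", {
  p <- fixed_pairs(c(100, 100), c(0.01, 0.01))
  expect_equal(ceac(p, c(10000, 10001))$probability, c(0, 1))
})

test_that("draw_ce_pairs is deterministic and honors n_draws", {
  cfg <- small_config(seed = 5)
  d <- generate_trial(cfg)
  tab <- build_analysis_table(d)
  p1 <- draw_ce_pairs(analysis_table = tab, perspective = "provider",
                      effect_kind = "response", n_draws = 40, seed = 9)
  p2 <- draw_ce_pairs(analysis_table = tab, perspective = "provider",
                      effect_kind = "response", n_draws = 40, seed = 9)
  expect_identical(p1$delta_cost, p2$delta_cost)
  expect_identical(p1$delta_effect, p2$delta_effect)
  expect_equal(nrow(p1), 40)
  p3 <- draw_ce_pairs(analysis_table = tab, perspective = "provider",
                      effect_kind = "response", n_draws = 40, seed = 10)
  expect_false(identical(p1$delta_cost, p3$delta_cost))
  # parametric method: same contract
  q1 <- draw_ce_pairs(analysis_table = tab, perspective = "provider",
                      effect_kind = "qaly", n_draws = 200, seed = 9,
                      method = "parametric")
  q2 <- draw_ce_pairs(analysis_table = tab, perspective = "provider",
                      effect_kind = "qaly", n_draws = 200, seed = 9,
                      method = "parametric")
  expect_identical(q1$delta_cost, q2$delta_cost)
})

test_that("identical arms center the pair cloud on the origin", {
  d <- generate_trial(small_config(seed = 77))
  bl <- d[d$arm == "blended", ]
  mirror <- bl
  mirror$patient_id <- paste0("M", mirror$patient_id)
  mirror$arm <- factor("standard", levels = levels(d$arm))
  mirror$n_online_sessions <- 0L
  mirror$n_feedback_messages <- 0L
  mirror$n_f2f_sessions <- bl$n_f2f_sessions
  dd <- rbind(bl, mirror)
  class(dd) <- class(d)
  # zero out session cost asymmetry (feedback exists only in blended arm)
  dd$n_feedback_messages <- 0L
  tab <- build_analysis_table(dd)
  p <- draw_ce_pairs(analysis_table = tab, perspective = "societal",
                     effect_kind = "response", n_draws = 60, seed = 2)
  expect_lt(abs(mean(p$delta_cost)), 3 * sd(p$delta_cost) / sqrt(nrow(p)) +
              1e-9)
  expect_lt(abs(mean(p$delta_effect)),
            3 * sd(p$delta_effect) / sqrt(nrow(p)) + 1e-9)
})

test_that("sensitivity suite: no inpatient use makes exclusion a no-op", {
  cfg <- small_config(seed = 15, cost_params = list(
    direct_medical = c(shape = 1.15, scale = 392),
    direct_nonmedical = c(shape = 0.23, scale = 1080),
    indirect_nonmedical = c(shape = 0.2, scale = 3560),
    inpatient_prob = 0, inpatient_cost = 5000))
  d <- generate_trial(cfg)
  tab <- build_analysis_table(d)
  main <- run_cea(analysis_table = tab, n_draws = 30, seed = 3)
  sens <- sensitivity_suite(variants = "exclude_inpatient",
                            analysis_table = tab, n_draws = 30, seed = 3)
  expect_equal(sens$exclude_inpatient$pairs$delta_cost,
               main$pairs$delta_cost)
  expect_equal(sens$exclude_inpatient$ceac$probability,
               main$ceac$probability)
})

test_that("cost aggregates decompose: indirect + direct parts = societal", {
  d <- generate_trial(small_config(seed = 16))
  tab <- build_analysis_table(d)
  est_soc <- estimate_cea_effects(tab, "societal", "response")
  est_ind <- estimate_cea_effects(tab, "societal", "response",
                                  indirect_only = TRUE)
  # direct (medical + nonmedical) delta via a derived column
  tab$cost_direct_parts <- tab$cost_societal - tab$cost_indirect_only
  direct <- fit_lmm(tab, "cost_direct_parts",
                    baseline = "base_window_societal",
                    include_time = FALSE)
  expect_equal(est_ind$dc + direct$group_effect$estimate, est_soc$dc,
               tolerance = 1e-6)
})

test_that("unknown sensitivity variants are rejected", {
  expect_error(sensitivity_suite(variants = "winsorize"), "winsorize")
})

test_that("ceac_stability: dispersion shrinks with n; zero variance is flat", {
  pop0 <- stability_population(cost_mean = c(1000, 800), cost_sd = c(0, 0),
                               effect_prob = c(1, 0))
  res0 <- ceac_stability(pop0, n_grid = c(10, 50), reps = 10,
                         wtp_grid = c(0, 1000, 5000), seed = 4)
  expect_true(all(res0$dispersion == 0))
  expect_equal(attr(res0, "stable_n"), 10)

  res <- ceac_stability(n_grid = c(10, 75, 500), reps = 40,
                        wtp_grid = seq(0, 30000, 10000), seed = 8)
  d10 <- res$dispersion[res$n == 10]
  d500 <- res$dispersion[res$n == 500]
  expect_true(all(d500 <= d10))
  expect_true(75 %in% eval(formals(ceac_stability)$n_grid))
})

test_that("ceac_stability output is deterministic under a fixed seed", {
  a <- ceac_stability(n_grid = c(10, 20), reps = 5,
                      wtp_grid = c(0, 5000), seed = 123)
  b <- ceac_stability(n_grid = c(10, 20), reps = 5,
                      wtp_grid = c(0, 5000), seed = 123)
  expect_identical(a$dispersion, b$dispersion)
})
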