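#' Monte Carlo draws of incremental cost-effect pairs
#'
#' Propagates uncertainty in the incremental cost (`dC`) and incremental
#' effect (`dE`) estimates to a cloud of cost-effect pairs. The default
#' `cluster_bootstrap` method resamples patients with replacement within
#' each arm and refits the two cost-effectiveness models of
#' [estimate_cea_effects()] on every replicate, which preserves the
#' within-patient correlation between costs and effects. The `parametric`
#' alternative draws independently from the normal sampling distributions of
#' the two fitted group coefficients and ignores that correlation (labeled
#' as such in the result). A fixed seed reproduces the pair set
#' bit-identically.
#'
#' Bootstrap replicates whose models fail outright are redrawn up to 10
#' times and then dropped with a count in the result; more than 1% dropped
#' replicates aborts the run.
#'
#' @param data `trial_data` (ignored when `analysis_table` is supplied).
#' @param perspective `"societal"` or `"provider"`.
#' @param effect_kind `"response"`, `"episode"`, or `"qaly"`.
#' @param n_draws number of Monte Carlo draws (default 5000).
#' @param seed integer seed.
#' @param method `"cluster_bootstrap"` (default) or `"parametric"`.
#' @param unit_costs a [unit_cost_table()].
#' @param exclude_inpatient,indirect_only sensitivity cost variants.
#' @param analysis_table optional precomputed [build_analysis_table()]
#'   output (lets the pipeline reuse one table across analyses).
#' @return object of class `ce_pairs`: a `data.frame` with columns
#'   `delta_cost`, `delta_effect` and metadata attributes (perspective,
#'   effect kind, method, seed, point estimates, dropped-replicate count).
#' @export
draw_ce_pairs <- function(data = NULL,
                          perspective = c("societal", "provider"),
                          effect_kind = c("response", "episode", "qaly"),
                          n_draws = 5000, seed = 1L,
                          method = c("cluster_bootstrap", "parametric"),
                          unit_costs = default_unit_costs(),
                          exclude_inpatient = FALSE, indirect_only = FALSE,
                          analysis_table = NULL) {
  perspective <- match.arg(perspective)
  effect_kind <- match.arg(effect_kind)
  method <- match.arg(method)
  tab <- if (is.null(analysis_table))
    build_analysis_table(data, unit_costs) else analysis_table
  point <- estimate_cea_effects(tab, perspective, effect_kind,
                                exclude_inpatient, indirect_only)
  set.seed(seed)
  if (method == "parametric") {
    dc <- stats::rnorm(n_draws, point$dc, point$dc_se)
    de <- stats::rnorm(n_draws, point$de, point$de_se)
    dropped <- 0L
  } else {
    first <- !duplicated(tab$patient_id)
    pids <- split(tab$patient_id[first], tab$arm[first])
    # patient blocks indexed once for fast replicate assembly
    blocks <- split(seq_len(nrow(tab)), tab$patient_id)
    dc <- de <- numeric(n_draws)
    dropped <- 0L
    for (i in seq_len(n_draws)) {
      ok <- FALSE
      for (attempt in 1:10) {
        samp <- unlist(lapply(pids, function(p)
          sample(p, length(p), replace = TRUE)), use.names = FALSE)
        idx <- unlist(blocks[samp], use.names = FALSE)
        rep_tab <- tab[idx, ]
        rep_tab$patient_id <- rep(seq_along(samp),
                                  lengths(blocks[samp]))
        est <- tryCatch(
          estimate_cea_effects(rep_tab, perspective, effect_kind,
                               exclude_inpatient, indirect_only),
          error = function(e) NULL)
        if (!is.null(est) && is.finite(est$dc) && is.finite(est$de)) {
          dc[i] <- est$dc
          de[i] <- est$de
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        dc[i] <- NA_real_
        de[i] <- NA_real_
        dropped <- dropped + 1L
      }
    }
    if (dropped > 0.01 * n_draws)
      stop(sprintf("%d of %d bootstrap replicates failed to converge",
                   dropped, n_draws), call. = FALSE)
    keep <- !is.na(dc)
    dc <- dc[keep]
    de <- de[keep]
  }
  out <- data.frame(delta_cost = dc, delta_effect = de)
  structure(out,
            perspective = perspective, effect_kind = effect_kind,
            method = method, seed = seed, n_draws = n_draws,
            dropped = dropped,
            point = list(dc = point$dc, de = point$de,
                         dc_se = point$dc_se, de_se = point$de_se,
                         dc_ci_wald = point$delta_cost$group_effect$ci,
                         de_ci_wald = point$delta_effect$group_effect$ci),
            class = c("ce_pairs", "data.frame"))
}

#' @exportS3Method base::print
print.ce_pairs <- function(x, ...) {
  p <- attr(x, "point")
  cat(sprintf("<ce_pairs> %d draws (%s, %s, %s)\n", nrow(x),
              attr(x, "perspective"), attr(x, "effect_kind"),
              attr(x, "method")))
  cat(sprintf("  point: dC=%.1f dE=%.4f; draw means: dC=%.1f dE=%.4f\n",
              p$dc, p$de, mean(x$delta_cost), mean(x$delta_effect)))
  invisible(x)
}

#' Incremental cost-effectiveness ratio with quadrant label
#'
#' `delta_cost / delta_effect`, labeled by its cost-effectiveness plane
#' quadrant — a bare ratio is sign-ambiguous (a negative ICER can mean
#' dominance or being dominated). A zero incremental effect yields an
#' undefined ICER (`NA` with label `"undefined"`), never infinity.
#'
#' @param delta_cost incremental cost (euro).
#' @param delta_effect incremental effect (response probability, episode
#'   probability, or QALYs).
#' @return object of class `icer`: list with `icer`, `quadrant`
#'   (NE/NW/SE/SW), and `dominance_label` (`dominant`, `dominated`,
#'   `tradeoff-NE`, `tradeoff-SW`, or `undefined`).
#' @export
icer <- function(delta_cost, delta_effect) {
  stopifnot(is.finite(delta_cost), length(delta_effect) == 1)
  if (!is.finite(delta_effect))
    stop("delta_effect must be finite", call. = FALSE)
  if (delta_effect == 0) {
    out <- list(icer = NA_real_, quadrant = NA_character_,
                dominance_label = "undefined",
                delta_cost = delta_cost, delta_effect = delta_effect)
  } else {
    quadrant <- quadrant_of(delta_cost, delta_effect)
    label <- switch(quadrant,
                    NE = "tradeoff-NE", SW = "tradeoff-SW",
                    SE = "dominant", NW = "dominated")
    out <- list(icer = delta_cost / delta_effect, quadrant = quadrant,
                dominance_label = label,
                delta_cost = delta_cost, delta_effect = delta_effect)
  }
  class(out) <- "icer"
  out
}

#' @exportS3Method base::print
print.icer <- function(x, ...) {
  if (is.na(x$icer)) cat("<icer> undefined (delta_effect = 0)\n")
  else cat(sprintf("<icer> %.0f per effect unit (%s, %s)\n",
                   x$icer, x$quadrant, x$dominance_label))
  invisible(x)
}

# Boundary convention (fixed, documented): dE > 0 is east, dC > 0 is north;
# dE = 0 counts west, dC = 0 counts south. Measure-zero for continuous
# draws.
quadrant_of <- function(dc, de) {
  ifelse(de > 0,
         ifelse(dc > 0, "NE", "SE"),
         ifelse(dc > 0, "NW", "SW"))
}

#' Cost-effectiveness plane quadrant distribution
#'
#' Fraction of Monte Carlo draws in each quadrant of the cost-effectiveness
#' plane, plus the ICER at the draw means. The proportions always partition
#' (sum to 1).
#'
#' @param pairs a `ce_pairs` set.
#' @return object of class `plane_summary`: list with `proportions` (named
#'   NE/NW/SE/SW), `icer` (an [icer()] at the mean draw), and
#'   `dominance_label`.
#' @export
plane_distribution <- function(pairs) {
  stopifnot(nrow(pairs) > 0)
  q <- quadrant_of(pairs$delta_cost, pairs$delta_effect)
  props <- vapply(c("NE", "NW", "SE", "SW"),
                  function(k) mean(q == k), numeric(1))
  ic <- icer(mean(pairs$delta_cost), mean(pairs$delta_effect))
  structure(list(proportions = props, icer = ic,
                 dominance_label = ic$dominance_label,
                 n_draws = nrow(pairs)),
            class = "plane_summary")
}

#' @exportS3Method base::print
print.plane_summary <- function(x, ...) {
  cat(sprintf("<plane_summary> NE=%.1f%% NW=%.1f%% SE=%.1f%% SW=%.1f%% (%s)\n",
              100 * x$proportions["NE"], 100 * x$proportions["NW"],
              100 * x$proportions["SE"], 100 * x$proportions["SW"],
              x$dominance_label))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay ceiling `lambda` in the grid, the probability
#' that the intervention is cost-effective: the fraction of draws with
#' positive net monetary benefit, `lambda * dE - dC > 0` (strict; ties
#' count as not cost-effective). At `lambda = 0` this is the probability of
#' a cost saving, `P(dC < 0)`.
#'
#' @param pairs a `ce_pairs` set.
#' @param wtp_grid strictly increasing willingness-to-pay ceilings (euro per
#'   effect unit); default 0 to 80,000 in steps of 1000.
#' @return `data.frame` of class `ceac_curve` with columns `wtp`,
#'   `probability`.
#' @export
ceac <- function(pairs, wtp_grid = seq(0, 80000, by = 1000)) {
  stopifnot(nrow(pairs) > 0, !is.unsorted(wtp_grid, strictly = TRUE))
  prob <- vapply(wtp_grid, function(lambda)
    mean(lambda * pairs$delta_effect - pairs$delta_cost > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, probability = prob),
            class = c("ceac_curve", "data.frame"))
}

#' Run one full cost-effectiveness analysis
#'
#' Convenience wrapper: draws the pair cloud, summarizes the plane, the
#' ICER (point estimates), the acceptability curve, and percentile /
#' Wald 95% intervals for the incremental cost and effect.
#'
#' @inheritParams draw_ce_pairs
#' @param wtp_grid willingness-to-pay grid for the acceptability curve.
#' @return list with `pairs`, `plane`, `icer`, `ceac`, `dc_ci`, `de_ci`
#'   (percentile, the default interval) and `dc_ci_wald`, `de_ci_wald`.
#' @export
run_cea <- function(data = NULL, perspective = "societal",
                    effect_kind = "response", n_draws = 5000, seed = 1L,
                    method = "cluster_bootstrap",
                    unit_costs = default_unit_costs(),
                    wtp_grid = seq(0, 80000, by = 1000),
                    exclude_inpatient = FALSE, indirect_only = FALSE,
                    analysis_table = NULL) {
  pairs <- draw_ce_pairs(data, perspective, effect_kind, n_draws, seed,
                         method, unit_costs, exclude_inpatient,
                         indirect_only, analysis_table)
  point <- attr(pairs, "point")
  list(pairs = pairs,
       plane = plane_distribution(pairs),
       icer = icer(point$dc, point$de),
       ceac = ceac(pairs, wtp_grid),
       dc_ci = stats::quantile(pairs$delta_cost, c(0.025, 0.975),
                               names = FALSE),
       de_ci = stats::quantile(pairs$delta_effect, c(0.025, 0.975),
                               names = FALSE),
       dc_ci_wald = point$dc_ci_wald,
       de_ci_wald = point$de_ci_wald)
}

#' Sensitivity analyses on the cost aggregate
#'
#' Reruns the cost-effectiveness analysis with variant cost outcomes:
#' `exclude_inpatient` drops hospital and psychiatric inpatient items (rare
#' but costly events can act as influential outliers); `indirect_only`
#' evaluates the absenteeism/presenteeism costs alone.
#'
#' @inheritParams run_cea
#' @param variants subset of `c("exclude_inpatient", "indirect_only")`.
#' @return named list of [run_cea()] results, one per variant.
#' @export
sensitivity_suite <- function(data = NULL, variants = c("exclude_inpatient",
                                                        "indirect_only"),
                              perspective = "societal",
                              effect_kind = "response", n_draws = 5000,
                              seed = 1L, method = "cluster_bootstrap",
                              unit_costs = default_unit_costs(),
                              wtp_grid = seq(0, 80000, by = 1000),
                              analysis_table = NULL) {
  unknown <- setdiff(variants, c("exclude_inpatient", "indirect_only"))
  if (length(unknown))
    stop(sprintf("unknown sensitivity variant: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  out <- list()
  for (v in variants)
    out[[v]] <- run_cea(data, perspective, effect_kind, n_draws, seed,
                        method, unit_costs, wtp_grid,
                        exclude_inpatient = v == "exclude_inpatient",
                        indirect_only = v == "indirect_only",
                        analysis_table = analysis_table)
  out
}

#' Population parameters for the acceptability-curve stability simulation
#'
#' Fixed population-level cost and effect distributions per arm, in the
#' spirit of a pre-trial sample-size simulation: costs are gamma with the
#' given mean/SD (degenerate SD 0 allowed), effects are Bernoulli response
#' probabilities (or normal when `effect_sd` is supplied).
#'
#' @param cost_mean,cost_sd length-2 numeric `(blended, standard)`, euro.
#' @param effect_prob length-2 response probabilities, used when
#'   `effect_sd` is `NULL`.
#' @param effect_mean,effect_sd optional continuous-effect alternative.
#' @return list of class `stability_population`.
#' @export
stability_population <- function(cost_mean = c(12400, 8500),
                                 cost_sd = c(13200, 7200),
                                 effect_prob = c(0.65, 0.60),
                                 effect_mean = NULL, effect_sd = NULL) {
  structure(list(cost_mean = cost_mean, cost_sd = cost_sd,
                 effect_prob = effect_prob, effect_mean = effect_mean,
                 effect_sd = effect_sd),
            class = "stability_population")
}

draw_arm_costs <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, scale = sd^2 / mean)
}

# Analytic CEAC of one simulated trial from the normal approximation of
# (dC, dE); a tie (0/0 net-benefit z) counts as not cost-effective,
# matching the strict net-benefit rule.
analytic_ceac <- function(dc, dc_se, de, de_se, wtp_grid) {
  vapply(wtp_grid, function(lambda) {
    nb <- lambda * de - dc
    s <- sqrt(lambda^2 * de_se^2 + dc_se^2)
    if (s == 0) return(as.numeric(nb > 0))
    stats::pnorm(nb / s)
  }, numeric(1))
}

#' Acceptability-curve stability across sample sizes
#'
#' Simulates, for each per-arm sample size in `n_grid`, `reps` trials from
#' fixed population cost/effect distributions, computes each trial's
#' acceptability curve (from the normal approximation of the incremental
#' estimates), and reports the across-trial dispersion (SD) of the
#' cost-effectiveness probability at each willingness-to-pay ceiling. The
#' smallest `n` whose maximal dispersion falls below `threshold` is
#' attached as `attr(, "stable_n")`. The default grid spans 10 to 500 per
#' arm and includes the design point n = 75.
#'
#' @param population a [stability_population()].
#' @param n_grid increasing per-arm sample sizes.
#' @param reps simulated trials per sample size (>= 2).
#' @param wtp_grid willingness-to-pay ceilings.
#' @param seed integer seed.
#' @param threshold dispersion considered "stable" (SD of probability).
#' @return `data.frame` (class `ceac_stability`) with columns `n`, `wtp`,
#'   `dispersion`, `mean_probability`; attributes `stable_n`, `threshold`.
#' @export
ceac_stability <- function(population = stability_population(),
                           n_grid = c(10, 25, 50, 75, 100, 150, 250, 500),
                           reps = 100, wtp_grid = seq(0, 30000, by = 5000),
                           seed = 1L, threshold = 0.05) {
  stopifnot(!is.unsorted(n_grid, strictly = TRUE), reps >= 2)
  set.seed(seed)
  pop <- population
  res <- list()
  stable_n <- NA_integer_
  for (n in n_grid) {
    probs <- matrix(NA_real_, reps, length(wtp_grid))
    for (r in seq_len(reps)) {
      cb <- draw_arm_costs(n, pop$cost_mean[1], pop$cost_sd[1])
      cs <- draw_arm_costs(n, pop$cost_mean[2], pop$cost_sd[2])
      if (is.null(pop$effect_sd)) {
        eb <- stats::rbinom(n, 1, pop$effect_prob[1])
        es <- stats::rbinom(n, 1, pop$effect_prob[2])
      } else {
        eb <- stats::rnorm(n, pop$effect_mean[1], pop$effect_sd[1])
        es <- stats::rnorm(n, pop$effect_mean[2], pop$effect_sd[2])
      }
      dc <- mean(cb) - mean(cs)
      de <- mean(eb) - mean(es)
      dc_se <- sqrt(stats::var(cb) / n + stats::var(cs) / n)
      de_se <- sqrt(stats::var(eb) / n + stats::var(es) / n)
      probs[r, ] <- analytic_ceac(dc, dc_se, de, de_se, wtp_grid)
    }
    disp <- apply(probs, 2, stats::sd)
    res[[as.character(n)]] <- data.frame(
      n = n, wtp = wtp_grid, dispersion = disp,
      mean_probability = colMeans(probs))
    if (is.na(stable_n) && max(disp) < threshold) stable_n <- n
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, stable_n = stable_n, threshold = threshold,
            class = c("ceac_stability", "data.frame"))
}
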