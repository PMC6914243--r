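# Shared lme4 control: fast, quiet; singular fits are legitimate here
# (degenerate synthetic data and bootstrap replicates routinely hit the
# variance boundary).
lmm_control <- function(loose = FALSE) {
  lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = "ignore",
    check.conv.grad = "ignore",
    check.conv.hess = "ignore",
    optCtrl = if (loose) list(xtol_abs = 1e-6, ftol_abs = 1e-6) else list())
}

new_model_estimate <- function(coefs, vc, group_term, fit_meta) {
  est <- coefs[group_term, "estimate"]
  se <- coefs[group_term, "se"]
  structure(list(
    coefficients = coefs,
    covariance = vc,
    group_effect = list(estimate = est, se = se,
                        ci = c(est - 1.96 * se, est + 1.96 * se)),
    fit_meta = fit_meta),
    class = "model_estimate")
}

#' @exportS3Method base::print
print.model_estimate <- function(x, ...) {
  g <- x$group_effect
  cat(sprintf("<model_estimate> group effect %.4g (95%% CI %.4g to %.4g)\n",
              g$estimate, g$ci[1], g$ci[2]))
  cat(sprintf("  n_obs=%d n_patients=%d converged=%s%s\n",
              x$fit_meta$n_obs, x$fit_meta$n_patients,
              x$fit_meta$converged,
              if (isTRUE(x$fit_meta$fallback_lm)) " (lm fallback)" else ""))
  invisible(x)
}

coef_table <- function(est, se) {
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             ci_lo = unname(est - 1.96 * se), ci_hi = unname(est + 1.96 * se),
             stringsAsFactors = FALSE, row.names = names(est))
}

# Fit lmer with two attempts (default optimizer, then bobyqa); fall back to
# a fixed-effects lm when the random-intercept fit errors out entirely
# (e.g. zero residual variance in degenerate noise-free data).
fit_lmm_engine <- function(d, rhs, reml = TRUE) {
  try_fit <- function(control) {
    warns <- character()
    fit <- withCallingHandlers(
      tryCatch(lme4::lmer(stats::as.formula(
        paste(".y ~", rhs, "+ (1 | patient_id)")),
        data = d, REML = reml, control = control),
        error = function(e) e),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(fit = fit, warns = warns)
  }
  a1 <- try_fit(lmm_control())
  if (!inherits(a1$fit, "error") && !length(a1$warns))
    return(list(fit = a1$fit, converged = TRUE, fallback = FALSE))
  a2 <- try_fit(lme4::lmerControl(optimizer = "bobyqa",
                                  calc.derivs = FALSE,
                                  check.conv.singular = "ignore",
                                  check.conv.grad = "ignore",
                                  check.conv.hess = "ignore"))
  if (!inherits(a2$fit, "error"))
    return(list(fit = a2$fit, converged = !length(a2$warns),
                fallback = FALSE))
  if (!inherits(a1$fit, "error"))
    return(list(fit = a1$fit, converged = FALSE, fallback = FALSE))
  list(fit = stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d),
       converged = TRUE, fallback = TRUE)
}

#' Baseline-adjusted linear mixed model for a longitudinal outcome
#'
#' Fits (by default with restricted maximum likelihood) a linear mixed model
#' on the follow-up rows of a long panel: fixed effects for treatment group,
#' assessment week as a categorical variable, optionally their interaction
#' and a baseline covariate; a random intercept per patient. Patients with
#' partially missing follow-ups contribute their observed rows
#' (likelihood-based handling under missing-at-random; no imputation, no
#' listwise deletion).
#'
#' @param data long `data.frame` with columns `patient_id`, `arm`, `week`,
#'   the outcome, and the baseline covariate if requested. Follow-up rows
#'   (`week > 0`) are modeled.
#' @param outcome name of the (numeric) outcome column.
#' @param baseline name of a patient-level baseline covariate column, or
#'   `NULL` for no baseline adjustment.
#' @param include_time include week as a categorical fixed effect.
#' @param group_time_interaction add the group x time interaction (gives
#'   per-assessment group contrasts).
#' @param random_intercept include the per-patient random intercept.
#' @param reml use restricted maximum likelihood (default).
#' @return a `model_estimate`: coefficient table, fixed-effect covariance,
#'   the group effect with Wald 95% CI, and fit metadata (convergence flag,
#'   singularity, lm fallback, n).
#' @export
fit_lmm <- function(data, outcome, baseline = NULL, include_time = TRUE,
                    group_time_interaction = FALSE, random_intercept = TRUE,
                    reml = TRUE) {
  d <- data[data$week > 0 & !is.na(data[[outcome]]), , drop = FALSE]
  if (!nrow(d)) stop("no non-missing follow-up outcomes", call. = FALSE)
  d$.y <- as.numeric(d[[outcome]])
  d$.week <- factor(d$week)
  terms <- "arm"
  if (include_time) terms <- c(terms, ".week")
  if (group_time_interaction) terms <- c(terms, "arm:.week")
  if (!is.null(baseline)) {
    d$.base <- as.numeric(d[[baseline]])
    terms <- c(terms, ".base")
  }
  rhs <- paste(terms, collapse = " + ")
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d)
  if (qr(mm)$rank < ncol(mm))
    stop("singular fixed-effect design", call. = FALSE)
  if (random_intercept) {
    res <- fit_lmm_engine(d, rhs, reml = reml)
  } else {
    res <- list(fit = stats::lm(stats::as.formula(paste(".y ~", rhs)), d),
                converged = TRUE, fallback = TRUE)
  }
  fit <- res$fit
  if (inherits(fit, "merMod")) {
    vc <- tryCatch(as.matrix(stats::vcov(fit)), error = function(e) NULL,
                   warning = function(w) NULL)
    if (is.null(vc) || anyNA(vc)) {
      # degenerate (zero-variance) mixed fit: fall back to fixed effects
      res <- list(fit = stats::lm(stats::as.formula(paste(".y ~", rhs)),
                                  d),
                  converged = TRUE, fallback = TRUE)
      fit <- res$fit
    }
  }
  if (inherits(fit, "merMod")) {
    est <- lme4::fixef(fit)
    singular <- lme4::isSingular(fit)
  } else {
    est <- stats::coef(fit)
    # a perfect fit (noise-free data) makes summary.lm warn; that is the
    # degenerate case the fallback exists for
    vc <- suppressWarnings(stats::vcov(fit))
    singular <- NA
  }
  se <- sqrt(diag(vc))
  meta <- list(converged = res$converged, singular = singular,
               fallback_lm = res$fallback && random_intercept,
               n_obs = nrow(d),
               n_patients = length(unique(d$patient_id)))
  new_model_estimate(coef_table(est, se), vc, "armblended", meta)
}

#' Logistic (mixed) model for a binary longitudinal outcome
#'
#' Fits a logistic model on follow-up rows with group and categorical time.
#' By default the random intercept is omitted (appropriate when all
#' patients share the same baseline state, e.g. everyone starts in a
#' depressive episode); set `random_intercept = TRUE` for a logistic mixed
#' model via `glmer`. Coefficients are reported on the log-odds scale with
#' an odds-ratio column. Complete separation (or a degenerate constant
#' outcome) is flagged via `fit_meta$infinite_se`, never silent.
#'
#' @inheritParams fit_lmm
#' @param outcome name of a logical/0-1 outcome column.
#' @return a `model_estimate`; `coefficients$or` holds odds ratios.
#' @export
fit_logistic_mixed <- function(data, outcome, include_time = TRUE,
                               random_intercept = FALSE) {
  d <- data[data$week > 0 & !is.na(data[[outcome]]), , drop = FALSE]
  if (!nrow(d)) stop("no non-missing follow-up outcomes", call. = FALSE)
  d$.y <- as.numeric(d[[outcome]])
  d$.week <- factor(d$week)
  rhs <- if (include_time) "arm + .week" else "arm"
  if (random_intercept) {
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(stats::as.formula(paste(".y ~", rhs, "+ (1 | patient_id)")),
                  data = d, family = stats::binomial())))
    est <- lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
  } else {
    fit <- suppressWarnings(
      stats::glm(stats::as.formula(paste(".y ~", rhs)), data = d,
                 family = stats::binomial()))
    est <- stats::coef(fit)
    vc <- stats::vcov(fit)
  }
  se <- sqrt(diag(vc))
  infinite_se <- any(se > 50) || any(abs(est) > 15)
  coefs <- coef_table(est, se)
  coefs$or <- exp(coefs$estimate)
  meta <- list(converged = TRUE, infinite_se = infinite_se,
               n_obs = nrow(d), n_patients = length(unique(d$patient_id)))
  if (infinite_se && stats::var(d$.y) == 0) {
    # constant outcome: no information about the group effect
    coefs["armblended", c("estimate", "ci_lo", "ci_hi")] <- 0
    coefs["armblended", "se"] <- Inf
    coefs["armblended", "or"] <- 1
  }
  new_model_estimate(coefs, vc, "armblended", meta)
}

#' Incremental cost and effect estimates for the cost-effectiveness analysis
#'
#' Fits the two baseline-adjusted mixed models of the cost-effectiveness
#' framework on an analysis table from [build_analysis_table()]: cumulative
#' cost on group (adjusted for the baseline window cost) and the chosen
#' effect on group (risk-difference linear mixed model for the binary
#' response/episode effects; mean difference for QALYs, adjusted for
#' baseline utility). Time is not included: each model yields one estimate
#' across all follow-ups.
#'
#' @param tab analysis table from [build_analysis_table()].
#' @param perspective `"societal"` or `"provider"`.
#' @param effect_kind `"response"`, `"episode"`, or `"qaly"`.
#' @param exclude_inpatient,indirect_only cost-variant flags passed through
#'   to the cost column choice (see [build_analysis_table()]).
#' @param binary_effect_model `"risk_difference"` (linear mixed model,
#'   default — the estimand used for the ICER) or `"logistic"` (exposed for
#'   completeness; a different estimand, not used for ICERs).
#' @return list with `delta_cost` and `delta_effect` (each a
#'   `model_estimate`) plus the estimates `dc`, `de` and their `se`s.
#' @export
estimate_cea_effects <- function(tab, perspective = c("societal", "provider"),
                                 effect_kind = c("response", "episode",
                                                 "qaly"),
                                 exclude_inpatient = FALSE,
                                 indirect_only = FALSE,
                                 binary_effect_model = c("risk_difference",
                                                         "logistic")) {
  perspective <- match.arg(perspective)
  effect_kind <- match.arg(effect_kind)
  binary_effect_model <- match.arg(binary_effect_model)
  cost_col <- cost_column(perspective, exclude_inpatient, indirect_only)
  cost_est <- fit_lmm(tab, cost_col, baseline = "base_window_societal",
                      include_time = FALSE)
  eff <- switch(effect_kind,
    response = if (binary_effect_model == "risk_difference")
      fit_lmm(tab, "response", baseline = "base_ids", include_time = FALSE)
    else fit_logistic_mixed(tab, "response", include_time = FALSE),
    episode = if (binary_effect_model == "risk_difference")
      fit_lmm(tab, "episode", baseline = NULL, include_time = FALSE)
    else fit_logistic_mixed(tab, "episode", include_time = FALSE),
    qaly = fit_lmm(tab, "qaly_cum", baseline = "base_utility",
                   include_time = FALSE))
  list(delta_cost = cost_est, delta_effect = eff,
       dc = cost_est$group_effect$estimate,
       de = eff$group_effect$estimate,
       dc_se = cost_est$group_effect$se,
       de_se = eff$group_effect$se,
       perspective = perspective, effect_kind = effect_kind)
}

cost_column <- function(perspective, exclude_inpatient, indirect_only) {
  if (indirect_only && perspective == "provider")
    stop("indirect_only is inconsistent with the provider perspective",
         call. = FALSE)
  if (indirect_only) return("cost_indirect_only")
  paste0("cost_", perspective,
         if (exclude_inpatient) "_noinpat" else "")
}

#' Build the patient x follow-up analysis table for the CEA models
#'
#' Merges the derived outcome and cost panels into one follow-up-level table
#' holding every cost aggregate the analyses need (societal and provider,
#' each with and without inpatient items, plus the indirect-only aggregate)
#' and the patient-level baselines used for adjustment (baseline depression
#' score, baseline utility, baseline window societal cost).
#'
#' @param data `trial_data`.
#' @param table a [unit_cost_table()].
#' @param params [rci_params()].
#' @param method,anchor_baseline passed to [derive_costs()].
#' @return `data.frame`, one row per patient x follow-up.
#' @export
build_analysis_table <- function(data, table = default_unit_costs(),
                                 params = rci_params(),
                                 method = "trapezoid",
                                 anchor_baseline = TRUE) {
  out <- derive_outcomes(data, params)
  cp <- derive_costs(data, table, method = method,
                     anchor_baseline = anchor_baseline)
  fup <- cp[cp$week > 0, c("patient_id", "week")]
  fup$cost_societal <- perspective_costs(cp, "societal")$cost[cp$week > 0]
  fup$cost_provider <- perspective_costs(cp, "provider")$cost[cp$week > 0]
  fup$cost_societal_noinpat <-
    perspective_costs(cp, "societal", exclude_inpatient = TRUE)$cost[cp$week > 0]
  fup$cost_provider_noinpat <-
    perspective_costs(cp, "provider", exclude_inpatient = TRUE)$cost[cp$week > 0]
  fup$cost_indirect_only <-
    perspective_costs(cp, "societal", indirect_only = TRUE)$cost[cp$week > 0]
  tab <- merge(out, fup, by = c("patient_id", "week"))
  base <- data[data$week == 0,
               c("patient_id", "ids_sr", "utility")]
  names(base) <- c("patient_id", "base_ids", "base_utility")
  bw <- derive_costs_baseline_window(cp)
  tab <- merge(tab, base, by = "patient_id")
  tab <- merge(tab, bw, by = "patient_id")
  tab <- tab[order(tab$patient_id, tab$week), ]
  rownames(tab) <- NULL
  tab
}

derive_costs_baseline_window <- function(cost_panel) {
  b <- cost_panel[cost_panel$week == 0, ]
  data.frame(patient_id = b$patient_id,
             base_window_societal = b$win_direct_medical +
               b$win_direct_nonmedical + b$win_indirect_nonmedical,
             stringsAsFactors = FALSE)
}
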