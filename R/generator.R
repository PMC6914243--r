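#' Configuration for the synthetic two-arm trial generator
#'
#' Builds a validated configuration object describing the stochastic world the
#' generator samples from: a two-arm psychotherapy trial (blended vs standard
#' care) with repeated assessments, depression severity on a 0--84 self-report
#' scale, EQ-5D utilities linked negatively to severity, right-skewed 4-week
#' resource-use costs with rare high-cost inpatient events, and logistic
#' visit-level missingness driven by age and employment.
#'
#' Defaults emulate a pilot depression trial in specialized mental health
#' care: arms of 53 and 49 patients assessed at weeks 0/10/20/30, baseline
#' severity 45.2 (SD 12.1) vs 41.5 (SD 11.6), utilities around 0.36--0.46,
#' skewed window costs with occasional inpatient spikes, and roughly a third
#' of follow-up visits missing, more often for younger and unemployed
#' patients.
#'
#' @param n_per_arm integer pair: patients in the (blended, standard) arm.
#' @param assessment_weeks strictly increasing non-negative integers starting
#'   at 0; week 0 is baseline.
#' @param baseline_ids_mean_sd list with elements `blended` and `standard`,
#'   each `c(mean, sd)` of baseline depression score (points).
#' @param time_effect mean change from baseline in depression score at each
#'   follow-up (points). Either one value per follow-up, or a single
#'   per-step value that accumulates (k-th follow-up gets `k * time_effect`).
#' @param group_effect additive effect of the blended arm on follow-up
#'   depression scores (points).
#' @param random_intercept_sd SD of the shared patient-level deviation added
#'   to all follow-up scores (points); controls between-assessment
#'   correlation beyond the baseline carry-over.
#' @param residual_sd SD of the visit-level score noise (points).
#' @param utility_link list `(intercept, slope, noise_sd)`: utility =
#'   intercept - slope * score + Gaussian noise, clamped to `[-0.33, 1]`
#'   (national-tariff floor).
#' @param episode_model list `(intercept, step, group)` on the logit scale:
#'   probability of a depressive episode at follow-up k is
#'   `plogis(intercept + step*(k-1) + group*[blended])`; baseline is always
#'   an episode (trial inclusion criterion).
#' @param cost_params list with gamma `(shape, scale)` pairs (euro per 4-week
#'   window) for `direct_medical`, `direct_nonmedical`,
#'   `indirect_nonmedical`, plus `inpatient_prob` (per-window event
#'   probability) and `inpatient_cost` (euro per event).
#' @param group_cost_effect additive blended-arm effect on follow-up window
#'   direct medical costs (euro; follow-up windows only, floored at 0).
#' @param session_model list of `c(mean, sd)` for `f2f_blended`,
#'   `online_blended`, `feedback_blended`, `f2f_standard`; counts are drawn
#'   from truncated-at-zero normals and rounded.
#' @param dropout_model list `(intercept, age, employed)`: per-visit
#'   missingness logit is `intercept + age*(age-40) + employed*[employed]`.
#'   `intercept = -Inf` disables missingness.
#' @param age_mean_sd,employment_rate baseline covariate distributions.
#' @param seed integer seed; same seed and config reproduce the dataset
#'   bit-identically.
#'
#' @return object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_per_arm = c(53L, 49L),
                             assessment_weeks = c(0L, 10L, 20L, 30L),
                             baseline_ids_mean_sd = list(
                               blended = c(45.2, 12.1),
                               standard = c(41.5, 11.6)),
                             time_effect = c(-11.4, -14.4, -17.6),
                             group_effect = 2,
                             random_intercept_sd = 6,
                             residual_sd = 9,
                             utility_link = list(intercept = 1.06,
                                                 slope = 0.015,
                                                 noise_sd = 0.25),
                             episode_model = list(intercept = 0,
                                                  step = -0.35,
                                                  group = 0.3),
                             cost_params = list(
                               direct_medical = c(shape = 1.15, scale = 392),
                               direct_nonmedical = c(shape = 0.23, scale = 1080),
                               indirect_nonmedical = c(shape = 0.20, scale = 3560),
                               inpatient_prob = 0.02,
                               inpatient_cost = 5000),
                             group_cost_effect = 150,
                             session_model = list(
                               f2f_blended = c(10.0, 4.6),
                               online_blended = c(9.6, 4.4),
                               feedback_blended = c(8.4, 4.2),
                               f2f_standard = c(13.3, 6.3)),
                             dropout_model = list(intercept = stats::qlogis(0.30),
                                                  age = -0.04,
                                                  employed = -0.7),
                             age_mean_sd = c(38.8, 10.9),
                             employment_rate = 0.58,
                             seed = 1L) {
  cfg <- list(n_per_arm = as.integer(n_per_arm),
              assessment_weeks = as.integer(assessment_weeks),
              baseline_ids_mean_sd = baseline_ids_mean_sd,
              time_effect = time_effect,
              group_effect = group_effect,
              random_intercept_sd = random_intercept_sd,
              residual_sd = residual_sd,
              utility_link = utility_link,
              episode_model = episode_model,
              cost_params = cost_params,
              group_cost_effect = group_cost_effect,
              session_model = session_model,
              dropout_model = dropout_model,
              age_mean_sd = age_mean_sd,
              employment_rate = employment_rate,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stop_cfg <- function(field, msg)
    stop(sprintf("invalid generator config: field '%s' %s", field, msg),
         call. = FALSE)
  if (length(cfg$n_per_arm) != 2 || any(is.na(cfg$n_per_arm)) ||
      any(cfg$n_per_arm <= 0))
    stop_cfg("n_per_arm", "must be two positive integers")
  wk <- cfg$assessment_weeks
  if (length(wk) < 2 || wk[1] != 0 || any(diff(wk) <= 0))
    stop_cfg("assessment_weeks",
             "must be strictly increasing and start at 0")
  for (a in c("blended", "standard")) {
    ms <- cfg$baseline_ids_mean_sd[[a]]
    if (length(ms) != 2 || ms[2] < 0)
      stop_cfg("baseline_ids_mean_sd", sprintf("(%s) needs c(mean, sd >= 0)", a))
  }
  nf <- length(wk) - 1L
  if (!(length(cfg$time_effect) %in% c(1L, nf)))
    stop_cfg("time_effect",
             sprintf("must have length 1 or %d (one per follow-up)", nf))
  for (f in c("random_intercept_sd", "residual_sd"))
    if (cfg[[f]] < 0) stop_cfg(f, "must be non-negative")
  if (cfg$utility_link$noise_sd < 0)
    stop_cfg("utility_link", "noise_sd must be non-negative")
  cp <- cfg$cost_params
  for (cat in c("direct_medical", "direct_nonmedical", "indirect_nonmedical"))
    if (any(cp[[cat]] <= 0))
      stop_cfg("cost_params", sprintf("(%s) gamma shape/scale must be > 0", cat))
  if (cp$inpatient_prob < 0 || cp$inpatient_prob > 1)
    stop_cfg("cost_params", "inpatient_prob must be in [0, 1]")
  if (cp$inpatient_cost < 0)
    stop_cfg("cost_params", "inpatient_cost must be >= 0")
  if (cfg$employment_rate < 0 || cfg$employment_rate > 1)
    stop_cfg("employment_rate", "must be in [0, 1]")
  invisible(cfg)
}

# Cumulative time effect at follow-ups 1..nf (scalar accumulates per step).
time_effect_vector <- function(cfg) {
  nf <- length(cfg$assessment_weeks) - 1L
  if (length(cfg$time_effect) == 1L) cfg$time_effect * seq_len(nf)
  else cfg$time_effect
}

#' Resource-use item names used by the generator and the default cost table
#' @return character vector of item column names (without the `ru_` prefix).
#' @export
resource_items <- function() {
  c("gp_visit", "specialist_visit", "medication_item",
    "psych_inpatient_day", "hospital_day",
    "informal_care_hour", "productivity_hour")
}

# Draw one truncated (at zero) normal count vector, rounded to integers.
rtrunc_count <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  as.integer(round(pmax(x, 0)))
}

#' Generate a synthetic two-arm trial dataset
#'
#' Samples a complete long-format panel (one row per patient per assessment
#' week, no missing values) from the world described by a
#' [generator_config()]. Follow-up depression scores are baseline +
#' cumulative time effect + arm effect + patient-level deviation + visit
#' noise, clamped to `[0, 84]` then rounded. Utilities follow the configured
#' negative link to severity, clamped to `[-0.33, 1]`. Window costs per
#' category are gamma draws (plus a Bernoulli inpatient event) converted to
#' resource-use counts with the default unit-cost table, so that costing the
#' dataset with that table reproduces the configured euro amounts.
#' Missingness is added separately by [apply_missingness()].
#'
#' @param config a [generator_config()].
#' @return a `data.frame` of class `trial_data` with columns `patient_id`,
#'   `arm`, `age`, `employed`, `week`, `ids_sr`, `utility`, `episode`,
#'   `ru_*` resource-use counts, `n_f2f_sessions`, `n_online_sessions`,
#'   `n_feedback_messages`. The seed and config are attached as attributes.
#' @seealso [apply_missingness()], [validate_dataset()]
#' @export
generate_trial <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  validate_generator_config(config)
  set.seed(config$seed)
  wk <- config$assessment_weeks
  nf <- length(wk) - 1L
  n_b <- config$n_per_arm[1]
  n_s <- config$n_per_arm[2]
  n <- n_b + n_s
  arm <- factor(rep(c("blended", "standard"), c(n_b, n_s)),
                levels = c("standard", "blended"))

  age <- round(pmin(pmax(stats::rnorm(n, config$age_mean_sd[1],
                                      config$age_mean_sd[2]), 18), 70))
  employed <- stats::runif(n) < config$employment_rate

  mu <- ifelse(arm == "blended",
               config$baseline_ids_mean_sd$blended[1],
               config$baseline_ids_mean_sd$standard[1])
  sdv <- ifelse(arm == "blended",
                config$baseline_ids_mean_sd$blended[2],
                config$baseline_ids_mean_sd$standard[2])
  ids0 <- stats::rnorm(n, mu, sdv)
  u_i <- stats::rnorm(n, 0, config$random_intercept_sd)
  teff <- time_effect_vector(config)

  ids <- matrix(NA_real_, n, nf + 1L)
  ids[, 1] <- ids0
  for (k in seq_len(nf)) {
    ids[, k + 1L] <- ids0 + teff[k] +
      config$group_effect * (arm == "blended") + u_i +
      stats::rnorm(n, 0, config$residual_sd)
  }
  # clamp before rounding; scores are integer points on a 0-84 scale
  ids <- round(pmin(pmax(ids, 0), 84))

  ul <- config$utility_link
  util <- ul$intercept - ul$slope * ids +
    matrix(stats::rnorm(n * (nf + 1L), 0, ul$noise_sd), n)
  util <- pmin(pmax(util, -0.33), 1)

  em <- config$episode_model
  episode <- matrix(NA, n, nf + 1L)
  episode[, 1] <- TRUE
  for (k in seq_len(nf)) {
    p <- stats::plogis(em$intercept + em$step * (k - 1L) +
                         em$group * (arm == "blended"))
    episode[, k + 1L] <- stats::runif(n) < p
  }

  # euro window costs per category, then conversion to item counts
  cp <- config$cost_params
  uc <- default_unit_costs()
  price <- uc$prices
  dm_split <- c(gp_visit = 0.2, specialist_visit = 0.5, medication_item = 0.3)
  items <- resource_items()
  ru <- array(0, dim = c(n, nf + 1L, length(items)),
              dimnames = list(NULL, NULL, items))
  for (k in seq_len(nf + 1L)) {
    dm <- stats::rgamma(n, shape = cp$direct_medical["shape"],
                        scale = cp$direct_medical["scale"])
    if (k > 1L)
      dm <- pmax(dm + config$group_cost_effect * (arm == "blended"), 0)
    dnm <- stats::rgamma(n, shape = cp$direct_nonmedical["shape"],
                         scale = cp$direct_nonmedical["scale"])
    inm <- stats::rgamma(n, shape = cp$indirect_nonmedical["shape"],
                         scale = cp$indirect_nonmedical["scale"])
    inpat <- stats::runif(n) < cp$inpatient_prob
    ru[, k, "gp_visit"] <- dm * dm_split["gp_visit"] / price["gp_visit"]
    ru[, k, "specialist_visit"] <-
      dm * dm_split["specialist_visit"] / price["specialist_visit"]
    ru[, k, "medication_item"] <- dm * dm_split["medication_item"] /
      (price["medication_item"] + uc$dispensing_fee)
    ru[, k, "psych_inpatient_day"] <-
      ifelse(inpat, cp$inpatient_cost / price["psych_inpatient_day"], 0)
    ru[, k, "informal_care_hour"] <- dnm / price["informal_care_hour"]
    ru[, k, "productivity_hour"] <- inm / price["productivity_hour"]
  }

  sm <- config$session_model
  f2f <- ifelse(arm == "blended",
                rtrunc_count(n, sm$f2f_blended[1], sm$f2f_blended[2]),
                rtrunc_count(n, sm$f2f_standard[1], sm$f2f_standard[2]))
  online <- ifelse(arm == "blended",
                   rtrunc_count(n, sm$online_blended[1], sm$online_blended[2]),
                   0L)
  feedback <- ifelse(arm == "blended",
                     rtrunc_count(n, sm$feedback_blended[1],
                                  sm$feedback_blended[2]),
                     0L)

  idx <- rep(seq_len(n), each = nf + 1L)
  kidx <- rep(seq_len(nf + 1L), times = n)
  out <- data.frame(patient_id = sprintf("P%04d", idx),
                    arm = arm[idx],
                    age = age[idx],
                    employed = employed[idx],
                    week = wk[kidx],
                    ids_sr = ids[cbind(idx, kidx)],
                    utility = util[cbind(idx, kidx)],
                    episode = episode[cbind(idx, kidx)],
                    stringsAsFactors = FALSE)
  for (it in items)
    out[[paste0("ru_", it)]] <- ru[cbind(idx, kidx, match(it, items))]
  out$n_f2f_sessions <- f2f[idx]
  out$n_online_sessions <- online[idx]
  out$n_feedback_messages <- feedback[idx]

  attr(out, "seed") <- config$seed
  attr(out, "generator_config") <- config
  class(out) <- c("trial_data", "data.frame")
  out
}

#' Impose covariate-dependent missingness on follow-up assessments
#'
#' Deletes follow-up measurements (scores, utilities, episode status and
#' resource use; never baseline rows or covariates) with per-visit
#' probability `plogis(intercept + age*(age-40) + employed*[employed])` from
#' the config's `dropout_model`. With a negative age coefficient, patients
#' with missing data are younger on average; a negative employment
#' coefficient makes unemployed patients more likely to have missing data.
#' By default dropout is non-monotone (a patient may return at a later
#' assessment); `monotone = TRUE` censors all visits after the first missing
#' one.
#'
#' @param data a complete `trial_data` panel from [generate_trial()].
#' @param config the [generator_config()] carrying `dropout_model`; the
#'   missingness random stream is derived from `config$seed` so generation
#'   and missingness are independently reproducible.
#' @param monotone logical; censor after first missing visit.
#' @return `trial_data` with `NA`s in measurement columns of missing visits.
#' @export
apply_missingness <- function(data, config, monotone = FALSE) {
  stopifnot(inherits(config, "generator_config"))
  dm <- config$dropout_model
  set.seed((config$seed + 1L) %% .Machine$integer.max)
  fup <- data$week > 0
  lp <- dm$intercept + dm$age * (data$age - 40) + dm$employed * data$employed
  p <- stats::plogis(lp)
  miss <- fup & (stats::runif(nrow(data)) < p)
  if (monotone) {
    for (pid in unique(data$patient_id[miss])) {
      rows <- which(data$patient_id == pid & fup)
      first <- min(which(miss[rows]))
      miss[rows[first:length(rows)]] <- TRUE
    }
  }
  meas <- c("ids_sr", "utility", "episode",
            paste0("ru_", resource_items()))
  for (col in meas) data[[col]][miss] <- NA
  data
}

#' @exportS3Method base::print
print.trial_data <- function(x, ...) {
  cat(sprintf("<trial_data> %d patients x %d assessments (%d rows)\n",
              length(unique(x$patient_id)), length(unique(x$week)), nrow(x)))
  cat(sprintf("  arms: %s\n",
              paste(sprintf("%s=%d", levels(x$arm),
                            tabulate(x$arm[!duplicated(x$patient_id)])),
                    collapse = ", ")))
  nmiss <- sum(is.na(x$ids_sr[x$week > 0]))
  cat(sprintf("  missing follow-up scores: %d\n", nmiss))
  invisible(x)
}

#' Write / read a trial dataset as CSV with seed metadata
#'
#' The seed (and package version) are recorded as `#`-prefixed comment lines
#' at the top of the file; [read_trial_csv()] restores them as attributes.
#'
#' @param data `trial_data`.
#' @param path file path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns a `trial_data`.
#' @export
write_trial_csv <- function(data, path) {
  con <- file(path, "w")
  on.exit(close(con))
  seed <- attr(data, "seed")
  writeLines(sprintf("# blendcea trial dataset; seed=%s",
                     if (is.null(seed)) "NA" else seed), con)
  utils::write.csv(as.data.frame(data), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  header <- readLines(path, n = 1L)
  df <- tryCatch(
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("failed to read '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  required <- c("patient_id", "arm", "week", "ids_sr", "utility")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("malformed trial CSV '%s': missing column(s) %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df$arm <- factor(df$arm, levels = c("standard", "blended"))
  if (grepl("seed=", header))
    attr(df, "seed") <- suppressWarnings(
      as.integer(sub(".*seed=", "", header)))
  class(df) <- c("trial_data", "data.frame")
  df
}
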