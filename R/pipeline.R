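#' Configuration of a full pipeline run
#'
#' Either a generator configuration (a synthetic dataset is drawn) or a path
#' to an existing long-format trial CSV — not both. All randomness flows
#' from `seed`: the generator, the missingness mechanism, and each
#' analysis's Monte Carlo stream get deterministic sub-seeds derived from
#' it.
#'
#' @param generator a [generator_config()], or `NULL` when `dataset_path`
#'   is given.
#' @param dataset_path path to a trial CSV from [write_trial_csv()], or
#'   `NULL`.
#' @param unit_costs a [unit_cost_table()] or a path to a unit-cost CSV.
#' @param analyses `data.frame` with columns `perspective`, `effect_kind`;
#'   default: the full 2 x 3 grid (societal/provider x
#'   response/episode/qaly).
#' @param n_draws Monte Carlo draws per analysis.
#' @param method `"cluster_bootstrap"` or `"parametric"`.
#' @param wtp_grid willingness-to-pay ceilings for the acceptability curves.
#' @param sensitivity character subset of
#'   `c("exclude_inpatient", "indirect_only")` to run as cost variants of
#'   the societal response analysis.
#' @param apply_dropout impose the configured missingness on generated data.
#' @param seed root seed.
#' @param output_dir directory for the run artifacts.
#' @return list of class `run_config`.
#' @export
run_config <- function(generator = generator_config(),
                       dataset_path = NULL,
                       unit_costs = default_unit_costs(),
                       analyses = default_analyses(),
                       n_draws = 1000, method = "cluster_bootstrap",
                       wtp_grid = seq(0, 80000, by = 1000),
                       sensitivity = character(),
                       apply_dropout = TRUE,
                       seed = 1L, output_dir = tempfile("blendcea_run")) {
  if (!is.null(generator) && !is.null(dataset_path))
    stop("supply either a generator config or a dataset path, not both",
         call. = FALSE)
  if (is.null(generator) && is.null(dataset_path))
    stop("one of generator or dataset_path is required", call. = FALSE)
  if (is.character(unit_costs)) unit_costs <- read_unit_costs(unit_costs)
  structure(list(generator = generator, dataset_path = dataset_path,
                 unit_costs = unit_costs, analyses = analyses,
                 n_draws = n_draws, method = method, wtp_grid = wtp_grid,
                 sensitivity = sensitivity, apply_dropout = apply_dropout,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' @rdname run_config
#' @export
default_analyses <- function() {
  expand.grid(perspective = c("societal", "provider"),
              effect_kind = c("response", "episode", "qaly"),
              stringsAsFactors = FALSE)[, 2:1][, c("perspective",
                                                   "effect_kind")]
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Generate (or load) the trial dataset, derive the outcome and cost panels,
#' fit the descriptive mixed models, run every configured
#' cost-effectiveness analysis plus sensitivity variants, and write all
#' artifacts (CSV tables plus a JSON manifest echoing the configuration and
#' seed) to the output directory. Identical configuration and seed give
#' byte-identical artifacts.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory artifacts: `data`,
#'   `outcomes`, `costs`, `models`, `cea` (one element per analysis),
#'   `sensitivity`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out_file <- function(...) file.path(config$output_dir, ...)

  data <- stage("load_data", {
    if (!is.null(config$dataset_path)) {
      read_trial_csv(config$dataset_path)
    } else {
      gen <- config$generator
      gen$seed <- config$seed
      d <- generate_trial(gen)
      if (config$apply_dropout) d <- apply_missingness(d, gen)
      write_trial_csv(d, out_file("dataset.csv"))
      d
    }
  })

  violations <- stage("validate", validate_dataset(data))
  if (nrow(violations))
    stop(sprintf("pipeline stage 'validate' failed: %d invariant violation(s); first: %s",
                 nrow(violations), violations$message[1]), call. = FALSE)

  outcomes <- stage("outcomes", derive_outcomes(data))
  costs <- stage("costing", derive_costs(data, config$unit_costs))
  utils::write.csv(outcomes, out_file("outcomes.csv"), row.names = FALSE)
  utils::write.csv(costs, out_file("costs.csv"), row.names = FALSE)

  tab <- stage("analysis_table",
               build_analysis_table(data, config$unit_costs))

  models <- stage("models", {
    rows <- list()
    add <- function(id, est) {
      cf <- est$coefficients
      if (is.null(cf$or)) cf$or <- NA_real_
      cf$model <- id
      rows[[length(rows) + 1]] <<- cf
    }
    add("ids_sr_time", fit_lmm(merge_outcome(data, "ids_sr"), "ids_sr",
                               baseline = "base_ids"))
    add("qaly_time", fit_lmm(tab, "qaly_cum", baseline = "base_utility"))
    add("response_logistic", fit_logistic_mixed(tab, "response"))
    add("episode_logistic", fit_logistic_mixed(tab, "episode"))
    do.call(rbind, rows)
  })
  utils::write.csv(models, out_file("models.csv"), row.names = FALSE)

  cea_rows <- list()
  cea_results <- list()
  for (i in seq_len(nrow(config$analyses))) {
    persp <- config$analyses$perspective[i]
    eff <- config$analyses$effect_kind[i]
    id <- paste(persp, eff, sep = "_")
    res <- stage(paste0("cea_", id),
                 run_cea(perspective = persp, effect_kind = eff,
                         n_draws = config$n_draws,
                         seed = (config$seed + 100L + i) %%
                           .Machine$integer.max,
                         method = config$method,
                         unit_costs = config$unit_costs,
                         wtp_grid = config$wtp_grid,
                         analysis_table = tab))
    cea_results[[id]] <- res
    p <- attr(res$pairs, "point")
    cea_rows[[id]] <- data.frame(
      perspective = persp, effect_kind = eff,
      delta_cost = p$dc, dc_lo = res$dc_ci[1], dc_hi = res$dc_ci[2],
      delta_effect = p$de, de_lo = res$de_ci[1], de_hi = res$de_ci[2],
      icer = res$icer$icer, quadrant = res$icer$quadrant,
      pct_ne = 100 * res$plane$proportions["NE"],
      pct_nw = 100 * res$plane$proportions["NW"],
      pct_se = 100 * res$plane$proportions["SE"],
      pct_sw = 100 * res$plane$proportions["SW"],
      stringsAsFactors = FALSE)
    utils::write.csv(res$ceac, out_file(sprintf("ceac_%s.csv", id)),
                     row.names = FALSE)
  }
  cea_summary <- do.call(rbind, cea_rows)
  rownames(cea_summary) <- NULL
  utils::write.csv(cea_summary, out_file("cea_summary.csv"),
                   row.names = FALSE)

  sens <- list()
  if (length(config$sensitivity))
    sens <- stage("sensitivity",
                  sensitivity_suite(variants = config$sensitivity,
                                    perspective = "societal",
                                    effect_kind = "response",
                                    n_draws = config$n_draws,
                                    seed = (config$seed + 999L) %%
                                      .Machine$integer.max,
                                    method = config$method,
                                    unit_costs = config$unit_costs,
                                    wtp_grid = config$wtp_grid,
                                    analysis_table = tab))

  manifest <- list(
    package = "blendcea",
    version = as.character(utils::packageVersion("blendcea")),
    seed = config$seed,
    n_draws = config$n_draws,
    method = config$method,
    n_patients = length(unique(data$patient_id)),
    n_rows = nrow(data),
    analyses = paste(config$analyses$perspective,
                     config$analyses$effect_kind, sep = "_"),
    sensitivity = config$sensitivity,
    wtp_grid = range(config$wtp_grid))
  jsonlite::write_json(manifest, out_file("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(data = data, outcomes = outcomes, costs = costs,
                 models = models, cea_summary = cea_summary,
                 cea = cea_results, sensitivity = sens,
                 manifest = manifest, output_dir = config$output_dir))
}

# attach the baseline score of an outcome as a column for fit_lmm
merge_outcome <- function(data, outcome) {
  base <- data[data$week == 0, c("patient_id", outcome)]
  names(base)[2] <- "base_ids"
  merge(data, base, by = "patient_id")
}

#' Validate a trial dataset against its structural invariants
#'
#' Checks one-row-per-patient-week uniqueness, complete baselines, score
#' and utility ranges, non-negative resource-use counts, and that the
#' standard arm has no online sessions or feedback messages. All violations
#' are reported (with patient/week coordinates), not just the first.
#'
#' @param data a `trial_data` or a path to a trial CSV.
#' @return `data.frame` with columns `rule`, `patient_id`, `week`,
#'   `message`; zero rows when the dataset is valid.
#' @export
validate_dataset <- function(data) {
  if (is.character(data)) data <- read_trial_csv(data)
  v <- list()
  flag <- function(rule, pid, week, msg)
    v[[length(v) + 1]] <<- data.frame(rule = rule, patient_id = pid,
                                      week = week, message = msg,
                                      stringsAsFactors = FALSE)
  dup <- duplicated(data[, c("patient_id", "week")])
  for (i in which(dup))
    flag("unique_patient_week", data$patient_id[i], data$week[i],
         sprintf("duplicated row for %s at week %d",
                 data$patient_id[i], data$week[i]))
  base <- data[data$week == 0, ]
  for (i in which(is.na(base$ids_sr) | is.na(base$utility)))
    flag("baseline_complete", base$patient_id[i], 0L,
         sprintf("missing baseline measurement for %s", base$patient_id[i]))
  bad <- which(!is.na(data$ids_sr) & (data$ids_sr < 0 | data$ids_sr > 84))
  for (i in bad)
    flag("ids_range", data$patient_id[i], data$week[i],
         sprintf("ids_sr %s out of [0, 84] for %s at week %d",
                 data$ids_sr[i], data$patient_id[i], data$week[i]))
  bad <- which(!is.na(data$utility) &
                 (data$utility < -0.33 | data$utility > 1))
  for (i in bad)
    flag("utility_range", data$patient_id[i], data$week[i],
         sprintf("utility %.3f out of [-0.33, 1] for %s at week %d",
                 data$utility[i], data$patient_id[i], data$week[i]))
  for (col in grep("^ru_", names(data), value = TRUE)) {
    bad <- which(!is.na(data[[col]]) & data[[col]] < 0)
    for (i in bad)
      flag("nonnegative_counts", data$patient_id[i], data$week[i],
           sprintf("%s negative for %s at week %d", col,
                   data$patient_id[i], data$week[i]))
  }
  std <- data$arm == "standard"
  bad <- which(std & (data$n_online_sessions > 0 |
                        data$n_feedback_messages > 0))
  for (i in bad)
    flag("standard_arm_offline", data$patient_id[i], data$week[i],
         sprintf("standard-arm patient %s has online activity",
                 data$patient_id[i]))
  if (!length(v))
    return(data.frame(rule = character(), patient_id = character(),
                      week = integer(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}
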