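#' Construct a unit-cost table
#'
#' Maps resource-use items to per-unit prices (euro, reference year
#' configurable by the user) and assigns each item to exactly one of three
#' cost categories: `direct_medical`, `direct_nonmedical`,
#' `indirect_nonmedical`. Also carries the costing constants: the pharmacy
#' dispensing fee added to every prescription, the therapist hourly rate,
#' the assumed therapist minutes per online feedback message, and the price
#' of a face-to-face therapy session.
#'
#' @param items `data.frame` with columns `item`, `price`, `category` and
#'   optional logicals `is_medication` (dispensing fee applies) and
#'   `is_inpatient` (removable by the inpatient sensitivity analysis).
#' @param dispensing_fee euro added per prescription item.
#' @param therapist_hourly_rate euro per therapist hour (feedback costing).
#' @param feedback_minutes assumed therapist minutes per feedback message.
#' @param f2f_session_price euro per face-to-face session.
#' @return object of class `unit_cost_table`.
#' @export
unit_cost_table <- function(items, dispensing_fee = 6,
                            therapist_hourly_rate = 85,
                            feedback_minutes = 30,
                            f2f_session_price = 85) {
  stopifnot(is.data.frame(items),
            all(c("item", "price", "category") %in% names(items)))
  if (any(items$price < 0)) stop("unit prices must be >= 0", call. = FALSE)
  if (anyDuplicated(items$item))
    stop("each item must appear exactly once", call. = FALSE)
  bad <- setdiff(items$category,
                 c("direct_medical", "direct_nonmedical",
                   "indirect_nonmedical"))
  if (length(bad))
    stop(sprintf("unknown cost category: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  if (is.null(items$is_medication)) items$is_medication <- FALSE
  if (is.null(items$is_inpatient)) items$is_inpatient <- FALSE
  structure(list(
    prices = stats::setNames(items$price, items$item),
    category = stats::setNames(items$category, items$item),
    medication_items = items$item[as.logical(items$is_medication)],
    inpatient_items = items$item[as.logical(items$is_inpatient)],
    dispensing_fee = dispensing_fee,
    therapist_hourly_rate = therapist_hourly_rate,
    feedback_minutes = feedback_minutes,
    f2f_session_price = f2f_session_price),
    class = "unit_cost_table")
}

#' Illustrative default unit-cost table
#'
#' Ballpark euro prices for the resource-use items the generator emits.
#' These defaults are NOT the national costing-manual values; they are
#' illustrative placeholders so the pipeline runs end to end. For a real
#' analysis supply the applicable reference-year prices via
#' [read_unit_costs()] or [unit_cost_table()].
#'
#' @return a `unit_cost_table`; `default_unit_costs_items()` returns the
#'   underlying item `data.frame` (handy for writing a template CSV).
#' @export
default_unit_costs <- function() {
  unit_cost_table(default_unit_costs_items())
}

#' @rdname default_unit_costs
#' @export
default_unit_costs_items <- function() {
  data.frame(
    item = c("gp_visit", "specialist_visit", "medication_item",
             "psych_inpatient_day", "hospital_day",
             "informal_care_hour", "productivity_hour"),
    price = c(33, 90, 25, 250, 480, 14, 34),
    category = c("direct_medical", "direct_medical", "direct_medical",
                 "direct_medical", "direct_medical",
                 "direct_nonmedical", "indirect_nonmedical"),
    is_medication = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    is_inpatient = c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Read a unit-cost table from a CSV file
#'
#' One item per line with columns `item, price, category` (optional
#' `is_medication`, `is_inpatient`); costing constants are passed as
#' arguments.
#'
#' @param path CSV path.
#' @inheritParams unit_cost_table
#' @return a `unit_cost_table`.
#' @export
read_unit_costs <- function(path, dispensing_fee = 6,
                            therapist_hourly_rate = 85,
                            feedback_minutes = 30, f2f_session_price = 85) {
  items <- utils::read.csv(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  unit_cost_table(items, dispensing_fee, therapist_hourly_rate,
                  feedback_minutes, f2f_session_price)
}

cost_categories <- c("direct_medical", "direct_nonmedical",
                     "indirect_nonmedical")

#' Cost one 4-week recall window of resource use
#'
#' Category totals are `sum(count * unit price)` over the window's items;
#' medication items contribute `count * (price + dispensing_fee)`. Every
#' used (non-zero, non-missing) item must be priced; an unpriced item is an
#' error naming the item, never a silent zero.
#'
#' @param resource_use named numeric vector of per-item counts.
#' @param table a [unit_cost_table()].
#' @return named numeric: euro totals for the three categories plus
#'   `inpatient` (the inpatient-item share of `direct_medical`).
#' @export
window_costs <- function(resource_use, table) {
  stopifnot(inherits(table, "unit_cost_table"))
  resource_use <- resource_use[!is.na(resource_use) & resource_use != 0]
  if (any(resource_use < 0))
    stop("resource-use counts must be non-negative", call. = FALSE)
  unpriced <- setdiff(names(resource_use), names(table$prices))
  if (length(unpriced))
    stop(sprintf("no unit price for item(s): %s",
                 paste(unpriced, collapse = ", ")), call. = FALSE)
  eff_price <- table$prices[names(resource_use)] +
    table$dispensing_fee * (names(resource_use) %in% table$medication_items)
  item_cost <- resource_use * eff_price
  out <- stats::setNames(numeric(4), c(cost_categories, "inpatient"))
  for (cat in cost_categories)
    out[cat] <- sum(item_cost[table$category[names(item_cost)] == cat])
  out["inpatient"] <- sum(item_cost[names(item_cost) %in%
                                      table$inpatient_items])
  out
}

#' Therapist cost of online feedback messages
#'
#' `n_messages * feedback_minutes / 60 * therapist_hourly_rate` euro;
#' applies to the blended arm only (standard care has no online feedback).
#'
#' @param n_messages non-negative message count(s).
#' @param table a [unit_cost_table()].
#' @return euro cost(s).
#' @export
feedback_cost <- function(n_messages, table) {
  if (any(n_messages < 0, na.rm = TRUE))
    stop("message counts must be non-negative", call. = FALSE)
  n_messages * table$feedback_minutes / 60 * table$therapist_hourly_rate
}

#' Cumulative costs from 4-week window costs
#'
#' Each assessment's window cost is converted to a per-week rate
#' (`window / 4`); the cumulative cost at week `t` is the trapezoid integral
#' of the piecewise-linear rate from 0 to `t`. Missing interior windows are
#' skipped (the rate is interpolated across the gap); windows after the last
#' observed one yield `NA`. A constant window cost of 400 euro therefore
#' accumulates at 100 euro/week. The alternative `method = "window_scale"`
#' multiplies each follow-up window by `gap/4` (2.5 for 10-week gaps) and
#' sums.
#'
#' @param weeks assessment weeks (strictly increasing, starting at 0).
#' @param window_cost euro per 4-week window at each assessment (`NA`
#'   allowed).
#' @param method `"trapezoid"` (default) or `"window_scale"`.
#' @param anchor_baseline logical; if `TRUE` (default) the week-0 window
#'   rate anchors the start of the rate curve. If `FALSE` the baseline
#'   window is treated as a pre-treatment reference: it is dropped and the
#'   first follow-up's rate is carried back to week 0.
#' @param window_weeks recall-window length (weeks).
#' @return cumulative euro at each assessment week (0 at week 0).
#' @export
cumulative_costs <- function(weeks, window_cost, method = c("trapezoid",
                                                            "window_scale"),
                             anchor_baseline = TRUE, window_weeks = 4) {
  method <- match.arg(method)
  stopifnot(length(weeks) == length(window_cost),
            !is.unsorted(weeks, strictly = TRUE), weeks[1] == 0)
  if (method == "window_scale") {
    gaps <- diff(weeks)
    contrib <- window_cost[-1] * gaps / window_weeks
    return(c(0, cumsum(ifelse(is.na(contrib), 0, contrib)) +
               ifelse(cumsum(is.na(contrib)) > 0, NA, 0)))
  }
  rate <- window_cost / window_weeks
  w <- weeks
  if (!anchor_baseline) rate[1] <- NA
  obs <- !is.na(rate)
  if (!any(obs)) return(rep(NA_real_, length(weeks)))
  if (!anchor_baseline && !obs[1]) {
    rate[1] <- rate[which(obs)[1]]  # carry first follow-up rate back
    obs[1] <- TRUE
  }
  if (sum(obs) < 2) return(rep(NA_real_, length(weeks)))
  last_obs <- max(w[obs])
  vapply(weeks, function(t) {
    if (t == 0) return(0)
    if (t > last_obs) return(NA_real_)
    grid <- sort(unique(c(w[obs][w[obs] <= t], 0, t)))
    rg <- stats::approx(w[obs], rate[obs], xout = grid)$y
    sum(diff(grid) * (utils::head(rg, -1) + utils::tail(rg, -1)) / 2)
  }, numeric(1))
}

#' Derive the cost panel from a trial dataset
#'
#' Costs every patient's 4-week recall windows with [window_costs()],
#' accumulates them over the study with [cumulative_costs()], and adds the
#' intervention's own delivery costs (face-to-face sessions at the session
#' price plus [feedback_cost()] for the blended arm's online feedback) to
#' cumulative direct medical costs, spread linearly over the study period.
#' Online sessions carry no platform cost (hosting costs are out of scope).
#'
#' @param data `trial_data`.
#' @param table a [unit_cost_table()].
#' @inheritParams cumulative_costs
#' @return `data.frame` of class `cost_panel`: one row per patient x
#'   assessment with window and cumulative euro by category, the inpatient
#'   share, and `cum_societal` / `cum_provider` aggregates.
#' @export
derive_costs <- function(data, table = default_unit_costs(),
                         method = "trapezoid", anchor_baseline = TRUE) {
  stopifnot(is.data.frame(data))
  ru_cols <- grep("^ru_", names(data), value = TRUE)
  items <- sub("^ru_", "", ru_cols)
  horizon <- max(data$week)
  rows <- lapply(split(data, data$patient_id), function(d) {
    d <- d[order(d$week), ]
    wc <- t(vapply(seq_len(nrow(d)), function(i) {
      counts <- stats::setNames(as.numeric(d[i, ru_cols]), items)
      if (all(is.na(counts)))
        return(stats::setNames(rep(NA_real_, 4),
                               c(cost_categories, "inpatient")))
      window_costs(counts, table)
    }, numeric(4)))
    session_total <- d$n_f2f_sessions[1] * table$f2f_session_price +
      feedback_cost(d$n_feedback_messages[1], table)
    cum <- sapply(c(cost_categories, "inpatient"), function(cat)
      cumulative_costs(d$week, wc[, cat], method = method,
                       anchor_baseline = anchor_baseline))
    cum_session <- session_total * d$week / horizon
    out <- data.frame(patient_id = d$patient_id, arm = d$arm, week = d$week,
                      stringsAsFactors = FALSE)
    for (cat in c(cost_categories, "inpatient")) {
      out[[paste0("win_", cat)]] <- wc[, cat]
      out[[paste0("cum_", cat)]] <- cum[, cat]
    }
    out$cum_session <- cum_session
    out$cum_direct_medical <- out$cum_direct_medical + cum_session
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$cum_provider <- out$cum_direct_medical
  out$cum_societal <- out$cum_direct_medical + out$cum_direct_nonmedical +
    out$cum_indirect_nonmedical
  out <- out[order(out$patient_id, out$week), ]
  class(out) <- c("cost_panel", "data.frame")
  out
}

#' Extract a cumulative cost series for a given analytic perspective
#'
#' The societal perspective sums all three categories; the provider
#' perspective keeps direct medical costs only. `exclude_inpatient` removes
#' hospital / psychiatric inpatient items before aggregation (sensitivity
#' analysis for rare costly events); `indirect_only` returns the
#' absenteeism/presenteeism (indirect nonmedical) costs alone and is
#' incompatible with the provider perspective.
#'
#' @param panel a `cost_panel` from [derive_costs()].
#' @param perspective `"societal"` or `"provider"`.
#' @param exclude_inpatient drop inpatient items from direct medical costs.
#' @param indirect_only return indirect nonmedical costs only.
#' @return `data.frame` with `patient_id`, `arm`, `week`, `cost` (euro,
#'   cumulative).
#' @export
perspective_costs <- function(panel, perspective = c("societal", "provider"),
                              exclude_inpatient = FALSE,
                              indirect_only = FALSE) {
  perspective <- match.arg(perspective)
  if (indirect_only && perspective == "provider")
    stop("indirect_only is inconsistent with the provider perspective",
         call. = FALSE)
  dm <- panel$cum_direct_medical -
    if (exclude_inpatient) panel$cum_inpatient else 0
  cost <- if (indirect_only) {
    panel$cum_indirect_nonmedical
  } else if (perspective == "provider") {
    dm
  } else {
    dm + panel$cum_direct_nonmedical + panel$cum_indirect_nonmedical
  }
  data.frame(patient_id = panel$patient_id, arm = panel$arm,
             week = panel$week, cost = cost, stringsAsFactors = FALSE)
}
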