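# weeks per year used when converting utility-weeks to QALYs
WEEKS_PER_YEAR <- 365.25 / 7

#' Parameters for reliable-change classification
#'
#' The reliable change index (RCI) divides the change score (follow-up minus
#' baseline) by the standard error of the difference scores. The published
#' constant for the 30-item depression self-report is 4.78 (Cronbach alpha
#' 0.84, stored as metadata only and never used in computation). Change is
#' "reliable improvement" (treatment response) when RCI < -1.96; remission
#' additionally requires a follow-up score below the no-depression cutoff
#' (< 13).
#'
#' @param se_diff standard error of the difference scores (points), > 0.
#' @param rci_cutoff response cutoff on the RCI scale, < 0.
#' @param remission_score_cutoff follow-up score must be strictly below this.
#' @param cronbach_alpha scale reliability; metadata only.
#' @return object of class `rci_params`.
#' @export
rci_params <- function(se_diff = 4.78, rci_cutoff = -1.96,
                       remission_score_cutoff = 13, cronbach_alpha = 0.84) {
  if (se_diff <= 0) stop("se_diff must be > 0", call. = FALSE)
  if (rci_cutoff >= 0) stop("rci_cutoff must be < 0", call. = FALSE)
  structure(list(se_diff = se_diff, rci_cutoff = rci_cutoff,
                 remission_score_cutoff = remission_score_cutoff,
                 cronbach_alpha = cronbach_alpha),
            class = "rci_params")
}

#' Reliable change index
#'
#' `(followup - baseline) / se_diff`; antisymmetric in its arguments.
#' Missing scores propagate to a missing RCI.
#'
#' @param baseline_score,followup_score scores in `[0, 84]` (vectorized).
#' @param params [rci_params()].
#' @return numeric RCI, `NA` where either score is missing.
#' @export
compute_rci <- function(baseline_score, followup_score,
                        params = rci_params()) {
  ok <- !is.na(baseline_score) & !is.na(followup_score)
  if (any(baseline_score[ok] < 0 | baseline_score[ok] > 84 |
          followup_score[ok] < 0 | followup_score[ok] > 84))
    stop("scores must lie in [0, 84]", call. = FALSE)
  (followup_score - baseline_score) / params$se_diff
}

#' Treatment response from the RCI
#'
#' Response (reliable improvement) is present iff `rci < rci_cutoff`
#' (strict); the boundary value itself counts as absent.
#'
#' @param rci numeric RCI values.
#' @param params [rci_params()].
#' @return logical (NA propagates).
#' @export
classify_response <- function(rci, params = rci_params()) {
  rci < params$rci_cutoff
}

#' Remission: reliable improvement plus a no-depression score
#'
#' True iff `rci < rci_cutoff` and `followup_score < remission_score_cutoff`
#' (both strict). Remission therefore implies response.
#'
#' @param rci numeric RCI values.
#' @param followup_score follow-up scores.
#' @param params [rci_params()].
#' @return logical.
#' @export
classify_remission <- function(rci, followup_score, params = rci_params()) {
  classify_response(rci, params) &
    (followup_score < params$remission_score_cutoff)
}

#' Treatment-completer classification
#'
#' A patient is a treatment completer when the total number of sessions
#' received is at least `threshold`. The default 14 is the smallest integer
#' not below 75% of the 18-session protocol.
#'
#' @param n_total_sessions non-negative session count(s).
#' @param threshold completer cutoff (sessions).
#' @return logical.
#' @export
classify_completer <- function(n_total_sessions, threshold = 14L) {
  if (any(n_total_sessions < 0, na.rm = TRUE))
    stop("session counts must be non-negative", call. = FALSE)
  n_total_sessions >= threshold
}

#' Cumulative QALYs from interpolated utilities
#'
#' Integrates the piecewise-linear interpolant of the utility measurements
#' over time (trapezoid rule) and converts utility-weeks to years by
#' dividing by 365.25/7. Missing interior utilities are skipped: the
#' interpolation spans the gap. Requires at least two non-missing points
#' including week 0; otherwise the result is missing.
#'
#' @param weeks assessment weeks, strictly increasing, starting at 0.
#' @param utilities utilities in `[-0.33, 1]`, `NA` allowed.
#' @param at weeks at which to report the cumulative QALY (default: all
#'   follow-up weeks). Values beyond the last non-missing utility give `NA`
#'   (no extrapolation).
#' @return numeric cumulative QALYs (years) at each `at` week.
#' @export
compute_qaly <- function(weeks, utilities, at = weeks[weeks > 0]) {
  stopifnot(length(weeks) == length(utilities), !is.unsorted(weeks,
                                                             strictly = TRUE))
  obs <- !is.na(utilities)
  if (sum(obs) < 2 || !obs[1] || weeks[1] != 0)
    return(rep(NA_real_, length(at)))
  w <- weeks[obs]
  u <- utilities[obs]
  vapply(at, function(t) {
    if (t > max(w)) return(NA_real_)
    grid <- sort(unique(c(w[w <= t], t)))
    ug <- stats::approx(w, u, xout = grid)$y
    sum(diff(grid) * (utils::head(ug, -1) + utils::tail(ug, -1)) / 2) /
      WEEKS_PER_YEAR
  }, numeric(1))
}

#' Depression severity class from a score
#'
#' Maps a score in `[0, 84]` to none / mild / moderate / severe / very
#' severe using configurable cutpoints (lower bounds of the four upper
#' classes). The default cutpoints 13/25/38/48 follow the published severity
#' index for the instrument and are consistent with the remission cutoff:
#' scores below 13 are "none".
#'
#' @param score numeric score(s) in `[0, 84]`.
#' @param cutpoints increasing numeric of length 4.
#' @return factor with levels none < mild < moderate < severe < very_severe.
#' @export
classify_severity <- function(score, cutpoints = c(13, 25, 38, 48)) {
  stopifnot(length(cutpoints) == 4, !is.unsorted(cutpoints, strictly = TRUE))
  if (any(score < 0 | score > 84, na.rm = TRUE))
    stop("scores must lie in [0, 84]", call. = FALSE)
  cut(score, breaks = c(-Inf, cutpoints, Inf), right = FALSE,
      labels = c("none", "mild", "moderate", "severe", "very_severe"),
      ordered_result = TRUE)
}

#' Derive the clinical outcome panel from a trial dataset
#'
#' Computes, for every patient and follow-up assessment: the RCI relative to
#' baseline, response, remission, episode status (passed through), the
#' cumulative QALY from week 0, and the per-patient completer flag
#' (face-to-face plus online sessions against the completer threshold).
#'
#' @param data a `trial_data` panel.
#' @param params [rci_params()].
#' @param completer_threshold sessions needed for completer status.
#' @return `data.frame` of class `outcome_panel`: one row per patient x
#'   follow-up week.
#' @export
derive_outcomes <- function(data, params = rci_params(),
                            completer_threshold = 14L) {
  stopifnot(is.data.frame(data))
  weeks <- sort(unique(data$week))
  fup <- weeks[weeks > 0]
  base <- data[data$week == 0, ]
  rows <- lapply(split(data, data$patient_id), function(d) {
    d <- d[order(d$week), ]
    b <- d[d$week == 0, ]
    f <- d[d$week > 0, ]
    rci <- compute_rci(rep(b$ids_sr, nrow(f)), f$ids_sr, params)
    data.frame(patient_id = f$patient_id,
               arm = f$arm,
               week = f$week,
               rci = rci,
               response = classify_response(rci, params),
               remission = classify_remission(rci, f$ids_sr, params),
               episode = f$episode,
               qaly_cum = compute_qaly(d$week, d$utility, at = f$week),
               completer = classify_completer(
                 b$n_f2f_sessions + b$n_online_sessions,
                 completer_threshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$patient_id, out$week), ]
  class(out) <- c("outcome_panel", "data.frame")
  out
}
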