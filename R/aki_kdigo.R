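#' Baseline serum creatinine at a reference date
#'
#' The baseline is the minimum SCr in the 7 days strictly before
#' `reference_date`; when that window is empty, the most recent value within
#' the previous 90 days is used. With no qualifying value the function
#' returns `NA` (the caller skips the patient at this date and logs it).
#'
#' @param series data.frame with columns `date` (Date) and `value` (mg/dL),
#'   sorted by date.
#' @param reference_date the date the baseline refers to.
#' @param window_days width of the minimum window, days.
#' @param fallback_days look-back for the most-recent fallback, days.
#' @return baseline SCr in mg/dL, or `NA_real_`.
#' @export
baseline_scr <- function(series, reference_date, window_days = 7,
                         fallback_days = 90) {
  d <- as.numeric(series$date) - as.numeric(as.Date(reference_date))
  in_win <- d >= -window_days & d < 0
  if (any(in_win)) return(min(series$value[in_win]))
  in_fb <- d >= -fallback_days & d < 0
  if (any(in_fb)) return(series$value[max(which(in_fb))])
  NA_real_
}

#' Detect and stage KDIGO creatinine AKI episodes
#'
#' An episode opens at the first measurement date `t >= ici_start` where
#' either KDIGO creatinine criterion holds:
#' * absolute: SCr(t) exceeds some measurement taken within the previous
#'   48 hours by >= 0.3 mg/dL;
#' * relative: SCr(t) >= 1.5x some measurement taken within the previous
#'   7 days (equivalently, 1.5x the 7-day-window baseline).
#'
#' The episode is staged by the peak SCr within 7 days of onset relative to
#' the [baseline_scr()] baseline: stage 1 = 1.5-1.9x or an absolute rise of
#' >= 0.3 mg/dL; stage 2 = 2.0-2.9x; stage 3 = >= 3.0x or peak >= 4.0 mg/dL.
#' A subsequent episode can open only after the 7-day staging window of the
#' previous one has closed. With `windows = FALSE` the look-back windows are
#' dropped and both criteria are evaluated against the running baseline
#' (an alternative operationalization some AKI studies use).
#'
#' @param series data.frame with `date`, `value` (mg/dL), sorted; values > 0.
#' @param ici_start Date of ICI initiation; detection starts here.
#' @param windows if `TRUE` (default) apply the 48-hour / 7-day KDIGO
#'   look-back windows.
#' @return data.frame of episodes (possibly 0-row) with columns
#'   `onset_date`, `stage`, `baseline_scr`, `trigger_scr`, `peak_scr`,
#'   `criterion`, `is_first`, sorted by onset.
#' @export
detect_episodes <- function(series, ici_start, windows = TRUE) {
  if (!nrow(series)) return(empty_episodes())
  if (any(series$value <= 0)) stop("detect_episodes: non-positive SCr value")
  if (is.unsorted(series$date)) stop("detect_episodes: series not sorted")
  dates <- as.numeric(series$date)
  vals <- series$value
  start <- as.numeric(as.Date(ici_start))

  episodes <- list()
  blocked_until <- -Inf   # staging window of an open episode
  for (i in seq_along(dates)) {
    t <- dates[i]
    if (t < start || t <= blocked_until) next
    prior <- which(dates < t)
    if (!length(prior)) next
    if (windows) {
      abs_hit <- any(t - dates[prior] <= 2 &
                       vals[i] - vals[prior] >= 0.3 - 1e-12)
      rel_hit <- any(t - dates[prior] <= 7 &
                       vals[i] >= 1.5 * vals[prior] - 1e-12)
    } else {
      base_now <- baseline_scr(series, as.Date(t, origin = "1970-01-01"))
      abs_hit <- !is.na(base_now) && vals[i] - base_now >= 0.3 - 1e-12
      rel_hit <- !is.na(base_now) && vals[i] >= 1.5 * base_now - 1e-12
    }
    if (!abs_hit && !rel_hit) next

    base <- baseline_scr(series, as.Date(t, origin = "1970-01-01"))
    if (is.na(base)) base <- min(vals[prior][t - dates[prior] <= 7],
                                 vals[prior][length(prior)])
    in_stage_win <- dates >= t & dates <= t + 7
    peak <- max(vals[in_stage_win])
    ratio <- peak / base
    stage <- if (ratio >= 3.0 - 1e-9 || peak >= 4.0 - 1e-9) 3L
             else if (ratio >= 2.0 - 1e-9) 2L else 1L
    episodes[[length(episodes) + 1L]] <- data.frame(
      onset_date = as.Date(t, origin = "1970-01-01"),
      stage = stage, baseline_scr = base, trigger_scr = vals[i],
      peak_scr = peak,
      criterion = if (abs_hit && rel_hit) "both"
                  else if (abs_hit) "absolute_increase" else "relative_increase",
      is_first = length(episodes) == 0L)
    blocked_until <- t + 7
  }
  if (!length(episodes)) return(empty_episodes())
  do.call(rbind, episodes)
}

empty_episodes <- function() {
  data.frame(onset_date = as.Date(character()), stage = integer(),
             baseline_scr = numeric(), trigger_scr = numeric(),
             peak_scr = numeric(), criterion = character(),
             is_first = logical())
}

#' First AKI episode with the 14-day multi-event rule
#'
#' Returns the first detected episode; when any additional episode opens
#' within 14 days of the first onset the patient is flagged
#' `multi_event_excluded` and is omitted from the evaluation/clustering set
#' (the frames remain usable for model-training labels).
#'
#' @param episodes data.frame from [detect_episodes()], sorted by onset.
#' @return list with `episode` (1-row data.frame or `NULL`) and
#'   `multi_event_excluded` (logical).
#' @export
first_episode_with_merge <- function(episodes) {
  if (!nrow(episodes))
    return(list(episode = NULL, multi_event_excluded = FALSE))
  first <- episodes[1L, , drop = FALSE]
  gap_hit <- nrow(episodes) > 1L &&
    any(as.numeric(episodes$onset_date[-1L] - first$onset_date) <= 14)
  list(episode = first, multi_event_excluded = gap_hit)
}

#' Apply the study's cohort filters
#'
#' Removes patients with (in order of precedence) end-stage renal disease at
#' ICI initiation, no serum creatinine measurement on/after ICI start, or
#' follow-up censored alive before 90 days after ICI start. Death within
#' 90 days is an outcome, not censoring, so deceased patients are retained.
#'
#' @param cohort an `aki_cohort`.
#' @return list with the filtered `cohort` and an `exclusions` data.table
#'   (`patient_id`, `reason`, `detail`), one primary reason per patient.
#' @export
apply_cohort_filters <- function(cohort) {
  reg <- cohort$registry
  scr_after <- cohort$labs[analyte == "SCR"][
    reg[, .(patient_id, ici_start)], on = "patient_id"][
      date >= ici_start, unique(patient_id)]
  excl <- list()
  for (i in seq_len(nrow(reg))) {
    r <- reg[i]
    reason <- NULL
    if (isTRUE(r$esrd_at_baseline)) {
      reason <- c("esrd_at_baseline", "ESRD at ICI initiation")
    } else if (!r$patient_id %in% scr_after) {
      reason <- c("no_renal_data_after_ici", "no SCr on/after ICI start")
    } else if (is.na(r$death_date) &&
               as.numeric(r$end_of_followup - r$ici_start) < 90) {
      reason <- c("censored_lt_3mo",
                  sprintf("censored alive at day %d",
                          as.integer(r$end_of_followup - r$ici_start)))
    }
    if (!is.null(reason))
      excl[[length(excl) + 1L]] <- data.table(
        patient_id = r$patient_id, reason = reason[1], detail = reason[2])
  }
  exclusions <- if (length(excl)) rbindlist(excl) else
    data.table(patient_id = character(), reason = character(),
               detail = character())
  keep <- setdiff(reg$patient_id, exclusions$patient_id)
  filtered <- structure(list(
    registry = reg[patient_id %in% keep],
    labs = cohort$labs[patient_id %in% keep],
    meds = cohort$meds[patient_id %in% keep],
    observations = cohort$observations[patient_id %in% keep],
    inpatient = cohort$inpatient[patient_id %in% keep]
  ), class = "aki_cohort", config = attr(cohort, "config"))
  list(cohort = filtered, exclusions = exclusions)
}

#' Detect episodes for every patient in a cohort
#'
#' @param cohort a filtered `aki_cohort`.
#' @param windows passed to [detect_episodes()].
#' @return data.table of all episodes with `patient_id`, plus attribute
#'   `first_episodes`: one row per AKI patient with the 14-day
#'   multi-event-exclusion flag.
#' @export
detect_cohort_episodes <- function(cohort, windows = TRUE) {
  reg <- cohort$registry
  scr <- cohort$labs[analyte == "SCR"]
  eps <- list()
  firsts <- list()
  for (i in seq_len(nrow(reg))) {
    pid <- reg$patient_id[i]
    s <- scr[patient_id == pid, .(date, value)]
    if (!nrow(s)) next
    e <- detect_episodes(s, reg$ici_start[i], windows = windows)
    if (!nrow(e)) next
    eps[[length(eps) + 1L]] <- data.table(patient_id = pid, e)
    fm <- first_episode_with_merge(e)
    firsts[[length(firsts) + 1L]] <- data.table(
      patient_id = pid, fm$episode,
      multi_event_excluded = fm$multi_event_excluded)
  }
  out <- if (length(eps)) rbindlist(eps) else
    data.table(patient_id = character(), empty_episodes())
  attr(out, "first_episodes") <- if (length(firsts)) rbindlist(firsts) else
    data.table(patient_id = character(), empty_episodes(),
               multi_event_excluded = logical())
  out
}
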