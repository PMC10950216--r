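#' Default feature specification table
#'
#' One row per engineered feature. Time-linked sources use four weekly
#' look-back windows labelled `(-1wk)` ... `(-4wk)`; window `w` covers
#' `(reference - 7w, reference - 7(w-1)]` days, so the four windows tile the
#' 28 days up to and including the reference date with no overlap.
#' Aggregators follow the source kind: labs use `last` and `max` per window
#' (plus a derived BUN/SCr ratio of window-last values), medications use
#' `any`, observations (dietary intake, body temperature) use `mean`, and
#' registry fields are static.
#'
#' @return data.table with columns `name`, `kind`
#'   (`lab`/`med`/`obs`/`derived`/`static`), `source`, `window`
#'   (1-4 or `NA` for static), `aggregator`.
#' @export
default_feature_specs <- function() {
  wk <- 1:4
  labs <- CJ(source = known_analytes(), window = wk,
             aggregator = c("last", "max"))
  labs[, `:=`(kind = "lab",
              name = sprintf("%s_%s(-%dwk)", source, aggregator, window))]
  derived <- CJ(source = "BUN_SCR_ratio", window = wk, aggregator = "last")
  derived[, `:=`(kind = "derived",
                 name = sprintf("BUN_SCR_ratio(-%dwk)", window))]
  meds <- CJ(source = c("PPI", "NSAID", "diuretic", "ICI"), window = wk,
             aggregator = "any")
  meds[, `:=`(kind = "med", name = sprintf("med_%s(-%dwk)", source, window))]
  obs <- CJ(source = c("diet_intake", "body_temp"), window = wk,
            aggregator = "mean")
  obs[, `:=`(kind = "obs", name = sprintf("%s_mean(-%dwk)", source, window))]
  inpt <- CJ(source = "inpatient", window = wk, aggregator = "any")
  inpt[, `:=`(kind = "inpatient", name = sprintf("inpatient(-%dwk)", window))]
  static <- data.table(
    source = c("age_mid", "sex_M", "days_since_ici",
               paste0("cancer_", c("Gastrointestinal", "Lung", "Urologic",
                                   "Skin", "Other")),
               paste0("ici_", c("PD-1", "PD-L1", "CTLA-4", "Combination"))),
    window = NA_integer_, aggregator = "static", kind = "static")
  static[, name := source]
  rbindlist(list(labs, derived, meds, obs, inpt, static), use.names = TRUE)[
    , .(name, kind, source, window, aggregator)]
}

#' Enumerate prediction reference dates for one patient
#'
#' Default policy: every date from ICI start to end of follow-up carrying at
#' least one new lab measurement. Points falling within 14 days after the
#' patient's first AKI onset are flagged ineligible for evaluation and
#' clustering (they stay in the matrix for training labels). A `daily`
#' policy yields one point per calendar day irrespective of labs.
#'
#' @param lab_dates Dates of the patient's lab measurements.
#' @param ici_start,end_of_followup Dates bounding the prediction period.
#' @param first_onset Date of first AKI onset, or `NULL`/`NA`.
#' @param policy `"lab_dates"` (default) or `"daily"`.
#' @return data.table with `date` and `eligible`.
#' @export
enumerate_prediction_points <- function(lab_dates, ici_start,
                                        end_of_followup, first_onset = NULL,
                                        policy = c("lab_dates", "daily")) {
  policy <- match.arg(policy)
  pts <- if (policy == "lab_dates") {
    sort(unique(lab_dates[lab_dates >= ici_start &
                            lab_dates <= end_of_followup]))
  } else {
    seq(as.Date(ici_start), as.Date(end_of_followup), by = "day")
  }
  eligible <- rep(TRUE, length(pts))
  if (!is.null(first_onset) && length(first_onset) && !is.na(first_onset[1])) {
    off <- as.numeric(pts - as.Date(first_onset[1]))
    eligible[off > 0 & off <= 14] <- FALSE
  }
  data.table(date = pts, eligible = eligible)
}

#' Assemble the sliding-window prediction matrix
#'
#' Builds one row ("frame") per (patient, reference date): the windowed
#' feature vector computed only from data on or before the reference date,
#' and the 7-day-ahead label, positive iff any AKI episode onset falls in
#' `(reference, reference + 7d]`. Absent lab/observation data yield missing
#' values (passed natively to the learner, no imputation); absent
#' medications yield 0.
#'
#' @param cohort filtered `aki_cohort`.
#' @param episodes data.table from [detect_cohort_episodes()].
#' @param specs feature specification table, see [default_feature_specs()].
#' @param policy prediction-point cadence policy.
#' @return data.table of class `prediction_matrix`: `patient_id`,
#'   `reference_date`, `label` (logical), `eligible`, then one column per
#'   feature; attributes `feature_names` and `specs`.
#' @export
assemble_matrix <- function(cohort, episodes, specs = default_feature_specs(),
                            policy = "lab_dates") {
  reg <- cohort$registry
  firsts <- attr(episodes, "first_episodes")

  grids <- vector("list", nrow(reg))
  for (i in seq_len(nrow(reg))) {
    pid <- reg$patient_id[i]
    fo <- if (!is.null(firsts) && nrow(firsts))
      firsts[patient_id == pid, onset_date] else as.Date(NA)
    pts <- enumerate_prediction_points(
      cohort$labs[patient_id == pid, date], reg$ici_start[i],
      reg$end_of_followup[i],
      first_onset = if (length(fo)) fo[1] else NULL, policy = policy)
    if (nrow(pts)) grids[[i]] <- data.table(patient_id = pid, ref = pts$date,
                                            eligible = pts$eligible)
  }
  grid <- rbindlist(grids)
  if (!nrow(grid)) stop("assemble_matrix: no prediction points")
  grid[, lo := ref - 28L]

  wide <- compute_window_features(cohort, grid, specs)

  # 7-day-ahead label: any episode onset in (ref, ref + 7]
  wide[, label := FALSE]
  if (nrow(episodes)) {
    on_tbl <- episodes[, .(patient_id, onset_date)]
    hit <- on_tbl[wide[, .(patient_id, lab0 = reference_date,
                           lab7 = reference_date + 7L)],
                  on = .(patient_id, onset_date > lab0, onset_date <= lab7),
                  nomatch = NULL, .(patient_id, reference_date = onset_date)]
    # join columns take i's values: onset_date>lab0 slot carries lab0
    if (nrow(hit)) {
      hit <- unique(hit)
      wide[hit, on = .(patient_id, reference_date), label := TRUE]
    }
  }
  feature_names <- specs$name
  setcolorder(wide, c("patient_id", "reference_date", "label", "eligible",
                      feature_names))
  setattr(wide, "feature_names", feature_names)
  setattr(wide, "specs", specs)
  setattr(wide, "class", c("prediction_matrix", class(wide)))
  wide[]
}

# Vectorized windowed aggregation over the (patient, reference-date) grid.
compute_window_features <- function(cohort, grid, specs) {
  out <- grid[, .(patient_id, reference_date = ref, eligible)]

  win_join <- function(tbl, valcol) {
    j <- tbl[grid, on = .(patient_id, date > lo, date <= ref),
             nomatch = NULL, allow.cartesian = TRUE,
             .(patient_id, ref = i.ref, date = x.date,
               src = src, value = get(paste0("x.", valcol)))]
    j[, window := as.integer(as.numeric(ref - date)) %/% 7L + 1L]
    j
  }

  # labs: last and max per (analyte, window)
  labs <- copy(cohort$labs)[, src := analyte]
  lj <- win_join(labs[, .(patient_id, date, src, value)], "value")
  setorder(lj, patient_id, ref, src, window, date)
  agg_last <- lj[, .(value = value[.N]), by = .(patient_id, ref, src, window)]
  agg_last[, name := sprintf("%s_last(-%dwk)", src, window)]
  agg_max <- lj[, .(value = max(value)), by = .(patient_id, ref, src, window)]
  agg_max[, name := sprintf("%s_max(-%dwk)", src, window)]

  # derived BUN/SCr ratio of window-last values
  ratio <- dcast(agg_last[src %in% c("BUN", "SCR")],
                 patient_id + ref + window ~ src, value.var = "value")
  for (cc in c("BUN", "SCR"))
    if (!cc %in% names(ratio)) ratio[, (cc) := NA_real_]
  ratio <- ratio[!is.na(BUN) & !is.na(SCR) & SCR > 0]
  drv <- ratio[, .(patient_id, ref, value = BUN / SCR,
                   name = sprintf("BUN_SCR_ratio(-%dwk)", window))]

  # medications: any exposure in window
  meds <- copy(cohort$meds)[, `:=`(src = drug_class, value = 1)]
  mj <- if (nrow(meds)) win_join(meds[, .(patient_id, date, src, value)],
                                 "value") else NULL
  med_any <- if (!is.null(mj) && nrow(mj))
    mj[, .(value = 1), by = .(patient_id, ref, src, window)][
      , name := sprintf("med_%s(-%dwk)", src, window)] else NULL

  # observations: mean per window
  obs <- copy(cohort$observations)[, src := kind]
  oj <- if (nrow(obs)) win_join(obs[, .(patient_id, date, src, value)],
                                "value") else NULL
  obs_mean <- if (!is.null(oj) && nrow(oj))
    oj[, .(value = mean(value)), by = .(patient_id, ref, src, window)][
      , name := sprintf("%s_mean(-%dwk)", src, window)] else NULL

  # inpatient status: expand intervals to daily events, then window 'any'
  ip_any <- NULL
  if (nrow(cohort$inpatient)) {
    ipd <- cohort$inpatient[, {
      d <- mapply(function(s, e) seq(s, e, by = "day"), start, end,
                  SIMPLIFY = FALSE)
      .(patient_id = rep(patient_id, lengths(d)),
        date = as.Date(unlist(d), origin = "1970-01-01"))
    }][, .(patient_id, date, src = "inpatient", value = 1)]
    ij <- win_join(ipd, "value")
    if (nrow(ij))
      ip_any <- ij[, .(value = 1),
                   by = .(patient_id, ref, src, window)][
                     , name := sprintf("inpatient(-%dwk)", window)]
  }

  long <- rbindlist(list(
    if (!is.null(ip_any)) ip_any[, .(patient_id, ref, name, value)],
    agg_last[, .(patient_id, ref, name, value)],
    agg_max[, .(patient_id, ref, name, value)],
    drv[, .(patient_id, ref, name, value)],
    if (!is.null(med_any)) med_any[, .(patient_id, ref, name, value)],
    if (!is.null(obs_mean)) obs_mean[, .(patient_id, ref, name, value)]
  ), use.names = TRUE)

  valid_names <- specs$name
  unknown_src <- setdiff(
    specs[kind %in% c("lab", "med", "obs"), unique(source)],
    c(known_analytes(), cohort$meds[, unique(drug_class)],
      cohort$observations[, unique(kind)], "PPI", "NSAID", "diuretic", "ICI",
      "diet_intake", "body_temp"))
  if (length(unknown_src))
    stop("assemble_matrix: unknown feature source(s): ",
         toString(unknown_src))
  long <- long[name %in% valid_names]

  wide <- if (nrow(long))
    dcast(long, patient_id + ref ~ name, value.var = "value") else
    out[, .(patient_id, ref = reference_date)]
  setnames(wide, "ref", "reference_date")
  wide <- wide[out, on = .(patient_id, reference_date)]

  # static registry-derived features
  reg <- cohort$registry
  age_mid <- c("20-39" = 30, "40-59" = 50, "60-79" = 70, ">=80" = 85)
  st <- reg[, .(patient_id, age_mid = age_mid[age_band],
                sex_M = as.numeric(sex == "M"), ici_start)]
  for (ct in c("Gastrointestinal", "Lung", "Urologic", "Skin", "Other"))
    st[, (paste0("cancer_", ct)) := as.numeric(reg$cancer_type == ct)]
  for (ag in c("PD-1", "PD-L1", "CTLA-4", "Combination"))
    st[, (paste0("ici_", ag)) := as.numeric(reg$ici_agent == ag)]
  wide <- st[wide, on = "patient_id"]
  wide[, days_since_ici := as.numeric(reference_date - ici_start)]
  wide[, ici_start := NULL]

  # medication/inpatient 'any' defaults to 0, labs/obs stay NA when absent
  for (nm in specs[kind %in% c("med", "inpatient"), name]) {
    if (!nm %in% names(wide)) wide[, (nm) := 0]
    else set(wide, which(is.na(wide[[nm]])), nm, 0)
  }
  for (nm in setdiff(specs$name, names(wide))) wide[, (nm) := NA_real_]
  wide
}

#' Build a single prediction frame
#'
#' Convenience wrapper around [assemble_matrix()] for one patient and one
#' reference date; used for spot checks and tests.
#'
#' @param cohort `aki_cohort` containing the patient.
#' @param patient_id patient identifier.
#' @param reference_date the reference date.
#' @param specs feature specification table.
#' @param episodes optional episode table for labelling (default: none).
#' @return 1-row `prediction_matrix`.
#' @export
build_frame <- function(cohort, patient_id, reference_date,
                        specs = default_feature_specs(), episodes = NULL) {
  pid <- patient_id
  sub <- structure(list(
    registry = cohort$registry[J(patient_id = pid), on = "patient_id"],
    labs = cohort$labs[J(patient_id = pid), on = "patient_id", nomatch = NULL],
    meds = cohort$meds[J(patient_id = pid), on = "patient_id", nomatch = NULL],
    observations = cohort$observations[J(patient_id = pid), on = "patient_id",
                                       nomatch = NULL],
    inpatient = cohort$inpatient[J(patient_id = pid), on = "patient_id",
                                 nomatch = NULL]
  ), class = "aki_cohort")
  grid <- data.table(patient_id = pid, ref = as.Date(reference_date),
                     eligible = TRUE)
  grid[, lo := ref - 28L]
  wide <- compute_window_features(sub, grid, specs)
  wide[, label := FALSE]
  if (!is.null(episodes) && nrow(episodes)) {
    off <- as.numeric(as.Date(episodes$onset_date) - as.Date(reference_date))
    wide[, label := any(off > 0 & off <= 7 &
                          episodes$patient_id == pid)]
  }
  setcolorder(wide, c("patient_id", "reference_date", "label", "eligible",
                      specs$name))
  setattr(wide, "feature_names", specs$name)
  setattr(wide, "specs", specs)
  setattr(wide, "class", c("prediction_matrix", class(wide)))
  wide[]
}
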