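#' Generate a synthetic ICI-treated EMR cohort with planted AKI mechanisms
#'
#' Simulates the longitudinal structure the downstream analysis assumes:
#' a patient registry, timestamped laboratory results (serum creatinine,
#' BUN, CRP, LDH, albumin, WBC, eosinophils), medication exposures (PPI,
#' NSAID, diuretic, ICI), clinical observations (dietary intake fraction,
#' body temperature) and inpatient intervals. A configurable fraction of
#' patients receives one planted AKI mechanism drawn *before* any
#' trajectory is simulated (no outcome leakage into the assignment):
#'
#' * `Hypovolemia` — diuretic exposure, falling dietary intake, rising
#'   BUN/SCr ratio;
#' * `Drug-related` — PPI/NSAID exposure, low-grade fever, rising
#'   eosinophils (immune-related adverse-event marker);
#' * `CancerCachexia` — monotone CRP and LDH rise, falling albumin, poor
#'   dietary intake, inpatient status, and the worst post-AKI survival;
#' * `Infection` — abrupt CRP/WBC spike with high fever.
#'
#' Each planted mechanism drives a creatinine ramp reaching 1.6-3.5x the
#' patient's baseline over 3-10 days, which the KDIGO detector in
#' [detect_episodes()] picks up, and imprints its feature signature over
#' the four weeks before onset. Post-AKI survival is exponential with the
#' mechanism-specific daily hazard from the config.
#'
#' @param config a [cohort_config()] object.
#' @return an object of class `aki_cohort`: a list of data.tables
#'   `registry`, `labs`, `meds`, `observations`, `inpatient`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    mechs <- names(config$mechanism_mix)

    # --- patient-level draws, all before trajectory simulation ---
    planted <- runif(n) < config$target_aki_fraction
    mechanism <- rep(NA_character_, n)
    if (any(planted) && sum(config$mechanism_mix) > 0)
      mechanism[planted] <- sample(mechs, sum(planted), replace = TRUE,
                                   prob = config$mechanism_mix)
    esrd <- !planted & runif(n) < 0.008
    censor_early <- !planted & !esrd & runif(n) < 0.045
    no_renal <- !planted & !esrd & !censor_early & runif(n) < 0.03

    age_band <- sample(c("20-39", "40-59", "60-79", ">=80"), n, TRUE,
                       prob = c(0.03, 0.17, 0.67, 0.13))
    sex <- sample(c("M", "F"), n, TRUE, prob = c(0.67, 0.33))
    cancer <- sample(c("Gastrointestinal", "Lung", "Urologic", "Skin",
                       "Other"), n, TRUE,
                     prob = c(0.12, 0.54, 0.12, 0.13, 0.09))
    ici <- sample(c("PD-1", "PD-L1", "CTLA-4", "Combination"), n, TRUE,
                  prob = c(0.85, 0.08, 0.03, 0.04))
    ici_start <- as.Date("2014-07-01") +
      sample.int(1900L, n, replace = TRUE) - 1L
    baseline_scr <- exp(rnorm(n, log(0.8), 0.27))

    pts <- vector("list", n)
    for (i in seq_len(n)) {
      pts[[i]] <- simulate_patient(
        id = sprintf("P%04d", i), config = config,
        seed = sub_seed(config$seed, i),
        planted = planted[i], mechanism = mechanism[i], esrd = esrd[i],
        censor_early = censor_early[i], no_renal = no_renal[i],
        age_band = age_band[i], sex = sex[i], cancer = cancer[i],
        ici_agent = ici[i], ici_start = ici_start[i],
        baseline_scr = baseline_scr[i])
    }

    cohort <- list(
      registry = rbindlist(lapply(pts, `[[`, "registry")),
      labs = rbindlist(lapply(pts, `[[`, "labs")),
      meds = rbindlist(lapply(pts, `[[`, "meds")),
      observations = rbindlist(lapply(pts, `[[`, "observations")),
      inpatient = rbindlist(lapply(pts, `[[`, "inpatient"))
    )
    for (tb in cohort) setkey(tb, NULL)
    setorder(cohort$labs, patient_id, date, analyte)
    setorder(cohort$meds, patient_id, date, drug_class)
    setorder(cohort$observations, patient_id, date, kind)
    setorder(cohort$inpatient, patient_id, start)
    structure(cohort, class = "aki_cohort", config = config)
  })
}

# One patient's trajectory. All times are day offsets from ICI start;
# negative days are pre-ICI history used for baseline creatinine.
simulate_patient <- function(id, config, seed, planted, mechanism, esrd,
                             censor_early, no_renal, age_band, sex, cancer,
                             ici_agent, ici_start, baseline_scr) {
  with_seed(seed, {
    fu <- config$followup_days
    end_day <- if (censor_early) sample(20:89, 1L) else fu

    onset <- NA_real_
    ramp_days <- NA_real_
    peak_mult <- NA_real_
    # per-patient severity of the feature signature, plus an occasional
    # mild comorbid secondary signature (drawn up front, before any
    # trajectory, like the mechanism itself)
    sev <- runif(1, 0.5, 1)
    sec_mech <- NA_character_
    sec_sev <- 0
    if (planted && runif(1) < 0.25) {
      sec_mech <- sample(setdiff(names(config$mechanism_mix), mechanism), 1L)
      sec_sev <- 0.3 * runif(1, 0.5, 1)
    }
    if (planted) {
      onset <- sample(30:max(31, fu - 45), 1L)
      ramp_days <- sample(3:10, 1L)
      # severity mix aims at a mostly stage-1 cohort
      sev <- sample(1:3, 1L, prob = c(0.70, 0.20, 0.10))
      peak_mult <- switch(sev, runif(1, 1.60, 1.95), runif(1, 2.05, 2.90),
                          runif(1, 3.0, 3.5))
    }

    # death: background hazard always; mechanism hazard after onset
    death_day <- Inf
    bg <- config$background_hazard
    if (bg > 0) death_day <- rexp(1, bg)
    if (planted) {
      hz <- config$hazard_by_mechanism[[mechanism]]
      # mechanism mortality acts once the creatinine ramp is established
      if (hz > 0) death_day <- min(death_day,
                                   onset + ramp_days + 2 + rexp(1, hz))
    }
    died <- is.finite(death_day) && death_day <= end_day
    if (died) end_day <- max(1, round(death_day))

    # --- inpatient intervals ---
    ip <- list()
    if (planted && !is.na(onset) && onset < end_day) {
      adm <- switch(mechanism,
        CancerCachexia = c(onset - 21, onset + 14),
        Infection      = c(onset - 3, onset + 10),
        Hypovolemia    = if (runif(1) < 0.4) c(onset, onset + 7),
        `Drug-related` = if (runif(1) < 0.3) c(onset, onset + 5))
      if (!is.null(adm)) ip[[length(ip) + 1L]] <- adm
    }
    if (runif(1) < 0.10) {   # unrelated background admission
      s <- sample(0:max(1, end_day - 10), 1L)
      ip[[length(ip) + 1L]] <- c(s, s + sample(4:10, 1L))
    }
    ip <- lapply(ip, function(x) pmin(pmax(x, -60), end_day))
    ip <- Filter(function(x) x[2] > x[1], ip)
    in_ip <- function(d) {
      if (!length(ip)) return(rep(FALSE, length(d)))
      Reduce(`|`, lapply(ip, function(x) d >= x[1] & d <= x[2]))
    }

    # --- lab measurement schedule ---
    p_gap <- 1 / config$lab_cadence_days
    days <- c()
    d <- -sample(45:60, 1L)          # pre-ICI history
    while (d <= end_day) {
      days <- c(days, d)
      gap <- if (in_ip(d)) sample(1:2, 1L) else 1L + rgeom(1L, p_gap)
      d <- d + gap
    }
    days <- unique(sort(c(days, 0)))
    if (planted && !is.na(onset) && onset < end_day) {
      extra <- onset + c(-2L, 0L, 1L, 3L, 5L, 7L, ramp_days, ramp_days + 2L)
      days <- unique(sort(c(days, extra[extra >= -60 & extra <= end_day])))
    }
    if (no_renal) days <- days[days < 0]
    days <- days[days <= end_day]
    if (!length(days)) days <- 0

    nd <- length(days)
    sig_lo <- if (planted) onset - 28 else Inf   # signature window
    w <- function(d) pmin(pmax((d - sig_lo) / 28, 0), 1)  # 0->1 ramp in window

    # creatinine multiplier from the planted mechanism ramp
    mult <- rep(1, nd)
    if (planted && !is.na(onset)) {
      rel <- days - onset
      up <- rel >= 0 & rel <= ramp_days
      mult[up] <- exp(log(peak_mult) * rel[up] / ramp_days)
      post <- rel > ramp_days
      if (mechanism == "CancerCachexia") {
        mult[post] <- peak_mult   # progressive, no recovery
      } else {
        dec <- pmax(0, 1 - (rel[post] - ramp_days) / 14)
        mult[post] <- exp(log(peak_mult) * dec)
      }
    }

    # AR(1) day-to-day physiological drift on the log scale
    phi <- 0.97
    sig_ar <- 0.03
    ar <- numeric(nd)
    ar[1] <- rnorm(1, 0, sig_ar)
    if (nd > 1) for (k in 2:nd) {
      g <- days[k] - days[k - 1]
      ar[k] <- phi^g * ar[k - 1] + sqrt(1 - phi^(2 * g)) * rnorm(1, 0, sig_ar)
    }

    # assay noise is roughly proportional to the level; noise_sd_scr is the
    # SD at the cohort-median baseline (0.8 mg/dL), scaled per patient
    noise_fac <- pmin(pmax(baseline_scr / 0.8, 0.5), 1.25)
    scr <- pmax(0.05, baseline_scr * mult * exp(ar) +
                        rnorm(nd, 0, config$noise_sd_scr * noise_fac))

    # companion labs with mechanism signatures over the 4 pre-onset weeks
    # patient-level baseline heterogeneity (chronic inflammation, tumor
    # burden, nutrition): large between-patient spread is typical of
    # oncology labs and is what makes raw values a poor mechanism readout
    crp0 <- exp(rnorm(1, log(0.3), 1.0))
    ldh0 <- 200 * exp(rnorm(1, 0, 0.25))
    alb0 <- rnorm(1, 3.9, 0.35)
    wbc0 <- 6 * exp(rnorm(1, 0, 0.25))
    eos0 <- 2 * exp(rnorm(1, 0, 0.5))
    bun0 <- rnorm(1, 16, 2.5)

    ww <- w(days)
    crp <- crp0 * exp(rnorm(nd, 0, 0.5))
    ldh <- ldh0 * exp(rnorm(nd, 0, 0.10))
    alb <- rnorm(nd, alb0, 0.15)
    wbc <- wbc0 * exp(rnorm(nd, 0, 0.15))
    eos <- eos0 * exp(rnorm(nd, 0, 0.25))
    bun_ratio <- rnorm(nd, bun0, 1.5)
    sig_list <- list()
    if (planted) sig_list <- c(sig_list, list(list(m = mechanism, s = sev)))
    if (!is.na(sec_mech))
      sig_list <- c(sig_list, list(list(m = sec_mech, s = sec_sev)))
    if (length(sig_list)) {
      late <- days > (onset - 14) & days <= min(onset + 7, end_day)
      spike <- days > (onset - 6) & days <= min(onset + 7, end_day)
      for (sg in sig_list) {
        s <- sg$s
        if (sg$m == "CancerCachexia") {
          crp <- crp * exp(ww * s * log(runif(1, 6, 15)))
          ldh <- ldh * exp(ww * s * log(runif(1, 1.5, 2.2)))
          alb <- alb - ww * s * runif(1, 1.0, 1.6)
        } else if (sg$m == "Infection") {
          crp[spike] <- crp[spike] * exp(s * log(runif(1, 15, 40)))
          wbc[spike] <- wbc[spike] * exp(s * log(runif(1, 2.0, 3.0)))
        } else if (sg$m == "Drug-related") {
          crp[late] <- crp[late] * exp(s * log(runif(1, 2, 4)))
          eos[late] <- eos[late] * exp(s * log(runif(1, 3, 5)))
        } else if (sg$m == "Hypovolemia") {
          bun_ratio <- bun_ratio * (1 + ww * s * runif(1, 0.8, 1.3))
        }
      }
    }
    bun <- pmax(2, bun_ratio * baseline_scr * mult * exp(0.5 * ar) +
                     rnorm(nd, 0, 1.5))

    avail <- function(p) runif(nd) < p
    lab_rows <- list(
      data.table(date = days, analyte = "SCR", value = round(scr, 2),
                 unit = "mg/dL"),
      data.table(date = days, analyte = "BUN", value = round(bun, 1),
                 unit = "mg/dL")[avail(0.95)],
      data.table(date = days, analyte = "CRP", value = round(crp, 2),
                 unit = "mg/dL")[avail(0.80)],
      data.table(date = days, analyte = "LDH", value = round(ldh, 0),
                 unit = "U/L")[avail(0.60)],
      data.table(date = days, analyte = "ALB", value = round(pmax(1, alb), 1),
                 unit = "g/dL")[avail(0.60)],
      data.table(date = days, analyte = "WBC", value = round(wbc, 1),
                 unit = "10^3/uL")[avail(0.90)],
      data.table(date = days, analyte = "EOS", value = round(eos, 1),
                 unit = "%")[avail(0.50)]
    )
    labs <- rbindlist(lab_rows)

    # --- observations: dietary intake fraction and body temperature ---
    obs_days <- sort(unique(c(days[days >= 0][runif(sum(days >= 0)) < 0.4],
                              if (length(ip))
                                unlist(lapply(ip, function(x)
                                  seq(max(0, ceiling(x[1])),
                                      floor(x[2]), by = 1L))))))
    obs_days <- obs_days[obs_days <= end_day]
    diet0 <- pmin(1, rnorm(1, 0.85, 0.10))
    temp0 <- rnorm(1, 36.5, 0.15)
    diet <- pmin(1, pmax(0, rnorm(length(obs_days), diet0, 0.07)))
    temp <- rnorm(length(obs_days), temp0, 0.20)
    if (length(sig_list) && length(obs_days)) {
      wo <- w(obs_days)
      late_o <- obs_days > (onset - 10) & obs_days <= min(onset + 7, end_day)
      spike_o <- obs_days > (onset - 6) & obs_days <= min(onset + 7, end_day)
      for (sg in sig_list) {
        s <- sg$s
        if (sg$m == "Hypovolemia") diet <- pmax(0, diet - wo * s * 0.5)
        if (sg$m == "CancerCachexia") diet <- pmax(0, diet - wo * s * 0.65)
        if (sg$m == "Drug-related")
          temp[late_o] <- pmax(temp[late_o],
                               36.8 + s * runif(sum(late_o), 0.7, 1.7))
        if (sg$m == "Infection")
          temp[spike_o] <- pmax(temp[spike_o],
                                36.8 + s * runif(sum(spike_o), 1.2, 2.7))
      }
    }
    observations <- rbindlist(list(
      data.table(date = obs_days, kind = "diet_intake",
                 value = round(diet, 2)),
      data.table(date = obs_days, kind = "body_temp",
                 value = round(temp, 1))
    ))

    # --- medications ---
    med_rows <- list(data.table(date = seq(0, end_day, by = 21L),
                                drug_class = "ICI"))
    if (runif(1) < 0.25)   # chronic PPI user
      med_rows <- c(med_rows, list(data.table(
        date = seq(0, end_day, by = 14L), drug_class = "PPI")))
    if (runif(1) < 0.11)
      med_rows <- c(med_rows, list(data.table(
        date = sort(sample(0:max(1, end_day), min(3, end_day + 1))),
        drug_class = "NSAID")))
    if (runif(1) < 0.08)
      med_rows <- c(med_rows, list(data.table(
        date = sort(sample(0:max(1, end_day), min(2, end_day + 1))),
        drug_class = "diuretic")))
    if (length(sig_list) && !is.na(onset) && onset < end_day) {
      wlo <- max(0, onset - 26)
      for (sg in sig_list) {
        if (sg$m == "Hypovolemia")
          med_rows <- c(med_rows, list(data.table(
            date = sort(sample(wlo:onset, max(1L, round(3 * sg$s)),
                               replace = TRUE)),
            drug_class = "diuretic")))
        if (sg$m == "Drug-related") {
          med_rows <- c(med_rows, list(data.table(
            date = seq(wlo, onset, by = 7L), drug_class = "PPI")))
          if (runif(1) < 0.7)
            med_rows <- c(med_rows, list(data.table(
              date = sort(sample(wlo:onset, max(1L, round(2 * sg$s)),
                                 replace = TRUE)),
              drug_class = "NSAID")))
        }
      }
    }
    meds <- unique(rbindlist(med_rows))

    to_date <- function(d) ici_start + round(d)
    registry <- data.table(
      patient_id = id, age_band = age_band, sex = sex, cancer_type = cancer,
      ici_agent = ici_agent, ici_start = ici_start,
      end_of_followup = to_date(end_day),
      death_date = if (died) to_date(end_day) else as.Date(NA),
      esrd_at_baseline = esrd,
      true_mechanism = if (planted) mechanism else NA_character_)

    list(
      registry = registry,
      labs = data.table(patient_id = id, date = to_date(labs$date),
                        analyte = labs$analyte, value = labs$value,
                        unit = labs$unit),
      meds = data.table(patient_id = id, date = to_date(meds$date),
                        drug_class = meds$drug_class),
      observations = data.table(patient_id = id,
                                date = to_date(observations$date),
                                kind = observations$kind,
                                value = observations$value),
      inpatient = if (length(ip)) data.table(
        patient_id = id,
        start = to_date(vapply(ip, `[`, 0, 1)),
        end = to_date(vapply(ip, `[`, 0, 2)))
      else data.table(patient_id = character(), start = as.Date(character()),
                      end = as.Date(character()))
    )
  })
}

#' @export
print.aki_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ICI cohort: %d patients, %d lab rows, %d med rows\n",
              nrow(x$registry), nrow(x$labs), nrow(x$meds)))
  if (!is.null(x$registry$true_mechanism)) {
    tm <- table(x$registry$true_mechanism, useNA = "no")
    if (length(tm))
      cat("  planted mechanisms:",
          paste(sprintf("%s=%d", names(tm), tm), collapse = ", "), "\n")
  }
  invisible(x)
}
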