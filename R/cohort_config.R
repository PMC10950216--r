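#' Configuration for the synthetic ICI-treated EMR cohort
#'
#' Bundles every knob of the synthetic cohort generator: cohort size, the
#' fraction of patients given a planted AKI mechanism, the mechanism mix,
#' follow-up length, lab sampling cadence, creatinine measurement noise and
#' per-mechanism post-AKI daily death hazards.
#'
#' Defaults emulate the structure reported for ICI-treated hospital cohorts:
#' roughly 18% of patients develop at least one AKI episode, baseline serum
#' creatinine has median ~0.8 mg/dL, and the cancer-cachexia mechanism
#' carries by far the worst post-AKI prognosis.
#'
#' @param n_patients number of patients to simulate.
#' @param target_aki_fraction fraction of patients given a planted AKI
#'   mechanism (realized KDIGO incidence also includes a small noise floor).
#' @param mechanism_mix named proportions over the four planted mechanisms
#'   (`Hypovolemia`, `Drug-related`, `CancerCachexia`, `Infection`);
#'   must sum to 1.
#' @param followup_days follow-up horizon after ICI start, days.
#' @param lab_cadence_days mean gap between outpatient lab draws, days.
#' @param noise_sd_scr measurement noise SD on serum creatinine, mg/dL.
#' @param hazard_by_mechanism named per-mechanism constant daily death hazard
#'   after AKI onset.
#' @param background_hazard daily death hazard outside post-AKI periods.
#' @param seed integer RNG seed; the cohort is a deterministic function of
#'   the full config.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 600L,
                          target_aki_fraction = 0.18,
                          mechanism_mix = c(Hypovolemia = 0.30,
                                            `Drug-related` = 0.30,
                                            CancerCachexia = 0.25,
                                            Infection = 0.15),
                          followup_days = 365L,
                          lab_cadence_days = 5,
                          noise_sd_scr = 0.05,
                          hazard_by_mechanism = c(Hypovolemia = 0.003,
                                                  `Drug-related` = 0.002,
                                                  CancerCachexia = 0.015,
                                                  Infection = 0.005),
                          background_hazard = 0.0004,
                          seed = 1L) {
  mechs <- c("Hypovolemia", "Drug-related", "CancerCachexia", "Infection")
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("cohort_config: n_patients must be a positive integer")
  if (!is.numeric(target_aki_fraction) ||
      target_aki_fraction < 0 || target_aki_fraction >= 1)
    stop("cohort_config: target_aki_fraction must lie in [0, 1)")
  if (!all(mechs %in% names(mechanism_mix)))
    stop("cohort_config: mechanism_mix must name all four mechanisms")
  mechanism_mix <- mechanism_mix[mechs]
  if (abs(sum(mechanism_mix) - 1) > 1e-9)
    stop("cohort_config: mechanism_mix must sum to 1")
  if (any(mechanism_mix < 0)) stop("cohort_config: negative mechanism weight")
  if (!all(mechs %in% names(hazard_by_mechanism)))
    stop("cohort_config: hazard_by_mechanism must name all four mechanisms")
  hazard_by_mechanism <- hazard_by_mechanism[mechs]
  if (any(!is.finite(hazard_by_mechanism)) || any(hazard_by_mechanism < 0))
    stop("cohort_config: hazards must be finite and >= 0")
  if (!is.finite(lab_cadence_days) || lab_cadence_days < 1)
    stop("cohort_config: lab_cadence_days must be a finite value >= 1")
  if (!is.finite(noise_sd_scr) || noise_sd_scr < 0)
    stop("cohort_config: noise_sd_scr must be finite and >= 0")
  structure(list(
    n_patients = as.integer(n_patients),
    target_aki_fraction = target_aki_fraction,
    mechanism_mix = mechanism_mix,
    followup_days = as.integer(followup_days),
    lab_cadence_days = lab_cadence_days,
    noise_sd_scr = noise_sd_scr,
    hazard_by_mechanism = hazard_by_mechanism,
    background_hazard = background_hazard,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic ICI cohort configuration\n")
  cat(sprintf("  n_patients: %d, target AKI fraction: %.2f, follow-up: %d d\n",
              x$n_patients, x$target_aki_fraction, x$followup_days))
  cat("  mechanism mix:",
      paste(sprintf("%s=%.2f", names(x$mechanism_mix), x$mechanism_mix),
            collapse = ", "), "\n")
  cat("  post-AKI daily hazards:",
      paste(sprintf("%s=%.4f", names(x$hazard_by_mechanism),
                    x$hazard_by_mechanism), collapse = ", "), "\n")
  invisible(x)
}
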