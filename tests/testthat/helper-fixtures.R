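suppressMessages(library(data.table))

# Hand-built miniature cohort for feature tests: dates are offsets from a
# fixed ICI start so window membership is easy to reason about.
tiny_cohort <- function(labs, meds = NULL, observations = NULL,
                        inpatient = NULL, ici_start = as.Date("2021-01-01"),
                        followup = 120, patient_id = "T001") {
  reg <- data.table(
    patient_id = patient_id, age_band = "60-79", sex = "M",
    cancer_type = "Lung", ici_agent = "PD-1", ici_start = ici_start,
    end_of_followup = ici_start + followup, death_date = as.Date(NA),
    esrd_at_baseline = FALSE, true_mechanism = NA_character_)
  empty_meds <- data.table(patient_id = character(),
                           date = as.Date(character()),
                           drug_class = character())
  empty_obs <- data.table(patient_id = character(),
                          date = as.Date(character()),
                          kind = character(), value = numeric())
  empty_ip <- data.table(patient_id = character(),
                         start = as.Date(character()),
                         end = as.Date(character()))
  structure(list(registry = reg, labs = labs,
                 meds = meds %||% empty_meds,
                 observations = observations %||% empty_obs,
                 inpatient = inpatient %||% empty_ip),
            class = "aki_cohort")
}

lab_rows <- function(patient_id, ici_start, day, analyte, value,
                     unit = "mg/dL") {
  data.table(patient_id = patient_id, date = as.Date(ici_start) + day,
             analyte = analyte, value = value, unit = unit)
}

# Minimal prediction_matrix for learner tests: features f1..fp generated by
# `fgen(n)`, labels by `labelfun(X)`.
toy_frames <- function(n_patients, frames_per_patient = 10, p = 3,
                       fgen = function(n, p) matrix(rnorm(n * p), n, p),
                       labelfun = function(X) X[, 1] > 0) {
  n <- n_patients * frames_per_patient
  X <- fgen(n, p)
  colnames(X) <- paste0("f", seq_len(p))
  dt <- data.table(
    patient_id = rep(sprintf("P%03d", seq_len(n_patients)),
                     each = frames_per_patient),
    reference_date = rep(as.Date("2021-01-01") + seq_len(frames_per_patient),
                         times = n_patients),
    label = as.logical(labelfun(X)), eligible = TRUE)
  dt <- cbind(dt, as.data.table(X))
  setattr(dt, "feature_names", colnames(X))
  setattr(dt, "class", c("prediction_matrix", class(dt)))
  dt[]
}

# The shared end-to-end run (main study conditions: n = 600, ~18% planted
# AKI, four mechanisms, fixed seed). Computed once per test session.
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- run_aki_pipeline(cohort_config(n_patients = 600, seed = 7))
    cache
  }
})

# Lighter single-configuration search space for replicate runs.
single_config <- function() {
  data.frame(max_depth = 4L, eta = 0.2, min_child_weight = 1, nrounds = 120L)
}
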