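#' Write / read a cohort as a directory of CSV tables
#'
#' Serializes the five cohort tables to `registry.csv`, `labs.csv`,
#' `meds.csv`, `observations.csv` and `inpatient.csv` with ISO-8601 dates.
#' `read_cohort()` inverts `write_cohort()` field-for-field, so
#' `read_cohort(write_cohort(x, d))` reproduces `x` and re-serialization is
#' byte-identical.
#'
#' @param cohort an `aki_cohort` object.
#' @param directory output directory, created if absent.
#' @return `write_cohort()` the directory path (invisibly); `read_cohort()`
#'   an `aki_cohort`.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "aki_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(cohort_schemas())) {
    fwrite(cohort[[nm]], file.path(directory, paste0(nm, ".csv")),
           dateTimeAs = "ISO", logical01 = FALSE)
  }
  invisible(directory)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  schemas <- cohort_schemas()
  out <- list()
  for (nm in names(schemas)) {
    path <- file.path(directory, paste0(nm, ".csv"))
    if (!file.exists(path)) stop("read_cohort: missing file ", path)
    dt <- fread(path, colClasses = schemas[[nm]], na.strings = "")
    for (cc in names(schemas[[nm]])[schemas[[nm]] == "Date"])
      if (cc %in% names(dt)) set(dt, j = cc, value = as.Date(dt[[cc]]))
    got <- names(dt)
    want <- names(schemas[[nm]])
    if (!identical(got, want))
      stop(sprintf("read_cohort: %s has columns [%s], expected [%s]",
                   path, toString(got), toString(want)))
    validate_cohort_table(nm, dt, path)
    out[[nm]] <- dt
  }
  structure(out, class = "aki_cohort")
}

cohort_schemas <- function() {
  list(
    registry = c(patient_id = "character", age_band = "character",
                 sex = "character", cancer_type = "character",
                 ici_agent = "character", ici_start = "Date",
                 end_of_followup = "Date", death_date = "Date",
                 esrd_at_baseline = "logical",
                 true_mechanism = "character"),
    labs = c(patient_id = "character", date = "Date", analyte = "character",
             value = "numeric", unit = "character"),
    meds = c(patient_id = "character", date = "Date",
             drug_class = "character"),
    observations = c(patient_id = "character", date = "Date",
                     kind = "character", value = "numeric"),
    inpatient = c(patient_id = "character", start = "Date", end = "Date")
  )
}

known_analytes <- function() c("SCR", "BUN", "CRP", "LDH", "ALB", "WBC", "EOS")

validate_cohort_table <- function(nm, dt, path) {
  if (nm == "labs" && nrow(dt)) {
    bad <- which(!dt$analyte %in% known_analytes())
    if (length(bad))
      stop(sprintf("read_cohort: unknown analyte '%s' in %s line %d",
                   dt$analyte[bad[1]], path, bad[1] + 1L))
    unsorted <- dt[, any(diff(as.integer(date)) < 0), by = patient_id]
    if (any(unsorted$V1))
      stop(sprintf("read_cohort: unsorted dates for patient %s in %s",
                   unsorted$patient_id[which(unsorted$V1)[1]], path))
    neg <- which(dt$analyte == "SCR" & dt$value <= 0)
    if (length(neg))
      stop(sprintf("read_cohort: non-positive SCr in %s line %d",
                   path, neg[1] + 1L))
  }
  invisible(TRUE)
}
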