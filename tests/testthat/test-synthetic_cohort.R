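test_that("cohort configuration validates its invariants", {
  expect_error(cohort_config(mechanism_mix = c(Hypovolemia = 0.5,
                                               `Drug-related` = 0.5,
                                               CancerCachexia = 0.2,
                                               Infection = -0.2)),
               "negative|sum")
  expect_error(cohort_config(target_aki_fraction = 1.2), "target_aki_fraction")
  expect_error(cohort_config(hazard_by_mechanism = c(Hypovolemia = Inf,
                                                     `Drug-related` = 0,
                                                     CancerCachexia = 0,
                                                     Infection = 0)),
               "finite")
  expect_error(cohort_config(lab_cadence_days = NaN), "cadence")
})

test_that("identical seeds give byte-identical serialized cohorts", {
  co1 <- generate_cohort(cohort_config(n_patients = 60, seed = 42))
  co2 <- generate_cohort(cohort_config(n_patients = 60, seed = 42))
  d1 <- file.path(tempdir(), "c1"); d2 <- file.path(tempdir(), "c2")
  write_cohort(co1, d1); write_cohort(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  co3 <- generate_cohort(cohort_config(n_patients = 60, seed = 43))
  expect_false(identical(co1$labs, co3$labs))
})

test_that("round-trip through CSV is identity and re-serialization is stable", {
  co <- generate_cohort(cohort_config(n_patients = 25, seed = 5))
  d1 <- file.path(tempdir(), "rt1")
  write_cohort(co, d1)
  back <- read_cohort(d1)
  for (nm in names(back))
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(co[[nm]]))
  d2 <- file.path(tempdir(), "rt2")
  write_cohort(back, d2)
  for (f in list.files(d1))
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
})

test_that("an empty cohort writes header-only files that read back empty", {
  schemas <- akireason:::cohort_schemas()
  empty <- structure(lapply(names(schemas), function(nm) {
    cols <- schemas[[nm]]
    dt <- data.table::as.data.table(
      lapply(cols, function(cl) switch(cl,
        character = character(), numeric = numeric(),
        logical = logical(), Date = as.Date(character()))))
    data.table::setnames(dt, names(cols))
    dt
  }), class = "aki_cohort")
  names(empty) <- names(schemas)
  d <- file.path(tempdir(), "empty_cohort")
  write_cohort(empty, d)
  for (f in list.files(d, full.names = TRUE))
    expect_length(readLines(f), 1L)   # header only
  back <- read_cohort(d)
  expect_true(all(vapply(back, nrow, 0L) == 0L))
})

test_that("read_cohort rejects malformed inputs with file and line", {
  co <- generate_cohort(cohort_config(n_patients = 3, seed = 1))
  d <- file.path(tempdir(), "bad_cohort")
  write_cohort(co, d)
  labs <- data.table::fread(file.path(d, "labs.csv"))
  labs$analyte[2] <- "UNKNOWN_CODE"
  data.table::fwrite(labs, file.path(d, "labs.csv"))
  expect_error(read_cohort(d), "unknown analyte.*line 3")
  write_cohort(co, d)
  unlink(file.path(d, "meds.csv"))
  expect_error(read_cohort(d), "missing file")
})

test_that("realized AKI incidence stays near the planted target", {
  res <- pipeline_fixture()
  frac <- nrow(res$first_episodes) / nrow(res$cohort$registry)
  expect_gte(frac, 0.13)
  expect_lte(frac, 0.23)
})

test_that("without planted mechanisms the detector's noise floor is < 2%", {
  co <- generate_cohort(cohort_config(n_patients = 400,
                                      target_aki_fraction = 0, seed = 11))
  filt <- apply_cohort_filters(co)
  fe <- attr(detect_cohort_episodes(filt$cohort), "first_episodes")
  expect_lt(nrow(fe) / nrow(filt$cohort$registry), 0.02)
})

test_that("mechanism assignment precedes trajectories (no outcome leakage)", {
  # mechanisms depend only on the config seed, not on trajectory noise:
  # cohorts differing only in SCr noise keep identical assignments
  c1 <- generate_cohort(cohort_config(n_patients = 80, seed = 3,
                                      noise_sd_scr = 0.01))
  c2 <- generate_cohort(cohort_config(n_patients = 80, seed = 3,
                                      noise_sd_scr = 0.10))
  expect_identical(c1$registry$true_mechanism, c2$registry$true_mechanism)
})

test_that("planted cachexia carries higher pre-onset CRP than hypovolemia", {
  cfg <- cohort_config(n_patients = 320, target_aki_fraction = 0.45,
                       mechanism_mix = c(Hypovolemia = 0.5,
                                         `Drug-related` = 0,
                                         CancerCachexia = 0.5,
                                         Infection = 0),
                       seed = 19)
  co <- generate_cohort(cfg)
  filt <- apply_cohort_filters(co)
  eps <- detect_cohort_episodes(filt$cohort)
  fe <- attr(eps, "first_episodes")
  dt <- merge(fe[, .(patient_id, onset_date)],
              filt$cohort$registry[, .(patient_id, true_mechanism)],
              by = "patient_id")
  crp <- filt$cohort$labs[analyte == "CRP"][dt, on = "patient_id",
                                            allow.cartesian = TRUE]
  crp <- crp[date > onset_date - 28 & date <= onset_date,
             .(mean_crp = mean(value)), by = .(patient_id, true_mechanism)]
  cach <- crp[true_mechanism == "CancerCachexia", mean_crp]
  hypo <- crp[true_mechanism == "Hypovolemia", mean_crp]
  expect_gte(length(cach), 30)
  expect_gte(length(hypo), 30)
  wt <- wilcox.test(cach, hypo, alternative = "greater")
  expect_lt(wt$p.value, 0.01)
})

test_that("10x cachexia hazard gives the shortest post-AKI survival", {
  base <- cohort_config(n_patients = 250, target_aki_fraction = 0.4,
                        seed = 23)
  hz <- base$hazard_by_mechanism
  hz[] <- c(0.002, 0.002, 0.02, 0.002)
  all_cach <- cohort_config(n_patients = 250, target_aki_fraction = 0.4,
                            mechanism_mix = c(Hypovolemia = 0,
                                              `Drug-related` = 0,
                                              CancerCachexia = 1,
                                              Infection = 0),
                            hazard_by_mechanism = hz, seed = 23)
  med_surv <- function(cfg) {
    co <- generate_cohort(cfg)
    filt <- apply_cohort_filters(co)
    fe <- attr(detect_cohort_episodes(filt$cohort), "first_episodes")
    fake <- structure(list(labels = setNames(rep(1L, nrow(fe)),
                                             fe$patient_id)),
                      class = "cluster_assignment")
    rec <- make_survival_records(filt$cohort$registry, fe, fake)
    fit <- survival::survfit(survival::Surv(rec$time_days,
                                            rec$event == "death") ~ 1)
    unname(summary(fit)$table["median"])
  }
  m_mixed <- med_surv(base)
  m_cach <- med_surv(all_cach)
  expect_true(is.na(m_mixed) || m_cach < m_mixed)
  expect_false(is.na(m_cach))
  expect_lt(m_cach, 90)
})
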