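test_that("prediction points follow lab dates and the 14-day rule", {
  ici <- as.Date("2021-01-01")
  pts <- enumerate_prediction_points(ici + c(0, 7, 14), ici, ici + 100)
  expect_equal(pts$date, ici + c(0, 7, 14))
  expect_true(all(pts$eligible))

  pts <- enumerate_prediction_points(ici + c(0, 21, 25, 30, 34, 35), ici,
                                     ici + 100, first_onset = ici + 20)
  expect_equal(pts$eligible,
               c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE))

  daily <- enumerate_prediction_points(ici + c(3, 9), ici, ici + 10,
                                       policy = "daily")
  expect_equal(daily$date, seq(ici, ici + 10, by = "day"))
})

test_that("window membership, medication any, and missing handling", {
  ici <- as.Date("2021-03-01")
  ref <- ici + 40
  labs <- lab_rows("T001", ici, c(40 - 3, 0), "CRP", c(5.0, 1.0))
  meds <- data.table::data.table(patient_id = "T001", date = ref - 2,
                                 drug_class = "diuretic")
  co <- tiny_cohort(labs, meds = meds, ici_start = ici)
  fr <- build_frame(co, "T001", ref)
  expect_equal(fr[["CRP_last(-1wk)"]], 5.0)
  expect_true(is.na(fr[["CRP_last(-2wk)"]]))
  expect_equal(fr[["med_diuretic(-1wk)"]], 1)
  expect_equal(fr[["med_diuretic(-2wk)"]], 0)
})

test_that("the four windows tile the 28 days before the reference exactly", {
  ici <- as.Date("2021-03-01")
  ref <- ici + 60
  # one measurement at every offset 0..28 before ref; value = offset
  offs <- 0:28
  labs <- lab_rows("T001", ici, 60 - offs, "CRP", offs)
  co <- tiny_cohort(labs, ici_start = ici)
  fr <- build_frame(co, "T001", ref)
  # 'last' in window w is the smallest offset in [7(w-1), 7w)
  expect_equal(fr[["CRP_last(-1wk)"]], 0)
  expect_equal(fr[["CRP_last(-2wk)"]], 7)
  expect_equal(fr[["CRP_last(-3wk)"]], 14)
  expect_equal(fr[["CRP_last(-4wk)"]], 21)
  # 'max' in window w is the largest offset in the window; offset 28 is
  # outside all four windows
  expect_equal(fr[["CRP_max(-1wk)"]], 6)
  expect_equal(fr[["CRP_max(-4wk)"]], 27)
})

test_that("the 7-day label horizon is half-open and closes at +7 days", {
  ici <- as.Date("2021-03-01")
  labs <- lab_rows("T001", ici, c(0, 5, 10), "SCR", c(0.8, 0.8, 0.8))
  co <- tiny_cohort(labs, ici_start = ici)
  eps <- data.frame(patient_id = "T001", onset_date = ici + 12)
  f5 <- build_frame(co, "T001", ici + 5, episodes = eps)
  expect_true(f5$label)            # onset at +7 exactly
  f12 <- build_frame(co, "T001", ici + 12, episodes = eps)
  expect_false(f12$label)          # onset at +0 is outside (ref, ref+7]
})

test_that("features never see data after the reference date", {
  co <- generate_cohort(cohort_config(n_patients = 10, seed = 31))
  # pick a patient that has labs beyond day 60 so the mutation is non-empty
  pid <- NULL
  for (i in seq_len(nrow(co$registry))) {
    r <- co$registry[i]
    if (nrow(co$labs[patient_id == r$patient_id &
                       date > r$ici_start + 60]) > 0) {
      pid <- r$patient_id; ref <- r$ici_start + 60; break
    }
  }
  expect_false(is.null(pid))
  base <- build_frame(co, pid, ref)
  mut <- data.table::copy(co$labs)
  idx <- mut$patient_id == pid & mut$date > ref
  mut[idx, value := value * 10 + 3]
  co2 <- co
  co2$labs <- mut
  mutated <- build_frame(co2, pid, ref)
  fn <- attr(base, "feature_names")
  expect_equal(as.data.frame(base)[, fn], as.data.frame(mutated)[, fn])
})

test_that("assemble_matrix concatenates patients and labels by episode scan", {
  ici <- as.Date("2021-03-01")
  labs <- rbind(lab_rows("A", ici, c(0, 10, 20), "SCR", c(0.8, 0.9, 0.8)),
                lab_rows("B", ici, c(3, 5, 9), "SCR", c(1.0, 1.1, 1.2)))
  co <- tiny_cohort(labs, ici_start = ici, patient_id = "A")
  co$registry <- rbind(co$registry,
                       data.table::copy(co$registry)[, patient_id := "B"])
  eps <- data.table::data.table(patient_id = "B", onset_date = ici + 10,
                                stage = 1L, baseline_scr = 1,
                                trigger_scr = 1.4, peak_scr = 1.4,
                                criterion = "absolute_increase",
                                is_first = TRUE)
  fr <- assemble_matrix(co, eps)
  expect_equal(nrow(fr), 6L)
  expect_equal(fr[patient_id == "B", label], c(TRUE, TRUE, TRUE))
  expect_equal(fr[patient_id == "A", label], c(FALSE, FALSE, FALSE))
})

test_that("matrix labels agree with a direct episode scan on a cohort", {
  co <- generate_cohort(cohort_config(n_patients = 60, seed = 13))
  filt <- apply_cohort_filters(co)
  eps <- detect_cohort_episodes(filt$cohort)
  fr <- assemble_matrix(filt$cohort, eps)
  # brute-force label: scan all onsets per frame
  want <- logical(nrow(fr))
  for (i in seq_len(nrow(fr))) {
    ons <- eps[patient_id == fr$patient_id[i], onset_date]
    off <- as.numeric(ons - fr$reference_date[i])
    want[i] <- any(off > 0 & off <= 7)
  }
  expect_equal(fr$label, want)
  frac <- mean(fr$label)
  expect_gt(frac, 0)
  expect_lt(frac, 0.5)
})

test_that("unknown feature sources are rejected", {
  ici <- as.Date("2021-03-01")
  co <- tiny_cohort(lab_rows("T001", ici, 0, "SCR", 0.8), ici_start = ici)
  specs <- default_feature_specs()
  bad <- data.table::copy(specs)
  bad[kind == "lab", source := "NOT_AN_ANALYTE"][1]
  expect_error(assemble_matrix(co, akireason:::empty_episodes(), bad),
               "unknown feature source")
})
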