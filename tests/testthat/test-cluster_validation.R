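test_that("2x2 Fisher exact equals hypergeometric enumeration", {
  tab <- matrix(c(3, 6, 7, 4), 2, 2)
  want <- fisher2x2_oracle(tab)
  expect_equal(round(want, 4), 0.3698)
  expect_equal(akireason:::fisher_p(tab), want, tolerance = 1e-12)

  set.seed(14)
  for (r in 1:25) {
    tb <- matrix(rpois(4, 6) + 1, 2, 2)
    expect_equal(akireason:::fisher_p(tb), fisher2x2_oracle(tb),
                 tolerance = 1e-9)
  }
})

test_that("Kruskal-Wallis null p-values are uniform", {
  set.seed(15)
  ps <- replicate(200, {
    x <- rnorm(60)
    g <- factor(rep(1:3, each = 20))
    kruskal.test(x, g)$p.value
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("characteristics table tests categorical and continuous rows", {
  res <- pipeline_fixture()
  ch <- res$characteristics
  expect_true(all(c("sex", "cancer_type", "stage", "inpatient_at_onset",
                    "baseline_scr") %in% ch$tests$variable))
  expect_true(all(ch$tests$p_value >= 0 & ch$tests$p_value <= 1,
                  na.rm = TRUE))
  expect_true(all(ch$tests$p_holm >= ch$tests$p_value, na.rm = TRUE))
  expect_equal(ch$tests[ch$tests$variable == "baseline_scr", ]$test,
               "kruskal-wallis")
  # an all-in-one-cluster assignment is rejected
  one <- res$clusters_shap
  one$labels[] <- 1L
  expect_error(cluster_characteristics_table(res$cohort, one,
                                             res$first_episodes),
               ">= 2")
})

test_that("label distribution GOF: marginal match gives 0, concentration 50", {
  # two clusters whose label mix equals the pooled marginal exactly
  labels <- data.table::data.table(
    patient_id = sprintf("P%03d", 1:40),
    label = rep(c("Hypovolemia", "Infection"), 20))
  cl <- structure(list(labels = setNames(rep(1:2, each = 20),
                                         labels$patient_id)),
                  class = "cluster_assignment")
  ld <- label_distribution(cl, labels)
  expect_equal(ld$gof$statistic, c(0, 0), tolerance = 1e-12)
  expect_equal(ld$gof$p_value, c(1, 1), tolerance = 1e-12)

  # one cluster concentrated on one of six equi-marginal labels: chisq = 50
  six <- c("Hypovolemia", "Cancer Cachexia", "Infection", "Drug-related",
           "Obstruction", "Others")
  lab2 <- data.table::data.table(
    patient_id = sprintf("Q%03d", 1:72),
    label = c(rep("Hypovolemia", 10),
              c(rep("Hypovolemia", 2), rep(six[-1], each = 12))))
  cl2 <- structure(list(labels = setNames(rep(c(1L, 2L), c(10, 62)),
                                          lab2$patient_id)),
                   class = "cluster_assignment")
  ld2 <- label_distribution(cl2, lab2)
  expect_equal(ld2$gof[cluster == 1, statistic], 50, tolerance = 1e-9)

  expect_error(label_distribution(cl2, lab2[1:10]), "unlabeled")
})

test_that("planted-mechanism clusters carry matching modal labels", {
  res <- pipeline_fixture()
  modal <- res$label_dist$modal
  mech_labels <- c("Hypovolemia", "Cancer Cachexia", "Infection",
                   "Drug-related")
  expect_gte(sum(modal$modal_label %in% mech_labels &
                   !duplicated(modal$modal_label)), 3)
})

test_that("KM estimator equals the hand product-limit", {
  # fixture: deaths at days 10 and 20 of n = 4, others censored at 90
  rec <- data.table::data.table(
    patient_id = sprintf("S%d", 1:4), cluster = 1L,
    time_days = c(10, 20, 90, 90),
    event = c("death", "death", "censored", "censored"),
    zero_followup = FALSE)
  sa <- survival_analysis(rec)
  expect_equal(min(sa$curves$survival), 0.5, tolerance = 1e-12)
  expect_equal(sa$flag, "single_group")

  set.seed(16)
  for (r in 1:20) {
    n <- sample(10:50, 1)
    tm <- sample(1:90, n, TRUE)
    ev <- runif(n) < 0.5
    rec <- data.table::data.table(
      patient_id = sprintf("R%03d", 1:n), cluster = 1L, time_days = tm,
      event = ifelse(ev, "death", "censored"), zero_followup = FALSE)
    sa <- survival_analysis(rec)
    for (at in c(30, 60, 90)) {
      got <- sa$curves[sa$curves$time <= at]
      got <- if (nrow(got)) got$survival[which.max(got$time)] else 1
      expect_equal(got, km_oracle(tm, as.integer(ev), at),
                   tolerance = 1e-12)
    }
  }
})

test_that("no deaths is flagged, curves stay at 1", {
  rec <- data.table::data.table(
    patient_id = sprintf("S%d", 1:6), cluster = rep(1:2, 3),
    time_days = 90, event = "censored", zero_followup = FALSE)
  sa <- survival_analysis(rec)
  expect_equal(sa$flag, "no_events")
  expect_true(all(sa$curves$survival == 1))
  expect_true(is.na(sa$logrank_p))
  rec0 <- data.table::data.table(patient_id = "a", cluster = 1,
                                 time_days = 0, event = "censored",
                                 zero_followup = TRUE)
  expect_error(survival_analysis(rec0), "censored at time 0")
})

test_that("k-group log-rank reduces to the two-sample statistic", {
  set.seed(17)
  for (r in 1:10) {
    n <- 40
    grp <- rep(1:2, each = n / 2)
    tm <- ceiling(rexp(n, ifelse(grp == 1, 0.01, 0.03)))
    tm <- pmin(tm, 90)
    ev <- as.integer(tm < 90)
    rec <- data.table::data.table(
      patient_id = sprintf("T%03d", 1:n), cluster = grp, time_days = tm,
      event = ifelse(ev == 1, "death", "censored"), zero_followup = FALSE)
    sa <- survival_analysis(rec)
    expect_equal(sa$logrank_chisq, logrank2_oracle(tm, ev, grp),
                 tolerance = 1e-6)
  }
})

test_that("ARI: identity, label-permutation invariance, null mean, oracle", {
  a <- setNames(rep(1:4, each = 5), sprintf("P%02d", 1:20))
  expect_equal(recovery_score(a, a), 1.0)
  perm <- setNames(c(3L, 4L, 1L, 2L)[a], names(a))
  expect_equal(recovery_score(a, perm), 1.0)
  expect_error(recovery_score(a, setNames(a, sprintf("X%02d", 1:20))),
               "mismatched")

  set.seed(18)
  null_ari <- replicate(100, {
    x <- sample(1:4, 112, TRUE)
    y <- sample(1:4, 112, TRUE)
    recovery_score(x, y)
  })
  expect_lt(abs(mean(null_ari)), 0.05)

  # cross-implementation identity against mclust
  for (r in 1:20) {
    x <- sample(1:5, 60, TRUE)
    y <- sample(1:3, 60, TRUE)
    expect_equal(recovery_score(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
})
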