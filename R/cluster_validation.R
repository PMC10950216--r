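#' Per-cluster clinical characteristics with Fisher / Kruskal-Wallis tests
#'
#' Emulates a clinical characteristics-by-cluster table: per-cluster counts
#' for sex, age band, cancer type, first-episode AKI stage and inpatient
#' status at onset, and per-cluster median (IQR) baseline SCr. Categorical
#' rows are tested with Fisher's exact test (seeded Monte-Carlo with 1e5
#' draws for tables beyond 2x2); continuous rows with the Kruskal-Wallis
#' test. No multiple-testing correction is applied (per-row p < 0.05
#' reporting); a Holm-adjusted column is added for transparency.
#'
#' @param cohort filtered `aki_cohort`.
#' @param clusters a `cluster_assignment`.
#' @param first_episodes first-episode table (`patient_id`, `onset_date`,
#'   `stage`, `baseline_scr`).
#' @param seed seed for the Monte-Carlo Fisher test.
#' @return list with `summary` (long data.table of per-cluster cells) and
#'   `tests` (variable, test, p_value, p_holm).
#' @export
cluster_characteristics_table <- function(cohort, clusters, first_episodes,
                                          seed = 1L) {
  lab <- data.table(patient_id = names(clusters$labels),
                    cluster = as.integer(clusters$labels))
  if (length(unique(lab$cluster)) < 2)
    stop("cluster_characteristics_table: need >= 2 non-empty clusters")
  dt <- cohort$registry[lab, on = "patient_id"]
  dt <- first_episodes[, .(patient_id, onset_date, stage, baseline_scr)][
    dt, on = "patient_id"]
  ip <- cohort$inpatient[dt[, .(patient_id, onset_date)],
                         on = .(patient_id, start <= onset_date,
                                end >= onset_date), nomatch = NULL,
                         .(patient_id)]
  dt[, inpatient_at_onset := patient_id %in% unique(ip$patient_id)]

  cat_vars <- c("sex", "age_band", "cancer_type", "stage",
                "inpatient_at_onset")
  tests <- list()
  summaries <- list()
  for (v in cat_vars) {
    tab <- table(dt[[v]], dt$cluster)
    p <- fisher_p(tab, seed = seed)
    tests[[v]] <- data.table(variable = v, test = "fisher", p_value = p)
    cnt <- as.data.table(tab)
    setnames(cnt, c("level", "cluster", "n"))
    summaries[[v]] <- data.table(variable = v, cnt)
  }
  kw <- stats::kruskal.test(dt$baseline_scr, factor(dt$cluster))
  tests[["baseline_scr"]] <- data.table(variable = "baseline_scr",
                                        test = "kruskal-wallis",
                                        p_value = kw$p.value)
  med <- dt[, .(level = sprintf("%.2f (%.2f-%.2f)",
                                median(baseline_scr),
                                quantile(baseline_scr, 0.25),
                                quantile(baseline_scr, 0.75)),
                n = .N), by = .(cluster)]
  summaries[["baseline_scr"]] <- data.table(variable = "baseline_scr",
                                            med[, .(level, cluster, n)])
  tests <- rbindlist(tests)
  tests[, p_holm := stats::p.adjust(p_value, "holm")]
  list(summary = rbindlist(summaries, use.names = TRUE), tests = tests[])
}

# Fisher exact p; exact for 2x2, seeded Monte-Carlo for larger tables.
fisher_p <- function(tab, seed = 1L, B = 1e5) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (any(dim(tab) < 2)) return(NA_real_)
  if (all(dim(tab) == 2)) return(stats::fisher.test(tab)$p.value)
  with_seed(seed, stats::fisher.test(tab, simulate.p.value = TRUE,
                                     B = B)$p.value)
}

#' Mechanism-label distribution per cluster with goodness-of-fit
#'
#' Counts the six annotation labels (`Hypovolemia`, `Cancer Cachexia`,
#' `Infection`, `Drug-related`, `Obstruction`, `Others`) within each
#' cluster and tests each cluster's distribution against the pooled
#' marginal with a chi-square goodness-of-fit test; label categories whose
#' expected count falls below 1 are collapsed into `Others`.
#'
#' @param clusters a `cluster_assignment`.
#' @param labels data.table (`patient_id`, `label`); every clustered
#'   patient must be labeled.
#' @return list with `counts` (cluster x label), `modal` (modal label per
#'   cluster) and `gof` (cluster, statistic, df, p_value).
#' @export
label_distribution <- function(clusters, labels) {
  cl <- data.table(patient_id = names(clusters$labels),
                   cluster = as.integer(clusters$labels))
  miss <- setdiff(cl$patient_id, labels$patient_id)
  if (length(miss))
    stop("label_distribution: unlabeled patient(s): ", toString(miss))
  dt <- labels[cl, on = "patient_id"]
  pooled <- dt[, .N, by = label]
  pooled[, p := N / sum(N)]
  gof <- list()
  for (k in sort(unique(dt$cluster))) {
    obs <- dt[cluster == k, .N, by = label]
    obs <- merge(pooled[, .(label, p)], obs, by = "label", all.x = TRUE)
    obs[is.na(N), N := 0L]
    nk <- sum(obs$N)
    obs[, E := nk * p]
    low <- obs$E < 1 & obs$label != "Others"
    if (any(low)) {
      if (!any(obs$label == "Others"))
        obs <- rbind(obs, data.table(label = "Others", p = 0, N = 0L, E = 0))
      low <- obs$E < 1 & obs$label != "Others"
      oth <- obs$label == "Others"
      obs$N[oth] <- obs$N[oth] + sum(obs$N[low])
      obs$E[oth] <- obs$E[oth] + sum(obs$E[low])
      obs <- obs[!low]
    }
    stat <- sum((obs$N - obs$E)^2 / obs$E)
    df <- nrow(obs) - 1L
    gof[[length(gof) + 1L]] <- data.table(
      cluster = k, statistic = stat, df = df,
      p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  }
  counts <- dcast(dt[, .N, by = .(cluster, label)], cluster ~ label,
                  value.var = "N", fill = 0L)
  modal <- dt[, .N, by = .(cluster, label)][
    order(cluster, -N, label)][, .SD[1], by = cluster][
      , .(cluster, modal_label = label, n = N)]
  list(counts = counts, modal = modal, gof = rbindlist(gof))
}

#' Build 90-day post-AKI survival records
#'
#' Time origin is the first AKI onset; time is capped at `horizon` days,
#' with `event = censored` at the cap when the patient is alive there.
#' Patients with no post-onset follow-up contribute time 0 censored and are
#' flagged.
#'
#' @param registry cohort registry table.
#' @param first_episodes first-episode table.
#' @param clusters a `cluster_assignment`.
#' @param horizon cap in days (default 90).
#' @return data.table (`patient_id`, `cluster`, `time_days`, `event`,
#'   `zero_followup`).
#' @export
make_survival_records <- function(registry, first_episodes, clusters,
                                  horizon = 90) {
  cl <- data.table(patient_id = names(clusters$labels),
                   cluster = as.integer(clusters$labels))
  dt <- registry[first_episodes[, .(patient_id, onset_date)],
                 on = "patient_id"][cl, on = "patient_id", nomatch = NULL]
  dt[, t_end := pmin(as.numeric(end_of_followup - onset_date), horizon)]
  dt[, t_death := ifelse(is.na(death_date), Inf,
                         as.numeric(death_date - onset_date))]
  dt[, event := ifelse(t_death <= t_end & t_death <= horizon,
                       "death", "censored")]
  dt[, time_days := pmax(0, pmin(t_end, t_death, horizon))]
  dt[, zero_followup := time_days <= 0 & event == "censored"]
  dt[, .(patient_id, cluster, time_days, event, zero_followup)]
}

#' Kaplan-Meier curves and k-group log-rank test per cluster
#'
#' Product-limit survival per cluster with a k-group log-rank test of
#' separation. With no events the curves are constant at 1 and the log-rank
#' p is `NA` with `flag = "no_events"`.
#'
#' @param records table from [make_survival_records()].
#' @return list with `curves` (tidy: cluster, time, n_risk, n_event,
#'   survival), `logrank_chisq`, `logrank_df`, `logrank_p`, `flag`.
#' @export
survival_analysis <- function(records) {
  stopifnot(nrow(records) > 0)
  if (all(records$time_days <= 0 & records$event == "censored"))
    stop("survival_analysis: all records censored at time 0")
  st <- as.integer(records$event == "death")
  fit <- survival::survfit(survival::Surv(records$time_days, st) ~
                             records$cluster)
  strata_names <- if (is.null(fit$strata)) as.character(records$cluster[1])
                  else sub("^records\\$cluster=", "", names(fit$strata))
  curves <- data.table(
    cluster = rep(strata_names,
                  times = if (is.null(fit$strata)) length(fit$time)
                          else fit$strata),
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    survival = fit$surv)
  flag <- NULL
  chisq <- df <- p <- NA_real_
  if (sum(st) == 0) {
    flag <- "no_events"
  } else if (length(unique(records$cluster)) >= 2) {
    sd_ <- survival::survdiff(survival::Surv(records$time_days, st) ~
                                records$cluster)
    df <- length(sd_$n) - 1L
    chisq <- sd_$chisq
    p <- stats::pchisq(chisq, df, lower.tail = FALSE)
  } else {
    flag <- "single_group"
  }
  list(curves = curves[], logrank_chisq = chisq, logrank_df = df,
       logrank_p = p, flag = flag)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement computed from the closed form
#' on the contingency table: 1 for identical partitions up to relabeling,
#' expectation 0 under independent random partitions.
#'
#' @param a,b named cluster-label vectors over the same ids (names are
#'   matched; unnamed vectors are compared positionally).
#' @return the adjusted Rand index.
#' @export
recovery_score <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("recovery_score: mismatched id sets")
    b <- b[names(a)]
  } else stopifnot(length(a) == length(b))
  n <- length(a)
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < 1e-12) return(1)
  (sum_ij - expected) / (max_index - expected)
}
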