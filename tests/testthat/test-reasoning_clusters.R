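# hand-built minimal inputs for the extraction contract
toy_extraction_inputs <- function(onset_day = 12, pred_days = c(5, 9),
                                  probs = c(0.8, 0.9), threshold = 0.5) {
  origin <- as.Date("2021-01-01")
  firsts <- data.table::data.table(
    patient_id = "A", onset_date = origin + onset_day, stage = 1L,
    baseline_scr = 1, trigger_scr = 1.4, peak_scr = 1.4,
    criterion = "absolute_increase", is_first = TRUE,
    multi_event_excluded = FALSE)
  preds <- data.table::data.table(
    patient_id = "A", reference_date = origin + pred_days,
    label = TRUE, eligible = TRUE, predicted_prob = probs)
  vals <- matrix(seq_len(2 * length(pred_days)), nrow = 2,
                 dimnames = list(c("feat1", "feat2"),
                                 as.character(origin + pred_days)))
  atts <- list(A = structure(list(
    patient_id = "A", dates = origin + pred_days, values = vals,
    base_value = 0, margin = rep(0, length(pred_days))),
    class = "attribution_matrix"))
  imp <- data.table::data.table(feature = c("feat1", "feat2"),
                                mean_abs_shap = c(2, 1), rank = 1:2)
  bundle <- list(decision_threshold = threshold)
  list(firsts = firsts, preds = preds, atts = atts, imp = imp,
       bundle = bundle, origin = origin)
}

test_that("extraction takes the latest positive pre-onset frame", {
  ti <- toy_extraction_inputs()
  sig <- extract_signatures(ti$firsts, ti$preds, ti$atts, ti$bundle,
                            K = 2, importance = ti$imp)
  expect_equal(sig$extraction_date, ti$origin + 9)
  expect_false(sig$subthreshold)
  expect_equal(sig$feat1, ti$atts$A$values["feat1", 2])
})

test_that("subthreshold fallback keeps the patient and flags it", {
  ti <- toy_extraction_inputs(probs = c(0.1, 0.2), threshold = 0.5)
  sig <- extract_signatures(ti$firsts, ti$preds, ti$atts, ti$bundle,
                            K = 2, importance = ti$imp)
  expect_equal(nrow(sig), 1L)
  expect_true(sig$subthreshold)
  expect_equal(sig$extraction_date, ti$origin + 9)
})

test_that("patients with no pre-onset point are skipped and logged", {
  ti <- toy_extraction_inputs(onset_day = 3, pred_days = c(5, 9))
  sig <- extract_signatures(ti$firsts, ti$preds, ti$atts, ti$bundle,
                            K = 2, importance = ti$imp)
  expect_equal(nrow(sig), 0L)
  expect_equal(attr(sig, "skipped"), "A")
})

test_that("multi-event-excluded patients are omitted from clustering", {
  ti <- toy_extraction_inputs()
  ti$firsts$multi_event_excluded <- TRUE
  sig <- extract_signatures(ti$firsts, ti$preds, ti$atts, ti$bundle,
                            K = 2, importance = ti$imp)
  expect_equal(nrow(sig), 0L)
})

make_signatures <- function(m, features = colnames(m)) {
  dt <- data.table::data.table(
    patient_id = rownames(m),
    extraction_date = as.Date("2021-02-01"),
    subthreshold = FALSE)
  dt <- cbind(dt, data.table::as.data.table(m))
  data.table::setattr(dt, "features", features)
  data.table::setattr(dt, "class",
                      c("reasoning_signatures", class(dt)))
  dt
}

test_that("well-separated centroids are recovered and k = n gives singletons", {
  set.seed(1)
  m <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
             matrix(rnorm(10, 8, 0.1), 5, 2))
  rownames(m) <- sprintf("P%02d", 1:10)
  colnames(m) <- c("s1", "s2")
  sig <- make_signatures(m)
  ca <- cluster_signatures(sig, k = 2)
  expect_equal(unname(ca$labels[1:5]), rep(ca$labels[[1]], 5))
  expect_equal(unname(ca$labels[6:10]), rep(ca$labels[[6]], 5))
  expect_false(ca$labels[[1]] == ca$labels[[6]])

  singles <- cluster_signatures(sig, k = 10)
  expect_equal(length(unique(singles$labels)), 10L)
  expect_error(cluster_signatures(sig, k = 11), "fewer signatures")
})

test_that("re-cutting the stored tree reproduces the identical partition", {
  set.seed(2)
  m <- matrix(rnorm(60), 15, 4,
              dimnames = list(sprintf("P%02d", 1:15), paste0("s", 1:4)))
  sig <- make_signatures(m)
  ca <- cluster_signatures(sig, k = 4)
  again <- recut_clusters(ca, 4)
  expect_identical(ca$labels, again$labels)
  expect_identical(recut_clusters(ca, 2)$k, 2L)
})

test_that("cluster labels are invariant to input order (ARI = 1)", {
  set.seed(3)
  m <- matrix(rnorm(80), 20, 4,
              dimnames = list(sprintf("P%02d", 1:20), paste0("s", 1:4)))
  sig <- make_signatures(m)
  shuf <- sig[sample(20)]
  data.table::setattr(shuf, "features", attr(sig, "features"))
  data.table::setattr(shuf, "class", class(sig))
  a <- cluster_signatures(sig, k = 3)$labels
  b <- cluster_signatures(shuf, k = 3)$labels
  expect_equal(recovery_score(a, b), 1.0)
})

test_that("raw-value comparator flags degenerate input, keeps patient set", {
  m <- matrix(1, 6, 3, dimnames = list(sprintf("P%02d", 1:6),
                                       paste0("s", 1:3)))
  sig <- make_signatures(m)
  fr <- data.table::data.table(
    patient_id = rownames(m), reference_date = as.Date("2021-02-01"),
    label = FALSE, eligible = TRUE, s1 = 1, s2 = 1, s3 = 1)
  data.table::setattr(fr, "feature_names", paste0("s", 1:3))
  expect_warning(ca <- cluster_raw_values(sig, fr, k = 2),
                 "zero-variance")
  expect_true(ca$degenerate)
  expect_setequal(names(ca$labels), rownames(m))

  res <- pipeline_fixture()
  expect_setequal(names(res$clusters_raw$labels),
                  names(res$clusters_shap$labels))
})

test_that("choose_k returns fixed k, finds planted blobs by silhouette", {
  expect_equal(choose_k(NULL, method = "fixed", k = 4), 4L)
  set.seed(4)
  m <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
             matrix(rnorm(40, 6, 0.2), 20, 2))
  rownames(m) <- sprintf("P%02d", 1:40)
  colnames(m) <- c("s1", "s2")
  sig <- make_signatures(m)
  ca <- cluster_signatures(sig, k = 2, scale_features = FALSE)
  expect_equal(choose_k(ca, data = m, method = "silhouette"), 2L)
  # search range clamps when only 3 signatures exist
  m3 <- m[1:3, , drop = FALSE]
  ca3 <- cluster_signatures(make_signatures(m3), k = 2,
                            scale_features = FALSE)
  expect_lte(choose_k(ca3, data = m3, method = "silhouette"), 3L)
})
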