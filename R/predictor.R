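#' Patient-level train/test split plan
#'
#' @param test_fraction fraction of patients held out for testing.
#' @param cv_folds number of cross-validation folds over training patients.
#' @param seed RNG seed governing the split and fold assignment.
#' @return object of class `split_plan`.
#' @export
split_plan <- function(test_fraction = 0.20, cv_folds = 5L, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, cv_folds >= 2)
  structure(list(test_fraction = test_fraction, cv_folds = as.integer(cv_folds),
                 unit = "patient", seed = as.integer(seed)),
            class = "split_plan")
}

#' Split patients into train and test sets, stratified on AKI status
#'
#' Every patient's frames fall wholly in one partition. The split is
#' stratified on patient-level AKI status so both partitions contain
#' positive patients; a partition with zero positives is an error.
#'
#' @param patient_ids character vector of patient ids.
#' @param is_aki logical vector, `TRUE` where the patient has any AKI frame.
#' @param plan a [split_plan()].
#' @return list with `train` and `test` id vectors.
#' @export
split_patients <- function(patient_ids, is_aki, plan = split_plan()) {
  stopifnot(length(patient_ids) == length(is_aki),
            !anyDuplicated(patient_ids))
  if (length(patient_ids) < 10) stop("split_patients: need >= 10 patients")
  if (!any(is_aki))
    stop("split_patients: no AKI-positive patients; stratified split impossible")
  with_seed(plan$seed, {
    test <- character()
    for (grp in list(patient_ids[is_aki], patient_ids[!is_aki])) {
      if (!length(grp)) next
      k <- max(1L, round(length(grp) * plan$test_fraction))
      test <- c(test, sample(grp, k))
    }
    train <- setdiff(patient_ids, test)
    if (!any(is_aki[patient_ids %in% test]) ||
        !any(is_aki[patient_ids %in% train]))
      stop("split_patients: a partition has zero AKI-positive patients")
    list(train = sort(train), test = sort(test))
  })
}

# stratified fold assignment over training patients
assign_folds <- function(patient_ids, is_aki, k, seed) {
  with_seed(seed, {
    fold <- integer(length(patient_ids))
    for (cl in c(TRUE, FALSE)) {
      idx <- which(is_aki == cl)
      if (length(idx))
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    setNames(fold, patient_ids)
  })
}

#' Default hyperparameter search space
#'
#' A small declared grid over tree depth, learning rate and leaf
#' regularization; selection is by mean cross-validated AUROC.
#'
#' @return data.frame, one row per candidate configuration.
#' @export
default_search_space <- function() {
  expand.grid(max_depth = c(3L, 5L), eta = c(0.1, 0.3),
              min_child_weight = c(1, 5), nrounds = 120L,
              KEEP.OUT.ATTRS = FALSE)
}

frames_to_xy <- function(frames, feature_names = NULL) {
  fn <- feature_names %||% attr(frames, "feature_names")
  missing_cols <- setdiff(fn, names(frames))
  if (length(missing_cols))
    stop("frames_to_xy: feature-name mismatch, missing: ",
         toString(utils::head(missing_cols, 5)))
  x <- as.matrix(as.data.frame(frames)[, fn, drop = FALSE])
  storage.mode(x) <- "double"
  list(x = x, y = as.numeric(frames$label), feature_names = fn)
}

fit_gbdt <- function(x, y, params, nrounds, monotone_constraints = NULL,
                     seed = 1L) {
  pars <- c(list(objective = "binary:logistic", tree_method = "hist",
                 nthread = 1, scale_pos_weight = sum(y == 0) / max(1, sum(y == 1))),
            params)
  if (!is.null(monotone_constraints))
    pars$monotone_constraints <- monotone_constraints
  with_seed(seed, xgboost::xgb.train(
    params = pars, data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = nrounds, verbose = 0))
}

#' Tune and train the 7-day AKI gradient-boosted classifier
#'
#' Splits patients 80/20 (per [split_patients()]), runs a grid search over a
#' small declared space with patient-level k-fold cross-validation on the
#' training patients (selection by mean CV AUROC), refits the winning
#' configuration on all training frames, and anchors the decision threshold
#' at the smallest probability cut reaching the target precision on the
#' pooled out-of-fold predictions — the held-out test frames stay untouched.
#' Class imbalance is handled by the learner's native positive-class weight.
#'
#' @param frames a `prediction_matrix`.
#' @param plan a [split_plan()].
#' @param search_space data.frame of candidate configurations; with a single
#'   row no search is performed (one CV pass still yields the out-of-fold
#'   predictions the threshold needs).
#' @param target_precision precision anchor for [select_threshold()].
#' @param monotone_constraints optional xgboost monotone-constraint vector.
#' @return object of class `aki_model`: fitted booster, tuned parameters,
#'   feature names, decision threshold, split ids, folds and CV traces.
#' @export
tune_and_train <- function(frames, plan = split_plan(),
                           search_space = default_search_space(),
                           target_precision = 0.25,
                           monotone_constraints = NULL) {
  pat <- data.table(patient_id = frames$patient_id, label = frames$label)[
    , .(is_aki = any(label)), by = patient_id]
  sp <- split_patients(pat$patient_id, pat$is_aki, plan)
  tr <- frames[frames$patient_id %in% sp$train, ]
  if (!any(tr$label) || all(tr$label))
    stop("tune_and_train: training frames must contain both classes")

  folds <- assign_folds(pat[patient_id %in% sp$train, patient_id],
                        pat[patient_id %in% sp$train, is_aki],
                        plan$cv_folds, plan$seed + 1L)
  xy <- frames_to_xy(tr)
  fold_of_frame <- folds[tr$patient_id]

  cv_results <- list()
  best <- NULL
  for (ci in seq_len(nrow(search_space))) {
    cfg <- search_space[ci, , drop = FALSE]
    pars <- as.list(cfg[setdiff(names(cfg), "nrounds")])
    oof <- rep(NA_real_, nrow(tr))
    aucs <- numeric(plan$cv_folds)
    for (f in seq_len(plan$cv_folds)) {
      hold <- fold_of_frame == f
      y_tr <- xy$y[!hold]
      if (length(unique(y_tr)) < 2 || length(unique(xy$y[hold])) < 2) {
        folds <- assign_folds(pat[patient_id %in% sp$train, patient_id],
                              pat[patient_id %in% sp$train, is_aki],
                              plan$cv_folds, plan$seed + 999L)
        fold_of_frame <- folds[tr$patient_id]
        hold <- fold_of_frame == f
        y_tr <- xy$y[!hold]
        if (length(unique(y_tr)) < 2 || length(unique(xy$y[hold])) < 2)
          stop("tune_and_train: degenerate single-class fold after resampling")
      }
      m <- fit_gbdt(xy$x[!hold, , drop = FALSE], y_tr, pars, cfg$nrounds,
                    monotone_constraints, seed = plan$seed + 10L + f)
      p <- predict(m, xgboost::xgb.DMatrix(xy$x[hold, , drop = FALSE]))
      oof[hold] <- p
      aucs[f] <- auroc(p, xy$y[hold])
    }
    cv_results[[ci]] <- data.frame(cfg, cv_auroc = mean(aucs))
    if (is.null(best) || mean(aucs) > best$cv_auroc + 1e-12) {
      best <- list(cfg = cfg, cv_auroc = mean(aucs), oof = oof)
    }
  }

  final <- fit_gbdt(xy$x, xy$y,
                    as.list(best$cfg[setdiff(names(best$cfg), "nrounds")]),
                    best$cfg$nrounds, monotone_constraints,
                    seed = plan$seed + 7L)
  thr <- select_threshold(best$oof, xy$y, target_precision)

  structure(list(
    model = final, params = as.list(best$cfg),
    feature_names = xy$feature_names, decision_threshold = thr,
    train_ids = sp$train, test_ids = sp$test, folds = folds,
    cv_results = do.call(rbind, cv_results), cv_auroc = best$cv_auroc,
    oof = data.table(patient_id = tr$patient_id,
                     reference_date = tr$reference_date,
                     prob = best$oof, label = xy$y == 1),
    target_precision = target_precision, seed = plan$seed
  ), class = "aki_model")
}

#' Smallest probability cut reaching a target precision
#'
#' Enumerates every candidate cut (the distinct predicted probabilities) and
#' returns the smallest at which precision on the supplied predictions is at
#' least `target_precision`; ties break toward the lower cut (higher
#' recall).
#'
#' @param probs predicted probabilities.
#' @param labels logical or 0/1 labels.
#' @param target_precision required precision (default 0.25).
#' @return the selected probability cut.
#' @export
select_threshold <- function(probs, labels, target_precision = 0.25) {
  labels <- as.logical(as.numeric(labels))
  stopifnot(length(probs) == length(labels))
  cuts <- sort(unique(probs))
  tp <- vapply(cuts, function(cc) sum(labels[probs >= cc]), 0)
  n <- vapply(cuts, function(cc) sum(probs >= cc), 0)
  prec <- tp / n
  ok <- which(prec >= target_precision - 1e-12)
  if (!length(ok))
    stop(sprintf(
      "select_threshold: precision %.3f unreachable (max achievable %.3f)",
      target_precision, max(prec)))
  cuts[min(ok)]
}

#' Predict 7-day AKI probabilities for a set of frames
#'
#' @param bundle an `aki_model`.
#' @param frames `prediction_matrix` rows to score.
#' @param output `"prob"` (default) or `"margin"` (log-odds).
#' @return copy of `frames` with `predicted_prob` and `predicted_positive`
#'   (`prob >= decision_threshold`).
#' @export
predict_series <- function(bundle, frames, output = c("prob", "margin")) {
  output <- match.arg(output)
  xy <- frames_to_xy(frames, bundle$feature_names)
  dm <- xgboost::xgb.DMatrix(xy$x)
  out <- copy(as.data.table(frames))
  out[, predicted_prob := predict(bundle$model, dm)]
  out[, predicted_positive := predicted_prob >= bundle$decision_threshold]
  if (output == "margin")
    out[, predicted_margin := predict(bundle$model, dm, outputmargin = TRUE)]
  setattr(out, "feature_names", attr(frames, "feature_names"))
  setattr(out, "specs", attr(frames, "specs"))
  out[]
}

#' @export
print.aki_model <- function(x, ...) {
  cat("7-day AKI GBDT model\n")
  cat(sprintf("  CV AUROC %.3f | threshold %.4f (precision target %.2f)\n",
              x$cv_auroc, x$decision_threshold, x$target_precision))
  cat(sprintf("  %d train / %d test patients, %d features\n",
              length(x$train_ids), length(x$test_ids),
              length(x$feature_names)))
  invisible(x)
}
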