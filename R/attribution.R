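#' Per-frame Shapley-value attributions arranged as patient time series
#'
#' Computes exact tree-path Shapley values (polynomial-time TreeSHAP) for
#' every supplied frame on the model's margin (log-odds) scale, where the
#' local-accuracy identity is exact: for each frame,
#' `base_value + sum(attributions) = margin prediction`. Values are grouped
#' per patient into a features x prediction-dates matrix.
#'
#' @param bundle an `aki_model`.
#' @param frames `prediction_matrix` rows to explain.
#' @return named list of `attribution_matrix` objects, one per patient:
#'   each a list with `patient_id`, `dates`, `values` (features x dates
#'   numeric matrix), `base_value`, and `margin` (model raw output per
#'   date).
#' @export
compute_attributions <- function(bundle, frames) {
  xy <- frames_to_xy(frames, bundle$feature_names)
  dm <- xgboost::xgb.DMatrix(xy$x)
  contrib <- predict(bundle$model, dm, predcontrib = TRUE)
  contrib <- as.matrix(contrib)
  # last column is the base value ("BIAS"/"(Intercept)" depending on version)
  stopifnot(colnames(contrib)[ncol(contrib)] %in% c("BIAS", "(Intercept)"))
  colnames(contrib)[ncol(contrib)] <- "BIAS"
  margin <- predict(bundle$model, dm, outputmargin = TRUE)

  ids <- frames$patient_id
  dates <- as.Date(frames$reference_date)
  out <- list()
  for (pid in unique(ids)) {
    idx <- which(ids == pid)
    idx <- idx[order(dates[idx])]
    if (anyDuplicated(dates[idx]))
      stop("compute_attributions: duplicate prediction dates for ", pid)
    vals <- t(contrib[idx, -ncol(contrib), drop = FALSE])
    colnames(vals) <- as.character(dates[idx])
    out[[pid]] <- structure(list(
      patient_id = pid, dates = dates[idx], values = vals,
      base_value = unname(contrib[idx[1], "BIAS"]),
      margin = unname(margin[idx])), class = "attribution_matrix")
  }
  out
}

#' Global feature importance: mean absolute attribution
#'
#' Ranks features by the mean of |attribution| across all frames of all
#' supplied patients, descending, ties broken by feature name.
#'
#' @param attributions list from [compute_attributions()].
#' @return data.table with `feature`, `mean_abs_shap`, `rank`.
#' @export
global_importance <- function(attributions) {
  stopifnot(length(attributions) >= 1)
  acc <- NULL
  n <- 0
  for (am in attributions) {
    s <- rowSums(abs(am$values))
    acc <- if (is.null(acc)) s else acc + s
    n <- n + ncol(am$values)
  }
  dt <- data.table(feature = names(acc), mean_abs_shap = acc / n)
  setorder(dt, -mean_abs_shap, feature)
  dt[, rank := .I]
  dt[]
}

#' Dependence-plot data for one feature at the signature-extraction frames
#'
#' One point per AKI patient: the feature's raw value and its attribution at
#' the patient's signature-extraction frame, with the patient's cluster
#' label when available. Missing raw values are flagged, never silently
#' dropped.
#'
#' @param signatures data.table from [extract_signatures()] (one row per
#'   patient with `patient_id`, `extraction_date`).
#' @param attributions list from [compute_attributions()].
#' @param frames the `prediction_matrix` the attributions were computed on.
#' @param feature feature name.
#' @param clusters optional `cluster_assignment` for color-coding.
#' @return data.table with `patient_id`, `value`, `shap`, `missing`,
#'   `cluster`.
#' @export
dependence_data <- function(signatures, attributions, frames, feature,
                            clusters = NULL) {
  if (!feature %in% attr(frames, "feature_names"))
    stop("dependence_data: unknown feature ", feature)
  fr <- as.data.table(frames)
  rows <- vector("list", nrow(signatures))
  for (i in seq_len(nrow(signatures))) {
    pid <- signatures$patient_id[i]
    ed <- as.Date(signatures$extraction_date[i])
    am <- attributions[[pid]]
    if (is.null(am)) stop("dependence_data: no attributions for ", pid)
    j <- match(as.character(ed), colnames(am$values))
    raw <- fr[patient_id == pid & reference_date == ed][[feature]]
    rows[[i]] <- data.table(
      patient_id = pid,
      value = if (length(raw)) raw[1] else NA_real_,
      shap = if (!is.na(j)) am$values[feature, j] else NA_real_,
      missing = !length(raw) || is.na(raw[1]))
  }
  out <- rbindlist(rows)
  out[, cluster := NA_integer_]
  if (!is.null(clusters))
    out[data.table(patient_id = names(clusters$labels),
                   cl = as.integer(clusters$labels)),
        on = "patient_id", cluster := cl]
  out[]
}

#' Export a patient's attribution heatmap as a tidy table
#'
#' Selects the `top_k` features by the patient's own mean |attribution| and
#' returns a long table (feature, date, value) ready for plotting. `top_k`
#' larger than the number of features is clamped.
#'
#' @param am an `attribution_matrix`.
#' @param top_k number of features to keep.
#' @return data.table with `patient_id`, `feature`, `date`, `shap`, ordered
#'   by decreasing patient-level importance.
#' @export
heatmap_export <- function(am, top_k = 20L) {
  stopifnot(inherits(am, "attribution_matrix"))
  top_k <- max(0L, min(as.integer(top_k), nrow(am$values)))
  if (top_k == 0L)
    return(data.table(patient_id = character(), feature = character(),
                      date = as.Date(character()), shap = numeric()))
  imp <- rowMeans(abs(am$values))
  ord <- order(-imp, names(imp))[seq_len(top_k)]
  sub <- am$values[ord, , drop = FALSE]
  out <- data.table(
    patient_id = am$patient_id,
    feature = rep(rownames(sub), times = ncol(sub)),
    date = rep(am$dates, each = nrow(sub)),
    shap = as.vector(sub))
  out[, feature := factor(feature, levels = rownames(sub))]
  setorder(out, feature, date)
  out[]
}
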