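#' Extract predictive-reasoning signatures immediately before first AKI
#'
#' For each AKI patient the extraction frame is the latest prediction point
#' strictly before the first episode onset whose predicted probability
#' reaches the model's decision threshold; when no pre-onset point is
#' above threshold the latest pre-onset point is used and the patient is
#' flagged `subthreshold` (retained, not dropped, so the clustered set
#' equals the AKI cohort). The signature is the vector of attributions of
#' the `K` globally top-ranked features at that frame; attributions missing
#' at the frame are set to 0. Patients with no pre-onset prediction point
#' are skipped and logged in the `skipped` attribute.
#'
#' @param first_episodes data.table of first episodes (`patient_id`,
#'   `onset_date`, `multi_event_excluded`); multi-event-excluded patients
#'   are omitted.
#' @param predictions frames scored by [predict_series()].
#' @param attributions list from [compute_attributions()].
#' @param bundle the fitted `aki_model` (for the decision threshold).
#' @param K number of top global features in the signature (default 20).
#' @param importance optional precomputed [global_importance()] table.
#' @return data.table of class `reasoning_signatures`: `patient_id`,
#'   `extraction_date`, `subthreshold`, then K attribution columns;
#'   attributes `features` (the K names) and `skipped`.
#' @export
extract_signatures <- function(first_episodes, predictions, attributions,
                               bundle, K = 20L,
                               importance = global_importance(attributions)) {
  K <- min(as.integer(K), nrow(importance))
  feats <- importance$feature[seq_len(K)]
  preds <- as.data.table(predictions)
  eligible_pat <- first_episodes[multi_event_excluded == FALSE]

  rows <- list()
  skipped <- character()
  for (i in seq_len(nrow(eligible_pat))) {
    pid <- eligible_pat$patient_id[i]
    onset <- as.Date(eligible_pat$onset_date[i])
    pp <- preds[patient_id == pid & reference_date < onset]
    if (!nrow(pp)) { skipped <- c(skipped, pid); next }
    pos <- pp[predicted_prob >= bundle$decision_threshold]
    sub_flag <- nrow(pos) == 0L
    ed <- if (sub_flag) max(pp$reference_date) else max(pos$reference_date)
    am <- attributions[[pid]]
    vec <- setNames(rep(0, K), feats)
    if (!is.null(am)) {
      j <- match(as.character(as.Date(ed)), colnames(am$values))
      if (!is.na(j)) {
        have <- intersect(feats, rownames(am$values))
        v <- am$values[have, j]
        v[is.na(v)] <- 0
        vec[have] <- v
      }
    }
    rows[[length(rows) + 1L]] <- data.table(
      patient_id = pid, extraction_date = as.Date(ed),
      subthreshold = sub_flag, t(vec))
  }
  out <- if (length(rows)) rbindlist(rows) else
    data.table(patient_id = character(),
               extraction_date = as.Date(character()),
               subthreshold = logical())
  setorder(out, patient_id)
  setattr(out, "features", feats)
  setattr(out, "skipped", skipped)
  setattr(out, "class", c("reasoning_signatures", class(out)))
  out[]
}

signature_matrix <- function(signatures) {
  feats <- attr(signatures, "features")
  m <- as.matrix(as.data.frame(signatures)[, feats, drop = FALSE])
  rownames(m) <- signatures$patient_id
  m
}

#' Hierarchical clustering of reasoning signatures
#'
#' Agglomerative clustering (Euclidean distance, Ward linkage by default)
#' of the per-patient signature vectors. Rows are ordered by patient id
#' before clustering so the result is invariant to input order; the full
#' linkage tree is retained so any k can be re-cut without recomputation.
#' By default each attribution column is z-standardized first
#' (`scale_features = TRUE`): although attributions share the margin scale,
#' their variances differ by orders of magnitude across features, and
#' unscaled Euclidean distances are dominated by the one or two
#' highest-variance features and by overall prediction confidence rather
#' than by the *pattern* of reasoning; standardizing also mirrors the
#' raw-value comparator, keeping the comparison like-for-like.
#'
#' @param signatures a `reasoning_signatures` table.
#' @param k number of clusters (>= 2).
#' @param metric distance metric for [stats::dist()].
#' @param linkage linkage method for [stats::hclust()] (`ward.D2` default).
#' @param scale_features z-standardize each attribution column first.
#' @return object of class `cluster_assignment`: named integer `labels`,
#'   `tree` (hclust), `k`, `source`, `features`, `flags`.
#' @export
cluster_signatures <- function(signatures, k = 4L, metric = "euclidean",
                               linkage = "ward.D2", scale_features = TRUE) {
  m <- signature_matrix(signatures)
  if (scale_features) {
    m <- scale(m)
    m[, !is.finite(colSums(m))] <- 0   # zero-variance columns
  }
  cluster_matrix(m, k, metric, linkage, source = "shap",
                 features = attr(signatures, "features"),
                 flags = signatures$subthreshold)
}

#' Comparator clustering on z-standardized raw feature values
#'
#' Applies the identical algorithm to the raw values of the same key
#' features at the same extraction frames, z-standardized per feature;
#' zero-variance features are dropped with a warning. This is the
#' "clustering without attribution weighting" comparator.
#'
#' @param signatures a `reasoning_signatures` table (defines patients and
#'   extraction frames).
#' @param frames the `prediction_matrix` holding raw feature values.
#' @param k,metric,linkage as in [cluster_signatures()].
#' @return a `cluster_assignment` over the same patient set.
#' @export
cluster_raw_values <- function(signatures, frames, k = 4L,
                               metric = "euclidean", linkage = "ward.D2") {
  feats <- attr(signatures, "features")
  fr <- as.data.table(frames)
  key <- signatures[, .(patient_id, reference_date = extraction_date)]
  raw <- fr[key, on = .(patient_id, reference_date)]
  m <- as.matrix(as.data.frame(raw)[, feats, drop = FALSE])
  rownames(m) <- raw$patient_id
  m <- m[order(rownames(m)), , drop = FALSE]
  # missing raw values impute to the feature mean (0 after z-scaling)
  for (j in seq_len(ncol(m))) {
    nas <- is.na(m[, j])
    if (all(nas)) m[, j] <- 0
    else if (any(nas)) m[nas, j] <- mean(m[!nas, j])
  }
  sds <- apply(m, 2, stats::sd)
  drop <- sds == 0 | !is.finite(sds)
  if (all(drop)) {
    # identical vectors: any cut is arbitrary; flagged degenerate below
    warning("cluster_raw_values: all features zero-variance; ",
            "clustering is degenerate")
  } else {
    if (any(drop)) {
      warning("cluster_raw_values: dropping zero-variance feature(s): ",
              toString(colnames(m)[drop]))
      m <- m[, !drop, drop = FALSE]
    }
    m <- scale(m)
  }
  cluster_matrix(m, k, metric, linkage, source = "raw",
                 features = colnames(m), flags = signatures$subthreshold)
}

cluster_matrix <- function(m, k, metric, linkage, source, features, flags) {
  if (nrow(m) < k) stop("clustering: fewer signatures than clusters")
  m <- m[order(rownames(m)), , drop = FALSE]
  tree <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  labels <- stats::cutree(tree, k = k)
  names(labels) <- rownames(m)
  structure(list(labels = labels, tree = tree, k = as.integer(k),
                 metric = metric, linkage = linkage, source = source,
                 features = features,
                 flags = setNames(flags, rownames(m)),
                 degenerate = length(unique(as.vector(stats::dist(m)))) <= 1L),
            class = "cluster_assignment")
}

#' Re-cut a stored linkage tree at a different k
#'
#' @param assignment a `cluster_assignment`.
#' @param k new number of clusters.
#' @return a new `cluster_assignment` sharing the same tree.
#' @export
recut_clusters <- function(assignment, k) {
  labels <- stats::cutree(assignment$tree, k = k)
  names(labels) <- assignment$tree$labels
  out <- assignment
  out$labels <- labels
  out$k <- as.integer(k)
  out
}

#' Choose the number of clusters
#'
#' `fixed` mode returns the configured k (dendrogram inspection analogue);
#' `silhouette` mode returns the k maximizing the mean silhouette width
#' over `k in [2, 8]` (clamped to the number of signatures).
#'
#' @param assignment a `cluster_assignment` (its tree is re-cut per k).
#' @param data the matrix the tree was built on (required for silhouette).
#' @param method `"fixed"` or `"silhouette"`.
#' @param k fixed k (default 4).
#' @return integer k.
#' @export
choose_k <- function(assignment, data = NULL,
                     method = c("fixed", "silhouette"), k = 4L) {
  method <- match.arg(method)
  if (method == "fixed") return(as.integer(k))
  stopifnot(!is.null(data))
  data <- data[order(rownames(data)), , drop = FALSE]
  kmax <- min(8L, nrow(data) - 1L)
  ks <- 2:kmax
  d <- stats::dist(data)
  sil <- vapply(ks, function(kk) {
    lab <- stats::cutree(assignment$tree, k = kk)
    mean(cluster::silhouette(lab, d)[, "sil_width"])
  }, 0)
  ks[which.max(sil)]
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Hierarchical clustering (%s, %s) of %d %s signatures, k = %d\n",
              x$metric, x$linkage, length(x$labels), x$source, x$k))
  print(table(cluster = x$labels))
  invisible(x)
}
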