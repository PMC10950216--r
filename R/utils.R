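#' @import data.table
#' @importFrom stats rnorm rbinom runif rexp rgeom quantile median setNames
NULL

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-patient sub-seed below 2^31.
sub_seed <- function(seed, i) {
  (as.numeric(seed) * 48271 + i * 16807) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' Computes AUROC as the probability that a randomly chosen positive frame
#' receives a higher score than a randomly chosen negative frame, with ties
#' counted as 1/2. Equivalent to the trapezoidal area under the empirical
#' ROC curve.
#'
#' @param scores numeric predicted scores (probabilities or margins).
#' @param labels logical or 0/1 vector, `TRUE`/1 = positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("auroc: need both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
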