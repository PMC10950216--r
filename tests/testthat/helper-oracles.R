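# Independent oracles used across the suite. These deliberately re-derive
# results by direct enumeration / hand computation, never by calling the
# code paths they check.

# Brute-force KDIGO episode scan: all measurement pairs with the 48-hour
# (+0.3 mg/dL) and 7-day (1.5x) windows, then the same 7-day staging-window
# suppression rule as the detector contract.
brute_force_onsets <- function(series, ici_start) {
  d <- as.numeric(series$date)
  v <- series$value
  start <- as.numeric(as.Date(ici_start))
  qualifying <- logical(length(d))
  for (i in seq_along(d)) {
    if (d[i] < start) next
    for (j in seq_along(d)) {
      if (d[j] >= d[i]) next
      gap <- d[i] - d[j]
      if (gap <= 2 && v[i] - v[j] >= 0.3 - 1e-12) qualifying[i] <- TRUE
      if (gap <= 7 && v[i] >= 1.5 * v[j] - 1e-12) qualifying[i] <- TRUE
    }
  }
  onsets <- numeric()
  blocked <- -Inf
  for (i in seq_along(d)) {
    if (qualifying[i] && d[i] > blocked) {
      onsets <- c(onsets, d[i])
      blocked <- d[i] + 7
    }
  }
  as.Date(onsets, origin = "1970-01-01")
}

random_scr_series <- function(n = NULL) {
  n <- n %||% sample(5:25, 1)
  days <- sort(sample(0:80, n))
  base <- exp(rnorm(1, log(0.9), 0.3))
  v <- base * exp(cumsum(rnorm(n, 0, 0.08)))
  jump <- runif(n) < 0.08
  v[jump] <- v[jump] * runif(sum(jump), 1.3, 2.5)
  data.frame(date = as.Date("2020-01-01") + days, value = round(v, 2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand product-limit estimator at a time t.
km_oracle <- function(time, event, at) {
  ts <- sort(unique(time[event == 1 & time <= at]))
  s <- 1
  for (tt in ts) {
    n_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

# Hand two-sample log-rank chi-square statistic.
logrank2_oracle <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- sort(unique(group))[1]
  ts <- sort(unique(time[event == 1]))
  o1 <- e1 <- vr <- 0
  for (tt in ts) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & group == g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) vr <- vr + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o1 - e1)^2 / vr
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration.
fisher2x2_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exhaustive Shapley enumeration for an xgboost tree ensemble with the
# path-dependent (cover-weighted) conditional value function.
shapley_oracle <- function(model, x_row, feature_names) {
  trees <- xgboost::xgb.model.dt.tree(model = model)
  nf <- length(feature_names)
  eval_tree <- function(tr, S) {
    node_val <- function(id) {
      nd <- tr[tr$Node == id & !is.na(tr$Node), ][1, ]
      if (nd$Feature == "Leaf") return(nd$Gain)
      f <- nd$Feature
      yes_id <- as.integer(sub(".*-", "", nd$Yes))
      no_id <- as.integer(sub(".*-", "", nd$No))
      miss_id <- as.integer(sub(".*-", "", nd$Missing))
      if (f %in% S) {
        xv <- x_row[[f]]
        if (is.na(xv)) return(node_val(miss_id))
        if (xv < nd$Split) node_val(yes_id) else node_val(no_id)
      } else {
        cov_of <- function(id) tr[tr$Node == id, ]$Cover[1]
        wy <- cov_of(yes_id); wn <- cov_of(no_id)
        (wy * node_val(yes_id) + wn * node_val(no_id)) / (wy + wn)
      }
    }
    node_val(0L)
  }
  v <- function(S) {
    tot <- 0
    for (tid in unique(trees$Tree))
      tot <- tot + eval_tree(as.data.frame(trees[trees$Tree == tid, ]), S)
    tot
  }
  # note: v() omits the ensemble's constant intercept (base_score margin);
  # it cancels in all Shapley differences, so phi is unaffected
  phi <- setNames(numeric(nf), feature_names)
  for (f in feature_names) {
    others <- setdiff(feature_names, f)
    for (sz in 0:length(others)) {
      subsets <- if (sz == 0) list(character()) else
        utils::combn(others, sz, simplify = FALSE)
      w <- factorial(sz) * factorial(nf - sz - 1) / factorial(nf)
      for (S in subsets)
        phi[f] <- phi[f] + w * (v(c(S, f)) - v(S))
    }
  }
  list(phi = phi, base = v(character()))
}

# Closed-form check value for ARI is computed inline in tests via
# mclust::adjustedRandIndex as the cross-implementation oracle.
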