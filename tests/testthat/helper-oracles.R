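# Independent oracles. Each reimplements a quantity from first principles,
# deliberately avoiding the package's own code paths.

# AUC by exhaustive pair counting: concordant pairs score 1, ties 1/2.
oracle_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Univariate screening score: |cov-like inner product| / column norm,
# computed column by column with explicit loops.
oracle_screen_scores <- function(x, y) {
  scores <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    xc <- x[, j] - mean(x[, j])
    yc <- y - mean(y)
    nrm <- sqrt(sum(xc^2))
    scores[j] <- if (nrm == 0) -Inf else abs(sum(xc * yc)) / nrm
  }
  stats::setNames(scores, colnames(x))
}

# End of the gap-tolerant coverage run starting at day 0, by brute-force
# day enumeration over the horizon. Intervals are half-open [start, end) in
# 0-based days; the returned value is the 0-based exclusive end of the run
# (i.e. number of days reached before a gap > bridge).
oracle_covered_run <- function(starts, ends, bridge, horizon) {
  covered <- rep(FALSE, horizon)
  for (i in seq_along(starts)) {
    lo <- max(1, starts[i] + 1); hi <- min(horizon, ends[i])
    if (lo <= hi) covered[lo:hi] <- TRUE
  }
  run_end <- 0; gap <- 0
  for (day in seq_len(horizon)) {
    if (covered[day]) { run_end <- day; gap <- 0 }
    else { gap <- gap + 1; if (gap > bridge) break }
  }
  run_end
}

# Largest-remainder apportionment, written independently.
oracle_largest_remainder <- function(w, n) {
  w <- w / sum(w)
  q <- w * n
  counts <- floor(q)
  left <- n - sum(counts)
  if (left > 0) {
    frac <- q - counts
    ord <- order(-frac, names(w))
    counts[ord[seq_len(left)]] <- counts[ord[seq_len(left)]] + 1
  }
  counts
}

# L1-penalized logistic regression by cyclic coordinate descent on the
# quadratic (IRLS) approximation, objective -(1/n) loglik + lambda ||b||_1,
# unpenalized intercept, no standardization (glmnet's parametrization).
oracle_lasso_logistic_cd <- function(x, y, lambda, max_iter = 2000,
                                     tol = 1e-12) {
  n <- nrow(x); p <- ncol(x)
  b0 <- 0; b <- rep(0, p)
  soft <- function(z, g) sign(z) * max(abs(z) - g, 0)
  for (it in seq_len(max_iter)) {
    old <- c(b0, b)
    eta <- b0 + drop(x %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-5)
    z <- eta + (y - mu) / w
    # coordinate updates on weighted least squares with L1 penalty
    for (inner in 1:50) {
      prev <- c(b0, b)
      r <- z - b0 - drop(x %*% b)
      b0 <- b0 + sum(w * r) / sum(w)
      r <- z - b0 - drop(x %*% b)
      for (j in seq_len(p)) {
        rj <- r + x[, j] * b[j]
        num <- sum(w * x[, j] * rj) / n
        den <- sum(w * x[, j]^2) / n
        bj_new <- soft(num, lambda) / den
        r <- rj - x[, j] * bj_new
        b[j] <- bj_new
      }
      if (max(abs(c(b0, b) - prev)) < tol) break
    }
    if (max(abs(c(b0, b) - old)) < 1e-10) break
  }
  list(intercept = b0, coefficients = stats::setNames(b, colnames(x)))
}

# Expected information gain by direct conditional-entropy enumeration.
oracle_information_gain <- function(values, labels, counts) {
  ent <- function(cnt) {
    cnt <- cnt[cnt > 0]; pr <- cnt / sum(cnt)
    -sum(pr * log2(pr))
  }
  prior <- ent(tapply(counts, labels, sum))
  cond <- 0
  for (a in unique(values)) {
    sel <- values == a
    cond <- cond + sum(counts[sel]) / sum(counts) *
      ent(tapply(counts[sel], labels[sel], sum))
  }
  prior - cond
}

# Minimum expected question count over all adaptive policies of depth <= cap,
# by exhaustive recursion. Rows are prototype indices; a policy stops when
# labels are constant among the surviving rows.
oracle_optimal_policy_cost <- function(rows, labels, counts, features,
                                       cap = 4) {
  recurse <- function(surv, asked, depth) {
    if (length(unique(labels[surv])) <= 1) return(0)
    if (depth >= cap) return(0)      # budget reached; no more questions
    best <- Inf
    for (f in setdiff(features, asked)) {
      vals <- rows[[f]][surv]
      if (length(unique(vals)) < 2) next
      cost <- 1
      for (a in unique(vals)) {
        sub <- surv[vals == a]
        cost <- cost + sum(counts[sub]) / sum(counts[surv]) *
          recurse(sub, c(asked, f), depth + 1)
      }
      best <- min(best, cost)
    }
    if (is.infinite(best)) 0 else best
  }
  recurse(seq_along(labels), character(0), 0)
}

# Expected question count of the package's greedy policy on a table,
# weighting each prototype row by count and answering with the row's value.
greedy_policy_cost <- function(table, label_fun, cap = 25L) {
  expected_interview_length(table, label_fun, question_budget = cap)
}

# McFadden R^2 from first principles at given predicted probabilities.
oracle_mcfadden <- function(p, y, p_null = mean(y)) {
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  ll0 <- sum(y * log(p_null) + (1 - y) * log(1 - p_null))
  1 - ll / ll0
}
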