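# Independent brute-force oracles used to pin down the fast implementations.
# Each oracle is written from the definition, not from the package code.

# Minimum assignment cost by exhaustive permutation search (n rows <= cols).
assignment_oracle <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m, n <= 7)
  best <- Inf
  rec <- function(row, used, acc) {
    if (row > n) {
      best <<- min(best, acc)
      return()
    }
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(row + 1L, used, acc + cost[row, j])
        used[j] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, m), 0)
  best
}

# ECE by direct per-bin accumulation.
ece_oracle <- function(p, y, n_bins) {
  conf <- apply(p, 1, max)
  pred <- apply(p, 1, which.max) - 1L
  total <- 0
  n <- nrow(p)
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins
    hi <- b / n_bins
    inb <- if (b < n_bins) conf >= lo & conf < hi else conf >= lo & conf <= hi
    if (any(inb)) {
      total <- total + sum(inb) / n *
        abs(mean(pred[inb] == y[inb]) - mean(conf[inb]))
    }
  }
  total
}

# AUROC by pairwise enumeration: P(unknown scores lower) + half ties.
auroc_oracle <- function(known, unknown) {
  tot <- 0
  for (u in unknown) {
    for (k in known) {
      tot <- tot + (u < k) + 0.5 * (u == k)
    }
  }
  tot / (length(known) * length(unknown))
}

# Average precision by scanning distinct detector thresholds.
aupr_oracle <- function(known, unknown) {
  det <- -c(known, unknown)
  pos <- c(rep(FALSE, length(known)), rep(TRUE, length(unknown)))
  prev_recall <- 0
  ap <- 0
  for (t in sort(unique(det), decreasing = TRUE)) {
    flagged <- det >= t
    precision <- sum(pos & flagged) / sum(flagged)
    recall <- sum(pos & flagged) / sum(pos)
    ap <- ap + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  ap
}

# FPR at >= target TPR by exhaustive threshold scan ("unknown" iff score < tau).
fpr95_oracle <- function(known, unknown, target = 0.95) {
  taus <- sort(unique(c(known, unknown, max(c(known, unknown)) + 1)))
  best <- 1
  found <- FALSE
  for (t in taus) {
    tpr <- mean(unknown < t)
    if (tpr >= target) {
      fpr <- mean(known < t)
      if (!found || fpr < best) best <- fpr
      found <- TRUE
    }
  }
  best
}

# Exact two-sided signed-rank p by full 2^n sign enumeration (midranks).
signed_rank_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  min(1, 2 * min(mean(w_all <= W + 1e-9), mean(w_all >= W - 1e-9)))
}

# Fixed-risk threshold by exhaustive scan over all candidate thresholds.
risk_threshold_oracle <- function(scores, correct, target) {
  taus <- c(min(scores) - 1, sort(unique(scores)))
  best <- NULL
  for (t in taus) {
    answered <- scores >= t
    if (!any(answered)) next
    risk <- mean(!correct[answered])
    if (risk <= target) {
      cov <- mean(answered)
      if (is.null(best) || cov > best$coverage) {
        best <- list(tau = t, coverage = cov, risk = risk)
      }
    }
  }
  best
}

# Random probability matrix with simplex rows.
random_prob_matrix <- function(n, K) {
  x <- matrix(stats::rexp(n * K), n, K)
  x / rowSums(x)
}
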