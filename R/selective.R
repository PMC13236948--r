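#' Per-sample confidence scores from logits
#'
#' Computes one of four confidence scores from temperature-scaled logits.
#' For all methods larger scores mean greater confidence:
#' * `msp`: maximum softmax probability, in `[1/K, 1]`;
#' * `entropy`: 1 minus the normalized Shannon entropy of the calibrated
#'   probabilities, in `[0, 1]`;
#' * `margin`: gap between the largest and second-largest calibrated
#'   probabilities, in `[0, 1]`;
#' * `energy`: negative energy, `logsumexp(z / T)` (shift-equivariant:
#'   adding c to a logit row raises the score by c / T).
#'
#' @param logits Numeric matrix (n x K), K >= 2.
#' @param T Positive temperature used for scaling (default 1).
#' @param method One of `"msp"`, `"entropy"`, `"margin"`, `"energy"`.
#' @return An object of class `score_vector`: tibble with `score`, plus
#'   attributes `method` and `temperature_used`.
#' @examples
#' z <- matrix(c(2, 0, 0, 0, 0, 0), 2, 3, byrow = TRUE)
#' confidence_score(z, method = "msp")$score
#' @export
confidence_score <- function(logits, T = 1,
                             method = c("msp", "entropy", "margin",
                                        "energy")) {
  method <- match.arg(method)
  logits <- as.matrix(logits)
  K <- ncol(logits)
  if (K < 2) stop("need K >= 2 classes", call. = FALSE)
  if (!is.finite(T) || T <= 0) stop("`T` must be > 0", call. = FALSE)
  score <- switch(
    method,
    msp = row_max(apply_temperature(logits, T)),
    entropy = {
      p <- apply_temperature(logits, T)
      h <- apply(p, 1, entropy_nat)
      1 - h / log(K)
    },
    margin = {
      p <- apply_temperature(logits, T)
      sorted <- t(apply(p, 1, sort, decreasing = TRUE))
      sorted[, 1] - sorted[, 2]
    },
    energy = row_logsumexp(logits / T)
  )
  out <- tibble::tibble(score = as.numeric(score))
  structure(out, class = c("score_vector", class(out)),
            method = method, temperature_used = T)
}

score_values <- function(scores) {
  if (inherits(scores, "score_vector") || is.data.frame(scores)) {
    scores$score
  } else {
    as.numeric(scores)
  }
}

#' Coverage and selective risk at a threshold
#'
#' A sample is answered iff its score is `>= tau`. Coverage is the answered
#' fraction; selective risk is the error rate among answered samples and is
#' `NA` (undefined) at zero coverage.
#'
#' @param scores A [confidence_score()] result or numeric vector.
#' @param correct Logical vector: was the prediction correct?
#' @param tau Threshold.
#' @return A one-row tibble with `tau`, `coverage`, `selective_risk`,
#'   `n_answered`.
#' @export
selective_metrics <- function(scores, correct, tau) {
  s <- score_values(scores)
  if (length(s) != length(correct)) {
    stop("`scores` and `correct` lengths differ", call. = FALSE)
  }
  answered <- s >= tau
  coverage <- mean(answered)
  risk <- if (any(answered)) mean(!correct[answered]) else NA_real_
  tibble::tibble(tau = tau, coverage = coverage, selective_risk = risk,
                 n_answered = sum(answered))
}

#' Coverage-risk curve
#'
#' Evaluates coverage and selective risk at every achievable operating point:
#' each distinct score value plus a below-minimum and an above-maximum
#' sentinel. Coverage is non-increasing in the threshold and equals 1 at the
#' lower sentinel.
#'
#' @inheritParams selective_metrics
#' @return A tibble of class `coverage_risk_curve` with one row per
#'   candidate threshold (columns as in [selective_metrics()]).
#' @export
coverage_risk_curve <- function(scores, correct) {
  s <- score_values(scores)
  if (length(s) < 1) stop("need >= 1 sample", call. = FALSE)
  taus <- c(min(s) - 1, sort(unique(s)), max(s) + 1)
  out <- dplyr::bind_rows(lapply(taus, function(t) {
    selective_metrics(s, correct, t)
  }))
  class(out) <- c("coverage_risk_curve", class(out))
  out
}

#' Coverage-risk trade-off plot
#'
#' @param object A [coverage_risk_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_risk_curve <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$selective_risk))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$coverage,
                                   y = .data$selective_risk)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, NA)) +
    ggplot2::labs(x = "coverage", y = "selective risk",
                  title = "Coverage-risk curve") +
    ggplot2::theme_minimal()
}

new_threshold_policy <- function(strategy, target_level, tau,
                                 coverage, risk, calibration_set_id) {
  structure(
    list(strategy = strategy, target_level = target_level, tau = tau,
         achieved_calibration_coverage = coverage,
         achieved_calibration_risk = risk,
         calibration_set_id = calibration_set_id),
    class = "threshold_policy"
  )
}

#' @export
print.threshold_policy <- function(x, ...) {
  tau_txt <- if (identical(x$tau, "abstain_all")) "abstain_all" else
    sprintf("%.6g", x$tau)
  cat(sprintf("<threshold_policy> %s @ %.3g: tau = %s (calib coverage %.4f, risk %s)\n",
              x$strategy, x$target_level, tau_txt,
              x$achieved_calibration_coverage,
              if (is.na(x$achieved_calibration_risk)) "undefined" else
                sprintf("%.4f", x$achieved_calibration_risk)))
  invisible(x)
}

#' Fixed-coverage threshold from calibration scores
#'
#' Chooses the largest score value whose calibration coverage is at least
#' `target_coverage`; under heavy ties the achieved coverage may exceed the
#' nominal level. The threshold is derived from calibration data only and is
#' meant to be transferred unchanged to test data.
#'
#' @param calib_scores Calibration-set scores ([confidence_score()] result or
#'   numeric vector).
#' @param target_coverage Target coverage in (0, 1].
#' @param calib_correct Optional logical vector; when supplied the achieved
#'   calibration risk is recorded in the policy.
#' @param calibration_set_id Identifier recorded for audit.
#' @return A `threshold_policy`.
#' @export
threshold_for_coverage <- function(calib_scores, target_coverage,
                                   calib_correct = NULL,
                                   calibration_set_id = "") {
  s <- score_values(calib_scores)
  if (length(s) == 0) stop("empty calibration set", call. = FALSE)
  if (target_coverage <= 0 || target_coverage > 1) {
    stop("`target_coverage` must lie in (0, 1]", call. = FALSE)
  }
  cand <- sort(unique(s), decreasing = TRUE)
  cov <- vapply(cand, function(t) mean(s >= t), numeric(1))
  ok <- which(cov >= target_coverage)
  tau <- cand[ok[1]]  # the largest score reaching the target
  coverage <- cov[ok[1]]
  risk <- if (!is.null(calib_correct)) {
    selective_metrics(s, calib_correct, tau)$selective_risk
  } else {
    NA_real_
  }
  new_threshold_policy("fixed_coverage", target_coverage, tau, coverage,
                       risk, calibration_set_id)
}

#' Fixed-risk threshold from calibration scores
#'
#' Among candidate thresholds (the distinct calibration score values plus
#' sentinels), selects the one maximizing calibration coverage subject to a
#' calibration selective risk of at most `target_risk`. When no threshold is
#' feasible the sentinel `"abstain_all"` is returned (coverage 0).
#'
#' @inheritParams threshold_for_coverage
#' @param calib_correct Logical vector of calibration correctness.
#' @param target_risk Maximum admissible calibration selective risk in
#'   `[0, 1)`.
#' @return A `threshold_policy`.
#' @export
threshold_for_risk <- function(calib_scores, calib_correct, target_risk,
                               calibration_set_id = "") {
  s <- score_values(calib_scores)
  if (length(s) == 0) stop("empty calibration set", call. = FALSE)
  if (target_risk < 0 || target_risk >= 1) {
    stop("`target_risk` must lie in [0, 1)", call. = FALSE)
  }
  cand <- c(min(s) - 1, sort(unique(s)))
  best <- NULL
  for (t in cand) {
    m <- selective_metrics(s, calib_correct, t)
    # scanning upwards with >= keeps the largest tau among coverage ties
    if (!is.na(m$selective_risk) && m$selective_risk <= target_risk) {
      if (is.null(best) || m$coverage >= best$coverage) best <- m
    }
  }
  if (is.null(best)) {
    return(new_threshold_policy("fixed_risk", target_risk, "abstain_all",
                                0, NA_real_, calibration_set_id))
  }
  new_threshold_policy("fixed_risk", target_risk, best$tau, best$coverage,
                       best$selective_risk, calibration_set_id)
}

#' Apply a threshold policy to test scores
#'
#' @param policy A `threshold_policy`.
#' @param scores Test-set scores.
#' @param correct Logical test-set correctness.
#' @return A one-row tibble: strategy, target level, tau, test coverage and
#'   selective risk.
#' @export
evaluate_policy <- function(policy, scores, correct) {
  stopifnot(inherits(policy, "threshold_policy"))
  if (identical(policy$tau, "abstain_all")) {
    return(tibble::tibble(strategy = policy$strategy,
                          target_level = policy$target_level,
                          tau = NA_real_, coverage = 0,
                          selective_risk = NA_real_, n_answered = 0L))
  }
  m <- selective_metrics(scores, correct, policy$tau)
  tibble::tibble(strategy = policy$strategy,
                 target_level = policy$target_level,
                 tau = policy$tau, coverage = m$coverage,
                 selective_risk = m$selective_risk,
                 n_answered = m$n_answered)
}

#' Unknown- and known-class rejection rates at a threshold
#'
#' Fraction of each group whose score falls strictly below `tau` (the
#' complement of the `>= tau` selection rule).
#'
#' @param known_scores,unknown_scores Scores of known-class and
#'   unknown-class samples (non-empty).
#' @param tau Threshold.
#' @return A one-row tibble with `unknown_rejection` and `known_rejection`.
#' @export
rejection_rates <- function(known_scores, unknown_scores, tau) {
  k <- score_values(known_scores)
  u <- score_values(unknown_scores)
  if (length(k) == 0 || length(u) == 0) {
    stop("both score sets must be non-empty", call. = FALSE)
  }
  tibble::tibble(unknown_rejection = mean(u < tau),
                 known_rejection = mean(k < tau))
}

#' AUROC for unknown detection
#'
#' Probability that a randomly drawn unknown sample receives a lower
#' confidence score than a randomly drawn known sample, with ties counted as
#' 1/2 (the Mann-Whitney statistic with unknowns as the low-score
#' positives).
#'
#' @param known_scores,unknown_scores Non-empty score sets.
#' @return Scalar in `[0, 1]`.
#' @export
auroc_unknown <- function(known_scores, unknown_scores) {
  k <- score_values(known_scores)
  u <- score_values(unknown_scores)
  if (length(k) == 0 || length(u) == 0) {
    stop("both score sets must be non-empty", call. = FALSE)
  }
  r <- rank(c(k, u))  # midranks handle ties
  n_k <- length(k)
  n_u <- length(u)
  # U statistic for "known ranks above unknown"
  U <- sum(r[seq_len(n_k)]) - n_k * (n_k + 1) / 2
  U / (n_k * n_u)
}

#' AUPR for unknown detection
#'
#' Average precision of the ranking that flags low-score samples as unknown
#' (unknowns are the positive class), using step interpolation: the sum of
#' precision times recall increments, scanning thresholds from the most to
#' the least confident rejection. Ties are handled by grouping equal scores
#' into a single step.
#'
#' @inheritParams auroc_unknown
#' @return Scalar in (0, 1].
#' @export
aupr_unknown <- function(known_scores, unknown_scores) {
  k <- score_values(known_scores)
  u <- score_values(unknown_scores)
  if (length(k) == 0 || length(u) == 0) {
    stop("both score sets must be non-empty", call. = FALSE)
  }
  detector <- -c(k, u)  # larger detector value = more unknown-like
  positive <- c(rep(FALSE, length(k)), rep(TRUE, length(u)))
  o <- order(detector, decreasing = TRUE)
  detector <- detector[o]
  positive <- positive[o]
  n_pos <- sum(positive)
  tp <- cumsum(positive)
  fp <- cumsum(!positive)
  # keep only the last row of every tied-score block
  last <- c(detector[-1] != detector[-length(detector)], TRUE)
  tp <- tp[last]
  fp <- fp[last]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  d_recall <- diff(c(0, recall))
  sum(precision * d_recall)
}

#' False positive rate at 95% true positive rate
#'
#' The fraction of known-class samples flagged as unknown at the least
#' conservative threshold whose unknown true-positive rate is at least 0.95
#' (step function over achievable thresholds, no interpolation).
#'
#' @inheritParams auroc_unknown
#' @param tpr_target Required unknown detection rate (default 0.95).
#' @return Scalar in `[0, 1]`.
#' @export
fpr_at_95tpr <- function(known_scores, unknown_scores, tpr_target = 0.95) {
  k <- score_values(known_scores)
  u <- score_values(unknown_scores)
  if (length(k) == 0 || length(u) == 0) {
    stop("both score sets must be non-empty", call. = FALSE)
  }
  # flag "unknown" when score < tau; candidate taus are achievable cutpoints
  cand <- sort(unique(c(k, u, max(c(k, u)) + 1)))
  tpr <- vapply(cand, function(t) mean(u < t), numeric(1))
  fpr <- vapply(cand, function(t) mean(k < t), numeric(1))
  ok <- which(tpr >= tpr_target)
  min(fpr[ok])
}
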