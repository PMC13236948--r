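# logits whose T=1 softmax equals the given probability rows
logits_for <- function(p) log(p)

test_that("confidence scores match their closed forms", {
  K <- 5
  unif <- matrix(log(rep(1 / K, K)), 1)
  expect_equal(confidence_score(unif, method = "msp")$score, 1 / K)
  expect_equal(confidence_score(unif, method = "entropy")$score, 0,
               tolerance = 1e-12)
  expect_equal(confidence_score(unif, method = "margin")$score, 0)
  zero <- matrix(0, 1, K)
  expect_equal(confidence_score(zero, method = "energy")$score, log(K))

  hot <- logits_for(matrix(c(1 - 2e-9, 1e-9, 1e-9), 1))
  expect_equal(confidence_score(hot, method = "msp")$score, 1,
               tolerance = 1e-6)
  expect_equal(confidence_score(hot, method = "entropy")$score, 1,
               tolerance = 1e-6)
  expect_equal(confidence_score(hot, method = "margin")$score, 1,
               tolerance = 1e-6)

  p <- matrix(c(0.7, 0.2, 0.1), 1)
  z <- logits_for(p)
  expect_equal(confidence_score(z, method = "msp")$score, 0.7,
               tolerance = 1e-9)
  expect_equal(confidence_score(z, method = "margin")$score, 0.5,
               tolerance = 1e-9)
  h <- -sum(p * log(p))
  expect_equal(confidence_score(z, method = "entropy")$score, 1 - h / log(3),
               tolerance = 1e-9)
  expect_equal(confidence_score(z, method = "entropy")$score, 0.27018,
               tolerance = 1e-4)
})

test_that("score invariances hold", {
  set.seed(40)
  z <- matrix(stats::rnorm(60, sd = 2), 12, 5)
  # msp and margin ignore relabeling of non-top classes
  reorder_tail <- t(apply(z, 1, function(r) {
    top <- which.max(r)
    rest <- setdiff(seq_along(r), top)
    r[c(top, sample(rest))]
  }))
  for (m in c("msp", "margin")) {
    expect_equal(confidence_score(z, 1.3, m)$score,
                 confidence_score(reorder_tail, 1.3, m)$score,
                 tolerance = 1e-12)
  }
  # energy is shift-equivariant: z + c raises the score by c / T
  for (T in c(0.5, 2)) {
    e0 <- confidence_score(z, T, "energy")$score
    e1 <- confidence_score(z + 3, T, "energy")$score
    expect_equal(e1 - e0, rep(3 / T, 12), tolerance = 1e-9)
  }
})

test_that("selective metrics follow the >= tau selection rule", {
  s <- c(0.9, 0.8, 0.4, 0.2)
  ok <- c(TRUE, FALSE, TRUE, FALSE)
  m <- selective_metrics(s, ok, 0.5)
  expect_equal(m$coverage, 0.5)
  expect_equal(m$selective_risk, 0.5)
  # tau below all scores: full coverage, risk = overall error rate
  m_all <- selective_metrics(s, ok, 0)
  expect_equal(m_all$coverage, 1)
  expect_equal(m_all$selective_risk, 0.5)
  # tau above all scores: zero coverage, undefined risk
  m_none <- selective_metrics(s, ok, 2)
  expect_equal(m_none$coverage, 0)
  expect_true(is.na(m_none$selective_risk))
})

test_that("coverage-risk curves agree with pointwise recomputation", {
  set.seed(41)
  s <- round(stats::runif(40), 2)  # force ties
  ok <- stats::runif(40) < 0.6
  curve <- coverage_risk_curve(s, ok)
  for (i in seq_len(nrow(curve))) {
    m <- selective_metrics(s, ok, curve$tau[i])
    expect_equal(curve$coverage[i], m$coverage)
    expect_equal(curve$selective_risk[i], m$selective_risk)
  }
  expect_true(all(diff(curve$coverage) <= 0))
  expect_equal(curve$coverage[1], 1)
  expect_equal(curve$selective_risk[1], mean(!ok))

  # scores that rank perfectly: zero risk up to the accuracy
  s2 <- c(4, 3, 2, 1)
  ok2 <- c(TRUE, TRUE, FALSE, FALSE)
  c2 <- coverage_risk_curve(s2, ok2)
  expect_true(all(c2$selective_risk[c2$coverage <= 0.5 &
                                      c2$coverage > 0] == 0))
  # constant scores: only coverages 1 and 0 are achievable
  c3 <- coverage_risk_curve(rep(0.5, 6), rep(TRUE, 6))
  expect_setequal(unique(c3$coverage), c(0, 1))
})

test_that("fixed-coverage thresholds reach the target from calibration data", {
  s <- seq(0.1, 1.0, by = 0.1)
  pol <- threshold_for_coverage(s, 0.8)
  expect_equal(pol$tau, 0.3)
  expect_equal(pol$achieved_calibration_coverage, 0.8)
  pol_full <- threshold_for_coverage(s, 1.0)
  expect_equal(pol_full$tau, 0.1)
  expect_equal(pol_full$achieved_calibration_coverage, 1)

  # heavy ties: achieved coverage exceeds the nominal level
  s_tie <- c(rep(0.5, 7), 0.8, 0.9, 1.0)
  pol_tie <- threshold_for_coverage(s_tie, 0.5)
  expect_gt(pol_tie$achieved_calibration_coverage, 0.5)
  # scan oracle: the chosen tau is the largest with coverage >= target
  cands <- sort(unique(s_tie), decreasing = TRUE)
  covs <- vapply(cands, function(t) mean(s_tie >= t), numeric(1))
  expect_equal(pol_tie$tau, cands[which(covs >= 0.5)[1]])

  expect_error(threshold_for_coverage(numeric(0), 0.5), "empty")
})

test_that("fixed-risk thresholds equal the exhaustive scan", {
  s <- seq(0.05, 1, by = 0.05)
  pol <- threshold_for_risk(s, rep(TRUE, 20), 0.05)
  expect_equal(pol$tau, min(s))
  expect_equal(pol$achieved_calibration_coverage, 1)
  expect_equal(pol$achieved_calibration_risk, 0)

  pol_bad <- threshold_for_risk(s, rep(FALSE, 20), 0.10)
  expect_identical(pol_bad$tau, "abstain_all")
  expect_equal(pol_bad$achieved_calibration_coverage, 0)
  expect_equal(evaluate_policy(pol_bad, s, rep(TRUE, 20))$coverage, 0)

  set.seed(42)
  for (i in 1:20) {
    s <- round(stats::runif(20), 1)
    ok <- stats::runif(20) < 0.7
    target <- sample(c(0.05, 0.1, 0.15, 0.3), 1)
    pol <- threshold_for_risk(s, ok, target)
    oracle <- risk_threshold_oracle(s, ok, target)
    if (is.null(oracle)) {
      expect_identical(pol$tau, "abstain_all")
    } else {
      expect_equal(pol$achieved_calibration_coverage, oracle$coverage)
      expect_lte(pol$achieved_calibration_risk, target)
    }
  }
})

test_that("rejection rates count scores strictly below tau", {
  known <- c(0.9, 0.8, 0.7)
  unknown <- c(0.1, 0.2)
  expect_equal(
    as.numeric(rejection_rates(known, unknown, 0.05)),
    c(0, 0)
  )
  expect_equal(
    as.numeric(rejection_rates(known, unknown, 0.5)),
    c(1, 0)
  )
  inter_k <- c(0.1, 0.3, 0.5)
  inter_u <- c(0.2, 0.4, 0.6)
  rr <- rejection_rates(inter_k, inter_u, 0.45)
  expect_equal(rr$unknown_rejection, 2 / 3)
  expect_equal(rr$known_rejection, 2 / 3)
  expect_error(rejection_rates(numeric(0), 1, 0), "non-empty")
})

test_that("open-set metrics equal their brute-force oracles", {
  expect_equal(auroc_unknown(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(auroc_unknown(c(0.3, 0.7), c(0.3, 0.7)), 0.5)
  expect_equal(aupr_unknown(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(fpr_at_95tpr(c(0.9, 0.8), c(0.1, 0.2)), 0.0)
  expect_equal(fpr_at_95tpr(rep(0.5, 5), rep(0.5, 5)), 1.0)

  set.seed(43)
  for (i in 1:25) {
    nk <- sample(3:20, 1)
    nu <- sample(3:20, 1)
    known <- round(stats::runif(nk), 1)
    unknown <- round(stats::runif(nu, 0, 0.8), 1)
    expect_equal(auroc_unknown(known, unknown),
                 auroc_oracle(known, unknown), tolerance = 1e-12)
    expect_equal(aupr_unknown(known, unknown),
                 aupr_oracle(known, unknown), tolerance = 1e-12)
    expect_equal(fpr_at_95tpr(known, unknown),
                 fpr95_oracle(known, unknown), tolerance = 1e-12)
  }

  # with scores independent of status, AUPR approaches the prevalence
  set.seed(44)
  known <- stats::runif(4000)
  unknown <- stats::runif(1000)
  expect_lt(abs(aupr_unknown(known, unknown) - 0.2), 0.03)
})
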