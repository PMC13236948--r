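test_that("temperature scaling matches closed forms and limits", {
  z <- matrix(c(2, 0), 1)
  expect_equal(apply_temperature(z, 1), softmax(z), tolerance = 1e-12)
  expect_equal(as.numeric(apply_temperature(z, 2)),
               c(exp(1) / (exp(1) + 1), 1 / (exp(1) + 1)), tolerance = 1e-9)
  zm <- matrix(stats::rnorm(40, sd = 3), 8, 5)
  p_hot <- apply_temperature(zm, 1000)
  expect_lt(max(abs(p_hot - 1 / 5)), 1e-2)
  # argmax preserved at any temperature
  for (T in c(0.1, 1, 7)) {
    expect_equal(max.col(apply_temperature(zm, T), ties.method = "first"),
                 max.col(softmax(zm), ties.method = "first"))
  }
  expect_error(apply_temperature(zm, 0), "> 0")
})

test_that("temperature fitting recovers the generating temperature", {
  lc <- make_logit_cohort(20000, 8, 2.0, seed = 30)
  fit <- fit_temperature(lc$logits, lc$labels)
  expect_gt(fit$temperature, 1.9)
  expect_lt(fit$temperature, 2.1)
  expect_lte(fit$nll_at_fit, fit$nll_at_unit + 1e-12)
  # grid + local refinement against an independent fine grid search
  grid <- seq(1.5, 2.5, by = 1e-3)
  nlls <- vapply(grid, function(T) {
    fieldshift:::nll_at_temperature(lc$logits, lc$labels, T)
  }, numeric(1))
  expect_lt(abs(fit$temperature - grid[which.min(nlls)]), 2e-3)

  # self-consistency null: labels drawn at T = 1 give T_hat near 1
  null <- make_logit_cohort(20000, 8, 1.0, seed = 31)
  fit1 <- fit_temperature(null$logits, null$labels)
  expect_gt(fit1$temperature, 0.9)
  expect_lt(fit1$temperature, 1.1)

  tf <- tidy(fit)
  expect_equal(tf$estimate, fit$temperature)
  expect_named(glance(fit),
               c("temperature", "nll_at_fit", "nll_at_unit", "at_bound",
                 "calibration_set_id"))
})

test_that("degenerate calibration sets return a bound with a warning", {
  z <- matrix(0, 20, 3)
  z[, 1] <- 40  # all margins >= 20, labels all equal the argmax
  expect_warning(fit <- fit_temperature(z, rep(0L, 20)), "bound")
  expect_equal(fit$temperature, 0.01)
  expect_true(fit$at_bound)
})

test_that("ECE equals the brute-force binning oracle", {
  # all confident and correct
  p <- diag(4)[rep(1, 6), ]
  expect_equal(expected_calibration_error(p, rep(0L, 6)), 0)
  # single incorrect sample with confidence 0.8
  expect_equal(expected_calibration_error(matrix(c(0.8, 0.2), 1), 1L), 0.8)

  set.seed(32)
  for (i in 1:100) {
    K <- sample(2:6, 1)
    n <- sample(5:80, 1)
    nb <- sample(c(5L, 10L, 15L), 1)
    p <- random_prob_matrix(n, K)
    y <- sample(0:(K - 1), n, replace = TRUE)
    expect_equal(expected_calibration_error(p, y, nb), ece_oracle(p, y, nb),
                 tolerance = 1e-12)
  }
  expect_error(expected_calibration_error(matrix(1, 1, 1), 0L, 0), "n_bins")
})

test_that("Brier score matches its closed forms", {
  K <- 21
  expect_equal(brier_score(diag(K)[c(1, 5), ], c(0L, 4L)), 0)
  expect_equal(brier_score(diag(2)[c(1, 1), ], c(1L, 1L)), 2)
  unif <- matrix(1 / K, 3, K)
  expect_equal(brier_score(unif, c(0L, 7L, 20L)), 1 - 1 / K)
  # direct summation on a random instance
  set.seed(33)
  p <- random_prob_matrix(40, 5)
  y <- sample(0:4, 40, replace = TRUE)
  Y <- matrix(0, 40, 5)
  Y[cbind(1:40, y + 1)] <- 1
  expect_equal(brier_score(p, y), mean(rowSums((Y - p)^2)), tolerance = 1e-12)
})

test_that("reliability tables reproduce ECE and honor the binning rule", {
  set.seed(34)
  p <- random_prob_matrix(500, 4)
  y <- sample(0:3, 500, replace = TRUE)
  tab <- reliability_table(p, y)
  expect_equal(sum(tab$count), 500)
  expect_equal(fieldshift:::ece_from_table(tab),
               expected_calibration_error(p, y), tolerance = 1e-15)

  # all confidences inside one bin -> a single populated row
  p1 <- matrix(c(0.52, 0.48), 10, 2, byrow = TRUE)
  tab1 <- reliability_table(p1, rep(0L, 10))
  expect_equal(sum(tab1$count > 0), 1)
  # confidence 1.0 lands in the last (right-closed) bin
  tabe <- reliability_table(diag(2), 0:1, n_bins = 15)
  expect_equal(tabe$count[15], 2)

  # near-uniform confidences spread over the achievable [0.5, 1] bins
  conf <- stats::runif(6000, 0.5, 1)
  p2 <- cbind(conf, 1 - conf)
  tab2 <- reliability_table(p2, sample(0:1, 6000, replace = TRUE), 10)
  occupied <- tab2$count[tab2$lower >= 0.5]
  expect_true(all(abs(occupied - 1200) < 5 * sqrt(1200)))
})
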