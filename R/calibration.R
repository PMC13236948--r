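#' Temperature-scaled probabilities
#'
#' Row-wise softmax of `logits / T`. Temperature scaling preserves the
#' argmax of every row, so accuracy is unchanged for any `T > 0`; `T = 1`
#' recovers the plain softmax and large `T` approaches the uniform
#' distribution.
#'
#' @param logits Numeric matrix (n x K).
#' @param T Positive scalar temperature.
#' @return Probability matrix (n x K).
#' @examples
#' apply_temperature(matrix(c(2, 0), 1), T = 2)
#' @export
apply_temperature <- function(logits, T) {
  if (!is.finite(T) || T <= 0) stop("`T` must be > 0", call. = FALSE)
  softmax(as.matrix(logits) / T)
}

#' Fit a scalar temperature by NLL minimization
#'
#' Finds the temperature minimizing the negative log-likelihood of the
#' calibration labels under `softmax(logits / T)`, via bounded 1-D Brent
#' minimization over `log T` within `bounds` (a single bounded parameter has
#' the same optimum under Brent as under quasi-Newton search). A coarse grid
#' first brackets the optimum; when the NLL decreases monotonically to a
#' bound, the bound is returned with `at_bound = TRUE` and a warning.
#'
#' @param logits Numeric matrix (n x K) from the calibration split.
#' @param labels 0-based integer labels.
#' @param bounds Length-2 positive vector of admissible temperatures
#'   (default `c(0.01, 1000)`).
#' @param tol Absolute tolerance on the fitted temperature (default 1e-6).
#' @param calibration_set_id Optional identifier recorded in the fit.
#' @return An object of class `temperature_fit`: list with `temperature`,
#'   `nll_at_fit`, `nll_at_unit` (NLL at T = 1), `at_bound`,
#'   `calibration_set_id`, and `optimizer_trace` (tibble of evaluated
#'   (T, NLL) pairs).
#' @examples
#' lc <- make_logit_cohort(2000, K = 6, true_temperature = 2, seed = 3)
#' fit_temperature(lc$logits, lc$labels)$temperature
#' @export
fit_temperature <- function(logits, labels, bounds = c(0.01, 1000),
                            tol = 1e-6, calibration_set_id = "") {
  logits <- as.matrix(logits)
  if (nrow(logits) < 2) stop("need >= 2 calibration samples", call. = FALSE)
  labels <- assert_labels(labels, nrow(logits), ncol(logits))
  if (length(bounds) != 2 || any(bounds <= 0) || bounds[1] >= bounds[2]) {
    stop("`bounds` must be increasing positive values", call. = FALSE)
  }
  trace_env <- new.env()
  trace_env$rows <- list()
  nll <- function(logT) {
    T <- exp(logT)
    val <- nll_at_temperature(logits, labels, T)
    trace_env$rows[[length(trace_env$rows) + 1L]] <-
      tibble::tibble(temperature = T, nll = val)
    val
  }
  lo <- log(bounds[1])
  hi <- log(bounds[2])
  grid <- seq(lo, hi, length.out = 41)
  vals <- vapply(grid, nll, numeric(1))
  i <- which.min(vals)
  at_bound <- FALSE
  if (i == 1L || i == length(grid)) {
    at_bound <- TRUE
    T_star <- exp(grid[i])
    warning("NLL is monotone towards a temperature bound; returning the bound")
  } else {
    opt <- stats::optimize(nll, lower = grid[i - 1L], upper = grid[i + 1L],
                           tol = tol / max(1, exp(grid[i])))
    T_star <- exp(opt$minimum)
  }
  nll_fit <- nll_at_temperature(logits, labels, T_star)
  nll_unit <- nll_at_temperature(logits, labels, 1)
  # the fit can never be worse than T = 1 when 1 is admissible
  if (bounds[1] <= 1 && 1 <= bounds[2] && nll_unit < nll_fit) {
    T_star <- 1
    nll_fit <- nll_unit
  }
  structure(
    list(temperature = T_star, nll_at_fit = nll_fit, nll_at_unit = nll_unit,
         at_bound = at_bound, calibration_set_id = calibration_set_id,
         optimizer_trace = dplyr::bind_rows(trace_env$rows)),
    class = "temperature_fit"
  )
}

nll_at_temperature <- function(logits, labels, T) {
  z <- logits / T
  lse <- row_logsumexp(z)
  z_true <- z[cbind(seq_len(nrow(z)), labels + 1L)]
  mean(lse - z_true)
}

#' @export
print.temperature_fit <- function(x, ...) {
  cat(sprintf("<temperature_fit> T = %.4f (NLL %.4f vs %.4f at T = 1)%s\n",
              x$temperature, x$nll_at_fit, x$nll_at_unit,
              if (x$at_bound) " [at bound]" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_temperature
#' @param x A `temperature_fit`.
#' @param ... Unused.
#' @export
tidy.temperature_fit <- function(x, ...) {
  tibble::tibble(term = "temperature", estimate = x$temperature,
                 at_bound = x$at_bound)
}

#' @rdname fit_temperature
#' @export
glance.temperature_fit <- function(x, ...) {
  tibble::tibble(temperature = x$temperature, nll_at_fit = x$nll_at_fit,
                 nll_at_unit = x$nll_at_unit, at_bound = x$at_bound,
                 calibration_set_id = x$calibration_set_id)
}

# Shared binning rule: equal-width bins on [0, 1], right-open except the
# last bin, which is right-closed so confidence 1 lands in bin n_bins.
confidence_bin <- function(confidence, n_bins) {
  pmin(floor(confidence * n_bins) + 1L, n_bins)
}

#' Expected calibration error
#'
#' Partitions predicted confidence (the max row probability) into `n_bins`
#' equal-width bins and returns the bin-count-weighted mean absolute gap
#' between mean confidence and empirical accuracy. Empty bins contribute 0.
#'
#' @param probabilities Matrix with simplex-valued rows.
#' @param labels 0-based integer labels.
#' @param n_bins Number of equal-width bins (default 15).
#' @return Scalar in `[0, 1]`.
#' @export
expected_calibration_error <- function(probabilities, labels, n_bins = 15L) {
  if (n_bins < 1) stop("`n_bins` must be >= 1", call. = FALSE)
  tab <- reliability_table(probabilities, labels, n_bins)
  ece_from_table(tab)
}

ece_from_table <- function(tab) {
  n <- sum(tab$count)
  keep <- tab$count > 0
  sum(tab$count[keep] / n *
        abs(tab$accuracy[keep] - tab$mean_confidence[keep]))
}

#' Multiclass Brier score
#'
#' Mean over samples of the squared error between the probability vector and
#' the one-hot label, summed over classes. Bounded in `[0, 2]`; a uniform
#' prediction over K classes scores `1 - 1/K`.
#'
#' @inheritParams expected_calibration_error
#' @return Scalar in `[0, 2]`.
#' @export
brier_score <- function(probabilities, labels) {
  assert_prob_matrix(probabilities)
  labels <- assert_labels(labels, nrow(probabilities), ncol(probabilities))
  Y <- matrix(0, nrow(probabilities), ncol(probabilities))
  Y[cbind(seq_len(nrow(Y)), labels + 1L)] <- 1
  mean(rowSums((Y - probabilities)^2))
}

#' Reliability table
#'
#' Per-bin statistics of the reliability diagram: sample count, mean
#' predicted confidence, and empirical accuracy in each equal-width
#' confidence bin. Recomputing the calibration-gap sum from the table
#' reproduces [expected_calibration_error()] exactly.
#'
#' @inheritParams expected_calibration_error
#' @return A tibble of class `reliability_table` with columns `bin`,
#'   `lower`, `upper`, `count`, `mean_confidence`, `accuracy`.
#' @export
reliability_table <- function(probabilities, labels, n_bins = 15L) {
  assert_prob_matrix(probabilities)
  labels <- assert_labels(labels, nrow(probabilities), ncol(probabilities))
  if (n_bins < 1) stop("`n_bins` must be >= 1", call. = FALSE)
  confidence <- row_max(probabilities)
  predicted <- max.col(probabilities, ties.method = "first") - 1L
  correct <- predicted == labels
  bin_idx <- confidence_bin(confidence, n_bins)
  counts <- vapply(seq_len(n_bins), function(b) sum(bin_idx == b),
                   integer(1))
  mean_conf <- vapply(seq_len(n_bins), function(b) {
    if (any(bin_idx == b)) mean(confidence[bin_idx == b]) else NA_real_
  }, numeric(1))
  acc <- vapply(seq_len(n_bins), function(b) {
    if (any(bin_idx == b)) mean(correct[bin_idx == b]) else NA_real_
  }, numeric(1))
  tab <- tibble::tibble(
    bin = seq_len(n_bins),
    lower = (seq_len(n_bins) - 1) / n_bins,
    upper = seq_len(n_bins) / n_bins,
    count = counts,
    mean_confidence = mean_conf,
    accuracy = acc
  )
  class(tab) <- c("reliability_table", class(tab))
  tab
}

#' Reliability diagram
#'
#' Plots empirical accuracy against mean predicted confidence per bin, with
#' the identity line marking perfect calibration and bar height showing the
#' sample share per bin.
#'
#' @param object A [reliability_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.reliability_table <- function(object, ...) {
  df <- dplyr::filter(object, .data$count > 0)
  n <- sum(object$count)
  ggplot2::ggplot(df) +
    ggplot2::geom_col(
      ggplot2::aes(x = (.data$lower + .data$upper) / 2, y = .data$count / n),
      width = 1 / nrow(object), fill = "grey85", colour = "grey60"
    ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(x = .data$mean_confidence,
                                     y = .data$accuracy)) +
    ggplot2::geom_line(ggplot2::aes(x = .data$mean_confidence,
                                    y = .data$accuracy)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "mean predicted confidence", y = "empirical accuracy",
                  title = "Reliability diagram") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
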