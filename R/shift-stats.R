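#' Exact two-sided Wilcoxon signed-rank test
#'
#' Shared signed-rank machinery for the descriptor shift tests and the
#' across-repeat paired comparisons. Zero differences are dropped (the
#' standard signed-rank convention). For untied absolute differences the
#' exact null distribution of the rank sum is used (via [stats::psignrank()]);
#' with midrank ties the full `2^n` sign enumeration is used for `n <= 12`
#' and a tie-corrected normal approximation (flagged in the result)
#' otherwise. The two-sided p-value is `min(1, 2 * min(P(W <= w),
#' P(W >= w)))`.
#'
#' @param differences Numeric vector of paired differences.
#' @return A list with `statistic` (positive-rank sum `W`), `n_effective`,
#'   `p_value`, and `method` (`"exact"`, `"exact_enumeration"`, or
#'   `"normal_approx"`).
#' @export
exact_signed_rank <- function(differences) {
  d <- differences[differences != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, n_effective = 0L, p_value = 1,
                method = "exact"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  has_ties <- anyDuplicated(abs(d)) > 0
  if (!has_ties) {
    # untied ranks are integers, so W is an integer rank sum
    p_le <- stats::psignrank(W, n)
    p_ge <- 1 - stats::psignrank(W - 1L, n)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = W, n_effective = n, p_value = p,
                method = "exact"))
  }
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    w_all <- as.numeric(signs %*% r)
    p_le <- mean(w_all <= W + 1e-9)
    p_ge <- mean(w_all >= W - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(statistic = W, n_effective = n,
                p_value = p, method = "exact_enumeration"))
  }
  # tie-corrected normal approximation
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (W - mu) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = W, n_effective = n, p_value = p,
       method = "normal_approx")
}

#' Paired class-level shift test for one descriptor
#'
#' Quantifies the paired two-domain difference across classes: the mean
#' target-minus-source delta, the paired Cohen's d (`mean(diff) / sd(diff)`,
#' with the n - 1 standard deviation), and the exact two-sided signed-rank
#' p-value from [exact_signed_rank()]. With 21 all-positive untied paired
#' differences, the attainable floor is `2 / 2^21 = 9.54e-7`.
#'
#' @param source_class_means,target_class_means Numeric vectors of per-class
#'   descriptor means, paired by class, length >= 5.
#' @return A one-row tibble with `delta`, `cohens_d`, `p_raw`, and `method`.
#' @export
paired_shift_test <- function(source_class_means, target_class_means) {
  if (length(source_class_means) != length(target_class_means)) {
    stop("class-mean vectors must be paired (equal length)", call. = FALSE)
  }
  if (length(source_class_means) < 5) {
    stop("need >= 5 paired classes", call. = FALSE)
  }
  d <- target_class_means - source_class_means
  s <- stats::sd(d)
  if (s == 0) {
    warning("zero variance of paired differences; Cohen's d is infinite")
    cohens_d <- sign(mean(d)) * Inf
  } else {
    cohens_d <- mean(d) / s
  }
  wt <- exact_signed_rank(d)
  tibble::tibble(delta = mean(d), cohens_d = cohens_d,
                 p_raw = wt$p_value, method = wt$method)
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, m * p)` for a family of `m` tests.
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @param m Family size; must be at least `length(p_values)`.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (m < length(p_values)) {
    stop("`m` must be >= the number of tests", call. = FALSE)
  }
  pmin(1, m * p_values)
}

#' Per-(class, domain) descriptor means
#'
#' Averages image-level descriptor values within each class and domain;
#' classes missing from either domain are dropped with a warning since the
#' paired test needs both sides.
#'
#' @param descriptors Tibble from [cohort_descriptors()] (columns `label`,
#'   `domain`, plus descriptor columns).
#' @return Tibble with one row per (label, domain) and the mean of every
#'   descriptor column.
#' @export
class_domain_aggregate <- function(descriptors) {
  stopifnot(all(c("label", "domain") %in% names(descriptors)))
  cols <- intersect(descriptor_names, names(descriptors))
  agg <- descriptors |>
    dplyr::group_by(.data$label, .data$domain) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(cols), mean),
                     .groups = "drop")
  counts <- table(agg$label)
  incomplete <- names(counts)[counts < 2]
  if (length(incomplete) > 0) {
    warning(sprintf("classes missing in one domain excluded: %s",
                    paste(incomplete, collapse = ", ")))
    agg <- agg[!(agg$label %in% as.integer(incomplete)), ]
  }
  agg
}

#' Descriptor-level domain-shift report
#'
#' Runs the paired class-level shift test for every descriptor, applies the
#' Bonferroni correction over the descriptor family, and flags significance
#' at `alpha`.
#'
#' @param descriptors Image-level descriptor tibble
#'   ([cohort_descriptors()]).
#' @param alpha Familywise significance level (default 0.05).
#' @return A tibble of class `shift_report` with one row per descriptor:
#'   `metric`, `delta`, `cohens_d`, `p_raw`, `p_bonferroni`,
#'   `significant`, `method`.
#' @export
shift_statistics <- function(descriptors, alpha = 0.05) {
  agg <- class_domain_aggregate(descriptors)
  cols <- intersect(descriptor_names, names(agg))
  src <- agg[agg$domain == "source", ]
  tgt <- agg[agg$domain == "target", ]
  src <- src[order(src$label), ]
  tgt <- tgt[order(tgt$label), ]
  stopifnot(identical(src$label, tgt$label))
  rows <- lapply(cols, function(metric) {
    res <- paired_shift_test(src[[metric]], tgt[[metric]])
    dplyr::bind_cols(tibble::tibble(metric = metric), res)
  })
  out <- dplyr::bind_rows(rows)
  out$p_bonferroni <- bonferroni_adjust(out$p_raw, m = length(cols))
  out$significant <- out$p_bonferroni < alpha
  out <- out[order(-abs(out$cohens_d)), ]
  class(out) <- c("shift_report", class(out))
  out
}

#' Effect-size overview of a shift report
#'
#' @param object A [shift_statistics()] result.
#' @param ... Unused.
#' @return A ggplot object (descriptors ordered by |Cohen's d|, significance
#'   after Bonferroni shown by fill).
#' @export
autoplot.shift_report <- function(object, ...) {
  df <- dplyr::mutate(object,
                      metric = stats::reorder(.data$metric,
                                              abs(.data$cohens_d)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$cohens_d,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "paired Cohen's d",
                  fill = "Bonferroni\nsignificant",
                  title = "Descriptor-level domain shift") +
    ggplot2::theme_minimal()
}

#' Border activation ratio of a heatmap
#'
#' Fraction of total heatmap mass falling within the outer `strip_fraction`
#' of the width and height on each side - a proxy for background-directed
#' attention in saliency maps. A uniform 10 x 10 map with the default strip
#' scores 0.64 (64 of 100 pixels lie in the strip).
#'
#' @param heatmap Non-negative 2-D numeric matrix with positive total mass.
#' @param strip_fraction Border width per side as a fraction of each
#'   dimension (default 0.2).
#' @return Scalar in `[0, 1]`.
#' @export
border_mass_ratio <- function(heatmap, strip_fraction = 0.2) {
  heatmap <- as.matrix(heatmap)
  if (any(heatmap < 0) || any(!is.finite(heatmap))) {
    stop("`heatmap` must be non-negative and finite", call. = FALSE)
  }
  total <- sum(heatmap)
  if (total <= 0) stop("`heatmap` total mass must be > 0", call. = FALSE)
  mask <- border_mask(nrow(heatmap), ncol(heatmap), strip_fraction)
  sum(heatmap[mask]) / total
}
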