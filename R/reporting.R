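#' Run configuration for the evaluation protocol
#'
#' Collects every protocol constant so it can be serialized verbatim into
#' reports: the score methods, the nominal coverage ladder (90-50%), the
#' target-risk ladder (5-15%), the calibration fraction, the repeat seeds,
#' and the reliability-diagram bin count.
#'
#' @param score_methods Character subset of
#'   `c("msp", "entropy", "margin", "energy")`.
#' @param coverage_targets Nominal coverage levels for fixed-coverage
#'   thresholding.
#' @param risk_targets Maximum selective-risk levels for fixed-risk
#'   thresholding.
#' @param calib_fraction Grouped field-calibration fraction (default 0.10).
#' @param n_bins Reliability bins (default 15).
#' @param repeats Number of repeated grouped splits (default 10).
#' @param base_seed First repeat seed (default 42; repeats use
#'   `base_seed ... base_seed + repeats - 1`).
#' @param hyper [head_hyper()] used for probe training.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(score_methods = c("msp", "entropy", "margin",
                                         "energy"),
                       coverage_targets = c(0.9, 0.8, 0.7, 0.6, 0.5),
                       risk_targets = c(0.05, 0.10, 0.15),
                       calib_fraction = 0.10,
                       n_bins = 15L,
                       repeats = 10L,
                       base_seed = 42L,
                       hyper = head_hyper()) {
  score_methods <- match.arg(score_methods,
                             c("msp", "entropy", "margin", "energy"),
                             several.ok = TRUE)
  structure(list(score_methods = score_methods,
                 coverage_targets = coverage_targets,
                 risk_targets = risk_targets,
                 calib_fraction = calib_fraction,
                 n_bins = as.integer(n_bins),
                 repeats = as.integer(repeats),
                 base_seed = as.integer(base_seed),
                 hyper = hyper),
            class = "run_config")
}

# Partition a feature cohort into the roles the protocol needs. The probe is
# trained on the stratified source split; the unknown pool is never eligible
# for any fitting role.
protocol_partitions <- function(cohort, split_seed = 42L) {
  m <- cohort$manifest
  src_idx <- which(m$domain == "source")
  split <- stratified_source_split(m$label[src_idx], seed = split_seed)
  # `split` is arranged by index, so its rows align with src_idx
  roles <- rep(NA_character_, nrow(m))
  roles[src_idx] <- split$role
  list(
    train = which(roles == "train"),
    val = which(roles == "val"),
    test = which(roles == "test"),
    target_known = which(m$domain == "target" & m$known_flag),
    unknown = which(!m$known_flag)
  )
}

#' Evaluate one calibration setting end to end
#'
#' Runs the full protocol on a synthetic feature cohort: trains a linear
#' probe on the stratified source training split, fits the temperature and
#' selective-prediction thresholds on the setting's calibration data, and
#' evaluates accuracy, calibration, selective prediction, and open-set
#' rejection on held-out data. Under setting `"A"` the calibration set is
#' the source validation split and the whole target known set is the test
#' set; under setting `"B"` a grouped parent-disjoint split carves a
#' `calib_fraction` field-calibration subset out of the target known set.
#' The unknown pool never enters any fitting step (asserted), and
#' calibration/test disjointness is verified before fitting.
#'
#' @param cohort A [make_feature_cohort()] result.
#' @param setting `"A"` (source-only calibration) or `"B"` (grouped field
#'   calibration).
#' @param config A [run_config()].
#' @param split_seed Seed for the source split and (setting B) the grouped
#'   calibration split.
#' @param head Optionally, a pre-trained `linear_head` (reused across
#'   repeated splits, since the probe does not depend on the
#'   calibration split).
#' @return An object of class `setting_report`: list of tibbles
#'   `classification`, `calibration`, `selective`, `openset`, plus
#'   `temperature_fit`, `setting`, `seeds`, and `config`.
#' @export
run_setting <- function(cohort, setting = c("A", "B"), config = run_config(),
                        split_seed = 42L, head = NULL) {
  setting <- match.arg(setting)
  stopifnot(inherits(cohort, "feature_cohort"))
  parts <- protocol_partitions(cohort, split_seed = split_seed)
  m <- cohort$manifest

  if (is.null(head)) {
    head <- train_linear_head(
      cohort$features[parts$train, , drop = FALSE], m$label[parts$train],
      cohort$features[parts$val, , drop = FALSE], m$label[parts$val],
      n_classes = cohort$config$n_known_classes,
      hyper = config$hyper, seed = split_seed
    )
  }

  if (setting == "A") {
    calib_idx <- parts$val
    field_test_idx <- parts$target_known
    calib_id <- "source_val"
  } else {
    tm <- m[parts$target_known, c("sample_id", "parent_id", "label")]
    gsplit <- grouped_calibration_split(tm, config$calib_fraction,
                                        seed = split_seed)
    assert_parent_disjoint(gsplit)
    calib_idx <- parts$target_known[gsplit$role == "field_calib"]
    field_test_idx <- parts$target_known[gsplit$role == "field_test"]
    calib_id <- sprintf("field_calib_seed%d", split_seed)
  }

  # leakage guards: calibration, test, and unknown roles must be disjoint
  if (length(intersect(calib_idx, field_test_idx)) > 0) {
    stop("leakage: calibration samples appear in the test set",
         call. = FALSE)
  }
  fitting_idx <- c(parts$train, parts$val, calib_idx)
  if (any(parts$unknown %in% fitting_idx)) {
    stop("leakage: unknown samples entered a fitting role", call. = FALSE)
  }

  logits_of <- function(idx) head_logits(head, cohort$features[idx, ,
                                                               drop = FALSE])
  z_calib <- logits_of(calib_idx)
  z_test <- logits_of(field_test_idx)
  z_in <- logits_of(parts$test)
  z_unk <- if (length(parts$unknown) > 0) logits_of(parts$unknown) else NULL

  tfit <- fit_temperature(z_calib, m$label[calib_idx],
                          calibration_set_id = calib_id)
  T_star <- tfit$temperature

  y_test <- m$label[field_test_idx]
  y_in <- m$label[parts$test]
  pred_test <- max.col(z_test, ties.method = "first") - 1L
  pred_in <- max.col(z_in, ties.method = "first") - 1L
  correct_test <- pred_test == y_test
  p_raw <- softmax(z_test)
  p_cal <- apply_temperature(z_test, T_star)
  # argmax preservation check (accuracy invariance under scaling)
  stopifnot(all(max.col(p_cal, ties.method = "first") - 1L == pred_test))

  classification <- tibble::tibble(
    dataset = c("source_test", "target_test"),
    accuracy = c(mean(pred_in == y_in), mean(correct_test)),
    macro_f1 = c(macro_f1(pred_in, y_in, cohort$config$n_known_classes),
                 macro_f1(pred_test, y_test, cohort$config$n_known_classes)),
    mean_pmax = c(mean(row_max(softmax(z_in))),
                  mean(row_max(p_raw)))
  )

  calibration <- tibble::tibble(
    setting = setting,
    temperature = T_star,
    ece_raw = expected_calibration_error(p_raw, y_test, config$n_bins),
    ece_calibrated = expected_calibration_error(p_cal, y_test,
                                                config$n_bins),
    brier_raw = brier_score(p_raw, y_test),
    brier_calibrated = brier_score(p_cal, y_test),
    mean_pmax_raw = mean(row_max(p_raw)),
    mean_pmax_calibrated = mean(row_max(p_cal))
  )

  y_calib <- m$label[calib_idx]
  pred_calib <- max.col(z_calib, ties.method = "first") - 1L
  correct_calib <- pred_calib == y_calib

  selective_rows <- list()
  openset_rows <- list()
  for (method in config$score_methods) {
    s_calib <- confidence_score(z_calib, T_star, method)
    s_test <- confidence_score(z_test, T_star, method)
    for (target in config$coverage_targets) {
      pol <- threshold_for_coverage(s_calib, target, correct_calib, calib_id)
      row <- evaluate_policy(pol, s_test, correct_test)
      row$method <- method
      if (!is.null(z_unk)) {
        s_unk <- confidence_score(z_unk, T_star, method)
        rr <- rejection_rates(s_test, s_unk, pol$tau)
        row <- dplyr::bind_cols(row, rr)
      }
      selective_rows[[length(selective_rows) + 1L]] <- row
    }
    for (target in config$risk_targets) {
      pol <- threshold_for_risk(s_calib, correct_calib, target, calib_id)
      row <- evaluate_policy(pol, s_test, correct_test)
      row$method <- method
      selective_rows[[length(selective_rows) + 1L]] <- row
    }
    if (!is.null(z_unk)) {
      s_unk <- confidence_score(z_unk, T_star, method)
      openset_rows[[length(openset_rows) + 1L]] <- tibble::tibble(
        method = method,
        auroc = auroc_unknown(s_test, s_unk),
        aupr_unknown = aupr_unknown(s_test, s_unk),
        fpr95 = fpr_at_95tpr(s_test, s_unk)
      )
    }
  }

  structure(
    list(
      classification = classification,
      calibration = calibration,
      selective = dplyr::bind_rows(selective_rows),
      openset = dplyr::bind_rows(openset_rows),
      temperature_fit = tfit,
      head = head,
      setting = setting,
      split_seed = split_seed,
      n_calib = length(calib_idx),
      n_test = length(field_test_idx),
      n_unknown = length(parts$unknown),
      unknown_in_fitting = 0L,
      config = config
    ),
    class = "setting_report"
  )
}

macro_f1 <- function(pred, truth, K) {
  f1 <- vapply(seq_len(K) - 1L, function(k) {
    tp <- sum(pred == k & truth == k)
    fp <- sum(pred == k & truth != k)
    fn <- sum(pred != k & truth == k)
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1[vapply(seq_len(K) - 1L, function(k) any(truth == k), logical(1))])
}

#' @export
print.setting_report <- function(x, ...) {
  cat(sprintf("<setting_report> setting %s (split seed %d)\n", x$setting,
              x$split_seed))
  cat(sprintf("  T = %.4f | calib n = %d, test n = %d, unknown n = %d\n",
              x$temperature_fit$temperature, x$n_calib, x$n_test,
              x$n_unknown))
  cat(sprintf("  target accuracy %.4f, ECE %.4f -> %.4f\n",
              x$classification$accuracy[2], x$calibration$ece_raw,
              x$calibration$ece_calibrated))
  invisible(x)
}

#' @rdname run_setting
#' @param x,object A `setting_report`.
#' @param ... Unused.
#' @export
glance.setting_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(setting = x$setting, split_seed = x$split_seed),
    x$calibration[, -1],
    tibble::tibble(accuracy_source = x$classification$accuracy[1],
                   accuracy_target = x$classification$accuracy[2])
  )
}

#' Repeat the grouped calibration split and summarize split-sensitive metrics
#'
#' Re-runs setting B once per seed (default 42-51): each repeat redraws the
#' grouped parent-disjoint calibration split, refits the temperature and all
#' thresholds, and recomputes the metric battery. The probe is trained once,
#' since it does not depend on the calibration split. Quantities are
#' summarized by mean, n - 1 standard deviation, and t-based 95% confidence
#' interval.
#'
#' @param cohort A [make_feature_cohort()] result.
#' @param config A [run_config()].
#' @param seeds Integer vector of distinct repeat seeds; defaults to
#'   `base_seed ... base_seed + repeats - 1` from `config`.
#' @return An object of class `repeat_summary`: list with `summary` (tibble:
#'   quantity, mean, sd, ci95_low, ci95_high, n), `per_repeat` (long tibble
#'   of raw values), and `reports` (the per-seed `setting_report`s).
#' @export
run_repeats <- function(cohort, config = run_config(), seeds = NULL) {
  seeds <- seeds %||% (config$base_seed + seq_len(config$repeats) - 1L)
  if (length(seeds) < 2) stop("need >= 2 repeats", call. = FALSE)
  if (anyDuplicated(seeds)) stop("repeat seeds must be distinct",
                                 call. = FALSE)
  head <- NULL
  reports <- vector("list", length(seeds))
  rows <- list()
  for (i in seq_along(seeds)) {
    rep_i <- run_setting(cohort, "B", config, split_seed = seeds[i],
                         head = head)
    head <- rep_i$head
    reports[[i]] <- rep_i
    sel80 <- rep_i$selective[rep_i$selective$method == "msp" &
                               rep_i$selective$strategy == "fixed_coverage" &
                               rep_i$selective$target_level == 0.8, ]
    risk10 <- rep_i$selective[rep_i$selective$method == "msp" &
                                rep_i$selective$strategy == "fixed_risk" &
                                rep_i$selective$target_level == 0.10, ]
    msp_open <- rep_i$openset[rep_i$openset$method == "msp", ]
    rows[[i]] <- tibble::tibble(
      seed = seeds[i],
      temperature = rep_i$temperature_fit$temperature,
      accuracy = rep_i$classification$accuracy[2],
      ece_raw = rep_i$calibration$ece_raw,
      ece_calibrated = rep_i$calibration$ece_calibrated,
      brier_calibrated = rep_i$calibration$brier_calibrated,
      coverage_at_80 = sel80$coverage,
      risk_at_80 = sel80$selective_risk,
      coverage_at_risk10 = risk10$coverage,
      auroc_unknown = if (nrow(msp_open) > 0) msp_open$auroc else NA_real_
    )
  }
  per_repeat <- dplyr::bind_rows(rows)
  long <- tidyr::pivot_longer(per_repeat, -"seed", names_to = "quantity")
  summary <- long |>
    dplyr::group_by(.data$quantity) |>
    dplyr::summarise(ci = list(summarize_ci(.data$value)), .groups = "drop") |>
    tidyr::unnest("ci")
  structure(list(summary = summary, per_repeat = per_repeat,
                 reports = reports, seeds = seeds, config = config),
            class = "repeat_summary")
}

#' @export
print.repeat_summary <- function(x, ...) {
  cat(sprintf("<repeat_summary> %d repeats (seeds %s)\n", length(x$seeds),
              paste(range(x$seeds), collapse = "-")))
  print(x$summary)
  invisible(x)
}

#' @rdname run_repeats
#' @param x,object A `repeat_summary`.
#' @param ... Unused.
#' @export
tidy.repeat_summary <- function(x, ...) x$summary

#' Mean, SD, and t-based 95% confidence interval
#'
#' `mean +/- t(0.975, n - 1) * sd / sqrt(n)`. The t interval is conservative
#' at small repeat counts.
#'
#' @param values Numeric vector, length >= 2.
#' @return One-row tibble: `mean`, `sd`, `ci95_low`, `ci95_high`, `n`.
#' @export
summarize_ci <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need >= 2 values", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  half <- stats::qt(0.975, n - 1) * s / sqrt(n)
  tibble::tibble(mean = m, sd = s, ci95_low = m - half, ci95_high = m + half,
                 n = n)
}

#' Paired comparison across repeated splits
#'
#' Exact two-sided Wilcoxon signed-rank p-value for paired per-repeat values
#' (each split seed is one paired observation); shares the signed-rank
#' implementation with the descriptor shift tests. All-zero differences give
#' p = 1.
#'
#' @param values_a,values_b Equal-length numeric vectors, paired by seed.
#' @return A one-row tibble with `statistic`, `p_value`, `method`.
#' @export
paired_comparison <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("paired vectors must have equal length", call. = FALSE)
  }
  res <- exact_signed_rank(values_a - values_b)
  tibble::tibble(statistic = res$statistic, p_value = res$p_value,
                 method = res$method)
}
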