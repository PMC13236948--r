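#' Generate a synthetic two-domain feature cohort
#'
#' Draws per-sample feature vectors with the statistical structure a frozen
#' encoder would produce in a controlled-to-field study. Source samples for
#' class k come from \eqn{N(\mu_k, I)}; target known samples from
#' \eqn{N(\mu_k + \delta_k, c \cdot I)} where \eqn{\|\delta_k\|} equals
#' `shift_mean` and `c = shift_cov_scale`; unknown samples come from extra
#' Gaussians whose means lie well outside the known-class dispersion radius
#' (at 2.2x the class-mean norm), so the open-set task is well posed but not
#' trivial. Shift directions \eqn{\delta_k} are drawn once per cohort and are
#' not shared across classes.
#'
#' Every target sample (known or unknown) carries a non-empty `parent_id`;
#' consecutive crops within a class share a parent when
#' `crops_per_parent > 1`.
#'
#' @param config A [cohort_config()].
#' @return An object of class `feature_cohort`: a list with
#'   * `features`: numeric matrix (n_samples x feature_dim),
#'   * `manifest`: tibble with `sample_id`, `parent_id`, `label` (0-based,
#'     -1 for unknown), `domain` (`"source"`/`"target"`), `known_flag`,
#'   * `class_means`, `shift_directions`: the generating geometry,
#'   * `config`: the input configuration.
#' @examples
#' cohort <- make_feature_cohort(cohort_config(
#'   n_known_classes = 3, n_unknown_classes = 1,
#'   samples_per_class_source = 20, samples_per_class_target = 10,
#'   unknown_pool_size = 10, feature_dim = 4, seed = 1))
#' table(cohort$manifest$domain, cohort$manifest$known_flag)
#' @export
make_feature_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  K <- config$n_known_classes
  d <- config$feature_dim

  with_seed(config$seed, {
    mu <- matrix(stats::rnorm(K * d), K, d)
    mu <- mu / sqrt(rowSums(mu^2)) * config$class_sep
    # Shift directions: a cohort-level systematic component (the domain-wide
    # appearance change) blended with an independent per-class direction, so
    # every class gets its own delta_k but the domain retains a coherent
    # drift that channel-statistic alignment can partially correct.
    shared <- stats::rnorm(d)
    shared <- shared / sqrt(sum(shared^2))
    f <- config$shift_shared_frac
    delta <- matrix(stats::rnorm(K * d), K, d)
    delta <- delta / sqrt(rowSums(delta^2))
    delta <- sqrt(f) * matrix(shared, K, d, byrow = TRUE) +
      sqrt(1 - f) * delta
    delta <- delta / sqrt(rowSums(delta^2)) * config$shift_mean
    if (config$n_unknown_classes > 0L) {
      mu_unk <- matrix(stats::rnorm(config$n_unknown_classes * d),
                       config$n_unknown_classes, d)
      mu_unk <- mu_unk / sqrt(rowSums(mu_unk^2)) * (2.2 * config$class_sep)
    } else {
      mu_unk <- matrix(numeric(0), 0, d)
    }

    n_src <- class_counts(config$samples_per_class_source, K, config$imbalance)
    n_tgt <- class_counts(config$samples_per_class_target, K, config$imbalance)
    sd_t <- sqrt(config$shift_cov_scale)

    blocks <- list()
    rows <- list()
    for (k in seq_len(K)) {
      x <- matrix(stats::rnorm(n_src[k] * d), n_src[k], d)
      blocks[[length(blocks) + 1L]] <- sweep(x, 2, mu[k, ], "+")
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sprintf("src_c%02d_%04d", k - 1L, seq_len(n_src[k])),
        parent_id = "",
        label = k - 1L,
        domain = "source",
        known_flag = TRUE
      )
    }
    for (k in seq_len(K)) {
      x <- matrix(stats::rnorm(n_tgt[k] * d) * sd_t, n_tgt[k], d)
      blocks[[length(blocks) + 1L]] <- sweep(x, 2, mu[k, ] + delta[k, ], "+")
      parent <- (seq_len(n_tgt[k]) - 1L) %/% config$crops_per_parent
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sprintf("tgt_c%02d_%04d", k - 1L, seq_len(n_tgt[k])),
        parent_id = sprintf("parent_c%02d_%04d", k - 1L, parent),
        label = k - 1L,
        domain = "target",
        known_flag = TRUE
      )
    }
    if (config$unknown_pool_size > 0L) {
      C <- config$n_unknown_classes
      n_unk <- rep(config$unknown_pool_size %/% C, C)
      extra <- config$unknown_pool_size %% C
      if (extra > 0L) n_unk[seq_len(extra)] <- n_unk[seq_len(extra)] + 1L
      for (u in seq_len(config$n_unknown_classes)) {
        if (n_unk[u] == 0L) next
        x <- matrix(stats::rnorm(n_unk[u] * d) * sd_t, n_unk[u], d)
        blocks[[length(blocks) + 1L]] <- sweep(x, 2, mu_unk[u, ], "+")
        parent <- (seq_len(n_unk[u]) - 1L) %/% config$crops_per_parent
        rows[[length(rows) + 1L]] <- tibble::tibble(
          sample_id = sprintf("unk_u%02d_%04d", u - 1L, seq_len(n_unk[u])),
          parent_id = sprintf("parent_u%02d_%04d", u - 1L, parent),
          label = -1L,
          domain = "target",
          known_flag = FALSE
        )
      }
    }

    features <- do.call(rbind, blocks)
    manifest <- dplyr::bind_rows(rows)
    rownames(features) <- manifest$sample_id
    structure(
      list(features = features, manifest = manifest,
           class_means = mu, shift_directions = delta, config = config),
      class = "feature_cohort"
    )
  })
}

# Per-class sample counts under the imbalance knob: counts decay
# geometrically with class index and are floored at 3 so every class can
# populate a 3-way split.
class_counts <- function(base_n, K, imbalance) {
  if (K == 0L) return(integer(0))
  n <- round(base_n * (1 - imbalance)^(seq_len(K) - 1L))
  pmax(3L, as.integer(n))
}

#' @export
print.feature_cohort <- function(x, ...) {
  m <- x$manifest
  cat("<feature_cohort>\n")
  cat(sprintf("  %d samples x %d features\n", nrow(x$features),
              ncol(x$features)))
  cat(sprintf("  source: %d, target known: %d, target unknown: %d\n",
              sum(m$domain == "source"),
              sum(m$domain == "target" & m$known_flag),
              sum(!m$known_flag)))
  invisible(x)
}

#' Subset a feature cohort by manifest predicate
#'
#' @param cohort A [make_feature_cohort()] result.
#' @param idx Logical or integer index into the cohort rows.
#' @return A `feature_cohort` restricted to the selected rows.
#' @export
cohort_slice <- function(cohort, idx) {
  stopifnot(inherits(cohort, "feature_cohort"))
  out <- cohort
  out$features <- cohort$features[idx, , drop = FALSE]
  out$manifest <- cohort$manifest[idx, , drop = FALSE]
  out
}

#' Generate a synthetic logit cohort with known ground-truth temperature
#'
#' Draws raw logit vectors with a class-dependent margin and then samples
#' each label from the softened softmax `softmax(z / true_temperature)`, so
#' the cohort's miscalibration is known exactly and temperature fitting can
#' be validated by parameter recovery. The per-row margin is added to one
#' uniformly chosen coordinate on top of standard-normal noise.
#'
#' @param n Number of samples (>= 1).
#' @param K Number of classes (>= 2).
#' @param true_temperature Positive scalar used to soften the label-sampling
#'   distribution.
#' @param margin Logit bonus of the designated coordinate (default 3, which
#'   keeps the temperature identifiable across the softening range the
#'   recovery properties assert); 0 makes all coordinates exchangeable so
#'   labels are marginally uniform.
#' @param seed Integer seed.
#' @return An object of class `logit_cohort`: list with `logits`
#'   (n x K matrix), `labels` (0-based integers), `true_temperature`, and a
#'   `manifest` tibble.
#' @examples
#' lc <- make_logit_cohort(1000, K = 5, true_temperature = 2, seed = 7)
#' fit_temperature(lc$logits, lc$labels)$temperature
#' @export
make_logit_cohort <- function(n, K, true_temperature, margin = 3, seed = 1L) {
  n <- as.integer(n)
  K <- as.integer(K)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  if (K < 2L) stop("`K` must be >= 2", call. = FALSE)
  if (!is.finite(true_temperature) || true_temperature <= 0) {
    stop("`true_temperature` must be > 0", call. = FALSE)
  }
  with_seed(seed, {
    z <- matrix(stats::rnorm(n * K), n, K)
    designated <- sample.int(K, n, replace = TRUE)
    z[cbind(seq_len(n), designated)] <-
      z[cbind(seq_len(n), designated)] + margin
    p <- softmax(z / true_temperature)
    u <- stats::runif(n)
    cum <- t(apply(p, 1, cumsum))
    labels <- as.integer(rowSums(u > cum))  # 0-based
    structure(
      list(
        logits = z,
        labels = labels,
        true_temperature = true_temperature,
        manifest = tibble::tibble(
          sample_id = sprintf("logit_%05d", seq_len(n)),
          label = labels
        )
      ),
      class = "logit_cohort"
    )
  })
}

#' @export
print.logit_cohort <- function(x, ...) {
  cat(sprintf("<logit_cohort> %d samples x %d classes, true T = %.3g\n",
              nrow(x$logits), ncol(x$logits), x$true_temperature))
  invisible(x)
}

#' Write a feature cohort to disk as plain-text files
#'
#' Writes `manifest.csv` (sample_id, parent_id, label, domain, known_flag)
#' and `features.csv` (sample_id + one column per feature dimension).
#'
#' @param cohort A `feature_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_feature_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "feature_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(dir, "manifest.csv")
  features_path <- file.path(dir, "features.csv")
  utils::write.csv(cohort$manifest, manifest_path, row.names = FALSE)
  feat <- as.data.frame(cohort$features)
  names(feat) <- sprintf("f%03d", seq_len(ncol(feat)))
  feat <- cbind(sample_id = cohort$manifest$sample_id, feat)
  utils::write.csv(feat, features_path, row.names = FALSE)
  invisible(c(manifest_path, features_path))
}
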