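#' Configuration for synthetic study cohorts
#'
#' Bundles the knobs that control the synthetic feature cohorts emulating a
#' controlled-to-field transfer study: a source domain of class-conditional
#' Gaussian feature clusters, a target domain whose per-class means are
#' translated and whose covariance is inflated, an unknown-class pool that is
#' absent from training, and parent-group structure over the target samples.
#'
#' The defaults mirror the scale of a 21-class leaf-disease study: 21 known
#' classes, 7 unknown categories pooled into 490 samples, and 99 target
#' samples per known class (2079 field crops, one crop per parent image).
#'
#' @param n_known_classes Number of known classes \eqn{K} shared by the two
#'   domains (default 21).
#' @param n_unknown_classes Number of categories pooled into the unknown set
#'   (default 7). May be 0 for a closed-set cohort.
#' @param samples_per_class_source Source-domain samples per known class.
#' @param samples_per_class_target Target-domain samples per known class.
#' @param feature_dim Dimension of the feature vectors.
#' @param class_sep Norm of each class-mean vector, in units of the source
#'   within-class standard deviation; controls task difficulty.
#' @param shift_mean Norm of the per-class source-to-target mean translation
#'   \eqn{\delta_k} (0 = no covariate shift).
#' @param shift_shared_frac Fraction (in `[0, 1]`) of each shift direction's
#'   squared norm contributed by a cohort-level systematic direction; the
#'   remainder is an independent per-class direction. Field imagery shows a
#'   coherent domain-wide appearance drift on top of class-specific change,
#'   so the default blends both (0.5).
#' @param shift_cov_scale Multiplicative inflation of the target covariance;
#'   must be >= 1.
#' @param unknown_pool_size Total number of unknown-class samples (target
#'   domain only).
#' @param crops_per_parent Number of target crops sharing one parent image;
#'   1 reproduces the one-crop-per-parent regime.
#' @param imbalance Class-imbalance knob in `[0, 1)`: 0 gives balanced
#'   classes; larger values tilt per-class counts geometrically.
#' @param seed Integer seed; generation is a pure function of config + seed.
#'
#' @return An object of class `cohort_config` (a named list).
#' @seealso [make_feature_cohort()], [make_logit_cohort()]
#' @export
cohort_config <- function(n_known_classes = 21L,
                          n_unknown_classes = 7L,
                          samples_per_class_source = 100L,
                          samples_per_class_target = 99L,
                          feature_dim = 16L,
                          class_sep = 4,
                          shift_mean = 6,
                          shift_shared_frac = 0.5,
                          shift_cov_scale = 2.5,
                          unknown_pool_size = 490L,
                          crops_per_parent = 1L,
                          imbalance = 0,
                          seed = 42L) {
  cfg <- list(
    n_known_classes = as.integer(n_known_classes),
    n_unknown_classes = as.integer(n_unknown_classes),
    samples_per_class_source = as.integer(samples_per_class_source),
    samples_per_class_target = as.integer(samples_per_class_target),
    feature_dim = as.integer(feature_dim),
    class_sep = as.numeric(class_sep),
    shift_mean = as.numeric(shift_mean),
    shift_shared_frac = as.numeric(shift_shared_frac),
    shift_cov_scale = as.numeric(shift_cov_scale),
    unknown_pool_size = as.integer(unknown_pool_size),
    crops_per_parent = as.integer(crops_per_parent),
    imbalance = as.numeric(imbalance),
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_known_classes < 2L) {
    stop("`n_known_classes` must be >= 2", call. = FALSE)
  }
  if (cfg$n_unknown_classes < 0L || cfg$unknown_pool_size < 0L) {
    stop("unknown-class counts must be >= 0", call. = FALSE)
  }
  if (cfg$n_unknown_classes == 0L && cfg$unknown_pool_size > 0L) {
    stop("`unknown_pool_size` > 0 requires `n_unknown_classes` >= 1",
         call. = FALSE)
  }
  if (cfg$samples_per_class_source < 1L || cfg$samples_per_class_target < 1L) {
    stop("samples per class must be positive", call. = FALSE)
  }
  if (cfg$feature_dim < 1L) stop("`feature_dim` must be positive", call. = FALSE)
  if (cfg$class_sep <= 0) stop("`class_sep` must be positive", call. = FALSE)
  if (cfg$shift_mean < 0) stop("`shift_mean` must be >= 0", call. = FALSE)
  if (cfg$shift_cov_scale < 1) {
    stop("`shift_cov_scale` must be >= 1", call. = FALSE)
  }
  if (cfg$shift_shared_frac < 0 || cfg$shift_shared_frac > 1) {
    stop("`shift_shared_frac` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$crops_per_parent < 1L) {
    stop("`crops_per_parent` must be >= 1", call. = FALSE)
  }
  if (cfg$imbalance < 0 || cfg$imbalance >= 1) {
    stop("`imbalance` must lie in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  known classes: %d, unknown categories: %d (pool %d)\n",
              x$n_known_classes, x$n_unknown_classes, x$unknown_pool_size))
  cat(sprintf("  per-class n: source %d, target %d; feature dim %d\n",
              x$samples_per_class_source, x$samples_per_class_target,
              x$feature_dim))
  cat(sprintf("  class sep %.2f, shift mean %.2f, cov scale %.2f\n",
              x$class_sep, x$shift_mean, x$shift_cov_scale))
  cat(sprintf("  crops per parent %d, imbalance %.2f, seed %d\n",
              x$crops_per_parent, x$imbalance, x$seed))
  invisible(x)
}
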