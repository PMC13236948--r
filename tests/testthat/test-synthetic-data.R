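small_config <- function(...) {
  cohort_config(
    n_known_classes = 4, n_unknown_classes = 2,
    samples_per_class_source = 30, samples_per_class_target = 20,
    unknown_pool_size = 20, feature_dim = 6, seed = 11, ...
  )
}

test_that("feature cohorts are bit-reproducible and validated", {
  c1 <- make_feature_cohort(small_config())
  c2 <- make_feature_cohort(small_config())
  expect_identical(c1$features, c2$features)
  expect_identical(c1$manifest, c2$manifest)

  expect_error(cohort_config(feature_dim = 0), "feature_dim")
  expect_error(cohort_config(shift_cov_scale = 0.5), "shift_cov_scale")
  expect_error(cohort_config(samples_per_class_source = 0), "positive")
  expect_error(cohort_config(n_unknown_classes = 0, unknown_pool_size = 5),
               "unknown_pool_size")
})

test_that("manifest structure matches the cohort contract", {
  cohort <- make_feature_cohort(small_config(crops_per_parent = 1))
  m <- cohort$manifest
  expect_equal(nrow(m), nrow(cohort$features))
  expect_true(all(m$label[!m$known_flag] == -1L))
  tgt <- m[m$domain == "target", ]
  expect_true(all(nzchar(tgt$parent_id)))
  # one crop per parent: parent ids are unique over target samples
  expect_equal(length(unique(tgt$parent_id)), nrow(tgt))

  c3 <- make_feature_cohort(small_config(crops_per_parent = 3))
  tgt3 <- c3$manifest[c3$manifest$domain == "target" & c3$manifest$known_flag, ]
  sizes <- table(tgt3$parent_id)
  expect_true(all(sizes <= 3))
})

test_that("no shift means no systematic source/target mean gap", {
  cfg <- cohort_config(
    n_known_classes = 3, n_unknown_classes = 0, unknown_pool_size = 0,
    samples_per_class_source = 4000, samples_per_class_target = 4000,
    feature_dim = 4, shift_mean = 0, shift_cov_scale = 1, seed = 2
  )
  cohort <- make_feature_cohort(cfg)
  m <- cohort$manifest
  for (k in 0:2) {
    mu_s <- colMeans(cohort$features[m$domain == "source" & m$label == k, ])
    mu_t <- colMeans(cohort$features[m$domain == "target" & m$label == k, ])
    # per-coordinate sampling noise ~ sd/sqrt(n) = 1/63; gap must be small
    expect_lt(max(abs(mu_s - mu_t)), 5 / sqrt(4000))
  }
})

test_that("injected shift degrades a source-trained probe on the target", {
  cfg <- cohort_config(
    n_known_classes = 4, n_unknown_classes = 0, unknown_pool_size = 0,
    samples_per_class_source = 200, samples_per_class_target = 200,
    feature_dim = 8, class_sep = 4, shift_mean = 5, seed = 3
  )
  cohort <- make_feature_cohort(cfg)
  m <- cohort$manifest
  src <- which(m$domain == "source")
  split <- stratified_source_split(m$label[src], seed = 1)
  tr <- src[split$index[split$role == "train"]]
  va <- src[split$index[split$role == "val"]]
  head <- train_linear_head(cohort$features[tr, ], m$label[tr],
                            cohort$features[va, ], m$label[va],
                            n_classes = 4, seed = 1)
  acc <- function(idx) {
    pred <- max.col(head_logits(head, cohort$features[idx, ]),
                    ties.method = "first") - 1L
    mean(pred == m$label[idx])
  }
  tgt <- which(m$domain == "target")
  expect_gt(acc(va) - acc(tgt), 0.10)
})

test_that("logit cohorts are deterministic with exchangeable null labels", {
  l1 <- make_logit_cohort(500, 6, 1.5, seed = 4)
  l2 <- make_logit_cohort(500, 6, 1.5, seed = 4)
  expect_identical(l1$logits, l2$logits)
  expect_identical(l1$labels, l2$labels)
  expect_error(make_logit_cohort(10, 6, 0), "true_temperature")
  expect_error(make_logit_cohort(10, 1, 1), "K")

  # margin 0: coordinates exchangeable, so the label marginal is uniform
  null <- make_logit_cohort(30000, 5, 1, margin = 0, seed = 5)
  freq <- tabulate(null$labels + 1L, 5) / 30000
  expect_lt(max(abs(freq - 0.2)), 0.02)
  # and far below the accuracy an informative margin produces
  signal <- make_logit_cohort(30000, 5, 1, margin = 4, seed = 5)
  acc_of <- function(lc) mean(max.col(lc$logits) - 1L == lc$labels)
  expect_lt(acc_of(null), acc_of(signal) - 0.3)
})

test_that("image cohorts are deterministic with values in [0, 1]", {
  c1 <- make_image_cohort(1, 3, 32, 0.7, seed = 6)
  c2 <- make_image_cohort(1, 3, 32, 0.7, seed = 6)
  expect_identical(c1$image, c2$image)
  rng <- range(unlist(c1$image))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
  expect_error(make_image_cohort(1, 2, 16, 0.5), "image_size")
  expect_error(make_image_cohort(1, 2, 32, 1.5), "clutter_level")

  d <- withr::local_tempdir()
  paths <- write_image_cohort(c1, d)
  expect_true(all(file.exists(paths)))
  expect_identical(png::readPNG(paths[1]),
                   round(c1$image[[1]] * 255) / 255)
})
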