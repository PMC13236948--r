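test_that("thumbnail vectors have the documented geometry", {
  gray <- array(0.5, c(8, 8, 3))
  v <- thumbnail_vector(gray)
  expect_length(v, 3072)
  expect_true(all(v == 0.5))

  # 32 x 32 input: flattening only, no resampling
  img <- array(stats::runif(32 * 32 * 3), c(32, 32, 3))
  v32 <- thumbnail_vector(img)
  expect_equal(sort(v32), sort(as.numeric(img)), tolerance = 1e-12)

  # mean preservation of the area-weighted bilinear downscale
  checker <- array(0, c(64, 64, 3))
  checker[, , 1] <- outer(1:64, 1:64, function(i, j) (i + j) %% 2)
  checker[, , 2] <- checker[, , 1]
  checker[, , 3] <- checker[, , 1]
  expect_equal(mean(thumbnail_vector(checker)), mean(checker),
               tolerance = 1e-6)

  expect_error(thumbnail_vector(matrix(1, 2, 2)), "array")
})

test_that("crop/source matching is optimal and handles excess crops", {
  set.seed(10)
  a <- matrix(stats::rnorm(12), 4, 3)
  res <- match_crops_to_sources(a, a)
  expect_equal(res$total_cost, 0, tolerance = 1e-12)
  expect_equal(res$pairs$source, res$pairs$crop)

  # 2 x 2 instance solvable by inspection: cost [[1,2],[2,1]]
  crops <- matrix(c(0, 3), 2, 1)
  srcs <- matrix(c(1, 2), 2, 1)
  cost <- fieldshift:::pairwise_euclidean(crops, srcs)
  expect_equal(cost, matrix(c(1, 2, 2, 1), 2, 2), ignore_attr = TRUE)
  res2 <- match_crops_to_sources(crops, srcs)
  expect_equal(res2$pairs$source, c(1L, 2L))
  expect_equal(res2$total_cost, 2)

  # random instances vs exhaustive permutation minimum
  for (i in 1:15) {
    n <- sample(2:6, 1)
    m <- n + sample(0:2, 1)
    crops <- matrix(stats::rnorm(n * 4), n, 4)
    srcs <- matrix(stats::rnorm(m * 4), m, 4)
    res <- match_crops_to_sources(crops, srcs)
    oracle <- assignment_oracle(fieldshift:::pairwise_euclidean(crops, srcs))
    expect_equal(res$total_cost, oracle, tolerance = 1e-9)
    expect_false(any(duplicated(res$pairs$crop)))
    expect_false(any(duplicated(res$pairs$source)))
  }

  # crops outnumber sources: the excess is reported unmatched, never imputed
  crops <- matrix(stats::rnorm(7 * 3), 7, 3)
  srcs <- matrix(stats::rnorm(4 * 3), 4, 3)
  res <- match_crops_to_sources(crops, srcs)
  expect_equal(nrow(res$pairs), 4)
  expect_length(res$unmatched_crops, 3)
  expect_setequal(c(res$pairs$crop, res$unmatched_crops), 1:7)

  expect_error(match_crops_to_sources(matrix(1, 1, 2), matrix(1, 1, 3)),
               "dimension")
})

test_that("stratified source split matches the 70/15/15 rounding rule", {
  sp <- stratified_source_split(rep(0L, 100), seed = 1)
  expect_equal(as.numeric(table(sp$role)[c("train", "val", "test")]),
               c(70, 15, 15))

  # different seeds shuffle membership but preserve per-role class counts
  labs <- rep(0:2, each = 60)
  s1 <- stratified_source_split(labs, seed = 1)
  s2 <- stratified_source_split(labs, seed = 2)
  expect_false(identical(s1$role, s2$role))
  expect_equal(table(s1$role, s1$label), table(s2$role, s2$label))

  # 21 classes x 97 samples: per-class counts within 1 of n * fractions
  labs <- rep(0:20, each = 97)
  sp <- stratified_source_split(labs, seed = 3)
  counts <- table(sp$label, sp$role)
  expect_true(all(abs(counts[, "train"] - 67.9) <= 1))
  expect_true(all(abs(counts[, "val"] - 14.55) <= 1))
  expect_true(all(abs(counts[, "test"] - 14.55) <= 1))

  expect_error(stratified_source_split(c(0, 0, 1), seed = 1), ">= 3")
  expect_error(stratified_source_split(rep(0, 10), c(0.5, 0.5, 0.5)),
               "fractions")
})

make_target_manifest <- function(n_classes = 21, per_class = 99,
                                 crops_per_parent = 1) {
  rows <- lapply(seq_len(n_classes) - 1L, function(k) {
    parent <- (seq_len(per_class) - 1L) %/% crops_per_parent
    tibble::tibble(
      sample_id = sprintf("c%02d_%03d", k, seq_len(per_class)),
      parent_id = sprintf("p%02d_%03d", k, parent),
      label = k
    )
  })
  dplyr::bind_rows(rows)
}

test_that("grouped calibration split is parent-disjoint at ~10%", {
  tm <- make_target_manifest()
  sp <- grouped_calibration_split(tm, 0.10, seed = 42)
  expect_s3_class(sp, "split_manifest")
  expect_true(assert_parent_disjoint(sp))
  n_cal <- sum(sp$role == "field_calib")
  # 2079 samples at one crop per parent: calibration lands near 10%
  expect_gte(n_cal / nrow(tm), 0.09)
  expect_lte(n_cal / nrow(tm), 0.11)
  frac <- tapply(sp$role == "field_calib", sp$label, mean)
  expect_true(all(frac >= 0.09 & frac <= 0.11))

  # with multiple crops per parent no parent straddles the two roles
  tm3 <- make_target_manifest(5, 60, crops_per_parent = 3)
  sp3 <- grouped_calibration_split(tm3, 0.10, seed = 7)
  split_roles <- tapply(sp3$role, sp3$parent_id,
                        function(r) length(unique(r)))
  expect_true(all(split_roles == 1))

  # single parent group per class cannot be split
  one <- tibble::tibble(sample_id = c("a", "b"), parent_id = c("p", "p"),
                        label = c(0L, 0L))
  expect_error(grouped_calibration_split(one, 0.1, 1), "parent groups")
})

test_that("repeated grouped splits differ by seed yet all satisfy invariants", {
  tm <- make_target_manifest(6, 40)
  manifests <- lapply(42:51, function(s) {
    sp <- grouped_calibration_split(tm, 0.10, seed = s)
    expect_true(assert_parent_disjoint(sp))
    sp
  })
  roles <- vapply(manifests, function(sp) paste(sp$role, collapse = ""),
                  character(1))
  expect_equal(length(unique(roles)), 10)
  # with one crop per parent the grouped sizes equal plain stratified sizes:
  # every class contributes ceiling-to-group-granularity of 10%, here 4 of 40
  for (sp in manifests) {
    expect_equal(as.numeric(table(sp$label[sp$role == "field_calib"])),
                 rep(4, 6))
  }
})

test_that("category alignment keeps only mapped labels", {
  map <- tibble::tibble(raw_label = c("Tomato___Late_blight", "Corn_rust"),
                        canonical_label = c("Tomato_LateBlight", "Corn_Rust"))
  out <- align_categories(c("Corn_rust", "unmapped"), map)
  expect_equal(out$canonical_label, c("Corn_Rust", NA))
})
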