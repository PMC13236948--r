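#' Flatten an image to a 32 x 32 RGB thumbnail vector
#'
#' Resizes an RGB image to 32 x 32 with bilinear interpolation (triangular
#' filter with support scaled to the resampling ratio, so downscaling
#' averages rather than point-samples), then flattens channel-last to a
#' length-3072 vector in `[0, 1]`. These vectors feed the one-to-one crop /
#' source-image matching used to reconstruct parent-image identifiers.
#'
#' @param image Numeric array `h x w x 3` with values in `[0, 1]` (values in
#'   `[0, 255]` are rescaled).
#' @param size Thumbnail side length (default 32).
#' @return Numeric vector of length `size * size * 3`.
#' @examples
#' img <- array(0.5, c(8, 8, 3))
#' all(thumbnail_vector(img) == 0.5)
#' @export
thumbnail_vector <- function(image, size = 32L) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("`image` must be an h x w x 3 array", call. = FALSE)
  }
  if (any(dim(image)[1:2] == 0)) stop("`image` has a zero dimension",
                                      call. = FALSE)
  if (max(image) > 1 + 1e-9) image <- image / 255
  out <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    out[, , ch] <- resize_bilinear(image[, , ch], size, size)
  }
  as.numeric(aperm(out, c(3, 2, 1)))  # channel-last flatten
}

# Separable bilinear resize. For downscaling the triangular kernel support is
# widened by the scale ratio (the convention of standard image libraries),
# which preserves local means instead of aliasing.
resize_bilinear <- function(m, out_r, out_c) {
  resize_axis <- function(mat, n_out, along_rows) {
    n_in <- if (along_rows) nrow(mat) else ncol(mat)
    if (n_in == n_out) return(mat)
    scale <- n_in / n_out
    support <- max(1, scale)
    centers <- (seq_len(n_out) - 0.5) * scale + 0.5  # input coordinates
    w <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      lo <- max(1L, floor(centers[i] - support))
      hi <- min(n_in, ceiling(centers[i] + support))
      j <- lo:hi
      wt <- pmax(0, 1 - abs(j - centers[i]) / support)
      if (sum(wt) == 0) {
        wt[which.min(abs(j - centers[i]))] <- 1
      }
      w[i, j] <- wt / sum(wt)
    }
    if (along_rows) w %*% mat else mat %*% t(w)
  }
  m <- resize_axis(m, out_r, TRUE)
  resize_axis(m, out_c, FALSE)
}

#' Minimum-cost one-to-one matching of crops to source images
#'
#' Solves the rectangular assignment problem on pairwise Euclidean distances
#' between crop thumbnail vectors and source thumbnail vectors, so every crop
#' is linked to at most one source image and vice versa. When crops outnumber
#' sources, the globally cheapest matching that saturates the source side is
#' returned and the leftover crops are reported as `unmatched_crops` (to be
#' dropped, never imputed). Ties between equidistant sources are broken
#' towards the lowest index.
#'
#' @param crop_vectors Numeric matrix, one row per crop.
#' @param source_vectors Numeric matrix, one row per source image; must have
#'   the same number of columns as `crop_vectors`.
#' @return An object of class `assignment_result`: list with `pairs` (tibble
#'   `crop`, `source`, `cost`; 1-based indices), `total_cost`, and
#'   `unmatched_crops` (integer vector).
#' @examples
#' a <- matrix(c(0, 0, 1, 1), 2, 2, byrow = TRUE)
#' match_crops_to_sources(a, a)$total_cost
#' @export
match_crops_to_sources <- function(crop_vectors, source_vectors) {
  crop_vectors <- as.matrix(crop_vectors)
  source_vectors <- as.matrix(source_vectors)
  if (nrow(crop_vectors) == 0 || nrow(source_vectors) == 0) {
    stop("need at least one crop and one source", call. = FALSE)
  }
  if (ncol(crop_vectors) != ncol(source_vectors)) {
    stop("crop and source vectors must have the same dimension",
         call. = FALSE)
  }
  cost <- pairwise_euclidean(crop_vectors, source_vectors)
  n_crop <- nrow(cost)
  n_src <- ncol(cost)

  if (n_crop <= n_src) {
    assign_col <- hungarian_assign(cost)      # for each crop, a source
    pairs <- tibble::tibble(
      crop = seq_len(n_crop),
      source = assign_col,
      cost = cost[cbind(seq_len(n_crop), assign_col)]
    )
    unmatched <- integer(0)
  } else {
    assign_col <- hungarian_assign(t(cost))   # for each source, a crop
    pairs <- tibble::tibble(
      crop = assign_col,
      source = seq_len(n_src),
      cost = cost[cbind(assign_col, seq_len(n_src))]
    )
    pairs <- pairs[order(pairs$crop), ]
    unmatched <- setdiff(seq_len(n_crop), pairs$crop)
  }
  structure(
    list(pairs = pairs, total_cost = sum(pairs$cost),
         unmatched_crops = unmatched),
    class = "assignment_result"
  )
}

pairwise_euclidean <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Hungarian algorithm (augmenting paths with potentials), O(n^2 m), for an
# n x m cost matrix with n <= m. Returns, for each row, the assigned column.
# Scanning columns in index order makes equidistant ties resolve to the
# lowest column index.
hungarian_assign <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  stopifnot(n <= m)
  INF <- sum(abs(cost)) + 1
  u <- numeric(n + 1)
  v <- numeric(m + 1)
  p <- integer(m + 1)   # p[j + 1] = row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 0L] - v[j + 1L]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) {
    if (p[j + 1L] > 0L) assignment[p[j + 1L]] <- j
  }
  assignment
}

#' Stratified three-way split of source-domain samples
#'
#' Assigns every sample to train / val / test with per-class proportions
#' matching `fractions` to within one sample per class per role. Boundaries
#' are computed per class as `round(n * cumsum(fractions))`, so per-role
#' counts never drift by more than rounding.
#'
#' @param labels Integer class labels (any coding).
#' @param fractions Length-3 positive vector summing to 1
#'   (default `c(0.70, 0.15, 0.15)`).
#' @param seed Integer seed controlling the shuffle.
#' @return A tibble with `index` (position in `labels`), `label`, and `role`
#'   (`"train"`, `"val"`, `"test"`).
#' @examples
#' sp <- stratified_source_split(rep(0:1, each = 100), seed = 1)
#' table(sp$role)
#' @export
stratified_source_split <- function(labels, fractions = c(0.70, 0.15, 0.15),
                                    seed = 42L) {
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("`fractions` must be 3 positive values summing to 1", call. = FALSE)
  }
  tab <- table(labels)
  if (any(tab < 3)) {
    stop("every class needs >= 3 samples to populate all three roles",
         call. = FALSE)
  }
  with_seed(seed, {
    out <- lapply(names(tab), function(cl) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      # cumulative rounding with every role guaranteed non-empty
      b1 <- min(max(1, round(n * fractions[1])), n - 2)
      b2 <- min(max(b1 + 1, round(n * (fractions[1] + fractions[2]))), n - 1)
      role <- rep(c("train", "val", "test"), times = c(b1, b2 - b1, n - b2))
      tibble::tibble(index = idx, label = rep(cl, n), role = role)
    })
    dplyr::bind_rows(out) |> dplyr::arrange(.data$index)
  })
}

#' Grouped calibration / test split over parent images
#'
#' Splits target-domain known samples into a field-calibration subset and a
#' field-test subset at the parent-image level, so no parent contributes
#' crops to both sides. Per class, parent groups are shuffled by `seed` and
#' added greedily to the calibration side until the class calibration
#' fraction first reaches `calib_fraction`.
#'
#' @param manifest Data frame with columns `sample_id`, `parent_id`, `label`;
#'   every row must have a non-empty `parent_id`.
#' @param calib_fraction Target calibration fraction in (0, 1), default 0.10.
#' @param seed Integer seed.
#' @param setting Setting tag recorded in the result (default `"B"`).
#' @return An object of class `split_manifest`: tibble with `sample_id`,
#'   `parent_id`, `label`, `role` (`"field_calib"` / `"field_test"`), plus
#'   attributes `seed`, `setting`, `calib_fraction`.
#' @export
grouped_calibration_split <- function(manifest, calib_fraction = 0.10,
                                      seed = 42L, setting = "B") {
  need <- c("sample_id", "parent_id", "label")
  if (!all(need %in% names(manifest))) {
    stop("`manifest` needs columns sample_id, parent_id, label",
         call. = FALSE)
  }
  if (any(!nzchar(manifest$parent_id))) {
    stop("every sample must have a non-empty parent_id", call. = FALSE)
  }
  if (calib_fraction <= 0 || calib_fraction >= 1) {
    stop("`calib_fraction` must lie in (0, 1)", call. = FALSE)
  }
  groups_per_class <- tapply(manifest$parent_id, manifest$label,
                             function(p) length(unique(p)))
  if (any(groups_per_class < 2)) {
    stop("every class needs >= 2 parent groups to split", call. = FALSE)
  }
  with_seed(seed, {
    out <- lapply(split(manifest, manifest$label), function(df) {
      parents <- unique(df$parent_id)
      parents <- parents[sample.int(length(parents))]
      sizes <- table(df$parent_id)[parents]
      n <- nrow(df)
      cum <- cumsum(as.integer(sizes))
      n_groups <- which(cum / n >= calib_fraction)[1]
      calib_parents <- parents[seq_len(n_groups)]
      df$role <- ifelse(df$parent_id %in% calib_parents,
                        "field_calib", "field_test")
      df
    })
    res <- dplyr::bind_rows(out)
    res <- res[match(manifest$sample_id, res$sample_id), ]
    res <- tibble::as_tibble(res[, c("sample_id", "parent_id", "label",
                                     "role")])
    structure(res, class = c("split_manifest", class(res)),
              seed = seed, setting = setting,
              calib_fraction = calib_fraction)
  })
}

#' Verify that a grouped split is leakage-free
#'
#' Checks that calibration and test parent-id sets are disjoint and that the
#' roles partition the manifest. Called internally before any fitting step.
#'
#' @param split A `split_manifest`.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
assert_parent_disjoint <- function(split) {
  calib <- unique(split$parent_id[split$role == "field_calib"])
  test <- unique(split$parent_id[split$role == "field_test"])
  if (length(intersect(calib, test)) > 0) {
    stop("parent-image overlap between calibration and test subsets",
         call. = FALSE)
  }
  if (!all(split$role %in% c("field_calib", "field_test"))) {
    stop("roles must partition the manifest", call. = FALSE)
  }
  invisible(TRUE)
}

#' Apply a category-alignment mapping to raw labels
#'
#' Canonicalizes dataset-specific label vocabularies through a user-supplied
#' two-column table, keeping only labels with a canonical match.
#'
#' @param labels Character vector of raw labels.
#' @param mapping Data frame with columns `raw_label`, `canonical_label`.
#' @return A tibble with `raw_label`, `canonical_label` (NA when unmatched).
#' @export
align_categories <- function(labels, mapping) {
  if (!all(c("raw_label", "canonical_label") %in% names(mapping))) {
    stop("`mapping` needs columns raw_label and canonical_label",
         call. = FALSE)
  }
  tibble::tibble(
    raw_label = labels,
    canonical_label = mapping$canonical_label[match(labels,
                                                    mapping$raw_label)]
  )
}
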