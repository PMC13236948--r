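#' Generate a synthetic two-domain image cohort
#'
#' Emulates the visual contrast between controlled single-leaf photographs
#' and heterogeneous field imagery. Source images contain one smooth,
#' anti-aliased elliptical foreground (the "leaf") on a uniform
#' low-saturation background. Target images start from the same recipe and
#' add `clutter_level`-controlled high-saturation distractor blobs placed
#' preferentially near the image border, plus border-concentrated
#' high-frequency texture. At `clutter_level = 0` the target generator is
#' byte-identical in distribution to the source generator, giving a null
#' cohort for type-I-error checks.
#'
#' @param n_per_class Images per class per domain.
#' @param n_classes Number of classes (class controls leaf hue and shape).
#' @param image_size Side length in pixels (>= 32).
#' @param clutter_level Real in `[0, 1]` controlling distractor count and
#'   border-texture amplitude in the target domain.
#' @param seed Integer seed; a fixed seed gives bit-identical images.
#' @return A tibble with columns `sample_id`, `label` (0-based), `domain`,
#'   and `image` (list column of `image_size x image_size x 3` arrays with
#'   values in `[0, 1]`).
#' @examples
#' cohort <- make_image_cohort(n_per_class = 1, n_classes = 2,
#'                             image_size = 32, clutter_level = 0.5, seed = 1)
#' dim(cohort$image[[1]])
#' @export
make_image_cohort <- function(n_per_class = 4L, n_classes = 21L,
                              image_size = 64L, clutter_level = 0.5,
                              seed = 1L) {
  image_size <- as.integer(image_size)
  if (image_size < 32L) stop("`image_size` must be >= 32", call. = FALSE)
  if (!is.finite(clutter_level) || clutter_level < 0 || clutter_level > 1) {
    stop("`clutter_level` must lie in [0, 1]", call. = FALSE)
  }
  if (n_per_class < 1L || n_classes < 1L) {
    stop("counts must be positive", call. = FALSE)
  }
  with_seed(seed, {
    rows <- list()
    for (domain in c("source", "target")) {
      clutter <- if (domain == "source") 0 else clutter_level
      for (k in seq_len(n_classes)) {
        for (i in seq_len(n_per_class)) {
          img <- render_leaf_image(image_size, class_index = k - 1L,
                                   n_classes = n_classes, clutter = clutter)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample_id = sprintf("%s_c%02d_%03d", substr(domain, 1, 3),
                                k - 1L, i),
            label = k - 1L,
            domain = domain,
            image = list(img)
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

# One synthetic leaf image. Consumes RNG; callers own the seed.
render_leaf_image <- function(size, class_index, n_classes, clutter) {
  xs <- matrix(rep(seq_len(size), each = size), size, size)   # column index
  ys <- matrix(rep(seq_len(size), times = size), size, size)  # row index

  # Background: low-saturation grayish green with a gentle vertical gradient.
  bg_v <- stats::runif(1, 0.65, 0.8)
  grad <- (ys / size - 0.5) * stats::runif(1, -0.06, 0.06)
  bg <- hsv_to_rgb_array(
    h = 0.25, s = stats::runif(1, 0.03, 0.08),
    v = pmin(1, pmax(0, bg_v + grad))
  )

  # Foreground ellipse: hue keyed to class, moderate saturation.
  hue <- 0.2 + 0.15 * class_index / max(1, n_classes - 1) +
    stats::rnorm(1, 0, 0.01)
  aspect <- 0.5 + 0.4 * ((class_index * 7L) %% n_classes) / max(1, n_classes)
  cx <- size * stats::runif(1, 0.42, 0.58)
  cy <- size * stats::runif(1, 0.42, 0.58)
  rx <- size * stats::runif(1, 0.24, 0.3)
  ry <- rx * aspect
  theta <- stats::runif(1, 0, pi)
  xr <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
  yr <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
  dist <- sqrt((xr / rx)^2 + (yr / ry)^2)
  alpha <- pmin(1, pmax(0, (1.05 - dist) / 0.1))  # anti-aliased edge
  leaf <- hsv_to_rgb_array(
    h = (hue %% 1), s = stats::runif(1, 0.4, 0.5),
    v = stats::runif(1, 0.45, 0.55)
  )
  img <- array(0, c(size, size, 3))
  for (ch in 1:3) {
    img[, , ch] <- bg[ch] * (1 - alpha) + leaf[ch] * alpha
  }

  # A dark lesion spot keyed to class, so classes differ inside the leaf.
  lx <- cx + rx * 0.3 * cos(2 * pi * class_index / max(1, n_classes))
  ly <- cy + ry * 0.3 * sin(2 * pi * class_index / max(1, n_classes))
  lesion <- pmin(1, pmax(0, (0.08 * size - sqrt((xs - lx)^2 + (ys - ly)^2)) /
                           (0.02 * size)))
  for (ch in 1:3) img[, , ch] <- img[, , ch] * (1 - 0.6 * lesion * alpha)

  if (clutter > 0) {
    # High-saturation distractor blobs, biased towards the border.
    n_blobs <- stats::rpois(1, clutter * 8)
    for (b in seq_len(n_blobs)) {
      edge_bias <- stats::runif(1) < 0.75
      pos <- if (edge_bias) {
        strip <- 0.18 * size
        p <- c(stats::runif(1, 1, size), stats::runif(1, 1, size))
        side <- sample.int(4, 1)
        if (side == 1) p[1] <- stats::runif(1, 1, strip)
        if (side == 2) p[1] <- stats::runif(1, size - strip, size)
        if (side == 3) p[2] <- stats::runif(1, 1, strip)
        if (side == 4) p[2] <- stats::runif(1, size - strip, size)
        p
      } else {
        c(stats::runif(1, 1, size), stats::runif(1, 1, size))
      }
      r <- size * stats::runif(1, 0.03, 0.08)
      blob_alpha <- pmin(1, pmax(0, (r - sqrt((xs - pos[1])^2 +
                                                (ys - pos[2])^2)) / 1.5))
      col <- hsv_to_rgb_array(h = stats::runif(1), s = stats::runif(1, 0.85, 1),
                              v = stats::runif(1, 0.6, 0.95))
      for (ch in 1:3) {
        img[, , ch] <- img[, , ch] * (1 - blob_alpha) + col[ch] * blob_alpha
      }
    }
    # Border-concentrated texture: high-frequency noise in the outer strip.
    strip <- border_mask(size, size, 0.2)
    noise <- matrix(stats::rnorm(size * size, 0, 0.25 * clutter), size, size)
    tint <- stats::runif(3, 0.4, 1)
    for (ch in 1:3) {
      img[, , ch] <- img[, , ch] + strip * noise * tint[ch]
    }
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  img
}

# Scalar HSV -> RGB triplet (h, s, v in [0, 1]).
hsv_to_rgb_array <- function(h, s, v) {
  col <- grDevices::hsv(h %% 1, s, v)
  as.numeric(grDevices::col2rgb(col)) / 255
}

# Logical mask of the outer `frac` strip (per side) of an nr x nc image.
border_mask <- function(nr, nc, frac) {
  wr <- round(frac * nr)
  wc <- round(frac * nc)
  rows <- seq_len(nr) <= wr | seq_len(nr) > nr - wr
  cols <- seq_len(nc) <= wc | seq_len(nc) > nc - wc
  outer(rows, rep(TRUE, nc)) | outer(rep(TRUE, nr), cols)
}

#' Write an image cohort as PNG files in per-class directories
#'
#' Lays images out as `dir/<domain>/class_<label>/<sample_id>.png` in 8-bit
#' RGB. Output is byte-identical for a fixed generator seed.
#'
#' @param cohort Tibble from [make_image_cohort()].
#' @param dir Output directory.
#' @return Invisibly, a character vector of file paths.
#' @export
write_image_cohort <- function(cohort, dir) {
  stopifnot(all(c("sample_id", "label", "domain", "image") %in% names(cohort)))
  paths <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sub <- file.path(dir, cohort$domain[i],
                     sprintf("class_%02d", cohort$label[i]))
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    paths[i] <- file.path(sub, paste0(cohort$sample_id[i], ".png"))
    png::writePNG(cohort$image[[i]], paths[i])
  }
  invisible(paths)
}
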