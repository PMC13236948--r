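# Low-level image machinery for the shift descriptors. Images are numeric
# h x w x 3 arrays in [0, 1]; gradients use replicate padding so constant
# images have exactly zero response.

pad_replicate <- function(m) {
  m <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
}

conv3 <- function(m, k) {
  p <- pad_replicate(m)
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (i in 1:3) {
    for (j in 1:3) {
      if (k[i, j] != 0) {
        out <- out + k[i, j] * p[i:(i + nr - 1), j:(j + nc - 1)]
      }
    }
  }
  out
}

# Sobel gradients scaled so a unit step in a [0, 1] image responds with
# magnitude ~1 per axis.
sobel_gradients <- function(gray) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE) / 4
  list(gx = conv3(gray, kx), gy = conv3(gray, t(kx)))
}

rgb_to_hsv_planes <- function(image) {
  rgb <- rbind(as.numeric(image[, , 1]), as.numeric(image[, , 2]),
               as.numeric(image[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  d <- dim(image)[1:2]
  list(h = matrix(hsv[1, ], d[1], d[2]),
       s = matrix(hsv[2, ], d[1], d[2]),
       v = matrix(hsv[3, ], d[1], d[2]))
}

# Uniform local binary pattern codes (8 neighbours, radius 1): uniform codes
# (<= 2 circular 0/1 transitions) keep distinct bins, all others share one.
lbp_codes <- function(gray) {
  nr <- nrow(gray)
  nc <- ncol(gray)
  if (nr < 3 || nc < 3) return(integer(0))
  center <- gray[2:(nr - 1), 2:(nc - 1)]
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, nr - 2, nc - 2)
  for (b in seq_along(offs)) {
    o <- offs[[b]]
    nb <- gray[(2 + o[1]):(nr - 1 + o[1]), (2 + o[2]):(nc - 1 + o[2])]
    code <- code + as.integer(nb >= center) * 2L^(b - 1L)
  }
  lbp_uniform_map()[as.integer(code) + 1L]
}

# Map each 8-bit code to a uniform-pattern bin (0..57 uniform, 58 other).
lbp_uniform_map <- local({
  map <- NULL
  function() {
    if (!is.null(map)) return(map)
    trans <- vapply(0:255, function(code) {
      bits <- as.integer(intToBits(code))[1:8]
      sum(bits != bits[c(2:8, 1)])
    }, numeric(1))
    m <- integer(256)
    uniform <- which(trans <= 2)
    m[uniform] <- seq_along(uniform) - 1L
    m[trans > 2] <- length(uniform)
    map <<- m
    map
  }
})

circular_sd <- function(angles) {
  if (length(angles) == 0) return(0)
  R <- sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
  sqrt(-2 * log(max(R, 1e-12)))
}

descriptor_names <- c(
  "mean_saturation", "var_saturation", "mean_value", "var_value",
  "mean_gray", "var_gray", "color_variance", "laplacian_variance",
  "sobel_edge_density", "border_edge_density", "center_edge_density",
  "gray_entropy", "lbp_entropy", "foreground_occupancy",
  "mean_hue_dispersion", "border_saturation_mean",
  "edge_orientation_entropy"
)

#' The 17 image-level shift descriptors
#'
#' Computes the descriptor battery used for model-free domain-shift
#' quantification: HSV color statistics (mean/variance of saturation and
#' value, circular hue dispersion, border-strip saturation), grayscale
#' statistics and spatial-frequency content (Laplacian variance; Sobel edge
#' density overall and restricted to the outer-20% border strip and to the
#' center), texture (entropy of the 256-bin gray histogram and of the
#' uniform 8-neighbour radius-1 LBP histogram, entropy of an 8-bin
#' gradient-orientation histogram over edge pixels, orientations folded to
#' `[0, pi/2]`), and a foreground-occupancy proxy (the
#' fraction of pixels with saturation > 0.25 or gradient magnitude > 0.1).
#' Edge densities use a gradient-magnitude threshold of 0.1 on `[0, 1]`
#' grayscale. All densities and the occupancy lie in `[0, 1]`; entropies are
#' non-negative; every descriptor is invariant to horizontal and vertical
#' flips.
#'
#' @param image Numeric `h x w x 3` array in `[0, 1]`, min side >= 16.
#' @param edge_threshold Gradient-magnitude threshold (default 0.1).
#' @param border_fraction Border-strip width as a fraction of each dimension
#'   per side (default 0.2).
#' @return A one-row tibble with 17 named descriptor columns.
#' @examples
#' img <- array(0.5, c(16, 16, 3))
#' compute_descriptors(img)$mean_saturation
#' @export
compute_descriptors <- function(image, edge_threshold = 0.1,
                                border_fraction = 0.2) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3) {
    stop("`image` must be an h x w x 3 RGB array", call. = FALSE)
  }
  if (min(dim(image)[1:2]) < 16) {
    stop("min image side must be >= 16", call. = FALSE)
  }
  if (any(!is.finite(image)) || min(image) < -1e-9 || max(image) > 1 + 1e-9) {
    stop("`image` values must lie in [0, 1]", call. = FALSE)
  }

  hsv <- rgb_to_hsv_planes(image)
  gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  g <- sobel_gradients(gray)
  mag <- sqrt(g$gx^2 + g$gy^2)
  lap <- conv3(gray, matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3))
  border <- border_mask(nrow(gray), ncol(gray), border_fraction)
  edges <- mag > edge_threshold

  gray_hist <- tabulate(pmin(floor(gray * 256) + 1L, 256L), nbins = 256L)
  lbp <- lbp_codes(gray)
  lbp_hist <- tabulate(lbp + 1L, nbins = 59L)
  # orientations folded to [0, pi/2] so the histogram is flip-invariant;
  # rounding keeps boundary angles (e.g. pi/4 diagonals) in a stable bin
  orient <- atan2(g$gy[edges], g$gx[edges]) %% pi
  orient <- round(pmin(orient, pi - orient), 9)
  orient_hist <- tabulate(pmin(floor(orient / (pi / 2) * 8) + 1L, 8L),
                          nbins = 8L)

  tibble::tibble(
    mean_saturation = mean(hsv$s),
    var_saturation = stats::var(as.numeric(hsv$s)),
    mean_value = mean(hsv$v),
    var_value = stats::var(as.numeric(hsv$v)),
    mean_gray = mean(gray),
    var_gray = stats::var(as.numeric(gray)),
    color_variance = mean(c(stats::var(as.numeric(image[, , 1])),
                            stats::var(as.numeric(image[, , 2])),
                            stats::var(as.numeric(image[, , 3])))),
    laplacian_variance = stats::var(as.numeric(lap)),
    sobel_edge_density = mean(edges),
    border_edge_density = mean(edges[border]),
    center_edge_density = mean(edges[!border]),
    gray_entropy = entropy_nat(gray_hist),
    lbp_entropy = entropy_nat(lbp_hist),
    foreground_occupancy = mean(hsv$s > 0.25 | mag > edge_threshold),
    mean_hue_dispersion = circular_sd(2 * pi * hsv$h[hsv$s > 0]),
    border_saturation_mean = mean(hsv$s[border]),
    edge_orientation_entropy = entropy_nat(orient_hist)
  )
}

#' Descriptor table for an image cohort
#'
#' Applies [compute_descriptors()] to every image of a cohort tibble.
#'
#' @param cohort Tibble with `sample_id`, `label`, `domain`, and an `image`
#'   list column (as produced by [make_image_cohort()]).
#' @return Tibble with `sample_id`, `label`, `domain` plus the 17 descriptor
#'   columns.
#' @export
cohort_descriptors <- function(cohort) {
  desc <- dplyr::bind_rows(lapply(cohort$image, compute_descriptors))
  dplyr::bind_cols(cohort[, c("sample_id", "label", "domain")], desc)
}
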