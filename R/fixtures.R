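# Synthetic fixtures emulating the two image classes the metric
# distinguishes: computer-generated screen content (noise-free flat regions,
# text-like strokes with sharp edges, an embedded smooth natural patch) and
# natural images (smooth fields with heavy-tailed gradient statistics).
# All generators are bit-reproducible for a fixed seed.

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

gaussian_blur_matrix <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  # separable blur, clamped (replicate) borders; kernel clipped to image size
  kr <- k
  if (length(kr) > nrow(img)) {
    kr <- k[seq_len(nrow(img) - (1 - nrow(img) %% 2))]; kr <- kr / sum(kr)
  }
  kc <- k
  if (length(kc) > ncol(img)) {
    kc <- k[seq_len(ncol(img) - (1 - ncol(img) %% 2))]; kc <- kc / sum(kc)
  }
  convolve2d(convolve2d(img, matrix(kr, ncol = 1)), matrix(kc, nrow = 1))
}

# Smoothed white-noise field evaluated away from borders: the noise is drawn
# on a grid padded by the kernel radius and cropped after blurring, so border
# pixels have the same variance as the interior.
smooth_noise <- function(height, width, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  big <- gaussian_blur_matrix(matrix(rnorm((height + 2 * r) * (width + 2 * r)),
                                     height + 2 * r, width + 2 * r), sigma)
  big[(r + 1):(r + height), (r + 1):(r + width), drop = FALSE]
}

#' Generate a screen-content-like fixture image
#'
#' Builds a computer-generated image with the three structural properties of
#' screen content: a perfectly flat (noise-free) background, glyph-like dark
#' strokes with sharp edges, filled rectangle shapes, and one low-pass noise
#' patch standing in for an embedded natural photograph. Deterministic for a
#' fixed seed.
#'
#' @param height,width Image size, at least 32x32.
#' @param n_text_blocks Number of glyph-like stroke blocks.
#' @param n_shapes Number of filled rectangles.
#' @param smooth_patch_fraction Fraction of the area covered by the smooth
#'   natural-like patch, in `[0, 1]`.
#' @param seed Integer RNG seed.
#' @return Luminance matrix (0-255).
#' @export
make_screen_fixture <- function(height = 256L, width = 256L, n_text_blocks = 12L,
                                n_shapes = 4L, smooth_patch_fraction = 0.15,
                                seed = 1L) {
  if (height < 32L || width < 32L) {
    stop_gradsim("Screen fixtures must be at least 32x32.", "gradsim_validation_error")
  }
  if (smooth_patch_fraction < 0 || smooth_patch_fraction > 1) {
    stop_gradsim("`smooth_patch_fraction` must lie in [0, 1].",
                 "gradsim_validation_error")
  }
  withr::with_seed(seed, {
    bg <- 235
    img <- matrix(bg, height, width)

    if (smooth_patch_fraction > 0) {
      side <- max(8L, floor(sqrt(smooth_patch_fraction * height * width)))
      ph <- min(side, height - 2L); pw <- min(side, width - 2L)
      r0 <- sample.int(height - ph, 1L)
      c0 <- sample.int(width - pw, 1L)
      patch <- smooth_noise(ph, pw, 2)
      patch <- 128 + 45 * patch / stats::sd(patch)
      img[r0:(r0 + ph - 1L), c0:(c0 + pw - 1L)] <- clip255(patch)
    }

    for (s in seq_len(n_shapes)) {
      sh <- sample(8:max(9L, height %/% 4), 1L)
      sw <- sample(8:max(9L, width %/% 4), 1L)
      r0 <- sample.int(height - sh, 1L)
      c0 <- sample.int(width - sw, 1L)
      img[r0:(r0 + sh - 1L), c0:(c0 + sw - 1L)] <- sample(60:200, 1L)
    }

    ink <- 25  # |bg - ink| = 210, guaranteeing sharp glyph edges
    for (b in seq_len(n_text_blocks)) {
      bh <- sample(6:12, 1L); bw <- sample(10:28, 1L)
      r0 <- sample.int(height - bh, 1L)
      c0 <- sample.int(width - bw, 1L)
      for (k in seq_len(sample(2:4, 1L))) {
        if (stats::runif(1) < 0.5) {       # horizontal stroke
          rr <- r0 + sample.int(bh, 1L) - 1L
          img[rr, c0:(c0 + bw - 1L)] <- ink
        } else {                           # vertical stroke
          cc <- c0 + sample.int(bw, 1L) - 1L
          img[r0:(r0 + bh - 1L), cc] <- ink
        }
      }
    }
    img
  })
}

#' Generate a natural-image-like fixture
#'
#' Smoothed white noise modulated by a smooth log-normal contrast envelope (a
#' Gaussian scale mixture), rescaled to 0-255. The contrast modulation gives
#' the forward-difference gradients the sharp zero peak and heavy tails
#' characteristic of natural images (positive excess kurtosis), which plain
#' smoothed Gaussian noise does not have.
#'
#' @param height,width Image size.
#' @param smoothing_sigma Positive Gaussian smoothing scale in pixels.
#' @param seed Integer RNG seed.
#' @return Luminance matrix (0-255).
#' @export
make_natural_fixture <- function(height = 256L, width = 256L,
                                 smoothing_sigma = 2, seed = 1L) {
  check_scalar_number(smoothing_sigma, "smoothing_sigma", lower = 0, strict = TRUE)
  if (height < 3L || width < 3L) {
    stop_gradsim("Natural fixtures must be at least 3x3.", "gradsim_validation_error")
  }
  withr::with_seed(seed, {
    base <- smooth_noise(height, width, smoothing_sigma)
    env <- smooth_noise(height, width, 3 * smoothing_sigma)
    env <- exp((env - mean(env)) / stats::sd(env))
    field <- base * env
    rng <- range(field)
    if (rng[2] - rng[1] < .Machine$double.eps) {
      matrix(128, height, width)
    } else {
      clip255(255 * (field - rng[1]) / (rng[2] - rng[1]))
    }
  })
}

#' Generate an oriented step-edge probe image
#'
#' Two half-planes split by a line through the image centre at the given
#' angle (counterclockwise from the x axis with y up, matching the direction
#' convention of [build_kernel_bank()]), with values differing by `contrast`.
#'
#' @param height,width Image size.
#' @param angle Edge angle in radians, in `[0, pi)`.
#' @param contrast Intensity difference across the edge.
#' @return Luminance matrix (0-255 after clipping).
#' @export
make_oriented_edge <- function(height = 64L, width = 64L, angle = 0,
                               contrast = 120) {
  if (!is.numeric(angle) || length(angle) != 1L || angle < 0 || angle >= pi) {
    stop_gradsim("`angle` must lie in [0, pi).", "gradsim_validation_error")
  }
  cy <- (height + 1) / 2
  cx <- (width + 1) / 2
  x <- matrix(rep(seq_len(width), each = height), height, width) - cx
  y <- matrix(rep(seq_len(height), times = width), height, width) - cy
  sa <- sin(angle); ca <- cos(angle)
  if (abs(sa) < 1e-12) sa <- 0            # keep lattice-aligned edges exact
  if (abs(ca) < 1e-12) ca <- 0
  s <- sa * x + ca * y                    # signed distance to the edge line
  base <- (255 - abs(contrast)) / 2
  clip255(base + ifelse(s > 0, abs(contrast), 0))
}
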