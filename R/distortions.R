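# Controlled distortions of luminance images. Every distortion is
# deterministic given its seed, is the identity at level 0, and clips its
# output to [0, 255].

DISTORTION_KINDS <- c("gaussian_noise", "gaussian_blur", "contrast_change",
                      "blockiness", "motion_blur")

#' Apply a controlled distortion to an image
#'
#' Distortion kinds and the meaning of `level`:
#' * `gaussian_noise` — additive white Gaussian noise, sigma in gray levels;
#' * `gaussian_blur` — Gaussian low-pass filter, sigma in pixels;
#' * `contrast_change` — gamma mapping 255 (I/255)^level (identity at
#'   level 1);
#' * `blockiness` — 8x8 block-DCT coefficient quantisation with step `level`;
#' * `motion_blur` — horizontal box blur of length `round(level)` pixels.
#'
#' `level = 0` returns a pixel-identical copy for every kind. Output is
#' clipped to `[0, 255]`.
#'
#' @param img Luminance matrix.
#' @param kind One of the five distortion kinds.
#' @param level Nonnegative distortion strength (units depend on `kind`).
#' @param seed Integer seed for stochastic kinds.
#' @return Luminance matrix with the input's shape.
#' @export
apply_distortion <- function(img, kind, level, seed = 1L) {
  check_gray_image(img)
  if (!is.character(kind) || length(kind) != 1L || !kind %in% DISTORTION_KINDS) {
    stop_gradsim(sprintf("Unknown distortion kind '%s'. Choose one of: %s.",
                         paste(kind, collapse = ","),
                         paste(DISTORTION_KINDS, collapse = ", ")),
                 "gradsim_validation_error")
  }
  check_scalar_number(level, "level", lower = 0)
  if (level == 0) return(img + 0)
  out <- switch(kind,
    gaussian_noise = withr::with_seed(seed, img + rnorm(length(img), 0, level)),
    gaussian_blur = gaussian_blur_matrix(img, level),
    contrast_change = 255 * (clip255(img) / 255)^level,
    blockiness = blockiness_dct(img, level),
    motion_blur = {
      len <- max(1L, round(level))
      if (len == 1L) img + 0 else convolve2d(img, matrix(1 / len, 1, len))
    }
  )
  clip255(out)
}

dct_basis_8 <- function() {
  n <- 8L
  C <- matrix(0, n, n)
  for (k in 0:(n - 1)) {
    a <- if (k == 0) sqrt(1 / n) else sqrt(2 / n)
    C[k + 1, ] <- a * cos((2 * (0:(n - 1)) + 1) * k * pi / (2 * n))
  }
  C
}

# JPEG-style blockiness: per 8x8 block, 2D DCT-II, uniform coefficient
# quantisation with the given step, inverse transform. The image is
# replicate-padded up to a multiple of 8 and cropped back.
blockiness_dct <- function(img, step) {
  h <- nrow(img); w <- ncol(img)
  H <- 8L * ceiling(h / 8L); W <- 8L * ceiling(w / 8L)
  pad <- img[pmin(seq_len(H), h), pmin(seq_len(W), w), drop = FALSE]
  C <- dct_basis_8()
  out <- pad
  for (br in seq_len(H / 8L)) {
    rs <- (8L * (br - 1L) + 1L):(8L * br)
    for (bc in seq_len(W / 8L)) {
      cs <- (8L * (bc - 1L) + 1L):(8L * bc)
      X <- C %*% pad[rs, cs] %*% t(C)
      out[rs, cs] <- t(C) %*% (round(X / step) * step) %*% C
    }
  }
  out[seq_len(h), seq_len(w), drop = FALSE]
}
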