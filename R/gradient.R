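# Classical gradient computation: template convolution (Prewitt/Sobel/Scharr),
# forward differences, L1/L2 magnitudes and arctangent direction.
#
# Coordinate convention used throughout the package: x is the column index
# (horizontal, increasing rightwards), y is the row index (vertical,
# increasing downwards). Images are stored as R matrices indexed [y, x].

#' 2D template convolution with replicate padding
#'
#' Applies a small coefficient template to an image. The template is applied
#' as written (sliding inner product, i.e. cross-correlation — the convention
#' used for image-processing operator templates); borders are handled by
#' replicating the nearest edge pixel, so the output has the input's shape.
#'
#' @param img Numeric matrix.
#' @param kernel Numeric matrix of coefficients, smaller than `img` in both
#'   dimensions. Odd dimensions centre the template on the output pixel.
#' @param padding Border rule; only `"replicate"` is supported.
#' @return Numeric matrix with the shape of `img`.
#' @examples
#' convolve2d(matrix(1:9, 3, 3), matrix(1))        # identity
#' convolve2d(matrix(5, 4, 4), sobel_template()$horizontal)  # all zero
#' @export
convolve2d <- function(img, kernel, padding = c("replicate")) {
  padding <- match.arg(padding)
  if (!is.matrix(img) || !is.numeric(img)) {
    stop_gradsim("`img` must be a numeric matrix.", "gradsim_validation_error")
  }
  if (!is.matrix(kernel) || !is.numeric(kernel)) {
    stop_gradsim("`kernel` must be a numeric matrix.", "gradsim_validation_error")
  }
  if (nrow(kernel) > nrow(img) || ncol(kernel) > ncol(img)) {
    stop_gradsim(sprintf("Kernel (%dx%d) must not exceed the image (%dx%d).",
                         nrow(kernel), ncol(kernel), nrow(img), ncol(img)),
                 "gradsim_validation_error")
  }
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  cr <- (kh + 1L) %/% 2L
  cc <- (kw + 1L) %/% 2L
  out <- matrix(0, h, w)
  # Shift-and-add: one vectorised accumulation per non-zero coefficient,
  # with index clamping implementing replicate padding exactly.
  for (i in seq_len(kh)) {
    ridx <- pmin(pmax(seq_len(h) + (i - cr), 1L), h)
    for (j in seq_len(kw)) {
      co <- kernel[i, j]
      if (co == 0) next
      cidx <- pmin(pmax(seq_len(w) + (j - cc), 1L), w)
      out <- out + co * img[ridx, cidx, drop = FALSE]
    }
  }
  out
}

#' Classic derivative operator templates
#'
#' Horizontal and vertical coefficient templates with the standard
#' unnormalised integer stencils (Prewitt +/-1, Sobel +/-1 and +/-2,
#' Scharr +/-3 and +/-10). The vertical template is the transpose of the
#' horizontal one, and every template sums to zero so constant images give a
#' zero response.
#'
#' @param name One of `"prewitt"`, `"sobel"`, `"scharr"`.
#' @return List with elements `name`, `horizontal`, `vertical` (3x3 matrices).
#' @export
operator_template <- function(name = c("prewitt", "sobel", "scharr")) {
  if (is.character(name) && length(name) == 1L &&
      !name %in% c("prewitt", "sobel", "scharr")) {
    stop_gradsim(sprintf("Unknown operator '%s'.", name), "gradsim_validation_error")
  }
  name <- match.arg(name)
  gh <- switch(name,
    prewitt = matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3, byrow = TRUE),
    sobel   = matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE),
    scharr  = matrix(c(-3, 0, 3, -10, 0, 10, -3, 0, 3), 3, 3, byrow = TRUE)
  )
  list(name = name, horizontal = gh, vertical = t(gh))
}

#' @rdname operator_template
#' @export
sobel_template <- function() operator_template("sobel")

#' Gradient components by operator template
#'
#' Convolves the image with the horizontal and vertical templates of a classic
#' derivative operator (replicate padding). The horizontal component responds
#' to change along columns (x), the vertical component to change along rows (y).
#'
#' @param img Numeric luminance matrix (0-255 scale), at least 3x3.
#' @param operator `"prewitt"`, `"sobel"` or `"scharr"`.
#' @return List of class `gradient_field` with `horizontal`, `vertical`,
#'   `operator`.
#' @export
gradient_components_template <- function(img, operator = c("prewitt", "sobel", "scharr")) {
  check_gray_image(img)
  tmpl <- operator_template(operator)
  structure(
    list(horizontal = convolve2d(img, tmpl$horizontal),
         vertical = convolve2d(img, tmpl$vertical),
         operator = tmpl$name),
    class = "gradient_field"
  )
}

#' Gradient components by forward differences
#'
#' First-order forward differences: the horizontal component at (x, y) is
#' I(x+1, y) - I(x, y) and the vertical component is I(x, y+1) - I(x, y),
#' with x the column and y the row index. The dangling last column
#' (respectively last row) is set to zero so both components keep the image's
#' shape.
#'
#' @param img Numeric matrix, at least 2x2.
#' @return List of class `gradient_field` with `horizontal`, `vertical`.
#' @examples
#' f <- gradient_components_forward(matrix(c(0, 2, 1, 3), 2, 2))
#' f$horizontal[1, 1]  # 1
#' f$vertical[1, 1]    # 2
#' @export
gradient_components_forward <- function(img) {
  check_gray_image(img, min_dim = 2L)
  h <- nrow(img); w <- ncol(img)
  mh <- matrix(0, h, w)
  mv <- matrix(0, h, w)
  mh[, -w] <- img[, -1, drop = FALSE] - img[, -w, drop = FALSE]
  mv[-h, ] <- img[-1, , drop = FALSE] - img[-h, , drop = FALSE]
  structure(list(horizontal = mh, vertical = mv, operator = "forward"),
            class = "gradient_field")
}

#' Gradient magnitudes
#'
#' `gradient_magnitude_l2()` is the Euclidean magnitude
#' sqrt(M_H^2 + M_V^2); `gradient_magnitude_l1()` is the absolute-sum
#' magnitude |M_H| + |M_V| used by the screen-content quality pipeline.
#'
#' @param field A `gradient_field` (or list with `horizontal`/`vertical`
#'   matrices of equal shape).
#' @return Nonnegative numeric matrix.
#' @export
gradient_magnitude_l2 <- function(field) {
  mh <- field$horizontal; mv <- field$vertical
  check_same_shape(mh, mv, "gradient components")
  sqrt(mh^2 + mv^2)
}

#' @rdname gradient_magnitude_l2
#' @export
gradient_magnitude_l1 <- function(field) {
  mh <- field$horizontal; mv <- field$vertical
  check_same_shape(mh, mv, "gradient components")
  abs(mh) + abs(mv)
}

#' Arctangent gradient direction
#'
#' Per-pixel arctan(M_V / M_H) mapped into `[0, pi)`. Where M_H = 0 and
#' M_V != 0 the direction is pi/2; where both components vanish it is 0 by
#' convention. The quadrant is resolved only up to orientation modulo pi
#' (gradient direction, not heading).
#'
#' @inheritParams gradient_magnitude_l2
#' @return Numeric matrix with values in `[0, pi)`.
#' @export
gradient_direction_arctan <- function(field) {
  mh <- field$horizontal; mv <- field$vertical
  check_same_shape(mh, mv, "gradient components")
  d <- atan(mv / mh)             # (-pi/2, pi/2); NaN where 0/0
  d[mh == 0 & mv != 0] <- pi / 2
  d[mh == 0 & mv == 0] <- 0
  d[d < 0] <- d[d < 0] + pi
  d
}
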