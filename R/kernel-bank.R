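# Directional kernel bank: 12 rotations of a base line kernel at pi/12 steps.
# Convolving the bank with the L1 gradient-magnitude map gives 12 direction
# responses; the strongest response assigns each pixel a quantised direction.

#' Build the 12-direction kernel bank
#'
#' The base kernel L0 is a horizontal line detector: ones along the centre row
#' of an odd square grid, normalised to unit absolute coefficient sum. Kernel
#' L_i is L0 rotated counterclockwise by i*pi/12 (angles measured from the x
#' axis with y up, the usual mathematical convention), resampled by bilinear
#' interpolation and renormalised to unit absolute sum. The lattice-aligned
#' rotations i = 0 and i = 6 use exact grid rotation.
#'
#' @param base_size Odd kernel side length, at least 3. Default 5.
#' @return Object of class `kernel_bank`: list with `kernels` (12 matrices),
#'   `angles` (i*pi/12), `base_size`.
#' @examples
#' bank <- build_kernel_bank(5)
#' length(bank$kernels)      # 12
#' sum(abs(bank$kernels[[4]]))  # 1
#' @export
build_kernel_bank <- function(base_size = 5L) {
  if (!is.numeric(base_size) || length(base_size) != 1L || !is.finite(base_size) ||
      base_size < 3 || base_size %% 2 != 1) {
    stop_gradsim("`base_size` must be an odd integer >= 3.", "gradsim_validation_error")
  }
  base_size <- as.integer(base_size)
  ctr <- (base_size + 1L) %/% 2L
  l0 <- matrix(0, base_size, base_size)
  l0[ctr, ] <- 1
  l0 <- l0 / sum(abs(l0))

  rot90 <- function(k) t(k[nrow(k):1, , drop = FALSE])

  rotate_bilinear <- function(k, theta) {
    n <- nrow(k)
    out <- matrix(0, n, n)
    ct <- cos(theta); st <- sin(theta)
    for (r in seq_len(n)) {
      v <- ctr - r                      # y offset, counterclockwise convention
      for (c in seq_len(n)) {
        u <- c - ctr                    # x offset (right)
        # target cell samples the base kernel at the back-rotated point
        xs <- ct * u + st * v
        ys <- -st * u + ct * v
        x0 <- floor(xs); y0 <- floor(ys)
        fx <- xs - x0; fy <- ys - y0
        acc <- 0
        for (dy in 0:1) {
          for (dx in 0:1) {
            wgt <- (if (dx == 0) 1 - fx else fx) * (if (dy == 0) 1 - fy else fy)
            if (wgt == 0) next
            rr <- ctr - (y0 + dy)
            cc <- x0 + dx + ctr
            if (rr >= 1 && rr <= n && cc >= 1 && cc <= n) {
              acc <- acc + wgt * k[rr, cc]
            }
          }
        }
        out[r, c] <- acc
      }
    }
    out
  }

  kernels <- vector("list", 12L)
  for (i in 0:11) {
    ki <- if (i == 0L) l0
          else if (i == 6L) rot90(l0)
          else rotate_bilinear(l0, i * pi / 12)
    kernels[[i + 1L]] <- ki / sum(abs(ki))
  }
  structure(list(kernels = kernels, angles = (0:11) * pi / 12,
                 base_size = base_size),
            class = "kernel_bank")
}

check_kernel_bank <- function(bank) {
  if (!inherits(bank, "kernel_bank") || length(bank$kernels) != 12L) {
    stop_gradsim("`bank` must be a 12-kernel `kernel_bank` object.",
                 "gradsim_validation_error")
  }
  invisible(bank)
}

#' Directional responses of a gradient-magnitude map
#'
#' Convolves the magnitude map with each of the twelve directional kernels
#' (replicate padding), giving one response layer per direction.
#'
#' @param magnitude Nonnegative numeric matrix, normally the L1
#'   forward-difference gradient magnitude of an image.
#' @param bank A [build_kernel_bank()] result.
#' @return Object of class `direction_responses`: list with `responses`
#'   (12 matrices) and `angles`.
#' @export
direction_responses <- function(magnitude, bank = build_kernel_bank()) {
  check_gray_image(magnitude, arg = "magnitude")
  check_kernel_bank(bank)
  resp <- lapply(bank$kernels, function(k) convolve2d(magnitude, k))
  structure(list(responses = resp, angles = bank$angles),
            class = "direction_responses")
}

#' Quantised direction map from directional responses
#'
#' For each pixel, picks the direction index n whose response is largest
#' (smallest index on ties) and assigns the direction n*pi/12.
#'
#' @param responses A [direction_responses()] result.
#' @return Object of class `direction_map`: list with `direction` (matrix of
#'   values on the grid i*pi/12) and `index` (integer matrix in 0..11).
#' @export
direction_map <- function(responses) {
  if (!inherits(responses, "direction_responses") ||
      length(responses$responses) != 12L) {
    stop_gradsim("`responses` must hold exactly 12 direction layers.",
                 "gradsim_validation_error")
  }
  layers <- responses$responses
  dm <- dim(layers[[1]])
  flat <- vapply(layers, as.vector, numeric(prod(dm)))
  dim(flat) <- c(prod(dm), 12L)   # vapply drops to a vector for 1-pixel maps
  n <- max.col(flat, ties.method = "first") - 1L
  idx <- matrix(n, dm[1], dm[2])
  structure(list(direction = idx * (pi / 12), index = idx),
            class = "direction_map")
}

#' Quantised gradient direction of an image
#'
#' Convenience pipeline: forward-difference components, L1 magnitude,
#' 12-direction responses, argmax direction map.
#'
#' @param img Numeric luminance matrix.
#' @param bank Kernel bank.
#' @return A `direction_map`.
#' @export
image_direction_map <- function(img, bank = build_kernel_bank()) {
  m <- gradient_magnitude_l1(gradient_components_forward(img))
  direction_map(direction_responses(m, bank))
}
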