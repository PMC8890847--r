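# Independent brute-force oracles used to check the vectorised pipeline.

# Nested-loop template application with explicit index clamping (replicate
# padding): the definition the package's convolve2d must reproduce.
oracle_convolve <- function(img, kernel) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  cr <- (kh + 1L) %/% 2L
  cc <- (kw + 1L) %/% 2L
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      acc <- 0
      for (i in seq_len(kh)) {
        for (j in seq_len(kw)) {
          rr <- min(max(r + i - cr, 1L), h)
          cj <- min(max(c + j - cc, 1L), w)
          acc <- acc + kernel[i, j] * img[rr, cj]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# Per-pixel loop over all 12 response layers, smallest index wins ties.
oracle_argmax_index <- function(layers) {
  dm <- dim(layers[[1]])
  out <- matrix(0L, dm[1], dm[2])
  for (r in seq_len(dm[1])) {
    for (c in seq_len(dm[2])) {
      best <- -Inf; besti <- 0L
      for (i in seq_along(layers)) {
        v <- layers[[i]][r, c]
        if (v > best) { best <- v; besti <- i - 1L }
      }
      out[r, c] <- besti
    }
  }
  out
}

oracle_forward_diff <- function(img) {
  h <- nrow(img); w <- ncol(img)
  mh <- matrix(0, h, w); mv <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (c in seq_len(w)) {
      if (c < w) mh[r, c] <- img[r, c + 1] - img[r, c]
      if (r < h) mv[r, c] <- img[r + 1, c] - img[r, c]
    }
  }
  list(horizontal = mh, vertical = mv)
}

oracle_popsd <- function(v) {
  v <- as.vector(v)
  sqrt(sum((v - sum(v) / length(v))^2) / length(v))
}

random_image <- function(h, w, seed) {
  withr::with_seed(seed, matrix(stats::runif(h * w, 0, 255), h, w))
}
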