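# Similarity maps and deviation pooling: DS, MS, GS and the pooled
# DSS/MSS/GSS quality scores.

#' Metric parameters
#'
#' Constants of the similarity maps. `c_d` and `c_m` are positive stability
#' constants on the 0-255 luminance scale (defaults 205 and 160); `alpha` and
#' `beta` weight the direction and magnitude similarity in the joint map
#' (defaults 1 and 1, giving them equal importance; `alpha = 0` reduces the
#' metric to magnitude only, `beta = 0` to direction only). `base_size` is the
#' directional kernel side length.
#'
#' @param c_d,c_m Positive stability constants.
#' @param alpha,beta Nonnegative exponents.
#' @param base_size Odd kernel size for the direction bank.
#' @return List of class `metric_params`.
#' @export
metric_params <- function(c_d = 205, c_m = 160, alpha = 1, beta = 1, base_size = 5L) {
  check_scalar_number(c_d, "c_d", lower = 0, strict = TRUE)
  check_scalar_number(c_m, "c_m", lower = 0, strict = TRUE)
  check_scalar_number(alpha, "alpha", lower = 0)
  check_scalar_number(beta, "beta", lower = 0)
  structure(list(c_d = c_d, c_m = c_m, alpha = alpha, beta = beta,
                 base_size = base_size),
            class = "metric_params")
}

similarity_map <- function(a, b, c0) {
  (2 * a * b + c0) / (a^2 + b^2 + c0)
}

#' Gradient-direction similarity map
#'
#' SSIM-style similarity between two quantised direction maps:
#' DS = (2 D_r D_d + C_d) / (D_r^2 + D_d^2 + C_d), computed on the raw
#' direction values in `[0, pi)`. Values lie in (0, 1] and equal 1 exactly
#' where the directions agree. With `circular = TRUE` the geometric angular
#' distance modulo pi is used instead (a non-default variant in which 0 and
#' 11*pi/12 count as close): DS = C_d / (C_d + delta^2).
#'
#' @param d_ref,d_dist Direction maps ([direction_map()] results or plain
#'   matrices of direction values) of equal shape.
#' @param c_d Positive stability constant (default 205).
#' @param circular Use circular angular distance instead of raw values.
#' @return Numeric matrix in (0, 1].
#' @export
direction_similarity <- function(d_ref, d_dist, c_d = 205, circular = FALSE) {
  dr <- if (inherits(d_ref, "direction_map")) d_ref$direction else d_ref
  dd <- if (inherits(d_dist, "direction_map")) d_dist$direction else d_dist
  check_scalar_number(c_d, "c_d", lower = 0, strict = TRUE)
  if (is.matrix(dr) || is.matrix(dd)) check_same_shape(dr, dd, "direction maps")
  if (circular) {
    delta <- abs(dr - dd)
    delta <- pmin(delta, pi - delta)
    c_d / (c_d + delta^2)
  } else {
    similarity_map(dr, dd, c_d)
  }
}

#' Gradient-magnitude similarity map
#'
#' MS = (2 M_r M_d + C_M) / (M_r^2 + M_d^2 + C_M) on gradient-magnitude maps;
#' values in (0, 1], equal to 1 where the magnitudes agree.
#'
#' @param m_ref,m_dist Nonnegative magnitude maps (or scalars) of equal shape.
#' @param c_m Positive stability constant (default 160).
#' @return Numeric matrix in (0, 1].
#' @export
magnitude_similarity <- function(m_ref, m_dist, c_m = 160) {
  check_scalar_number(c_m, "c_m", lower = 0, strict = TRUE)
  if (is.matrix(m_ref) || is.matrix(m_dist)) {
    check_same_shape(m_ref, m_dist, "magnitude maps")
  }
  similarity_map(m_ref, m_dist, c_m)
}

#' Joint similarity map
#'
#' GS = DS^alpha * MS^beta elementwise. `alpha = 0` reduces to the magnitude
#' term only; `beta = 0` to the direction term only.
#'
#' @param ds_map,ms_map Similarity maps of equal shape.
#' @param alpha,beta Nonnegative exponents.
#' @return Numeric matrix in (0, 1].
#' @export
joint_similarity <- function(ds_map, ms_map, alpha = 1, beta = 1) {
  check_scalar_number(alpha, "alpha", lower = 0)
  check_scalar_number(beta, "beta", lower = 0)
  if (is.matrix(ds_map) || is.matrix(ms_map)) {
    check_same_shape(ds_map, ms_map, "similarity maps")
  }
  ds_map^alpha * ms_map^beta
}

#' Deviation pooling
#'
#' Pools a per-pixel similarity map into a single score: the population
#' standard deviation sqrt(mean((v - mean(v))^2)) over all pixels. Larger
#' pooled deviation means stronger, less uniform degradation, hence worse
#' perceived quality.
#'
#' @param map Nonempty numeric matrix or vector.
#' @return Single nonnegative number.
#' @examples
#' deviation_pool(c(1, 0, 1, 0))  # 0.5
#' @export
deviation_pool <- function(map) {
  v <- as.vector(map)
  if (length(v) == 0L || !is.numeric(v)) {
    stop_gradsim("`map` must be a nonempty numeric map.", "gradsim_validation_error")
  }
  sqrt(mean((v - mean(v))^2))
}

#' Full-reference quality score for an image pair
#'
#' Runs the whole screen-content quality pipeline on a reference/distorted
#' pair: forward-difference L1 gradient magnitudes, 12-direction kernel-bank
#' direction maps, the DS/MS/GS similarity maps, and deviation pooling into
#' DSS, MSS and GSS. Identical images give DSS = MSS = GSS = 0; larger GSS
#' means worse quality. All stages are symmetric in the two images.
#'
#' @param ref,dist Luminance matrices (0-255 scale) of identical shape, at
#'   least 3x3.
#' @param params A [metric_params()] list.
#' @return Object of class `quality_result` with fields `ds_map`, `ms_map`,
#'   `gs_map`, `dss`, `mss`, `gss`, `n_pixels`, `m_ds`, `m_gs`, `params`.
#' @examples
#' img <- make_screen_fixture(height = 48, width = 48, seed = 1)
#' noisy <- apply_distortion(img, "gaussian_noise", level = 15, seed = 2)
#' res <- score_pair(img, noisy)
#' res$gss
#' @export
score_pair <- function(ref, dist, params = metric_params()) {
  check_gray_image(ref, arg = "ref")
  check_gray_image(dist, arg = "dist")
  check_same_shape(ref, dist, "images")
  if (!inherits(params, "metric_params")) {
    params <- do.call(metric_params, as.list(params))
  }
  bank <- build_kernel_bank(params$base_size)

  m_ref <- gradient_magnitude_l1(gradient_components_forward(ref))
  m_dist <- gradient_magnitude_l1(gradient_components_forward(dist))
  d_ref <- direction_map(direction_responses(m_ref, bank))
  d_dist <- direction_map(direction_responses(m_dist, bank))

  ds <- direction_similarity(d_ref, d_dist, params$c_d)
  ms <- magnitude_similarity(m_ref, m_dist, params$c_m)
  gs <- joint_similarity(ds, ms, params$alpha, params$beta)

  structure(
    list(ds_map = ds, ms_map = ms, gs_map = gs,
         dss = deviation_pool(ds), mss = deviation_pool(ms),
         gss = deviation_pool(gs),
         n_pixels = length(gs), m_ds = mean(ds), m_gs = mean(gs),
         params = params),
    class = "quality_result"
  )
}

#' @export
print.quality_result <- function(x, ...) {
  cat(sprintf("Gradient-similarity quality score (%d pixels)\n", x$n_pixels))
  cat(sprintf("  DSS: %.6f   MSS: %.6f   GSS: %.6f\n", x$dss, x$mss, x$gss))
  cat(sprintf("  mean DS: %.5f   mean GS: %.5f\n", x$m_ds, x$m_gs))
  invisible(x)
}

#' Score a batch of image pairs
#'
#' Takes a data frame with `ref` and `dist` columns (file paths readable by
#' [load_image()]) and returns it with `dss`, `mss`, `gss`, `n_pixels`
#' columns appended, one row per pair.
#'
#' @param pairs Data frame with character columns `ref` and `dist`.
#' @param params A [metric_params()] list.
#' @return A tibble.
#' @export
score_batch <- function(pairs, params = metric_params()) {
  if (!is.data.frame(pairs) || !all(c("ref", "dist") %in% names(pairs))) {
    stop_gradsim("`pairs` must be a data frame with `ref` and `dist` columns.",
                 "gradsim_validation_error")
  }
  scores <- purrr::map2(pairs$ref, pairs$dist, function(r, d) {
    res <- score_pair(load_image(r), load_image(d), params)
    tibble::tibble(dss = res$dss, mss = res$mss, gss = res$gss,
                   n_pixels = res$n_pixels)
  })
  dplyr::bind_cols(tibble::as_tibble(pairs), dplyr::bind_rows(scores))
}
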