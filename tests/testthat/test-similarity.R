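test_that("similarity maps hit their worked scalar values and symmetries", {
  # direction similarity of 0 vs 11*pi/12 with C_d = 205
  d <- 11 * pi / 12
  expect_equal(direction_similarity(matrix(0), matrix(d))[1, 1],
               205 / (d^2 + 205), tolerance = 1e-12)
  expect_equal(205 / (d^2 + 205), 0.96112, tolerance = 1e-5)
  # magnitude similarity of 10 vs 5 with C_M = 160
  expect_equal(magnitude_similarity(matrix(10), matrix(5))[1, 1], 260 / 285,
               tolerance = 1e-12)
  expect_equal(260 / 285, 0.91228, tolerance = 1e-5)
  # equality gives exactly 1; symmetry holds for random maps
  a <- random_image(5, 5, seed = 1) * pi / 255
  b <- random_image(5, 5, seed = 2) * pi / 255
  expect_true(all(direction_similarity(a, a) == 1))
  expect_equal(direction_similarity(a, b), direction_similarity(b, a))
  expect_equal(magnitude_similarity(a, b), magnitude_similarity(b, a))
  expect_true(all(direction_similarity(a, b) > 0 & direction_similarity(a, b) <= 1))
  expect_error(direction_similarity(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "gradsim_validation_error")
  expect_error(magnitude_similarity(matrix(1), matrix(1), c_m = 0),
               class = "gradsim_validation_error")
})

test_that("circular direction similarity treats 0 and 11*pi/12 as close", {
  raw <- direction_similarity(matrix(0), matrix(11 * pi / 12))
  circ <- direction_similarity(matrix(0), matrix(11 * pi / 12), circular = TRUE)
  expect_gt(circ[1, 1], raw[1, 1])
  expect_equal(direction_similarity(matrix(0.4), matrix(0.4), circular = TRUE)[1, 1], 1)
})

test_that("joint similarity is the weighted product with exact reductions", {
  ds <- matrix(0.9); ms <- matrix(0.8)
  expect_equal(joint_similarity(ds, ms)[1, 1], 0.72)
  dsm <- random_image(4, 4, seed = 5) / 300 + 0.1
  msm <- random_image(4, 4, seed = 6) / 300 + 0.1
  expect_equal(joint_similarity(dsm, msm, alpha = 0, beta = 2), msm^2)
  expect_equal(joint_similarity(dsm, msm, alpha = 3, beta = 0), dsm^3)
  expect_error(joint_similarity(dsm, msm, alpha = -1),
               class = "gradsim_validation_error")
})

test_that("deviation pooling is the population standard deviation over pixels", {
  expect_equal(deviation_pool(matrix(0.5, 3, 3)), 0)
  expect_equal(deviation_pool(c(1, 0, 1, 0)), 0.5)
  v <- random_image(6, 6, seed = 9)
  expect_equal(deviation_pool(v), oracle_popsd(v))
  # invariant under pixel permutation
  expect_equal(deviation_pool(v), deviation_pool(sample(as.vector(v))))
  expect_error(deviation_pool(numeric(0)), class = "gradsim_validation_error")
})

test_that("score_pair is zero on identical images and symmetric in its arguments", {
  img <- make_screen_fixture(48, 48, seed = 1)
  self <- score_pair(img, img)
  expect_identical(self$gss, 0)
  expect_identical(self$dss, 0)
  expect_identical(self$mss, 0)
  expect_true(all(self$gs_map == 1))
  noisy <- apply_distortion(img, "gaussian_noise", 20, seed = 2)
  ab <- score_pair(img, noisy)
  ba <- score_pair(noisy, img)
  expect_equal(ab$gss, ba$gss)
  expect_equal(ab$dss, ba$dss)
  expect_gt(ab$gss, 0)
  expect_identical(ab$n_pixels, length(img))
  expect_error(score_pair(img, img[1:40, ]), class = "gradsim_validation_error")
})

test_that("with beta = 0 the GSS ranking of distorted variants equals the DSS ranking", {
  ref <- make_screen_fixture(64, 64, seed = 4)
  variants <- list(
    apply_distortion(ref, "gaussian_noise", 8, seed = 1),
    apply_distortion(ref, "gaussian_blur", 1.5),
    apply_distortion(ref, "blockiness", 60),
    apply_distortion(ref, "gaussian_noise", 35, seed = 2)
  )
  p_dir <- metric_params(alpha = 1, beta = 0)
  scores <- purrr::map(variants, ~ score_pair(ref, .x, p_dir))
  gss <- purrr::map_dbl(scores, "gss")
  dss <- purrr::map_dbl(scores, "dss")
  expect_equal(gss, dss)                 # GS = DS when beta = 0
  expect_identical(order(gss), order(dss))
})

test_that("quality_result tidiers and batch scoring return well-formed tibbles", {
  ref <- make_screen_fixture(32, 32, seed = 2)
  dst <- apply_distortion(ref, "gaussian_noise", 15, seed = 1)
  res <- score_pair(ref, dst)
  g <- glance(res)
  expect_s3_class(g, "tbl_df")
  expect_identical(g$gss, res$gss)
  td <- tidy(res)
  expect_identical(td$pooled_deviation, c(res$dss, res$mss, res$gss))

  d <- withr::local_tempdir()
  rp <- file.path(d, "ref.png"); dp <- file.path(d, "dist.png")
  write_image_png(ref, rp); write_image_png(dst, dp)
  out <- score_batch(tibble::tibble(ref = rp, dist = dp))
  expect_identical(nrow(out), 1L)
  expect_true(all(c("dss", "mss", "gss", "n_pixels") %in% names(out)))
  expect_equal(out$gss, score_pair(load_image(rp), load_image(dp))$gss)
})
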