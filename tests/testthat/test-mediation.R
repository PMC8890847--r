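test_that("published correlation matrices are valid and consistent", {
  r4 <- survey_correlation("subscales")
  r3 <- survey_correlation("composite")
  for (r in list(r4, r3)) {
    expect_equal(r, t(r))
    expect_equal(unname(diag(r)), rep(1, ncol(r)))
    expect_gt(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_equal(r4["health_literacy", "depression"], -0.374)
  expect_equal(r3["depression", "health_literacy"], -0.374)
  # composite correlations derived from the subscale matrix
  norm <- sqrt(2 * (1 + 0.610))
  expect_equal(r3["health_literacy", "daily_activity"], (0.398 + 0.563) / norm)
  expect_equal(r3["depression", "daily_activity"], (-0.200 - 0.298) / norm)
})

test_that("survey simulator reproduces the requested correlation structure", {
  # identity correlation: near-independent columns
  id <- diag(3); dimnames(id) <- list(letters[1:3], letters[1:3])
  tab <- simulate_survey(1e5, id, seed = 1)
  r <- stats::cor(as.matrix(tab))
  expect_lt(max(abs(r[upper.tri(r)])), 0.02)
  # published matrix: depression/health-literacy r within 0.01 at n = 1e5
  tab2 <- simulate_survey(1e5, survey_correlation("subscales"), seed = 2)
  expect_equal(stats::cor(tab2$depression, tab2$health_literacy), -0.374,
               tolerance = 0.03)
  # determinism and rescaling
  expect_identical(simulate_survey(200, seed = 5), simulate_survey(200, seed = 5))
  sc <- simulate_survey(5000, survey_correlation("subscales"), seed = 3,
                        scales = survey_scales())
  expect_equal(mean(sc$health_literacy), 57.60, tolerance = 1)
  expect_equal(stats::sd(sc$health_literacy), 21.96, tolerance = 1)
  expect_false(attr(sc, "standardized"))
  # non-PSD matrix rejected with the offending eigenvalue named
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  colnames(bad) <- rownames(bad) <- letters[1:3]
  expect_error(simulate_survey(100, bad), "eigenvalue",
               class = "gradsim_validation_error")
})

test_that("pearson_matrix matches the closed-form correlation and flags degenerate input", {
  tab <- simulate_survey(200, seed = 7)
  pm <- pearson_matrix(tab)
  x <- as.matrix(tab)
  # brute-force covariance oracle
  manual <- stats::cov(x) / (apply(x, 2, stats::sd) %o% apply(x, 2, stats::sd))
  expect_equal(unname(pm$r), unname(manual))
  expect_equal(diag(pm$r), setNames(rep(1, 3), colnames(x)))
  # y = -x exactly
  d <- data.frame(x = 1:10, y = -(1:10))
  expect_equal(pearson_matrix(d)$r["x", "y"], -1)
  expect_error(pearson_matrix(data.frame(a = rep(1, 10), b = 1:10)),
               class = "gradsim_validation_error")
  td <- tidy(pm)
  expect_identical(nrow(td), 3L)
  expect_true(all(td$p_value >= 0 & td$p_value <= 1))
})

test_that("standardized OLS reduces to the Pearson correlation in simple regression", {
  tab <- simulate_survey(500, seed = 11)
  fit <- ols_standardized(tab, "daily_activity", "depression")
  expect_equal(fit$coefficients$beta,
               stats::cor(tab$daily_activity, tab$depression), tolerance = 1e-12)
  # exact fit: y = x
  d <- data.frame(y = 1:20 + 0, x = 1:20 + 0)
  f2 <- suppressWarnings(ols_standardized(d, "y", "x"))
  expect_equal(f2$coefficients$beta, 1)
  expect_equal(f2$r2, 1)
  expect_equal(f2$adj_r2, 1)
  # null case
  d0 <- withr::with_seed(3, data.frame(y = stats::rnorm(5000), x = stats::rnorm(5000)))
  expect_lt(abs(ols_standardized(d0, "y", "x")$coefficients$beta), 0.05)
  # collinear predictors rejected
  dc <- data.frame(y = stats::rnorm(50), a = 1:50 + 0, b = 2 * (1:50) + 0)
  expect_error(ols_standardized(dc, "y", c("a", "b")),
               class = "gradsim_validation_error")
  expect_error(ols_standardized(d[1:2, ], "y", "x"),
               class = "gradsim_validation_error")
})

test_that("three-step mediation: exact decomposition and R2 monotonicity", {
  tab <- simulate_mediation(382, seed = 21)
  fit <- baron_kenny(tab)
  p <- fit$paths
  # OLS identity on standardized variables: c = c' + a*b, exact per sample
  expect_equal(unname(p["c"]), unname(p["c_prime"] + p["a"] * p["b"]),
               tolerance = 1e-9)
  expect_lte(fit$steps$step1$adj_r2, fit$steps$step1$r2)
  expect_lte(fit$steps$step3$adj_r2, fit$steps$step3$r2)
  expect_gte(fit$steps$step3$r2, fit$steps$step1$r2)
  expect_equal(fit$indirect, unname(p["a"] * p["b"]))
  g <- glance(fit)
  expect_identical(g$verdict, fit$verdict)
  td <- tidy(fit)
  expect_identical(td$path, c("c", "a", "c_prime", "b"))
  expect_true(all(c("b", "beta", "se", "t_value", "p_value") %in% names(td)))
})

test_that("mediation verdicts match the generating mechanism", {
  # no mediator path: a = 0 -> no mediation
  none <- baron_kenny(simulate_mediation(2e4, a = 0, b = 0.5, c_prime = -0.4,
                                         seed = 1))
  expect_identical(none$verdict, "none")
  # no direct effect: c' = 0 -> full mediation at large n
  full <- baron_kenny(simulate_mediation(1e5, a = -0.5, b = 0.5, c_prime = 0,
                                         seed = 2))
  expect_identical(full$verdict, "full")
  # the published path model gives partial mediation
  part <- baron_kenny(simulate_mediation(1e5, seed = 3))
  expect_identical(part$verdict, "partial")
  expect_error(simulate_mediation(100, a = 0.9, b = 0.9, c_prime = 0.9),
               class = "gradsim_validation_error")
  expect_error(baron_kenny(data.frame(x = 1:5)), class = "gradsim_validation_error")
})

test_that("estimates concentrate on the generating paths as n grows", {
  est <- function(n, reps, seed0) {
    m <- vapply(seq_len(reps), function(i) {
      f <- baron_kenny(simulate_mediation(n, seed = seed0 + i))
      f$paths[c("a", "b", "c_prime")]
    }, numeric(3))
    rowMeans(m)
  }
  truth <- c(a = -0.446, b = 0.482, c_prime = -0.388)
  small <- est(382, 40, 1000)
  big <- est(1e4, 10, 2000)
  expect_equal(unname(small), unname(truth), tolerance = 0.05)
  expect_equal(unname(big), unname(truth), tolerance = 0.02)
})
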