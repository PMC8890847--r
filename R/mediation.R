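# Three-step (Baron-Kenny) mediation analysis of depression, health literacy
# and daily-activity ability, plus a multivariate-normal survey simulator
# matching the published correlation structure, for parameter-recovery
# studies when the raw survey data are unavailable.

#' Published survey correlation structure
#'
#' Correlation matrix of the survey variables. `"subscales"` returns the full
#' 4x4 published matrix over basic daily living ability, functional daily
#' living ability, health literacy and depression. `"composite"` collapses
#' the two daily-living subscales into one equally-weighted composite
#' (`daily_activity`), with its correlations derived analytically from the
#' 4x4 matrix, and orders columns depression, health_literacy,
#' daily_activity.
#'
#' @param mode `"composite"` (3x3, default) or `"subscales"` (4x4).
#' @return Named correlation matrix.
#' @export
survey_correlation <- function(mode = c("composite", "subscales")) {
  mode <- match.arg(mode)
  vars4 <- c("basic_adl", "functional_adl", "health_literacy", "depression")
  r4 <- diag(4)
  dimnames(r4) <- list(vars4, vars4)
  r4["basic_adl", "functional_adl"] <- 0.610
  r4["basic_adl", "health_literacy"] <- 0.398
  r4["functional_adl", "health_literacy"] <- 0.563
  r4["basic_adl", "depression"] <- -0.200
  r4["functional_adl", "depression"] <- -0.298
  r4["health_literacy", "depression"] <- -0.374
  r4[lower.tri(r4)] <- t(r4)[lower.tri(r4)]
  if (mode == "subscales") return(r4)
  # composite = (basic + functional) / sqrt(2 (1 + r_bf)):
  # corr(composite, z) = (r_bz + r_fz) / sqrt(2 (1 + r_bf))
  norm <- sqrt(2 * (1 + r4["basic_adl", "functional_adl"]))
  r_da_hl <- (r4["basic_adl", "health_literacy"] +
                r4["functional_adl", "health_literacy"]) / norm
  r_da_dep <- (r4["basic_adl", "depression"] +
                 r4["functional_adl", "depression"]) / norm
  vars3 <- c("depression", "health_literacy", "daily_activity")
  r3 <- diag(3)
  dimnames(r3) <- list(vars3, vars3)
  r3["depression", "health_literacy"] <- -0.374
  r3["depression", "daily_activity"] <- r_da_dep
  r3["health_literacy", "daily_activity"] <- r_da_hl
  r3[lower.tri(r3)] <- t(r3)[lower.tri(r3)]
  r3
}

#' Published survey score scales
#'
#' Means and standard deviations of the published total scores (health
#' literacy 57.60 +/- 21.96), for rescaling standardized simulated draws to
#' the instrument scale. Variables without a published scale keep mean 0,
#' sd 1.
#'
#' @return Tibble with columns `variable`, `mean`, `sd`.
#' @export
survey_scales <- function() {
  tibble::tibble(
    variable = c("health_literacy"),
    mean = c(57.60),
    sd = c(21.96)
  )
}

#' Simulate a survey table from a correlation matrix
#'
#' Draws multivariate standardized normal subjects with the requested
#' correlation structure; deterministic for a fixed seed. Optionally rescales
#' named columns to instrument means/SDs.
#'
#' @param n Number of subjects, at least 10.
#' @param correlation Symmetric positive-semidefinite correlation matrix with
#'   unit diagonal and column names; defaults to
#'   `survey_correlation("composite")`.
#' @param seed Integer RNG seed.
#' @param scales Optional data frame with `variable`, `mean`, `sd` columns
#'   (e.g. [survey_scales()]); matching columns are rescaled.
#' @return Tibble with one column per variable; attribute `standardized` is
#'   `TRUE` when no rescaling was applied.
#' @export
simulate_survey <- function(n, correlation = survey_correlation("composite"),
                            seed = 1L, scales = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 10) {
    stop_gradsim("`n` must be a single count >= 10.", "gradsim_validation_error")
  }
  p <- ncol(correlation)
  if (!is.matrix(correlation) || nrow(correlation) != p ||
      max(abs(correlation - t(correlation))) > 1e-8 ||
      max(abs(diag(correlation) - 1)) > 1e-8) {
    stop_gradsim("`correlation` must be a symmetric matrix with unit diagonal.",
                 "gradsim_validation_error")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop_gradsim(sprintf(
      "`correlation` is not positive semi-definite (smallest eigenvalue %.6f).",
      min(ev)), "gradsim_validation_error")
  }
  vars <- colnames(correlation)
  if (is.null(vars)) vars <- paste0("v", seq_len(p))
  draws <- withr::with_seed(seed,
    MASS::mvrnorm(n = n, mu = rep(0, p), Sigma = correlation))
  colnames(draws) <- vars
  out <- tibble::as_tibble(draws)
  standardized <- TRUE
  if (!is.null(scales)) {
    for (i in seq_len(nrow(scales))) {
      v <- scales$variable[i]
      if (v %in% names(out)) {
        out[[v]] <- out[[v]] * scales$sd[i] + scales$mean[i]
        standardized <- FALSE
      }
    }
  }
  attr(out, "standardized") <- standardized
  out
}

#' Simulate survey data from a mediation path model
#'
#' Generates standardized trivariate data under the linear path model
#' mediator = a * predictor + e1, outcome = c' * predictor + b * mediator +
#' e2, with independent normal errors scaled so every variable has unit
#' population variance. The implied total effect is c = c' + a b. Defaults
#' are the published path estimates (depression -> health literacy
#' a = -0.446; health literacy -> daily activity b = 0.482; direct effect
#' c' = -0.388).
#'
#' @param n Number of subjects.
#' @param a,b,c_prime Standardized path coefficients.
#' @param seed Integer RNG seed.
#' @return Tibble with columns `depression`, `health_literacy`,
#'   `daily_activity`; attributes `paths` (the generating values and implied
#'   total effect).
#' @export
simulate_mediation <- function(n, a = -0.446, b = 0.482, c_prime = -0.388,
                               seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || n < 10) {
    stop_gradsim("`n` must be a single count >= 10.", "gradsim_validation_error")
  }
  s1_sq <- 1 - a^2
  s2_sq <- 1 - (c_prime^2 + b^2 + 2 * a * b * c_prime)
  if (s1_sq <= 0 || s2_sq <= 0) {
    stop_gradsim("Path coefficients imply non-positive residual variance; the standardized model is infeasible.",
                 "gradsim_validation_error")
  }
  withr::with_seed(seed, {
    x <- rnorm(n)
    m <- a * x + sqrt(s1_sq) * rnorm(n)
    y <- c_prime * x + b * m + sqrt(s2_sq) * rnorm(n)
    out <- tibble::tibble(depression = x, health_literacy = m,
                          daily_activity = y)
  })
  attr(out, "paths") <- c(a = a, b = b, c_prime = c_prime, c = c_prime + a * b)
  attr(out, "standardized") <- TRUE
  out
}

#' Pearson correlation matrix with p-values
#'
#' Pairwise Pearson correlations over the numeric columns of a data frame,
#' with two-sided p-values from the t transform on n - 2 degrees of freedom.
#'
#' @param data Data frame with at least 4 rows; all columns numeric with
#'   nonzero variance.
#' @return Object of class `pearson_matrix` with `r`, `p`, `n`. `tidy()`
#'   returns one row per variable pair.
#' @export
pearson_matrix <- function(data) {
  if (!is.data.frame(data) || nrow(data) < 4L) {
    stop_gradsim("`data` must be a data frame with at least 4 rows.",
                 "gradsim_validation_error")
  }
  x <- as.matrix(data)
  if (!is.numeric(x)) {
    stop_gradsim("All columns must be numeric.", "gradsim_validation_error")
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop_gradsim(sprintf("Zero-variance column(s): %s.",
                         paste(colnames(x)[sds == 0], collapse = ", ")),
                 "gradsim_validation_error")
  }
  n <- nrow(x)
  r <- stats::cor(x)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n), class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson correlations (n = %d):\n", x$n))
  print(round(x$r, digits))
  invisible(x)
}

#' @export
tidy.pearson_matrix <- function(x, ...) {
  nm <- colnames(x$r)
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble::tibble(var1 = nm[idx[, 1]], var2 = nm[idx[, 2]],
                 r = x$r[idx], p_value = x$p[idx], n = x$n)
}

#' Ordinary least squares on standardized variables
#'
#' Standardizes the response and predictor columns (sample mean 0, sd 1),
#' fits OLS, and reports both the raw-scale coefficients (B) and the
#' standardized coefficients (beta) with their standard errors, t and p
#' values, plus R^2 and adjusted R^2. In simple regression the standardized
#' coefficient equals the Pearson correlation.
#'
#' @param data Data frame containing the variables.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names.
#' @return List of class `ols_fit` with `coefficients` (tibble: term, b,
#'   beta, se, t_value, p_value), `r2`, `adj_r2`, `f_value`, `n`.
#' @export
ols_standardized <- function(data, response, predictors) {
  cols <- c(response, predictors)
  if (!all(cols %in% names(data))) {
    stop_gradsim(sprintf("Missing columns: %s.",
                         paste(setdiff(cols, names(data)), collapse = ", ")),
                 "gradsim_validation_error")
  }
  n <- nrow(data)
  if (n <= length(predictors) + 1L) {
    stop_gradsim("Too few rows for the requested regression.",
                 "gradsim_validation_error")
  }
  d <- data[cols]
  if (length(predictors) > 1L) {
    xm <- as.matrix(d[predictors])
    if (kappa(stats::cor(xm)) > 1e8) {
      stop_gradsim("Predictors are (near-)collinear.", "gradsim_validation_error")
    }
  }
  zd <- as.data.frame(lapply(d, function(v) as.vector(scale(v))))
  fml <- stats::as.formula(paste(response, "~",
                                 paste(predictors, collapse = " + ")))
  fit_raw <- stats::lm(fml, data = d)
  fit_std <- stats::lm(fml, data = zd)
  sm <- summary(fit_std)
  co <- sm$coefficients[predictors, , drop = FALSE]
  res <- list(
    coefficients = tibble::tibble(
      term = predictors,
      b = unname(coef(fit_raw)[predictors]),
      beta = unname(co[, 1]),
      se = unname(co[, 2]),
      t_value = unname(co[, 3]),
      p_value = unname(co[, 4])
    ),
    r2 = sm$r.squared,
    adj_r2 = sm$adj.r.squared,
    f_value = unname(sm$fstatistic["value"]),
    n = n
  )
  structure(res, class = "ols_fit")
}

#' Three-step mediation analysis
#'
#' The classic three-step test of whether a mediator transmits the effect of
#' a predictor on an outcome. Step 1 regresses the outcome on the predictor
#' (total effect c); step 2 the mediator on the predictor (path a); step 3
#' the outcome on predictor and mediator jointly (direct effect c' and path
#' b). All coefficients are reported standardized (and raw). The verdict is
#' `"partial"` when a, b and c are all significant and |c'| < |c| with c'
#' still significant, `"full"` when c' loses significance, and `"none"` when
#' any required path is not significant. The indirect effect a*b is reported
#' descriptively; on any one sample the OLS identity c = c' + a*b holds
#' exactly for standardized fits.
#'
#' @param data Data frame with the three variables.
#' @param outcome,mediator,predictor Column names (defaults: daily_activity,
#'   health_literacy, depression).
#' @param alpha_level Two-sided significance level for the verdict
#'   (default 0.05).
#' @return Object of class `mediation_fit` with per-step `ols_fit`s, the
#'   paths, `indirect`, `r2_change`, `verdict`. `tidy()` gives one row per
#'   path; `glance()` a one-row summary.
#' @examples
#' d <- simulate_mediation(382, seed = 1)
#' fit <- baron_kenny(d)
#' glance(fit)
#' @export
baron_kenny <- function(data, outcome = "daily_activity",
                        mediator = "health_literacy",
                        predictor = "depression", alpha_level = 0.05) {
  if (!all(c(outcome, mediator, predictor) %in% names(data))) {
    stop_gradsim(sprintf("`data` must contain columns '%s', '%s', '%s'.",
                         outcome, mediator, predictor),
                 "gradsim_validation_error")
  }
  if (nrow(data) < 4L) {
    stop_gradsim("Too few subjects for the three-step analysis.",
                 "gradsim_validation_error")
  }
  step1 <- ols_standardized(data, outcome, predictor)
  step2 <- ols_standardized(data, mediator, predictor)
  step3 <- ols_standardized(data, outcome, c(predictor, mediator))

  c_hat <- step1$coefficients$beta[1]
  a_hat <- step2$coefficients$beta[1]
  c_prime_hat <- step3$coefficients$beta[step3$coefficients$term == predictor]
  b_hat <- step3$coefficients$beta[step3$coefficients$term == mediator]

  p_c <- step1$coefficients$p_value[1]
  p_a <- step2$coefficients$p_value[1]
  p_cp <- step3$coefficients$p_value[step3$coefficients$term == predictor]
  p_b <- step3$coefficients$p_value[step3$coefficients$term == mediator]

  verdict <- if (p_c < alpha_level && p_a < alpha_level && p_b < alpha_level) {
    if (p_cp >= alpha_level) "full"
    else if (abs(c_prime_hat) < abs(c_hat)) "partial"
    else "none"
  } else "none"

  structure(
    list(steps = list(step1 = step1, step2 = step2, step3 = step3),
         paths = c(c = c_hat, a = a_hat, b = b_hat, c_prime = c_prime_hat),
         indirect = a_hat * b_hat,
         r2_change = step3$r2 - step1$r2,
         alpha_level = alpha_level,
         variables = c(outcome = outcome, mediator = mediator,
                       predictor = predictor),
         verdict = verdict),
    class = "mediation_fit"
  )
}

#' @export
print.mediation_fit <- function(x, ...) {
  v <- x$variables
  cat(sprintf("Three-step mediation: %s -> %s -> %s\n",
              v["predictor"], v["mediator"], v["outcome"]))
  cat(sprintf("  c = %.3f, a = %.3f, b = %.3f, c' = %.3f (indirect a*b = %.3f)\n",
              x$paths["c"], x$paths["a"], x$paths["b"], x$paths["c_prime"],
              x$indirect))
  cat(sprintf("  R2: step 1 = %.3f, step 3 = %.3f (change %.3f)\n",
              x$steps$step1$r2, x$steps$step3$r2, x$r2_change))
  cat(sprintf("  Verdict: %s mediation (alpha = %g)\n", x$verdict, x$alpha_level))
  invisible(x)
}

#' @export
tidy.mediation_fit <- function(x, ...) {
  v <- x$variables
  rows <- list(
    c(step = 1L, path = "c", resp = v[["outcome"]], term = v[["predictor"]]),
    c(step = 2L, path = "a", resp = v[["mediator"]], term = v[["predictor"]]),
    c(step = 3L, path = "c_prime", resp = v[["outcome"]], term = v[["predictor"]]),
    c(step = 3L, path = "b", resp = v[["outcome"]], term = v[["mediator"]])
  )
  fits <- list(x$steps$step1, x$steps$step2, x$steps$step3, x$steps$step3)
  purrr::map2_dfr(rows, fits, function(rw, f) {
    co <- f$coefficients[f$coefficients$term == rw[["term"]], ]
    tibble::tibble(step = as.integer(rw[["step"]]), path = rw[["path"]],
                   response = rw[["resp"]], term = rw[["term"]],
                   b = co$b, beta = co$beta, se = co$se,
                   t_value = co$t_value, p_value = co$p_value,
                   r2 = f$r2, adj_r2 = f$adj_r2, f_value = f$f_value)
  })
}

#' @export
glance.mediation_fit <- function(x, ...) {
  tibble::tibble(
    c = unname(x$paths["c"]), a = unname(x$paths["a"]),
    b = unname(x$paths["b"]), c_prime = unname(x$paths["c_prime"]),
    indirect = x$indirect,
    r2_step1 = x$steps$step1$r2, adj_r2_step1 = x$steps$step1$adj_r2,
    r2_step3 = x$steps$step3$r2, adj_r2_step3 = x$steps$step3$adj_r2,
    r2_change = x$r2_change, verdict = x$verdict,
    nobs = x$steps$step1$n
  )
}
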