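# Ordinary least squares with inference, the three-model suite, and the
# Holm step-down multiple-testing correction. Fitting is delegated to
# stats::lm behind a stable interface; coefficients are raw slopes in
# natural units (degrees per year, degrees per mm), with standardized
# betas available behind a flag.

#' Fit an ordinary least-squares model on a cohort table
#'
#' Complete-case least squares of `response` on `predictors` with an
#' intercept, returning estimates, standard errors, t statistics,
#' two-sided p-values (t distribution, `n - p - 1` df), the coefficient of
#' determination and its adjusted version.
#'
#' @param table a `cohort_table` (or any data frame).
#' @param response name of the response column.
#' @param predictors character vector of predictor column names.
#' @param standardize if `TRUE`, response and predictors are scaled to
#'   unit variance first, so slopes are standardized betas.
#' @return an object of class `"ols_fit"`.
#' @export
fit_ols <- function(table, response, predictors, standardize = FALSE) {
  df <- as.data.frame(table)[, c(response, predictors), drop = FALSE]
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  p <- length(predictors)
  n <- nrow(df)
  if (n < p + 2L)
    stop("too few complete cases (", n, ") to fit ", p,
         " predictor(s); need at least ", p + 2L, call. = FALSE)
  if (standardize)
    df[] <- lapply(df, function(v) as.numeric(scale(v)))
  fml <- stats::reformulate(predictors, response = response)
  fit <- stats::lm(fml, data = df)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design: predictor(s) ",
         paste(bad, collapse = ", "),
         " are collinear with the remaining terms", call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(term = rownames(ct), estimate = ct[, 1L],
                      se = ct[, 2L], t = ct[, 3L], p = ct[, 4L],
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(response_name = response, predictor_names = predictors,
                 coefficients = coefs, r2 = sm$r.squared,
                 adj_r2 = sm$adj.r.squared, n_used = n,
                 residual_sd = sm$sigma, standardized = standardize,
                 lm = fit),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, digits = 4L, ...) {
  cat("Least-squares fit: ", x$response_name, " ~ ",
      paste(x$predictor_names, collapse = " + "),
      if (x$standardized) "  (standardized)", "\n", sep = "")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  cat(sprintf("R2 = %.*g, adjusted R2 = %.*g, residual sd = %.*g, n = %d\n",
              digits, x$r2, digits, x$adj_r2, digits, x$residual_sd,
              x$n_used))
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
predict.ols_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$lm)
  else stats::predict(object$lm, newdata = as.data.frame(newdata), ...)
}

#' @export
residuals.ols_fit <- function(object, ...) stats::residuals(object$lm)

#' Holm step-down adjustment of p-values
#'
#' Step-down familywise error control: sort ascending, multiply the i-th
#' smallest by `m - i + 1`, enforce a monotone cumulative maximum, cap at
#' 1, and return in the original order. Equals Bonferroni for the smallest
#' p-value and is uniformly more powerful overall.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order (names preserved).
#' @export
holm_adjust <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1))
    stop("p_values must be numeric in [0, 1] with no missing values",
         call. = FALSE)
  stats::p.adjust(p_values, method = "holm")
}

#' Fit the three-model suite of the lateral-angle analysis
#'
#' Fits (a) lateral angle on age, (b) the simple angle-breadth regression
#' in both directions (their R-squared is direction-invariant and is
#' reported once, with both slopes), and (c) lateral angle on age and
#' biauricular breadth jointly, the covariate-adjusted model that
#' separates the age effect from the breadth effect. The suite's primary
#' slope p-values are Holm-adjusted.
#'
#' @param table a `cohort_table`.
#' @param standardize passed to [fit_ols()].
#' @return an object of class `"model_suite"` with components `model_a`,
#'   `model_b` (list `angle_on_aub`, `aub_on_angle`, `r2`), `model_c`, and
#'   `holm_adjusted_p`.
#' @export
model_suite <- function(table, standardize = FALSE) {
  stopifnot(inherits(table, "cohort_table"))
  model_a <- fit_ols(table, "lateral_angle_deg", "age_years",
                     standardize = standardize)
  b1 <- fit_ols(table, "lateral_angle_deg", "aub_mm",
                standardize = standardize)
  b2 <- fit_ols(table, "aub_mm", "lateral_angle_deg",
                standardize = standardize)
  model_c <- fit_ols(table, "lateral_angle_deg", c("age_years", "aub_mm"),
                     standardize = standardize)
  slope_p <- function(fit, term) {
    fit$coefficients$p[fit$coefficients$term == term]
  }
  raw_p <- c(angle_vs_age = slope_p(model_a, "age_years"),
             angle_vs_aub = slope_p(b1, "aub_mm"),
             adjusted_age = slope_p(model_c, "age_years"),
             adjusted_aub = slope_p(model_c, "aub_mm"))
  structure(list(model_a = model_a,
                 model_b = list(angle_on_aub = b1, aub_on_angle = b2,
                                r2 = b1$r2),
                 model_c = model_c,
                 holm_adjusted_p = holm_adjust(raw_p),
                 raw_p = raw_p),
            class = "model_suite")
}

#' @export
print.model_suite <- function(x, digits = 4L, ...) {
  cat("== Model A: lateral angle ~ age ==\n")
  print(x$model_a, digits = digits)
  cat("\n== Model B: angle <-> breadth (direction-invariant R2 = ",
      format(x$model_b$r2, digits = digits), ") ==\n", sep = "")
  print(x$model_b$angle_on_aub, digits = digits)
  print(x$model_b$aub_on_angle, digits = digits)
  cat("\n== Model C: lateral angle ~ age + breadth ==\n")
  print(x$model_c, digits = digits)
  cat("\nHolm-adjusted primary p-values:\n")
  print(signif(x$holm_adjusted_p, digits))
  invisible(x)
}
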