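# The growth-divergence procedure: sex-stratified LOESS growth curves,
# the female-minus-male difference curve on a shared age grid, a
# stratified bootstrap of that curve, pointwise BCa confidence bands, and
# detection of contiguous age windows in which the band excludes zero.

# Split a measurement column into per-sex (age, value) vectors.
.sex_data <- function(table, variable) {
  df <- as.data.frame(table)
  keep <- !is.na(df[[variable]]) & !is.na(df$sex) & !is.na(df$age_years)
  list(age_f = df$age_years[keep & df$sex == "F"],
       val_f = df[[variable]][keep & df$sex == "F"],
       age_m = df$age_years[keep & df$sex == "M"],
       val_m = df[[variable]][keep & df$sex == "M"])
}

.shared_grid <- function(age_f, age_m, grid_step) {
  lo <- max(min(age_f), min(age_m))
  hi <- min(max(age_f), max(age_m))
  if (hi <= lo)
    stop("the age ranges of the two sexes do not overlap", call. = FALSE)
  seq(lo, hi, by = grid_step)
}

#' Female-minus-male smoothed difference curve
#'
#' Fits one LOESS smoother per sex on (age, variable), evaluates both on a
#' common age grid restricted to the overlap of the sexes' observed age
#' ranges (no extrapolation), and returns the female-minus-male
#' difference. Negative values mean males are larger.
#'
#' @param table a `cohort_table`.
#' @param variable measurement column (default biauricular breadth).
#' @param grid_step grid spacing in years.
#' @param span,degree LOESS parameters, see [loess_fit()].
#' @return an object of class `"diff_curve"` with `grid`, `diff`, per-sex
#'   sample sizes and per-grid-point local support counts.
#' @export
sex_difference_curve <- function(table, variable = "aub_mm",
                                 grid_step = 0.5, span = 0.75, degree = 1L) {
  d <- .sex_data(table, variable)
  for (v in list(d$age_f, d$age_m))
    if (length(v) < degree + 2L || ceiling(span * length(v)) < degree + 2L)
      stop("too few non-missing '", variable,
           "' observations in one sex for span = ", span, call. = FALSE)
  grid <- .shared_grid(d$age_f, d$age_m, grid_step)
  cf <- .loess_eval(d$age_f, d$val_f, grid, span, degree)
  cm <- .loess_eval(d$age_m, d$val_m, grid, span, degree)
  structure(list(grid = grid, diff = cf$pred - cm$pred,
                 female = cf$pred, male = cm$pred,
                 n_f = length(d$age_f), n_m = length(d$age_m),
                 support_f = cf$support, support_m = cm$support,
                 span = span, degree = degree, grid_step = grid_step,
                 variable = variable),
            class = "diff_curve")
}

#' @export
print.diff_curve <- function(x, ...) {
  cat("Female-minus-male ", x$variable, " difference curve: grid ",
      format(min(x$grid), digits = 3L), "-",
      format(max(x$grid), digits = 3L), " y (", length(x$grid),
      " points), span ", x$span, ", n = ", x$n_f, " F / ", x$n_m, " M\n",
      sep = "")
  invisible(x)
}

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated interval for a scalar statistic. The
#' bias term `z0` is the normal quantile of the proportion of bootstrap
#' replicates below the observed statistic (ties counted half, proportion
#' clamped to `[1/(B+1), B/(B+1)]` with a warning when it hits 0 or 1).
#' The acceleration `a` comes from the jackknife skewness formula
#' `a = sum(d^3) / (6 * sum(d^2)^1.5)` with `d` the jackknife mean minus
#' each leave-one-out value. The interval is the pair of empirical
#' quantiles (type 7) of the replicates at the BCa-adjusted levels; with
#' `z0 = 0` and `a = 0` it reduces exactly to the percentile interval.
#'
#' @param replicates bootstrap replicate statistics (at least 100).
#' @param observed the statistic on the original sample.
#' @param jackknife leave-one-out statistics; `NULL` sets `a = 0`.
#' @param alpha two-sided miscoverage level, in (0, 0.5).
#' @return `c(lo, hi)`.
#' @export
bca_interval <- function(replicates, observed, jackknife = NULL,
                         alpha = 0.05) {
  stopifnot(is.numeric(replicates), length(observed) == 1L)
  if (length(replicates) < 100L)
    stop("need at least 100 bootstrap replicates", call. = FALSE)
  if (!(alpha > 0 && alpha < 0.5))
    stop("alpha must be strictly inside (0, 0.5)", call. = FALSE)
  res <- .bca_cols(matrix(replicates, ncol = 1L), observed,
                   if (is.null(jackknife)) NULL
                   else matrix(jackknife, ncol = 1L),
                   alpha)
  c(res$lo, res$hi)
}

# Columnwise BCa over a replicate matrix R (B x g), observed vector (g),
# jackknife matrix J (n x g) or NULL.
.bca_cols <- function(R, observed, J, alpha) {
  B <- nrow(R); g <- ncol(R)
  obs_mat <- matrix(observed, nrow = B, ncol = g, byrow = TRUE)
  p_less <- (colSums(R < obs_mat) + 0.5 * colSums(R == obs_mat)) / B
  clamped <- p_less <= 0 | p_less >= 1
  p_less <- pmin(pmax(p_less, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(p_less)

  if (is.null(J)) {
    a <- rep(0, g)
  } else {
    ok <- stats::complete.cases(J)
    Jc <- J[ok, , drop = FALSE]
    d <- matrix(colMeans(Jc), nrow = nrow(Jc), ncol = g, byrow = TRUE) - Jc
    s2 <- colSums(d^2)
    a <- ifelse(s2 > 0, colSums(d^3) / (6 * s2^1.5), 0)
  }

  zl <- stats::qnorm(alpha / 2)
  zu <- stats::qnorm(1 - alpha / 2)
  a1 <- stats::pnorm(z0 + (z0 + zl) / (1 - a * (z0 + zl)))
  a2 <- stats::pnorm(z0 + (z0 + zu) / (1 - a * (z0 + zu)))

  lo <- hi <- numeric(g)
  degenerate <- 0L
  for (i in seq_len(g)) {
    ri <- R[, i]
    if (max(ri) == min(ri)) {
      lo[i] <- hi[i] <- ri[1L]
      degenerate <- degenerate + 1L
    } else {
      q <- stats::quantile(ri, c(a1[i], a2[i]), type = 7L, names = FALSE)
      lo[i] <- q[1L]; hi[i] <- q[2L]
    }
  }
  if (degenerate > 0L)
    warning(degenerate, " grid point(s) had identical replicates; the ",
            "degenerate point interval is returned there", call. = FALSE)
  if (any(clamped & !(R[1L, ] == observed & degenerate > 0L)))
    warning("all replicates fell on one side of the observed statistic ",
            "for ", sum(clamped), " grid point(s); z0 clamped",
            call. = FALSE)
  list(lo = lo, hi = hi, z0 = z0, a = a)
}

#' Bootstrap the sex-difference curve with BCa bands
#'
#' Draws `B` resamples with replacement (stratified by sex, each sex's
#' sample size preserved; or pooled when `stratified = FALSE`), recomputes
#' the full female-minus-male LOESS difference curve for each, and forms a
#' pointwise BCa confidence band per grid age. The acceleration term uses
#' leave-one-case-out jackknife curves (stratified recomputation).
#' Replicates in which a local fit is rank-deficient are dropped and
#' counted; more than 10% failures is an error suggesting a larger span.
#' The same seed yields an identical ensemble.
#'
#' @inheritParams sex_difference_curve
#' @param B number of bootstrap replicates.
#' @param seed integer seed for the private bootstrap stream.
#' @param alpha band level (pointwise two-sided miscoverage).
#' @param stratified resample within sex (`TRUE`, default) or pooled.
#' @return an object of class `"boot_ensemble"` with the observed
#'   `diff_curve`, the replicate matrix, `bca_lo`/`bca_hi`, the failed
#'   replicate count and the seed.
#' @export
bootstrap_difference <- function(table, variable = "aub_mm",
                                 grid_step = 0.5, span = 0.75, degree = 1L,
                                 B = 1000L, seed = NULL, alpha = 0.05,
                                 stratified = TRUE) {
  observed <- sex_difference_curve(table, variable, grid_step, span, degree)
  d <- .sex_data(table, variable)
  n_f <- length(d$age_f); n_m <- length(d$age_m)
  grid <- observed$grid
  g <- length(grid)

  curve_fm <- function(af, vf, am, vm) {
    if (length(af) < degree + 2L || length(am) < degree + 2L)
      return(rep(NA_real_, g))
    cf <- .loess_eval(af, vf, grid, span, degree, on_singular = "na")$pred
    cm <- .loess_eval(am, vm, grid, span, degree, on_singular = "na")$pred
    cf - cm
  }

  # Jackknife: leave one case out, recompute within its sex only.
  cm_full <- observed$male
  cf_full <- observed$female
  J <- matrix(NA_real_, n_f + n_m, g)
  for (j in seq_len(n_f))
    J[j, ] <- .loess_eval(d$age_f[-j], d$val_f[-j], grid, span, degree,
                          on_singular = "na")$pred - cm_full
  for (j in seq_len(n_m))
    J[n_f + j, ] <- cf_full -
      .loess_eval(d$age_m[-j], d$val_m[-j], grid, span, degree,
                  on_singular = "na")$pred

  R <- .with_seed(seed, {
    out <- matrix(NA_real_, B, g)
    n_tot <- n_f + n_m
    for (b in seq_len(B)) {
      if (stratified) {
        i_f <- sample.int(n_f, n_f, replace = TRUE)
        i_m <- sample.int(n_m, n_m, replace = TRUE)
        out[b, ] <- curve_fm(d$age_f[i_f], d$val_f[i_f],
                             d$age_m[i_m], d$val_m[i_m])
      } else {
        idx <- sample.int(n_tot, n_tot, replace = TRUE)
        isf <- idx <= n_f
        af <- d$age_f[idx[isf]]; vf <- d$val_f[idx[isf]]
        im <- idx[!isf] - n_f
        out[b, ] <- curve_fm(af, vf, d$age_m[im], d$val_m[im])
      }
    }
    out
  })

  ok <- stats::complete.cases(R)
  n_failed <- sum(!ok)
  if (n_failed > 0.1 * B)
    stop(n_failed, " of ", B, " bootstrap replicates failed (rank-",
         "deficient local fits); increase the span or the sample size",
         call. = FALSE)
  if (sum(ok) < 100L)
    stop("fewer than 100 usable bootstrap replicates", call. = FALSE)
  band <- .bca_cols(R[ok, , drop = FALSE], observed$diff, J, alpha)

  structure(list(observed = observed, replicates = R[ok, , drop = FALSE],
                 B = B, n_failed = n_failed, bca_lo = band$lo,
                 bca_hi = band$hi, alpha = alpha, seed = seed,
                 stratified = stratified, jackknife = J),
            class = "boot_ensemble")
}

#' @export
print.boot_ensemble <- function(x, ...) {
  flagged <- sum(x$bca_lo > 0 | x$bca_hi < 0)
  cat("Bootstrap ensemble of the ", x$observed$variable,
      " difference curve: B = ", x$B, " (", x$n_failed, " failed), ",
      if (x$stratified) "sex-stratified" else "pooled", " resampling, ",
      100 * (1 - x$alpha), "% pointwise BCa band; ", flagged, " of ",
      length(x$observed$grid), " grid ages exclude 0\n", sep = "")
  invisible(x)
}

#' @export
plot.boot_ensemble <- function(x, ...) {
  grid <- x$observed$grid
  ylim <- range(c(x$bca_lo, x$bca_hi, 0))
  graphics::plot(grid, x$observed$diff, type = "n", ylim = ylim,
                 xlab = "Age (years)",
                 ylab = paste0("Female - male ", x$observed$variable),
                 main = "Sex divergence with pointwise BCa band", ...)
  graphics::polygon(c(grid, rev(grid)), c(x$bca_lo, rev(x$bca_hi)),
                    col = "grey85", border = NA)
  graphics::lines(grid, x$observed$diff, lwd = 2)
  graphics::abline(h = 0, lty = 3)
  flagged <- x$bca_lo > 0 | x$bca_hi < 0
  if (any(flagged)) graphics::rug(grid[flagged], col = "red")
  invisible(x)
}

#' Detect contiguous divergence windows
#'
#' Flags grid ages whose BCa interval excludes zero, merges consecutive
#' flagged ages into runs, and keeps runs of at least `min_run` grid
#' points (the default, 2 points at the default half-year grid, suppresses
#' single-point flicker). Each window reports which sex is larger.
#'
#' @param ensemble a `boot_ensemble`.
#' @param min_run minimum run length in grid points.
#' @return an object of class `"divergence_windows"`: a data frame with
#'   columns `start_age`, `end_age`, `sign` (`"M>F"` or `"F>M"`).
#' @export
detect_divergence_windows <- function(ensemble, min_run = 2L) {
  stopifnot(inherits(ensemble, "boot_ensemble"), min_run >= 1L)
  grid <- ensemble$observed$grid
  flag <- ensemble$bca_lo > 0 | ensemble$bca_hi < 0
  runs <- rle(flag)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_run
  out <- data.frame(start_age = grid[starts[keep]],
                    end_age = grid[ends[keep]],
                    sign = vapply(which(keep), function(i) {
                      m <- mean(ensemble$observed$diff[starts[i]:ends[i]])
                      if (m < 0) "M>F" else "F>M"
                    }, character(1L)),
                    stringsAsFactors = FALSE)
  structure(out, class = c("divergence_windows", "data.frame"),
            min_run = min_run)
}

#' @export
print.divergence_windows <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No divergence windows (no run of >=", attr(x, "min_run"),
        "grid ages excludes 0)\n")
  } else {
    cat("Divergence windows (runs of >=", attr(x, "min_run"),
        "grid ages whose BCa interval excludes 0):\n")
    print(as.data.frame(x), row.names = FALSE)
  }
  invisible(x)
}
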