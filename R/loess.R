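# Local polynomial regression (LOESS) built directly from its definition:
# at each evaluation point the ceiling(span * n) nearest training points
# are fit by weighted least squares of the requested degree, with tricube
# weights on distance scaled by the neighborhood radius. No robustness
# iterations. The degree-0/1 paths are closed-form and vectorized over
# evaluation points, which keeps the bootstrap loop fast.

.tricube <- function(u) (1 - pmin(abs(u), 1)^3)^3

# Vectorized evaluation of a local fit at points x0.
# Returns list(pred, support); on_singular = "error" or "na".
.loess_eval <- function(x, y, x0, span, degree, on_singular = "error") {
  n <- length(x)
  k <- min(n, max(degree + 2L, ceiling(span * n)))
  D <- abs(outer(x0, x, "-"))
  dq <- apply(D, 1L, function(r) sort.int(r, partial = k)[k])
  dq_safe <- ifelse(dq > 0, dq, .Machine$double.xmin)
  W <- .tricube(D / dq_safe)
  support <- as.integer(rowSums(W > 0))

  if (degree == 0L) {
    Sw <- rowSums(W)
    pred <- rowSums(W * rep(y, each = length(x0))) / Sw
  } else if (degree == 1L) {
    # Fit centered at x0: y ~ 1 + (x - x0); the intercept is the prediction.
    M <- W %*% cbind(1, x, x * x, y, x * y)
    Sw <- M[, 1L]; Swx <- M[, 2L]; Swxx <- M[, 3L]
    Swy <- M[, 4L]; Swxy <- M[, 5L]
    Sz <- Swx - x0 * Sw
    Szz <- Swxx - 2 * x0 * Swx + x0 * x0 * Sw
    Szy <- Swxy - x0 * Swy
    denom <- Sw * Szz - Sz * Sz
    pred <- (Szz * Swy - Sz * Szy) / denom
    bad <- !is.finite(pred) | denom <= .Machine$double.eps * Sw * pmax(Szz, 1)
    pred[bad] <- NA_real_
  } else {
    pred <- vapply(seq_along(x0), function(i) {
      w <- W[i, ]
      use <- w > 0
      z <- x[use] - x0[i]
      X <- cbind(1, z, z * z)
      if (qr(X * sqrt(w[use]))$rank < 3L) return(NA_real_)
      fit <- stats::lm.wfit(X, y[use], w[use])
      fit$coefficients[1L]
    }, numeric(1L))
  }

  if (anyNA(pred) && on_singular == "error")
    stop("local fit rank-deficient (neighborhood has no spread in x) at ",
         "evaluation point x = ", x0[which(is.na(pred))[1L]], call. = FALSE)
  list(pred = as.numeric(pred), support = support)
}

#' Fit a LOESS smoother
#'
#' Locally weighted polynomial regression: at each evaluation point, a
#' weighted least-squares fit of the given degree over the
#' `ceiling(span * n)` nearest training points, with tricube weights on
#' distance scaled by the neighborhood radius. Predictions are defined
#' only within the training range of `x` (no extrapolation).
#'
#' @param x,y training data (finite numeric vectors of equal length).
#' @param span fraction of points in each local neighborhood, in (0, 1].
#' @param degree local polynomial degree, 0, 1 or 2.
#' @return an object of class `"la_smoother"`.
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 1L) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            all(is.finite(x)), all(is.finite(y)))
  degree <- as.integer(degree)
  if (!(degree %in% 0:2)) stop("degree must be 0, 1 or 2", call. = FALSE)
  if (!(span > 0 && span <= 1)) stop("span must be in (0, 1]", call. = FALSE)
  n <- length(x)
  if (ceiling(span * n) < degree + 2L)
    stop("span * n = ", span * n, " is too small: each neighborhood needs ",
         "at least degree + 2 = ", degree + 2L, " points", call. = FALSE)
  structure(list(x = x, y = y, span = span, degree = degree),
            class = "la_smoother")
}

#' @export
predict.la_smoother <- function(object, newdata = NULL, ...) {
  x0 <- if (is.null(newdata)) object$x else as.numeric(newdata)
  rng <- range(object$x)
  if (any(x0 < rng[1L] | x0 > rng[2L]))
    stop("prediction outside the training x-range [", rng[1L], ", ",
         rng[2L], "] is not defined (no extrapolation)", call. = FALSE)
  .loess_eval(object$x, object$y, x0, object$span, object$degree,
              on_singular = "error")$pred
}

#' @export
print.la_smoother <- function(x, ...) {
  cat("LOESS smoother: n = ", length(x$x), ", span = ", x$span,
      ", degree = ", x$degree, ", x-range [",
      format(min(x$x), digits = 4L), ", ", format(max(x$x), digits = 4L),
      "]\n", sep = "")
  invisible(x)
}

#' @export
residuals.la_smoother <- function(object, ...) {
  object$y - predict(object)
}
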