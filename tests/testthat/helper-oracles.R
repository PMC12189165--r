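# Independent brute-force oracles used to check the package's
# implementations. These deliberately use naive formulations (explicit
# normal equations, exhaustive pairwise comparison, two-pass moments) so
# they share no code path with the implementation under test.

# OLS by explicit normal equations.
bf_ols <- function(y, X) {
  X1 <- cbind(1, X)
  beta <- solve(t(X1) %*% X1, t(X1) %*% y)
  fitted <- X1 %*% beta
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  n <- length(y); p <- ncol(X1) - 1L
  sigma2 <- rss / (n - p - 1L)
  se <- sqrt(diag(solve(t(X1) %*% X1)) * sigma2)
  tval <- as.numeric(beta) / se
  list(beta = as.numeric(beta), se = se, t = tval,
       p = 2 * pt(-abs(tval), n - p - 1L),
       r2 = 1 - rss / tss,
       adj_r2 = 1 - (rss / (n - p - 1L)) / (tss / (n - 1L)),
       residual_sd = sqrt(sigma2))
}

# AUC by exhaustive pairwise Mann-Whitney comparison, half credit ties.
bf_auc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Two-pass summary statistics.
bf_summary <- function(v) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n == 0)
    return(list(n = 0L, mean = NA_real_, sd = NA_real_, median = NA_real_,
                min = NA_real_, max = NA_real_))
  m <- sum(v) / n
  list(n = n, mean = m,
       sd = if (n > 1) sqrt(sum((v - m)^2) / (n - 1)) else NA_real_,
       median = median(v), min = min(v), max = max(v))
}

# Local tricube-weighted least squares at a single evaluation point,
# written from the definition.
bf_loess_point <- function(x, y, x0, span, degree) {
  n <- length(x)
  k <- min(n, max(degree + 2, ceiling(span * n)))
  d <- abs(x - x0)
  dq <- sort(d)[k]
  w <- (1 - pmin(d / dq, 1)^3)^3
  z <- x - x0
  X <- switch(as.character(degree),
              "0" = cbind(rep(1, n)),
              "1" = cbind(1, z),
              "2" = cbind(1, z, z^2))
  beta <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
  beta[1L]
}

# Textbook BCa interval (written independently of the package).
bf_bca <- function(reps, obs, jack, alpha) {
  B <- length(reps)
  p <- (sum(reps < obs) + 0.5 * sum(reps == obs)) / B
  p <- min(max(p, 1 / (B + 1)), B / (B + 1))
  z0 <- qnorm(p)
  d <- mean(jack) - jack
  a <- if (sum(d^2) > 0) sum(d^3) / (6 * sum(d^2)^1.5) else 0
  adj <- function(z) pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  quantile(reps, c(adj(qnorm(alpha / 2)), adj(qnorm(1 - alpha / 2))),
           type = 7, names = FALSE)
}

# Small hand-built cohort table.
toy_cohort <- function() {
  as_cohort_table(data.frame(
    specimen_id = c("a", "b", "c", "d", "e", "f"),
    collection = c("Vienna", "Vienna", "Graz", "Graz", "Terzer", "NMDID"),
    sex = c("F", "M", "F", "M", "F", "M"),
    age_years = c(2, 3, 10, 12, 0.5, 25),
    lateral_angle_deg = c(48, 44, NA, 39, 50, NA),
    aub_mm = c(85, 90, 110, 115, 75, 125),
    stringsAsFactors = FALSE))
}
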