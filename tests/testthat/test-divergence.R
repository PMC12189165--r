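# Sex-difference curves, the bootstrap BCa band, and window detection.

# Cohort with explicit per-sex ages/values on a single "other" block.
manual_cohort <- function(age_f, val_f, age_m, val_m) {
  n_f <- length(age_f); n_m <- length(age_m)
  as_cohort_table(data.frame(
    specimen_id = c(paste0("f", seq_len(n_f)), paste0("m", seq_len(n_m))),
    collection = "other", sex = rep(c("F", "M"), c(n_f, n_m)),
    age_years = c(age_f, age_m), aub_mm = c(val_f, val_m),
    stringsAsFactors = FALSE))
}

test_that("identical data per sex give an identically-zero difference", {
  age <- seq(0, 20, by = 0.5)
  val <- 75 + 14 * log1p(age)
  tab <- manual_cohort(age, val, age, val)
  dc <- sex_difference_curve(tab)
  expect_equal(dc$diff, rep(0, length(dc$grid)), tolerance = 1e-10)
})

test_that("swapping sex labels negates the difference curve", {
  set.seed(6)
  age_f <- runif(60, 0, 25); age_m <- runif(60, 0, 25)
  val_f <- 75 + 14 * log1p(age_f) + rnorm(60, sd = 3)
  val_m <- 78 + 14 * log1p(age_m) + rnorm(60, sd = 3)
  d1 <- sex_difference_curve(manual_cohort(age_f, val_f, age_m, val_m),
                             grid_step = 1)
  d2 <- sex_difference_curve(manual_cohort(age_m, val_m, age_f, val_f),
                             grid_step = 1)
  expect_equal(d1$diff, -d2$diff, tolerance = 1e-10)
  # grid restricted to the overlap of both sexes' age ranges
  expect_gte(min(d1$grid), max(min(age_f), min(age_m)))
  expect_lte(max(d1$grid), min(max(age_f), max(age_m)))
})

test_that("noise-free curves recover the generator's dimorphism ramp", {
  # dense regular design and a narrow span keep smoothing bias small, so
  # the female-minus-male curve tracks -delta * ramp(age)
  g <- growth_params(delta = 6, sigma_aub = 0)
  age <- seq(0, 30, by = 0.05)
  tab <- manual_cohort(age, mean_aub(age, "F", g),
                       age, mean_aub(age, "M", g))
  dc <- sex_difference_curve(tab, grid_step = 0.5, span = 0.05)
  truth <- -g$delta * pubertal_ramp(dc$grid, g$tau, g$ramp_width)
  expect_lt(max(abs(dc$diff - truth)), 0.2)
  expect_lt(min(dc$diff), -5.5)   # full adult gap reached
  expect_gt(max(dc$diff), -0.05)  # no pre-pubertal dimorphism
})

test_that("bca_interval implements the textbook formula", {
  # symmetric replicates with flat jackknife: reduces to the percentile
  # interval exactly
  reps <- 500.5 + c(-(250:1), 1:250) * 1.9
  jack <- rep(3, 40)
  ci <- bca_interval(reps, 500.5, jack, alpha = 0.05)
  expect_equal(ci, quantile(reps, c(0.025, 0.975), type = 7, names = FALSE))
  # replicates 1..1000 with flat jackknife: percentile quantiles again
  ci2 <- bca_interval(1:1000, 500.5, rep(0, 30), alpha = 0.05)
  expect_equal(ci2, quantile(1:1000, c(0.025, 0.975), type = 7,
                             names = FALSE))
  expect_true(ci2[1] > 25 && ci2[1] < 27)
  expect_true(ci2[2] > 974 && ci2[2] < 976)
  # skewed replicates and jackknife: matches the independent oracle
  set.seed(12)
  reps3 <- rexp(1000)
  jack3 <- rexp(25)
  obs3 <- median(reps3)
  expect_equal(bca_interval(reps3, obs3, jack3),
               bf_bca(reps3, obs3, jack3, 0.05), tolerance = 1e-12)
  # guards
  expect_error(bca_interval(1:1000, 500, NULL, alpha = 0.5), "alpha")
  expect_error(bca_interval(1:50, 25), "100")
  expect_warning(ci4 <- bca_interval(rep(2, 200), 2), "identical")
  expect_equal(suppressWarnings(bca_interval(rep(2, 200), 2)), c(2, 2))
})

test_that("bca_interval agrees with boot::boot.ci on a mean statistic", {
  skip_if_not_installed("boot")
  set.seed(33)
  x <- rgamma(60, shape = 2)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 2000)
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  jack <- vapply(seq_along(x), function(j) mean(x[-j]), numeric(1))
  mine <- bca_interval(bt$t[, 1], mean(x), jack, alpha = 0.05)
  # same formula, different quantile interpolation: agree closely
  expect_equal(mine, ref, tolerance = 0.01)
})

test_that("zero-noise bootstrap bands are narrow and seed-reproducible", {
  g <- growth_params(delta = 6, sigma_aub = 0)
  set.seed(41)
  age_f <- runif(120, 0, 28); age_m <- runif(120, 0, 28)
  tab <- manual_cohort(age_f, mean_aub(age_f, "F", g),
                       age_m, mean_aub(age_m, "M", g))
  ens <- bootstrap_difference(tab, B = 200, seed = 10, grid_step = 1)
  # resampling reshuffles exact-curve points: width shrinks but stays
  # finite, and remains well below the observed difference scale
  expect_lt(max(ens$bca_hi - ens$bca_lo), max(abs(ens$observed$diff)))
  ens2 <- bootstrap_difference(tab, B = 200, seed = 10, grid_step = 1)
  expect_identical(ens$bca_lo, ens2$bca_lo)
  expect_identical(ens$bca_hi, ens2$bca_hi)
  expect_identical(ens$replicates, ens2$replicates)
  # changing B changes the band, not the observed curve
  ens3 <- bootstrap_difference(tab, B = 300, seed = 10, grid_step = 1)
  expect_identical(ens3$observed$diff, ens$observed$diff)
})

test_that("excess replicate failures raise an actionable error", {
  tab <- manual_cohort(c(0, 0.5, 1, 10), c(75, 76, 80, 110),
                       c(0, 0.5, 1, 10), c(75, 74, 79, 104))
  expect_error(
    suppressWarnings(bootstrap_difference(tab, B = 200, seed = 3,
                                          span = 1, grid_step = 2)),
    "increase the span|failed")
})

test_that("window detection merges runs and honours min_run and sign", {
  grid <- seq(10, 20, by = 0.5)
  mk_ens <- function(lo, hi, diff) {
    structure(list(observed = list(grid = grid, diff = diff,
                                   variable = "aub_mm"),
                   bca_lo = lo, bca_hi = hi, alpha = 0.05, B = 100,
                   n_failed = 0, stratified = TRUE),
              class = "boot_ensemble")
  }
  g <- length(grid)
  # all intervals containing zero: no windows
  w0 <- detect_divergence_windows(mk_ens(rep(-1, g), rep(1, g),
                                         rep(0, g)))
  expect_equal(nrow(w0), 0L)
  # grid ages 12-18 exclude zero (negative: males larger)
  lo <- rep(-1, g); hi <- rep(1, g)
  sel <- grid >= 12 & grid <= 18
  lo[sel] <- -3; hi[sel] <- -0.5
  w1 <- detect_divergence_windows(mk_ens(lo, hi, ifelse(sel, -2, 0)))
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$start_age, 12)
  expect_equal(w1$end_age, 18)
  expect_equal(w1$sign, "M>F")
  # a single flagged grid age is suppressed by min_run = 2
  lo2 <- rep(-1, g); hi2 <- rep(1, g)
  lo2[5] <- 0.2
  w2 <- detect_divergence_windows(mk_ens(lo2, hi2, rep(0.5, g)))
  expect_equal(nrow(w2), 0L)
  w3 <- detect_divergence_windows(mk_ens(lo2, hi2, rep(0.5, g)),
                                  min_run = 1)
  expect_equal(nrow(w3), 1L)
  expect_equal(w3$sign, "F>M")
})

test_that("insufficient per-sex data is an explicit error", {
  tab <- manual_cohort(c(1, 2), c(80, 85), seq(0, 10), 75 + seq(0, 10))
  expect_error(sex_difference_curve(tab), "too few")
  # non-overlapping age ranges
  tab2 <- manual_cohort(seq(0, 5, by = 0.5), rnorm(11, 80),
                        seq(10, 15, by = 0.5), rnorm(11, 100))
  expect_error(sex_difference_curve(tab2), "do not overlap")
})
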