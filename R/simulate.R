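# Synthetic cohort generator.
#
# Biauricular breadth (AUB) follows a logarithmic growth curve shared by
# both sexes, plus a male-only pubertal dimorphism ramp: a logistic rise
# from 0 to delta centred at tau. The lateral angle is coupled linearly
# (negatively) to AUB; any sex difference in the angle is, by default,
# mediated entirely by breadth.

#' Growth-curve parameters for biauricular breadth
#'
#' @param b0 mean AUB at birth, mm.
#' @param b1 logarithmic growth coefficient, mm per log-year
#'   (`b1 * log(1 + age)`).
#' @param delta adult male-minus-female AUB difference, mm.
#' @param tau midpoint of the pubertal ramp, years.
#' @param ramp_width logistic scale of the ramp, years.
#' @param sigma_aub residual standard deviation of AUB, mm.
#' @return an object of class `"growth_params"`.
#' @export
growth_params <- function(b0 = 75, b1 = 14, delta = 5.6, tau = 13,
                          ramp_width = 1.5, sigma_aub = 5) {
  stopifnot(sigma_aub >= 0, ramp_width > 0, delta >= 0)
  structure(list(b0 = b0, b1 = b1, delta = delta, tau = tau,
                 ramp_width = ramp_width, sigma_aub = sigma_aub),
            class = "growth_params")
}

#' Angle-coupling parameters
#'
#' @param a0 intercept, degrees.
#' @param a1 coupling of the lateral angle to AUB, degrees per mm
#'   (negative: broader crania have smaller angles).
#' @param sigma_angle residual standard deviation of the angle, degrees.
#' @param sex_effect_direct additive male effect on the angle, degrees,
#'   independent of breadth. Defaults to 0 (dimorphism purely
#'   breadth-mediated); expose it to simulate a direct anatomical sex
#'   effect instead.
#' @return an object of class `"angle_params"`.
#' @export
angle_params <- function(a0 = 75, a1 = -0.274, sigma_angle = 5,
                         sex_effect_direct = 0) {
  stopifnot(sigma_angle >= 0)
  structure(list(a0 = a0, a1 = a1, sigma_angle = sigma_angle,
                 sex_effect_direct = sex_effect_direct),
            class = "angle_params")
}

#' Default age-block design of the synthetic cohort
#'
#' Four blocks mimic the four-collection study design: three historical
#' subadult collections carrying both measurements, and a modern block
#' (ages 12-30) contributing breadth only. Block weights follow the
#' published per-collection sample sizes (50:41:17:96); ages are uniform
#' within each block's range.
#'
#' @return a data frame with columns `collection`, `weight`, `age_min`,
#'   `age_max`, `angle_measured`.
#' @export
default_age_blocks <- function() {
  data.frame(
    collection = c("Vienna", "Graz", "Terzer", "NMDID"),
    weight = c(50, 41, 17, 96) / 204,
    age_min = c(0.1, 3, 0.1, 12),
    age_max = c(11, 21, 3, 30),
    angle_measured = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' Configuration of a synthetic cohort
#'
#' @param n_per_sex specimens per sex (split over age blocks by weight).
#' @param blocks age-block design, see [default_age_blocks()].
#' @param growth a [growth_params()] object.
#' @param angle an [angle_params()] object.
#' @param angle_available_max_age lateral angle is generated only for rows
#'   with age at or below this cap (and only in blocks marked
#'   `angle_measured`), mirroring the real design in which the modern CT
#'   sample contributes breadth only.
#' @param seed integer seed for the cohort's private random stream; `NULL`
#'   uses (and advances) the current stream.
#' @return an object of class `"sim_config"`.
#' @export
sim_config <- function(n_per_sex = 100, blocks = default_age_blocks(),
                       growth = growth_params(), angle = angle_params(),
                       angle_available_max_age = 21, seed = NULL) {
  stopifnot(n_per_sex >= 1, inherits(growth, "growth_params"),
            inherits(angle, "angle_params"))
  req <- c("collection", "weight", "age_min", "age_max", "angle_measured")
  if (!is.data.frame(blocks) || !all(req %in% names(blocks)) ||
      nrow(blocks) < 1L)
    stop("blocks must be a data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  if (any(blocks$weight < 0) || sum(blocks$weight) <= 0)
    stop("block weights must be non-negative and sum to > 0", call. = FALSE)
  if (any(blocks$age_min < 0) || any(blocks$age_max > 30) ||
      any(blocks$age_min > blocks$age_max))
    stop("block age ranges must lie within [0, 30] with age_min <= age_max",
         call. = FALSE)
  structure(list(n_per_sex = as.integer(n_per_sex), blocks = blocks,
                 growth = growth, angle = angle,
                 angle_available_max_age = angle_available_max_age,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' Pubertal dimorphism ramp
#'
#' Logistic rise from 0 to 1 with midpoint `tau` and scale `width`,
#' shifted and rescaled so that the ramp is exactly 0 at age 0 (both sexes
#' share the birth mean `b0`) and tends to 1 as age grows.
#'
#' @param age age in years.
#' @param tau midpoint, years.
#' @param width logistic scale, years.
#' @return ramp values in `[0, 1)`.
#' @export
pubertal_ramp <- function(age, tau, width) {
  r0 <- stats::plogis(-tau / width)
  (stats::plogis((age - tau) / width) - r0) / (1 - r0)
}

#' Expected biauricular breadth at a given age
#'
#' `b0 + b1 * log(1 + age)` for females, plus `delta * ramp(age)` for
#' males. Strictly increasing in age; the male-female difference tends to
#' `delta` in adulthood.
#'
#' @param age age in years (vectorized).
#' @param sex `"F"` or `"M"` (vectorized or scalar).
#' @param params a [growth_params()] object.
#' @return expected AUB in mm.
#' @export
mean_aub <- function(age, sex, params = growth_params()) {
  stopifnot(all(age >= 0), all(sex %in% c("F", "M")))
  base <- params$b0 + params$b1 * log1p(age)
  base + (sex == "M") * params$delta *
    pubertal_ramp(age, params$tau, params$ramp_width)
}

# Run code under a private RNG stream, restoring the caller's stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic apportionment of n over block weights (largest remainder).
.allocate_blocks <- function(n, w) {
  w <- w / sum(w)
  raw <- n * w
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0L) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Simulate a synthetic cohort table
#'
#' Draws ages uniformly within each configured block, breadth from the
#' growth model plus Gaussian noise, and the lateral angle from its linear
#' coupling to breadth plus Gaussian noise (only where the study design
#' makes the angle available). The same seed yields an identical table.
#'
#' @param config a [sim_config()] object.
#' @return a `cohort_table`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    bl <- config$blocks
    g <- config$growth
    an <- config$angle
    rows <- list()
    for (sx in c("F", "M")) {
      n_b <- .allocate_blocks(config$n_per_sex, bl$weight)
      for (i in seq_len(nrow(bl))) {
        if (n_b[i] == 0L) next
        age <- stats::runif(n_b[i], bl$age_min[i], bl$age_max[i])
        aub <- mean_aub(age, sx, g) + stats::rnorm(n_b[i], 0, g$sigma_aub)
        has_angle <- bl$angle_measured[i] &
          age <= config$angle_available_max_age
        angle <- rep(NA_real_, n_b[i])
        if (any(has_angle)) {
          k <- sum(has_angle)
          angle[has_angle] <- an$a0 + an$a1 * aub[has_angle] +
            an$sex_effect_direct * (sx == "M") +
            stats::rnorm(k, 0, an$sigma_angle)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          specimen_id = sprintf("%s_%s_%03d", bl$collection[i], sx,
                                seq_len(n_b[i])),
          collection = bl$collection[i], sex = sx, age_years = age,
          lateral_angle_deg = angle, aub_mm = aub,
          excluded_flag = FALSE, exclusion_reason = "",
          stringsAsFactors = FALSE)
      }
    }
    as_cohort_table(do.call(rbind, rows))
  })
}
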