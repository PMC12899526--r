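#' @title BMI distributions, shifts, and overweight/obesity prevalence
#'
#' @description
#' Stratum-level BMI is represented parametrically (normal by default,
#' lognormal optional). An intervention shifts the distribution location by
#' the per-stratum weight change divided by squared mean height; the spread is
#' left unchanged (location-shift assumption). Overweight and obesity
#' prevalences are tail areas at the conventional 25 and 30 kg/m^2 cutpoints.
#'
#' @name bmi-distribution
NULL

#' Construct a parametric BMI distribution
#'
#' @param mean Mean BMI, kg/m^2 (for `lognormal`, the mean on the natural
#'   scale).
#' @param sd Standard deviation, kg/m^2, > 0.
#' @param family `"normal"` or `"lognormal"`.
#' @return A `ssbtax_bmi` list with `family`, `mean`, `sd`.
#' @export
bmi_distribution <- function(mean, sd, family = c("normal", "lognormal")) {
  family <- match.arg(family)
  if (!is.finite(mean) || mean <= 0) stop("`mean` must be positive", call. = FALSE)
  if (!is.finite(sd) || sd <= 0) stop("`sd` must be positive", call. = FALSE)
  structure(list(family = family, mean = mean, sd = sd), class = "ssbtax_bmi")
}

# Distribution function of a ssbtax_bmi at q.
.bmi_cdf <- function(dist, q) {
  if (dist$family == "normal") {
    stats::pnorm(q, dist$mean, dist$sd)
  } else {
    # moment-matched lognormal
    s2 <- log(1 + (dist$sd / dist$mean)^2)
    mu <- log(dist$mean) - s2 / 2
    stats::plnorm(q, mu, sqrt(s2))
  }
}

# Density of a ssbtax_bmi at x.
.bmi_pdf <- function(dist, x) {
  if (dist$family == "normal") {
    stats::dnorm(x, dist$mean, dist$sd)
  } else {
    s2 <- log(1 + (dist$sd / dist$mean)^2)
    mu <- log(dist$mean) - s2 / 2
    stats::dlnorm(x, mu, sqrt(s2))
  }
}

#' Shift a BMI distribution by a weight change
#'
#' Location shift: the mean moves by `delta_weight / mean_height^2`; the
#' standard deviation is unchanged.
#'
#' @param dist A [bmi_distribution()].
#' @param delta_weight Weight change in kg (negative for loss).
#' @param mean_height Stratum mean height in metres.
#' @return A shifted `ssbtax_bmi`.
#' @export
shift_distribution <- function(dist, delta_weight, mean_height) {
  stopifnot(inherits(dist, "ssbtax_bmi"))
  if (!is.finite(delta_weight)) stop("`delta_weight` must be finite", call. = FALSE)
  if (!is.finite(mean_height) || mean_height <= 0) {
    stop("`mean_height` must be positive", call. = FALSE)
  }
  bmi_distribution(dist$mean + delta_weight / mean_height^2, dist$sd, dist$family)
}

#' Overweight and obesity prevalence of a BMI distribution
#'
#' Overweight is `F(30) - F(25)` and obesity `1 - F(30)`, with `F` the
#' distribution function and cutpoints 25 and 30 kg/m^2 by default.
#'
#' @param dist A [bmi_distribution()].
#' @param cutpoints Length-2 numeric: overweight and obesity thresholds.
#' @return Tibble with columns `overweight`, `obesity` (proportions).
#' @export
bmi_prevalence <- function(dist, cutpoints = c(25, 30)) {
  stopifnot(inherits(dist, "ssbtax_bmi"), length(cutpoints) == 2)
  f25 <- .bmi_cdf(dist, cutpoints[1])
  f30 <- .bmi_cdf(dist, cutpoints[2])
  tibble::tibble(overweight = f30 - f25, obesity = 1 - f30)
}

#' Calibrate a BMI distribution to a mean and an obesity target
#'
#' Solves for the standard deviation such that `P(BMI >= 30)` equals
#' `target_obesity` at the given mean. For a normal family this inverts the
#' normal distribution function in closed form; the degenerate case
#' `mean = 30` (any sd gives 50%) returns the smallest-sd convention of
#' 1e-3 kg/m^2 when the target is 0.5 and errors otherwise.
#'
#' @param target_mean Target mean BMI, kg/m^2.
#' @param target_obesity Target obesity proportion in (0, 1).
#' @param family Distribution family.
#' @param cutpoint Obesity threshold (default 30 kg/m^2).
#' @return A calibrated `ssbtax_bmi` reproducing both targets.
#' @export
calibrate_bmi <- function(target_mean, target_obesity,
                          family = c("normal", "lognormal"), cutpoint = 30) {
  family <- match.arg(family)
  if (!is.finite(target_obesity) || target_obesity <= 0 || target_obesity >= 1) {
    stop("`target_obesity` must lie in (0, 1)", call. = FALSE)
  }
  if (family == "normal") {
    z <- stats::qnorm(1 - target_obesity)
    gap <- cutpoint - target_mean
    if (abs(gap) < 1e-9) {
      if (abs(target_obesity - 0.5) < 1e-9) return(bmi_distribution(target_mean, 1e-3))
      stop("infeasible: mean at the cutpoint forces obesity = 0.5", call. = FALSE)
    }
    sd <- gap / z
    if (!is.finite(sd) || sd <= 0) {
      stop("infeasible mean/obesity pair for the normal family", call. = FALSE)
    }
    return(bmi_distribution(target_mean, sd))
  }
  # lognormal: solve for sd numerically
  fn <- function(sd) {
    1 - .bmi_cdf(bmi_distribution(target_mean, sd, "lognormal"), cutpoint) - target_obesity
  }
  lo <- 1e-4; hi <- 50
  if (fn(lo) * fn(hi) > 0) stop("infeasible mean/obesity pair for the lognormal family", call. = FALSE)
  sd <- stats::uniroot(fn, c(lo, hi), tol = 1e-10)$root
  bmi_distribution(target_mean, sd, "lognormal")
}

#' Per-stratum weight change from energy-intake changes
#'
#' Runs the Hall model once per stratum through a reference individual
#' carrying the stratum's mean BMI (via `mean_height`), the age-group
#' midpoint, and the stratum's sex, and returns the weight change trajectory
#' evaluated at the requested years together with its asymptote.
#'
#' @param energy_changes Tibble from [energy_change()] (columns `sex`,
#'   `age_group`, `income`, `delta_kcal_day`).
#' @param bmi_baseline Tibble with columns `sex`, `age_group`, `income`,
#'   `mean_bmi`, `sd_bmi`, `mean_height_m`.
#' @param years Years after the intervention start at which to report the
#'   achieved weight change (default 1:5; the asymptote is always added).
#' @param horizon Horizon (years) treated as the asymptote.
#' @return `energy_changes` joined with `bmi_baseline` plus columns
#'   `delta_weight_eq` (kg, asymptotic) and `delta_weight_y<k>` for each
#'   requested year.
#' @export
stratum_weight_response <- function(energy_changes, bmi_baseline,
                                    years = 1:5, horizon = 30) {
  df <- dplyr::inner_join(energy_changes, bmi_baseline,
                          by = c("sex", "age_group", "income"))
  if (nrow(df) == 0) stop("no overlapping strata between inputs", call. = FALSE)
  mid_age <- function(g) {
    nums <- suppressWarnings(as.numeric(unlist(strsplit(as.character(g), "[^0-9]+"))))
    nums <- nums[is.finite(nums)]
    if (length(nums) == 0) 45 else mean(range(nums))
  }
  res <- purrr::pmap(df, function(sex, age_group, income, delta_kcal_day,
                                  mean_bmi, sd_bmi, mean_height_m, ...) {
    age <- max(20, min(80, mid_age(age_group)))
    ind <- reference_individual(sex, age = age, height = mean_height_m,
                                weight = mean_bmi * mean_height_m^2)
    st <- initialize_balance(ind)
    tr <- simulate_weight(st, kcal_to_kj(delta_kcal_day), horizon = horizon,
                          step = 1 / 52, out_times = c(0, years, horizon))
    s <- trajectory_summary(tr)
    out <- c(s$delta_final,
             stats::approx(tr$time, tr$weight - tr$weight[1], xout = years, rule = 2)$y)
    stats::setNames(out, c("delta_weight_eq", paste0("delta_weight_y", years)))
  })
  dplyr::bind_cols(df, dplyr::bind_rows(res))
}

#' Prevalence table before and after the intervention
#'
#' Builds baseline and post-intervention overweight/obesity prevalences per
#' stratum from the calibrated BMI distributions and the equilibrium weight
#' change.
#'
#' @param weight_response Output of [stratum_weight_response()].
#' @return Long tibble: `sex`, `age_group`, `income`, `scenario`
#'   (`"baseline"`/`"intervention"`), `overweight`, `obesity`.
#' @export
prevalence_table <- function(weight_response) {
  purrr::pmap_dfr(weight_response, function(sex, age_group, income, mean_bmi,
                                            sd_bmi, mean_height_m,
                                            delta_weight_eq, ...) {
    d0 <- bmi_distribution(mean_bmi, sd_bmi)
    d1 <- shift_distribution(d0, delta_weight_eq, mean_height_m)
    dplyr::bind_rows(
      dplyr::mutate(bmi_prevalence(d0), scenario = "baseline"),
      dplyr::mutate(bmi_prevalence(d1), scenario = "intervention")
    ) |>
      dplyr::mutate(sex = sex, age_group = age_group, income = income,
                    .before = 1)
  })
}
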