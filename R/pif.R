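#' @title Potential impact fractions and incidence adjustment
#'
#' @description
#' The potential impact fraction (PIF) is the proportional reduction in
#' disease incidence obtained by shifting the BMI distribution from its
#' baseline `F0` to the post-intervention `F1`:
#' `PIF = (E0[RR] - E1[RR]) / E0[RR]`, where the dose-response follows the
#' standard GBD convention of a log-linear relative risk per 5 BMI units
#' above the theoretical minimum-risk exposure level (TMREL), flat below it:
#' `RR(b) = rr5 ^ (max(b - tmrel, 0) / 5)`.
#'
#' @name pif
NULL

#' Discrete (mass-point) BMI distribution
#'
#' Used mainly as an exact enumeration oracle for the quadrature engine.
#'
#' @param x BMI mass points.
#' @param p Probabilities (summing to 1).
#' @return A `ssbtax_bmi_mass` object.
#' @export
bmi_mass_points <- function(x, p) {
  stopifnot(length(x) == length(p), all(p >= 0))
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1", call. = FALSE)
  structure(list(x = x, p = p), class = "ssbtax_bmi_mass")
}

# Relative risk at BMI b.
.rr_at <- function(b, rr5, tmrel) rr5 ^ (pmax(b - tmrel, 0) / 5)

# Mean relative risk under a distribution (parametric: midpoint quadrature).
.mean_rr <- function(dist, rr5, tmrel, grid) {
  if (inherits(dist, "ssbtax_bmi_mass")) {
    return(sum(dist$p * .rr_at(dist$x, rr5, tmrel)))
  }
  stopifnot(inherits(dist, "ssbtax_bmi"))
  w <- .bmi_pdf(dist, grid$mid) * grid$dx
  sum(w * .rr_at(grid$mid, rr5, tmrel)) / sum(w)
}

# Fixed quadrature grid on [lo, hi] with n midpoints.
.pif_grid <- function(n = 1000, lo = 10, hi = 60) {
  edges <- seq(lo, hi, length.out = n + 1)
  list(mid = (edges[-1] + edges[-(n + 1)]) / 2, dx = diff(edges)[1])
}

#' Potential impact fraction of a BMI shift
#'
#' @param dist0 Baseline BMI distribution ([bmi_distribution()] or
#'   [bmi_mass_points()]).
#' @param dist1 Post-intervention distribution (same stratum).
#' @param rr5 Relative risk per 5 kg/m^2 of BMI above `tmrel`.
#' @param tmrel Theoretical minimum-risk exposure level, kg/m^2.
#' @param n_quad Quadrature points for parametric distributions.
#' @return PIF as a proportion (<= 1; 0 when the distributions or the risk
#'   are equal).
#' @export
pif <- function(dist0, dist1, rr5, tmrel = 22.5, n_quad = 1000) {
  if (!is.finite(rr5) || rr5 < 0) stop("`rr5` must be >= 0", call. = FALSE)
  if (rr5 == 1) return(0)
  grid <- .pif_grid(n_quad)
  e0 <- .mean_rr(dist0, rr5, tmrel, grid)
  e1 <- .mean_rr(dist1, rr5, tmrel, grid)
  if (!is.finite(e0) || e0 <= 0) stop("non-integrable baseline distribution", call. = FALSE)
  (e0 - e1) / e0
}

#' Apply a PIF to an incidence surface
#'
#' `i'(a) = i(a) * (1 - PIF(a))`; PIF above 1 is rejected.
#'
#' @param incidence Incidence hazard by age.
#' @param pif_by_age PIF per age (scalar recycled).
#' @return Adjusted incidence vector.
#' @export
adjusted_incidence <- function(incidence, pif_by_age) {
  if (any(pif_by_age > 1 + 1e-12)) stop("PIF must be <= 1", call. = FALSE)
  incidence * (1 - pif_by_age)
}

#' Diabetes-mediation adjustment for IHD/stroke incidence
#'
#' Diabetes acts both as an outcome and as a risk factor for ischaemic heart
#' disease and stroke. When the intervention changes diabetes prevalence from
#' `p0` to `p1`, the population-average incidence of the downstream disease
#' is multiplied by `(1 + p1 (RR - 1)) / (1 + p0 (RR - 1))`.
#'
#' @param incidence Incidence hazard by age (IHD or stroke).
#' @param p0,p1 Diabetes prevalence by age, baseline and scenario (in \[0,1\]).
#' @param rr Relative risk of the downstream disease given diabetes (>= 0).
#' @return Adjusted incidence vector.
#' @export
diabetes_adjust <- function(incidence, p0, p1, rr) {
  if (!is.finite(rr) || rr < 0) stop("`rr` must be >= 0", call. = FALSE)
  if (any(p0 < 0 | p0 > 1) || any(p1 < 0 | p1 > 1)) {
    stop("prevalences must lie in [0, 1]", call. = FALSE)
  }
  incidence * (1 + p1 * (rr - 1)) / (1 + p0 * (rr - 1))
}

#' PIF table across strata, diseases and phase-in years
#'
#' Computes PIFs per (disease, sex, age group, income) from the calibrated
#' baseline BMI distributions and the achieved weight change of each phase-in
#' year (from the Hall trajectory), plus the equilibrium shift used from the
#' last phase-in year onwards.
#'
#' @param weight_response Output of [stratum_weight_response()].
#' @param rr_table Tibble: `disease`, `sex`, `rr5` (optionally `rr5_lo`,
#'   `rr5_hi`), one row per disease/sex.
#' @param tmrel TMREL, kg/m^2.
#' @param years Phase-in years present in `weight_response` (default 1:5).
#' @return Long tibble: `disease`, `sex`, `age_group`, `income`, `year`
#'   (1..length(years) then `Inf` for equilibrium), `pif`.
#' @export
pif_table <- function(weight_response, rr_table, tmrel = 22.5, years = 1:5) {
  ycols <- paste0("delta_weight_y", years)
  stopifnot(all(ycols %in% names(weight_response)))
  grid <- .pif_grid()
  lev <- c(years, Inf)
  # one dose-response matrix [grid x disease] per sex
  rrmat <- lapply(split(rr_table, rr_table$sex), function(rs) {
    m <- vapply(rs$rr5, function(r) .rr_at(grid$mid, r, tmrel),
                numeric(length(grid$mid)))
    colnames(m) <- rs$disease
    m
  })
  out <- purrr::pmap(weight_response, function(sex, age_group, income,
                                               mean_bmi, sd_bmi,
                                               mean_height_m,
                                               delta_weight_eq, ...) {
    dots <- list(...)
    shifts <- c(unlist(dots[ycols]), delta_weight_eq) / mean_height_m^2
    rm <- rrmat[[sex]]
    w0 <- stats::dnorm(grid$mid, mean_bmi, sd_bmi)
    e0 <- colSums(w0 * rm) / sum(w0)
    pifs <- vapply(shifts, function(dm) {
      w1 <- stats::dnorm(grid$mid, mean_bmi + dm, sd_bmi)
      e1 <- colSums(w1 * rm) / sum(w1)
      (e0 - e1) / e0
    }, numeric(ncol(rm)))  # [disease x level]
    list(sex = sex, age_group = age_group, income = income,
         disease = rep(colnames(rm), times = length(lev)),
         year = rep(lev, each = ncol(rm)), pif = as.vector(pifs))
  })
  tibble::tibble(
    disease = unlist(lapply(out, `[[`, "disease")),
    sex = rep(vapply(out, `[[`, "", "sex"),
              each = length(lev) * ncol(rrmat[[1]])),
    age_group = rep(vapply(out, `[[`, "", "age_group"),
                    each = length(lev) * ncol(rrmat[[1]])),
    income = rep(vapply(out, `[[`, "", "income"),
                 each = length(lev) * ncol(rrmat[[1]])),
    year = unlist(lapply(out, `[[`, "year")),
    pif = unlist(lapply(out, `[[`, "pif"))
  )
}
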