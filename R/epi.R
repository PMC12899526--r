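#' @title Consistent disease input surfaces
#'
#' @description
#' Produces internally consistent single-year-of-age incidence, prevalence,
#' cause-specific mortality and case-fatality surfaces for each modelled
#' disease from coarser (five-year age group) inputs. Each disease follows a
#' three-state model (healthy, diseased, dead) with zero remission; the
#' musculoskeletal conditions carry no disease-specific death state. The
#' solvers are deterministic: a yearly difference-equation cohort model plus
#' per-age root finding, ascending in age.
#'
#' @name disease-inputs
NULL

#' Modelled diseases
#'
#' The seven BMI-related conditions in the model: type 2 diabetes, ischaemic
#' heart disease, stroke and hypertensive heart disease carry a
#' disease-specific death state; low back pain and hip/knee osteoarthritis do
#' not. Costing basis: prevalent case-years for low back pain and T2DM,
#' incident cases for the others. Remission is zero for all.
#'
#' @return Tibble with columns `disease`, `has_death_state`, `cost_basis`,
#'   `remission_rate`.
#' @export
disease_specs <- function() {
  tibble::tibble(
    disease = c("T2DM", "IHD", "stroke", "HHD",
                "low_back_pain", "hip_OA", "knee_OA"),
    has_death_state = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    cost_basis = c("prevalence", "incidence", "incidence", "incidence",
                   "prevalence", "incidence", "incidence"),
    remission_rate = 0
  )
}

#' Model age range
#'
#' Single years of age covered by the simulation; 100 is absorbing.
#' @return Integer vector 20:100.
#' @export
model_ages <- function() 20:100

# Parse "20-24" / "95+" style labels into c(lower, upper_exclusive).
.parse_group <- function(g, max_age = 101) {
  g <- as.character(g)
  nums <- suppressWarnings(as.numeric(unlist(regmatches(g, gregexpr("[0-9]+", g)))))
  if (length(nums) == 0) stop("unparseable age group: ", g, call. = FALSE)
  lo <- nums[1]
  hi <- if (length(nums) >= 2) nums[2] + 1 else max_age
  c(lo, hi)
}

#' Smooth five-year age-group rates to single years of age
#'
#' Interpolates the cumulative person-time integral of the rate with a
#' monotone (Hyman-filtered) cubic spline and differences it back to single
#' years, so each age group's person-time-weighted mean is preserved exactly
#' and the output is nonnegative whenever the input is. Constant input
#' reproduces a constant curve.
#'
#' @param rates Tibble with columns `age_group` (labels like `"20-24"`,
#'   `"95+"`) and `value` (rate, >= 0).
#' @param ages Output ages; default [model_ages()]. Groups must cover them.
#' @return Tibble with columns `age`, `value`.
#' @export
smooth_to_single_year <- function(rates, ages = model_ages()) {
  stopifnot(all(c("age_group", "value") %in% names(rates)))
  if (any(!is.finite(rates$value)) || any(rates$value < 0)) {
    stop("rates must be finite and >= 0", call. = FALSE)
  }
  bounds <- t(vapply(rates$age_group, .parse_group, numeric(2),
                     max_age = max(ages) + 1))
  ord <- order(bounds[, 1])
  bounds <- bounds[ord, , drop = FALSE]
  vals <- rates$value[ord]
  if (any(bounds[-1, 1] != bounds[-nrow(bounds), 2])) {
    stop("age groups must be contiguous; missing group detected", call. = FALSE)
  }
  if (bounds[1, 1] > min(ages) || bounds[nrow(bounds), 2] < max(ages) + 1) {
    stop("age groups must cover ", min(ages), "-", max(ages), call. = FALSE)
  }
  knots <- c(bounds[1, 1], bounds[, 2])
  cum <- c(0, cumsum(vals * (bounds[, 2] - bounds[, 1])))
  fn <- stats::splinefun(knots, cum, method = "hyman")
  single <- pmax(fn(ages + 1) - fn(ages), 0)
  tibble::tibble(age = ages, value = single)
}

#' Forward three-state cohort simulation
#'
#' Yearly difference-equation update of a healthy/diseased/dead cohort with
#' zero remission: healthy individuals acquire the disease at rate
#' `incidence`, everyone faces `background` mortality, and diseased
#' individuals face the additional `case_fatality` hazard. Deaths among the
#' diseased are attributed to the disease in proportion
#' `f / (f + background)`. Mass (healthy + diseased + cumulative dead) is
#' conserved. This simulator is the oracle against which the two inverse
#' solvers are validated.
#'
#' @param incidence,case_fatality,background Per-year hazards, vectors along
#'   `ages`.
#' @param p0 Prevalence at the first age.
#' @param ages Ages (default [model_ages()]).
#' @return Tibble per age: `healthy`, `diseased`, `dead_cum` (fractions of
#'   the initial cohort, start of year), `prevalence`, `cause_mortality`
#'   (disease-attributed deaths that year per person alive at the start),
#'   `incident` (new cases that year per person alive at the start).
#' @export
forward_three_state <- function(incidence, case_fatality, background,
                                p0 = 0, ages = model_ages()) {
  n <- length(ages)
  stopifnot(length(incidence) == n, length(case_fatality) == n,
            length(background) == n, p0 >= 0, p0 < 1)
  if (any(incidence < 0) || any(case_fatality < 0) || any(background < 0)) {
    stop("rates must be >= 0", call. = FALSE)
  }
  H <- 1 - p0; D <- p0; dead <- 0
  out <- matrix(NA_real_, n, 6)
  for (k in seq_len(n)) {
    alive <- H + D
    out[k, 1:3] <- c(H, D, dead)
    out[k, 4] <- if (alive > 0) D / alive else 0
    ninc <- H * (1 - exp(-incidence[k]))
    H2 <- H - ninc
    D2 <- D + ninc
    qh <- 1 - exp(-background[k])
    fd <- case_fatality[k] + background[k]
    qd <- 1 - exp(-fd)
    deaths_h <- H2 * qh
    deaths_d <- D2 * qd
    share <- if (fd > 0) case_fatality[k] / fd else 0
    out[k, 5] <- if (alive > 0) deaths_d * share / alive else 0
    out[k, 6] <- if (alive > 0) ninc / alive else 0
    H <- H2 - deaths_h
    D <- D2 - deaths_d
    dead <- dead + deaths_h + deaths_d
  }
  tibble::tibble(age = ages, healthy = out[, 1], diseased = out[, 2],
                 dead_cum = out[, 3], prevalence = out[, 4],
                 cause_mortality = out[, 5], incident = out[, 6])
}

#' Solve case fatality from incidence, prevalence and cause mortality
#'
#' For a fatal disease, finds the case-fatality hazard `f(a)` such that the
#' forward three-state model reproduces the observed cause-specific mortality
#' surface, ascending one age at a time. Where no nonnegative solution exists
#' (cause deaths exceed what the diseased pool can supply, or cause deaths
#' are reported with no prevalent cases) the value is clamped with a logged
#' diagnostic.
#'
#' @param incidence Incidence hazard by age.
#' @param prevalence Prevalence by age (used for the starting state).
#' @param cause_mortality Disease-attributed death rate per person alive, by
#'   age.
#' @param background Background (non-disease) mortality hazard by age.
#' @param ages Ages (default [model_ages()]).
#' @param quiet Suppress clamp diagnostics.
#' @return Tibble with `age`, `case_fatality`; attribute `n_clamped` counts
#'   ages where clamping occurred.
#' @export
solve_case_fatality <- function(incidence, prevalence, cause_mortality,
                                background, ages = model_ages(), quiet = FALSE) {
  n <- length(ages)
  stopifnot(length(incidence) == n, length(prevalence) == n,
            length(cause_mortality) == n, length(background) == n)
  H <- 1 - prevalence[1]; D <- prevalence[1]
  f <- numeric(n)
  clamped <- 0L
  for (k in seq_len(n)) {
    alive <- H + D
    ninc <- H * (1 - exp(-incidence[k]))
    H2 <- H - ninc
    D2 <- D + ninc
    m_target <- cause_mortality[k]
    model_m <- function(fk) {
      fd <- fk + background[k]
      share <- if (fd > 0) fk / fd else 0
      D2 * (1 - exp(-fd)) * share / alive
    }
    if (m_target <= 0 || alive <= 0) {
      fk <- 0
      if (m_target > 0) clamped <- clamped + 1L
    } else if (D2 <= 1e-12) {
      fk <- 0
      clamped <- clamped + 1L
    } else if (model_m(50) < m_target) {
      fk <- 50
      clamped <- clamped + 1L
    } else {
      fk <- stats::uniroot(function(x) model_m(x) - m_target, c(0, 50),
                           tol = 1e-12)$root
    }
    f[k] <- fk
    fd <- fk + background[k]
    H <- H2 * exp(-background[k])
    D <- D2 * exp(-fd)
  }
  if (clamped > 0 && !quiet) {
    message("solve_case_fatality: clamped at ", clamped,
            " age(s) where the data admit no nonnegative solution")
  }
  structure(tibble::tibble(age = ages, case_fatality = f), n_clamped = clamped)
}

#' Infer incidence from prevalence under zero remission
#'
#' Finds the incidence hazard `i(a)` whose forward simulation reproduces the
#' prevalence surface, given case fatality and background mortality. With
#' remission fixed at zero, prevalence can only fall through excess mortality
#' among the diseased; prevalence falling faster than mortality can explain
#' is an error.
#'
#' @inheritParams solve_case_fatality
#' @param case_fatality Case-fatality hazard by age.
#' @return Tibble with `age`, `incidence`.
#' @export
infer_incidence <- function(prevalence, case_fatality, background,
                            ages = model_ages()) {
  n <- length(ages)
  stopifnot(length(prevalence) == n, length(case_fatality) == n,
            length(background) == n)
  H <- 1 - prevalence[1]; D <- prevalence[1]
  inc <- numeric(n)
  for (k in seq_len(n)) {
    target <- if (k < n) prevalence[k + 1] else prevalence[n]
    p_next <- function(ik) {
      ninc <- H * (1 - exp(-ik))
      H2 <- (H - ninc) * exp(-background[k])
      D2 <- (D + ninc) * exp(-(case_fatality[k] + background[k]))
      if (H2 + D2 <= 0) return(1)
      D2 / (H2 + D2)
    }
    if (p_next(0) > target + 1e-10) {
      stop("prevalence at age ", ages[min(k + 1, n)],
           " falls faster than mortality can explain (remission is zero)",
           call. = FALSE)
    }
    if (p_next(20) < target) {
      ik <- 20
    } else {
      ik <- stats::uniroot(function(x) p_next(x) - target, c(0, 20),
                           tol = 1e-12)$root
    }
    inc[k] <- ik
    ninc <- H * (1 - exp(-ik))
    H <- (H - ninc) * exp(-background[k])
    D <- (D + ninc) * exp(-(case_fatality[k] + background[k]))
  }
  tibble::tibble(age = ages, incidence = inc)
}

#' Build consistent single-year epidemiology from grouped inputs
#'
#' Tidy wrapper over the smoothing and consistency steps: takes long-format
#' grouped counts (`measure` in `incidence`, `prevalence`, `deaths`,
#' `population`; counts or rates by 5-year group), smooths each surface to
#' single years, converts to rates, and solves case fatality for diseases
#' with a death state (zero for the others).
#'
#' @param epi_inputs Long tibble: `disease`, `sex`, `age_group`, `measure`,
#'   `value`. `deaths` is the disease-attributed death count (or rate when
#'   `population` is absent).
#' @param background Tibble `sex`, `age`, `value`: background mortality
#'   hazard shared by all diseases.
#' @param specs Disease table from [disease_specs()].
#' @return Tibble `disease`, `sex`, `age`, `incidence`, `prevalence`,
#'   `case_fatality`.
#' @export
consistent_epi <- function(epi_inputs, background, specs = disease_specs()) {
  ages <- model_ages()
  combos <- dplyr::distinct(epi_inputs, .data$disease, .data$sex)
  purrr::pmap_dfr(combos, function(disease, sex) {
    sub <- epi_inputs[epi_inputs$disease == disease & epi_inputs$sex == sex, ]
    grab <- function(m) {
      g <- sub[sub$measure == m, c("age_group", "value")]
      if (nrow(g) == 0) return(NULL)
      smooth_to_single_year(g, ages)$value
    }
    pop <- grab("population")
    as_rate <- function(x) if (!is.null(pop)) x / pop else x
    inc <- as_rate(grab("incidence"))
    prev <- grab("prevalence")
    if (!is.null(pop)) prev <- prev / pop
    dth <- as_rate(grab("deaths"))
    bg <- background$value[background$sex == sex][seq_along(ages)]
    fatal <- specs$has_death_state[specs$disease == disease]
    cf <- if (isTRUE(fatal) && !is.null(dth)) {
      solve_case_fatality(inc, prev, dth, bg, ages, quiet = TRUE)$case_fatality
    } else {
      rep(0, length(ages))
    }
    tibble::tibble(disease = disease, sex = sex, age = ages,
                   incidence = inc, prevalence = prev, case_fatality = cf)
  })
}
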