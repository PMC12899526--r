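#' @title Proportional multistate life table engine
#'
#' @description
#' A closed cohort, structured by sex and single year of age, is advanced in
#' annual cycles. Each disease contributes a healthy/diseased sub-table
#' (fractions of the alive cohort); total mortality each cycle composes the
#' background hazard (all-cause net of the modelled causes) with the
#' case-fatality hazards weighted by disease prevalence, so baseline total
#' mortality matches the all-cause input without double counting. Diseases
#' are independent except for the diabetes-to-IHD/stroke mediation.
#' Life-years accrue with a half-cycle correction; the terminal age is
#' absorbing (its cycle is the cohort's last). Intervention effects enter as
#' potential impact fractions on incidence, phased in with the weight
#' trajectory.
#'
#' @name lifetable
NULL

#' Simulation configuration
#'
#' @param start_year First simulated calendar year.
#' @param min_age,max_age Cohort age range; `max_age` is absorbing.
#' @param discount_rate Annual discount rate applied to QALYs and costs
#'   (cases are always counted undiscounted).
#' @param case_horizon Years over which disease cases are counted.
#' @param ppp_factor BRL per international dollar for cost conversion.
#' @param tmrel Theoretical minimum-risk exposure level for the BMI
#'   dose-response, kg/m^2.
#' @return A `ssbtax_config` list.
#' @export
sim_config <- function(start_year = 2022, min_age = 20, max_age = 100,
                       discount_rate = 0.05, case_horizon = 20,
                       ppp_factor = 2.531, tmrel = 22.5) {
  if (discount_rate < 0) stop("`discount_rate` must be >= 0", call. = FALSE)
  if (case_horizon < 1) stop("`case_horizon` must be >= 1", call. = FALSE)
  structure(list(start_year = start_year, min_age = min_age, max_age = max_age,
                 discount_rate = discount_rate, case_horizon = case_horizon,
                 ppp_factor = ppp_factor, tmrel = tmrel),
            class = "ssbtax_config")
}

# Build an [ages x diseases] matrix from a long per-age table.
.rate_matrix <- function(epi_sex, ages, diseases, col) {
  m <- matrix(0, length(ages), length(diseases),
              dimnames = list(ages, diseases))
  for (d in diseases) {
    sub <- epi_sex[epi_sex$disease == d, ]
    idx <- match(ages, sub$age)
    if (any(is.na(idx))) stop("epi surface for ", d, " does not cover all ages",
                              call. = FALSE)
    m[, d] <- sub[[col]][idx]
  }
  m
}

# Expand a (age_group, value) table to a per-age vector.
.expand_groups <- function(groups, values, ages) {
  out <- rep(NA_real_, length(ages))
  for (j in seq_along(groups)) {
    b <- .parse_group(groups[j], max_age = max(ages) + 1)
    out[ages >= b[1] & ages < b[2]] <- values[j]
  }
  if (any(is.na(out))) stop("age groups do not cover all model ages", call. = FALSE)
  out
}

# PIF matrices per phase year for one sex/income: list over phase years
# 1..5 and "eq", each [ages x diseases].
.pif_matrices <- function(pif_tbl, sex, ages, diseases) {
  sub <- pif_tbl[pif_tbl$sex == sex, ]
  yrs <- sort(unique(sub$year[is.finite(sub$year)]))
  mk <- function(y) {
    s <- sub[sub$year == y, ]
    m <- matrix(0, length(ages), length(diseases),
                dimnames = list(ages, diseases))
    for (d in intersect(diseases, unique(s$disease))) {
      sd <- s[s$disease == d, ]
      m[, d] <- .expand_groups(sd$age_group, sd$pif, ages)
    }
    m
  }
  list(years = yrs, phase = lapply(yrs, mk), eq = mk(Inf))
}

#' Run the multistate life table for one scenario
#'
#' @param epi Consistent epidemiology tibble (`disease`, `sex`, `age`,
#'   `incidence`, `prevalence`, `case_fatality`), e.g. from
#'   [consistent_epi()] or a synthetic bundle.
#' @param population Cohort counts: tibble `sex`, `age`, `count`.
#' @param mortality All-cause mortality hazard: tibble `sex`, `age`, `value`.
#' @param config A [sim_config()].
#' @param pif_tbl Optional PIF table (from [pif_table()], already filtered to
#'   one income level); `NULL` runs the baseline (no intervention).
#' @param mediation Optional list with `rr_ihd` and `rr_stroke`: relative
#'   risks of IHD/stroke given diabetes; requires `baseline_run` for the
#'   counterfactual diabetes prevalence.
#' @param baseline_run Baseline `ssbtax_run`, needed when `mediation` is
#'   supplied.
#' @return A `ssbtax_run` object: per sex, yearly arrays of life-years,
#'   deaths, mid-cycle disease prevalence, prevalent person-years and
#'   incident cases, plus the conservation error.
#' @export
run_cohort <- function(epi, population, mortality, config = sim_config(),
                       pif_tbl = NULL, mediation = NULL, baseline_run = NULL) {
  stopifnot(inherits(config, "ssbtax_config"))
  ages <- config$min_age:config$max_age
  A <- length(ages)
  diseases <- sort(unique(epi$disease))
  if (!is.null(mediation)) {
    if (is.null(baseline_run)) {
      stop("`mediation` requires `baseline_run` for counterfactual diabetes prevalence",
           call. = FALSE)
    }
    if (!"T2DM" %in% diseases) stop("mediation requires a T2DM surface", call. = FALSE)
    if (mediation$rr_ihd < 0 || mediation$rr_stroke < 0) {
      stop("mediation relative risks must be >= 0", call. = FALSE)
    }
  }
  sexes <- sort(unique(population$sex))
  res <- list()
  for (sx in sexes) {
    epi_s <- epi[epi$sex == sx, ]
    I <- .rate_matrix(epi_s, ages, diseases, "incidence")
    Fm <- .rate_matrix(epi_s, ages, diseases, "case_fatality")
    P0 <- .rate_matrix(epi_s, ages, diseases, "prevalence")
    if (any(I > 1)) stop("incidence hazard > 1/year after adjustment", call. = FALSE)
    msub <- mortality[mortality$sex == sx, ]
    allc <- msub$value[match(ages, msub$age)]
    if (any(is.na(allc))) stop("mortality surface does not cover all ages", call. = FALSE)
    # background = all-cause net of modelled causes at baseline prevalence
    bg <- pmax(allc - rowSums(P0 * Fm), 1e-8)
    pop <- population[population$sex == sx, ]
    alive <- pop$count[match(ages, pop$age)]
    alive[is.na(alive)] <- 0
    init_total <- sum(alive)
    pm <- if (!is.null(pif_tbl)) .pif_matrices(pif_tbl, sx, ages, diseases)

    P <- P0
    H <- 1 - P
    Tn <- A
    life_years <- numeric(Tn)
    deaths <- numeric(Tn)
    qdead <- 0
    prev_mid <- array(0, c(Tn, A, length(diseases)))
    prev_start <- array(0, c(Tn, A, length(diseases)))
    prev_py <- array(0, c(Tn, A, length(diseases)))
    inc_cases <- array(0, c(Tn, A, length(diseases)))
    ly_age <- matrix(0, Tn, A)
    cons_err <- 0
    for (t in seq_len(Tn)) {
      Pif <- if (is.null(pif_tbl)) NULL
             else if (t <= length(pm$years)) pm$phase[[t]] else pm$eq
      ieff <- if (is.null(Pif)) I else I * (1 - Pif)
      if (!is.null(mediation)) {
        p1 <- P[, "T2DM"]
        p0 <- baseline_run$by_sex[[sx]]$prev_start[t, , match("T2DM", diseases)]
        for (dd in c("IHD", "stroke")) {
          if (dd %in% diseases) {
            rr <- if (dd == "IHD") mediation$rr_ihd else mediation$rr_stroke
            ieff[, dd] <- diabetes_adjust(ieff[, dd], p0, p1, rr)
          }
        }
      }
      ninc <- H * (1 - exp(-ieff))
      P2 <- P + ninc
      H2 <- H - ninc
      M <- bg + rowSums(P2 * Fm)
      q <- 1 - exp(-M)
      q[A] <- 1  # terminal age: absorbing
      dth <- alive * q
      ly <- alive * (1 - q / 2)
      life_years[t] <- sum(ly)
      deaths[t] <- sum(dth)
      qdead <- qdead + sum(dth)
      prev_start[t, , ] <- P
      prev_mid[t, , ] <- P2
      prev_py[t, , ] <- P2 * ly
      inc_cases[t, , ] <- ninc * alive
      ly_age[t, ] <- ly
      # survivor composition per disease (background hazard cancels)
      Psurv <- P2 * exp(-Fm)
      Pn <- Psurv / (Psurv + H2)
      Pn[!is.finite(Pn)] <- 0
      alive_next <- alive - dth
      cons_err <- max(cons_err, abs((sum(alive_next) + qdead) - init_total) /
                        max(init_total, 1))
      # age everyone by one year; no new entrants
      alive <- c(0, alive_next[-A])
      P <- rbind(P0[1, , drop = FALSE] * 0, Pn[-A, , drop = FALSE])
      H <- 1 - P
    }
    res[[sx]] <- list(ages = ages, diseases = diseases,
                      life_years = life_years, deaths = deaths,
                      prev_mid = prev_mid, prev_start = prev_start,
                      prev_py = prev_py,
                      inc_cases = inc_cases, ly_age = ly_age,
                      init_total = init_total, conservation_error = cons_err)
  }
  structure(list(by_sex = res, config = config, diseases = diseases,
                 ages = ages),
            class = "ssbtax_run")
}

#' Utility-weighted life-year stream
#'
#' `QALY(y) = sum_ages life_years * max(0, 1 - sum_d prev_d * dec_d)`:
#' additive utility decrements across diseases, floored at zero.
#'
#' @param run A `ssbtax_run`.
#' @param decrements Tibble `disease`, `sex`, `decrement` (utility units in
#'   \[0,1\]), optionally `age_group` for age-banded decrements.
#' @return Tibble `year` (0-based cycle), `sex`, `qaly` (undiscounted).
#' @export
qaly_stream <- function(run, decrements) {
  stopifnot(inherits(run, "ssbtax_run"))
  if (any(decrements$decrement < 0 | decrements$decrement > 1)) {
    stop("decrements must lie in [0, 1]", call. = FALSE)
  }
  purrr::imap_dfr(run$by_sex, function(rs, sx) {
    dec <- matrix(0, length(rs$ages), length(rs$diseases),
                  dimnames = list(rs$ages, rs$diseases))
    sub <- decrements[decrements$sex == sx | !("sex" %in% names(decrements)), ]
    for (d in intersect(rs$diseases, unique(sub$disease))) {
      sd <- sub[sub$disease == d, ]
      dec[, d] <- if ("age_group" %in% names(sd) && !all(is.na(sd$age_group))) {
        .expand_groups(sd$age_group, sd$decrement, rs$ages)
      } else sd$decrement[1]
    }
    Tn <- length(rs$life_years)
    q <- vapply(seq_len(Tn), function(t) {
      burden <- matrix(rs$prev_mid[t, , ], ncol = length(rs$diseases))
      w <- pmax(0, 1 - rowSums(burden * dec))
      sum(rs$ly_age[t, ] * w)
    }, numeric(1))
    tibble::tibble(year = seq_len(Tn) - 1L, sex = sx, qaly = q)
  })
}

#' Healthcare cost stream
#'
#' Prevalence-basis diseases cost `cost_per_case` per prevalent case-year;
#' incidence-basis diseases cost once per incident case. Hypertensive heart
#' disease contributes zero cost by construction.
#'
#' @param run A `ssbtax_run`.
#' @param costs Tibble `disease`, `sex`, `age_group`, `cost_per_case` (BRL).
#' @param specs Disease table from [disease_specs()] (supplies the cost
#'   basis).
#' @return Tibble `year`, `sex`, `cost` (BRL, undiscounted).
#' @export
cost_stream <- function(run, costs, specs = disease_specs()) {
  stopifnot(inherits(run, "ssbtax_run"))
  if (any(costs$cost_per_case < 0)) stop("costs must be >= 0", call. = FALSE)
  if (any(costs$cost_per_case[costs$disease == "HHD"] != 0)) {
    warning("HHD costs are fixed at zero; nonzero entries ignored", call. = FALSE)
    costs$cost_per_case[costs$disease == "HHD"] <- 0
  }
  purrr::imap_dfr(run$by_sex, function(rs, sx) {
    cm <- matrix(0, length(rs$ages), length(rs$diseases),
                 dimnames = list(rs$ages, rs$diseases))
    sub <- costs[costs$sex == sx, ]
    for (d in intersect(rs$diseases, unique(sub$disease))) {
      sd <- sub[sub$disease == d, ]
      cm[, d] <- .expand_groups(sd$age_group, sd$cost_per_case, rs$ages)
    }
    basis <- specs$cost_basis[match(rs$diseases, specs$disease)]
    basis[is.na(basis)] <- "incidence"
    Tn <- length(rs$life_years)
    cost <- vapply(seq_len(Tn), function(t) {
      tot <- 0
      for (j in seq_along(rs$diseases)) {
        vol <- if (basis[j] == "prevalence") rs$prev_py[t, , j] else rs$inc_cases[t, , j]
        tot <- tot + sum(vol * cm[, j])
      }
      tot
    }, numeric(1))
    tibble::tibble(year = seq_len(Tn) - 1L, sex = sx, cost = cost)
  })
}

#' Present value of a yearly stream
#'
#' `PV = sum_y v_y / (1 + rate)^(y - base)`; the base year is undiscounted.
#'
#' @param values Yearly values.
#' @param rate Discount rate (>= 0).
#' @param years Year indices (default 0-based sequence).
#' @param base Base year index.
#' @return Present value (scalar).
#' @export
discount <- function(values, rate, years = seq_along(values) - 1L, base = 0) {
  if (rate < 0) stop("`rate` must be >= 0", call. = FALSE)
  sum(values / (1 + rate)^(years - base))
}

#' Compare baseline and intervention runs
#'
#' QALY gains and cost savings are present-value differences at the
#' configured discount rate (costs converted to international dollars at the
#' PPP factor); cases averted are undiscounted incident-case differences over
#' the case horizon. Per-capita scalings use the initial adult cohort.
#'
#' @param baseline,intervention `ssbtax_run` objects on the same cohort.
#' @param decrements Utility decrements for [qaly_stream()].
#' @param costs Cost table for [cost_stream()].
#' @param config A [sim_config()]; defaults to the runs' config.
#' @return A `ssbtax_delta` tibble: per sex, `qaly_gain`, `qaly_per_million`,
#'   `cost_saving_int` (Int$), `cost_saving_per_100k`, and one
#'   `cases_averted_<disease>` and `cases_averted_per_100k_<disease>` column
#'   pair per disease.
#' @export
compare_runs <- function(baseline, intervention, decrements, costs,
                         config = NULL) {
  stopifnot(inherits(baseline, "ssbtax_run"), inherits(intervention, "ssbtax_run"))
  if (is.null(config)) config <- baseline$config
  if (!identical(names(baseline$by_sex), names(intervention$by_sex)) ||
      !identical(baseline$ages, intervention$ages)) {
    stop("runs are on mismatched cohorts", call. = FALSE)
  }
  for (sx in names(baseline$by_sex)) {
    if (abs(baseline$by_sex[[sx]]$init_total -
            intervention$by_sex[[sx]]$init_total) > 1e-6) {
      stop("runs are on mismatched cohorts", call. = FALSE)
    }
  }
  q0 <- qaly_stream(baseline, decrements)
  q1 <- qaly_stream(intervention, decrements)
  c0 <- cost_stream(baseline, costs)
  c1 <- cost_stream(intervention, costs)
  r <- config$discount_rate
  out <- purrr::map_dfr(names(baseline$by_sex), function(sx) {
    n0 <- baseline$by_sex[[sx]]$init_total
    qg <- discount(q1$qaly[q1$sex == sx], r) - discount(q0$qaly[q0$sex == sx], r)
    cs <- (discount(c0$cost[c0$sex == sx], r) -
             discount(c1$cost[c1$sex == sx], r)) / config$ppp_factor
    row <- tibble::tibble(sex = sx, qaly_gain = qg,
                          qaly_per_million = qg / n0 * 1e6,
                          cost_saving_int = cs,
                          cost_saving_per_100k = cs / n0 * 1e5)
    hz <- seq_len(min(config$case_horizon, length(baseline$by_sex[[sx]]$life_years)))
    for (j in seq_along(baseline$diseases)) {
      d <- baseline$diseases[j]
      av <- sum(baseline$by_sex[[sx]]$inc_cases[hz, , j]) -
        sum(intervention$by_sex[[sx]]$inc_cases[hz, , j])
      row[[paste0("cases_averted_", d)]] <- av
      row[[paste0("cases_averted_per_100k_", d)]] <- av / n0 * 1e5
    }
    row
  })
  structure(out, class = c("ssbtax_delta", class(out)), config = config)
}
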