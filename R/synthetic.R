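#' @title Synthetic input bundles
#'
#' @description
#' Generates complete, internally consistent input bundles emulating the
#' national data sources the model expects (household-budget beverage
#' consumption, survey BMI distributions, burden-of-disease epidemiology,
#' hospital admission costs, census population), so that every stage and the
#' end-to-end pipeline can run and be tested without external downloads.
#' Epidemiological surfaces are built by forward simulation from parametric
#' (Gompertz-like) incidence and case-fatality curves, so the consistency
#' solvers round-trip by construction. BMI strata are calibrated to the
#' published overweight/obesity prevalence pattern, rescaled to hit the
#' all-adult obesity anchors exactly; elasticity magnitudes are
#' literature-plausible stand-ins scaled to hit the energy-intake anchors.
#'
#' @name synthetic-data
NULL

#' Configuration of the synthetic bundle
#'
#' @param seed Integer seed; the bundle is reproducible byte-for-byte.
#' @param pop_scale Cohort size per sex.
#' @param obesity_target Named vector, all-adult baseline obesity proportion
#'   per sex (defaults: men 0.198, women 0.236).
#' @param dei_target Named vector, population-mean energy-intake change in
#'   kcal/person/day under the 20% tax, per income level (defaults: total
#'   -26.4, lower -18.1, upper -29.0).
#' @param rate_scale Multiplier on all disease incidence/fatality curves.
#' @return A `ssbtax_fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, pop_scale = 1e5,
                           obesity_target = c(male = 0.198, female = 0.236),
                           dei_target = c(total = -26.4, lower = -18.1,
                                          upper = -29.0),
                           rate_scale = 1) {
  stopifnot(all(obesity_target > 0 & obesity_target < 1), rate_scale > 0)
  structure(list(seed = as.integer(seed), pop_scale = pop_scale,
                 obesity_target = obesity_target, dei_target = dei_target,
                 rate_scale = rate_scale),
            class = "ssbtax_fixture_config")
}

#' Five-year age-group labels covering the model ages
#' @return Character vector `"20-24"` ... `"90-94"`, `"95+"`.
#' @export
age_group_labels <- function() {
  c(paste(seq(20, 90, 5), seq(24, 94, 5), sep = "-"), "95+")
}

# Published overweight/obesity baseline pattern by sex and age group
# (proportions, "total" income), used as the calibration shape.
.bmi_pattern <- function() {
  g <- age_group_labels()
  men_ob <- c(9.4, 15.8, 22.4, 24.6, 22.8, 24.6, 22.8, 22.3, 21.1, 17.8,
              17.8, 15.0, 11.4, 4.3, 10.9, 10.9) / 100
  men_ow <- c(29.9, 38.9, 41.5, 43.6, 45.1, 44.5, 42.8, 42.3, 43.4, 42.9,
              39.2, 38.1, 41.1, 35.1, 32.3, 32.3) / 100
  wom_ob <- c(13.5, 19.7, 23.6, 25.0, 27.0, 25.8, 26.7, 26.8, 25.2, 26.2,
              25.2, 19.8, 18.9, 14.8, 12.5, 12.5) / 100
  wom_ow <- c(26.6, 29.4, 30.4, 35.4, 36.3, 36.6, 37.2, 35.8, 38.7, 38.1,
              36.0, 33.9, 33.1, 31.4, 25.0, 25.0) / 100
  dplyr::bind_rows(
    tibble::tibble(sex = "male", age_group = g, obesity = men_ob, overweight = men_ow),
    tibble::tibble(sex = "female", age_group = g, obesity = wom_ob, overweight = wom_ow)
  )
}

# Normal BMI parameters reproducing (overweight, obesity) at cutpoints 25/30.
.bmi_from_targets <- function(overweight, obesity) {
  z1 <- stats::qnorm(1 - overweight - obesity)
  z2 <- stats::qnorm(1 - obesity)
  sd <- 5 / (z2 - z1)
  tibble::tibble(mean_bmi = 25 - sd * z1, sd_bmi = sd)
}

# Gompertz-like disease rate parameters (per person-year at age 20, log
# slope per year of age), sex multipliers applied downstream.
.disease_params <- function() {
  tibble::tribble(
    ~disease,        ~i0,     ~gi,   ~f0,    ~gf,   ~male_mult,
    "T2DM",          2.0e-3,  0.045, 2.5e-3, 0.050, 1.0,
    "IHD",           6.0e-4,  0.055, 4.0e-3, 0.055, 2.0,
    "stroke",        3.5e-4,  0.060, 5.0e-3, 0.055, 1.1,
    "HHD",           1.8e-4,  0.060, 3.0e-3, 0.060, 0.8,
    "low_back_pain", 1.6e-2,  0.012, 0,      0,     0.8,
    "hip_OA",        6.0e-4,  0.035, 0,      0,     0.9,
    "knee_OA",       1.2e-3,  0.038, 0,      0,     0.7
  )
}

#' Generate a full synthetic input bundle
#'
#' @param cfg A [fixture_config()].
#' @return A named list (`ssbtax_bundle`) with elements `categories`,
#'   `consumption`, `elasticities`, `elasticity_se`, `bmi_baseline`,
#'   `population`, `epi`, `epi_grouped`, `mortality`, `rr`, `mediation`,
#'   `utility`, `costs`, and the generating parameters in
#'   `attr(, "generator")`.
#' @export
make_fixture <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "ssbtax_fixture_config"))
  withr_seed(cfg$seed, .make_fixture_impl(cfg))
}

.make_fixture_impl <- function(cfg) {
  ages <- model_ages()
  groups <- age_group_labels()
  sexes <- c("female", "male")
  incomes <- c("lower", "total", "upper")
  cats <- beverage_categories()

  # --- population: declining pseudo-pyramid, pop_scale per sex ------------
  shape <- exp(-0.028 * (ages - 20))
  population <- tidyr::expand_grid(sex = sexes, age = ages) |>
    dplyr::mutate(count = cfg$pop_scale * shape[match(.data$age, ages)] / sum(shape))
  grp_of <- function(a) groups[pmin(findInterval(a, seq(20, 95, 5)), 16)]
  pop_groups <- population |>
    dplyr::mutate(age_group = grp_of(.data$age)) |>
    dplyr::group_by(.data$sex, .data$age_group) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")

  # --- BMI strata: published pattern, rescaled to the obesity anchors ------
  pat <- .bmi_pattern()
  pat <- dplyr::inner_join(pat, pop_groups, by = c("sex", "age_group"))
  pat <- pat |>
    dplyr::group_by(.data$sex) |>
    dplyr::mutate(obesity = .data$obesity *
                    cfg$obesity_target[[unique(.data$sex)]] /
                    stats::weighted.mean(.data$obesity, .data$count)) |>
    dplyr::ungroup()
  inc_adj <- tibble::tibble(income = incomes,
                            ob_mult = c(0.90, 1.00, 1.12),
                            ow_mult = c(0.96, 1.00, 1.04))
  bmi_baseline <- tidyr::expand_grid(pat, income = incomes) |>
    dplyr::inner_join(inc_adj, by = "income") |>
    dplyr::mutate(obesity = pmin(.data$obesity * .data$ob_mult, 0.6),
                  overweight = pmin(.data$overweight * .data$ow_mult, 0.6)) |>
    dplyr::mutate(.bmi_from_targets(.data$overweight, .data$obesity),
                  mean_height_m = ifelse(.data$sex == "male", 1.73, 1.61)) |>
    dplyr::select("sex", "age_group", "income", "mean_bmi", "sd_bmi",
                  "mean_height_m")

  # --- beverage consumption: mL/person/day by category and stratum --------
  base_vol <- c(60, 120, 40, 50, 30, 25, 10)  # by category id
  age_idx <- seq_along(groups)
  age_factor <- 1.5 - 0.9 * (age_idx - 1) / (length(groups) - 1)
  consumption <- tidyr::expand_grid(sex = sexes, age_group = groups,
                                    income = incomes, category = cats$id) |>
    dplyr::mutate(
      volume_ml_day = base_vol[.data$category] *
        age_factor[match(.data$age_group, groups)] *
        ifelse(.data$sex == "male", 1.2, 0.85) *
        c(lower = 0.8, total = 1.0, upper = 1.15)[.data$income] *
        exp(stats::rnorm(dplyr::n(), 0, 0.03))
    )

  # --- elasticities: plausible stand-ins scaled to the dEI anchors ---------
  E <- matrix(0.05, 7, 7)
  diag(E) <- c(-1.00, -1.10, -0.95, -1.00, -0.90, -0.85, -0.80)
  E[6, ] <- 0; E[, 6][-6] <- 0.02
  E[6, 2] <- 0.40; E[6, 6] <- -0.85   # diet substitutes for soft drinks
  el_base <- tidyr::expand_grid(income = incomes, row_category = 1:7,
                                col_category = 1:7) |>
    dplyr::mutate(value = E[cbind(.data$row_category, .data$col_category)])
  # population-mean dEI under the 20% tax with the unscaled matrix
  scale_for <- function(inc) {
    ec <- energy_change(consumption[consumption$income == inc, ],
                        el_base[el_base$income == inc, ],
                        tax_scenario(0.20, 1.0), cats)
    w <- pop_groups$count[match(paste(ec$sex, ec$age_group),
                                paste(pop_groups$sex, pop_groups$age_group))]
    cfg$dei_target[[inc]] / stats::weighted.mean(ec$delta_kcal_day, w)
  }
  scales <- vapply(incomes, scale_for, numeric(1))
  elasticities <- el_base |>
    dplyr::mutate(value = .data$value * scales[.data$income])
  elasticity_se <- elasticities |>
    dplyr::mutate(se = abs(.data$value) * 0.02) |>
    dplyr::select(-"value")

  # --- epidemiology: forward-simulated, self-consistent surfaces ----------
  dp <- .disease_params()
  bg_pars <- c(male = 9e-4, female = 6e-4)
  mortality <- tidyr::expand_grid(sex = sexes, age = ages) |>
    dplyr::mutate(value = bg_pars[.data$sex] * exp(0.085 * (.data$age - 20)))
  epi <- purrr::pmap_dfr(tidyr::expand_grid(dp, sex = sexes),
    function(disease, i0, gi, f0, gf, male_mult, sex) {
      mult <- if (sex == "male") male_mult else 1
      i <- cfg$rate_scale * mult * i0 * exp(gi * (ages - 20))
      f <- cfg$rate_scale * f0 * exp(gf * (ages - 20))
      bg <- bg_pars[[sex]] * exp(0.085 * (ages - 20))
      fwd <- forward_three_state(i, f, bg, p0 = 0, ages = ages)
      tibble::tibble(disease = disease, sex = sex, age = ages,
                     incidence = i, prevalence = fwd$prevalence,
                     case_fatality = f, cause_mortality = fwd$cause_mortality)
    })
  # all-cause = background + modelled cause mortality at baseline prevalence
  cause_tot <- epi |>
    dplyr::group_by(.data$sex, .data$age) |>
    dplyr::summarise(cm = sum(.data$prevalence * .data$case_fatality),
                     .groups = "drop")
  mortality <- mortality |>
    dplyr::inner_join(cause_tot, by = c("sex", "age")) |>
    dplyr::mutate(value = .data$value + .data$cm) |>
    dplyr::select("sex", "age", "value")
  # grouped long-format inputs (rates), person-time weighted
  epi_grouped <- epi |>
    dplyr::mutate(age_group = grp_of(.data$age)) |>
    dplyr::group_by(.data$disease, .data$sex, .data$age_group) |>
    dplyr::summarise(incidence = mean(.data$incidence),
                     prevalence = mean(.data$prevalence),
                     deaths = mean(.data$cause_mortality), .groups = "drop") |>
    tidyr::pivot_longer(c("incidence", "prevalence", "deaths"),
                        names_to = "measure", values_to = "value")
  epi <- dplyr::select(epi, -"cause_mortality")

  # --- relative risks, mediation, utilities, costs ------------------------
  rr <- tidyr::expand_grid(
    tibble::tribble(
      ~disease,        ~rr5, ~rr5_lo, ~rr5_hi,
      "T2DM",          2.20, 1.90,    2.55,
      "IHD",           1.50, 1.35,    1.67,
      "stroke",        1.40, 1.25,    1.57,
      "HHD",           1.60, 1.40,    1.83,
      "low_back_pain", 1.15, 1.08,    1.22,
      "hip_OA",        1.25, 1.15,    1.36,
      "knee_OA",       1.35, 1.22,    1.49
    ), sex = sexes)
  mediation <- tibble::tibble(
    pathway = c("rr_ihd", "rr_stroke"),
    rr = c(2.00, 1.80), lo = c(1.70, 1.50), hi = c(2.35, 2.16)
  )
  utility <- tidyr::expand_grid(
    tibble::tribble(
      ~disease,        ~decrement, ~se,
      "T2DM",          0.06, 0.012,
      "IHD",           0.08, 0.016,
      "stroke",        0.12, 0.024,
      "HHD",           0.07, 0.014,
      "low_back_pain", 0.05, 0.010,
      "hip_OA",        0.06, 0.012,
      "knee_OA",       0.06, 0.012
    ), sex = sexes)
  cost_mean <- c(T2DM = 800, IHD = 8000, stroke = 9000, HHD = 0,
                 low_back_pain = 300, hip_OA = 12000, knee_OA = 11000)
  costs <- tidyr::expand_grid(disease = names(cost_mean), sex = sexes,
                              age_group = groups) |>
    dplyr::mutate(
      cost_per_case = cost_mean[.data$disease] *
        exp(stats::rnorm(dplyr::n(), 0, 0.05)) *
        (1 + 0.004 * (match(.data$age_group, groups) - 1)),
      cost_per_case = ifelse(.data$disease == "HHD", 0, .data$cost_per_case),
      rel_sd = 0.20
    )

  structure(list(
    categories = cats, consumption = consumption,
    elasticities = elasticities, elasticity_se = elasticity_se,
    bmi_baseline = bmi_baseline, population = population,
    epi = epi, epi_grouped = epi_grouped, mortality = mortality,
    rr = rr, mediation = mediation, utility = utility, costs = costs
  ), class = "ssbtax_bundle",
  generator = list(config = cfg, disease_params = dp, bg_pars = bg_pars,
                   elasticity_scales = scales))
}

#' Null-intervention bundle
#'
#' Identical to [make_fixture()] but with all elasticities set to zero, so
#' the tax produces no demand response and the pipeline must return an
#' all-zero outcome delta.
#'
#' @inheritParams make_fixture
#' @return A `ssbtax_bundle`.
#' @export
make_null_fixture <- function(cfg = fixture_config()) {
  b <- make_fixture(cfg)
  b$elasticities$value <- 0
  b$elasticity_se$se <- 0
  b
}

#' Three-age, one-disease toy life table
#'
#' A cohort small enough that survivors, incident cases, QALYs and costs can
#' be recomputed by hand; used as the spreadsheet-style oracle fixture for
#' the life-table engine. The companion file
#' `inst/extdata/toy_lifetable_expected.csv` stores the frozen expected
#' outputs.
#'
#' @return List with `epi`, `population`, `mortality`, `config`, `pif_tbl`,
#'   `utility`, `costs`.
#' @export
make_toy_lifetable <- function() {
  ages <- 60:62
  epi <- tibble::tibble(
    disease = "T2DM", sex = "male", age = ages,
    incidence = c(0.10, 0.12, 0.15),
    prevalence = c(0.20, 0.25, 0.30),
    case_fatality = c(0.05, 0.06, 0.07)
  )
  population <- tibble::tibble(sex = "male", age = ages,
                               count = c(1000, 800, 600))
  mortality <- tibble::tibble(sex = "male", age = ages,
                              value = c(0.020, 0.025, 0.030) +
                                epi$prevalence * epi$case_fatality)
  pif_tbl <- tibble::tibble(disease = "T2DM", sex = "male",
                            age_group = "60+", income = "total",
                            year = Inf, pif = 0.2)
  utility <- tibble::tibble(disease = "T2DM", sex = "male", decrement = 0.1)
  costs <- tibble::tibble(disease = "T2DM", sex = "male", age_group = "60+",
                          cost_per_case = 1000)
  list(epi = epi, population = population, mortality = mortality,
       config = sim_config(min_age = 60, max_age = 62, discount_rate = 0.05,
                           case_horizon = 3),
       pif_tbl = pif_tbl, utility = utility, costs = costs)
}

#' Write a bundle to CSV files
#'
#' @param bundle A `ssbtax_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(bundle, dir) {
  stopifnot(inherits(bundle, "ssbtax_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in names(bundle)) {
    readr::write_csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Read a bundle written by [write_fixture()]
#'
#' @param dir Directory containing the CSV files.
#' @return A `ssbtax_bundle`.
#' @export
read_fixture <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  b <- purrr::map(files, readr::read_csv, show_col_types = FALSE)
  names(b) <- sub("\\.csv$", "", basename(files))
  structure(b, class = "ssbtax_bundle")
}
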