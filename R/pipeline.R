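#' @title End-to-end tax impact pipeline
#'
#' @description
#' Chains the modules: tax scenario -> price and demand response -> energy
#' intake change per stratum -> Hall weight trajectories -> BMI shifts and
#' PIFs -> multistate life table for baseline and intervention -> outcome
#' deltas (QALYs, costs, cases averted), with optional Monte Carlo
#' uncertainty.
#'
#' @name pipeline
NULL

#' Prepare a simulation for one income level
#'
#' Computes everything that does not change across Monte Carlo draws: the
#' stratum energy-intake changes, the Hall weight responses, and the baseline
#' life-table run (whose states are draw-independent).
#'
#' @param bundle Input bundle (see [make_fixture()] for the expected
#'   elements).
#' @param income Income level: `"total"`, `"lower"` or `"upper"`.
#' @param scenario A [tax_scenario()].
#' @param config A [sim_config()].
#' @return A `ssbtax_prepared` list.
#' @export
prepare_simulation <- function(bundle, income = "total",
                               scenario = tax_scenario(),
                               config = sim_config()) {
  cons <- bundle$consumption[bundle$consumption$income == income, ]
  el <- bundle$elasticities[bundle$elasticities$income == income, ]
  ec <- energy_change(cons, el, scenario, bundle$categories)
  bmi <- bundle$bmi_baseline[bundle$bmi_baseline$income == income, ]
  wr <- stratum_weight_response(ec, bmi)
  baseline <- run_cohort(bundle$epi, bundle$population, bundle$mortality,
                         config)
  structure(list(bundle = bundle, income = income, scenario = scenario,
                 config = config, energy_change = ec, weight_response = wr,
                 baseline = baseline),
            class = "ssbtax_prepared")
}

#' Run one scenario evaluation, optionally under a parameter draw
#'
#' Applies a Monte Carlo draw (if any) to the uncertain parameters, builds
#' the PIF table, runs the intervention life table with diabetes mediation,
#' and compares it against the baseline run.
#'
#' @param prep A `ssbtax_prepared` from [prepare_simulation()].
#' @param draw Named list of parameter values (see [build_mc_params()]);
#'   `NULL` uses the point estimates.
#' @param mediate Apply the diabetes-to-IHD/stroke mediation (default TRUE).
#' @return A `ssbtax_delta` tibble (one row per sex).
#' @export
simulate_scenario <- function(prep, draw = NULL, mediate = TRUE) {
  stopifnot(inherits(prep, "ssbtax_prepared"))
  b <- prep$bundle
  rr <- b$rr
  util <- b$utility
  costs <- b$costs
  wr <- prep$weight_response
  med <- list(rr_ihd = b$mediation$rr[b$mediation$pathway == "rr_ihd"],
              rr_stroke = b$mediation$rr[b$mediation$pathway == "rr_stroke"])
  if (!is.null(draw)) {
    for (d in unique(rr$disease)) {
      key <- paste0("rr_", d)
      if (key %in% names(draw)) rr$rr5[rr$disease == d] <- draw[[key]]
    }
    if ("rr_dm_ihd" %in% names(draw)) med$rr_ihd <- draw$rr_dm_ihd
    if ("rr_dm_stroke" %in% names(draw)) med$rr_stroke <- draw$rr_dm_stroke
    for (d in unique(util$disease)) {
      key <- paste0("u_", d)
      if (key %in% names(draw)) util$decrement[util$disease == d] <- draw[[key]]
    }
    for (d in unique(costs$disease)) {
      key <- paste0("cost_", d)
      if (key %in% names(draw)) {
        costs$cost_per_case[costs$disease == d] <-
          costs$cost_per_case[costs$disease == d] * draw[[key]]
      }
    }
    if ("dei_scale" %in% names(draw)) {
      # Hall response is linear in the intake change at this scale, so the
      # weight columns scale with the intervention-effect draw.
      wcols <- grep("^delta_weight", names(wr), value = TRUE)
      wr[wcols] <- wr[wcols] * draw$dei_scale
    }
  }
  ptab <- pif_table(wr, rr, tmrel = prep$config$tmrel)
  intervention <- run_cohort(b$epi, b$population, b$mortality, prep$config,
                             pif_tbl = ptab,
                             mediation = if (mediate) med,
                             baseline_run = prep$baseline)
  compare_runs(prep$baseline, intervention, util, costs, prep$config)
}

#' One-shot tax impact at point estimates
#'
#' @inheritParams prepare_simulation
#' @param mediate Apply diabetes mediation.
#' @return A `ssbtax_delta` tibble.
#' @export
tax_impact <- function(bundle, income = "total", scenario = tax_scenario(),
                       config = sim_config(), mediate = TRUE) {
  prep <- prepare_simulation(bundle, income, scenario, config)
  simulate_scenario(prep, mediate = mediate)
}

#' Uncertain-parameter table for a bundle
#'
#' Builds the Monte Carlo sampling specification from the bundle's parameter
#' tables: lognormal relative risks (from their 95% CIs), truncated-normal
#' utility decrements, gamma cost multipliers (mean 1, relative SD from the
#' cost table), and a normal multiplier on the intervention's energy-intake
#' effect.
#'
#' @param bundle Input bundle.
#' @param dei_rel_ci Half-width of the 95% CI on the intervention effect,
#'   relative to its mean (default 0.032, the relative width of the
#'   energy-intake change interval).
#' @return Tibble for [mc_spec()].
#' @export
build_mc_params <- function(bundle, dei_rel_ci = 0.032) {
  rr1 <- bundle$rr[!duplicated(bundle$rr$disease), ]
  params <- dplyr::bind_rows(
    tibble::tibble(name = paste0("rr_", rr1$disease), law = "lognormal_ci",
                   mean = rr1$rr5, lo = rr1$rr5_lo, hi = rr1$rr5_hi,
                   sd = NA_real_),
    tibble::tibble(name = c("rr_dm_ihd", "rr_dm_stroke"), law = "lognormal_ci",
                   mean = bundle$mediation$rr, lo = bundle$mediation$lo,
                   hi = bundle$mediation$hi, sd = NA_real_),
    {
      u1 <- bundle$utility[!duplicated(bundle$utility$disease), ]
      tibble::tibble(name = paste0("u_", u1$disease), law = "truncnorm",
                     mean = u1$decrement, lo = NA_real_, hi = NA_real_,
                     sd = u1$se)
    },
    {
      c1 <- bundle$costs[!duplicated(bundle$costs$disease), ]
      tibble::tibble(name = paste0("cost_", c1$disease), law = "gamma_meansd",
                     mean = 1, lo = NA_real_, hi = NA_real_, sd = c1$rel_sd)
    },
    tibble::tibble(name = "dei_scale", law = "normal_ci", mean = 1,
                   lo = 1 - dei_rel_ci, hi = 1 + dei_rel_ci, sd = NA_real_)
  )
  params$sd[params$name == "cost_HHD"] <- 0
  params
}

#' Monte Carlo tax impact with uncertainty intervals
#'
#' Repeats [simulate_scenario()] under parameter draws and summarises each
#' outcome cell (per sex: QALYs per million, cost savings per 100,000,
#' cases averted per 100,000 per disease) by mean and 95% uncertainty
#' interval.
#'
#' @inheritParams tax_impact
#' @param n_runs Monte Carlo runs (2000 for the full design; smaller values
#'   for quick work).
#' @param seed Integer seed; identical seed and spec replay identically.
#' @param params Parameter table; default [build_mc_params()].
#' @return A `ssbtax_mc` tibble (`cell`, `mean`, `lo95`, `hi95`).
#' @export
tax_impact_mc <- function(bundle, income = "total", scenario = tax_scenario(),
                          config = sim_config(), n_runs = 2000, seed = 1L,
                          params = build_mc_params(bundle), mediate = TRUE) {
  prep <- prepare_simulation(bundle, income, scenario, config)
  spec <- mc_spec(params, n_runs = n_runs, seed = seed)
  model <- function(draw) {
    delta_to_cells(simulate_scenario(prep, draw, mediate = mediate))
  }
  run_mc(model, spec)
}

#' Flatten an outcome delta to named cells
#'
#' @param delta A `ssbtax_delta`.
#' @return Named numeric vector `<sex>.<measure>`.
#' @export
delta_to_cells <- function(delta) {
  cols <- setdiff(names(delta), "sex")
  cells <- unlist(lapply(seq_len(nrow(delta)), function(i) {
    stats::setNames(as.numeric(delta[i, cols]),
                    paste(delta$sex[i], cols, sep = "."))
  }))
  cells
}
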