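#' @title Demand response: tax to prices, volumes, and energy intake
#'
#' @description
#' Converts a beverage tax scenario into consumer price changes, purchased
#' volume changes through own- and cross-price elasticities, and the implied
#' change in daily energy intake per population stratum. The response is
#' first-order: fixed point elasticities applied to a single proportional
#' price change.
#'
#' @name demand-response
NULL

#' Default beverage categories
#'
#' The seven non-alcoholic beverage categories used in the tax simulation,
#' with taxability flags and energy densities. Sugar-containing categories
#' (1-5, 7) are taxed; light/diet soft drinks (6) are untaxed but respond to
#' the tax through cross-price elasticities. Taxability is a plain column and
#' can be overridden.
#'
#' @return Tibble with columns `id`, `name`, `taxed`, `kcal_per_ml`.
#' @export
beverage_categories <- function() {
  tibble::tibble(
    id = 1:7,
    name = c("sugary juices/drinks", "soft drinks", "sugary dairy drinks",
             "sweetened juices/drinks", "sweetened dairy drinks",
             "light/diet soft drinks", "sports/energy drinks"),
    taxed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    kcal_per_ml = c(0.45, 0.42, 0.70, 0.40, 0.65, 0.02, 0.45)
  )
}

.check_categories <- function(categories) {
  req <- c("id", "name", "taxed", "kcal_per_ml")
  if (!all(req %in% names(categories))) {
    stop("`categories` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(categories$id)) stop("category ids must be unique", call. = FALSE)
  if (any(categories$kcal_per_ml < 0)) stop("energy densities must be >= 0", call. = FALSE)
  invisible(categories)
}

#' Define a tax scenario
#'
#' @param tax_rate Ad valorem tax rate as a proportion (0.20 for the 20%
#'   excise base case).
#' @param pass_through Fraction of the tax transmitted to consumer prices
#'   (1 = full pass-through, the best-case assumption).
#' @return A `ssbtax_scenario` list.
#' @export
tax_scenario <- function(tax_rate = 0.20, pass_through = 1.0) {
  if (!is.finite(tax_rate) || tax_rate < 0) stop("`tax_rate` must be >= 0", call. = FALSE)
  if (!is.finite(pass_through) || pass_through < 0 || pass_through > 1) {
    stop("`pass_through` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(tax_rate = tax_rate, pass_through = pass_through),
            class = "ssbtax_scenario")
}

#' Price changes implied by a tax scenario
#'
#' Taxed categories see a proportional price increase of
#' `tax_rate * pass_through`; untaxed categories see none.
#'
#' @param categories Category table (see [beverage_categories()]), first
#'   argument so calls chain with the pipe.
#' @param scenario A [tax_scenario()].
#' @return The category tibble with a `price_change` column (proportion).
#' @export
build_price_change <- function(categories = beverage_categories(),
                               scenario = tax_scenario()) {
  .check_categories(categories)
  stopifnot(inherits(scenario, "ssbtax_scenario"))
  dplyr::mutate(categories,
                price_change = ifelse(.data$taxed,
                                      scenario$tax_rate * scenario$pass_through, 0))
}

#' Volume response through price elasticities
#'
#' First-order demand response: for category i with baseline volume V_i,
#' `delta_volume_i = V_i * sum_j e_ij * price_change_j`, where `e_ij` is the
#' percent volume change of category i per 1% price change of category j.
#' Untaxed categories can still change through cross-price terms. Post-change
#' volumes are floored at zero (with a warning) since the linear response
#' carries no physical constraint.
#'
#' @param consumption Long tibble of baseline volumes with columns `sex`,
#'   `age_group`, `income`, `category` (id), `volume_ml_day`.
#' @param elasticities Long tibble with columns `income`, `row_category`,
#'   `col_category`, `value` (the 7x7 matrix per income stratum).
#' @param price_changes Output of [build_price_change()] (columns `id`,
#'   `price_change`).
#' @return `consumption` with columns `delta_volume_ml_day` and
#'   `volume_post_ml_day` added.
#' @export
apply_elasticities <- function(consumption, elasticities, price_changes) {
  req <- c("sex", "age_group", "income", "category", "volume_ml_day")
  if (!all(req %in% names(consumption))) {
    stop("`consumption` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(consumption$volume_ml_day < 0)) stop("volumes must be >= 0", call. = FALSE)
  # Percent-volume response per category and income stratum:
  # r_i = sum_j e_ij * dP_j.
  resp <- elasticities |>
    dplyr::inner_join(
      dplyr::select(price_changes, col_category = "id", "price_change"),
      by = "col_category"
    ) |>
    dplyr::group_by(.data$income, category = .data$row_category) |>
    dplyr::summarise(rel_change = sum(.data$value * .data$price_change),
                     .groups = "drop")
  missing <- dplyr::anti_join(
    dplyr::distinct(consumption, .data$income, .data$category),
    resp, by = c("income", "category")
  )
  if (nrow(missing) > 0) {
    stop("missing elasticity row for category ",
         paste(unique(missing$category), collapse = ", "),
         " (income ", paste(unique(missing$income), collapse = ", "), ")",
         call. = FALSE)
  }
  out <- consumption |>
    dplyr::inner_join(resp, by = c("income", "category")) |>
    dplyr::mutate(delta_volume_ml_day = .data$volume_ml_day * .data$rel_change,
                  volume_post_ml_day = .data$volume_ml_day + .data$delta_volume_ml_day) |>
    dplyr::select(-"rel_change")
  if (any(out$volume_post_ml_day < 0)) {
    warning("post-change volumes below zero were floored at 0", call. = FALSE)
    out <- dplyr::mutate(
      out,
      delta_volume_ml_day = pmax(.data$volume_post_ml_day, 0) - .data$volume_ml_day,
      volume_post_ml_day = pmax(.data$volume_post_ml_day, 0)
    )
  }
  out
}

#' Energy-intake change from volume changes
#'
#' Sums `delta_volume * energy_density` over categories within each stratum:
#' `delta_kcal = sum_i delta_V_i * kappa_i` (kcal/person/day).
#'
#' @param volume_changes Output of [apply_elasticities()].
#' @param categories Category table with `id` and `kcal_per_ml`.
#' @return Tibble with one row per (`sex`, `age_group`, `income`) and column
#'   `delta_kcal_day`.
#' @export
volume_to_energy <- function(volume_changes, categories = beverage_categories()) {
  .check_categories(categories)
  miss <- setdiff(unique(volume_changes$category), categories$id)
  if (length(miss) > 0) {
    stop("no energy density for category ", paste(miss, collapse = ", "), call. = FALSE)
  }
  volume_changes |>
    dplyr::inner_join(dplyr::select(categories, category = "id", "kcal_per_ml"),
                      by = "category") |>
    dplyr::group_by(.data$sex, .data$age_group, .data$income) |>
    dplyr::summarise(
      delta_kcal_day = sum(.data$delta_volume_ml_day * .data$kcal_per_ml),
      .groups = "drop"
    )
}

#' Convert beverage servings to millilitres
#'
#' Standard servings are converted at 250 mL per serving.
#'
#' @param servings Number of servings (>= 0).
#' @return Volume in mL.
#' @export
servings_to_ml <- function(servings) {
  if (any(!is.finite(servings)) || any(servings < 0)) {
    stop("`servings` must be >= 0", call. = FALSE)
  }
  250 * servings
}

#' Full demand step: scenario to energy-intake change
#'
#' Convenience wrapper chaining [build_price_change()],
#' [apply_elasticities()] and [volume_to_energy()].
#'
#' @inheritParams apply_elasticities
#' @inheritParams build_price_change
#' @return Tibble of `delta_kcal_day` per (`sex`, `age_group`, `income`).
#' @export
energy_change <- function(consumption, elasticities,
                          scenario = tax_scenario(),
                          categories = beverage_categories()) {
  pc <- build_price_change(categories, scenario)
  apply_elasticities(consumption, elasticities, pc) |>
    volume_to_energy(categories)
}

#' Monte Carlo confidence bounds on the energy-intake change
#'
#' Propagates user-supplied standard errors on the elasticity entries to the
#' stratum-level energy change by resampling the elasticity matrix
#' (independent normal perturbations per entry) and recomputing the demand
#' step.
#'
#' @inheritParams energy_change
#' @param elasticity_se Tibble matching `elasticities` with column `se`
#'   replacing `value`; entries absent from it get zero standard error.
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return `energy_change()` output with `lower` and `upper` (2.5th/97.5th
#'   centile) columns.
#' @export
energy_change_bounds <- function(consumption, elasticities, elasticity_se,
                                 scenario = tax_scenario(),
                                 categories = beverage_categories(),
                                 n = 200, seed = 1L) {
  base <- energy_change(consumption, elasticities, scenario, categories)
  el <- dplyr::left_join(
    elasticities,
    dplyr::rename(elasticity_se, se = "se"),
    by = intersect(names(elasticities)[names(elasticities) != "value"],
                   names(elasticity_se))
  )
  el$se[is.na(el$se)] <- 0
  draws <- withr_seed(seed, {
    purrr::map(seq_len(n), function(k) {
      ek <- dplyr::mutate(el, value = .data$value + stats::rnorm(dplyr::n(), 0, .data$se))
      energy_change(consumption, dplyr::select(ek, -"se"), scenario, categories)$delta_kcal_day
    })
  })
  m <- do.call(cbind, draws)
  base$lower <- apply(m, 1, stats::quantile, probs = 0.025, names = FALSE)
  base$upper <- apply(m, 1, stats::quantile, probs = 0.975, names = FALSE)
  base
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  code
}
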