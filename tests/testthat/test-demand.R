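test_that("price changes follow tax rate times pass-through for taxed categories", {
  cats <- beverage_categories()
  pc <- build_price_change(cats, tax_scenario(0.20, 1.0))
  expect_equal(pc$price_change[pc$taxed], rep(0.20, sum(cats$taxed)))
  expect_equal(pc$price_change[!pc$taxed], rep(0, sum(!cats$taxed)))
  expect_equal(unique(build_price_change(cats, tax_scenario(0.20, 0))$price_change), 0)
  pc2 <- build_price_change(cats, tax_scenario(0.10, 0.5))
  expect_equal(pc2$price_change[pc2$taxed][1], 0.05)
  expect_error(tax_scenario(-0.1), "tax_rate")
  expect_error(tax_scenario(0.2, 1.4), "pass_through")
})

test_that("volume response reproduces hand arithmetic for own and cross terms", {
  cats <- tibble::tibble(id = 1:2, name = c("a", "b"),
                         taxed = c(TRUE, TRUE), kcal_per_ml = c(0.4, 0.4))
  cons <- tibble::tibble(sex = "male", age_group = "20-24", income = "total",
                         category = 1:2, volume_ml_day = c(250, 100))
  # own-price only: V 250 mL, e_own = -1, dP = 0.20 -> -50 mL/day
  el <- tibble::tibble(income = "total",
                       row_category = c(1, 1, 2, 2),
                       col_category = c(1, 2, 1, 2),
                       value = c(-1, 0, 0, 0))
  v <- apply_elasticities(cons, el, build_price_change(cats, tax_scenario(0.20, 1)))
  expect_equal(v$delta_volume_ml_day[v$category == 1], -50)
  expect_equal(v$delta_volume_ml_day[v$category == 2], 0)
  # cross term: e_12 = +0.5, dP_2 = 0.20, V_1 = 100 -> +10 mL/day
  cons2 <- dplyr::mutate(cons, volume_ml_day = c(100, 50))
  el2 <- dplyr::mutate(el, value = c(0, 0.5, 0, 0))
  v2 <- apply_elasticities(cons2, el2, build_price_change(cats, tax_scenario(0.20, 1)))
  expect_equal(v2$delta_volume_ml_day[v2$category == 1], 10)
  # null price change
  v0 <- apply_elasticities(cons, el, build_price_change(cats, tax_scenario(0, 1)))
  expect_equal(v0$delta_volume_ml_day, c(0, 0))
  # missing elasticity row names the category
  expect_error(
    apply_elasticities(cons, el[el$row_category == 1, ],
                       build_price_change(cats, tax_scenario(0.20, 1))),
    "category 2"
  )
})

test_that("energy conversion sums volume changes times energy density", {
  cats <- tibble::tibble(id = 1:2, name = c("sug", "diet"),
                         taxed = c(TRUE, FALSE), kcal_per_ml = c(0.4, 0))
  vc <- tibble::tibble(sex = "male", age_group = "20-24", income = "total",
                       category = 1:2, volume_ml_day = c(200, 50),
                       delta_volume_ml_day = c(-50, 30),
                       volume_post_ml_day = c(150, 80))
  e <- volume_to_energy(vc, cats)
  expect_equal(e$delta_kcal_day, -50 * 0.4)  # diet category contributes 0
  vc0 <- dplyr::mutate(vc, delta_volume_ml_day = 0)
  expect_equal(volume_to_energy(vc0, cats)$delta_kcal_day, 0)
})

test_that("servings convert at 250 mL per serving", {
  expect_equal(servings_to_ml(1), 250)
  expect_equal(servings_to_ml(0), 0)
  expect_equal(servings_to_ml(2.5), 625)
  expect_error(servings_to_ml(-1))
})

test_that("demand response is linear and matches a brute-force category sum", {
  b <- default_bundle()
  cons <- b$consumption[b$consumption$income == "total", ]
  el <- b$elasticities[b$elasticities$income == "total", ]
  e1 <- energy_change(cons, el, tax_scenario(0.10, 1.0))
  e2 <- energy_change(cons, el, tax_scenario(0.20, 1.0))
  expect_equal(e2$delta_kcal_day, 2 * e1$delta_kcal_day, tolerance = 1e-12)
  # null scenario gives an identically zero table
  e0 <- energy_change(cons, el, tax_scenario(0, 1.0))
  expect_true(all(e0$delta_kcal_day == 0))
  e0b <- energy_change(cons, el, tax_scenario(0.2, 0))
  expect_true(all(e0b$delta_kcal_day == 0))
  # brute-force hand sum over the 7 categories for a few strata
  pc <- build_price_change(b$categories, tax_scenario(0.20, 1.0))
  emat <- matrix(0, 7, 7)
  emat[cbind(el$row_category, el$col_category)] <- el$value
  strata <- dplyr::distinct(e2, sex, age_group)[c(1, 9, 20), ]
  for (k in seq_len(nrow(strata))) {
    sub <- cons[cons$sex == strata$sex[k] & cons$age_group == strata$age_group[k], ]
    sub <- sub[order(sub$category), ]
    dv <- sub$volume_ml_day * as.vector(emat %*% pc$price_change)
    expected <- sum(dv * b$categories$kcal_per_ml)
    got <- e2$delta_kcal_day[e2$sex == strata$sex[k] &
                               e2$age_group == strata$age_group[k]]
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("post-change volumes are floored at zero with a warning", {
  cats <- tibble::tibble(id = 1, name = "a", taxed = TRUE, kcal_per_ml = 0.4)
  cons <- tibble::tibble(sex = "male", age_group = "20-24", income = "total",
                         category = 1, volume_ml_day = 100)
  el <- tibble::tibble(income = "total", row_category = 1, col_category = 1,
                       value = -6)
  expect_warning(
    v <- apply_elasticities(cons, el, build_price_change(cats, tax_scenario(0.20, 1))),
    "floored"
  )
  expect_equal(v$volume_post_ml_day, 0)
  expect_equal(v$delta_volume_ml_day, -100)
})

test_that("elasticity-uncertainty bounds bracket the point estimate", {
  b <- default_bundle()
  cons <- b$consumption[b$consumption$income == "total", ]
  el <- b$elasticities[b$elasticities$income == "total", ]
  se <- b$elasticity_se[b$elasticity_se$income == "total", ]
  bounds <- energy_change_bounds(cons, el, se, n = 50, seed = 7)
  expect_true(all(bounds$lower <= bounds$delta_kcal_day + 1e-9))
  expect_true(all(bounds$upper >= bounds$delta_kcal_day - 1e-9))
  # zero standard errors collapse the interval
  se0 <- dplyr::mutate(se, se = 0)
  b0 <- energy_change_bounds(cons, el, se0, n = 20, seed = 7)
  expect_equal(b0$lower, b0$delta_kcal_day, tolerance = 1e-12)
  expect_equal(b0$upper, b0$delta_kcal_day, tolerance = 1e-12)
})
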