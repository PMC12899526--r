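groups_for <- function(values) {
  tibble::tibble(age_group = age_group_labels(), value = values)
}

test_that("smoothing preserves constants and group means", {
  const <- smooth_to_single_year(groups_for(rep(0.02, 16)))
  expect_equal(const$value, rep(0.02, 81), tolerance = 1e-12)
  # group-wise re-aggregation matches the input (mean preservation)
  set.seed(5)
  for (k in 1:10) {
    vals <- runif(16, 0, 0.2)
    sm <- smooth_to_single_year(groups_for(vals))
    expect_true(all(sm$value >= 0))
    groups <- age_group_labels()
    idx <- pmin(findInterval(sm$age, seq(20, 95, 5)), 16)
    reagg <- as.vector(tapply(sm$value, idx, mean))
    expect_equal(reagg, vals, tolerance = 1e-8)
  }
  # linear-in-age group means come back (approximately) linear
  mids <- c(seq(22, 92, 5), 97.5)
  lin <- smooth_to_single_year(groups_for(0.001 * mids))
  fit <- lm(value ~ age, data = lin[lin$age < 95, ])
  expect_gt(summary(fit)$r.squared, 0.999)
  expect_error(smooth_to_single_year(groups_for(rep(0.1, 16))[-3, ]), "missing")
})

test_that("forward three-state simulation obeys its closed forms", {
  ages <- model_ages()
  n <- length(ages)
  z <- rep(0, n)
  # no incidence, start healthy: prevalence stays zero
  fwd0 <- forward_three_state(z, z, rep(0.01, n), p0 = 0)
  expect_true(all(fwd0$prevalence == 0))
  # f = background = 0, constant incidence: p(a+1) = p(a) + (1-p(a))(1-e^-i)
  i <- rep(0.03, n)
  fwd <- forward_three_state(i, z, z, p0 = 0)
  p_exp <- numeric(n)
  for (k in 2:n) p_exp[k] <- p_exp[k - 1] + (1 - p_exp[k - 1]) * (1 - exp(-0.03))
  expect_equal(fwd$prevalence, p_exp, tolerance = 1e-12)
  expect_true(all(diff(fwd$prevalence) >= 0))  # zero-remission monotonicity
  # mass conservation at every age
  fwd2 <- forward_three_state(i, rep(0.05, n), rep(0.02, n), p0 = 0.1)
  expect_equal(fwd2$healthy + fwd2$diseased + fwd2$dead_cum, rep(1, n),
               tolerance = 1e-12)
})

test_that("case fatality round-trips through the forward model", {
  ages <- model_ages()
  n <- length(ages)
  i <- 0.002 * exp(0.04 * (ages - 20))
  f_true <- rep(0.05, n)
  bg <- 0.001 * exp(0.08 * (ages - 20))
  fwd <- forward_three_state(i, f_true, bg, p0 = 0)
  sol <- solve_case_fatality(i, fwd$prevalence, fwd$cause_mortality, bg,
                             quiet = TRUE)
  # skip the first ages where there are no diseased yet
  ok <- fwd$prevalence > 1e-4
  expect_lt(max(abs(sol$case_fatality[ok] - f_true[ok]) / f_true[ok]), 0.02)
  # zero cause mortality gives zero case fatality
  sol0 <- solve_case_fatality(i, fwd$prevalence, rep(0, n), bg, quiet = TRUE)
  expect_equal(sol0$case_fatality, rep(0, n))
  # infeasible input (deaths but no prevalent cases) exercises the clamp path
  expect_message(
    solc <- solve_case_fatality(rep(0, n), rep(0, n), rep(0.01, n), bg),
    "clamped"
  )
  expect_gt(attr(solc, "n_clamped"), 0)
})

test_that("incidence is recovered from prevalence under zero remission", {
  ages <- model_ages()
  n <- length(ages)
  i_true <- 0.003 * exp(0.03 * (ages - 20))
  f <- rep(0.04, n)
  bg <- 0.001 * exp(0.08 * (ages - 20))
  fwd <- forward_three_state(i_true, f, bg, p0 = 0)
  inv <- infer_incidence(fwd$prevalence, f, bg)
  ok <- seq_len(n - 1)  # last age has no next-age constraint
  expect_lt(max(abs(inv$incidence[ok] - i_true[ok]) / i_true[ok]), 0.02)
  # zero prevalence everywhere gives zero incidence
  inv0 <- infer_incidence(rep(0, n), f, bg)
  expect_equal(inv0$incidence, rep(0, n))
  # prevalence falling faster than mortality can explain is infeasible
  p_bad <- pmax(0.5 - 0.05 * (ages - 20), 0)
  expect_error(infer_incidence(p_bad, rep(0, n), rep(0, n)), "remission")
})

test_that("grouped inputs produce a consistent single-year surface", {
  b <- default_bundle()
  out <- consistent_epi(b$epi_grouped, b$mortality)
  expect_setequal(unique(out$disease), disease_specs()$disease)
  expect_true(all(out$incidence >= 0 & out$case_fatality >= 0))
  expect_true(all(out$prevalence >= 0 & out$prevalence < 1))
  # non-fatal diseases get zero case fatality
  nf <- disease_specs()$disease[!disease_specs()$has_death_state]
  expect_true(all(out$case_fatality[out$disease %in% nf] == 0))
  # recovered case fatality tracks the generating curve away from the edges
  gen <- attr(b, "generator")$disease_params
  f_gen <- gen$f0[gen$disease == "IHD"] * exp(gen$gf[gen$disease == "IHD"] *
                                                (model_ages() - 20))
  got <- out[out$disease == "IHD" & out$sex == "male", ]
  mid <- got$age >= 40 & got$age <= 90
  expect_lt(stats::median(abs(got$case_fatality[mid] - f_gen[mid]) / f_gen[mid]),
            0.10)
})
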