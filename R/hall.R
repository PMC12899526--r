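#' @title Hall dynamic energy-balance model for adult body weight
#'
#' @description
#' Implements the adult body-weight dynamics of Hall and colleagues: a
#' compartment model tracking body fat, lean tissue, glycogen (with its bound
#' water), extracellular fluid, and adaptive thermogenesis under a change in
#' daily energy intake. The model's headline behaviour for a sustained intake
#' change is an approximately exponential approach to a new equilibrium
#' weight, with roughly 1 kg of eventual weight change per 100 kJ/day of
#' sustained intake change and about 95% of the change reached by three
#' years.
#'
#' All internal energy units are kJ/day; kcal inputs are converted at
#' 4.184 kJ/kcal.
#'
#' @name hall-model
NULL

# Model coefficients (Hall adult model). Energy densities in kJ/kg,
# rate coefficients in kJ/kg/day, eta terms in kJ/kg.
.hall_const <- list(
  rho_F   = 39500,  # fat tissue energy density
  rho_L   = 7600,   # lean tissue energy density
  rho_G   = 17600,  # glycogen energy density (dry)
  gamma_F = 13,     # resting metabolic cost of fat mass
  gamma_L = 92,     # resting metabolic cost of lean mass
  eta_F   = 750,    # fat synthesis/turnover cost
  eta_L   = 960,    # lean synthesis/turnover cost
  beta_TEF = 0.10,  # thermic effect of food, fraction of intake
  beta_AT  = 0.14,  # adaptive thermogenesis, fraction of intake change
  tau_AT   = 14,    # adaptive thermogenesis time constant, days
  G_b      = 0.5,   # baseline glycogen, kg
  h_G      = 2.7,   # kg water bound per kg glycogen
  carb_frac = 0.5,  # carbohydrate fraction of intake
  Na_conc  = 3220,  # extracellular sodium concentration, mg/L
  xi_Na    = 3000,  # sodium excretion response, mg/L/day
  xi_CI    = 4000,  # carbohydrate effect on renal sodium, mg/day
  Na_b     = 4000,  # baseline sodium intake, mg/day
  kcal_to_kJ = 4.184
)

#' Kilocalories to kilojoules
#'
#' @param kcal Energy in kcal.
#' @return Energy in kJ (4.184 kJ per kcal).
#' @export
kcal_to_kj <- function(kcal) kcal * .hall_const$kcal_to_kJ

#' Define a reference individual
#'
#' A reference individual anchors the population-level weight response: each
#' population stratum is simulated through one individual carrying the
#' stratum's mean BMI, sex-specific mean height, and age-group midpoint.
#'
#' @param sex `"male"` or `"female"`.
#' @param age Age in years (adults, 18+).
#' @param height Height in metres; must lie in (1.2, 2.2).
#' @param weight Weight in kg.
#' @param pal Physical activity level (total energy expenditure over resting),
#'   dimensionless, >= 1. Used to set baseline energy intake.
#' @return A `ssbtax_individual` list with fields `sex`, `age`, `height`,
#'   `weight`, `pal`.
#' @export
reference_individual <- function(sex = c("male", "female"), age = 40,
                                 height = 1.75, weight = 85, pal = 1.6) {
  sex <- match.arg(sex)
  if (!is.finite(height) || height <= 1.2 || height >= 2.2) {
    stop("`height` must lie in (1.2, 2.2) metres", call. = FALSE)
  }
  if (!is.finite(weight) || weight <= 0) stop("`weight` must be positive", call. = FALSE)
  if (!is.finite(age) || age < 18 || age > 110) {
    stop("`age` must be an adult age in years", call. = FALSE)
  }
  if (!is.finite(pal) || pal < 1) stop("`pal` must be >= 1", call. = FALSE)
  structure(list(sex = sex, age = age, height = height, weight = weight, pal = pal),
            class = "ssbtax_individual")
}

# Deurenberg body-fat regression: percent body fat from BMI, age, sex.
.body_fat_fraction <- function(bmi, age, sex) {
  male <- as.numeric(sex == "male")
  bf <- (1.20 * bmi + 0.23 * age - 10.8 * male - 5.4) / 100
  pmin(pmax(bf, 0.05), 0.60)
}

# Mifflin-St Jeor resting metabolic rate, kcal/day.
.rmr_kcal <- function(weight, height, age, sex) {
  s <- if (sex == "male") 5 else -161
  10 * weight + 625 * height - 5 * age + s
}

#' Initialize the energy-balance state of an individual
#'
#' Constructs a Hall-model state in energy equilibrium: simulating the state
#' with a zero intake change holds body weight constant. Baseline fat mass is
#' taken from the Deurenberg BMI-age-sex regression, lean mass closes the mass
#' balance, and the maintenance constant is solved from the baseline energy
#' budget. The physical-activity coefficient is, by default, calibrated so
#' that the model reproduces the equilibrium rule of 1 kg of eventual weight
#' change per `rho_rule` kJ/day of sustained intake change.
#'
#' @param ind A [reference_individual()].
#' @param energy_intake Baseline energy intake, kJ/day. Default: resting
#'   metabolic rate (Mifflin-St Jeor) times `ind$pal`.
#' @param delta_pa Physical-activity energy cost per kg of body weight,
#'   kJ/kg/day. Default `NULL` calibrates it to the `rho_rule` equilibrium.
#' @param rho_rule Equilibrium response used for the default calibration,
#'   kJ/day of sustained intake change per kg of eventual weight change.
#' @return A `ssbtax_hall_state` list with compartments `fat`, `lean`,
#'   `glycogen`, `ecf` (deviation from baseline, L), `at` (adaptive
#'   thermogenesis, kJ/day) and model constants.
#' @export
initialize_balance <- function(ind, energy_intake = NULL, delta_pa = NULL,
                               rho_rule = 100) {
  stopifnot(inherits(ind, "ssbtax_individual"))
  cn <- .hall_const
  bmi <- ind$weight / ind$height^2
  if (bmi < 12 || bmi > 70) stop("nonphysical anthropometry: BMI outside (12, 70)", call. = FALSE)
  fat <- .body_fat_fraction(bmi, ind$age, ind$sex) * ind$weight
  lean <- ind$weight - fat
  if (is.null(energy_intake)) {
    energy_intake <- kcal_to_kj(.rmr_kcal(ind$weight, ind$height, ind$age, ind$sex)) * ind$pal
  }
  if (energy_intake <= 0) stop("`energy_intake` must be positive", call. = FALSE)
  if (is.null(delta_pa)) {
    # Calibrate so a sustained change dEI settles at dEI / rho_rule kg:
    # (1 - beta_TEF - beta_AT) * rho_rule = (gamma_F + gamma_L q)/(1 + q) + delta_pa
    # with q = dL/dF = 10.4 / fat (Forbes partitioning at baseline).
    q <- 10.4 / fat
    delta_pa <- (1 - cn$beta_TEF - cn$beta_AT) * rho_rule -
      (cn$gamma_F + cn$gamma_L * q) / (1 + q)
    if (delta_pa < 0) delta_pa <- 0
  }
  K <- (1 - cn$beta_TEF) * energy_intake -
    cn$gamma_F * fat - cn$gamma_L * lean - delta_pa * ind$weight
  structure(list(
    fat = fat, lean = lean, glycogen = cn$G_b, ecf = 0, at = 0,
    weight0 = ind$weight, height = ind$height, sex = ind$sex, age = ind$age,
    EI0 = energy_intake, K = K, delta_pa = delta_pa
  ), class = "ssbtax_hall_state")
}

#' Body weight of a Hall state
#'
#' Sum of the fat and lean compartments plus glycogen-bound water and the
#' extracellular-fluid deviation from baseline.
#'
#' @param state A `ssbtax_hall_state`.
#' @return Body weight in kg.
#' @export
hall_weight <- function(state) {
  cn <- .hall_const
  state$fat + state$lean + (state$glycogen - cn$G_b) * (1 + cn$h_G) + state$ecf
}

# Quasi-steady glycogen and extracellular-fluid deviations under a constant
# intake change. Both compartments equilibrate within days, far below the
# integration step, so they are treated as instantaneous functions of the
# intake change rather than stiff state variables.
.hall_fast <- function(st, delta_EI) {
  cn <- .hall_const
  ci_ratio <- (st$EI0 + delta_EI) / st$EI0
  G <- cn$G_b * sqrt(max(ci_ratio, 0))
  dNa <- cn$Na_b * delta_EI / st$EI0
  ecf <- (dNa - cn$xi_CI * (1 - ci_ratio)) / cn$xi_Na
  list(glycogen = G, ecf = ecf,
       mass = (G - cn$G_b) * (1 + cn$h_G) + ecf)
}

# Time derivatives of the slow subsystem (fat, lean, adaptive thermogenesis);
# y is the state vector, delta_EI the sustained intake change in kJ/day,
# fast_mass the quasi-steady glycogen-water + fluid mass deviation.
.hall_deriv <- function(y, st, delta_EI, fast_mass) {
  cn <- .hall_const
  F_ <- y[1]; L_ <- y[2]; AT <- y[3]
  EI <- st$EI0 + delta_EI
  dAT <- (cn$beta_AT * delta_EI - AT) / cn$tau_AT
  bw <- F_ + L_ + fast_mass
  resid <- (1 - cn$beta_TEF) * EI - AT -
    (st$K + cn$gamma_F * F_ + cn$gamma_L * L_ + st$delta_pa * bw)
  p <- (10.4 * cn$rho_L / cn$rho_F) / (10.4 * cn$rho_L / cn$rho_F + F_)
  eb <- resid / (1 + cn$eta_F * (1 - p) / cn$rho_F + cn$eta_L * p / cn$rho_L)
  dF <- (1 - p) * eb / cn$rho_F
  dL <- p * eb / cn$rho_L
  c(dF, dL, dAT)
}

#' Simulate a body-weight trajectory under a sustained intake change
#'
#' Integrates the Hall compartment system with a fixed-step fourth-order
#' Runge-Kutta scheme and returns the yearly (or finer) weight and BMI
#' trajectory. Under a constant negative intake change the trajectory
#' decreases monotonically towards an asymptote.
#'
#' @param state A `ssbtax_hall_state` from [initialize_balance()].
#' @param delta_EI Sustained change in energy intake, kJ/day (negative for a
#'   reduction). Use [kcal_to_kj()] for kcal inputs.
#' @param horizon Simulation horizon in years.
#' @param step Integration step in years; must be at most 1/52 (weekly).
#' @param out_times Times (years) at which to report the trajectory; default
#'   a weekly grid.
#' @return A `ssbtax_trajectory` tibble with columns `time` (years),
#'   `weight` (kg), `bmi` (kg/m^2); the initial state is row one. Attributes
#'   carry `delta_EI` and the originating state.
#' @export
simulate_weight <- function(state, delta_EI, horizon = 10, step = 1 / 52,
                            out_times = NULL) {
  stopifnot(inherits(state, "ssbtax_hall_state"))
  if (!is.finite(delta_EI)) stop("`delta_EI` must be finite", call. = FALSE)
  if (step > 1 / 52 + 1e-12) stop("`step` must be <= 1/52 year for stability", call. = FALSE)
  dt_days <- step * 365
  n_steps <- ceiling(horizon / step)
  if (is.null(out_times)) out_times <- seq(0, horizon, by = 1 / 52)
  out_times <- sort(unique(pmin(out_times, horizon)))

  y <- c(state$fat, state$lean, state$at)
  fast <- .hall_fast(state, delta_EI)
  bw_of <- function(y, fm) y[1] + y[2] + fm
  w0 <- bw_of(y, 0)  # baseline: fast compartments at their baseline values

  times <- numeric(n_steps + 1)
  weights <- numeric(n_steps + 1)
  weights[1] <- w0
  for (k in seq_len(n_steps)) {
    k1 <- .hall_deriv(y, state, delta_EI, fast$mass)
    k2 <- .hall_deriv(y + dt_days / 2 * k1, state, delta_EI, fast$mass)
    k3 <- .hall_deriv(y + dt_days / 2 * k2, state, delta_EI, fast$mass)
    k4 <- .hall_deriv(y + dt_days * k3, state, delta_EI, fast$mass)
    y <- y + dt_days / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(y)) || y[1] < 0 || y[2] < 0 ||
        abs(bw_of(y, fast$mass) - w0) > 0.9 * w0) {
      stop("integration diverged; use a smaller `step`", call. = FALSE)
    }
    times[k + 1] <- k * step
    weights[k + 1] <- bw_of(y, fast$mass)
  }
  w_out <- stats::approx(times, weights, xout = out_times, rule = 2)$y
  out <- tibble::tibble(time = out_times, weight = w_out,
                        bmi = w_out / state$height^2)
  structure(out, class = c("ssbtax_trajectory", class(out)),
            delta_EI = delta_EI, state = state)
}

#' Equilibrium weight change implied by the 100 kJ/day rule
#'
#' The reduced-form anchor of the dynamic model: every sustained `rho_rule`
#' kJ/day change in energy intake eventually changes body weight by 1 kg.
#' Serves as the closed-form oracle for [simulate_weight()].
#'
#' @param delta_EI Sustained intake change, kJ/day.
#' @param rho_rule kJ/day per kg of eventual weight change (default 100).
#' @return Equilibrium weight change in kg.
#' @export
equilibrium_weight_change <- function(delta_EI, rho_rule = 100) {
  delta_EI / rho_rule
}

#' Reduced-form exponential weight trajectory
#'
#' One-line stand-in for the full compartment model: an exponential approach
#' to the equilibrium of [equilibrium_weight_change()] with time constant
#' `tau` years, so 95% of the change is reached by `3 * tau` years.
#'
#' @param delta_EI Sustained intake change, kJ/day.
#' @param times Times in years.
#' @param tau Time constant in years (default 1).
#' @param rho_rule Passed to [equilibrium_weight_change()].
#' @return Tibble with `time` and `delta_weight` (kg).
#' @export
reduced_weight_trajectory <- function(delta_EI, times, tau = 1, rho_rule = 100) {
  dw <- equilibrium_weight_change(delta_EI, rho_rule)
  tibble::tibble(time = times, delta_weight = dw * (1 - exp(-times / tau)))
}

#' Weight change summary of a trajectory
#'
#' @param traj A `ssbtax_trajectory`.
#' @return Named list: `delta_final` (kg change at the last time point) and
#'   `fraction_at` function mapping a time in years to the achieved fraction
#'   of the final change.
#' @export
trajectory_summary <- function(traj) {
  stopifnot(inherits(traj, "ssbtax_trajectory"))
  w0 <- traj$weight[1]
  dfin <- traj$weight[nrow(traj)] - w0
  list(
    delta_final = dfin,
    fraction_at = function(t) {
      wt <- stats::approx(traj$time, traj$weight, xout = t, rule = 2)$y
      if (abs(dfin) < 1e-12) return(rep(0, length(t)))
      (wt - w0) / dfin
    }
  )
}
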