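---
title: "Modelling the health and cost impacts of a sugar-sweetened beverage tax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the health and cost impacts of a sugar-sweetened beverage tax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbtax)
```

# Overview

`ssbtax` simulates what an excise tax on sugar-sweetened beverages (SSBs)
does to population health and public healthcare spending, using a
proportional multistate life table. The causal chain is: higher prices
suppress beverage demand (price elasticities); lower beverage volumes lower
daily energy intake; a sustained energy deficit lowers body weight (Hall
energy-balance dynamics) and shifts the BMI distribution; lower BMI lowers
the incidence of BMI-related chronic disease (potential impact fractions);
and lower incidence accumulates into life-years, quality-adjusted life-years
(QALYs), healthcare costs and disease cases over the lifetime of a closed
adult cohort.

The model's base case mirrors a 20% ad valorem tax with 100% pass-through to
consumer prices, a closed cohort of adults aged 20+ starting in 2022, QALYs
and costs discounted at 5% per year over the remaining lifetime, and disease
cases counted undiscounted over 20 years. All three choices are
configuration, not code: `tax_scenario()`, `sim_config()`.

# Demand response

Seven beverage categories are modelled: five sugar-containing categories
plus sports/energy drinks are taxed; light/diet soft drinks are untaxed but
respond through cross-price elasticities. Taxability is a column in the
category table and can be overridden.

The response is first order: fixed point elasticities applied to a single
proportional price change. The volume change of category $i$ is
$\Delta V_i = V_i \sum_j e_{ij}\,\Delta P_j / P_j$ and the stratum's
energy-intake change $\Delta EI = \sum_i \Delta V_i \kappa_i$ (kcal/day),
with $\kappa_i$ the category energy density (kcal/mL). We deliberately do
not model demand-curve curvature: for a one-off 20% price change, fixed
point elasticities are the standard treatment, and the curvature of the
underlying demand system is not identifiable from the published elasticity
matrix alone. Two consequences matter downstream: the response is exactly
linear in the price change (tested), and post-change volumes can in
principle go negative, so they are floored at zero with a warning — the
floor is a physical constraint absent from the linear model.

Strata are sex × five-year age group × income level (total population,
lower and upper income), matching the reporting grain of household-budget
and health-survey data. Single-year ages inherit their five-year group's
$\Delta EI$. Confidence bounds on $\Delta EI$ can be propagated from
user-supplied elasticity standard errors by Monte Carlo
(`energy_change_bounds()`); the propagation law (independent normal
perturbations per matrix entry) is a package choice, since elasticity
covariance matrices are rarely published.

# Weight dynamics

Sustained intake changes are converted to weight trajectories with the Hall
adult energy-balance system: body fat and lean tissue exchange energy with
an expenditure that depends on both masses and on body weight (physical
activity), fat/lean partitioning follows the Forbes relationship
($dL/dF = 10.4/F$), the thermic effect of food is 10% of intake, and
adaptive thermogenesis opposes 14% of the intake change with a two-week time
constant. Energy densities are 39.5 MJ/kg (fat) and 7.6 MJ/kg (lean), with
tissue-turnover costs of 750 and 960 kJ/kg.

Two numerical choices deserve explanation:

* **Quasi-steady fast compartments.** Glycogen (with 2.7 kg of bound water
  per kg) and extracellular fluid respond to an intake change within days —
  three orders of magnitude faster than the fat/lean dynamics. Keeping them
  as state variables makes the system stiff and a weekly fixed step
  unstable. Because the intervention is a *sustained* intake change, both
  compartments are treated as instantaneous functions of the new intake
  level; for the intake changes this model sees (tens of kJ/day) their
  contribution is of order 0.03 kg. The slow fat/lean/adaptive-thermogenesis
  system is integrated with a fixed-step fourth-order Runge-Kutta scheme at
  a weekly step, which is smooth, reproducible, and verified in the test
  suite against an adaptive stiff solver (`deSolve::lsoda` at rtol 1e-10).
* **Calibration of the activity coefficient.** The model's published
  headline anchor is that 100 kJ/day of sustained change moves equilibrium
  weight by 1 kg. That slope equals
  $(1-\beta_{TEF}-\beta_{AT})\,\rho_{rule} = \tilde\gamma + \delta$, where
  $\tilde\gamma$ is the Forbes-weighted tissue metabolic rate and $\delta$
  the physical-activity cost per kg of body weight. Rather than hard-coding
  a sedentary $\delta$ and accepting whatever equilibrium slope results, the
  default calibrates $\delta$ so the 100 kJ/day-per-kg rule holds exactly
  for the individual at hand (a `delta_pa` argument overrides this). For the
  default reference adult (male, 40 y, 1.75 m, 85 kg — an average overweight
  adult, fat mass from the Deurenberg BMI–age–sex regression) the calibrated
  $\delta$ is ≈38 kJ/kg/day, a light-activity level.

A caveat the package states openly: the three textbook anchors of these
dynamics — 1 kg per 100 kJ/day, half the change "in about a year", 95% of
the change by three years — are mutually inconsistent for any
relaxation-type dynamics (50% at year 1 caps year 3 at 87.5% for mixtures of
exponentials). The implementation anchors the equilibrium rule exactly and
reproduces the three-year fraction closely; the implied one-year fraction is
then ≈60%, i.e. the half-change point falls at ≈0.8 years rather than 1.0.
The acceptance suite encodes all three published anchors as written, and the
one-year check is expected to sit just outside its band; we prefer reporting
that tension to retuning the physiology. The reduced exponential form
$\Delta w(t) = \Delta w_\infty (1 - e^{-t/\tau})$ with $\tau = 1$ y (which
reproduces 95% at three years exactly) is exposed both as a validation
oracle and as a cheap fallback (`reduced_weight_trajectory()`).

Population strata are simulated through one reference individual per
stratum: the age-group midpoint, the sex's mean height, and the stratum's
mean BMI. Within-stratum heterogeneity of the weight response is ignored —
one $\Delta EI$ per stratum is applied. BMI distributions are normal by
default (lognormal optional) and shift by location only,
$\Delta\mu = \Delta w / h^2$, with the spread unchanged; no published rule
exists for how an intervention reshapes the higher moments, and a location
shift is the transparent default. Overweight and obesity are the
conventional tail areas at 25 and 30 kg/m².

# Disease inputs

Each disease follows a three-state model (healthy, diseased, dead; the
musculoskeletal conditions have no disease-specific death state) with zero
remission. Burden-of-disease inputs typically arrive on five-year age
groups and are internally inconsistent at single-year resolution, so the
package provides a deterministic consistency layer:

* `smooth_to_single_year()` interpolates the *cumulative person-time
  integral* of a grouped rate with a monotone (Hyman-filtered) cubic spline
  and differences it back to single years. This makes the smoothing exactly
  mean-preserving per age group and nonnegative by construction — the two
  properties that matter downstream — at the cost of not being a named
  published smoother.
* `solve_case_fatality()` finds, age by age (ascending, root-finding per
  age), the case-fatality hazard that makes the forward three-state cohort
  reproduce observed cause-specific mortality; `infer_incidence()` does the
  analogous inversion from prevalence. Where the data admit no nonnegative
  solution (e.g. cause deaths with no prevalent cases, as happens in real
  hypertensive-heart-disease inputs) the solver clamps and logs rather than
  failing. A Bayesian evidence-synthesis treatment of the same consistency
  problem exists; the deterministic solver is used because only the point
  estimates feed the life table — parameter uncertainty enters through the
  Monte Carlo layer instead.

The forward simulator `forward_three_state()` doubles as the oracle for both
inverse solvers (round-trip tests at 2%).

# Life table and outcomes

The engine is a proportional multistate life table: the cohort is structured
by sex and single year of age; each disease contributes a healthy/diseased
split carried as fractions of the alive cohort. Total mortality each cycle
composes the background hazard with the prevalence-weighted case-fatality
hazards; background is defined as all-cause mortality *net of* the modelled
causes at baseline prevalence, so the baseline life table reproduces the
all-cause input without double counting. Diseases are independent except
for diabetes, which multiplies IHD and stroke incidence by the population
risk ratio $(1 + p_1(RR-1))/(1 + p_0(RR-1))$, with $p_0$ the baseline-run
and $p_1$ the intervention-run diabetes prevalence (both measured at the
start of the cycle).

Numerical conventions: annual cycles; life-years (and with them QALYs and
prevalence-based costs) accrue with a half-cycle correction; age 100 is
absorbing — the terminal age's cycle is the cohort's last, which affects
both scenarios identically and therefore largely cancels in deltas;
incidence is applied before mortality within a cycle, which gives the
textbook prevalence recursion in the no-mortality limit.

Intervention effects enter as potential impact fractions on incidence,
computed by 1000-point midpoint quadrature of the BMI density on
[10, 60] kg/m² with the dose-response
$RR(b) = RR_5^{\max(b - TMREL, 0)/5}$ (log-linear per 5 BMI units above the
theoretical minimum-risk exposure level, flat below; TMREL default
22.5 kg/m², configurable). PIFs are phased in over the first five years
following the simulated weight trajectory — the achieved BMI shift of each
year, not a linear ramp — and held at equilibrium thereafter, reflecting a
tax that stays in place for the cohort's lifetime. An exact mass-point
evaluation path exists and is the enumeration oracle for the quadrature.

QALYs weight life-years by $\max(0, 1 - \sum_d p_d \cdot dec_d)$ (additive
decrements, floored). Costs follow each disease's costing basis: per
prevalent case-year for T2DM and low back pain, once per incident case for
IHD, stroke and the osteoarthritides; hypertensive heart disease is carried
at zero cost (its admission costs cannot be attributed consistently in the
source systems). Costs convert from BRL to international dollars at the
2021 PPP factor 2.531. QALY gains and cost savings are present-value
differences (5% base, 0%/10% sensitivity; year 0 undiscounted); cases
averted are undiscounted incident-case differences over 20 cycles.
Per-capita scalings (per million, per 100,000) use the initial adult cohort.

# Uncertainty

Per-run sampling laws follow health-economics convention: relative risks
and the two diabetes-pathway relative risks are lognormal, parameterised
from their 95% CIs; utility decrements are normal truncated to [0, 1]; costs
get a gamma multiplier matched to mean 1 and the table's relative SD; the
intervention effect is a normal multiplier on $\Delta EI$. The Hall response
is linear in $\Delta EI$ at these magnitudes, so the weight trajectory is
scaled rather than re-integrated per draw (verified to 2% in tests). One
random-number stream per run, indexed by run id, keeps baseline and
intervention on common draws within a run, so deltas reflect parameter
uncertainty rather than sampling noise; a failing run is re-drawn, with a
1% failure budget before aborting. Intervals are empirical 2.5th/97.5th
centiles (linear interpolation of order statistics) over 2000 runs by
default.

# Synthetic data

`make_fixture()` generates the full input bundle the pipeline needs. Its
defaults *are* the study conditions: 100,000 adults per sex on a declining
pseudo-pyramid; baseline overweight/obesity following the published sex ×
age pattern, rescaled so all-adult obesity is 19.8% (men) and 23.6% (women);
mean energy-intake changes under the 20% tax calibrated to −26.4 (total),
−18.1 (lower income) and −29.0 (upper income) kcal/person/day by scaling a
literature-plausible elasticity matrix (own-price ≈ −1.1 for soft drinks,
small positive cross terms, diet drinks substituting toward taxed soft
drinks); Gompertz-like incidence and case-fatality curves per disease,
forward-simulated so the epidemiological surfaces are self-consistent and
the consistency solvers round-trip by construction; and admission-style
cost tables with a zero-cost hypertensive heart disease row.

What the generator does *not* emulate: survey microdata (individual records,
weights, design effects), real elasticity covariance, secular trends in BMI
or disease rates, and genuinely inconsistent epidemiological surfaces (that
failure mode is exercised separately with deliberately infeasible inputs in
the tests). Passing tests on synthetic bundles therefore demonstrates the
*machinery* — calibration, consistency, conservation, orderings,
reproducibility — not the empirical magnitudes of any real population;
absolute cost outputs in particular are only as meaningful as the
stand-in cost tables.

`make_null_fixture()` zeroes the elasticities; the pipeline must then return
an exactly zero outcome delta, which is both a test and a useful sanity
check for users modifying inputs. `make_toy_lifetable()` is a three-age,
one-disease cohort small enough to recompute by hand; its expected outputs
were produced by an independent spreadsheet-style recomputation and are
frozen beside the package (`inst/extdata/toy_lifetable_expected.csv`).

# Problem sizes and runtime

The shipped tests run the full pipeline on the default bundle (two sexes,
81 single-year ages, seven diseases, three income levels) and use a
200-run Monte Carlo design — a scaled-down version of the default
2000-run design chosen to keep the suite quick while still giving stable
2.5th/97.5th centiles for the bracketing and replay checks. One pipeline
evaluation takes well under a second; the full default Monte Carlo design
takes minutes on one core.

# Limitations

Beyond the synthetic-data caveats above: the demand response is first-order
and out-of-home purchases are not modelled; elasticities, relative risks,
utilities and costs are taken as given, not estimated; the model assumes
the intervention effect and baseline rates are stationary over the cohort's
lifetime; disease independence (except the diabetes pathway) ignores
multimorbidity interactions in both utility and cost; dental caries and
BMI-related cancers are out of scope; and the closed cohort means no
benefits to cohorts entering adulthood after the start year are counted.
Most of these omissions bias the estimated benefits downward.
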