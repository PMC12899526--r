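# ssbtax

Simulation of the population health and healthcare cost impacts of an excise
tax on sugar-sweetened beverages (SSBs), built as a proportional multistate
life table in the PRIMEtime tradition. The package is aimed at health
economists and epidemiologists who want a tested, reusable pipeline from a
fiscal scenario to quality-adjusted life years (QALYs), healthcare costs and
chronic-disease cases averted — with Monte Carlo uncertainty — without
depending on restricted national survey extracts: a synthetic-data generator
produces complete, internally consistent input bundles for development and
testing.

## The model

The pipeline chains five stages:

1. **Demand.** An ad valorem tax *t* with pass-through φ raises the consumer
   price of each taxed beverage category by ΔP/P = tφ. With own- and
   cross-price elasticities e₍ᵢⱼ₎ (percent volume change of category *i* per
   1% price change of category *j*), the first-order volume response is
   ΔVᵢ = Vᵢ Σⱼ e₍ᵢⱼ₎ ΔPⱼ/Pⱼ, and the energy-intake change per stratum is
   ΔEI = Σᵢ ΔVᵢ κᵢ with κᵢ the energy density (kcal/mL).
2. **Weight.** A sustained ΔEI drives the Hall energy-balance system (body
   fat, lean tissue, glycogen and its bound water, extracellular fluid,
   adaptive thermogenesis). Its headline behaviour: every sustained
   100 kJ/day changes equilibrium weight by about 1 kg, with ~95% of the
   change reached by three years.
3. **Risk.** Stratum BMI distributions shift by Δw/h²; the potential impact
   fraction PIF = (E₀[RR] − E₁[RR]) / E₀[RR], with RR(b) =
   RR₅^(max(b−TMREL,0)/5), scales disease incidence: i′ = i(1 − PIF).
   Diabetes acts both as an outcome and as a risk factor for IHD and stroke
   via the population risk ratio (1 + p₁(RR−1))/(1 + p₀(RR−1)).
4. **Life table.** A closed adult cohort (ages 20–100, single years, both
   sexes) advances in annual cycles; each of the seven BMI-related diseases
   (T2DM, IHD, stroke, hypertensive heart disease, low back pain, hip and
   knee osteoarthritis) contributes a healthy/diseased sub-table with zero
   remission. QALYs apply additive utility decrements; costs accrue per
   prevalent case-year or per incident case depending on the disease; QALYs
   and costs are discounted (5% base case, 0%/10% sensitivity), cases are
   counted undiscounted over 20 years.
5. **Uncertainty.** 2000 Monte Carlo runs (configurable) resample relative
   risks (lognormal), utility decrements (truncated normal), costs (gamma)
   and the intervention effect (normal), giving means and 2.5th–97.5th
   centile intervals.

## Worked example

```r
library(ssbtax)

# Weight dynamics of a reference adult under -100 kJ/day, sustained
st <- initialize_balance(reference_individual())
tr <- simulate_weight(st, delta_EI = -100, horizon = 50, step = 1/52,
                      out_times = c(0, 1, 3, 50))
glance(tr)
#>   delta_EI delta_weight_final fraction_year1 fraction_year3
#> 1     -100              -1.01          0.618          0.941

# Full pipeline on a synthetic Brazil-like input bundle: 20% tax, 100%
# pass-through, 5% discounting
bundle <- make_fixture(fixture_config(seed = 1))
impact <- tax_impact(bundle, income = "total")
tidy(impact)
#>   sex    measure                        value
#> 1 female qaly_per_million              16690.
#> 2 female cost_saving_per_100k        2223116.
#> 3 female cases_averted_per_100k_IHD      121.
#> 4 female cases_averted_per_100k_T2DM     450.
#> 5 male   qaly_per_million              18323.
#> 6 male   cost_saving_per_100k        2658314.
#> 7 male   cases_averted_per_100k_IHD      246.
#> 8 male   cases_averted_per_100k_T2DM     511.
```

Read: the sustained 100 kJ/day reduction settles at −1.01 kg, 61.8% of it
reached after one year and 94.1% after three. On the synthetic bundle the
20% tax gains ~18,300 QALYs per million men and ~16,700 per million women
over the cohort's lifetime, saves ~Int$2.2–2.7M per 100,000 adults in
modelled healthcare costs, and averts ~450–510 T2DM cases per 100,000 adults
over 20 years. The QALY and case figures are the same order as published
estimates for Brazil; the absolute cost figures depend on the synthetic cost
tables, which are stand-ins.

Uncertainty intervals:

```r
mc <- tax_impact_mc(bundle, n_runs = 2000, seed = 1)
tidy(mc)          # mean, lo95, hi95 per sex and outcome
autoplot(mc, measures = "qaly_per_million")
```

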