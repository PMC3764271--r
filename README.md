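# cvdoffset

Municipal governments shape population health through "distal" levers —
urban planning, transport, housing, green space — long before the health
sector sees the consequences. `cvdoffset` is a scenario engine for putting
numbers on that chain for cardiovascular disease (CVD): it estimates how a
municipal intervention shifts population mean risk factors through
behavioural ("proximal") channels, and converts those shifts into avoided
acute events, avoided deaths, and health-sector cost savings over a
multi-year horizon. Its audience is health-impact analysts supporting city
policy makers who must compare investments such as cycling infrastructure,
walkable neighbourhoods or air-quality regulation.

## The model

The unit of computation is a **stratum**: an age-band × sex cell of the city
carrying a head count and mean risk-factor levels (systolic blood pressure,
total and HDL cholesterol, BMI, and smoking / diabetes / treated-hypertension
prevalences). For each stratum the ten-year CVD probability is evaluated at
the stratum means with the sex-specific general-CVD risk function

> p₁₀ = 1 − S₀(10)^exp(LP − L̄P),   LP = β₁ ln(age) + β₂ ln(TC) + β₃ ln(HDL) + β₄ ln(SBP) + β₅·smoking + β₆·diabetes

where prevalences enter as fractional indicator values and the SBP
coefficient is the treated-prevalence-weighted mix of the treated and
untreated terms. A constant-hazard conversion h = −ln(1 − p₁₀)/10 yields
expected annual events `count · (1 − e^(−h))`, spread over six admission
categories (heart attack, stroke, heart failure, acute hypoglycaemic attack,
renal failure, coronary bypass) by a configurable split.

An **intervention** carries six assessment metrics: (1) the fraction of the
city population affected, (2) its impact on distal determinants, (3) a 1–10
municipal influence score, (4) its proximal behaviour-channel effects, (5)
an evidence grade per effect, and (6) a cost-effectiveness score. The causal
chain is: effective reach = count × reach × influence/10 × distal impact;
channel unit-deltas × intensity × evidence weight give additive risk-factor
deltas; partial coverage moves each stratum mean by the mixture rule
delta × affected/count. Comparing treated against baseline projections gives
events avoided per category and year, deaths avoided via case fatality, and
cumulative (undiscounted by default) savings via unit costs.

## Worked example

A commuter-cycling scenario in a synthetic city of 100,000, where 52% of
residents are cyclists or potential cyclists, the municipality controls 70%
of the investment, and the exercise channel acts on strong evidence over a
5-year horizon:

```r
library(cvdoffset)

pop <- generate_population(population_config(100000, seed = 20,
                                             name = "helsingborg-like"))
baseline <- scenario(pop, horizon = 5)
treated  <- scenario(pop, helsingborg_intervention(), horizon = 5)
report   <- compare_scenarios(baseline, treated)
report
#> <cost_offset_report> over 5 year(s):
#>   events avoided: 107.4 (baseline 4784.4 -> treated 4677.0)
#>   deaths avoided: 17.2
#>   savings: EUR 568,791
```

Reading: against a baseline of ~4,784 expected acute admissions over five
years, the intervention's deliverable reach of 36,400 persons
(100,000 × 0.52 × 0.7) lowers stratum mean SBP, cholesterol and BMI enough
to avoid ~107 admissions and ~17 deaths, saving about €0.57M at the default
unit-cost table. `tidy(report)` gives the category × year detail,
`glance(report)` the one-row summary, `autoplot(report)` the category
breakdown. Every report echoes the parameter packs in force (channel table,
split, costs, fatality, evidence weights), since the shipped magnitudes are
documented, editable stand-ins.

A command-line interface wraps the same functions
(`inst/cli/cvdoffset generate|run|score|compare`), driven by YAML configs;
see `cvd_example()` for the shipped Sheffield-like (population 530,000) and
Helsingborg-style fixtures.

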