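---
title: "The cost-offset model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cost-offset model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdoffset)
```

# The model in one paragraph

`cvdoffset` estimates the cardiovascular burden a city can avoid by
investing in its living environment. It follows the causal sequence
*living and working conditions → lifestyle → behaviour → risk factors →
health outcomes*: a municipal intervention (in one of six domains —
education, economy, housing, security, environment, health promotion)
reaches part of the population, acts through behavioural channels
(exercise, air quality, stress, diet, smoking cessation), shifts population
mean risk factors, and thereby changes the expected number of acute
admissions in six categories and their cost.

# Population representation

The engine operates on **strata, not individuals**: age-band × sex cells
carrying mean risk-factor levels. This is deliberate — the model's logic is
that admissions correlate with *mean population-level* risk factors (mean
SBP, mean cholesterol, mean BMI, smoking prevalence, by age and sex) — and
it keeps every operation closed-form and fast. The price is a Jensen gap:
the risk function is convex in its inputs over most of its domain, so
evaluating it at stratum means is not identical to averaging individual
risks. The test suite quantifies the stratum-vs-individual relationship
with a per-individual oracle (each simulated person carries the stratum
mean profile, so the oracle isolates the aggregation arithmetic rather
than between-person variance, which stratum means cannot represent at all).

The default age structure uses 10-year bands 30–39 … 80–89 plus an under-30
band. The risk equations are defined for ages 30–89 only; strata outside
that range are **kept in the accounting but contribute zero events**, and
every projection reports the excluded head count. We see no defensible way
to score children with Framingham-family equations, so the all-ages total
is retained for reach and eligibility arithmetic while risk arithmetic
stays inside its valid domain. Risk is evaluated at the band midpoint.

# The risk equation and its pack

The default coefficient pack is the published sex-specific general-CVD
function (D'Agostino et al., *Circulation* 2008): log-hazard coefficients
on ln(age), ln(TC), ln(HDL), ln(SBP) (treated/untreated), smoking and
diabetes indicators, with 10-year baseline survival 0.88936 (men) and
0.95012 (women). Packs are **data, not code** — YAML/JSON documents loaded
by `read_coefficients()` — because the calibration a given deployment wants
(for instance a locally modified Framingham variant) should be replaceable
without touching logic.

Three mean-level conventions matter:

* Smoking, diabetes and treated-hypertension prevalences enter the linear
  predictor as fractional indicator values — the expected value of the
  individual indicator — and the SBP term uses the
  treated-prevalence-weighted mix of the treated and untreated coefficients.
* Profiles carry cholesterol in mmol/L (the European convention); the pack
  stores the published coefficients' unit conversion (38.67 mg/dL per
  mmol/L) and `ten_year_risk()` applies it.
* BMI is carried in profiles and shifted by interventions, but the default
  lipid-based pack has **no BMI term**; packs may supply an `lbmi`
  coefficient (the office-based variant of the same family uses one). With
  the default pack, an intervention's BMI effect is tracked but does not
  move risk — a known limitation stated here rather than patched with an
  invented coefficient.

## Time conversion

Ten-year risk is converted to a constant annual hazard,
`h = -log(1 - p10)/10`, and expected events per stratum-year are
`count * (1 - exp(-h))`. This is the simplest convention consistent with a
multi-year horizon; the population is closed and static (no ageing,
migration or event-driven depletion over the horizon), so yearly
expectations are constant. Recurrence and competing risks are out of scope:
the output is a first-order burden estimate, not a survival analysis.

## Event categories

Total expected events are spread over the six admission categories by a
split that must sum to 1 (tolerance 1e-9). Two of the categories (acute
hypoglycaemic attacks, renal failure) are not Framingham endpoints; how
they were attached to a CVD risk function in the model this package
re-implements was never published. The split table is therefore an
explicit, documented stand-in (`event_split()`: 30% heart attack, 25%
stroke, 20% heart failure, 10% bypass, 8% hypoglycaemic, 7% renal) and is
echoed in every report. Totals are invariant under any permutation of the
split, which the suite checks.

# Interventions and the six metrics

An intervention carries six assessment metrics. Two design questions were
genuinely open:

* **How does a 1–10 municipal influence score enter a quantitative
  pipeline?** We read it as the *deliverable fraction* of the intervention
  — the share not held by central government or market forces — so it
  enters multiplicatively as `influence/10`. Effective reach per stratum is
  `count × reach_fraction × influence/10 × distal_impact`.
* **Are "impact on distal determinants" (metric 2) and "impact on proximal
  determinants" (metric 4) one chained quantity or two?** We keep them
  distinct: metric 2 is a [0,1] multiplier on reach, metric 4 is the set of
  channel effects. Collapsing them would make one of the two published
  metrics redundant, which seems the less faithful reading.

Evidence grades (moderate / strong / very strong) are numerified as
monotone confidence weights 0.5 / 0.75 / 1.0 — the grading was published as
stars with no numbers, so the weights are a simple monotone, configurable
choice. Deltas are linear in intensity and weight, so a moderate-evidence
effect contributes exactly half of a very-strong one at equal intensity.

The behaviour-channel table (`behaviour_channels()`) holds each channel's
risk-factor shift at unit intensity. The physiological signs are fixed —
exercise lowers SBP, cholesterol and BMI and raises HDL; stress reduction
lowers SBP — and the constructor enforces them. The magnitudes (e.g.
exercise: −2 mmHg SBP, −0.1 mmol/L TC, −0.3 kg/m² BMI at unit intensity)
are literature-plausible placeholders for a calibration that was never
published; they ship as editable data and every report prints the table in
force. At the shipped defaults, unit intensity corresponds roughly to a
population moving from inactive to meeting activity guidelines.

Partial coverage uses the mixture-mean rule: if `affected` of `count`
persons receive delta `d`, the stratum mean moves by `d·affected/count`.
Shifted profiles must still satisfy the invariant ranges (SBP 70–250 mmHg,
TC 1–15 mmol/L, HDL 0.3–5 mmol/L, BMI 12–60 kg/m², prevalences 0–1);
violations are errors naming the stratum and field — **never silently
clamped**, because clamping would quietly change the delta actually
applied.

# Cost offset

A report compares baseline and treated projections of the *same*
population and horizon: events avoided per category and year (negative
values from harmful interventions are reported, not clipped — surfacing
unintended consequences is part of the model's purpose), deaths avoided
via per-category case fatality, and savings via per-category unit costs.
Savings are cumulative health-sector savings over the horizon,
undiscounted by default with an optional annual discount rate. Unit costs
and case fatality are configurable stand-ins (no tariff was published for
the original model); investment costs, social-care streams and QALYs are
out of scope.

With several interventions, scenario application is sequential and
additive with a documented no-overlap assumption. Attribution uses
leave-one-out marginal contributions normalised to sum to the total
avoided; raw marginals are reported alongside, since marginals need not
sum to the total through the nonlinear risk function. If all marginals are
zero the shares fall back to equal.

# The synthetic population generator

No city's stratum table ships with the package, so the generator emulates
a European city: a default pyramid patterned on a large UK city (about 40%
under 30, a working-age majority, female surplus at older ages) and linear
risk-factor age ramps (value at age 30 plus per-decade slope; e.g. male
mean SBP 122 mmHg + 4.5 per decade, declining smoking prevalence, rising
diabetes and treated hypertension) with typical European adult survey
magnitudes. Counts are allocated by **largest-remainder rounding**, chosen
because it conserves the configured total exactly for every pyramid; ties
in the remainders are broken by entry order. Stratum means get truncated
Gaussian jitter (small SDs, since they perturb *means*); truncation to the
invariant ranges is acceptable here — unlike in `apply_deltas()` — because
the jitter is noise, not a quantity whose size carries meaning.

Determinism: one master seed; each stratum derives a substream seed by a
stable polynomial hash of its (age band, sex) key, with all intermediates
exact in double arithmetic. Consequently equal configurations are
bit-identical, counts never depend on the seed, and adding or removing a
stratum does not shift any other stratum's draws.

What the generator does *not* emulate: geographic and socio-economic
heterogeneity within strata, correlation between risk factors, secular
trends, migration and ageing. Passing tests on generated cities therefore
demonstrate the engine's arithmetic and invariants, not the realism of any
particular city's inputs — real deployments should load their own stratum
CSV via `read_population()`.

# Numerical choices and degenerate inputs

* Eligibility and similar person counts use half-up rounding
  (`floor(x + 0.5)`), not banker's rounding, so printed examples follow
  everyday arithmetic.
* `annual_hazard(1)` is an error (infinite hazard), as is any probability
  outside [0, 1); the inversion `1 - exp(-10h) = p` is exact to 1e-12
  across the [0, 0.99] grid, which the suite asserts.
* Zero-count strata, empty intervention lists, zero-intensity effects and
  self-comparisons all flow through and give exact zeros; conservation
  (baseline = treated + avoided per category/year) holds to 1e-9 across
  randomised scenarios.
* Effective reach is kept real-valued (an expectation), not rounded, so
  linearity properties hold exactly; only user-facing eligibility counts
  are integers.

Problem sizes in the shipped suite were chosen to exercise the properties
at comfortable scale: synthetic cities of 10³–5.3×10⁵ persons, 100
randomised conservation scenarios, 1,000 randomised monotonicity profiles,
and a 10⁵-draw per-individual Monte-Carlo check against the stratum
arithmetic.

# Known limitations

* Mean-level evaluation carries a Jensen-gap bias relative to
  individual-level risk averaging; it is the model's defining
  approximation, not an implementation shortcut.
* Default channel magnitudes, event split, unit costs and case fatality
  are documented stand-ins; absolute outputs should be read as
  order-of-magnitude policy comparisons, and the package's own reports
  echo every such table precisely so the assumptions travel with the
  numbers.
* The BMI channel is inert under the default lipid-based pack (above).
* Portfolios of interventions are additive; no interaction or overlap
  modelling.
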