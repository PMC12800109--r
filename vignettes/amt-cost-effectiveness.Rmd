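---
title: "Methods: cost-utility and financial-impact modelling of digital anemia management in hemodialysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cost-utility and financial-impact modelling of digital anemia management in hemodialysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amtcea)
```

## The decision problem

Adult in-center hemodialysis (HD) patients are almost universally anemic and
are managed with erythropoiesis-stimulating agents (ESAs). Conventional
protocol-driven ESA dosing produces substantial intrapatient hemoglobin (Hb)
variability, and higher Hb variability is associated with higher mortality and
hospitalization. A model-predictive anemia management tool (AMT) — a
digital-avatar controller that recommends personalized ESA doses from routine
clinical data — reduces Hb variability in randomized-trial conditions.
`amtcea` asks two questions about that reduction:

1. **Payer (Medicare) perspective** — is lifetime AMT use cost-effective
   versus standard of care (SOC), measured in quality-adjusted life-years
   (QALYs) and net monetary benefit, `NMB = λ·ΔE − ΔC`?
2. **Provider perspective** — does a dialysis facility profit from adopting
   AMT, given that under the bundled ESRD Prospective Payment System any ESA
   savings accrue to the facility, not to Medicare?

## The effect-translation chain

The trial measured Hb variability, not deaths or admissions, so both clinical
effects are projected from secondary evidence:

* **Mortality.** A cohort-study hazard ratio of 1.09 per 1 g/dL of Hb SD is
  exponentiated to the trial's ΔSD of 0.2 g/dL:
  `HR = 1.09^(−0.2) = 0.983` (`mortality_hr_from_sd()`), with range
  0.974–0.997 at the ΔSD confidence limits 0.3 and 0.04. This assumes a
  log-linear (proportional-hazards) relation between variability and death.
* **Hospitalization.** An observational odds ratio of 0.53 (95% CI 0.45–0.62)
  for low- versus high-variability patients is first expressed as a
  standardized mean difference with Chinn's conversion,
  `SMD = ln(OR)/(π/√3) ≈ −0.35` (`chinn_smd()`; the constant is carried at
  full precision, ≈1.8138, not the rounded 1.81 — printed values still
  reproduce at printed precision). Because the trial achieved only a 0.2 SD
  reduction, the log-odds are rescaled by `0.2/0.35 ≈ 0.57`
  (`scale_odds_ratio()`), giving an adjusted OR of 0.70 (CI 0.63–0.76). The
  OR is converted to a relative risk at the baseline annual hospitalization
  probability — obtained from the 1.49 events/patient-year rate as
  `p0 = 1 − exp(−1.49)`, the package's stated convention, which reproduces the
  published RR of 0.91 — and the avoided rate is
  `(1 − RR) × 1.49 ≈ 0.13` events/patient-year
  (`or_to_rr()`, `avoided_hospitalization_rate()`).

`derive_effects()` runs the whole chain with unrounded intermediates:

```{r effects}
derive_effects(load_parameters())
```

## The Markov cohort model

`run_cohort()` simulates a closed cohort through two states, alive and dead,
in 1-year cycles. Hospitalizations are events within the alive state, not a
separate state. Key numerical choices:

* **Life-table half-cycle correction**: person-years in cycle *t* are
  `(alive_start + alive_end)/2`, and discounting uses the mid-cycle factor
  `(1+r)^−(t−0.5)`; both implement the assumption that transitions occur on
  average halfway through a cycle.
* **Age-band inputs**: annual mortality, maintenance cost and incidence are
  piecewise-constant over bands 18–44, 45–64, 65–74, 75+; a sub-cohort uses
  the band containing its current integer age, and the 75+ band is absorbing.
  The hazard ratio is applied uniformly across bands on the
  probability→rate→probability path `1 − (1−q)^HR`.
* **Stopping rule**: simulation ends at the first cycle after which fewer
  than 0.1% of the cohort remains alive; the engine matches an independent
  closed-form life-table annuity to 1e−9 under constant mortality.
* **Cohort construction** (a genuinely open design point: the source analysis
  does not print its starting-age distribution): the default cohort mixes the
  four bands proportionally to incident counts, down-weights the under-65
  bands by the Medicare coverage share (0.55), and starts sub-cohorts at band
  midpoints (31, 54.5, 69.5, 80; the open-ended band at 80). Any
  `cohort_spec()` may be substituted. Under-65 annual maintenance cost is not
  published; it defaults to the 65–74 value (102,206 USD), is flagged
  `cost_imputed`, and is overridable. Consequently absolute lifetime
  costs/QALYs are treated as qualitative, while the desk-derivable chain
  above and the provider arithmetic are exact.

Both arms share the HD utility weight 0.69; there is no per-admission
disutility (none is published). The AMT arm applies the derived mortality HR
and the reduced hospitalization rate `1.49 − 0.13` (floored at zero).

## Economics

The willingness-to-pay threshold λ is proxied by the cost-utility ratio of
dialysis versus no kidney replacement therapy — i.e. the SOC arm against a
zero-cost, zero-benefit comparator (`wtp_proxy()`), a deliberately
conservative threshold — unless `wtp_threshold` is configured. `nmb()` is
linear in λ with slope ΔE; `annualize_nmb()` divides lifetime NMB by the
*discounted* AMT life expectancy, as literally specified. With the published
lifetime NMB and life expectancy this gives ≈2121 USD/year, not the published
2443; the discrepancy is documented rather than repaired, since the
annualization actually used upstream is not recoverable.

## Provider and payer financial analyses

`nfia()` composes three closed-form terms per patient-year: ESA savings
`0.4 µg/kg/30d × 81.4 kg × 365/30 × 1.3 $/µg ≈ $515` (the 365/30
annualization, not 12 calendar months, is what reproduces the published
profit; the median weight 81.4 kg is used, as the rounded 81 kg does not),
Quality Incentive Program avoided penalty
`265.57 × 156 × 0.0012 = $49.71`, minus implementation costs — the published
aggregate $347/patient-year in the full scenario, or per-session component
sums for the consumables+AMT and AMT-only scenarios (the published aggregate's
component split is not printed, so the build-up is not forced to equal it).
Net ≈ $218/patient-year, ≈ $15.2k for a 70-patient facility.

`budget_impact()` multiplies incident Medicare cases (59,630 in the 65+
bands; under-65 bands optionally added at the coverage share) by the lifetime
incremental cost per case from the Markov model; negative values are savings.
The published $94M/year figure is not derivable from the published inputs and
is not targeted.

## Uncertainty analysis

**What the parameter-set sampler emulates.** The probabilistic sensitivity
analysis (`run_psa()`) draws each uncertain input independently from exactly
the published family and parameters: Beta-PERT(3.462, 2.538) on (0.04, 0.30)
for the Hb SD reduction (the CI endpoints as support, since exactly these
reproduce the printed shapes via `pert_shape_params()`); lognormal (0.086,
0.040) for the mortality HR; lognormal (−0.092, 0.014) for the
hospitalization RR, sampled directly and injected downstream of the Chinn
chain (the chain defines the base case; the published distribution defines
the PSA); Beta(50.737, 22.795) for utility; Gamma(k = 1002, θ = 18.23) for
hospitalization cost (kept verbatim although its mean, ≈18,266, differs from
the 17,226 base case — the source does not reconcile this); Uniform(0.50,
0.60) for the under-65 Medicare share; a lognormal calibrated from the weight
median/IQR; and a normal calibrated from the ESA dose-reduction CI (negative
draws allowed — its CI crosses zero). No correlation structure is imposed
(none is published), and the utility-premium scenario is excluded from PSA.
What a green PSA test does *not* establish: anything about parameter
correlation, about the published percentile interval (seed- and
cohort-dependent, treated as qualitative), or about real-world effect
persistence beyond the trial's horizon.

λ is held fixed at its base-case value throughout DSA and PSA: re-proxying it
per draw would let the SOC arm's own sampled costs partially cancel the very
variation being measured.

The tornado (`one_way_dsa()`) varies one parameter at a time over its
published range at base-case values of all others; entries are sorted by NMB
spread, and the Hb SD reduction is the dominant bar, matching the headline
one-way result. Defaults: `n = 1000`, `seed = 20260103`, percentile
(2.5/97.5) intervals, seed recorded in all outputs.

```{r psa}
psa <- run_psa(n = 200, seed = 20260103)  # n scaled down for the vignette
psa
```

## Scenario: in-range utility premium

The base case assumes no direct utility effect of Hb time-in-range. Setting
`utility_premium_enabled = TRUE` applies `Δu × Δ(in-range) = 0.005 × 0.10 =
0.0005` QALYs per life-year to the AMT arm only; by construction this raises
AMT QALYs by exactly `0.0005 ×` (discounted AMT life-years), which the tests
assert exactly.

## Known limitations

* Absolute lifetime costs and QALYs depend on the unpublished starting-age
  construction and under-65 costs; only their signs, orderings and the
  desk-derivable quantities are asserted.
* Mortality and hospitalization effects are projections from secondary
  observational evidence, not trial endpoints; the proportional-hazards
  mapping is a working assumption.
* Single currency-year (2022 USD) inputs; no inflation engine.
* No treatment switching, transplantation, or modality change; no ESA
  adverse-event offsets (conservative for the intervention).
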