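---
title: "Methods: dynamic exposure and population toxicokinetics of PFAS in beef cattle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic exposure and population toxicokinetics of PFAS in beef cattle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdtk)
```

`herdtk` couples a daily dietary-exposure model for cattle on
PFAS-contaminated farmland to a stochastic one-compartment toxicokinetic
model. This vignette is the package's account of the science: the model
and its assumptions, the parameters that matter, what the synthetic farm
generator does and does not emulate, and the numerical and design choices
made where the design was genuinely open.

## The exposure model

The simulation clock is daily, day 0 is the calf's birth date, and all
intervals are closed on both ends. Each day is assigned one primary
feeding mode — nursing-plus-pasture, pasture, stored feed, or clean
(purchased) feed — from the life history; clean-feed interventions take
precedence over stored-feed windows because an intervention replaces the
contaminated ration mid-winter.

Concentration units are fixed at the schema boundary: soil, feed, forage,
and muscle in ng/g dry weight; serum, plasma, and milk in ng/mL; water in
ng/L. Tissue/serum interconversion assumes unit density (1 ng/mL ≡
1 ng/g), and milk mass is converted at 1 kg ≈ 1 L.

**Stored feed.** Feed grown on a field is `soil × TF`, where TF is a
site-specific soil-to-plant transfer factor supplied in the scenario
configuration (no soil-property regression is attempted; co-located
soil/plant sampling is the right way to obtain TFs). Second-cut hay
multiplies TF by 2.7 (PFOS) or 2.1 (PFDA), reflecting the higher uptake
observed in later cuttings. When a lot has a measured hay concentration,
the measurement overrides the estimate and transfer factors are never
consulted — the test suite enforces this with a NaN sentinel. An annual
crop is mixed as the bale-fraction-weighted average over lots, which is
always inside the min–max envelope of the lot concentrations and is
monotone in every soil input.

Within a winter, cuts are fed out in a configured order. Farm records
rarely state the rule, so it is an explicit config (ordered
`(year, cut, n_days)` entries) rather than an inference; the default
feeds the second cut first, for a number of days proportional to its
bale share. Feeding order matters because of kinetics, not mass balance:
doses fed earlier decay longer before slaughter.

**Pasture, soil, water, milk.** Grazing days draw forage at
`soil × TF` (dual-use hay fields grazed after a cutting can be flagged
to use the second-cut TF) weighted by the grazing allocation, plus
incidental soil ingestion at 4% of forage dry-matter intake — the
conventional soil-ingestion rate for cattle on contaminated land. Water
exposure is piecewise-constant segments (ng/L), so a filter installation
is simply a 0 ng/L segment; non-detects default to 0, configurable to
MDL/2 or MDL. Nursing calves additionally receive dam milk at
`Pmilk × dam serum`.

**Physiology.** Body weight follows a Brody curve
`BW(t) = W∞ − (W∞ − W0)·e^(−kt)` (defaults 40 kg birth, 600 kg mature,
k = 0.004/day); any monotone curve satisfying the same boundary
behaviour could be substituted. The dam's milk yield follows a Wood
curve `MY(t) = A(t+14)^b e^(−c(t+14))·YP/10` with A = 1.69, b = 0.57,
c = 0.009/day and breed-adjusted peak YP = 8.16 kg/day, which peaks at
`b/c − 14 ≈ 49` days post-calving; milk converts to dry matter at 13%.
Nursing-calf forage intake is `max(0, (0.0783·BW − 4.87·DMI_milk)/DE_F)`
with forage digestible energy DE_F = 2.895 Mcal/kg — the clamp at zero is
a physical constraint (the source publications are silent on the negative
branch). After weaning — a hard switch on the weaning date — dry-matter
intake defaults to 2.5% of body weight and water intake to
0.08 L/kg body weight with an optional warm-weather term (off by
default); these are declared substitutes for literature equations that
the upstream publications cite but do not print, and each is a single
exposed parameter.

**The dam.** The milk pathway needs a breeding-stock trajectory. The dam
is modeled as an adult at constant body weight on the farm calendar:
November–April stored feed at the crop-year weighted first-cut average,
summer pasture weighted by acreage, the same water series extended
backwards in time, mean toxicokinetic parameters, zero initial burden,
and a start three years before calving (≈15 PFOS half-lives, so the dam
is effectively at her periodic steady state by calving). A single
deterministic dam run feeds all calf draws, and the calf's initial serum
is `maternal_transfer × dam serum at calving`. The maternal-transfer
ratio is a required scenario input with package default 1.0 — the value
is farm- and compound-specific and no cattle value is established; treat
the default as a placeholder to be set deliberately.

## The toxicokinetic model

Body burden A (ng) follows first-order elimination with end-of-step dose
crediting:

    A(t+1) = A(t)·exp(−k) + dose(t+1),   k = ln 2 / DT50.

Serum is `A / (Vd·BW·1000)` with BW time-varying, so growth dilution is
automatic — a fixed-volume compartment would contradict the growth
modeling. Muscle and milk are constant partitions `PM × serum` and
`Pmilk × serum`, asserted (not assumed) on every day of every test
scenario. The discrete daily integrator differs from the continuous
one-compartment ODE by less than ~2% at realistic rates
(k ≤ 0.02/day); the acceptance checks verify the geometric steady state
`D/(1 − e^(−k))` to 0.1% and exact log-linear decay. Mass balance
(cumulative dose = terminal burden + cumulative elimination) closes to
1e−9 relative per trajectory.

Default per-analyte parameters (mean ± SD):

| Analyte | DT50 (days) | Vd (L/kg) | PM (–) | Pmilk (–) |
|---|---|---|---|---|
| PFOS | 74.1 ± 13.4 | 0.085 ± 0.01 | 0.08 ± 0.02 | 0.015 ± 0.004 |
| PFDA | 60.4 ± 10.4 | 0.085 ± 0.01 | 0.08 ± 0.02 | 0.015 ± 0.004 |

PFDA's half-life and muscle partition are analyte-specific; its Vd and
Pmilk reuse the PFOS values because PFDA-specific cattle data are not
available, and `vd_sensitivity()` quantifies the consequence: at steady
state serum is exactly inversely proportional to Vd, so a 2-fold Vd error
is a 2-fold serum error with unchanged dynamics.

**Population draws.** Each of N (default 100) simulated animals draws
independent normal parameters truncated below at 0.01 × mean by
resampling, plus per-animal feed and water intake factors
(normal, mean 1, SD 0.30, truncated at 0.1). Intake variation is
specified in the source literature only as "30%"; we chose per-animal
(not per-day) factors because the ensemble summarizes between-animal
spread, and we apply the feed factor to everything the animal eats —
stored feed, forage, incidental soil, and milk, since a nursing calf's
feed *is* milk. Parameter correlations are not modeled (none are
reported). A fixed seed reproduces an ensemble bit-identically.

## Evaluation

Biomonitoring is matched to the same calendar day of the ensemble
summary — no interpolation, since the model is daily. Plasma records are
harmonized to serum equivalents (×1.060 PFOS, ×1.047 PFDA) and flagged.
Percentage error is `100(modeled − measured)/measured` on unrounded
means; published tables that round before printing can therefore differ
by one integer point, and the package reports unrounded values rather
than matching printed rounding. MAPE is the mean absolute percentage
error; fold ratio is `max(m/o, o/m)`. The partition-coefficient
meta-analysis forms per-pair tissue/serum ratios, per-dataset means, and
a meta-mean weighted by dataset n (equal weighting available — the
estimator behind published "meta-means" is not stated, so the choice is
surfaced in the API, not hidden). Action levels ship as configuration:
3.4 ng/g (Maine), 0.3 ng/g (EU), 4.1 ng/g (USDA screening) for PFOS in
muscle; none exist for PFDA, and the plotting function draws no
reference line where none is configured.

Depuration half-lives are estimated by per-animal log-linear regression
`log(conc) ~ day`, averaged across animals. With 8 animals × 5 timepoints
over 120 days and 10% lognormal noise, the estimator recovers a true
DT50 within 15% in ≥90% of replicates (exercised by the acceptance
suite at 20 replicates).

## Management and economics

`prioritize_feed()` schedules lots highest-concentration-first subject to
bale availability. For linear first-order kinetics this minimizes the
terminal burden over all permutations of the same lots (rearrangement
inequality: decreasing concentrations paired with increasing decay
weights), which the tests verify against brute-force enumeration.
`simulate_management()` reruns the ensemble under a variant — baseline,
a terminal clean-feed window, or prioritized feeding in the first or
second winter — under paired seeds so differences are attributable to
the intervention, and reports below-action-level fractions at the end
date. Bale-to-day allocation assumes uniform daily demand within a
window (no within-winter demand profile is available).

Economics is deliberately simple: sellable meat is
`live × 0.63 × (1 − 0.175)` (hanging fraction, bone subtraction), and
net revenue compares retail meat sales minus feed/grain costs against
live-auction price × live weight. Prices are time-varying external data
and must be supplied in the configuration; the package ships no price
feeds, so published dollar figures are reproducible only given the same
price inputs.

## The synthetic farm generator

`generate_farm()` emulates the study-system archetype: 14 fields of
which 6 are biosolids-amended hay fields (soil PFOS 8.2–19.8 ng/g, PFDA
65.2–111 ng/g, truncated lognormal within each range), 7 clean pastures
(PFOS < 1 ng/g, PFDA < 2.8 ng/g), and one dual-use hay/pasture field;
transfer factors 0.1 (PFOS) and 0.025 (PFDA), chosen so first-cut feed
lands near 1.2–1.3 ng/g PFOS and 2.1–2.3 ng/g PFDA as observed for such
soils; well water at 1.3 ng/L PFOS (PFDA non-detect → 0) until a filter
date, then 0; a sinusoidal weather series; and a calf born May 1 with
the seasonal calendar archetype — ~6-month grazing summers alternating
~6-month stored-feed winters, weaning at the first winter, sale at 18 or
slaughter at 24 months. Soil heterogeneity is per-field lognormal with
no spatial correlation (the analysis only consumes per-field
composites), and measurement noise is multiplicative lognormal, matching
non-negative concentration data. All randomness is fixed by one seed and
the emitted file bundle is byte-identical under it.

Two generator defaults deserve emphasis. First, the default rotation
keeps growing animals on the clean pastures; the dual-use field's
six-week autumn grazing window is opt-in (`dual_autumn = TRUE`), because
it is a farm-specific event rather than part of the archetypal
accumulation/depuration calendar, and including it superimposes an
autumn exposure pulse on the winter signal. Second, the generator's true
maternal-transfer ratio defaults to 0.05. The design contract for the
default farm is that every ensemble draw — including animals at the
intake-factor truncation floor of 0.1 — peaks during a stored-feed
window; a structural analysis of the linear model shows this requires
the day-0 maternal serum to sit below about 10% of the winter
feed-driven peak. The generated farm therefore represents herds whose
lifetime accumulation is dominated by the animal's own dietary exposure,
with in-utero transfer a small initial condition.

What passing tests on synthetic farms do **not** show: real soil–plant
transfer varies several-fold between seasons for reasons that remain
unexplained (the package exposes measured-hay override mode precisely
because estimated feed concentrations can underpredict badly in such
years); real herds share grazing and feed inventories across animal
groups; real biomonitoring has matrix effects beyond multiplicative
noise; and the generator's growth, intake, and water rules are the
package defaults, so they cannot falsify those defaults.

## Numerical choices and degenerate inputs

- Kinetic recursion via a linear filter (`stats::filter`), exact for the
  stated update; no ODE solver is needed.
- Truncations by resampling (parameters at 0.01 × mean, intake factors
  at 0.1) rather than clamping, so no probability mass piles at the
  bound.
- Weather gaps are forward-filled up to 7 days; longer gaps are
  validation errors. Water series must cover the life history
  explicitly (0 is an explicit concentration, not a default).
- A pasture day not covered by any grazing interval is treated as clean
  pasture (zero forage and soil concentration); the generator always
  emits full coverage.
- Zero total bales, missing soil values, dangling field references,
  unparseable dates, and out-of-range sampling dates raise typed
  validation errors (`herdtk_validation_error`), never crashes
  downstream.
- Ensemble summaries are stored with the ensemble and are recomputable
  from the member trajectories; the tests assert equality.

## Problem sizes

The test and acceptance workloads use 100-draw ensembles over 730-day
life histories (the study's own ensemble size), 10,000-draw parameter
recovery checks, 20-replicate half-life recovery, and full permutation
enumeration on 4–5-lot feed-plan instances; the complete suite runs in
well under a minute on one CPU.

## Known limitations

- One compartment only: no enterohepatic recirculation, no separate
  liver/kidney pools, no in-utero kinetics (maternal transfer is an
  initial condition).
- Absorption fraction is 1 (administered dose = absorbed dose); the
  one-compartment description includes no bioavailability term.
- Transfer factors are scalar inputs; no mechanistic plant-uptake model.
- The dam is deterministic and identical for all calf draws; dam-level
  variability would widen calf ensembles slightly during nursing.
- No Bayesian calibration: parameter uncertainty is forward-propagated
  from fixed means/SDs, not updated against biomonitoring.
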