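---
title: "Methods: fuzzy health-risk assessment for toxic metals in road dust"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fuzzy health-risk assessment for toxic metals in road dust}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzydust)
```

## The model

Deterministic health-risk assessment feeds point estimates into the USEPA
exposure equations. Two sources of error dominate in practice: using the
*total* metal concentration where only the gastric-soluble
(bioaccessible) fraction can be absorbed, and ignoring the uncertainty of
the most sensitive inputs. `fuzzydust` addresses both. Concentrations
enter as bioaccessible values (SBET-measured `CDBA`, mg/kg), and the
sensitive inputs are triangular fuzzy numbers (TFNs).

A TFN `(a1, a2, a3)` encodes minimum, most-expected and maximum value.
Cutting it at confidence `alpha` gives the interval

```
[ (a2 - a1) * alpha + a1,  a3 - (a3 - a2) * alpha ]
```

and all downstream arithmetic is interval arithmetic on these cuts:
sums add endpoints, products multiply them, and quotients take
`[l1/u2, u1/l2]`. These endpoint formulas are exact for non-negative
intervals, which covers every quantity in this model (concentrations,
rates, weights, times); operands with negative endpoints are rejected
rather than silently mishandled, because the printed formulas would be
wrong for them. The default cut is `alpha = 0.9`, the conventional
confidence level for this kind of assessment; it is an argument
everywhere, and results are reported as interval endpoints together with
the alpha used, never as a single collapsed number.

Per pathway and receptor, intakes in mg/(kg·d) are

```
INTAKE_ing    = CDBA * ED * EF * IngR / (BW * AT) * 1e-6
INTAKE_inh    = CDBA * ED * EF * InhR / (BW * AT * PEF)
INTAKE_dermal = CDBA * ED * EF * SA * SSAR * ABS / (BW * AT) * 1e-6
```

with `CDBA`, `IngR`, `InhR`, `BW` fuzzy and the rest crisp. The
non-carcinogenic endpoint uses `HQ = INTAKE / RfD` per pathway, summed
over pathways per metal and over metals into the hazard index `HI`
(`HI < 1`: no significant risk). The carcinogenic endpoint uses
`CR = INTAKE * SF`, summed over pathways into a per-metal total-CR
interval.

Applying the bioaccessible concentration to all three pathways is a
deliberate model-faithfulness choice: SBET simulates the gastric phase,
so strictly the adjustment is best motivated for ingestion, but the
equations are implemented exactly as the model defines them. No
gastrointestinal-absorption rescaling of the dermal reference dose is
applied.

### Classification

Total CR is classified into levels I–V:
I `(-Inf, 1e-6)`, II `[1e-6, 1e-5)`, III `[1e-5, 5e-5)`,
IV `[5e-5, 1e-4)`, V `[1e-4, 1)`, each lower-closed and upper-open. The
membership of a computed interval in a level is the length of their
overlap divided by a normalizing length, and the assigned level is the
one with maximum membership.

Two normalizations are in circulation, and they differ: dividing by the
**computed interval's** length makes the degrees sum to 1 over a
contiguous scheme; dividing by the **level's** length does not (and gives
an unbounded level weight zero). Both are implemented
(`normalization = "computed_interval"` or `"level_interval"`); the first
is the default precisely because its degrees form a partition of unity.
The choice is exposed, not silently merged.

### Degenerate inputs and tie-breaks

* A zero-width (crisp) interval would give the default normalization a
  vanishing denominator; it is classified as a point mass on the level
  containing the point.
* Membership ties are broken toward the more severe level — conservative
  for health protection.
* CR values at or above the top of the scheme (1) are clamped into
  level V with a warning rather than rejected, so a pathological
  parameter set still yields a (maximally severe) verdict.
* Under the level-width normalization an interval wholly inside the
  unbounded level I has an all-zero membership vector; the pipeline then
  assigns the level containing the interval midpoint.
* With every TFN degenerate the whole pipeline reduces exactly (to
  floating-point accuracy) to the classical crisp model; the test suite
  verifies this against an independently coded scalar implementation.

## Parameters

Receptor scenarios (adult, child) and per-metal toxicity values ship as
YAML under `inst/extdata/` and are **standards-derived** — taken from
HJ 25.3-2019 / USEPA dust-exposure conventions, not from any particular
survey — and fully overridable.

| parameter | adult | child | units |
|---|---|---|---|
| IngR (fuzzy) | (70, 100, 130) | (140, 200, 260) | mg/day |
| InhR (fuzzy) | (10.15, 14.5, 18.85) | (5.25, 7.5, 9.75) | m³/day |
| BW (fuzzy) | (45.4, 56.8, 68.2) | (15.4, 19.2, 23.0) | kg |
| ED | 24 | 6 | yr |
| EF | 350 | 350 | days/yr |
| AT (non-carc.) | 8760 | 2190 | days |
| AT (carc.) | 25550 | 25550 | days |
| SA | 5700 | 2800 | cm² |
| SSAR | 0.07 | 0.2 | mg/(cm²·day) |
| ABS | 0.001 | 0.001 | – |
| PEF | 1.36e9 | 1.36e9 | m³/kg |

The fuzzy spreads (±30 % around the standard default for intake rates,
±20 % for body weight) represent plausible receptor variability; they are
design defaults, not measurements. Averaging time follows the usual
convention of differing by endpoint — `ED × 365` days for
non-carcinogenic effects, a 70-year lifetime for carcinogenic ones — even
though the intake equations write a single `AT`; both are configuration
fields. Reference doses exist for Cd, Ni, As, Zn, Cu, Cr (so Pb
contributes no HQ) and slope factors for Cd, Ni, As, Pb (ingestion +
inhalation for Cd and Pb, inhalation only for Ni, all three pathways for
As), matching the metal sets such assessments actually report.

The bioaccessibility rate is `RD = CDBA / CT`, computed per sample and
then averaged per metal. (A ratio taken the other way around would exceed
1 and contradict every reported percentage.) RD is scale-invariant and
validated against `0 <= CDBA <= CT` at data entry.

Screening values for the exceedance statistics (e.g. GB 15618-2018
risk-screening concentrations) depend on land use and soil pH and
therefore have **no bundled default**; they are a required user input.
Exceedance is strict (`CT > screening`).

## The synthetic generator

The generator emulates a four-site × four-season composite-sampling
campaign with 34 samples: 2 replicates per site × season plus 2 extra
replicates at the S2 hotspot (the true replicate layout of such a
campaign is a design choice; placing the extras at the hotspot matches
its role as the pollution focus).

* **Concentration law.** Log-normal per metal (switchable to gamma), the
  standard model for environmental concentrations, with mean equal to
  the pooled target × season effect × site effect and a default
  coefficient of variation of 0.3 — a typical within-campaign spread for
  road-dust metals. Effects are renormalized against the realized layout
  so the expected pooled mean equals the target exactly.
* **Calibration targets.** Pooled means Cd 0.68, Ni 33.7, As 11.2,
  Pb 64.3, Zn 703, Cu 79.4, Cr 79.2 mg/kg; mean bioaccessibility rates
  Cd 42.32 % > Zn 29.72 % > Cu 20.51 % > Ni 15.3 % > Cr 6.87 % >
  As 6.2 % > Pb 3.1 %.
* **Seasonal structure.** Multiplicative season effects averaging to 1
  per metal: summer-elevated for Ni, As, Pb, Zn, Cr (Ni and As calibrated
  so their summer means are 35.2 and 12.5 mg/kg, i.e. 1.045× and 1.116×
  the pooled mean; the others use a generic 1.10 summer effect);
  Cd lowest in spring and highest in autumn; Cu the mirror image.
* **Hotspot.** S2 is enriched 1.3× for Cd and As; the magnitude is a free
  design value chosen to make the hotspot visible without dominating the
  pooled calibration.
* **Bioaccessible fraction.** `CDBA = CT × f` with `f ~ Beta` centred on
  the metal's target rate at precision 400, i.e. a per-sample standard
  deviation of roughly 1–2 percentage points — consistent with rates that
  are stable across seasons and sites. `CDBA <= CT` holds by
  construction.
* **Determinism.** A config + seed pair reproduces the table exactly; the
  generator saves and restores the caller's RNG state.

What the generator does **not** emulate: spatial dispersion and wind
fields, temporal autocorrelation between seasons, measurement censoring,
and correlated multi-metal sources. Passing tests on synthetic data
therefore demonstrate that the pipeline is correct and well-calibrated
under the stated statistical structure, not that any particular field
site satisfies that structure.

## Numerical choices

* Alpha-cut endpoints at `alpha = 1` can cross by one ulp; they are
  clamped to their midpoint.
* Interval products/quotients validate non-negativity instead of
  implementing signed interval arithmetic (out of scope for this model).
* `tfn_from_samples` uses the sample mean as the most-expected value
  (`center_rule = "median"` is available); with a single observation the
  TFN is crisp.
* The dominant pathway per metal is the one with the largest CR-interval
  midpoint — a simple, monotone comparator; the model itself does not
  prescribe one.
* Results use a single alpha cut by default; sweeping alpha is a loop for
  the caller, since every function takes alpha explicitly.

## Test problem sizes

The suite checks the interval algebra against a brute-force grid oracle
on 1000 random TFN pairs at four alpha levels, crisp-vs-fuzzy equivalence
on 100 random parameter sets, membership normalization on 1000 random
intervals, and generator calibration over 200 seeds (pooled Zn mean
within 3 % of target; bioaccessibility ordering reproduced in at least
95 % of seeds). These sizes give the properties sharp statistical teeth
while keeping the whole suite around two minutes on one core.

## Known limitations

* No Monte Carlo or probabilistic assessment: TFNs were chosen over
  Monte Carlo for their fit to sparse, low-precision data, and the two
  approaches answer slightly different questions.
* Two receptor classes only; no age-integrated lifetime weighting and no
  blood-lead (IEUBK-style) modelling for Pb.
* No significance testing of RD across seasons/regions; the summary
  tables expose the inputs if a user wants to run one externally.
* Per-metal total CR is reported, but totals are not summed across metals
  into a single site verdict — the model does not define such a sum.
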