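---
title: "Modelling nitrogen partitioning from a urea-supplemented pasture diet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nitrogen partitioning from a urea-supplemented pasture diet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npartition)
```

## The experimental model

Fresh temperate pasture is already rich in crude protein (CP), and most of
that surplus N leaves a grazing cow in urine, where it concentrates in urine
patches and leaches toward groundwater. To study N partitioning one needs
diets that differ *only* in N. On pasture that is achieved by dosing feed
urea on top of a common pasture base: urea is pure rumen-degradable
non-protein N, so structural carbohydrates, sugars and energy density stay
fixed while dietary CP rises.

`npartition` models the two-phase form of such an experiment:

* **Phase 1 (grazing, 21 d, 15 cows, 3 treatments).** Cows are acclimated on
  a stepped ramp (88 → 176 → 351 → 450 → 600 → 690 g urea/d; 4/3/4/3/4/3
  days; 2 daily doses below 351 g/d, 3 at or above) to avoid ammonia
  toxicity. The medium-N group runs only the first three steps, starting on
  day 11, so all groups finish on their final dose together. The biological
  readout is milk yield versus urea dose.
* **Phase 2 (metabolism stalls, 7 collection days, 10 cows, 2 treatments).**
  Total collection of refusals, feces, milk and urine volume. The medium-N
  dose is reduced to 250 g/d — phase 1 shows that beyond ~350 g/d (about 2%
  of dry-matter intake) milk yield falls, so the balance study stays in the
  safe range.

## The two statistical models

**Split-line milk response.** Milk yield is modelled as a continuous
two-segment linear function of urea dose,

$$y = a + b_1 \min(x, c) + b_2 \max(x - c, 0),$$

where $c$ is the breakpoint (g/d) at which the dose stops being harmless.
`fit_splitline()` estimates $c$ by *profiling*: for each candidate $c$ the
model is linear in the hinge basis $\{1, x, (x-c)_+\}$ and is fit by OLS;
the candidate with the smallest SSE wins. The default candidate set is a
10 g/d grid spanning the interior of the observed doses (the two smallest
and two largest distinct dose levels are excluded from the span so both
segments keep at least two distinct support points), followed by a
refinement pass at 1 g/d resolution within ±10 g/d of the grid winner. A
grid profile was chosen over general nonlinear least squares because it is
deterministic, exhaustively testable, and exact whenever the true breakpoint
is on the grid; the refinement pass keeps the resolution cost low. Ties in
SSE go to the smallest breakpoint, and the refinement pass only replaces the
grid winner on a strict (beyond 1e-9 relative) improvement, so degenerate
single-line data report the smallest candidate rather than grid dust. The
slope-change p-value is the F-test of the hinge term against the
single-line null at the selected breakpoint; when the fit is exact (SSE
numerically zero) the p-value is reported as 0. The post-breakpoint decline
is conventionally reported as $-100\,b_2$, kg milk per 100 g urea.

**Urinary N regression.** With N retention assumed zero (non-pregnant,
mid-lactation cows at stable condition), urinary N is estimated *by
difference*: intake N − fecal N − milk N. `fit_urine_regression()` then
pools all cow-days and fits OLS of estimated urine N on N intake. Pooling
(rather than per-cow aggregation) mirrors the convention of plotting one
point per cow per day; `per_cow = TRUE` provides the aggregated alternative.
Negative estimated urine N is flagged, never clipped, so that upstream data
faults stay visible.

**Treatment comparison.** `compare_treatments()` fits a linear mixed model
with a fixed treatment effect and a random cow intercept by REML — the
animal-as-experimental-unit analysis for repeated measures — and reports
least-squares means, SEM, and a p-value using the conservative between-cow
denominator degrees of freedom (cows − treatments). Compound symmetry (the
random intercept with independent residuals) is the simplest covariance
consistent with that design; an AR(1) residual option was considered and
deliberately left out of this version. On degenerate zero-residual input the
mixed model cannot be estimated; LS means then fall back to direct cell
means (identical on these designs, since every cow sits in one treatment)
with SEM 0.

## Unit conversions and energy balance

The fixed conversion factors are field standards: feed CP = N × 6.25, milk
N % = milk CP % / 6.38, and feed-grade urea contains 46.6% N (0.466 g N/g;
not a measured value here, but the manufacturing standard, exposed as
`urea_n_fraction`).

Phase-1 intake cannot be measured at grazing, so `estimate_phase1_dmi()`
back-calculates it from metabolizable-energy (ME) requirements:
maintenance `0.56 MJ × BW^0.75`, walking `0.0037 MJ/kg BW per km`,
body-weight change (per-cow OLS slope of weight on day, valued at a
configurable 30 MJ/kg — the coefficient is a stated assumption, and for the
stall phase BW is stable so the term is ~0), and milk energy
`(0.0929·fat% + 0.0547·CP% + 0.0395·lactose%) Mcal/kg × yield / 0.65`.
The Mcal total is converted to MJ by *dividing* by 0.238 Mcal/MJ: the
composition coefficients produce Mcal, so dividing is the only dimensionally
coherent direction, even though applied-literature formula strings sometimes
read as a multiplication. `convert = "literal_mcal"` preserves that literal
arithmetic for audit. Total ME divided by pasture ME (11.8 MJ/kg DM at
grazing) gives DMI. The parenthesization treats the three composition terms
as a per-kg energy multiplied by yield — the only reading with coherent
units. No pregnancy term is included (the herd is non-pregnant by design).

## What the generator emulates — and what it does not

`simulate_phase1()` draws a herd (BW 505 ± 10.4 kg, 103 ± 9.4 days in milk,
BCS 4.1 ± 0.04, parity ≥ 2), assigns the ramp doses, and generates milk
yield as the true split-line value plus a Gaussian cow intercept plus a
Gaussian cow-day residual. `simulate_phase2()` draws intake (20 kg DM
offered minus a refusal draw) and pasture CP (18.4 ± 1.69% of DM), computes
true N intake, sets total non-urine N to $(1-s)\,I - a$ plus noise, splits
it 0.515/0.485 between feces and milk (matching the observed means of
~133 vs ~123 g/d), and **back-solves** the observable fields (fecal N
concentration per kg of drawn wet fecal mass; milk CP % from drawn yield) so
that `n_balance()` recovers the intended components exactly. The implied
urinary N therefore follows $a + sI + \varepsilon$ by construction, with
defaults $a = -174.2$, $s = 0.86$.

Defaults the study conditions do not pin down are stated assumptions chosen
once at realistic magnitudes: milk residual and cow SDs of 1.5 kg/d each,
urinary-N residual SD 15 g/d and cow SD 10 g/d, wet fecal mass 44 ± 4 kg/d,
urine volume 35 ± 4 L/d. The published treatment SEMs (e.g. 14.2 g/d for
urine N) are consistent with these magnitudes. Negative implied quantities
(possible only under extreme settings) are clipped to zero with a warning.

Passing recovery tests on these data shows the estimators are correct and
well-behaved at study scale under Gaussian, compound-symmetric noise. It
does **not** show robustness to what real collections contain: volatile
ammonia losses from unacidified urine containers, assay error in fecal N,
diurnal intake patterns, or non-Gaussian refusal behaviour. None of those
are modelled, deliberately — the generator exists to validate the pipeline,
not to emulate a laboratory.

## Interfaces

Every stage is a data-frame-in/tibble-out function, so the pipe is the
pipeline; `run_pipeline()` drives simulate → balance → fits → comparison and
(optionally) writes a reproducible bundle: canonical versioned CSVs (comma
delimiter, point decimal, UTF-8, schema comment line), fit JSONs, a
provenance block recording the seed, a config hash and every constant
tagged `printed` or `assumed`, and a plain-text report. Reading back
validates the schema and rejects malformed rows by cow and day. These
functions, rather than a shell executable, are the package's interface: the
natural caller is an R session or script, and a wrapper would add a second
argument-parsing surface without new capability.

## Numerical choices and test scale

Exact reconstructions (noise-free data with the truth on the candidate
grid) are asserted to machine precision; OLS routes are cross-checked
against explicit normal-equations oracles at 1e-6 or tighter. Stochastic
recovery uses 200 seeded replicates at study scale (15 cows × 21 d for the
split-line; 10 cows × 7 d for the urinary-N line), the balance-closure
property is checked over 10,000 simulated rows, and the whole suite runs in
well under a minute — sizes chosen so the checks are statistically
meaningful yet quick to iterate.

## Known limitations

* Urinary N is estimated by difference, so it inherits every error in
  intake, fecal and milk N; the closure identity holds exactly by
  construction and is a bookkeeping property, not a validation of any row.
* The split-line stage treats cow-days as independent; cow-level
  correlation widens the true sampling variability of the breakpoint
  relative to the pooled fit's nominal precision.
* LS means computed from per-cow-day data can differ slightly from
  published tables that average differently; the package reports its own
  per-cow-day convention.
* The breakpoint search is grid-based; a breakpoint between 1 g/d grid
  points is resolved only to the nearest grid point.
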