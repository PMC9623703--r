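# npartition

Nitrogen partitioning in grazing dairy cows, modelled by supplementing a
basal pasture diet with graded doses of feed urea.

Urinary nitrogen from grazing cows is the dominant route by which surplus
dietary N reaches waterways, so experiments that manipulate dietary crude
protein (CP) while holding everything else constant are the workhorse for
testing mitigation strategies. On fresh pasture that manipulation is hard —
sward CP varies with season, regrowth and fertiliser — but dosing urea on top
of a common pasture base raises dietary N cleanly. `npartition` implements
the complete analysis pipeline for such a two-phase experiment:

1. **Grazing acclimation phase** (15 cows, 21 days): cows are stepped up to
   0, 351 or 690 g urea/d on a fixed ramp. Milk yield `y` (kg/d) responds to
   urea dose `x` (g/d) as a continuous two-segment ("split-line") model

   `y = a + b₁·min(x, c) + b₂·max(x − c, 0)`

   with breakpoint `c` ≈ 350 g/d: a mild rise below it, a decline of about
   2.35 kg milk per 100 g urea beyond it (the onset of intake depression).
   The breakpoint is estimated by profiling the hinge-basis OLS fit over a
   candidate grid and minimizing SSE.
2. **Metabolism-stall phase** (10 cows, 7 collection days): total collection
   of feed refusals, feces and milk. The four-way N balance per cow-day is

   `N intake = fecal N + milk N + urinary N`  (retention ≈ 0),

   with intake from dry-matter intake × pasture CP/6.25 plus urea N, milk N
   from milk CP/6.38, and urinary N **estimated by difference**. Pooled OLS
   across cow-days gives the headline relationship
   `urine N = −174.2 + 0.86 × N intake` (g/d).

Because no raw data from such experiments are deposited, the package ships a
seeded synthetic-data generator (`simulate_phase1()`, `simulate_phase2()`)
that uses these printed models as ground truth, so every stage — the
energy-balance back-calculation of intake, the balance table, both fits and
the repeated-measures mixed-model treatment comparison — is testable by
parameter recovery.

## Worked example

```r
library(npartition)

cfg <- sim_config(seed = 2021)   # study-scale defaults
rep <- run_pipeline(cfg)

rep$splitline
#> Split-line (broken-stick) fit
#>   y = 20.1 +0.007002 * min(x, 313) -0.02108 * max(x - 313, 0)
#>   breakpoint: 313   n: 315   SSE: 1763   R-sq: 0.345
#>   slope-change p-value: 7.3e-21

rep$urine_fit
#> Urinary N ~ N intake (pooled OLS over cow-days)
#>   urine N = -195.1 +0.8945 * N intake   (g/d)
#>   R-sq: 0.946   n: 70   slope p-value: 1.04e-44

rep$comparisons
#>       parameter lsmean_low lsmean_medium    sem   p_value n_cows n_days
#> 1    n_intake_g     562.20        675.91 8.9409 1.864e-05     10      7
#> 2     fecal_n_g     131.61        136.62 3.2365 3.049e-01     10      7
#> 3      milk_n_g     123.94        128.67 3.0480 3.049e-01     10      7
#> 4 urine_n_est_g     306.65        410.62 8.2565 2.005e-05     10      7
#> 5   diet_cp_pct      18.45         22.01 0.2818 1.964e-05     10      7
```

One simulated replicate behaves like the real experiment: the split-line
breakpoint lands near 350 g/d (here 313, within sampling noise of a single
replicate), the urinary-N regression recovers a slope near 0.86 and an
intercept near −174 g/d, the urea dose raises N intake and urinary N sharply
(p < 0.001) while fecal and milk N barely move — exactly the partitioning
signature the method is designed to expose. `autoplot()` on either fit
object draws the dose-response or regression; `tidy()`/`glance()` return the
coefficients as tibbles. `run_pipeline(cfg, out_dir = "out")` additionally
writes every intermediate CSV, the fit JSONs, a provenance block
(seed, config hash, printed-vs-assumed constants) and a plain-text report,
byte-identical for a fixed seed.

Individual stages are ordinary data-frame-in/tibble-out functions and
compose with the pipe:

```r
sim_config(seed = 1) |>
  simulate_phase2() |>
  n_balance() |>
  fit_urine_regression()
```

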