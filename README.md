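# aedesfuse

Fuses a statistical reconstruction of adult female *Aedes aegypti*
abundance with mechanistic population models, so that a
mechanistically-grounded simulation tracks observed abundance exactly
and can then be perturbed — e.g. by insecticide-spraying campaigns —
while staying anchored to the data.

It is aimed at vector-borne-disease modellers who have a flexible
statistical abundance surface (a GAM fitted to household surveys, say)
and want the counterfactual power of a stage-structured, spatially
explicit model without refitting one from scratch.

## The model

Per location, eggs `E`, larvae `L`, pupae `P` and adult females `N`
follow

    dE/dt = n_E a(T) N / 2 − (d_E + μ_E) E
    dL/dt = d_E E − (d_L + μ_L + μ_c(t) + L²/κ) L
    dP/dt = d_L L − (d_P + μ_P + μ_c(t)) P
    dN/dt = d_P P − μ_N N

with all vital rates temperature-driven (enthalpy-model development,
threshold-exponential mortalities, air→water conversion for the
immature stages; constants live in `inst/extdata/thermal_default.yaml`).
The carrying capacity is fixed by the dominance rule
`mean(L)²/κ = 10 mean(μ_L)` and scales across locations with squared
initial abundance, so every location is a rescaled copy of one
normalized system.

The key step is the inverse calibration (`calibrate()`): given a target
abundance series `N(t)` it reconstructs `P`, `E`, `L` in closed
sequence (finite differences plus per-day Radau integration) and solves
the larval equation for the residual immature mortality `μ_c(t) ≥ 0`
that makes the model reproduce the target. That forcing then drives a
stochastic agent-based model (`run_abm()`): deterministic per-building
immatures, individual adults with Poisson emergence, exponential
daily-death conversion, and movement within 100 m at daily probability
0.3. ULV and TIRS campaign models (`campaign_spec()`,
`apply_campaign()`) add instantaneous or residual adult mortality on a
zone-ordered schedule, and `zone_matrix()`, `age_stats()` and
`rebound_metrics()` summarize the spatial, age-structure and rebound
consequences. A synthetic-city generator (`synth_spec()` and friends)
provides desk-scale stand-ins for the building table, temperature
record and separable abundance surface.

## Worked example

```r
library(aedesfuse)

spec   <- synth_spec(n_buildings = 500, n_days = 730, seed = 42)
temps  <- generate_temperature(spec)
city   <- generate_city(spec)
target <- generate_target_abundance(city, spec)

cal <- calibrate(target$series$N_city, temps)
cal
#> Calibration of residual immature mortality mu_c(t)
#>   days: 730  kappa_norm: 1.95384  scale (N at day 0): 25000
#>   mu_c range: [1.058, 2.093] per day; clamped days: 0
#>   self-consistency relative RMSD: 0.01211 (burn-in 30 days excluded)

run   <- run_abm(city, cal, N0 = target$weights, seed = 43)
ode_N <- cal$N_forward * sum(target$weights)
cor(run$city_series$N_total, ode_N)
#> [1] 0.9993

runs <- apply_campaign(city, cal, target$weights,
                       campaign_spec("ULV", start_day = 365,
                                     buildings_per_day = 60), seed = 43)
rebound_metrics(runs$sprayed$city_series$N_total,
                runs$baseline$city_series$N_total, campaign_start = 365)
#> ULV: minimum 10,132 adults on day 389 (64% below same-day baseline)
#> rebound: within 10% of baseline after 2.7 months, within 1% after 3.9
```

Reading the numbers: `mu_c` is the calibrated residual larval/pupal
mortality (per day) that absorbs whatever the temperature-driven rates
cannot explain — always non-negative, here never clamped. The 1.2%
self-consistency RMSD says the forward model reproduces the target it
was calibrated to. The 0.9993 correlation says one stochastic
agent-based replicate tracks the deterministic trajectory at
~25,000-adult scale. The campaign output shows the characteristic
ULV response: a sharp trough just after the campaign ends, then a
density-dependence-driven rebound over a few months.

A thin CLI over the same functions is in `inst/cli/aedesfuse.R`
(subcommands `synth`, `calibrate`, `simulate-ode`, `simulate-abm`,
`spray`, `summarize`).

The methods vignette (`vignettes/model-fusion.Rmd`) documents the
model, the calibration algebra, the numerical conventions and the
design choices in detail.

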