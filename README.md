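# ageflux

Demand-gated, age-structured simulation and estimation of mRNA (and
protein) level fluctuations in single cells.

Measured cellular RNA levels fluctuate, and the net transcription and
degradation rates behind those fluctuations are hard to measure
directly in living systems.  `ageflux` implements a deterministic,
discrete-time model in which both are emergent: molecules carry an
**age** (steps since transcription) that sets their survival and
activity, transcription occurs in fixed-size **pulses**, and pulsing is
gated by a **demand for activity** — production fires at step *t* iff
the total activity falls short of the demand,

```
B[0,t] = B0                      (pulse, iff TA[t-1] < DA[t])
B[x,t] = B[x-1,t-1] * d[x-1]     (aging with survival d)
A[x,t] = B[x,t] * a[x]
TB[t]  = sum_x B[x,t]            (total abundance)
TA[t]  = sum_x A[x,t]            (total activity)
```

From this loop the package derives, and lets you analyse:

* **one-unit dynamics** (`simulate_unit`) — cycles, fixed points and
  stimulus-driven fluctuations under constant, rotating, logistic or
  arbitrary demand schedules;
* **coupled units** (`coupled_model`, `simulate_chain`) — an
  RNA→protein two-unit model in which the unmet protein demand drives
  transcription, and general chains/webs of units;
* **exact cycle analysis** (`detect_cycles`, `resample_trajectory`) —
  period, amplitude, sub-cycles and sampling-interval aliasing, by
  exact state recurrence (the dynamics are deterministic, so no
  spectral estimation is needed);
* **age-distribution inference** (`simulate_labelling`,
  `infer_age_distribution`) — a staggered labelling design whose
  adjacent-group differences recover the per-age abundance exactly;
* **parameter estimation** (`fit_exhaustive`,
  `estimate_demand_windowed`) — exhaustive grid-search least squares
  recovering RNA lifespan, per-age survival rates, pulse transcription
  level, demand and accumulated transcription/degradation (hence net
  rates) from a time series of abundances, with R² and MdAPE
  diagnostics;
* **synthetic data** (`generate_series`) — seeded series with stored
  ground truth for recovery studies.

## Worked example

```r
library(ageflux)

## one unit: decreasing (type B) survival, activity 1 at every age
profile <- make_profile("B", "A")
traj <- simulate_unit(profile, pulse_policy(100),
                      demand_schedule("constant", level = 50),
                      horizon = 60)
detect_cycles(traj)
#> <cycle_report> periodic, period 5, amplitude 84, transient 3
```

At demand 50 the level cycles every 5 steps (it climbs while activity
is below demand, then decays); the amplitude is max − min of the total
level over one steady period.  Raising the demand to an unattainable
400 makes every step pulse, and a staggered-labelling experiment read
off at harvest recovers the steady per-age ladder:

```r
lab <- simulate_labelling(profile, pulse_policy(100), 400,
                          labelling_design(n_groups = 7, harvest_time = 17))
lab$labelled_totals
#> group_6 group_5 group_4 group_3 group_2 group_1 group_0
#>     364     358     343     312     262     190     100
infer_age_distribution(lab)
#> <age_distribution> total 364
#> age_0 age_1 age_2 age_3 age_4 age_5 age_6
#>   100    90    72    50    31    15     6
```

Each group's labelled total is the sum of cohorts younger than its
exposure lag, so adjacent differences are exactly the per-age levels;
their total, 364, is the steady-state abundance.

The inverse problem — here a series synthesised at a known parameter
set (a 70-minute yeast-like course sampled every 5 minutes) and handed
to the exhaustive-search fitter:

```r
prof <- age_profile(c(0.9, 0.9, 0.5, 0))     # survival by age
series <- generate_series(prof, pulse_policy(1.4), 2, horizon = 14,
                          step_length = 5, organism = "yeast")
fit <- fit_exhaustive(series,
                      fit_spec(pulse_grid = (1:30) / 10,
                               demand_grid = (1:10) / 2,
                               init_grid = "empty", refine_pulse = FALSE))
fit
#> <fit_result>
#>   lifespan 20 (step 5 )
#>   pulse level 1.4
#>   survival 0.9 0.9 0.5 0
#>   demand 2
#>   SSE 0  R2 1  MdAPE 0
#>   accumulated transcription 11.2 , degradation 8.54
```

The fitter recovers the generating parameters exactly (SSE 0): a
20-minute RNA lifespan, pulse transcription of 1.4 units per event,
per-age survival 0.9/0.9/0.5, demand 2.  Accumulated transcription
minus accumulated degradation always equals the net level change over
the experiment; dividing by the duration gives the net transcription
and degradation rates (`metabolic_report(fit)`).

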