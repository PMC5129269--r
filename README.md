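# wfcsim

`wfcsim` simulates the dynamic evolution of **work-family conflict (WFC)**
for construction-industry employees over the 36-month life cycle of a
project. It is written for occupational-health and organizational-behaviour
researchers who want to explore, rather than survey, how the two directions
of conflict — **WIFC** (work interference with family) and **FIWC** (family
interference with work) — feed back on satisfaction and performance in the
work and family domains, and how the moderators *work flexibility*,
*organizational support* and *family support* shift those outcomes.

The package has two layers:

* a small generic **stock-and-flow engine**: piecewise-linear lookup tables
  with step discontinuities, first-order exponential delays (`DELAY1`-style,
  `dy/dt = (x − y)/D`), deterministic fixed-step Euler integration with
  topologically ordered auxiliary evaluation, guarded divisions, feedback-loop
  enumeration, and lossless JSON model serialization;
* the **WFC model** itself: 18 variables — stocks `job_satisfaction` (starts
  at 5) and `family_satisfaction` (starts at 1.5), their increment rates,
  thirteen auxiliaries and the `work_flexibility` constant — plus two delay
  states, wired as

  ```
  working_time            = workload                      (stepped lookup of time)
  job_involvement         = job_satisfaction × working_time
  job_performance         = working_time × job_experience × job_involvement × delay1(job_satisfaction) / 10
  organizational_support  = 0.1 × job_performance
  job_pressure            = workload / (job_performance × organizational_support × work_flexibility)
  WIFC                    = 0.05 × job_involvement × job_pressure / work_flexibility

  family_involvement      = 100 × family_satisfaction / working_time
  family_support          = 1.0 × family_involvement
  family_performance      = delay1(family_satisfaction) × family_involvement / 10
  family_pressure         = 1 / (family_support × family_performance)
  FIWC                    = 0.05 × family_involvement × family_pressure

  d(job_satisfaction)/dt    = −λJ × FIWC      (λJ = 1 /month)
  d(family_satisfaction)/dt = −λF × WIFC      (λF = 0.25 /month)
  ```

  Workload follows the project stages (decision 4.5 months, design 4.5,
  construction 27, split at month 18): 6 → 9 → 12 → 8, as a right-continuous
  step lookup; job experience ramps linearly from 0.5 to 0.7.

## Worked example

```r
library(wfcsim)

traj <- run_scenario("current")          # baseline, 36 months, dt = 0.0625
run_summary(traj)
#> <run_summary> scenario 'current'
#>   WIFC > FIWC at 39.2% of saved points
#>   WIFC in [0.00993005, 0.0444444], FIWC in [0.0133333, 0.0301665]
#>   final: job_satisfaction = 4.18563, family_satisfaction = 1.31086,
#>          job_performance = 78.9184, family_performance = 2.15675

trend_signs(traj, "wifc")
#> <trend_report> 'wifc' (flat tolerance 1e-06)
#>   start  end      first        last   trend
#> 1   0.0  4.5 0.04444444 0.041640870 falling
#> 2   4.5  9.0 0.01849232 0.017830897 falling
#> 3   9.0 18.0 0.01002563 0.009946675 falling
#> 4  18.0 36.0 0.02238159 0.021505717 falling

compare_runs(traj, run_scenario("current_1"))   # work flexibility 1 -> 5
#> <comparison_report> 'current_1' vs baseline 'current'
#>              variable final_base final_alt  mean_base   mean_alt rel_change dominates
#> 1    job_satisfaction   4.185626  4.286333   4.601772   4.639220 0.02406018      TRUE
#> 2 family_satisfaction   1.310861  1.492605   1.399425   1.496018 0.13864481      TRUE
#> 3     job_performance  78.918390 82.654090 104.996812 106.536922 0.04733624      TRUE
#> 4  family_performance   2.156754  2.785215   2.327425   2.642953 0.29139178      TRUE
```

Reading the output: both conflicts start at their hand-computable values
(WIFC = 2/45 ≈ 0.0444, FIWC = 1/75 ≈ 0.0133); WIFC decays as job experience
and performance build up, rebounds when the workload drops at month 18
(performance falls with working time), and both satisfaction stocks erode
monotonically. Raising work flexibility to 5 improves all four outcomes at
month 36, with the largest relative gain in family performance (+29%) —
flexibility damps WIFC quadratically, which protects family satisfaction and
involvement. The `trend_report` stages are right-open: the month-18 point
belongs to the second construction phase, matching the workload step.

A shell interface covers the same operations
(`run`, `compare`, `loops`, `dump-model`):

```sh
Rscript inst/cli/wfcsim run --scenario current_3 --out current_3.csv
Rscript inst/cli/wfcsim compare --base current --alt current_2
Rscript inst/cli/wfcsim loops
```

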