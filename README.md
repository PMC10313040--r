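# cycleASF

Quantifying how synchronized populations of cycling cells lose synchrony —
and reading cell-cycle period variability off the decay.

## Who this is for

Cell biologists and modelers analyzing DNA-content timecourses
(propidium-iodide flow cytometry or equivalents) of cells released from a
synchronizing arrest, and anyone who needs a transparent, scriptable
alternative to black-box cytometry software for (a) measuring population
synchrony over time and (b) deconvolving DNA histograms into G1/S/G2
fractions.

## What it computes

**Auto-similarity function (ASF).** The synchrony of a population at
successive sampling times is the two-sample Kuiper statistic between the
empirical CDFs of the per-cell DNA measurements:

    Σ(t_i, t_j) = sup_v [F_i(v) − F_j(v)]₊ + sup_v [F_j(v) − F_i(v)]₊

Σ = 1 means the two snapshots are fully separated (a synchronized cohort
caught moving), Σ = 0 means indistinguishable distributions (asynchrony).
The statistic is rank-based, hence invariant to gain, units and any
monotone distortion of the fluorescence axis, and its two-sided (Kuiper)
form weights the cyclic DNA axis symmetrically.

**Single-cell interphase model.** DNA content over one cycle of period τ:

    dna(t) = dna₀ · (1 + 1/(1 + exp(−β (t − s)))),  β = 8/τ,  s = 2τ/3

so S phase is the middle third of the cycle (8 h at τ = 24 h) and content
saturates toward 2·dna₀. Population noise is error-in-variables: per cell
per cycle, τ' = τ̄ + N(0, σ_τ²) and dna₀' = dna₀ + N(0, σ_dna²)
(Poisson comparison families available).

**Pipeline.** `simulate_population()` runs cohorts through repeated noisy
cycles (synchronized release or asynchronous control); `asf_successive()`
/ `asf_matrix()` quantify synchrony; `fit_logistic_decay()` summarizes the
decay by a logistic rate (1/h); `estimate_sigma_tau()` inverts an observed
decay curve into a period-variability estimate by grid-search simulation;
`build_histogram()` + `djf_fit()` give Dean–Jett–Fox-style G1/S/G2
percentages; `read_events_table()` / `write_timecourse()` move everything
through a plain long-format CSV (`cell_id, time_h, fluorescence_au`, plus
optional ground-truth columns). FCS ingestion is not included: no FCS
parser is available in the supported dependency set, and the CSV path is
the package's first-class interchange format — export list-mode events to
CSV upstream.

## Worked example

```r
library(cycleASF)

# Synchronized release (double-thymidine-block design: 1000 cells,
# sampled every 8 h for 88 h), period noise 24 ± 3 h:
tc <- emulate_synchronized_experiment(noise_spec(24, 3, 0.05),
                                      n_cells = 1000, seed = 42)
series <- asf_successive(tc)
series
#>  t_start t_end value
#>        0     8 0.997
#>        8    16 0.989
#>       16    24 0.784
#>       ...
#>       72    80 0.380
#>       80    88 0.408

fit_logistic_decay(series)
#> <logistic_fit> upper 1, lower 0.36, rate 0.06487 1/h, t_half 45.6 h (rss 0.0231)

# Asynchronous control: flat at the finite-sample floor (~0.05 at n = 1000)
ctrl <- emulate_asynchronous_experiment(noise_spec(24, 3, 0.05),
                                        n_cells = 1000, seed = 43)
round(asf_successive(ctrl)$value, 3)
#> [1] 0.050 0.053 0.039 0.036 0.047 0.042 0.035 0.042 0.055 0.057 0.048

# Invert the observed decay into a period-SD estimate:
est <- estimate_sigma_tau(normalize_series(series), grid = 1:5, reps = 3,
                          base = simulation_config(init_age_fraction = 0.5,
                                                   seed = 7))
est$estimate
#> [1] 3
est$profile
#>   sigma_tau  discrepancy
#> 1         1 1.2879697447
#> 2         2 0.3931630460
#> 3         3 0.0006946053
#> 4         4 0.2850446299
#> 5         5 0.7723264224
```

Reading: the synchronized series decays from ~1 toward the asynchronous
floor following a logistic curve whose rate (0.065/h here) is the
desynchronization-rate summary; the discrepancy profile is sharply convex
around the generating σ_τ = 3 h, which the estimator recovers.

## Command line

```sh
Rscript exec/cycleASF simulate --n-cells 1000 --sigma-tau 3 --seed 7 --out tc.csv
Rscript exec/cycleASF asf --input tc.csv --out asf.csv --fit-out fit.json
Rscript exec/cycleASF classify --input tc.csv --out phases.csv
Rscript exec/cycleASF estimate-noise --input tc.csv --grid 1,2,3,4,5 --seed 7 --out est.json
```

Each run writes a `<out>.log` recording version, seed and effective
configuration; identical seed + flags ⇒ byte-identical outputs.

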