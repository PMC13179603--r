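# dmscc

Analysis of **dynamic microfluidic single-cell cultivation (dMSCC)**
experiments: yeast microcolonies growing in picoliter monolayer chambers
while the perfused medium oscillates between glucose excess (50 g/L) and
glucose limitation (10 mg/L) on a fixed 30 s period. The share of each
period spent at excess — the duty cycle *f* = *y*/*p* — is stepped by
2 s between conditions, and the question is how second-scale differences
in nutrient availability reshape growth, energy state, glycolytic flux
and cell size.

The package is for experimenters and modellers who have (or want to
simulate) per-cell segmentation tables from such cultivations. It
provides:

- **Chip model** — the square-wave environment, per-array 2 s time
  shifts, first-order along-array pulse smoothing
  (dC/dt = k(n)·(C_channel − C), k(n) = k₀·δⁿ⁻¹), and dye-trace pulse
  metrics (effective durations from 50%-amplitude crossings, onset
  shift, definition = achieved/nominal amplitude).
- **Synthetic data** — an agent-based generator of budding colonies
  with two-phase growth adaptation, calibrated dose–response maps,
  ratiometric sensor readouts, heritable subpopulations and lognormal
  measurement noise; the stand-in for segmented microscopy data.
- **Growth analysis** — specific growth rates as slopes of ordinary
  least-squares fits of ln(total colony area) vs time: µ_max as the
  maximal slope over a sliding 3 h window after the onset of the
  dynamics, µ_ini over the first hour after onset, and the adaptation
  time as the intersection of the two regression lines,
  t* = (b_ini − b_max)/(s_max − s_ini), gated by µ_ini < µ_max and
  µ_ini/µ_max < 0.9. Plus excess-control normalization, the
  time-weighted baseline f·µ_exc + (1−f)·µ_lim, and a Monod fit
  µ = µ_m·S/(K_s + S) against the duty-cycle-weighted mean glucose.
- **Population statistics** — QUEEN-2m ATP ratio (uvGFP/GFP) and GlyRNA
  flux ratio (CFP/RFP; lower = more flux), per-timepoint median +
  IQR(25–75) over all pooled cells, window mean-of-medians over the
  fixed 10–18 h window, normalized to the excess control.
- **Sweeps and reports** — full condition sweeps over 2 s-stepped
  excess durations with replicate means, monotone spline summaries and
  deterministic TSV/JSON reports.

## Worked example

Simulate one condition — Ethanol Red, 9 s excess / 21 s limitation —
and its excess control, then run the full analysis:

```r
library(dmscc)

params  <- default_strain_params("Ethanol Red")
profile <- make_profile(excess_s = 9, limitation_s = 21)
cells   <- simulate_experiment(sim_config(seed = 1, profile, n_chambers = 10),
                               params)
dim(cells)
#> [1] 14895    17

res <- analyze_condition(cells)   # filter -> pool -> growth + pop stats
res$fit_ini
#> <growth_fit> mu = 0.0636 1/h over [4.00, 5.00) h (n = 8, R^2 = 0.9401)
res$fit_max
#> <growth_fit> mu = 0.1453 1/h over [14.93, 17.93) h (n = 23, R^2 = 0.9997)
res$adaptation
#> <adaptation_result> mu_ini = 0.0636, mu_max = 0.1453 1/h (ratio 0.438); t_adapt = 2.928 h

ctrl <- analyze_condition(simulate_experiment(
  sim_config(1, make_profile(30, 0), n_chambers = 10), params))
normalize_mu(res$fit_max$slope, ctrl$fit_max$slope)
#> [1] 0.7168848
normalize_summary(res$queen, ctrl$queen)
#> <pop_summary> queen_ratio: window [10, 18] h mean-of-medians 0.5231 (IQR 0.4718-0.7300, 15 timepoints), normalized 0.7868
```

Reading the numbers: after the oscillation starts at 4 h the colony
grows at 0.064 h⁻¹ for about 2.9 h, then speeds up to 0.145 h⁻¹ — an
adapted rate at 72% of the constant-excess control, even though glucose
is abundant only 30% of the time. The population ATP readout settles at
79% of the control; the wide IQR reflects Ethanol Red's two heritable
ATP subpopulations.

A full dose–response sweep (all strains, all 2 s steps, controls
included) is one call:

```r
sweep <- run_sweep(sweep_config(seeds = 1))
write_report(sweep, "out/")
```

## Documentation

The methods vignette (`vignettes/dmscc-methods.Rmd`) describes the
models, their assumptions, every tunable parameter with units and
defaults, what the synthetic-data generator does and does not emulate,
and the numerical conventions (window semantics, percentile definition,
tie-breaking, degenerate inputs).
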