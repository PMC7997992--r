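# chromint

Chromatic integration analysis for retinal ganglion cells.

Mouse retinal ganglion cells pool a UV-sensitive (S-opsin) and a
green-sensitive (M-opsin/rod) input channel. Whether that pooling is linear
or nonlinear is measured with dichromatic full-field steps: a ladder of 22
opsin-isolating UV/green Weber-contrast combinations in which every
combination faces its exact contrast negation. A linearly integrating cell
has a *balance point* — a contrast combination where a stimulus and its
reversal evoke the same (null) response — while nonlinear cells either fire
extra spikes there (Off and On–Off types) or are actively suppressed below
baseline (On types).

`chromint` implements this workflow end to end, for experimenters analysing
spike-train exports and for modellers studying the phenomenon in
simulation:

* **Stimulus construction** — silent-substitution source contrasts from a
  2×2 opsin transfer matrix (`opsin_isolating_contrast()`), the 22-step
  contrast ladder (`chromatic_integration_set()`), seeded Fisher–Yates
  presentation orders, chromatic drifting gratings in spatial anti-phase,
  contrast-reversing gratings, binary white noise, and the random-exclusion
  local-spot stimulus on a 44×24 grid (`local_spot_frame()`,
  `simulate_spot_run()`).
* **Simulation** — linear–nonlinear Poisson model cells in eight archetypes
  with ground-truth labels, populations with a ventral UV gradient, and
  spike trains for every stimulus ensemble (`model_cell()`,
  `simulate_population()`, `simulate_step_responses()`).
* **Analysis** — PSTHs, chromatic-integration curves, the crossing point
  with its conservative lower bound, and every index used to classify
  cells:

  | quantity | definition |
  |---|---|
  | chromatic nonlinearity index | signed crossing lower bound / max&#124;R&#124; over all 22 stimuli; &#124;NLI&#124; ≥ 0.1 is nonlinear |
  | UV-green index | (f_green − f_UV)/(f_green + f_UV) from pure-colour peak rates; < −0.7 is UV-selective |
  | On–Off index | (R_On − R_Off)/(&#124;R_On&#124; + &#124;R_Off&#124;) for the stronger colour; ±0.6 thresholds |
  | polarity bias | slope difference of the two curves at the balance point |
  | relative UV sensitivity | 1 − C_UV/(C_UV + C_green) at the interpolated crossing |
  | grating / spatial NLI | F2/F1 at the smallest F1; max F2 / max F1 over reversing conditions |
  | DSI / OSI | normalised vector sum with a 1000-shuffle permutation test |

* **Geometry** — spike-triggered averages, SVD space–time separation, 2-D
  Gaussian receptive-field fits with the equal-area 1.5-σ diameter, and the
  retinal dorsal–ventral midline from UV-selective cell positions.
* **Natural scenes** — linear vs per-channel-rectified Off models on
  two-channel (UV, green) contrast images, synthetic skyline scenes, and
  per-column logistic transition analysis.

## A worked example

```r
library(chromint)

set <- chromatic_integration_set()       # 22 combinations, 11 per set
cell <- model_cell("nonlinear-On", baseline_rate = 10, cell_id = "demo")
raster <- simulate_step_responses(cell, set, n_trials = 50, seed = 1)
chromatic_cell_summary(raster, set)
#>   cell_id    nli uv_green on_off polarity_bias relative_uv_sensitivity
#> 1    demo -0.337        0  0.888           8.6                   0.374
#>   crossing_exists max_abs_response polarity linearity special
#> 1            TRUE             25.2       On nonlinear    none

find_crossing(integration_curves(raster, set))
#> Crossing in bracket [7, 8], lower-bound activity -8.50 Hz
#>   interpolated contrasts: green 0.075, UV 0.125
```

The simulated nonlinear On cell is recovered as such: its curves cross
where green ≈ 7.5% opposes UV ≈ −12.5%, and the response there sits 8.5 Hz
*below* baseline — suppression at the balance point — giving a chromatic
nonlinearity index of −0.34 (nonlinear, negative sign) alongside an On
polarity (On–Off index 0.89).

A full population run — simulate 200 cells, classify each, fit the
midline, and evaluate the scene models — is one call:

```r
out <- run_pipeline(default_run_config(seed = 1), out_dir = "run1")
out$agreement
#> [1] 0.99                  # recovered labels vs simulated archetypes
out$scene$mean_difference_in_band
#> [1] 0.0614                # nonlinear - linear response, opposing-contrast band
#> (mean difference outside the band: 1.7e-05)
```

`run1/` then holds `classification.csv`, `midline.json`,
`scene_summary.json` and a `manifest.json` with the seeds and config hash;
identical configurations give byte-identical tables.

## Documentation

The methods vignette
(`vignettes/chromatic-integration-methods.Rmd`) documents the response
model, every index definition and threshold, the crossing-rule conventions,
the simulator's assumptions and limitations, and the numerical choices.
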