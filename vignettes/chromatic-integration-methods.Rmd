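---
title: "Chromatic integration in retinal ganglion cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatic integration in retinal ganglion cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromint)
```

## The scientific question

Mouse photoreceptors split light into a UV-sensitive channel (S-opsin,
dominant in the ventral retina) and a green-sensitive channel (M-opsin and
rods). Every retinal ganglion cell pools these two chromatic inputs, and the
pooling can be *linear* — opposite-sign UV and green contrasts of matched
strength cancel, leaving no response — or *nonlinear* — opposing contrasts
fail to cancel, producing either extra spikes or active suppression at the
balance point. `chromint` implements the complete desk-scale workflow for
this question: the dichromatic stimulus ensembles, a phenomenological
spiking simulator that produces the response patterns seen in recordings,
the full set of response indices and classifications, receptive-field and
retina-geometry estimation, and a pair of image-computable models that ask
what nonlinear chromatic integration is good for in natural scenes.

## Opsin-isolating stimuli

Because UV and green primaries each co-activate both opsin classes, stimulus
contrasts are specified at the *opsin* level and converted to source
contrasts by silent substitution: with the 2x2 contrast-form transfer matrix
$A$ (rows = S, M opsins; columns = UV, green sources), the source contrasts
for an opsin-contrast target $c$ are $A^{-1} c$. Rods are treated as sharing
the M row, so an M-isolating stimulus co-activates rods at approximately the
target contrast while an S-isolating stimulus silences both. The matrix may
also be supplied in absolute form (isomerisations per unit source intensity)
together with the two background intensities; it is then normalised
internally, and contrast form is canonical. A determinant below a configured
tolerance raises a calibration error; source contrasts outside $[-1, 1]$
trigger an out-of-gamut warning but are returned unclipped so the caller can
decide.

## The chromatic-integration stimulus and its curves

The core stimulus is a ladder of 22 UV/green Weber-contrast combinations in
two sets: green-On-UV-Off runs from (green $+20\%$, UV $0$) to (green $0$,
UV $-20\%$) in 2% steps, and green-Off-UV-On contains the exact contrast
negations. Steps last 500 ms, separated by 2 s of background (the
experimental protocols used 1.5 or 2 s; the longer gap is the default).
Presentation order is a Fisher-Yates shuffle of all repeats, reproducible
from a seed.

Responses are summarised per combination as the baseline-subtracted rate
$R$: the mean rate 50–250 ms after onset minus the rate in the 200 ms before
onset. Baselines are pooled over the trial window rather than estimated per
trial — with matched 200-ms windows the two estimators have the same
expectation and the pooled version is less noisy for low-rate cells. The 22
values are aligned as two 11-point curves so that each combination faces its
negation; dispersion is the across-trial SEM with an $n-1$ denominator.

### The crossing point and its conservative lower bound

The balance point is the crossing of the two curves: a bracket of
neighbouring indices where one curve is strictly higher on one side and
lower *or equal* on the other (curves that touch therefore count as
crossing). Assuming only that both curves run monotonically inside the
bracket, the response magnitude at the crossing is bounded below by:
per curve, the bracketing value closer to zero (zero if that curve's two
values straddle zero); then the farther-from-zero of the two curves'
values, keeping its sign. Equivalently, it is the signed distance from zero
to the intersection of the two curves' value intervals — the package's
tests exploit this equivalence as an independent brute-force oracle.

When several brackets qualify, the one whose lower bound is closest to zero
is used; exact ties (typically several zero-bound brackets in noisy linear
cells) are broken by proximity to the ladder midpoint and then by the lower
index. The tie situation is genuinely ambiguous — no tie-break can commute
with relabelling the channels — so the convention is fixed and documented
rather than hidden.

The **chromatic nonlinearity index** divides the signed lower bound by the
maximum response over all 22 stimuli. The maximum is taken over *absolute*
values by default, so that strongly suppressive responses also provide the
scale; `normalizer = "signed"` switches to the maximum signed response.
Cells with $|$index$| \ge 0.1$ are nonlinear: positive values mean extra
spikes at balance (the nonlinear Off / On-Off pattern), negative values mean
suppression below baseline (the nonlinear On pattern). Cells whose curves
never cross have no index and are UV-selective or colour-opponent instead.

### The remaining step-stimulus indices

* **UV-green index** $(f_\mathrm{green} - f_\mathrm{UV}) /
  (f_\mathrm{green} + f_\mathrm{UV})$, from peak PSTH rates (10-ms bins,
  50–250 ms window, maximum over contrast signs) under the four pure-colour
  stimuli. Below $-0.7$ the cell is UV-selective.
* **On-Off index** $(R_\mathrm{On} - R_\mathrm{Off}) / (|R_\mathrm{On}| +
  |R_\mathrm{Off}|)$ for the stronger pure colour; beyond $\pm 0.6$ the cell
  is On or Off, between it is On-Off.
* **Balance-point polarity bias**: the slope of the green-Off-UV-On curve
  across the crossing bracket minus the slope of the green-On-UV-Off curve.
  Negative values mean the balance-point response is Off-driven.
* **Relative UV sensitivity** $1 - C_\mathrm{UV} / (C_\mathrm{UV} +
  C_\mathrm{green})$ from the absolute contrasts at the linearly
  interpolated curve intersection. Along the ladder the two absolute
  contrasts sum to the maximal contrast, so the value is also the green
  contrast fraction at balance; it is computed whenever the interpolated
  intersection stays within the ladder, including end brackets.

Classification is a fixed decision tree: UV-selective (UV-green index below
threshold) takes precedence; otherwise absence of a crossing marks
colour-opponency; otherwise polarity follows the On-Off index and linearity
the nonlinearity index, with the index sign recorded.

## The local-spot stimulus

To test whether the nonlinearity needs the receptive-field surround, the
same 22 combinations are shown in 160-µm spots on a 44 x 24 vertex grid
(160 µm pitch). Each 500-ms frame selects locations by random sequential
adsorption: pick a uniformly random vertex not yet inside any selected
vertex's 5 x 5 exclusion square (±2 vertices each way, clipped at borders),
select it, repeat until every vertex is covered — which is exactly when no
eligible vertex remains, since eligibility and coverage are the same
condition. Selected spots get independent uniform contrast draws. On the
full grid this saturates at 80–90 spots per frame, re-selects each location
about every 6.4 s, and yields about 600 selections per location over a
65-minute run; `simulate_spot_run()` reproduces these statistics and
`scripts/acceptance.R` recomputes them from scratch.

The grid description in the source protocol mentions both a 320-µm avoidance
distance per direction and the 5 x 5 square; these are the same rule (two
vertices of 160 µm each way), and the operational square rule is what the
package implements. Per-cell analysis selects the vertex maximising the
summed absolute pure-colour responses and excludes cells whose selected
vertex lies farther from the white-noise receptive-field centre than the
receptive-field radius.

## Gratings, harmonics and selectivity

Chromatic drifting gratings put the two colours in exact spatial anti-phase
(480 µm period, 1 s temporal period) with per-channel amplitudes from the
same ladder; reversing gratings use spatial periods 32–448 µm plus full
field with 1/2/2/4/4/1 phases and 30 one-second reversals at full contrast.
Response PSTHs are folded over one temporal period (first period after each
condition switch excluded) and Fourier amplitudes are reported in the
single-sided sinusoid convention: $r(t) = m + a\sin(2\pi f t)$ has $F_1 = a$
exactly at the DFT bin, which is exact because the PSTH spans an integer
number of periods. The **grating nonlinearity index** is $F_2/F_1$ at the
combination with the smallest $F_1$ (nearest the balance point; ties go to
the lower stimulus index), with cells never exceeding 5 Hz excluded as
unreliable. The **spatial nonlinearity index** is the maximum $F_2$ over
all reversing conditions divided by the maximum $F_1$, maxima taken
independently; values above 1 indicate frequency doubling.

Direction and orientation selectivity use the normalised vector sum over
eight equidistant directions (angle doubled for orientation). Significance
comes from shuffling the per-repetition counts across all angles and
repetitions 1000 times; the percentile of the observed index is converted
to a p-value with add-one smoothing, $p = (k+1)/(n+1)$, which avoids $p=0$
and makes the test slightly conservative. A cell is DS when index $> 0.3$,
$p < 0.05$ and its mean rate is at least 1 Hz; OS analogously among non-DS
cells.

## Receptive fields and the dorsal-ventral midline

Receptive fields come from binary checkerboard white noise: the
spike-triggered average over 20 frame lags (ensemble mean subtracted) is
separated into space and time by singular value decomposition, signed so the
dominant spatial lobe is positive (an Off cell's temporal profile then peaks
negative). The spatial component is fitted with an elliptical 2-D Gaussian
by Levenberg-Marquardt least squares, initialised from the map's thresholded
centroid and second moments; non-convergent fits fall back to the moment
estimate and are flagged. The receptive-field diameter is the diameter of
the circle with the same area as the 1.5-σ contour, $3\sqrt{\sigma_x
\sigma_y}$.

The retina's dorsal-ventral axis is estimated from the UV-selective cells:
the midline passes through the centre of mass of *all* receptive-field
centres, and its angle maximises the ratio of the mean signed distance of
the UV-selective cells to the standard deviation of those distances, by
grid search in 0.5° steps over half a turn. The normal is then signed so
UV-selective cells lie at negative (ventral) distances. The objective is
evaluated on the UV-selective cells only, which matches the rationale of
orienting by where those cells concentrate; `objective_cells = "all"`
switches to all centres. Retinas with fewer than 3 UV-selective cells are
excluded. With the default simulated populations (roughly 40 UV-selective
cells spread through the ventral half of a 3 x 3 mm patch) the recovered
angle is typically within a few degrees of the generating axis.

## The simulator: what it emulates and what it does not

Model cells are linear-nonlinear Poisson units with archetype-specific
combination rules on the two opsin contrasts (weights jittered around 1,
gain in Hz per unit drive, baseline rate, Gaussian receptive field on a
virtual retina):

* linear On / Off: half-wave rectified signed sum; linear On-Off: the sum of
  both rectifications with an Off/On asymmetry ratio (default 0.7), because
  exactly symmetric lobes would make the two curves coincide and leave the
  crossing undefined;
* nonlinear Off: per-channel rectification before summation, so opposing
  contrasts fail to cancel;
* nonlinear On: rectified sum minus a suppression term proportional to the
  overlap of opposing-sign contrasts (gain 2 by default), making the net
  drive negative at balance — the depth of suppression is not constrained
  by published measurements and is exposed as a parameter;
* nonlinear On-Off: rectified Off terms plus a scaled linear On term
  (default 0.6, Off-dominated, giving the negative polarity biases);
* UV-selective: green weight 0; colour-opponent: opposite-signed weights
  without rectification, so one curve always lies above the other.

The opposing-contrast nonlinearity is gated by a `surround_active` flag:
under full-field stimulation it is on, under local-spot stimulation it is
off and the same cell integrates linearly. This encodes the experimental
observation that restricting the stimulus to the receptive-field centre
linearises chromatic integration; the package makes no claim about the
circuit mechanism. Spike trains are inhomogeneous Poisson with the evoked
drive confined to the 50–250 ms transient window (an optional sustained
tail is off by default) and rates floored at zero after summation.
Populations place cells uniformly on a rectangle with a logistic
dorsal-ventral gradient (slope 4 per mm by default) enriching UV-selective
and nonlinear archetypes ventrally.

Simulated grating responses are rectified sinusoids of the drive with a
Gaussian modulation-transfer attenuation at the grating's spatial
frequency; spatially nonlinear cells add a full-wave-rectified subunit
component (weight 1.5) for periods finer than the receptive-field diameter.

What passing tests on these cells shows is that the *analysis* recovers the
generating structure under realistic spike-count noise — archetype
classification agrees with ground truth on at least 95% of a 200-cell
population at 50 trials per combination, and every simulated nonlinear On
cell gets a negative index while every nonlinear Off/On-Off cell gets a
positive one. It does not validate the simulator against biology: the cells
have no adaptation, no correlated variability, no sustained-transient
diversity beyond one parameter, and Poisson spiking understates the
regularity of real retinal spike trains.

## Natural-scene models

Two image-computable Off-type models share a circular Gaussian receptive
field (25-pixel σ, truncated at ±3σ, unit sum) applied independently to the
UV and green Weber-contrast maps of a scene (each channel normalised by its
own mean, modelling independent adaptation). The linear model sums the two
filtered signals and half-wave rectifies; the nonlinear model rectifies each
channel before the sum. "Off-type" is implemented as sign inversion of the
filtered contrast before rectification. Algebraically the nonlinear response
is never below the linear one, with equality exactly where the two filtered
signals share a sign — both facts are enforced as tests. Models are
evaluated on randomly sampled patch locations without repetition; locations
whose kernel support leaves the image are flagged invalid rather than
silently dropped.

The synthetic skyline generator produces the scene structure that matters
for this comparison: a bright sky over a dimmer foreground with the UV
transition above the green one (logistic vertical profiles, default rows
120 and 150 of a 300 x 550 image, multiplicative log-normal noise, mild
horizontal texture). The rows between the two transitions carry opposing
channel contrasts, which is exactly where the two models disagree. Per
image column, a 4-parameter logistic (floor, amplitude, midpoint, width) is
fitted to each channel's contrast profile — four parameters rather than
fewer because the two asymptote levels are not known a priori — initialised
from the column's range and half-range crossing; columns whose fit fails or
whose midpoint leaves the image are excluded. The median UV-green midpoint
difference recovers the generator's transition offset to within a pixel or
two at low noise, degrading gracefully as noise grows.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and restores the caller's
RNG state; `run_pipeline()` derives per-stage seeds from one top-level seed
and records them in its manifest, so identical configurations produce
byte-identical result tables. The shipped test suite uses problem sizes
chosen to give stable statistics at interactive runtimes: 10,000 random
curve pairs for the crossing-rule oracle, a 200-cell population at 50
trials for end-to-end recovery, 7,800 spot frames for the re-selection
statistics, 500 null replicates for permutation-test calibration, and a few
thousand sampled patches per scene.

## Known limitations

* The simulator is phenomenological; its suppression and surround-gating
  terms are calibrated to reproduce observed response *patterns*, not
  fitted to data.
* The crossing tie-break convention is one of several defensible readings
  of "closest to zero"; alternatives change indices only for cells with
  multiple equal-bound crossings, which are overwhelmingly noisy linear
  cells.
* Harmonic amplitudes are read at exact DFT bins, which assumes the PSTH
  covers an integer number of periods; no interpolation between bins is
  attempted.
* The conversion between receptive-field size in pixels and degrees of
  visual angle for the scene models is deliberately omitted: the underlying
  viewing-geometry assumptions are not reproducible from published numbers
  under any obvious convention.
* Scene input/output is deliberately minimal (matrices in R; import from
  raster files is left to the caller), and no real two-channel image data
  ship with the package.

## A worked example

```{r example, eval = FALSE}
set <- chromatic_integration_set()
cell <- model_cell("nonlinear-On", baseline_rate = 10, cell_id = "demo")
raster <- simulate_step_responses(cell, set, n_trials = 50, seed = 1)
chromatic_cell_summary(raster, set)

out <- run_pipeline(default_run_config(seed = 1), out_dir = "run1")
out$agreement
```
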