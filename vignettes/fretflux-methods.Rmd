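---
title: "Methods: from FRET biosensor movies to metabolic flux readouts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from FRET biosensor movies to metabolic flux readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretflux)
```

## The measurement problem

Genetically encoded FRET biosensors report intracellular analyte
concentrations as a fluorescence ratio between two emission channels.
Lactate sensors of the Laconic type lose FRET efficiency when lactate
binds, so the donor/acceptor (mTFP/Venus) ratio *rises* with lactate;
glucose sensors of the FLII type gain FRET efficiency with glucose, and
their acceptor-over-donor ratio likewise rises with analyte. fretflux
standardizes on ratios that increase with analyte for both families.

A ratio by itself is not a flux. The pipeline therefore implements the
transport-manipulation logic used in two-photon imaging of acute retinal
tissue:

* **Trans-acceleration (20 mM oxamate).** Oxamate is a non-metabolized
  monocarboxylate transporter (MCT) substrate. Saturating the outward-facing
  carrier site accelerates the exchange cycle and exports intracellular
  lactate, driving the sensor toward its zero-lactate level. Anchoring the
  trace to this floor turns the pre-intervention plateau into a *basal
  lactate* readout.
* **MCT block (5 µM AR-C155858).** With MCT1/2 export blocked, lactate
  accumulates at the net production rate: the initial post-block slope is a
  *lactate production* proxy and the late plateau an *accumulation
  amplitude*. AR-C155858 does not inhibit MCT4; any MCT4 component lets
  lactate escape and biases the slope downward (see the bias properties
  below).
* **Glucose transport block (20 µM cytochalasin B).** With GLUT import
  blocked, intracellular glucose decays at the hexokinase rate: the
  magnitude of the initial negative slope is a *glucose consumption*
  proxy. A terminal aglycemia step provides the zero-glucose anchor for
  *basal glucose*.
* **Aglycemia (0 mM glucose).** Used both as a protocol of its own and as
  the independent confirmation that oxamate really empties the lactate
  pool: both must converge to the same sensor floor.

## The forward model

The simulator exists so that every stage of the analysis can be tested
against known ground truth; no imaging data ship with the package. It is a
minimal two-state carrier model per cell, with state `glc_in` and `lac_in`
(mM):

$$\frac{d\,\mathrm{glc}}{dt} = V_g\!\left[\frac{G_o}{K_g+G_o} -
  \frac{\mathrm{glc}}{K_g+\mathrm{glc}}\right](1-b_{cytB}) - J_{hk},
\qquad J_{hk} = \frac{V_h\,\mathrm{glc}}{K_h+\mathrm{glc}}$$

$$\frac{d\,\mathrm{lac}}{dt} = \phi\, J_{hk} - J_{mct}, \qquad
J_{mct} = V_m^{\mathrm{eff}}\!\left[\frac{\mathrm{lac}}{K_m+\mathrm{lac}} -
  \frac{L_o}{K_m(1+ox/K_{ox})+L_o}\right]$$

with $V_m^{\mathrm{eff}} = V_m\,(1 + g_{ta}\,ox/(K_{ox}+ox))$ under
oxamate and $V_m^{\mathrm{eff}} \times f_{mct4}$ under AR-C155858. Bath
switches are instantaneous steps (the perfusion system exchanges the
chamber in well under the analysis windows; a first-order exchange lag is
available but defaults to off). $\phi \in [0,2]$ is the number of lactate
molecules produced per glucose consumed and encodes the glycolytic versus
oxidative fate of pyruvate — it is the parameter the knockout scenarios
manipulate.

Defaults (all configurable through `kinetic_params()`): $V_h$ = 0.01 mM/s,
$K_h$ = 0.05 mM, $V_g$ = 0.05 mM/s, $K_g$ = 3 mM, $\phi$ = 1.2, $V_m$ =
0.08 mM/s, $K_m$ = 3 mM, $g_{ta}$ = 50, $K_{ox}$ = 2 mM, $f_{mct4}$ = 0,
bath glucose 6 mM, bath lactate 0. These give a basal steady state of
about 2.66 mM glucose and 0.52 mM lactate and a basal hexokinase flux of
about 0.01 mM/s — a strongly glycolytic cell, consistent with
photoreceptors being net lactate producers. Two of these values deserve
comment:

* $g_{ta}$ = 50 is deliberately large. The experimental observation the
  simulator must reproduce is that oxamate depletes intracellular lactate
  to essentially the same sensor level as aglycemia. In the carrier model
  the oxamate floor is $\phi J_{hk} K_m/(V_m^{\mathrm{eff}}-\phi J_{hk})$,
  so only a strong trans-acceleration gain pushes that floor near zero.
  With the defaults the two endpoints differ by about 2% of the basal
  delta-ratio.
* The lactate sensor default `kd` is 8 mM (`laconic_sensor()`), reflecting
  the low affinity of Laconic-type sensors. This matters scientifically:
  delta-ratio amplitudes and slopes are concentration-proportional only in
  the quasi-linear sensor range. A high-affinity sensor (kd near 1 mM)
  saturates over the simulated excursions (0.5 to 8 mM) and would compress
  — for amplitudes even invert — group differences. The glucose sensor
  default stays at kd = 0.6 mM, realistic for FLII-type sensors; its fit
  windows are short enough that local linearization holds.

The solver is `deSolve::lsoda` (rtol 1e-8, atol 1e-9 mM), integrated
segment by segment so that bath-switch kinks coincide with segment
boundaries, with fluxes clamped so that no pool is drained below zero.

## Rendering and the cohort hierarchy

`render_movie()` turns a concentration series into a two-channel stack:
elliptical cells on a uniform background, denominator channel carrying the
cell's intensity scale, numerator carrying intensity times ratio. Poisson
shot noise on expected counts, Gaussian read noise, per-channel
exponential bleaching (the ratio cancels common-mode bleaching only when
the two rates match) and an integer-pixel random-walk xy drift are applied
after signal synthesis; every random element is seeded, and the true drift
path is recorded in the stack metadata so registration can be tested
against truth.

`generate_cohort()` reproduces the "N slices from N mice" design:
independent lognormal multipliers (unit mean) on the three Vmax parameters
at the mouse level (CV 0.05) and slice level (CV 0.15), mosaic knockout at
the cell level as a Bernoulli draw per cell. The CV split puts most
variability at the slice level, where slice preparation dominates in
practice; it also keeps slice-level rank tests close to nominal size
despite slices sharing a mouse (within-mouse correlation is small relative
to between-slice scatter). Trace-mode cohorts add Gaussian noise of SD
0.005 ratio units directly to the ratio — the scale of masked-mean shot
noise for a few thousand foreground pixels at roughly 100 counts.

What the generator does *not* emulate: z-drift and focus loss, perfusion
lag, pH effects on MCT transport, phototransduction-driven metabolic
transients, sensor expression gradients, autofluorescence. Passing tests
therefore demonstrate the correctness of the analysis chain under
controlled conditions, not robustness to every artifact of real tissue.

## The image pipeline

1. **Registration.** Per-frame integer offsets maximize the FFT
   cross-correlation of the zero-mean channel-sum image against a
   reference frame (first frame by default). Both channels are shifted by
   the same offset; exposed pixels are filled with the frame median and
   marked invalid so they never enter masked statistics. Subpixel
   registration is deliberately omitted: the ratio of channel means is
   insensitive to common sub-pixel shifts, and integer recovery is exact
   on integer-rendered drift.
2. **Masking.** Li's minimum cross-entropy threshold, computed once on the
   time-averaged channel-sum image; the static mask is applied to all
   frames, avoiding frame-to-frame mask jitter in the trace. The Li
   iteration `t' = (mu_b - mu_f)/(ln mu_b - ln mu_f)` needs positive
   means, so images with nonpositive minima are shifted by `1 - min` and
   the threshold shifted back. Convergence is declared at 0.5 intensity
   units, after which the partition is stable and the fixed point is exact.
3. **Extraction.** The frame ratio is the ratio of masked channel means
   (not the mean of pixel ratios, which amplifies noise in dim pixels),
   excluding invalid fill pixels and zero-denominator pixels. The trace is
   then smoothed with a centered moving average — 11 frames for lactate,
   5 for glucose traces — whose window shrinks symmetrically at the edges
   so no values are invented. Smoothing is applied to the assembled ratio
   trace rather than per pixel; for the linear operations involved the
   order only matters in the presence of masking artifacts.

## Readout estimation

Traces are anchored subtractively: `end_zero` subtracts the mean over the
final 30 s (the depleted/aglycemic floor), `baseline` the mean over the
60 s before the first intervention. Subtractive anchoring preserves the
linear map between delta-ratio and concentration in the quasi-linear
range; a divisive dR/R0 variant exists for comparison with other software.
The windows (60 s baseline, 30 s anchor, 10 s post-onset delay, 60 s slope
fit, 60 s plateau) are package choices, configurable in
`analysis_config()` — the delay absorbs perfusion dead time, and a 60 s
fit is long enough for a stable OLS line at ordinary frame rates yet short
enough that curvature from carrier saturation stays below the estimation
tolerance.

* basal = mean delta-ratio over the baseline window (end-zero anchored),
  with an `unstable_baseline` flag when the within-window linear drift
  exceeds 0.01 ratio/min;
* amplitude = mean delta-ratio over the terminal plateau window
  (baseline anchored), with a `saturation` flag above 95% of the sensor
  range;
* slope = OLS slope over the fit window in delta-ratio per minute, with
  r² and a `low_r2` flag below 0.5. Consumption protocols give negative
  slopes; the consumption rate is the magnitude.

Flagged traces are excluded from group statistics by default but always
written with their flags visible. Optional conversion to mM applies the
exact algebraic sensor inverse to basal/amplitude and divides slopes by
the local sensor gain at the fit-window midpoint.

## Group statistics

Slice-level readouts are compared with the Mann-Whitney test (exact
enumeration when both groups have n ≤ 8 and no ties, otherwise the normal
approximation with tie and continuity corrections) for two groups, and
the tie-corrected Kruskal-Wallis test for three or more. Many-to-one post
hoc comparisons are Dunn-style z statistics on the pooled ranks with
Bonferroni adjustment — a deliberately rank-based choice for internal
consistency with the omnibus test, even though figure legends in this
field often name the parametric Dunnett procedure after a Kruskal-Wallis
test; the parametric Dunnett path is available via `posthoc = "dunnett"`
(multcomp). The slice is the observational unit, matching how such data
are reported; a per-mouse-median mode exists because slices within a
mouse are not independent.

## Numerical and design notes

* Tie-breaking in registration prefers the smallest Euclidean offset,
  then row-major order, making results deterministic on symmetric inputs.
* Constant images are rejected by both registration ("no structure") and
  thresholding ("threshold undefined") rather than silently defaulting.
* All stochastic steps (rendering, cohorts, drift) run under derived
  seeds; rerunning any generator with the same seed is bit-identical.
* Every driver output embeds an MD5 hash of the configuration;
  `run_compare()` refuses tables whose hash differs from the active
  config.
* Monte-Carlo cohort checks in the test suite and acceptance script run
  the simulator on a 2–4 s output grid rather than the 5.94 Hz
  acquisition grid; the readouts are 60 s window means and OLS slopes,
  which are insensitive to grid density, and this keeps hundreds of
  replicate cohorts cheap.

## Known limitations

* The carrier model lumps all MCT isoforms into one Vmax with an
  AR-C-insensitive fraction; it does not model pH coupling or
  pentose-phosphate branching.
* Whole-frame analysis only: no single-cell segmentation, no z motion.
* The Li threshold assumes a foreground/background intensity mixture; on
  pathological unimodal images the iteration still converges but the mask
  is not meaningful (the mask-fraction diagnostic exposes this).
* The type-I-error calibration of slice-level tests holds for the
  default variance split; cohorts with dominant mouse-level variance
  should use the mouse-aggregated mode.
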