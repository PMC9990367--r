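# fretflux

Turns two-photon, two-channel FRET biosensor movies of retinal tissue into
cellular metabolic readouts, and compares them across animal groups. The
sensors are ratiometric: Laconic-type lactate sensors report rising
intracellular lactate as a rising donor/acceptor (mTFP/Venus) ratio, and
FLII-type glucose sensors report rising glucose as a rising FRET ratio.
Fluxes are obtained pharmacologically:

| protocol | drug | readout |
|---|---|---|
| `trans_acceleration` | 20 mM oxamate | basal lactate (end-zero anchored ΔR) |
| `mct_block` | 5 µM AR-C155858 | lactate production rate (ΔR/min) and accumulation amplitude |
| `glut_block_then_aglycemia` | 20 µM cytochalasin B, then 0 mM glucose | glucose consumption rate and basal glucose |
| `aglycemia_only` | 0 mM glucose | zero-analyte anchor / basal lactate |

Under MCT block, `d[lac]/dt = φ·J_hk`, so the initial post-block slope of
the sensor trace is (sensor gain) × (net lactate production); under GLUT
block, `d[glc]/dt = −J_hk`, so the initial decay slope reports hexokinase
flux. The image pipeline follows the field's conventions: FFT
cross-correlation drift registration, Li minimum cross-entropy tissue
masking on the time-averaged image, masked ratio-of-means extraction,
centered temporal smoothing (11 frames for lactate, 5 for glucose traces,
5.94 Hz acquisition default). Group comparisons are nonparametric:
Mann-Whitney for two groups, tie-corrected Kruskal-Wallis with Dunn-style
many-to-one post hoc tests (Bonferroni) for three, with a parametric
Dunnett alternative.

Because no raw imaging data are publicly available for this preparation,
the package ships a seeded forward simulator (carrier-kinetics ODE →
sensor binding → noisy, drifting two-channel movies → hierarchical
mouse/slice cohorts with mosaic knockout) so that every pipeline stage is
testable against ground truth. See the methods vignette
(`vignettes/fretflux-methods.Rmd`) for the model and all design choices.

## Worked example

Simulate a two-genotype lactate-production experiment and run the full
chain:

```r
library(fretflux)

cfg <- load_config(list(
  seed = 11, log_level = "error",
  sensor = list(type = "laconic"),
  protocol = list(name = "mct_block"),
  pipeline = list(frame_rate = 1),            # coarse grid for the demo
  cohort = list(groups = list(
    list(name = "ctrl", n_mice = 5, slices_per_mouse = 2),
    list(name = "ko", n_mice = 5, slices_per_mouse = 2,
         param_overrides = list(lac_prod_frac = 1.8)))),
  scene = list(shape = c(48L, 48L), n_cells = 6L, intensity = 200),
  noise = list(shot = TRUE, read_sd = 0.5, drift_sd = 0.2),
  paths = list(outdir = tempfile("fretflux_demo"))))

cmp <- run_all(cfg)   # ~40 s: renders, registers, masks, extracts, compares
subset(cmp$summary, readout == "slope")
#>   readout group  n n_mice n_excluded     median       mean          sd
#> 3   slope  ctrl 10      5          0 0.02184211 0.02204481 0.002729482
#> 4   slope    ko 10      5          0 0.03000960 0.03016977 0.004491646
subset(cmp$comparisons, readout == "slope")
#>   readout group_a group_b         method statistic           p adjusted_p stars
#> 2   slope    ctrl      ko mann_whitney_u         7 0.001314945         NA    **
#>                                             note
#> 2 normal approximation, tie/continuity corrected
```

The knockout group produces lactate 1.5× faster; because the low-affinity
sensor compresses high concentrations slightly, the pipeline recovers a
~1.4× higher median slope (0.030 vs 0.022 Δratio/min), and the
Mann-Whitney test rejects at p ≈ 0.0013. One stack can also be handled
piecewise: `read_movie_tiff()` → `register_stack()` → `build_mask()` →
`extract_ratio_trace()` → `analyze_trace()`.

A command-line wrapper with `simulate` / `process` / `compare` / `run-all`
subcommands lives at `inst/cli/fretflux.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/fretflux.R", package="fretflux"))')" \
    run-all --config my_run.yaml --seed 7
```

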