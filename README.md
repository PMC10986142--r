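# glut4layers

Layer-resolved quantification of GLUT4 localization in single muscle-fibre
confocal images, with a synthetic ground-truth generator and
repeated-measures mixed-model statistics.

## The problem

GLUT4 is the insulin-responsive glucose transporter of skeletal muscle: how
much of it sits at or near the plasma membrane (PM), and in what kind of
cluster, proxies the muscle's capacity for insulin-stimulated glucose
uptake. A standard immunofluorescence assay images one fibre cross-section
per field in three channels — dystrophin (PM marker), GLUT4, and MHC1
(slow myosin, marking type I fibres) — and asks, per fibre:

- how strongly GLUT4 colocalizes with the membrane (pixel-wise Pearson
  coefficient between the GLUT4 and dystrophin channels),
- how its fluorescence and its detected puncta distribute over the PM band
  and the five concentric 1 µm layers beneath it, and
- how counts of *small* (< 1 µm equivalent diameter, mobile
  vesicular/endosomal pools) versus *large* (> 1 µm, trans-Golgi-associated
  clusters) spots shift across biopsy timepoints, training status,
  infusion arms and fibre types.

`glut4layers` implements that pipeline end to end, and — because real
biopsy images ship with no ground truth — a phantom generator that renders
fibres with known contours, planted spots and planted effect sizes, so
every stage is validated by parameter recovery.

## Method at its core

1. **Membrane segmentation.** The dystrophin ridge is found with an active
   contour (snake): a closed curve `v` minimising
   `∫ α|v'|² + β|v''| ² − κ (G_σ * I)(v) ds`, evolved semi-implicitly and
   declared converged when the mean vertex displacement per iteration drops
   below 0.02 px. The curve settles on the intensity maximum across the
   ring — the membrane midline.
2. **Layers.** A signed Euclidean distance map `d` to the contour (exact
   point-to-segment, positive inside) defines the PM band `|d| ≤ 1.5 px`
   (3 px thick) and layers `L_k: d ∈ (1.5 + (k−1)w, 1.5 + kw]` px with
   `w = 1 µm` in pixels, `k = 1..5`.
3. **Spot detection.** One Otsu threshold per participant — the maximiser
   of the between-class variance `ω₀ω₁(μ₀−μ₁)²` of the pooled in-fibre
   histogram of all that participant's images — then 8-connected
   components, area-equivalent diameter `2√(area/π)`, small/large split at
   1 µm, layer assignment by centroid.
4. **Colocalization.** Pearson's r between GLUT4 and dystrophin over the
   fibre (the PM-band-only alternative is a config switch).
5. **Statistics.** `lmer`-fitted linear mixed models with a subject random
   intercept (fibres are rows; biopsies at 0/2/6 h repeat within subject),
   Satterthwaite degrees of freedom, and Bonferroni-adjusted pairwise
   biopsy contrasts via `emmeans`.

## Worked example

```r
library(glut4layers)

spec  <- effect_spec()   # study conditions: PCC uplift 0->2 h, PM small-spot
                         # decline 2->6 h, 99%/95% PM small fractions, ...
study <- simulate_study(spec, n_subjects_per_cell = 1,
                        images_per_timepoint = 2, seed = 42)
run   <- run_pipeline(study$images, study$design, pipeline_config(seed = 42))
run
#> <glut4_run> 24 fibres measured (ok: 24)
run$measurements[1:4, c("image_id", "group", "timepoint_h", "fibre_type",
                        "small_PM", "pcc")]
#> 1 img00001 trained 0 I  35 ...
#> 2 img00002 trained 0 II 40 ...

# statistics at realistic study size (measurement-level generator)
m   <- simulate_measurements(spec, n_subjects_per_cell = 5,
                             fibres_per_timepoint = 30, seed = 42)
fit <- fit_mixed_model(m, "pcc", fixed = "timepoint")
posthoc_pairwise(fit, "timepoint")
#>   comparison               estimate adj.p.value significant
#> 1 timepoint0 - timepoint2  -0.0114  0.000281    TRUE
#> 2 timepoint0 - timepoint6  -0.0143  0.0000030   TRUE
#> 3 timepoint2 - timepoint6  -0.0029  0.962       FALSE

summarize_study(m)$small_fraction |> dplyr::filter(layer == "PM")
#>   group     layer small large small_fraction
#> 1 sedentary PM    22539  1245          0.948
#> 2 trained   PM    24127   263          0.989
```

The contrast table reproduces the expected qualitative pattern: membrane
colocalization rises from 0 to 2 h and stays elevated at 6 h (0v2 and 0v6
significant, 2v6 not), and the PM small-spot fractions sit near 99%
(trained) and 95% (sedentary). `tidy(fit)`, `glance(fit)`,
`plot_pcc_timecourse(m)` and `plot_spot_counts(m)` give coefficient
tables, variance components and figures.

A thin command-line wrapper is included:

```sh
Rscript inst/cli/glut4.R simulate --out simdir --seed 1 --subjects 2 --images 3
Rscript inst/cli/glut4.R run-all  --in simdir --out rundir --seed 1
Rscript inst/cli/glut4.R analyze  --measurements rundir/measurements.csv --out stats
```

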