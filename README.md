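# cestaptw

APTw CEST MRI z-spectrum processing in R, with synthetic phantoms that
carry analytic ground truth.

Amide proton transfer-weighted (APTw) imaging is a CEST MRI contrast:
a saturation pulse applied at the amide resonance (+3.5 ppm from water)
attenuates the water signal in proportion to amide proton content and
exchange, which makes the technique sensitive to protein-related changes
such as neuroinflammation in hippocampal tissue. The standard readout is
the magnetization transfer ratio asymmetry

```
APTw = MTRasym(3.5 ppm) = MTR(+3.5 ppm) − MTR(−3.5 ppm),   MTR = 1 − S_sat/S0
```

reported in percent. Healthy tissue is typically *negative* (the
−3.5 ppm NOE/MT background outweighs the amide pool); pathology shifts it
toward zero. Because the asymmetry subtracts two points of a steep line,
it is biased by per-voxel B0 field errors, so quantification is preceded
by a WASSR correction: a low-power acquisition densely samples the direct
water line (33 offsets, −0.8…+0.8 ppm), each voxel's spectrum is fitted
with a 12th-order polynomial and interpolated at 0.01 ppm, the fitted
minimum gives the water shift, and the APTw spectrum (25 offsets,
−6…+6 ppm) is spline-interpolated and re-centred before MTRasym is taken.

The package provides, for cohorts of synthetic subjects (no scanner data
required):

* `phantomSpec()` / `buildPhantom()` / `simulateCohort()` — multi-pool
  Lorentzian z-spectrum phantoms (APTw + WASSR acquisition pair, shared
  smooth B0 field, Gaussian noise, group-dependent amide depth) with
  analytic ground truth (`trueMtrAsym()`);
* `b0Map()` / `fitWassrVoxel()` — the WASSR B0 stage;
* `aptwMap()` / `mtrAsym()` / `meanMtrAsymCurve()` — the correction and
  quantification stage;
* `summarizeROI()` / `compareGroups()` — per-subject ROI means and the
  group battery (one-way ANOVA, Tukey HSD, Lilliefors normality,
  left/right laterality t-tests);
* `powerExperiment()` / `runPipeline()` — repeated-cohort calibration and
  power experiments, and the orchestrated end-to-end run;
* NIfTI + JSON-sidecar I/O (`readStack()`, `writeMap()`, `readMasks()`,
  `loadConfig()`) and a CLI front end (`inst/cli/cestaptw.R`) with
  `simulate`, `b0`, `aptw`, `stats`, `power`, `demo` and `run`
  subcommands.

## Worked example

Simulate a three-group cohort (CTRL and two endotoxemia-like groups,
n = 7 each, 16 × 16 grid), run the full chain, and compare groups:

```r
library(cestaptw)
cfg <- pipelineConfig(grid_shape = c(16L, 16L), seed = 3L)
res <- runPipeline(cfg)
res$comparison
#> One-way ANOVA: F = 72.781, p = 2.368e-09
#> Group means (%):
#>   CTRL  LPS05  LPS10
#> -1.922 -0.399 -0.406
#> Tukey HSD:
#>  group_a group_b         diff        p_adj significant
#>     CTRL   LPS05  1.523235842 1.272614e-08        TRUE
#>     CTRL   LPS10  1.516431131 1.364473e-08        TRUE
#>    LPS05   LPS10 -0.006804711 9.987943e-01       FALSE
```

The CTRL group sits near −1.9% (net-negative healthy tissue), both
LPS-like groups near −0.4%; the ANOVA and both CTRL contrasts are highly
significant while the two LPS-like groups — whose amide settings differ
only marginally — are statistically indistinguishable. Per-subject,
per-ROI means live in `res$summaries`:

```r
head(res$summaries, 3)
#>   subject_id group               roi mean_aptw_percent n_valid_voxels
#> 1    CTRL_01  CTRL  left_hippocampus         -1.941054             11
#> 2    CTRL_01  CTRL right_hippocampus         -2.257531             11
#> 3    CTRL_01  CTRL               avg         -2.099293             22
```

The same run from a shell:

```sh
Rscript inst/cli/cestaptw.R demo --outdir demo_out --seed 3
```

See `vignettes/aptw-pipeline.Rmd` for the forward model, the default
calibration and its rationale, and the numerical choices in each stage.

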