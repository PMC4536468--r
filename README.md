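# spindlemetry

Quantitative analytics for 3D mitotic-spindle imaging: where does the
metaphase plate sit inside the spindle, how do sister kinetochores move,
and does the cell divide symmetrically?

## The problem

In metazoan mitosis the chromosomes congress onto a metaphase plate in
the middle of the bipolar spindle. Cells with an unequal centriole
complement at the two poles (2:1 cells) assemble spindles with an
off-centre plate, and entering anaphase in that state misplaces the
cleavage furrow and produces daughter cells of unequal size. Measuring
this requires turning point detections from fluorescence time-lapse
imaging (centrioles, kinetochores, cortex points) into geometry and
kinetics:

* **Half-spindle ratio.** The plate plane is fitted to the kinetochore
  cloud by orthogonal least squares and intersected with the spindle
  axis (the line through the two pole centroids). With L1 the distance
  from the reference pole to the intersection and L2 from the other
  pole,

      R = L1 / L2,

  where the reference pole is the 2-centriole pole in 2:1 cells and the
  grandmother-centriole (brightest centrin) pole otherwise. R = 1 is a
  centred plate; a band of 0.85 < R < 1.15 is treated as centred in
  cohort summaries.

* **Kinetochore kinetics.** Sister pairs (mutual nearest neighbours
  within 2 um) yield inter-kinetochore distances, intra-kinetochore
  offsets delta = (d_outer - d_inner)/2 from two-colour snapshots, and
  axis-projected oscillation autocorrelations whose first minimum marks
  the half-period.

* **Phenotypes and cohorts.** Per-cell classifiers (anaphase onset,
  spindle rotation > 90 degrees in XY, daughter size ratio > 1.2,
  attachment-marker-negative cells, minus-end asymmetry) feed cohort
  summaries with anaphase-aligned median-R trajectories, bootstrap
  confidence bands and the standard test battery (Welch t,
  Mann-Whitney U, Levene, paired t, Fisher exact, exact binomial).

A synthetic spindle generator with complete ground truth (pole
geometry, true R over time, oscillation parameters, anaphase frame,
daughter sizes, marker labels) backs every stage of the pipeline with a
quantitative oracle. See the methods vignette
(`vignettes/spindle-geometry-methods.Rmd`) for the models, defaults and
design decisions.

## Worked example

Simulate a small cohort of 2:1 cells whose plates start off-centre
(true median R = 1.12) and relax towards the centre before anaphase,
then run the full analysis:

```r
library(spindlemetry)

cfg <- sim_config(n_cells = 8, config_label = "C21",
                  plate_offset_ratio_true = list(median = 1.12, sd_log = 0.04),
                  centering_tau_s = 240, anaphase_at_s = 262.5, seed = 42)
coh <- simulate_cohort(cfg)
coh$cells[[1]]
#> <cell_series> cell_001: 41 frames, dt = 7.5 s, config C21, group simulated
#>   annotated anaphase frame: 35
#>   detections: CENTRIOLE=123, CORTEX=82, KT_INNER=1886

an <- analyze_cohort(coh$cells)
head(an$per_cell[, c("metaphase_R", "anaphase_R", "anaphase_frame",
                     "half_period_s", "rotating")], 4)
#>   metaphase_R anaphase_R anaphase_frame half_period_s rotating
#> 1       1.097      1.077             35          37.5    FALSE
#> 2       1.108      1.026             35          37.5    FALSE
#> 3       1.115      1.025             35          37.5    FALSE
#> 4       1.030      1.003             35          37.5    FALSE

summarize_cohort(an$per_cell)
#> <cohort_summary>
#>   C21  n =   8  median R = 1.097  outside [0.85, 1.15]: 0.0%  above: 0.0%
```

Each cell starts with an elevated metaphase R (off-centre plate) and
reaches anaphase with R closer to 1 (the plate has centred); the 80-s
sister oscillations appear as an autocorrelation half-period of 37.5 s
on the 7.5-s sampling grid. Count statistics use the exact tests:

```r
count_tests(8L, "exact_binomial", n = 8L)
#> <test_result> exact_binomial: statistic = 8, p = 0.007812 (two.sided; n = 8)
#>    null p0 = 0.5
```

A thin command-line wrapper covers the same flow
(`inst/cli/spindlemetry.R` with `simulate`, `analyze` and `report`
subcommands; detection/metadata CSV in, metrics CSV and summary JSON
out).

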