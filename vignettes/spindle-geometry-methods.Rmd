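---
title: "Quantifying metaphase plate position, kinetochore kinetics and division symmetry"
author: "spindlemetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying metaphase plate position, kinetochore kinetics and division symmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlemetry)
```

## The measurement problem

In a bipolar mitotic spindle the congressed chromosomes form the
metaphase plate, normally in the middle of the pole-to-pole axis. Cells
with an unequal complement of centrioles at the two poles (2:1 cells)
build spindles whose plate sits off-centre, and if such a cell enters
anaphase before re-centring the plate, the cytokinetic furrow is
misplaced and the division is asymmetric. Quantifying this behaviour
from 3D fluorescence time-lapse imaging requires a chain of point-cloud
analytics:

* cluster centriole detections into two **spindle poles**;
* fit the **metaphase plate plane** to the kinetochore cloud;
* intersect the plane with the **spindle axis** and form the
  half-spindle lengths $L_1$ (reference pole to intersection) and $L_2$
  (other pole), whose ratio $R = L_1/L_2$ measures plate position;
* pair sister kinetochores, follow their **inter-kinetochore distance**
  (a centromere tension proxy), their **intra-kinetochore offset**
  $\delta = (d_\text{outer} - d_\text{inner})/2$ and their axis-projected
  oscillations;
* classify per-cell phenotypes (anaphase onset, spindle rotation,
  asymmetric division, attachment-immaturity by an outer-kinetochore
  marker, minus-end asymmetry) and aggregate cohorts with the standard
  test battery.

`spindlemetry` implements this chain on tabular 3D detections (one
labelled point with intensity per row), never on pixels: coordinates
arrive in micrometres with any voxel anisotropy already applied. The
package also ships a synthetic spindle generator with complete ground
truth, so that every stage can be validated quantitatively rather than
by eye.

## Conventions

Frames are 0-based; times are in seconds; all lengths in micrometres.
The detection schema is fixed
(`cell_id, frame, time_s, channel, x_um, y_um, z_um, intensity`) with
five channels: `CENTRIOLE`, `KT_INNER` (inner-kinetochore marker such as
CENPA), `KT_OUTER` (e.g. HEC1), `ATTACH_MARK` (an attachment-maturity
marker such as SKAP) and `CORTEX`.

The **reference pole** carries the numerator half-spindle $L_1$. In 2:1
cells it is the pole with two centrioles, overriding brightness; in 2:2,
1:1 and wild-type cells it is the pole containing the single brightest
centriole detection (the grandmother centriole, which carries the most
centrin marker). Intensity ties are an error rather than an arbitrary
choice: real centrin intensities are strictly ordered, and the simulator
encodes this as relative levels 4:3:2:2
(grandmother : mother : daughters).

## Geometry

**Pole clustering** is an exhaustive 2-group partition of the 2--4
centriole detections minimising total within-group pairwise distance
(at most 7 partitions). With poles roughly 10 um apart and centrioles
well under 1 um from their pole centroid, the optimal partition is
unambiguous; near-ties (within 1e-6) raise an error instead of guessing.

**The plate plane** is fitted by orthogonal (total) least squares: the
plane through the centroid whose normal is the smallest principal axis
of the centred kinetochore cloud. We chose total rather than coordinate
regression because localisation noise is 3D and the plate has no
privileged axis in the image frame. Collinear clouds (second principal
variance below 1e-12 of the leading one) are rejected.

**The spindle axis** is the line through the two pole *centroids*,
unweighted by intensity: centrioles within a pole are two orders of
magnitude closer together than the pole separation, so weighting is
immaterial, and an unweighted centroid is reproducible across channels.
The plate position is the plane--axis intersection solved parametrically;
the normal is oriented towards the reference pole, and intersections
outside the pole-to-pole segment (possible in late anaphase or
degenerate fits) are flagged but still reported with their $R$.

**Spindle centring in the cell** uses the midpoint of the poles as
spindle centre and the midpoint of the two axis--cortex intersection
points (nearest cortex point on each side, projected onto the axis) as
cell centre.

## Kinetochore kinetics

**Pairing** is mutual-nearest-neighbour with a 2.0-um gate, accepted
greedily by increasing distance. The gate is twice the 1.0-um
inter-kinetochore rest length; with plate neighbours at least ~1.5 um
apart laterally, sisters are always each other's nearest neighbour, so
the pairing recovers the true pairs (the test suite verifies 100%
recovery up to 0.1-um localisation noise). Distance ties resolve by
acceptance order, which is documented rather than hidden.

**Oscillations** are analysed as the signed projection of the pair
centre onto the spindle axis (origin at the spindle centre, positive
towards the reference pole). The autocorrelation estimator is
mean-subtracted and biased-normalised,
$\hat\rho_k = \sum_t \tilde x_t \tilde x_{t+k} / \sum_t \tilde x_t^2$:
dividing by $N$ rather than $N-k$ trades a small damping for
guaranteed $|\hat\rho_k|\le 1$ and stability at long lags. Gaps up to
20% of a series are tolerated (products containing a gap are dropped);
more is an error, not a silent extrapolation. Profiles are averaged
pointwise across the pairs of a cell first and across cells second, so
every cell carries equal weight regardless of its pair count.

The **half-period** is the lag of the first strict local minimum of the
averaged profile, provided the minimum is deeper than -0.1; shallower
dips are treated as noise and the scan continues. On a 7.5-s grid a
sinusoid of period $T$ yields a first minimum within one sampling
interval of $T/2$, which the tests check for $T \in \{40, 60, 80, 120\}$
s; 23 averaged white-noise series of 80 samples stay well inside the
no-call band.

## Phenotype rules

* **Anaphase onset**: first frame at which the median inter-kinetochore
  distance reaches 1.5x the baseline (median of the first three frames),
  sustained for two consecutive frames. The rule is ours -- onset was
  scored from images in the assays this package emulates -- so it is
  validated against simulator ground truth (recovery within one frame
  on noise-free data) rather than asserted.
* **Rotation**: the per-frame axis (reference pole to other pole,
  keeping pole identity across frames by nearest-centroid matching) is
  projected to XY and compared with the initial axis; a cell rotates
  when the *net* orientation change exceeds 90 degrees. Both net and
  cumulative readings were considered; net is the call because a
  slowly wobbling spindle that never leaves its sector should not count,
  and the maximum net angle is what a manual scorer sees.
* **Division symmetry**: daughter size ratio max/min strictly greater
  than 1.2. "Size" is whatever positive scalar the upstream measurement
  provides (2D area or 3D volume); the ratio semantics are identical.
* **Attachment maturity**: a kinetochore is marker-negative below 0.3x
  the cell median marker intensity; a pair counts when at least one
  member is negative; the cell is flagged when more than 30% of pairs
  (strictly) are negative. The 0.3 factor replaces visual thresholding
  and is configurable.
* **Minus-end asymmetry**: pole intensity fold above 1.5 (analyst-set,
  flagged as such in reports).

All boundary comparisons are strict, and the tests pin the boundaries
(ratio 1.2 is symmetric, 30% negative pairs is not flagged, 90 degrees
is not rotating).

## The synthetic generator

The generator emulates the two live imaging regimes used for this kind
of assay -- 5-min videos at 7.5-s resolution and 15-min videos at 30-s
resolution -- and fixed-cell snapshots. Defaults describe a metaphase
HeLa spindle: poles 10 um apart, 23 sister pairs (matching the ~20
tracked kinetochores per cell such assays report), rest separation
1.0 um, oscillation amplitude 0.3 um and period 80 s (conventional
values for HeLa kinetochore oscillations; the sources this package is
built around report regular oscillations without printing amplitude or
period, so both are configurable), isotropic localisation noise 0.05 um,
and a cell radius of 9 um. Pair centres occupy a 5-um plate disc with a
1.5-um minimum spacing (random sequential adsorption), which both
matches the crowding of a real plate and guarantees unambiguous sister
pairing. Centriole intensities are fixed at 4:3:2:2 so a strict
grandmother always exists.

Modelling choices where the emulated assays state none:

* **Oscillations** are per-pair sinusoids with a common period and
  random phases -- the simplest motion with a defined autocorrelation.
* **Centering** is an exponential relaxation of the plate offset towards
  the spindle centre with time constant `centering_tau_s`: the
  one-parameter monotone model that reproduces "median R approaches 1
  over time" and makes the aligned-trajectory property exactly testable.
* **Anaphase** ramps sister separation linearly, doubling after 15 s
  (about 4 um/min of relative separation, on the fast side of anaphase A
  plus early anaphase B), which places the 1.5x detection threshold one
  frame after onset at 7.5-s sampling.
* **Cohort spread** of the true ratio is log-normal. For the recovery
  experiments we use `sd_log = 0.04`: large enough to populate the
  R > 1.15 tail in an off-centre cohort, small enough that the median of
  a 60-cell cohort estimates the true median to +-0.02. The spread seen
  in live cells is larger, but it contains measurement noise and
  between-experiment variation that the recovery experiment
  deliberately excludes.

The generator does *not* emulate photophysics, point-spread functions,
pixelation, detection failures or misattached (merotelic) kinetochores.
Passing the synthetic validation therefore shows that the analytics are
correct on their stated input contract -- typed, metric point detections
-- not that any upstream detection software is accurate.

## Cohort statistics

Per-cell metaphase $R$ is the mean over the first three available
frames. Emulated assays describe the early-metaphase value both as "the
earliest time point" and as "the first three time points"; the mean over
up to three frames reconciles the two and is configurable down to one.
The per-cell anaphase $R$ is taken from the last frame before onset.

Aligned trajectories synchronise cells at anaphase onset ($t = 0$), bin
on the sampling grid and report the across-cell median with a 95%
percentile bootstrap band. We resample *whole cells* (not frames, and
jointly across bins): cells are the independent units, and joint
resampling preserves the within-cell correlation of neighbouring bins.
The band choice (bootstrap rather than rank-based or parametric) is
declared in the report provenance block.

Group comparisons delegate to the standard implementations: Welch's
t test, Mann--Whitney U (exact when both groups have $n \le 20$ and no
ties, otherwise normal approximation with tie correction), the
median-centred Brown--Forsythe/Levene variance test, the paired t test,
Fisher's exact test and the two-sided exact binomial test. All p values
are two-sided and reported raw. The test suite cross-checks the exact
tests against full enumeration and the Mann--Whitney p against
exhaustive permutation, and calibrates type-I error on null
simulations; note that exact conditional tests are intrinsically
conservative at moderate counts (the attained size of Fisher's test at
$n = 30$ per group is about 0.027 for any Bernoulli null, a property of
the test, not of the implementation).

## Numerical choices and degenerate inputs

* Plane--axis intersections require $|\hat n \cdot \hat u| > 10^{-6}$;
  a plate parallel to the axis is an error.
* Pole partitions and brightest-centriole assignments refuse ties
  (1e-6 and 1e-9 respectively) instead of picking silently.
* The greedy track linker breaks equidistant candidates towards the
  lowest input row index; it is plumbing for inputs without track
  identities, not a contribution -- when the simulator's identities are
  available the linker merely reproduces them.
* Autocorrelation requires at least 8 valid samples and variance > 0.
* Reports round-trip integers bit-identically and reals to at least 12
  significant digits.

## Problem sizes used in the validation experiments

The shipped validation (test suite and `scripts/acceptance.R`) runs, per
experiment: 200 random geometries against an independent line--plane
solver; noise-free single cells for exact identity; two 60-cell cohorts
(4 frames each) for median-R recovery; single 600-s cells per
oscillation period; 20 snapshots of 35 pairs (700 pairs) for the
intra-kinetochore offset; 40-cell labelled cohorts per classifier; a
15-cell long-regime cohort for centering dynamics; and 2000 null
simulations for test calibration. These sizes were chosen to make
sampling error comfortably smaller than the tolerances being checked.

## Limitations

The pipeline consumes detections and inherits their biases; it performs
no deconvolution, no detection and no sub-pixel localisation. The
sister-pairing and anaphase rules assume a congressed, bioriented plate
and will degrade on prometaphase clouds. The rotation call is a net XY
criterion and ignores out-of-plane rotation. The statistical battery
reports raw p values by design; users comparing many conditions should
apply their own multiplicity control.
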