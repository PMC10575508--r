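---
title: "Methods: suitability, resistance and corridor connectivity across a protected-area network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: suitability, resistance and corridor connectivity across a protected-area network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Wide-ranging wildlife such as savanna elephants persist in
human-dominated landscapes only if the protected areas (PAs) they use
remain functionally connected. As cropland and settlement expand, the
habitat between PAs erodes first, pinching movement into narrow
corridors that eventually sever. `corridorscape` implements the full
analysis chain used in landscape-connectivity studies of this problem:

1. quantify land-use change over multiple time steps;
2. model habitat suitability per time step from presence records and
   environmental covariates;
3. transform suitability into movement resistance;
4. extract least-cost corridors between every PA pair and grade their
   quality;
5. locate pinch points and rank corridor importance with circuit
   theory;
6. validate the modelled surfaces and corridors against independent
   field data (transects, interview reports).

Because the aerial-survey and satellite data behind published studies
of this kind are not redistributable, the package ships a synthetic
landscape generator with a *known* ground truth. Every algorithm can
therefore be tested end to end: the generator plants a dominant,
recoverable ecological signal, and the test suite checks that the
modelling chain finds it.

## Ensemble habitat suitability

Suitability is modelled from presence points plus pseudo-absences
(default 1,000, drawn uniformly from non-presence background cells).
Four learners are fitted — regularized (ridge) logistic regression,
boosted regression trees, a spline-basis GAM, and a probability random
forest — each over `replications = 10` rounds of a stratified 75/25
train/test split that preserves the presence:absence ratio. Learners
are scored by held-out AUC (the Mann–Whitney rank formulation, ties
counted ½), and the ensemble prediction is the accuracy-weighted
average with weights proportional to each learner's mean AUC,
normalized to sum to one. The learners are backed by the standard
libraries (`glmnet`, `xgboost`, `splines` + `stats::glm.fit`,
`ranger`); the ensemble logic, evaluation and weighting are the
package's own.

Variable importance uses the jackknife: each covariate is removed in
turn, the ensemble refitted, and the raw importance is
`max(0, AUC_full − AUC_without)`, normalized to percent contributions.
Before fitting, `collinearityFilter()` screens covariate pairs with
|Pearson r| > 0.7 over jointly complete cells and drops the
later-listed member of each offending pair — correlation is computed
once over all jointly valid cells rather than per pair, so the
screen is order-stable and reproducible.

Continuous suitability is classed by exact Jenks natural breaks
(Fisher's optimal 1-D partitioning, implemented as a weighted dynamic
program over the unique values) into marginal/moderate/high, and
binarized at the threshold maximizing sensitivity + specificity over
the midpoints of adjacent sorted unique scores (ties resolve to the
lowest cut).

## From suitability to resistance

Resistance follows the negative-exponential transform

\[ R(h) = 100 - 99\,\frac{1 - e^{-c\,h}}{1 - e^{-c}} \]

mapping suitability \(h = 1\) to resistance 1 and \(h = 0\) to 100,
exactly. The shape factor \(c\) is conventionally tested at
\(\{2, 1, 0.5, 0.25\}\); the default 0.25 is nearly linear, the larger
values discount intermediate suitability progressively more strongly.
`sensitivityScan()` reproduces the evidence base for this choice: a
16-row table of corridor count and area over
\(\{2,1,0.5,0.25\} \times \{200,150,100,50\}\).

## Least-cost corridors

Cost-weighted distance (CWD) accumulates over the 8-connected grid
with the standard cost-distance convention: moving between adjacent
cells \(i, j\) costs `cellsize · d · (R_i + R_j)/2` with \(d = 1\) for
cardinal and \(\sqrt 2\) for diagonal moves. The implementation
relaxes all eight neighbour shifts in vectorized passes until a
fixpoint, which is exact for positive costs; the test suite proves
equality against two independent oracles (exhaustive path enumeration
on small grids, and Dijkstra via `igraph` on larger ones). Path
backtracking breaks cost ties deterministically toward the lower row,
then the lower column.

Per PA pair the package reports the least-cost path cost (cw-km), its
geometric length (km), the edge-to-edge Euclidean distance (km), and
two quality ratios: **CWD:EUD** (cost per straight-line km — how much
the landscape inflates the crow-flight distance) and **CWD:LCP** (cost
per path km — the mean resistance encountered along the optimal
route, bounded in [1, 100]). The corridor swath is the truncated
normalized corridor: cells where `cwdA + cwdB − lcpCost` is at most
the cutoff (default 200 cw-km; 150/100/50 are the conventional
alternatives). Masks are nested in the cutoff by construction. PA
masks that touch or overlap yield a degenerate zero-cost link rather
than an error, since no matrix separates them.

## Circuit theory

For pinch-point mapping, the resistance surface becomes a conductance
graph: nodes are cells, adjacent cells are joined by
`g = 1/(cellsize · d · (R_i + R_j)/2)`. Each PA is collapsed *exactly*
into one supernode — the zero-internal-resistance limit of the usual
convention of tying focal-region cells together with a very large
finite conductance. The exact collapse was chosen because it keeps the
Laplacian well-conditioned; a 1e6-conductance tie produces the same
physics but degrades the solve's numerics for no benefit. One ampere
is injected at the source supernode, the destination is grounded, and
the reduced sparse Laplacian system is solved with `Matrix`; the
relative residual is checked against 1e-8 and the solve aborts if it
is exceeded. Per-cell current density is half the sum of absolute
currents on the cell's incident edges, so a one-cell bottleneck
carries the full injected ampere. Pinch-point maps are solved on the
truncated corridor domain (plus the two PA masks), matching the
practice of running circuit models corridor by corridor.

Corridor importance uses current-flow centrality on the *reduced* PA
network: each link is a resistor whose resistance is its least-cost
path cost, 1 A is passed between every unordered PA pair in turn, and
a link's centrality is the sum of the absolute currents it carries.
The choice of link resistance = `lcpCost` makes centrality reflect
both topology and corridor quality.

## Land-cover change and validation

`changeStatistics()` works directly on per-class percent cover: per
interval changes in percent points, plus average annual rates over the
full span in %/yr and km²/yr (span = last year label − first).
`composeChangeTable()` derives the cover matrix from classified
rasters. Map accuracy uses the standard confusion matrix with overall
accuracy and Cohen's kappa from the row/column marginals. Corridor
encroachment reports the percent of each corridor's cells classed as
cropland per time step; with the generator's nested cropland series it
is non-decreasing by construction. Corridor activity summarizes
per-link sighting reports (mean, sample SD, seasons) and classes a
link "active" if any respondent reported at least one sighting,
otherwise "inactive".

## The synthetic generator: realism and limits

Defaults are the package's study conditions: a 60 × 60 km window at
1 km resolution, 9 rectangular PAs on a jittered grid, three time
steps labelled 2000/2010/2019 with cropland growing
6.71% → 8.79% → 13.14% of the window, and ~300 presence points per
step.

* **Covariates.** Elevation, an EVI proxy and rainfall are
  Gaussian-smoothed white-noise fields (correlation length 6 cells);
  slope is the maximum absolute central difference of elevation;
  ruggedness is slope plus small noise — deliberately collinear so the
  screen always has a pair to catch; houses are scattered points,
  roads and rivers are random-walk polylines, each contributing an
  exact Euclidean distance surface (two-pass separable distance
  transform).
* **Cropland.** Growth spreads outward from a few settlement nuclei by
  cost-distance over a preference surface (flat, river-near, non-PA
  cells first), taking exactly the target cell count per step, so the
  series is nested and the change table is monotone.
* **Ground truth.** True suitability is a logistic function of the
  standardized covariates under configured effect weights in which
  distance to cropland carries the strictly dominant positive weight
  (enforced by the config's validity). The linear predictor is
  standardized and passed through a sharpened offset logistic
  (`sharpness = 4`, `offset = 0.9`), confining high suitability
  (> 0.5) to roughly the upper fifth of the window. This calibration
  mirrors the compressed distributions reported for large herbivores
  in fragmented landscapes (order 17–21% of the window highly
  suitable) and gives the presence/background contrast an ensemble
  can resolve at AUC > 0.8; with a flat logistic the theoretical AUC
  ceiling of the design sits near 0.79 and no model, however good,
  can clear the bar.
* **Validation data.** Transects sit on a 5-km grid with Bernoulli
  presence at the true suitability; interview reports are Poisson
  counts proportional to each corridor's mean current density, with
  one configurable link forced silent — so the "9 active, 1 inactive"
  structure of a real corridor survey is reproducible at any network
  size.

Limits worth keeping in mind: fields are stationary and isotropic,
PAs are rectangles, cropland ignores roads, there is no
observation error in the presence points beyond sampling, and the
time steps share one covariate base (only distance-to-cropland
changes). The generator is a test harness with known truth, not a
landscape simulator.

## Numerical choices

* CWD by vectorized fixpoint relaxation: exact for positive costs,
  no heap required, and fast in R because each sweep is eight
  whole-matrix operations.
* Exact squared Euclidean distance transform (lower-envelope
  algorithm), with a finite "far" fill so the envelope algebra never
  produces `Inf − Inf`.
* Jenks by exact dynamic programming on unique values — not the
  common heuristic reimplementations — verified against exhaustive
  partition search.
* Circuit solves on the sparse reduced Laplacian with an explicit
  residual check (1e-8); supernodes collapsed exactly rather than via
  large finite conductances.
* All randomness flows from one master seed through named substreams
  (a hash of the stream name added to the seed), so stages are
  independently reproducible and reordering stages does not silently
  change downstream draws.
* ASCII-grid raster I/O writes `%.17g`, making write/read round-trips
  lossless at double precision.

## Resolved design questions

Where the analysis convention leaves latitude, the package fixes these
choices: collinearity is computed over all jointly complete cells;
ensemble weights are proportional to raw mean AUC (not rescaled or
thresholded); pseudo-absences are drawn once per time step and shared
by all learners and replications; the corridor quality ratios are
reported as dimensionless mean-resistance measures; links default to
all unordered PA pairs; and link centrality weights each link by its
least-cost cost. Each choice is documented at the function it affects.
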