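---
title: "Modeling ravine-breeding dragonfly habitat: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ravine-breeding dragonfly habitat: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Stream-breeding dragonflies with amphibious life cycles tie their
persistence to two coupled habitats: first- and second-order seepage
streams incised into sandy uplands, where nymphs develop, and the
open-canopy terrestrial matrix around those streams, where adults forage
and disperse. `ravinehab` models both: it derives multi-scale terrain,
hydrology, soil, land-cover and climate covariates from gridded inputs,
fits a presence–background maximum-entropy model with bias-matched
background, refines the continuous prediction into breeding habitat,
extends it with terrestrial habitat, and quantifies protected-area coverage
and projected urbanization threat.

## The model

Maxent's presence–background estimate is the exponential-family density
over background cells that maximizes entropy subject to matching the
presence means of a feature expansion. We fit it directly as the convex
program

$$\min_\lambda\; -\tfrac1m \sum_{i \in \text{pres}} f(x_i)\cdot\lambda
 + \log \sum_{b \in \text{bg}} e^{f(x_b)\cdot\lambda}
 + \sum_j r\,\beta_j |\lambda_j|$$

by monotone proximal-gradient descent with backtracking, declaring
convergence when the L1 subgradient (KKT) conditions hold to `1e-6`. The
objective decreases monotonically by construction (tested), and the fit is
validated against a derivative-free shrinking-grid-search oracle on small
problems.

Features are linear, quadratic, pairwise products of continuous variables,
forward/reverse hinges at empirical quantile knots, and one indicator per
observed landform class; every feature is scaled to [0, 1] on the pooled
presence+background sample. Default per-feature regularization weights are
a documented simplification of Maxent's sample-size-interpolated tables:
$1/\sqrt m$ for linear/quadratic/product terms ($m$ = presence count), 0.5
for hinges, 0.25 for categorical indicators. Threshold features are
excluded deliberately: hinges subsume them and they overfit small samples.

The map output is the complementary log-log transform
$1 - \exp(-e^{H}\,\mathrm{raw})$, where `raw` is normalized to sum to one
over the training background and $H$ is the entropy of that distribution —
so a completely uninformative model maps to $1 - e^{-1} \approx 0.632$
everywhere (tested as an identity).

## Key parameters, defaults, and why

* **Cell size 60 m** — matches the positional uncertainty of occurrence
  records and the resampled covariate resolution.
* **Focal radius 120 m** (neighborhood mean for slope, TPI, soils) —
  chosen among {60, 120, 540} m by total weight-of-evidence information
  value, decile-binned with 0.5-count smoothing; the candidate radii span
  nymph- to adult-scale habitat use. The selection machinery is itself part
  of the package (`select_radius()`).
* **Geomorphons: search 10 cells, skip 3, flatness 1°** — skip smooths
  micro-relief; the 8-direction ternary pattern indexes the standard
  10-class lookup table. Landform classes 6–10 (slope, hollow, footslope,
  valley, pit) are the "potential stream valley" stratum used both for
  flowline cleaning and for background sampling.
* **Flow-accumulation threshold 300 cells** — the headwater-density default
  for real continental-scale inputs. On the 24 × 24 km synthetic world the
  same drainage logic needs a proportionally lower threshold (25 cells in
  the shipped experiments) because catchments are far smaller; this is a
  scale adaptation, not a tuning knob, and the threshold is an explicit
  parameter everywhere.
* **Reach length ≤ 1 km** — junction-to-junction segments are subdivided so
  the one-record-per-reach thinning unit approximates real hydrography
  reaches rather than entire tributaries.
* **Snapping radius 300 m, downslope constraint** — adults are moved to
  the nearest stream cell not higher than their own cell. "Downslope" is
  operationalized as elevation-non-increasing; steepest-descent path
  tracing was rejected as over-specified.
* **Background: 10,000 points, landform 6–10, road weight
  $e^{-d/\tau}$, τ = 500 m** — restricting the background to the stratum
  that contains (by construction) the presences, and weighting it toward
  roads, cancels the corresponding survey biases instead of letting the
  model learn them. The exponential decay is a stand-in for the unstated
  "distance function"; τ is configurable.
* **Regularization multiplier 1, feature classes L/Q/H (+P, categorical)**
  — the AICc selection grid {0.5, 1, 2} × {L, LQ, LQH, LQHP} is available
  via `select_model()`; `AICc = 2k − 2\log L + 2k(k+1)/(n−k−1)` with `k`
  counting nonzero coefficients and the raw prediction renormalized over
  the evaluation landscape.
* **ESS threshold** — the equal-sensitivity/specificity point on pooled
  cross-validated held-out scores (computing it on the averaged map instead
  is a configuration switch).
* **Refinement**: upper Jenks class (exact two-class Fisher partition —
  deterministic, unlike the iterative heuristic), removal of ≤ 2-cell
  patches more than 1 km from larger ones (8-connectivity; the paper-silent
  connectivity choice), removal of cells whose 500-m circular neighborhood
  is more than half developed/barren, then a 500-m terrestrial extension
  over evergreen/shrub/herbaceous cover with canopy strictly below 50%.

## Numerical and degenerate-input choices

* Focal neighborhoods use the cell-center-within-radius rule, shrink at
  grid edges, and exclude missing cells from means; an all-missing
  neighborhood stays missing.
* Categorical grids resample by nearest neighbor even though the source
  workflow resampled "each raster" bilinearly — interpolating class codes
  is meaningless. This is the one documented deviation in the raster layer.
* Distance transforms are exact Euclidean (Felzenszwalb–Huttenlocher),
  verified against brute force.
* Depressions are filled by the iterative Planchon–Darboux scheme with an
  epsilon gradient of 1e-4 m/step so D8 routing never stalls; ties cannot
  occur because filled elevations are strictly decreasing along flow.
* Sinuosity is path length over endpoint chord (1 for straight segments,
  +∞ for closed ones); the straight-artifact rule only fires at length
  ≥ 300 m because "long" is unquantified in the source procedure — both
  gates are parameters.
* Rule 5 of the flowline cleaning (isolated short fragments) iterates to a
  fixed point so the whole cascade is idempotent.
* SEDI log arguments are clamped to [1/(2n), 1 − 1/(2n)] so perfect
  classification stays finite without moving interior values; TSS and SEDI
  are exactly zero at equal hit and false-alarm rates (tested as
  identities).
* The ANOVA correlation ratio η is flagged at η ≥ 0.70 (not η²); both are
  reported so either convention can be audited.
* Percent contribution is Σ|λ_j|·sd_j per variable over the background —
  a path-independent simplification of Maxent's training-path accounting,
  documented as such.

## The synthetic world: what it emulates, what it does not

`generate_world()` builds a 400 × 400-cell (24 × 24 km) landscape at 60-m
cells: a south-dipping plain with smoothed noise, incised by meandering
dendritic ravine walks (24 m maximum incision) whose floors carry woody
wetlands and whose walls carry evergreen forest; a two-scale land-use
mosaic (fine patchiness plus watershed-scale intensity, so percent
agriculture genuinely varies between subwatersheds); smoothed random soil
and climate fields; random road transects; protected-area blobs at a 20%
target fraction; pour-point watersheds; and a development-probability
surface decaying from the developed blobs. Occurrences (211 records, 60%
nymphs, ~30% within 100 m of roads — the road-bias factor is solved so the
realized record-level share hits the target) are drawn from a known
logistic suitability truth and adults are displaced up to 300 m upslope.

A green test on this world establishes that the pipeline recovers a truth
of the stated form under realistic sampling biases. It does **not**
establish performance on real rasters: the synthetic terrain is not
hydrologically calibrated, its land-cover classes have no spectral
confusion, soil fields are smooth rather than survey-polygonal, and the
landscape is three orders of magnitude smaller than a real range-wide
extent. Headline numbers from the source study (AUC 0.98, TSS 0.88,
132 occurrences, 2212 → 502 km²) depend on restricted occurrence data and
continental rasters and are therefore covered by property-based acceptance
(parameter recovery, oracle equivalences, cascade idempotence) plus exact
reproduction of the published table arithmetic — not by re-estimation.

Two stated-world experiments back the property acceptance:

* `recovery_experiment()` — truth logistic in slope (+1.6/°) and percent
  agriculture (−0.8/pp) only; 180 presences drawn proportional to truth
  over landform classes 6–10; 4,000 uniform background points from the
  same stratum. Recovery means held-out AUC ≥ 0.85 and {slope,
  pct_agriculture} as the top-2 permutation importances. Across seeds the
  experiment delivers AUC ≈ 0.95 with the correct top-2 — mirroring, as a
  property, the dominance of slope and catchment agriculture in the
  published importance table.
* `endtoend_recovery()` — the default four-variable truth pushed through
  the entire pipeline (flowline cleaning, snapping, thinning, bias-matched
  background, refinement cascade); the delineated breeding habitat must
  cover ≥ 70% of truly suitable (truth > 0.7) carved ravine cells.
  Observed: 0.94–0.99 across seeds.

Background size is scaled to 4,000 (from the 10,000 default) in the
shipped experiments to fit single-CPU time budgets; the parameter is the
user-facing default elsewhere.

## Design choices where the source was open

* "Reach" equals one cleaned flowline segment (≤ 1 km), the thinning unit.
* "Connected to woody wetlands" is interpreted locally: a majority of
  segment cells in landform classes 6–10 **and** at least one cell
  8-adjacent to woody wetland — testable without transitive closure.
* Adjacent-land-use exposure is reported both as ring cover (share of the
  one-cell buffer ring) and as habitat-area share (habitat cells with an
  exposed ring neighbor), since the published table convention is
  ambiguous.
* The urbanization split uses the probability classes < 50% / ≥ 50% with
  protected-area projections zeroed before intersection; the operation is
  order-invariant (tested).
* Raster exchange uses plain-text ESRI ASCII grids and CSV/JSON vectors:
  the deliverable is text-only and the target environment carries no
  GeoTIFF-capable R package. The interfaces are format-thin; swapping in
  GeoTIFF I/O would touch only `grid_read_asc()`/`grid_write_asc()`.

## Known limitations

* No coordinate-reference-system handling: one planar metric grid.
* D8 routing only (no D-infinity); flow on wide flat valley floors can
  braid unrealistically.
* The maxent engine is not a bit-for-bit Maxent 3.4.1 clone: β defaults
  are simplified, hinge knots sit at quantiles, and percent contribution
  is path-independent. Headline metrics agree in regime, not to the digit.
* Collinearity screening reports but does not automatically drop variables.
* The CLI regenerates the synthetic world from the config seed rather than
  consuming arbitrary external rasters; feeding real data in means calling
  the R functions directly on grids read with `grid_read_asc()`.
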