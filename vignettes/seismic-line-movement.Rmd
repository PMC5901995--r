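---
title: "Predator movement along regenerating seismic lines: models and methods"
author: "seismicmove"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predator movement along regenerating seismic lines: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seismicmove)
```

## The scientific problem

Seismic lines are narrow (~8 m) linear clearings cut through boreal forest
for geophysical exploration. They act as movement corridors for predators —
wolves and grizzly bears — and thereby increase predator overlap with
threatened woodland caribou. Decades after cutting, vegetation regrows at
very different rates, and the management question is whether that natural
regeneration is ever sufficient to erase the predator response, and which
lines (by vegetation height, wetness, landcover, density) should be
prioritised for active restoration.

`seismicmove` implements the full two-scale analysis of that question:

* **Broad scale — step selection functions (SSF).** Each observed movement
  step between consecutive GPS fixes is compared with K = 10 "available"
  steps sharing its start point, via conditional logistic regression. The
  covariates are attributes of the seismic-line network at the step's end
  point.
* **Fine scale — movement rates near lines.** For steps ending within 100 m
  of a line, log movement rate (m/h) is modelled with Gaussian
  random-intercept mixed models in vegetation height, season and forest
  cover, and the height response is located with piecewise (hinge)
  regression and a bootstrap confidence interval.

Because the underlying telemetry and LiDAR data are proprietary, the
package ships a first-class synthetic generator with known ground truth
(selection coefficients, stationary bouts, breakpoints), so that every
stage of the pipeline is testable by parameter recovery.

## The models

### Conditional logistic step selection

For stratum $s$ with one used step ($x_{us}$) and K available steps, the
weighted conditional log-likelihood is

$$\ell(\beta) = \sum_s w_s\!\left[\beta^\top x_{us} -
  \log \sum_{j \in s} \exp(\beta^\top x_j)\right],$$

maximised by Newton–Raphson with step-halving from $\beta = 0$
(convergence at gradient max-norm $10^{-8}$, at most 50 iterations). Any
covariate constant within a stratum cancels, which the tests exploit as an
invariance check. The weights $w_s$ are inverse fix-success probabilities
(1/PFix), so habitats where collars fail more often are not
under-represented; they default to 1. Separation — a covariate perfectly
ranking used steps, which drives the MLE to infinity — is detected via the
log-likelihood approaching zero and reported with the offending covariate's
name.

Successive steps are serially dependent, so the naive inverse-information
covariance is complemented by a cluster-robust sandwich
$A^{-1} B A^{-1}$, where clusters follow a rolling-span rule: a new
independence cluster starts when the time since the cluster's first step
exceeds 5 days (wolves) or 24 h (grizzly bears). Models M1–M5 (distance
decay `eDist` alone, then crossed with vegetation height, wetness, density,
landcover) compete by $QIC_U = -2\ell + 2p$ with Akaike-style weights; the
winner is refit per individual and pooled per coefficient by
inverse-(robust)-variance weighting with a $1.96\,(\sum_i 1/v_i)^{-1/2}$
CI half-width. "Inverse-weighted coefficients" admits more than one
reading; inverse-variance weighting is the standard two-stage population
estimator consistent with reporting $\beta \pm$ 95% CI, and is what we
implement.

Predictive skill uses rank-frequency k-fold cross-validation: 100 repeats
of an 80/20 stratum split; in each test stratum the 11 member scores are
ranked and the frequency of each rank among used steps is Spearman-correlated
with the rank index ($r_{s1}$), with a randomly drawn available step taking
the used role for the null statistic ($r_{s0}$). Average ranks at ties are
rounded to integer bins; the pseudo-used draw is uniform per stratum per
repeat. These two conventions are declared rather than inherited from any
particular prior implementation.

### Line covariates

* `eDist` $= 1 - e^{-0.002\,d}$, distance (m) from the step **end** to the
  nearest 100-m line segment — end points rather than along-step sampling,
  because a narrow line intersects only a sliver of any step.
* `Veght`: mean vegetation height of the nearest segment, attributed by a
  least-cost path through the height raster — Dijkstra on the 8-connected
  corridor within a configurable half-width (default 5 m on ~8-m lines),
  with cell cost = height + $10^{-6}$ per metre to break ties toward
  shorter paths. This follows the lowest-vegetation lane (game trails)
  instead of averaging the full cleared width, and is provably $\le$ the
  corridor mean.
* `eWAM` $= 1 - e^{-1.55\,w}$ of depth-to-water (m), effectively constant
  beyond 3 m (roots no longer reach water).
* `Density`: km/km² of line in a 1-km circular moving window on a 30-m
  grid (exact per-cell lengths by grid traversal, then a circular-kernel
  moving sum).
* `fLand`: the landcover class (Conifer/Mixed/Non-forest) intersecting the
  longest share of the segment, ties broken lexicographically and flagged;
  Non-forest is the reference category.

### Movement rates and the breakpoint

Near-line steps (end point within 100 m; at least 20 per animal-season)
enter `log_rate ~` M6 (season), M7 (height × season) or M8 (height ×
season × forest) with a random intercept per individual (or individual
within pack, chosen by AICc). REML estimates are reported; a
maximum-likelihood refit supplies the log-likelihood for
$AICc = -2\ell + 2p + 2p(p+1)/(n-p-1)$ so fixed structures are comparable.
Wolf steps at 2-h intervals are converted to m/h by dividing the distance by
2 before logging; vegetation height enters as $\log(Veght+1)$. Fit quality
is summarised by variance-decomposition (marginal/conditional) $R^2$.

When the winning model retains the height term, the height response is
located post-hoc by a two-segment continuous hinge
$y = a + b_L\min(x - c, 0) + b_R\max(x - c, 0)$, with the breakpoint $c$
chosen by exhaustive least-squares scan over observed $x$ values in the
central 90% of the range. The two hinge arms are pointwise orthogonal, so
each candidate's normal equations reduce to closed-form sums over sorted
data and the whole scan is O(n) — important because the 95% CI comes from a
1,000-replicate case-resampling percentile bootstrap, and coverage is
verified over 100 simulated datasets. The hinge runs on the model's
covariate scale $\log(Veght+1)$ and the breakpoint is reported back in
metres; a kink location is invariant under a monotone transform, so nothing
is lost. The CI is reported as a half-width around the point estimate, and
is labelled as such (a "95% CI = h" display is ambiguous between half- and
full widths; we pick the half-width and say so).

## The synthetic generator

`make_landscape()` builds a square study area with ~70% of the target line
length as long parallel transects on an uneven spacing gradient (so the
density covariate has spatial contrast) plus random cross-lines, clipped and
appended until the realized density matches the request. Per-segment
vegetation heights are lognormal with parameters solved from two
interpretable inputs — the mean height (default 0.81 m) and the share of
segments below 1 m (default 75%) — taking the more right-skewed of the two
admissible roots. Wetness and landcover are smooth random fields; the
height raster is a tall-canopy background with line corridors carved down
to their segment heights.

`simulate_ssf_track()` is a biased correlated random walk: at each step, 50
candidate endpoints are proposed from a gamma step-length and von Mises
turn-angle kernel and one is chosen with probability
$\propto \exp(\beta^\top x)$. Fifty candidates (well above the 10 used in
fitting) make the discrete choice a close approximation of the continuous
selection kernel. The kernels are configurable because real analyses use
empirical species-sex-season distributions; one kernel per track is enough
for parameter-recovery testing but is not a replication of empirical
histograms. Boundaries reflect rather than truncate, and — importantly —
available steps generated for fitting are reflected at the same boundary:
an available endpoint projected beyond the study area would sit
artificially far from every line and masquerade as avoidance. Stationary
bouts (`inject_stationary_bouts()`) and fix thinning with 1/PFix weights
(`thin_fixes()`) complete the telemetry emulation.

Step-end covariates for both the generator and (optionally) stratum
construction come from a precomputed 30-m `covariate_index()` — the same
resolution at which the real covariates are mapped — making generation and
estimation use one covariate definition and large simulations fast. Exact
point-to-segment distances remain available (`nearest_segment()`) and are
verified against a brute-force oracle.

### What passing tests do and do not show

The generator emulates the *design* of the study — fix schedules, seasons,
stationary bouts, missed fixes, right-skewed line regeneration, density
gradients — but not geographic realism (no projections, rivers, terrain,
snow, prey fields) and no interaction between animals. Parameter recovery
on synthetic data therefore validates the estimation machinery, not the
ecological conclusions: it shows that *if* movement follows the assumed
selection kernel, the pipeline returns the right coefficients, rankings and
breakpoints at realistic sample sizes.

Two known, deliberate approximations temper recovery accuracy. Available
steps are drawn from the *observed* step-length/turn-angle pools (as in the
field workflow), which are themselves selection-biased; and the generative
choice set is finite (50 candidates). Both shave a few percent off
interaction coefficients (attenuation of order 10% in our conditions) — a
well-known property of empirical-availability SSF designs — and both are
inside the Monte-Carlo tolerance used by the recovery checks.

## Numerical and design choices

* **Stationary classifier.** The field workflow used an unpublished GIS
  clustering tool; our concrete, deterministic definition labels a maximal
  run of consecutive fixes stationary when its span exceeds the duration
  threshold (6 h wolves / 7 h bears) and every fix lies within the radius
  (300 m / 100 m) of the run centroid, grown greedily from the run's first
  fix. Classifier checks simulate travelling animals (directional
  persistence $\kappa = 1.5$; cruising speeds of ~800 m/h for wolves at 2-h
  fixes and ~500 m/h for bears at 1-h fixes) carrying eight multi-hour
  rest/kill bouts per track; a nearly-uniform turn kernel would loiter by
  chance and blur the truth labels themselves.
* **Independence clusters.** "More than five days apart" is implemented as
  a rolling span — a new cluster whenever the time since the cluster's
  first step exceeds the gap — which reproduces both the wolf (2-h steps
  over 10 days, 5-day gap, 2 clusters) and bear (hourly steps over 3 days,
  24-h gap, 3 clusters) boundary cases.
* **Pack decorrelation.** Same-pack steps at the same timestamp whose
  start points chain within 200 m (transitive closure) count once; the
  survivor is drawn uniformly under the run seed.
* **Rarefaction** keeps the fix nearest each 2-h target within a ±5-min
  tolerance and restarts the schedule after gaps; it never invents fixes
  and is idempotent.
* **Screening** removes one member of any covariate pair with $|r| > 0.6$
  and then iteratively any column with VIF > 3, dropping the later-listed
  offender so the decision is deterministic.
* **QIC_U** is $-2\ell + 2p$ without a robust-trace correction; whether the
  original selection used one is not documented, so the simpler form is
  declared and used consistently for all candidates.
* **Segmenting** cuts polylines at exact 100-m arc-length marks; a terminal
  remainder under 50 m folds into the final piece, so piece lengths stay in
  [50, 150] m and total length is conserved exactly.
* **PFix weighting** multiplies stratum log-likelihood contributions
  (weighted conditional likelihood). Whether the original analysis weighted
  the likelihood or only summaries is ambiguous; weighting the likelihood
  is the coherent choice for an inverse-probability correction.
* **M4** (density interaction) stays in the candidate set for completeness
  even where no season selects it.
* **Problem sizes.** The recovery conditions are 20 animals × 300 steps
  (≈6,000 strata) on a 5 × 5 km landscape at 1.45 km/km², with 20 seeded
  replicate cohorts for Monte-Carlo spread; cross-validation uses 100
  repeats; breakpoint coverage uses 100 datasets × 1,000 bootstrap
  replicates; the mixed-model check uses 40 animals × 50 observations.
  These sizes give stable Monte-Carlo behaviour while keeping a full run
  on a single CPU in minutes.

## Limitations

* The SSF is the plain conditional-logistic form: no integrated
  movement-kernel estimation, no home-range or utilisation-distribution
  modelling.
* One breakpoint only; no temporal autocorrelation structures in the rate
  models; male-wolf rate models are out of scope (the design restricts to
  females).
* The least-cost height operator starts from a rasterised height field;
  raw LiDAR point-cloud processing is out of scope.
* Coordinates are planar metres throughout; no projection handling.

## Reproducing the headline numbers

`scripts/acceptance.R --seed <int> --out <path>` regenerates the study
conditions from scratch — landscape, tracks, strata, fits, cross-validation,
classifier checks, breakpoint bootstrap, mixed model — and writes each
quantity with the problem size it was computed on. The test suite
(`tests/testthat/`) runs the same checks with assertions, including the
independent oracles: dense grid search for the conditional-logistic MLE,
`survival::clogit` as a cross-check, exhaustive path enumeration and
`igraph` for the least-cost path, brute-force scans for distances and
filters, and closed-form arithmetic for the criteria.
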