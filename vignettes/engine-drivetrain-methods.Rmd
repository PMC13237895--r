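---
title: "Methods: the LHS engine–drivetrain model in lhsdrive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the LHS engine–drivetrain model in lhsdrive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhsdrive)
```

## The model and its assumptions

`lhsdrive` treats a Learning Health System as a mechanical drivetrain. A CTSA
hub supplies engine power; community empowerment — measured by the Community
Transmission Index (CTI) — acts as a variable transmission; four learning
cycles (clinical care, education, research, governance) are the wheels. The
core assumptions are:

* **Transmission is saturating, not linear.** The proportion of institutional
  capacity converted into translational effort follows a logistic curve
  `T(M) = 1/(1 + exp(-a(M - m0)))`, so empowerment has threshold behaviour:
  little effect until it approaches the midpoint `m0`, then rapid gains.
* **Friction declines with maturity.** Contextual friction (mistrust,
  misalignment, coordination barriers) is reduced by a Hill function
  `R(M) = r_max M^eta / (M^eta + c^eta)`, zero at `M = 0` and approaching
  `r_max < 1`: empowerment can never remove all friction.
* **Each wheel is a contest between transmitted power and residual
  friction.** The direct drive
  `f_j = v_max_j E_j T(M) / (E_j T(M) + F_j (1 - R(M)))` is bounded by the
  wheel's velocity cap, strictly increasing in engine power and CTI, and
  strictly decreasing in friction. Only the ratio `E_j/F_j` matters, so both
  are expressed in arbitrary positive resource units.
* **Learning spills over linearly and statically.** Coupled velocities solve
  `v = (I - K)^{-1} f` — the fixed point of a linear spillover system, not a
  differential equation. There is no continuous-time dynamics here; one call
  is one evaluation period, and longitudinal sequencing is left to the
  caller. Because `K` is nonnegative with zero diagonal and spectral radius
  below 1, spillovers can only amplify (`v >= f`, elementwise).

System performance is summarized by the gain index `TEI-G = ||v||_W/||f||_W`,
the bottleneck index `TEI-B = min_j v_j / sum_j alpha_j v_j`, their product
`TEI`, the bottleneck and mission-weighted system speeds, and an economic
layer (innovation throughput, revenue, expense, ROI).

## The CTI instrument

Eight domains are rated 0–4 by three raters (academic, health system,
community). Ratings are normalized (`r/4`), averaged across raters, then
weighted and summed. Three instrument-level choices deserve explanation:

* **Aggregation divisor.** Raters are combined by the arithmetic mean of the
  three normalized scores. This matches the instrument's description of the
  scores being averaged; it keeps each domain score inside `[0, 1]` so the
  composite stays a true 0–1 index.
* **Major discrepancies.** The instrument calls for consensus review of major
  discrepancies but does not define "major". We operationalize it as any
  (project, domain) where the raw ratings spread by 2 or more rubric points
  — i.e. the raters disagree about more than adjacent anchors. Flagged cells
  are never auto-resolved; the package only reports them.
* **Kappa weighting.** Reliability uses weighted Cohen's kappa with
  *quadratic* weights by default (the convention for ordinal rubrics, where
  a 0-vs-4 disagreement should cost far more than a 2-vs-3 one); linear
  weights are selectable. Kappa is reported as undefined (`NA`, with a
  warning) when both raters are constant, never silently 0.

Band cut-points (0.25 / 0.50 / 0.70 / 0.85) are left-closed, with 1.0
included in the top band, so the five bands partition `[0, 1]` exactly.

The default weights are `D1 0.16, D2 0.10, D3 0.12, D4 0.10, D5 0.16,
D6 0.12, D7 0.12, D8 0.12`. The equity-forward preset raises D8 (equity) to
0.20 and shrinks D2–D4 by the common factor 0.75, leaving D1, D5, D6, D7
untouched, so the vector still sums to 1.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `a` (logistic slope) | 10 | — | steep but smooth maturity threshold around `m0` |
| `m0` (midpoint) | 0.5 | CTI | transition mid-scale, between Advisory and Collaborative |
| `r_max` (max friction reduction) | 0.6 | fraction | even mature engagement leaves structural friction |
| `eta` (Hill exponent) | 2 | — | mildly sigmoidal friction response |
| `c` (half-saturation) | 0.5 | CTI | half the friction benefit arrives mid-scale |
| `v_max` | 1.40, 1.13, 1.39, 1.26 | month⁻¹ | per-wheel velocity caps (calibration, below) |
| `K` | see below | fraction | cross-cycle spillovers |
| `alpha` (mission weights) | 0.25 each | — | balanced mission by default |

The four dominant spillovers in the default `K` are Governance→Clinical 0.18,
Governance→Education 0.10, Governance→Research 0.10 and Clinical→Research
0.12 — governance as the system accelerator, clinical practice feeding
research. The remaining off-diagonal cells are free calibration choices,
each ≤ 0.10, representing education's broad stabilizing spillovers and
modest research-to-practice and feedback-to-governance paths. The full
matrix has spectral radius well below 1.

## The synthetic portfolio generator

`simulate_portfolio()` emulates a hub's project portfolio:

* project CTI from a beta(2.2, 2.0) distribution — heterogeneous maturity
  with mean ≈ 0.52, covering all five bands;
* per-wheel engine power and friction from log-normal(0, 0.3) draws —
  right-skewed institutional resource variation with a unit median;
* per-wheel velocity caps and economic coefficients fixed at the config
  values.

The velocity caps and economic coefficients were calibrated **once** so that
the default portfolio's mean cycle velocities fall near 0.75 / 0.59 / 0.73 /
0.60 month⁻¹, organization-level (≈ 25-project) expenses near \$1.4M and
revenues near \$2.9M — plausible magnitudes for an academic health system's
translational portfolio. They are calibration anchors, not estimates: none of
the default constants was fit to data.

What the generator does **not** emulate: longitudinal CTI trajectories
(periods are independent), correlation between a project's engine power and
its friction, portfolio-level resource constraints (projects are
independent), non-stationary economics, or measurement error in milestone
timestamps. Passing tests therefore demonstrate internal consistency of the
model and pipeline, not validity against real institutional data.

`generate_rating_fixtures()` plays the same role for the instrument: it
builds 3-rater sheets with controllable agreement (perfect / high / low) and
an optional target maturity band, by rejection sampling on the scored
composite.

## Monte Carlo protocol

Each iteration draws the five transmission constants from uniform ranges
(`a` ∈ [6, 14], `m0` ∈ [0.4, 0.6], `r_max` ∈ [0.4, 0.8], `eta` ∈ [1.5, 3],
`c` ∈ [0.3, 0.7] — symmetric about the deterministic defaults) and a
coupling scale factor in [0.5, 1.5]. If scaling would push the spectral
radius of `K` to 1 or beyond, the matrix is rescaled to radius 0.95 and the
iteration flagged; no iteration ever runs with an unstable coupling. Within
an iteration every project is deterministic given the drawn parameters;
variation across iterations reflects parameter uncertainty.

Portfolio size supports two regimes: a fixed count (e.g. 1,000 projects per
iteration) and a rounded-normal(25, 3) draw; the default configuration uses
the latter, which is the regime whose summary statistics the package's own
acceptance run reports (500 iterations ≈ 12,500 project records). Summaries
report means, SDs, medians and 2.5–97.5 percentile simulation intervals.

Reproducibility uses one master seed that generates an independent child
seed per iteration (drawn with replacement, so iteration *i*'s stream does
not depend on how many iterations follow); identical seed + configuration
gives byte-identical outputs, and a longer run extends a shorter one.

## Numerical and statistical choices

* The coupled system is solved with a dense linear solve of `(I - K)v = f`,
  never an explicit inverse; the truncated Neumann series `sum K^n f` is
  used only as an independent test oracle (agreement to 1e-10 for spectral
  radius ≤ 0.9).
* Weight vectors (domain, mission, milestone rows) must sum to 1 within
  1e-9; ratings must be exact integers 0–4.
* The TEI-G norm is the weighted Euclidean norm with the mission weights by
  default; a weighted 1-norm (ratio of weighted means) is selectable. The
  instrument text does not pin the norm; the Euclidean choice penalizes
  concentration of velocity in a single wheel slightly more.
* Typology cuts: both fixed thresholds and cohort median-splits are
  supported; median-split is the default for cohort analyses, and values at
  or above a cut classify as "high". With per-iteration median splits the
  four states are near-balanced by construction, so state proportions are
  descriptive of the splitting rule, not an external prevalence claim.
* Percentile-scaled velocities beyond their 5th/95th anchors are returned
  unclamped with an `out_of_range` flag — clamping would silently hide
  benchmark drift.
* Milestone latencies are attributed to wheels by the row-stochastic
  interpretation weights, which conserves total latency exactly.
* Kruskal–Wallis tests use the standard tie correction and the chi-square
  approximation (group sizes in simulated cohorts are large). IQRs are
  (25th, 75th) percentiles with linear interpolation.
* Global ROI is reported both as mean-of-ratios (average project ROI) and
  ratio-of-means (total revenue over total expense); the two differ whenever
  ROI correlates with project size, and neither is privileged.
* VIFs come from the diagonal of the inverse predictor correlation matrix
  (equivalently `1/(1 - R_j^2)`); the ROI regression can show a negative or
  near-zero CTI coefficient *conditional on* TEI and mean velocity even
  though the marginal CTI–ROI association is strongly positive — a
  conditioning artifact among collinear mediators, not a causal statement.

## Problem sizes in the shipped tests

The property suite uses 1,000 random stable couplings for the
Neumann-series check, 200-draw parameter sweeps for the midpoint and
half-saturation identities, and 200 random rater tables for the kappa
oracle. The directional check runs 100 iterations × 200 projects and asks
for a positive within-iteration Spearman correlation between CTI and TEI
and between CTI and ROI in at least 99 of 100 iterations, plus a higher
median TEI in the top CTI quartile than the bottom. The acceptance script
runs the full default configuration (500 iterations). These sizes keep the
whole suite under a minute per property while leaving negligible sampling
slack.

## Known limitations

* All results are simulation-based; no empirical estimation of the
  transmission constants, spillovers or stage sensitivities is provided, and
  nothing here supports causal claims about real institutions.
* The spillover matrix is static; feedback from performance back onto `K`
  (learning that strengthens coupling) is outside the model.
* Economic forms are the simplest monotone parameterizations (linear revenue
  and cost in velocity and throughput); real cost structures are lumpier.
* The instrument's qualitative anchors are documented but not administered
  by the package; no survey tooling is included.
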