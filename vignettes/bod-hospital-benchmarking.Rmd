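---
title: "Benefit-of-the-Doubt composite indicators for hospital KPI panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benefit-of-the-Doubt composite indicators for hospital KPI panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bodbench)
```

## The problem

Hospital regulators publish monthly panels of key performance indicators
(KPIs) spanning access (waiting-time compliance), clinical safety
(adverse-event rates), productivity (case throughput, bed occupancy), and
care appropriateness (readmissions, outpatient-surgery uptake).  Judging a
hospital requires collapsing these heterogeneous indicators into one
score, and any fixed weighting is contestable.  The Benefit-of-the-Doubt
(BoD) approach sidesteps that: each entity is scored under the weighting
*most favourable to itself*, subject to the same feasibility constraints
for everyone.  An entity that looks poor even under its own best weights
is unambiguously underperforming.

`bodbench` implements this model family for monthly panels of entities
organized in peer groups, plus the surrounding machinery a real analysis
needs: direction-aware standardization, multiple imputation of missing
cells, benchmark-consistency analytics around a structural shock, and a
synthetic data generator with known ground truth for validation.

## The models

Let $y_{i,j} \in (0, 1]$ be the standardized value of variable $j =
1,\dots,n$ for entity-month $i = 1,\dots,m$ within one peer group.  For a
target $t$ the **optimistic** composite indicator is

$$CI^{opti}_t = \max_{\alpha_{t,j} \ge 0} \sum_j \alpha_{t,j} y_{t,j}
\quad \text{s.t.} \quad \sum_j \alpha_{t,j} y_{i,j} \le 1 \;\; \forall i,$$

so $CI^{opti}_t \in (0, 1]$ and a score of 1 means no common weighting
certificate can push the entity below the best observed practice — the
entity-month is a *benchmark*.  The **pessimistic** model reverses the
view: minimize the same objective subject to every entity-month scoring
at least 1.  Its raw score is $\ge 1$ (1 = on the frontier of worst
observed practice) and is mapped to $[0,1]$ for comparability by the
linear min-max rescaling $(CI - \min)/(\max - \min)$, applied within each
peer group.

Two optional weight restrictions bound how much the optimization can
concentrate weight:

* **multiplier share**: $\alpha_{t,j} / \sum_i \alpha_{t,i} \ge w_j$ —
  every multiplier carries at least the share $w_j$;
* **pie share**: $\alpha_{t,j} y_{t,j} / \sum_i \alpha_{t,i} y_{t,i} \ge
  w_j$ — every *variable's contribution to the score* is at least $w_j$,
  which punishes poor performance on any single variable (partial
  non-compensability).

Both are ratio constraints; with $\alpha \ge 0$ they linearize exactly to
$(1 - w_j)\alpha_j - w_j \sum_{i \ne j} \alpha_i \ge 0$ and
$\alpha_j y_{t,j} - w_j \sum_i \alpha_i y_{t,i} \ge 0$, which is how the
solver states them.  The default minimum weight is $w_j = 1/(2n)$ —
0.03125 for the 16-variable catalogue — a mild floor that keeps every
variable relevant without dictating the weighting; the restricted models
are feasible whenever $\sum_j w_j \le 1$, which the configuration layer
enforces.  Multipliers are reported but are dimensionless after
standardization and should not be interpreted as prices; ties among
alternate optimal multiplier vectors are resolved arbitrarily by the
solver (the score itself is unique).

### Reference set: pooled months per peer group

Frontiers are built per peer group, pooling all months of the horizon
into one reference set (a meta-frontier).  Scores are then comparable
across time within a group, which is what pre/post-shock comparisons
need.  A consequence worth knowing: adding months can only tighten
scores, and a month's score reflects the whole horizon's best practice,
not just its contemporaries.

## Standardization

Variables are first oriented so that larger always means better:
desirable KPIs pass through, undesirable KPIs are negated (equivalent to
reflecting the min-max formula), and the neutral bed-occupancy KPI is
replaced by minus its deviation from the 80–90% band (zero inside the
band, growing linearly outside) and then treated as undesirable.  The
band deviation is anchored at the observed extreme deviations rather than
fixed endpoints, because the field convention specifies only a linear
decrease away from the band; this is a documented modelling choice.

Oriented values are then mapped to the ascending scale

$$y_{i,j} = 0.99\,\frac{y^{unstd}_{i,j} - \min_i y^{unstd}_{i,j}}
{\max_i y^{unstd}_{i,j} - \min_i y^{unstd}_{i,j}} + 0.01,$$

so each variable spans exactly $[0.01, 1]$ within its scope.  The lower
bound is deliberately not 0: the pie-share constraint divides by weighted
values, and a zero would make the restriction degenerate.  The
standardization scope defaults to *per peer group over all months*,
matching the group-wise frontiers; a pooled scope is available by
argument.  A constant column (max = min) raises an error by default —
silently keeping it would distort the weight restrictions — with an
optional fill value for deliberate overrides.  Scores are invariant under
positive affine transformations of raw desirable columns, which the test
suite asserts through the whole pipeline.

## Missing data

Registry panels have sporadic missing cells (about 3% under the emulated
conditions).  Rather than dropping entities or plugging in column means,
each missing cell receives $K$ independent random draws from a
distribution truncated to the observed $[\min, \max]$ of its variable
within the standardization scope, and the full
standardize-and-score pipeline runs once per replicate.  Every
entity-month thus carries a score *distribution*; its mean (the expected
score) drives the downstream analytics, and entity-months of a complete
panel have degenerate distributions, identical to a single run.

The truncated-interval distribution is normal by default, located at the
observed column mean with the observed column standard deviation
(interval-midpoint location and a uniform alternative are available; the
scale falls back to a quarter of the interval width when fewer than two
values are observed).  These location/scale choices are assumptions — the
emulated study protocol fixes only "a normal distribution within the
observed interval" — and are therefore exposed in
`imputation_config()` rather than hard-coded.  Draws are made on the raw
scale, before orientation and standardization, because the interval is
defined by raw variable extremes.  Cells are drawn independently; no
joint model across variables is attempted.  The reference protocol uses
$K = 5000$; validation runs here use $K \in \{50, 200\}$, which is
already enough to stabilize expected scores at panel sizes of interest
(the masking experiment in the test suite requires Spearman rank
correlation $\ge 0.95$ between expected and complete-data scores at $K =
200$ on a 40-entity, 65-month panel with 3% of cells masked).

## Solving the linear programs

No linear-programming package is part of this package's dependency
footprint; the LPs are solved by a self-contained dense simplex written
in C++ (two-phase primal with a dual-simplex fast path and Bland-rule
anti-cycling).  Two structural observations make the production path
fast and exact:

1. **Duality.** Each BoD program has only $n$ variables (16 in the
   standard catalogue) but $m$ entity-month constraints (hundreds under
   a meta-frontier).  The solver therefore works on the LP dual, which
   has just $n$ rows, and recovers the multipliers $\alpha$ as the dual
   values of the dual — exactly the primal solution by strong duality.
   The optimistic dual is stated in a negated $\le$ form whose all-slack
   basis is dual feasible, so a short dual-simplex sweep replaces
   phase 1 entirely.

2. **Pareto pruning.** With $\alpha \ge 0$, the constraint of an
   entity-month that is weakly dominated (componentwise) by another is
   implied by the dominator's constraint.  Only the Pareto-maximal rows
   (optimistic) or Pareto-minimal rows (pessimistic) of the reference
   set are passed to the solver.  This pruning is *exact* — scores are
   bit-for-bit unchanged — and on realistic panels it removes the vast
   majority of rows, because mostly-zero safety rates and correlated
   quality produce heavy domination.

Correctness is guarded by an independent oracle, `oracle_score()`, which
enumerates every vertex of the small-instance constraint polyhedron and
takes the best feasible objective.  The test suite requires
solver-oracle agreement within $10^{-6}$ on hundreds of random instances
across all orientation/restriction combinations, along with analytic
frontier facts (column-extreme holders score exactly 1; optimistic
scores lie in $(0,1]$; pessimistic scores are $\ge 1$) and restriction
monotonicity (adding a restriction can never improve an optimum).

Numerical tolerances: the benchmark flag uses a $10^{-6}$ relative
tolerance around 1 (LP solvers return $1 - \varepsilon$ at optimality);
the simplex uses $10^{-9}$ pivoting tolerances internally.

## Benchmark analytics

Downstream of scoring, the package reproduces the standard
benchmark-consistency toolkit:

* `monthly_rankings()` — per (group, month) descending ranks; scores
  within tolerance of the monthly maximum share rank 1 and form the
  monthly benchmark set;
* `top_entities()` — the $k$ entities with the highest mean expected
  score over a window, ties broken lexicographically;
* `benchmark_frequency()` / `frequency_table()` — the fraction of window
  months whose benchmark set intersects a given entity set, for $k = 1,
  2, \dots$ (nondecreasing in $k$ by construction);
* `prepost_summary()` — per-entity average scores and rank-1 shares
  before and after a split month (the pre window *includes* the split
  month), plus each group's pre-window top-$k$ set and its combined
  benchmark frequency in both windows; ties credit every tied entity,
  so shares can sum to more than 100%;
* `gap_series()` — the monthly mean-score gap between designated top and
  bottom sets, with pre/post averages and the OLS trend slope on the
  0-based month index;
* `evolution_summary()` — per-month min / Q1 / mean / Q3 / max (the
  five-line evolution chart).  Quartiles use linear interpolation
  (type 7), a convention documented here because none is universal.

## The synthetic generator

`generate_panel()` emulates the statistical structure the analysis
assumes, with ground truth for validation: 40 entities in four peer
groups (14/11/9/6), 65 months from January 2017, and 16 variables
matching the catalogue's directions (6 desirable, 9 undesirable, 1
neutral).  Each KPI is baseline(latent quality) × small seasonal term ×
shock trajectory + noise, clipped to its plausible range:

* **Latent quality** in $[0,1]$ per entity; two randomly designated
  *top* entities per group carry qualities 0.85 and 0.95, the rest are
  evenly spread over $[0.35, 0.70]$ and split into mid/low tiers.
* **Shock**: April 2020 multiplies performance by $1 - d$ with
  dimension-specific depth $d$ (access 0.45, productivity 0.30, care
  appropriateness 0.20, safety 0.10 — access hit hardest), followed by
  exponential recovery whose half-life and asymptote depend on the tier:
  top entities recover in ~3 months and overshoot to 1.08 × baseline,
  low-tier entities recover slowly toward 0.94 × baseline.  Smaller
  later waves (scales 0.25–0.35) are superimposed.  Seasonality is kept
  small (amplitude 0.015) so the shock dominates the morphology.
* **Safety rates** are zero-inflated: usually 0, with rare exponential
  spikes whose probability and size shrink with quality — reproducing
  the skew of real adverse-event rates, where occasionally a single
  event briefly reorders a month's ranking.
* **Occupancy** is built from synthetic bed-days divided by beds ×
  365.25/12 days, fluctuating around the 80–90 band and dropping far
  below it in lockdown months.
* **Monthly form**: a lognormal month-to-month factor (sd 0.05 for top,
  0.15/0.18 for mid/low tiers) rotates the monthly benchmark among the
  stronger entities — weaker entities fluctuate more — without
  disturbing long-run rankings.
* **Missingness** is completely at random at rate 0.03, resampled if a
  draw would empty a variable within a group.  No informative
  missingness mechanism is modelled, as none is specified by the
  emulated protocol.

What passing tests on this generator do show: the pipeline recovers
designed rankings, shock timing, and divergence direction under
realistic noise, skew, and missingness.  What they cannot show:
behaviour under informative missingness, reporting artefacts, genuine
institutional heterogeneity, or any real hospital's trajectory — the
generator makes no attempt to match real descriptive statistics beyond
scale and skew.

## Validation problem sizes

The shipped test suite runs, among others: ~200-instance random
solver-vs-oracle sweeps (2–4 variables, 3–6 entity-months, all model
configurations); the full 40 × 65 × 16 synthetic panel through scoring
under all four orientation/restriction pairs; a 20-seed ground-truth
recovery batch (top-2 identification, shock-month dip in every group,
gap divergence); and a masking experiment at $K = 200$ on the default
panel.  These sizes were chosen as the smallest that exercise every
code path at full structural realism.

## Known limitations

* The BoD family is ordinal across weighting schemes but compensatory in
  its linear aggregation (outside the pie-share floor); geometric
  aggregation is out of scope.
* Meta-frontier pooling assumes no structural frontier shift within the
  horizon; a windowed reference set is not the default and pre/post
  comparisons inherit that assumption.
* Per-cell independent imputation understates cross-variable dependence;
  expected scores are robust to this at low missingness rates, score
  *quantiles* less so.
* Vertex enumeration is exponential and guarded to ≤ 4 variables / ≤ 6
  entity-months; it is a test oracle, not a fallback solver.
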