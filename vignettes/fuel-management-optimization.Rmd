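---
title: "Optimizing non-spatial fuel-management rules in multi-ownership landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimizing non-spatial fuel-management rules in multi-ownership landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`fuelscape` couples a stochastic simulator of multi-ownership cork oak
landscapes with an elitist multi-objective genetic algorithm, to find simple
clearing rules — interval/proportion prescriptions for a few groups of
landowners — that balance management cost, fire risk and biodiversity at the
landscape scale when compliance is uncoordinated and imperfect. This vignette
documents the model, its parameters and the design decisions, in the spirit
of a methods appendix.

## The landscape model

Landscapes are offset-row ("odd-r") lattices of hexagonal 1-ha cells. Because
every computed quantity depends only on cell areas and adjacency, the hexagon
geometry itself never enters: a 180×180 lattice stands in for an 18×18 km
block, and any lattice of the same cell count and hex adjacency would give
identical results. Tests and examples use smaller lattices (30×30, 50×50);
cell area is fixed at 1 ha so area always equals cell count.

Ownership is created by region growing: a seed cell is drawn uniformly among
unassigned cells, a target area is drawn from a Gamma distribution
(moment-matched: shape = mean²/variance, scale = variance/mean; base
parameters mean 20 ha, variance 100 ha²), rounded to the nearest cell and
floored at one cell, and the patch expands by uniform draws from its
unassigned frontier until the target is met or the frontier is exhausted.
Realized areas therefore only *approximately* follow the Gamma — late patches
are squeezed by earlier ones — which is why the distributional checks in the
test-suite target the sampler, not the realized mosaic. Each holding receives
one initial understory age, uniform on the integers 0–70 y (the simulator
advances age in 1-year steps, so integer granularity is natural). Pools of
landscapes are generated once (full scale: 2000) and reused across
evaluations, with per-landscape seeds derived from the pool seed.

## Dynamics under a management regime

A regime has 1–5 groups, each with a clearing interval in [3, 100] years and
a proportion of landowners; 100 encodes "never manage". Owners are assigned
to groups by independent draws with the given proportions (proportions refer
to *counts of landowners*, not area), re-drawn for every replicate landscape —
the rule does not say who complies with which interval.

Implementation uncertainty makes realized intervals Gamma with mean equal to
the prescribed interval and constant shape (base 100), i.e. standard
deviation equal to a tenth of the prescription, growing with the interval.
The sensitivity axis re-parameterizes the model by the variance at the
100-year interval: shape = 100²/V, for V in {1, 5, 10, 50, 100, 500, 1000}.

Three timing decisions are genuinely open and fixed as follows:

* **Per-event redraw.** A fresh Gamma interval is drawn at every clearing
  event, rather than once per owner — ongoing timing noise, not a fixed
  per-owner bias. The long-run clearing rate of an owner prescribed *m* years
  is then exactly 1/*m*, and the fraction of time a holding spends below age
  *a* converges to min(*a*/*m*, 1); both are tested.
* **Time-zero rule.** A holding older than its *prescribed* (mean) interval at
  the start is cleared in year 0; ties (age = interval) also clear. Younger
  holdings first clear in the year their age reaches their *sampled* interval.
* **Year order.** Each year: due owners clear (whole holding, age → 0),
  the per-year summaries are recorded (cleared cells appear at age 0), then
  every cell ages one year. Sampled due-times are continuous; clearing
  happens in the first integer year at or past the due time, and the next due
  time advances from the previous due time (not the integer year), so no
  rounding bias accumulates in the renewal rate.

Biomass regrows along a monomolecular curve B(a) = b_max(1 − e^(−r·a)) with
b_max = 20 000 kg/ha and r = 0.06 y⁻¹, reaching ≈95% of the plateau by age
50 — regrowth is fast early and nearly flat after 50 years. The cited
empirical curve for the study system is not reprinted here; the functional
form and rate are the package's own parameterization (exposed via
`biomass_curve()`), and every optimization objective is invariant to
`b_max`'s absolute scale (cost and age-class areas ignore biomass; skewness
is scale-free; edge contrast scales all solutions equally and is
range-standardized before any cross-objective comparison).

## Objectives

Six objectives, all computed per year and summarized with worst-case annual
values — extremes rather than means, so single years of extreme fire risk are
not averaged away:

* **cost**: mean % of landscape cleared per year, over *all* years (minimize);
* **fuel load**: maximum annual per-hectare mean biomass (minimize);
* **edge contrast**: minimum annual population variance of the absolute
  biomass differences over all unordered adjacent cell pairs (maximize);
* **fuel concentration**: minimum annual population skewness g₁ = m₃/m₂^{3/2}
  of per-cell biomass (maximize; 0 is returned for a zero-variance landscape);
* **mid- / late-successional area**: minimum annual % of cells aged 30–60
  (inclusive) / ≥61 years (maximize).

All objectives except cost discard the first 20 years (burn-in) so the
landscape can adapt to the regime; the simulation itself always starts at
year 0. Internally all six are stored in canonical minimization form
(maximized objectives negated), with an exact bijection back to display form.
Two conventions worth noting: fuel load is the per-hectare *mean*, not the
landscape sum (equivalent up to the fixed area, but the mean is what is
reported); and population (biased) moments are used for both surface metrics,
appropriate for the large cell counts involved and fixed for reproducibility.

Replicate evaluations aggregate with the componentwise **worst case** (the
maximum in canonical form): a regime is as good as its worst replicate
landscape.

## The optimizer

The search is NSGA-II over real-coded genotypes of k intervals ∈ [3, 100] and
k non-negative weights (proportions = normalized weights; an all-zero weight
vector decodes to uniform proportions). Zero-weight groups are representable,
so the effective number of groups can collapse below k during the search.
Strategies k = 1…5 are run separately and pooled afterwards
(`combine_frontiers()`).

Operator choices the problem statement leaves open are fixed at the reference
defaults and exposed as configuration: simulated binary crossover with
probability 0.7 and distribution index 5, bounded polynomial mutation with
per-gene probability 0.2 and index 10, binary tournament selection by
(rank, crowding), and (μ+λ) elitist survival with crowding truncation.
Survivors keep their evaluated objective vectors (no re-evaluation on fresh
landscapes); each evaluation draws its replicate landscapes from the pool
without replacement under a per-evaluation derived seed, so entire runs are
bit-reproducible from one master seed.

Crowding distances use the standard normalized neighbour-gap sum with
infinite boundary values; an objective with zero range across a front
contributes nothing (including no boundary infinities) rather than producing
0/0.

**Hypervolume monitoring.** Convergence is tracked with the hypervolume
indicator, bounded by the componentwise worst value attained in any
generation. In two dimensions an exact sweep is used; with six objectives the
volume is estimated by Monte-Carlo with a fixed sample (10⁵ points at full
scale, 2·10⁴ in the desk preset) shared across generations. The reported
series is computed on the *cumulative nondominated archive* — every solution
found up to each generation — rather than on the evolving population front:
with six objectives and a modest population nearly all individuals are
rank 1, so crowding truncation can momentarily shrink the population front's
dominated region, whereas the archive series is non-decreasing by
construction and makes stabilization easy to read. The population front is
retained separately.

## Post-processing

* **Level diagrams.** Objectives are range-standardized over the frontier
  (best = 0) and weighted 6 (cost), 3 (each biodiversity), 2 (each fire)
  inside a Euclidean distance to the ideal point, so the worst possible
  solution scores √(6² + 2·3² + 3·2²) = √66 ≈ 8.12. The weights equalize the
  three objective *groups* in terms of summed weight; note that inside the
  Euclidean norm the groups' summed squared weights (36/18/12) are not equal —
  the formula is implemented exactly as stated, and this caveat is the
  reason the level-diagram axis should be read as one particular weighting,
  not a canonical scalarization. Whether standardization is taken over a
  single-strategy frontier or the pooled five-strategy frontier is left to
  the caller (`level_scores()` standardizes over whatever table it is given);
  the pooled frontier from `combine_frontiers()` is the recommended input,
  since cross-strategy comparison is the main use.
* **Restriction scenarios.** Built-ins: annual cost within 5% or 10%
  (±0.375 percentage points); each fire objective within the 25% best
  frontier results; mid- and late-successional areas ≥9.9%; and a compromise
  (cost ≤20%, fire objectives within the best 60%, both age classes ≥9%).
  Percentile thresholds use linear-interpolation quantiles over the input
  frontier — the percentile convention is not otherwise pinned down, so it is
  fixed and documented here. Filters are monotone: adding a constraint never
  enlarges the result.
* **Re-simulation.** `compromise_rescan()` implements chosen regimes in
  fresh random landscapes (default 100 simulations) and reports per-year
  means ± SD of all trajectory variables, including the young (<10 y) age
  class.
* **Regime distances.** Each regime becomes a Gaussian-mixture density over
  the interval axis (kernels at the group intervals, sd 5 years, weights =
  proportions; no-management groups sit at 100). Distance = 1 − intersection
  of two densities, computed by trapezoid rule on a fixed grid. The grid
  spans [3, 100] extended by *four* bandwidths ([−17, 120], step 0.1):
  with a three-bandwidth extension a group at interval 3 loses ≈1.4·10⁻³ of
  its mass beyond the grid edge, violating the 10⁻³ normalization tolerance
  the package promises, so the slightly wider grid is used. Densities are
  deliberately not truncated or renormalized at the bounds; identity of
  indiscernibles on this grid holds to the same ≈10⁻³ tail tolerance.
* **PCoA.** Classical scaling (double-centred −½D², eigendecomposition,
  coordinates scaled by √λ), delegated to `stats::cmdscale` behind the
  package surface and verified against an explicit double-centering oracle.
  Negative eigenvalues (the density distance is not exactly Euclidean) are
  dropped from both the coordinates and the variance-explained denominator.

## Sensitivity sweeps

`run_sweep()` repeats the optimization once per level of either axis
(landholding-area pairs 20/100 … 200/10000; maximum variances 1 … 1000),
holding everything else fixed; each level regenerates its own pool (the area
axis requires it; the uncertainty axis does the same for symmetry) with
seeds derived from the base seed by a fixed hash, so levels are independent
but reproducible, and the V = 100 level coincides with the base shape-100
model. `compare_runs()` scenario-filters each level's frontier, pools the
survivors, and embeds their pairwise density distances with PCoA; fewer than
two pooled solutions yields an explicit "skipped" result instead of an
embedding. The full-scale sweep design uses 400 generations and 12
replicates per evaluation.

## What the synthetic landscapes do and do not capture

The generator emulates: fine-grained multi-ownership (mean 20-ha holdings),
contiguous properties, a heterogeneous initial age mosaic, and whole-holding
clearing. It deliberately omits: real cadastral geometry, environmental
heterogeneity (slope, soils, climate) and its effect on succession, fire
ignition and spread (the three fire objectives are structural surrogates),
partial-property treatment, economic revenue, and any behavioural model of
landowners beyond the Gamma timing noise. Passing tests therefore certify
the machinery — distributional recovery, renewal-theory limits, oracle
equivalence of the metrics and of the optimizer's components — on the
idealized generator, not ecological predictions for any real landscape.

## Problem sizes and numerical conventions

The package ships two presets. The `full`-scale preset (180×180 cells, pool
2000, population 800, 400 generations, 24 replicates) defines the full study
conditions. The `desk` preset — 30×30 cells, pool 20, population 40, 30
generations, 4 replicates, three-group strategy — is the size the package
itself uses for its end-to-end checks and examples, chosen so a complete
optimization with hypervolume tracking finishes in minutes on one core while
still exercising every code path. The test-suite's distributional checks use
10⁵ draws (tolerances of three standard errors); the compromise-regime
composition checks use ten 50×50 landscapes over 100 years.

Remaining conventions: Gamma target areas are rounded to whole cells and
floored at 1; ages are integers; the late-successional class ">60 years" is
age ≥ 61; degenerate inputs are defined rather than erroring where a
convention is defensible (zero-variance skewness = 0, single-solution level
scores = 0, all-zero genotype weights = uniform proportions), and rejected
otherwise (empty biomass maps, fewer than three skewness values, horizons
not exceeding the burn-in, non-symmetric distance matrices).

## Known limitations

Frontier compositions of full-scale runs (which strategies dominate, where
the compromise regimes sit) emerge from ~10⁷ landscape-years of simulation
and are not reproducible at desk scale; the package's verifiable anchors are
the distribution- and renewal-theory-level quantities its acceptance script
recomputes. The Monte-Carlo hypervolume at six objectives carries sampling
error (a fixed shared sample keeps the *series* internally consistent); the
exact sweep is available only in two dimensions. And the simulator's yearly
time step means sub-annual timing is invisible: prescriptions differing by
less than a year are effectively identical.
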