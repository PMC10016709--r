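---
title: "Facility location, sizing and growth time for cultivated-resource restoration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Facility location, sizing and growth time for cultivated-resource restoration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefplan)
```

## The planning problem

A restoration program growing a resource on land — the motivating case
is coral fragments settled on tile units in ex-situ aquaculture tanks —
faces three coupled decisions: where to open growth facilities along the
coast, how much floor area each needs, and how long to hold each unit in
the facility before deploying it to the wild. The residence (growth)
time `t` couples everything: units deployed young survive poorly, so
demand for *surviving* units inflates into a much larger production
requirement `X = D / P(t)`; units held long survive better but occupy
floor space and incur operating cost the whole time. `reefplan`
minimizes total annualized cost over facility openings, production
allocation, integer vessel trips and the growth time simultaneously.

## Survival curves

`survival_spec()` defines `P(t)`, the fraction of deployed units alive
one year after deployment, in four parametric forms, each with a scaling
factor `c` and horizontal shift `t0` (years): an increasing concave
*asymptotic* curve `pmax − 1/(c(t−t0) + 1/pmax)` (the base case, with
`c = 25`, `t0 = 0`, `pmax = 0.1` by default), a capped *linear* ramp
`c(t−t0)`, a *logistic* sigmoid `pmax/(1+e^{−c(t−t0)})`, and a
*pseudo-gamma* hump `c(t−t0)e^{−c(t−t0)}` (peak `e^{−1}` at `t0 + 1/c`)
representing units that acclimate to artificial conditions when held too
long. All forms pass through a common truncation to `[0, pmax]`; a
floor `pmin` (default 0, hence inactive) is applied afterwards as a
lower clamp.

Growth times whose survival does not exceed the allowable minimum
`pmin_allow` are *excluded* from optimization rather than evaluated:
near-zero survival implies astronomically large production quantities
and meaningless inner problems. No canonical value for the cutoff
exists, so the default is `1e-4` — small enough that the entire default
grid of the base case (survival 0.0048 at `t = 0.02`) stays feasible,
while a curve that is flat at zero is excluded outright. Excluded grid
points are reported in the solve trace with their exclusion flag, never
skipped silently.

## From reefs to demand clusters

A reef of area `A` km² is idealized as a disc of radius
`r = sqrt(10^6 A / π)` metres. Restoration targets an *atoll*: an
annular band of width `r_width` (default 20 m) centred on the reef
perimeter, with area `2π r·r_width`; reefs with `r ≤ 100` m are small
enough that the whole outward-buffered disc `π(r + r_width/2)²` is
restored instead. Planted density `d_c` (default 1 coral/m²) converts
restored area to an annual demand in corals. (The disc/annulus pair is
continuous in intent; the annulus branch is the geometrically evident
reading of an atoll of given width around the perimeter.)

Reefs are aggregated into demand clusters by a north-to-south sweep:
sorted by latitude descending (ties by longitude, then id), adjacent
reefs join the current cluster while its cumulative *annual* demand
stays within one vessel load `s_c` (432,000 units by default), so a
single trip can serve the whole cluster; a reef alone exceeding `s_c`
becomes a singleton. The sweep reproduces the intended scale — a
default 50-reef field yields ≈ 7 million corals of demand in ≈ 20
clusters. Cluster coordinates are the unweighted mean of member
coordinates (cluster extents are sub-degree, so weighting is
immaterial). Each trip serving a cluster additionally incurs an
intra-cluster allowance modelled as a round-trip star tour from the
centroid, `2 Σ d(centroid, reef)` km: the simplest rule that grows with
the number of member reefs and vanishes for singletons. Greedy sweeping
and the star tour are deliberate simplifications; optimal clustering and
routing are out of scope.

## Costs

Capital is amortized with the capital recovery factor
`CRF = i/(1 − (1+i)^{−n})` (5% p.a. over 25 years gives 0.0709525/yr);
an annuity is the standard engineering-economics convention and
reproduces the intended cost composition of the model's base case.
Little's law sizes facilities: producing `X` units/yr with residence
`t` holds `t·X` units in process, occupying `a·t·X` m² at
`a = 8.05/24000` m²/unit. Annual cost of a plan is then

* fixed capital `CRF · c_f_cap · ΣY_j`,
* variable capital `CRF · c_v_cap · a · t · ΣX_ij`,
* operating `c_f_op · t · ΣX_ij`,
* transport `Σ c_ij · T_ij`, with
  `c_ij = c_d_op (2·haversine(j, i) + allowance_i)`.

Distances are haversine on a 6371-km sphere: vessel legs are modelled
as straight lines, and spherical-versus-ellipsoidal error is orders of
magnitude below the uncertainty in `c_d_op`. Note the per-unit cost
couples to `t` linearly — the dimensional reading consistent with
Little's-law sizing — so the unit production cost is
`u(t) = t(CRF·c_v_cap·a + c_f_op)`.

The seven default candidate sites are approximate public coordinates of
the Queensland port cities (Bundaberg through Cairns); any registry with
`id`, `lat`, `lon` substitutes.

## The two-stage optimizer

With `t` fixed, the problem is a linear MIP over production `X_ij ≥ 0`
(continuous: corals as a flow approximation, rounded only for display),
integer trips `T_ij`, and binary openings `Y_j` — see `build_mip()` for
the four constraint families. Two printed-model subtleties are resolved
deliberately: the minimum-deployment-events constraint is gated as
`t·Σ_i T_ij ≥ Y_j` (an ungated `≥ 1` would forbid ever closing a
facility, contradicting the model's own purpose), and the big-M bound
`M = Σd_i / min P` uses the grid-global minimum included survival, so
one facility can always absorb all production at any included `t`.

The outer stage enumerates the growth-time grid (`0.02` to `1.0` years
in `0.02` steps by default), skips excluded points, solves the inner
MIP at every included point, and keeps the incumbent under *strict*
improvement — ties resolve to the smallest growth time. `t*` is
therefore within half a grid step of the continuous optimum. The
package deliberately discretizes `t`; a global mixed-integer nonlinear
solve is a non-goal.

### Backend and formulation tightening

No functioning LP/MILP library is available to R here, so the inner MIP
is solved by HiGHS through scipy's `milp` interface in a python
subprocess; all grid points of a solve are serialized into one batched
call, so process startup is paid once per solve, not per grid point.
The interface (`milp_model` → `solve`) is a narrow
variables/constraints/bounds structure that any MILP backend could
implement.

Proving optimality at gap 0 with only the weak big-M linking is slow
(fractional `Y_j` make fixed costs nearly free in the LP relaxation, and
140 general-integer trip variables each carry a rounding gap). The
formulation is therefore tightened with reductions that provably keep
the optimum: aggregate trip cuts `Σ_j T_ij ≥ ceil(d_i/(P(t)s_c))`
(implied by capacity, demand and integrality), bounds
`X_ij ≤ d_i/P(t)` and `T_ij ≤ ceil(d_i/(P(t)s_c)) + ceil(1/t)` (excess
production or trips only ever add cost, so some optimum satisfies
them), and `ΣY_j ≥ 1` whenever demand is positive. On a 50-reef,
7-port, ~20-cluster instance the full 50-point grid then solves to
proven optimality in a few seconds on one CPU.

### The enumeration oracle

`brute_force_oracle()` verifies the solver by an independent route.
For fixed `t` and a fixed open set `S`, the unit production cost is
identical across facilities, so production cost is a constant and only
trips and opening costs vary; the remainder is an integer
transportation problem — minimize `Σ c_ij T_ij` subject to row sums
`Σ_j T_ij ≥ ceil(x_i/s_c)` and column sums `Σ_i T_ij ≥ ceil(1/t)` for
`j ∈ S`. The oracle enumerates all `2^|J|` subsets and solves each
transportation problem *exactly* by dynamic programming over columns:
the state is the vector of still-uncovered row needs, and the optimal
top-up of a column to its minimum trip count is analytic (empty trips
go to the column's cheapest row, which also dominates any loaded trip
beyond a row's need — hence allocations bounded by the needs are
exhaustive). Exactness rests on linear trip costs and that argument;
the implementation guards itself to ≤ 6 clusters/facilities and small
trip counts. Across hundreds of random small instances the oracle and
the MIP agree to ~1e-15 relative.

## Synthetic reef fields

The reference reef database behind the motivating case study is
proprietary, so `generate_synthetic_reefs()` provides a synthetic
stand-in: `n_reefs` points uniform over a 142–153°E × 10–25°S band with
lognormal areas (`meanlog = 1.15`, `sdlog = 1`, in km²). The lognormal
parameters were chosen once from the demand arithmetic — an annulus
reef of radius `r` demands `≈ 40πr` corals, so a mean radius near 1.1 km
makes 50 reefs total ≈ 7 million corals/yr — and every default 50-reef
seed lands within the intended `[3e6, 1.5e7]` band with ≈ 20 clusters.
What the generator does *not* emulate: reefs hugging a coastline or
shelf (points are uniform in the box), spatial clustering of real reef
archipelagos, and any correlation between area and position. Tests
passing on synthetic fields therefore exercise the *mechanics*
(clustering, costing, optimization) at realistic scale, not the
geographic conclusions one would draw for a real coastline.

All randomness flows through explicit seeds (`with_seed` save/restores
the global RNG state); no function reads global random state.

## Sensitivity studies

Four scripted sweeps mirror the analyses one runs on such a model:
random reef subsets (facility selection frequency and count
distribution), per-parameter cost scaling by `2^x` (with `x = −Inf`
allowed for a zero parameter, scanning outward from 0 until the
facility set changes), a `pmax` sweep (0.1–1.0), and an 11×11 `c × t0`
grid per survival form, with all-excluded survival grids recorded as
infeasible cells rather than errors. One range needs repair: the
documented linear-form scaling range starts at 0, but `c = 0` makes
survival identically zero (and violates `c > 0`), so the default linear
grid spans `[0.05, 0.5]`. Expected directions — higher fixed capital ⇒
weakly fewer facilities, higher transport cost ⇒ weakly more, cost
non-increasing in `pmax` — are asserted in the test-suite on a fixed
50-reef synthetic instance.

## Numerical choices and limitations

* Grid endpoints: `t_max` is included iff it lies on the arithmetic
  grid within 1e-12; trip/event counts use a tolerant ceiling
  (`ceil(x − 1e-9)`) so `1/0.1` does not round to 11 trips.
* `mip_gap` defaults to 0 (proven optimality) so oracle comparisons are
  exact; set a positive gap or `time_limit` for very large instances.
* Solutions are validated arithmetically outside the solver
  (`check_solution()`), and the cost breakdown recomposes the objective
  to ~1e-9 relative.
* Problem sizes used by the test-suite — 100 random ≤ 4×4 instances for
  oracle equivalence, and one 50-reef/7-port field solved at grid steps
  0.04 (sensitivity directions) and 0.02 (full-scale solve) — keep a
  full run in a few minutes on one CPU.
* Out of scope, deliberately: multi-mode (truck + barge) transport and
  heterogeneous fleets, per-site cost heterogeneity, staged facility
  expansion, carbon accounting, multi-species or environment-dependent
  survival, non-greedy clustering, and fitting survival curves to
  empirical data.
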