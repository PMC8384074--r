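---
title: "Methods: the ecoevosim simulation engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ecoevosim simulation engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ecoevosim simulates the joint dynamics of dispersal, geographic
isolation, divergence, speciation, trait evolution and ecological
regulation on dynamic gridded landscapes. This vignette documents the
model itself, the numerical choices behind it, and the places where the
design was genuinely open and a decision had to be made.

## State and time

The landscape is a fixed grid of sites; each time slice (default
170 kyr) carries per-site temperature and aridity. Temperatures are in
normalized units with an affine anchoring of 0.01 unit to 1 °C, so a
Brownian step of σ = 0.005 corresponds to ±0.5 °C per time step;
aridity lies in [0, 1]. A site is habitable at a slice iff its
environmental values are non-missing (a separate mask may be supplied
and is AND-ed in). Steps count down to 0 at the present, matching a
forward simulation from a deep-time starting point.

A species is a set of populations (site, integer abundance, temperature
optimum `t_opt`) plus a symmetric non-negative divergence matrix over
its occupied sites. Abundance is in whole individuals so that carrying
capacity reduction ("remove individuals until k is reached") is exactly
defined. The genealogy records every species ever created with its
parent, origin and extinction steps and event latitudes, and converts
to an `ape` phylogeny with branch lengths in Myr.

## Connection costs

Costs between habitable sites are shortest paths on the 8-neighbour
(queen) grid graph — queen adjacency avoids axis-aligned artifacts in
reachability. Each hop is weighted by its haversine length (Earth
radius 6371 km, cell-centre coordinates) times a crossing factor:
non-habitable cells are by default twice as difficult to cross as
habitable ones. Because a per-hop factor of the *destination* cell
would make path costs direction-dependent whenever consecutive hop
lengths differ, hops are weighted by the *mean* of the two endpoint
factors; this keeps the cost matrix exactly symmetric and reproduces
the land–water–land doubling (total 3 hops' length instead of 2) when
hop lengths are equal. Whether the distances should be path-based at
all (rather than straight-line with a single multiplier) is itself a
design choice: we use path-based costs so that barriers of different
strengths act through the cells a route actually traverses. Longitude
wrap-around is on for global grids (auto-detected) and off for regional
toys. In local mode, entries beyond a cutoff radius are dropped; the
local matrix is exactly the full matrix with long entries removed.

## The step cycle

Within one step the engine applies, in a fixed order: habitability
update, speciation, dispersal, trait mutation, ecology, observers.
Speciation uses the previous step's positions (it runs before
dispersal), and trait homogenization runs after ecology within the
same step while mutation runs in the evolution slot — splitting the
evolution process this way keeps the abundance weights used by
homogenization consistent with the post-regulation state. Species are
processed in ascending id and sites in ascending id everywhere, and a
single seeded RNG stream is consumed in that documented order, so
identical seed + configuration + landscape gives bit-identical outputs
and observer frequency cannot alter a trajectory (observers are pure).

**Speciation.** Occupied sites are clustered by connected components of
the cost graph thresholded at the species' clustering distance.
Clustering should reflect dispersal capacity, but no unique formula
follows from that requirement; we fix the clustering distance to the
dispersal kernel's median (Weibull: Ψ·(ln 2)^(1/ɸ)), a deterministic
quantity that is not redrawn. Divergence accrues by the per-species
rate between sites in different clusters and decays within clusters;
whether decay should equal accrual is a free choice, and we default to
symmetric bookkeeping (decay = the accrual baseline of 1 per step).
Divergence is tracked at site-pair granularity; a colonist copies the
divergence row of its seeding source, which keeps merges well defined
and reproduces cluster-level behaviour. Splitting builds a graph on
clusters with an edge where the *minimum* cross-pair divergence is
still below the threshold Ϟ; components of that graph become species
(so a chain of mutually compatible clusters never splits). Reaching the
threshold (≥) speciates. The component with the greatest total
abundance keeps the parent's identity (ties to the lowest cluster
label) — no convention for parent retention is canonical, and this rule
is deterministic and biologically sensible (the largest remnant is
"the same species").

**Dispersal.** One kernel draw per (source, vacant habitable target)
pair per step; success iff cost ≤ draw; among successful sources one
colonizer is chosen uniformly. Draw granularity (per pair rather than
per species) was an open choice; per-pair draws make long-shot
colonization probabilities independent across routes. A new colonist
receives round(a_max/2) founder individuals before its first ecology
step and its source's trait value.

**Evolution.** `t_opt` takes independent Normal(0, σ) increments. σ is
a standard deviation: the intended correspondence of the explored range
0.001–0.010 with ±0.1–1 °C of trait change per step only holds for an
SD, so the parameter is treated as one even where a σ² notation is
conventional.

**Ecology.** Suitability is a linear ramp of half-width ω (default 0.1
≃ 10 °C): abundance = round(a_max · max(0, 1 − |t_opt − T|/ω)). One
occasionally sees niche abundance described as *increasing* with the
optimum–temperature distance; that reading contradicts niche logic, so
the decreasing form is used and the functional form is swappable (a
Gaussian alternative is built in). Capacities are k_base at maximum
energy; in the energy-scaled mode
k = round(k_base · (T·(1−aridity))^k_power). The product form for area
energy is the package's own construction, anchored only to the
requirements that capacity rise with temperature, fall with aridity,
and be modulated by k_power. Reduction removes single individuals
uniformly at random until
the site total equals k (the kept individuals are multivariate
hypergeometric), and zero-abundance populations are locally extinct.

**Abort rules.** Runs halt when extant species exceed a global cap or
any site's richness exceeds a local cap (defaults 50 000 and 10 000,
matching the validity filters), with partial outputs flushed.

## Model configurations and exploration

`make_model()` wires five configurations: M1 (null: no ecology, no
evolution, constant divergence), M2 (niche + Brownian evolution), M3
(M2 + temperature-dependent divergence), M4 (M2 + uniform capacity),
M5 (M4 with energy-scaled capacity). M3's rate is
base·(1 + (m−1)·T^d_power) with m = 3 fixed, which satisfies both of
its anchors — a power-law temperature response plus a constant, exactly
3× faster at the warmest sites — though other forms satisfy the same
anchors; this one is the package's choice.

Parameter exploration uses an unscrambled Sobol sequence (Joe–Kuo
direction numbers, implemented in the package and cross-checked against
an independent reference implementation) with the all-zeros first point
skipped; no scrambling keeps sampling reproducible and prefix-stable.
Explored ranges: ɸ ∈ [2, 5], Ψ ∈ [550, 850] km, σ ∈ [0.001, 0.010],
Ϟ ∈ [6, 60], d_power ∈ [2, 6], k_power ∈ [1, 4]. Defaults are the
range midpoints, except Ϟ = 6 — the lower anchor, corresponding to
speciation after ~1 Myr of isolation at 170-kyr steps — chosen so that
desk-scale 100-step runs contain several complete radiation cycles.

## Summary statistics

* `ldg_percent_loss` — band means of richness over absolute latitude,
  divided by their maximum (max-normalization is the package's
  convention), OLS slope × (−100). Bands are not area-weighted.
* `ldg_curve_correlation` — band means divided by habitable-site counts
  (a proxy for land area), scaled to max 1, Pearson-correlated with a
  reference curve.
* `beta_splitting_ml` — Aldous beta-splitting likelihood maximized over
  β ∈ (−2, 10], normalization by explicit summation; topology-only.
* `nltt_difference` — both lineage-through-time curves normalized to
  [0, 1] on both axes (root → present; lineages ÷ final count), then
  ∫|Δ| over the merged step grid.
* `range_size_stats` — octave (log2) bins of range area; the SRD slope
  is OLS of log10(frequency+1) on the bin midpoint. This slope is on a
  log-count scale and is a declared substitute: it is not comparable to
  percentage-scale SRD magnitudes reported in the empirical literature.
* `band_rates` — events per 1-Myr window within/between the tropics
  (boundary 23.45°) and extratropics (to 66.55°).
* `pom_acceptance` — combined verdict over LDG ∈ [1.1, 5.4] %/deg,
  β ∈ [−1.4, −0.3], range-size decrease (5 % tolerance), curve r > 0.4,
  nLTT < 0.15, ≥ 20 extant species.

## Synthetic landscapes and what tests can show

`latitudinal_world()` emulates the structure the case studies assume: a
monotone equator-to-pole temperature gradient (defaults 0.8 to 0.1
normalized units at the grid edge), a subtropical aridity bump (peak
0.5 at 25°), and deep-time dynamics — a cooling trend (default
amplitude 0.1 ≃ 10 °C, the scale of long-term Cenozoic-style cooling)
or an oscillation. `island_ontogeny()` uses a triangular habitable-area
profile peaking mid-sequence (it does not reproduce any geomorphological
model), and `barrier_toy()` is a fixed two-bank world split by a
one-cell river. All generators are pure functions of their arguments.

The default desk world is 20 × 10 cells at 10° resolution (no polar
rows) over 100 steps — small enough for minutes-scale replicate
experiments while keeping five latitude bands for LDG slopes. At this
resolution inter-cell distances (≈ 790–1110 km) exceed the default
clustering distance (≈ 630 km), so populations are effectively always
geographically isolated and radiations are fast and strongly
structured; real 1° landscapes have connected clusters and slower
turnover. Passing tests on these worlds therefore demonstrate the
mechanics and their qualitative consequences (e.g. an emergent poleward
richness decline under energy-limited ecology and its absence under the
null model), not quantitative agreement with empirical data, which
would require reconstructed paleolandscapes and empirical range and
phylogeny compilations that are outside the package's scope.

The replicate experiments in the test-suite and in
`scripts/acceptance.R` use 5–10 seeds per condition and a desk-scale
abort cap of 3000 species (the null model grows without ecological
limits and is halted by the cap by design; its recorded state at the
cap is the state compared).

## Known limitations

* No explicit population genetics, hybridization, evolving dispersal,
  Ornstein–Uhlenbeck traits, or trait-mediated competition.
* The divergence decay rate, parent-identity rule, energy form and
  suitability form are genuinely open design points; the package's
  choices are parameterized or documented above.
* Cost symmetrization (mean of endpoint factors) differs from a strict
  destination-cell weighting whenever consecutive hop lengths differ.
* β-splitting on trees containing simultaneous multi-way radiations
  (zero-length internal edges) treats the arbitrary binary resolution
  as topology, which biases β downward; this is inherent to applying a
  binary-split statistic to burst-like radiations.
* The ML estimator of β is median-centred but mean-upward-skewed on
  trees of ≲100 tips: its search domain is hard-bounded at −2 on the
  left while near-balanced small trees produce large positive ML values
  on the right. Averages of β̂ over replicate small trees therefore sit
  above the generating value even under the true model (we measure a
  mean of ≈ +0.3 at β = 0 with 64 tips); median summaries are the
  appropriate aggregate at desk scale.
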