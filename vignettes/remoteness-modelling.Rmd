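---
title: "Modelling geographic remoteness from emergency obstetric care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling geographic remoteness from emergency obstetric care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Maternal deaths are largely preventable when emergency obstetric care
(EmOC) is reached in time; the usual planning benchmark is that basic
EmOC should be reachable within two hours. In rural districts with
sparse road networks, "how far is the nearest facility" is poorly
captured by network (road-graph) routing, because much of the population
lives away from any road and reaches one on foot. Raster cost-distance
modelling handles this directly: every 50 m cell of the landscape
carries a traversal cost, and accumulated travel time is computed from
every cell to the nearest facility.

`emocaccess` implements this analysis as a reusable pipeline:

1. derive a stream network with Strahler orders from a DEM (streams of
   high order act as travel barriers);
2. assemble a per-scenario cost ("pace") surface from land cover, roads
   burned in on top, and stream barriers;
3. solve multi-source cost distance from the EmOC facilities and
   classify the result into 0–30 / 30–60 / 60–90 / 90–120 / >120 minute
   zones;
4. disaggregate zone-level census population onto built-infrastructure
   cells or mapped dwelling points;
5. compute, per administrative zone and scenario, the **remoteness
   index** — the proportion of the population *strictly more than* 120
   minutes from EmOC — and the number of fertile-aged women it
   represents;
6. relate zone-level maternal mortality ratios (MMR, deaths per 100,000
   live births) to remoteness and season with a Poisson log-link GLM.

Because the original district's geodata are not published, the package
ships a synthetic-landscape generator with known ground truth; every
stage is exercised and tested against it.

## Travel scenarios and the speed table

Four scenarios are modelled: transport mode (ambulance "car" on all
roads vs public "bus" on major roads only) crossed with season (dry vs
wet). Each land-cover or road class carries a speed in km/h
(`default_speed_table()`); pace is its reciprocal,
`pace = 60 / (1000 * v)` minutes per metre. Off-road classes carry
walking speeds (1–4 km/h depending on ground and season); in the bus
scenarios, local roads carry walking speed because buses do not serve
them. One consequence of the shipped table worth knowing: on national
roads in the wet season the bus speed (40 km/h) exceeds the car speed
(25 km/h), so bus travel can locally be *faster* than ambulance travel
there — see "Known behaviour" below.

Streams with Strahler order above 6 are barriers to travel
(`barrier_order_min = 7`). The original rule is stated without seasonal
qualification, so barriers apply in both seasons by default
(`barrier_seasons`); whether a barrier interrupts a road that crosses it
is controlled by `barrier_overrides_roads` (default `TRUE`, consistent
with remoteness in the source setting being attributed to wet-season
flooding rather than to bridged crossings).

## Numerical choices

* **Cost distance.** 8-connectivity; diagonal steps cost
  `sqrt(2) * cellsize`; the edge cost between neighbouring cells is the
  distance times the *mean* of their paces — the standard raster
  cost-distance semantics. The solver is a multi-source Dijkstra
  (C++), with heap ties broken by (time, row-major index) so results
  are bitwise reproducible. Unreachable cells get `Inf` and are
  classified remote: a population that cannot reach care at all is
  remote under the definition.
* **Interval boundaries.** Travel-time zones are closed on the right:
  exactly 120 minutes falls in the 90–120 zone, because "more than two
  hours" is strict. The remoteness index uses the same strict
  inequality.
* **Pit filling.** Priority-flood with an epsilon increment (1e-6 m)
  guarantees a strictly draining surface, hence acyclic D8 routing, in
  one pass. D8 ties are broken by a fixed neighbour enumeration
  (E, SE, S, SW, W, NW, N, NE).
* **Rasterization.** A cell is crossed by a road if the polyline
  intersects its square footprint (supercover traversal), not if it
  passes near the centre; this keeps diagonal roads connected.
  Where classes collide the highest code (fastest road) wins.
* **Population.** Kept as real numbers throughout; rounding to whole
  persons would bias the remoteness proportions. Dwelling points on
  shared cell edges belong to the cell to their south-east (half-open
  footprints), so border assignment is deterministic.
* **GLM.** Fitted by IRLS on the Poisson score equations, log link,
  convergence at `max |delta| < 1e-10` (100-iteration cap), SEs from
  the inverse Fisher information. The remoteness covariate is
  standardized by **two** standard deviations so its coefficient is
  comparable to the binary season covariate (dry = 1, wet = 0); the
  raw-scale coefficients are also reported
  (`b_raw = b_2sd / (2 sd)`).

## The two GLM response modes

The source analysis regresses the MMR itself on remoteness and season
under a Poisson family. Regressing a ×100,000-scaled ratio with Poisson
variance is statistically awkward — the implied dispersion depends on
the number of births — so the package exposes both:

* `response_mode = "mmr"` (default): the literal model. Non-integer
  responses are accepted; the quasi-likelihood score equations are
  solved. Reported SEs assume unit dispersion on the MMR scale and
  should be read comparatively, not as calibrated Poisson SEs
  (a `quasipoisson` dispersion option is available).
* `response_mode = "deaths_offset"`: deaths as the response with offset
  `log(births / 100000)`. Coefficients stay on the log-MMR scale and
  the Poisson SEs are correctly calibrated. Parameter-recovery tests
  use this mode for exactly that reason: with 32 zones × 2 seasons and
  large birth counts, each generating coefficient is recovered within
  3 reported SEs in ≥99% of replicates.

MMR is averaged over years as the mean of yearly ratios (pooled
deaths/births available via `mmr_pooling = "pooled"`); zone-years with
zero births are dropped with a warning.

## What the synthetic generator emulates

`simulate_region()` produces a study region whose statistical shape
mirrors the modelled district: smoothed-noise terrain (Gaussian-filtered
white noise; kernel width scales with `roughness`), a four-class land
cover (forest in valleys, scrub/grass mid-slope, rocky tops), a
three-tier road network (a national spine through uniformly sampled
towns ordered along their first principal axis, provincial branches,
local feeders), nearest-seed administrative zones, facilities on major
roads (default 4 basic + 1 comprehensive), and dwellings placed by
rejection sampling with acceptance probability
`0.02 + 0.98 * exp(-d/decay)` in distance `d` to the nearest road —
density decays with distance to roads, with a small floor so that every
zone acquires at least one infrastructure cell within the bounded
resampling retries. Zone deaths are drawn from the known Poisson model
`deaths ~ Pois(births * exp(b0 + b_r r + b_s s) / 1e5)` and the truth
is recorded for recovery tests.

Defaults for the full pipeline are district-scale: 512 × 512 cells of
50 m (25.6 km across), 32 zones, 1598 dwellings, 5 years of mortality
at 2000 births per zone-year, `b0 = 5.5` (≈245 deaths per 100,000 —
typical of high-mortality settings), `b_r = 1.0`, `b_s = 0.12`. Unit
and property tests run on smaller grids (8–96 cells) and the
monotonicity sweeps on 96-cell grids with 200 m cells, sizes chosen so
the full suite runs in well under a minute of solver time while still
producing non-trivial remoteness.

What the generator does **not** emulate: real drainage networks (the
DEM is smoothed noise, not fluvially carved), supervised land-cover
classification error, road quality variation within a class, and
spatial autocorrelation of mortality beyond what remoteness induces.
Passing tests therefore demonstrate the correctness of the *method* —
solver exactness, conservation, monotonicity, parameter recovery — not
the realism of any particular travel-time map.

## Known behaviour and limitations

* Because the wet-season national-road speeds order car (25) below bus
  (40), the intuitive "bus accessibility ≤ car accessibility" can
  invert by a few tenths of a percentage point of remote share on
  landscapes where remote pockets sit near the national spine. In
  sweep experiments over 50 synthetic landscapes the inversion appeared
  in 3, always below 0.006 in absolute share. The dry-season ordering
  (all bus speeds ≤ car speeds) is a theorem and always holds, as do
  wet ≥ dry for a fixed mode and the rule that adding a facility never
  increases any zone's remoteness.
* Travel time is static: no time-of-day, road-damage persistence, or
  waiting/request time (the delay in *requesting* care is outside the
  geographic model).
* Walking speed is not slope-dependent (no Tobler correction) and
  travel is isotropic.
* The GLM is a fixed-effects Poisson regression; it makes no attempt at
  spatial autocorrelation, zone random effects, or causal adjustment.
* All layers must share one planar metric frame, shape and transform
  exactly; the package performs no reprojection or resampling beyond
  nearest-neighbour semantics implicit in its own rasterization.
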