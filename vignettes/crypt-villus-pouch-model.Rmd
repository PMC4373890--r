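---
title: "The crypt-villus pouch model: methods and parameter choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The crypt-villus pouch model: methods and parameter choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pouchsim)
```

## What the model represents

`pouchsim` is an agent-based model of ileal pouch epithelium at cellular
resolution. The pouch is a cylinder tiled with crypt-villus units; each unit
carries two square prisms — a crypt invagination and a villus projection —
whose four lateral faces are unwrapped into 2D grids. This folded-grid
representation stores only the epithelial *surface*, a small fraction of
what a full 3D voxel lattice would need, while preserving the adjacency that
matters for cell motion and morphogen diffusion.

One timestep is 15 simulated minutes. Each lattice site holds at most one
epithelial cell agent (stem, progenitor, enterocyte, or metaplastic) and a
vector of 18 relative mediator concentrations spanning the morphogen pathway
(Wnt, BMP, Hh, PTEN/PI3K/Akt) and the inflammatory pathway (TLR activation,
NF-kB, TNF-alpha, IFN-gamma, RIP kinase, JAK/STAT3, ROS, IL-6/10/13/15).

## The folded grid

Within one prism, each component is stored as a tube: `rows x W` sites with
`W = 4 * face_width` columns wrapping circularly (faces are contiguous
column ranges). Three closures turn the set of tubes into one connected
surface:

* **Tip and valley caps.** The villus tip and the crypt valley are closed by
  one cap row of `W/2` sites lying along a fold line; cap site `k` joins the
  opposite-face columns `k` and `W-1-k`. The cap line's two end sites have
  degree 3; every other site in the model has degree 4.
* **Inter-unit flats.** The villus base (row 0) connects, column-mirrored,
  to the crypt mouth (top row) of the lattice neighbour unit in each face's
  direction. This realizes the offset alternation of crypts and villi: each
  villus is fed by the four crypts around it. The unit lattice wraps
  circumferentially (cylinder) but not axially.
* **Closed pouch ends.** Where an axial neighbour does not exist (the two
  ends of the pouch, which are anatomically closed), the flat folds back
  onto the same unit with a face-local column mirror. Without this closure
  the boundary conveyor columns would have no crypt feeding them and would
  drain irreversibly — an artifact, not a biological boundary condition.

The neighbour relation is symmetric and degree-bounded by 4 everywhere, and
the whole surface is a single closed fold: diffusion with zero decay
conserves mass to floating tolerance.

The number of faces per prism is fixed at four. The fold rules map each
face onto one of the four unit-lattice directions, so other face counts
would need a different inter-unit topology; we treat this as a structural
assumption rather than a parameter.

## Cell rules

All rules are two-phase (they read the previous sub-phase's state and write
the next) and all stochastic decisions draw from a counter-based RNG keyed
by `(master seed, site, timestep, stream)`, which makes every trajectory a
pure function of configuration and seed.

* **Division.** Stem and progenitor cells divide when their cycle clock
  reaches the cycle length, the local proliferation drive
  `WNT + w_stat3 * STAT3` is at least `theta_wnt`, and an empty neighbour
  site exists (contact inhibition otherwise). The daughter goes to an empty
  neighbour chosen via the site RNG; stem daughters placed in the crypt
  base rows stay stem, all others become progenitors; both clocks reset.
* **Differentiation.** Progenitors become enterocytes when local BMP
  reaches `theta_bmp` or positionally upon entering the villus component.
* **Migration.** Non-stem cells attempt one move per step toward higher
  rank along the crypt-base-to-villus-tip axis into empty sites: a passive
  mitotic-pressure conveyor, not force-based mechanics. Competing moves
  onto one site are resolved by the owner of the destination with a
  deterministic site-RNG tie-break.
* **Shedding.** Enterocytes and metaplastic cells in the top `shed_rows`
  villus rows and the tip cap are removed with probability `p_shed` per
  step — the sink that balances crypt proliferation at homeostasis.
* **Death.** Each agent dies with probability
  `1 - exp(-(a_ros * ROS + a_tnfa * TNFA))`: zero in clean tissue and
  monotone in both mediators.
* **Metaplasia.** Agents in stool-contacted units accumulate
  `TLR_ACT * IP` exposure. When a unit's mean exposure crosses the
  threshold the unit converts: resident enterocytes become metaplastic and
  the unit's villus target height drops linearly with excess exposure to a
  floor (a flatter, colon-like mucosa). Shedding extends down to the target
  height, and the periodic resize check deletes emptied top rows — villus
  shortening is gradual and never removes an occupied row. Conversion is
  irreversible by default (`metaplasia_reversible` switches this), because
  exposure as implemented only accumulates.

## Signaling

Secreted mediators (Wnt, BMP, Hh, TNF-alpha, IFN-gamma, interleukins, ROS)
diffuse on the folded grid with an explicit 5-point stencil and decay
multiplicatively; intracellular mediators (kinases, transcription factors,
receptor activation) have `D = 0`. This split is a biological convention;
the underlying machinery does not depend on it. The network is a signed,
weighted edge list applied synchronously:

    next = clamp0( cur + basal + input
                   + sum(stimulatory w * source)
                   - sum(inhibitory w * source)
                   - lam * cur )

For mediators that diffuse, the decay is taken during the diffusion pass
and the network pass applies reactions only, so no mediator is decayed
twice per step. Acyclic chains therefore have closed-form fixed points
(`w/lam` cascades) that the tests check; the one feedback loop shipped by
default (NF-kB <-> TNF-alpha) has its weights chosen inside the linear
stability region.

Wnt and Hh are emitted at the crypt base (bottom two rows plus the valley
cap), BMP near the villus tip. With the default diffusivities and decays
this yields monotone gradients along the crypt-to-tip axis (Spearman rho of
-1/+1 on per-row means at steady state), which is the calibration target —
none of the rate constants is a measured quantity, and all are exposed in
the configuration. IL-13 and IL-15 connectors ship with zero weight because
their directionality is not pinned down; they are present in the edge table
for users to activate.

`apply_knockout()` models a gene knockout: emission, constitutive
production and every stimulatory edge producing the mediator are zeroed,
and the residual concentration decays naturally. PTEN knockout raises the
PI3K and Akt fixed points (dis-inhibition); Wnt knockout lets the crypt
proliferation drive fall monotonically to its no-Wnt baseline and silences
division.

## The stool surrogate

The fecal stream is modeled as a slow-flowing liquid: the pouch fills over
16 steps (4 hours) and then empties; one parcel of stool enters per step;
a parcel's inflammatory potential follows `IP_t = IP_{t-1} + delta_IP`
exactly, so stasis makes stool more inflammatory. No fluid dynamics is
attempted — only epithelial contact matters. Contacted units receive TLR
activation input proportional to the mean IP of resident parcels.

Filling proceeds from the terminal (distal) end by default, a
gravity/stasis surrogate: terminal units are contacted for more of the
cycle and during its late, high-IP part, so cumulative TLR drive is
monotone non-increasing from terminal to proximal. This is the generative
mechanism of the distal-dominant metaplasia gradient, and switching
`fill_direction` to `proximal_first` reverses the gradient — a mechanism
check used in the tests. IP accumulates per parcel by default; a pouch-wide
scalar mode is available (`per_parcel = FALSE`) since the recurrence does
not itself carry a spatial index.

`calibrate_delta_ip()` bisects the IP increment until the terminal-quartile
metaplastic fraction reaches a target, mirroring how the stool's
inflammatory potential is calibrated to the point where metaplasia is
induced.

## Congruent sections and exact equivalence

For parallel execution the unit lattice is tiled into near-equal
rectangular blocks of units (congruent sections), one per logical worker.
Every grid crossing a block boundary is extended by exactly one cell: the
ghost layer is precisely the set of foreign neighbours of owned sites, and
it is refreshed by copying from owners before any cross-boundary read.
Workers are realized as sequential sub-domain sweeps inside one process;
the exchange plan and the access guard carry the contract, not the
transport.

Three design rules make a run on P workers bit-identical to a serial run:

1. **Two-phase updates everywhere**, so iteration order cannot leak into
   results.
2. **Counter-based RNG** keyed by stable site coordinates, so a deviate
   never depends on worker layout.
3. **Owner-resolves conflicts**: an empty site's owner picks the winning
   division placement or migration move among the candidates in its one-cell
   neighbourhood, with a site-RNG tie-break. Cross-boundary outcomes are
   communicated back through an accepted-source field that lives within the
   ghost layer, so no rule ever reads more than one cell from an owned site
   (`check_partition_invariants()` enforces this, and runs every step in
   debug mode).

The strongest test in the suite runs the same scenario with 1, 2 and 4
workers and requires byte-identical state dumps and time series.

## Parameter defaults and why

| parameter | default | units | rationale |
|---|---|---|---|
| template | villus 50, crypt 12 rows, face width 6 | rows/cols | full-occupancy villus:crypt site ratio 4.04, so the homeostatic population ratio sits at the histological ~4:1 |
| cap rows | 1 | rows | simplest closed fold |
| cell diameter | 10 | um | rendering only; no rule depends on it |
| `cycle_len_stem` | 96 | steps (24 h) | physiological order |
| `cycle_len_progenitor` | 48 | steps (12 h) | transit-amplifying cells cycle faster |
| `theta_wnt` | 0.2 | rel. conc. | places the proliferative zone in the lower half of the crypt under the default Wnt gradient |
| `theta_bmp` | 0.5 | rel. conc. | differentiation completes near the villus entry |
| `p_shed` | 0.012 | 1/step | see below |
| `stem_rows` | 3 | rows | stem compartment = crypt base rows + valley cap |
| `shed_rows` | 2 | rows | extrusion zone at the tip |
| `death_a_ros`, `death_a_tnfa` | 0.004 | 1/(conc. step) | sub-1%/step death at typical inflammatory tone; ulceration requires a bolus |
| `delta_ip` | 0.05 | IP/step | terminal-quartile metaplasia within ~100 cycles at desk scale |
| `tlr_gain` | 0.5 | TLR input per IP | keeps inflammatory tone below the denudation regime |
| `metaplasia_exposure_threshold` | 3 | exposure | crossed only under sustained distal contact |
| `fill_steps` | 16 | steps | 4 h at 15 min/step |

The shedding probability deserves a note. Tissue throughput is
supply-limited: each crypt can export at most roughly one cell per mouth
column per stem cycle when the villus is draining (progenitors transit too
fast to divide), and substantially more when the villus is full and
progenitors are jammed inside the crypt. Shedding demand
(`p_shed x shed-zone sites`) must stay below the jammed-regime supply or
the tissue collapses to a sparse state. With the default template the
balance point is near `p_shed = 0.02`; the default 0.012 leaves a safety
margin while keeping villus occupancy (and hence the 4:1 ratio) high. Small
toy geometries used in tests have few mouth columns and therefore a low
supply floor; tests that need sustained regeneration on toys shorten the
cycle lengths instead of touching the shipped defaults.

## Numerical choices

* Explicit Euler stencil with the `4 D <= 1` stability guard (also
  preserves non-negativity); one stencil step per 15-minute model step.
* Missing neighbours (only the cap-line ends) contribute the centre value:
  zero-flux.
* The network update clamps at zero only where an inhibitory edge exists;
  elsewhere non-negativity is structural.
* Placement conflicts are ordered by `(destination, tie-break deviate,
  site key)` — fully deterministic even in the measure-zero case of equal
  deviates.
* Shrink requests are clamped to one row above the highest occupied row
  and logged; cap rows re-attach at the new height and keep their payload.
* CSV writers use fixed formatting so that a (config, seed) pair determines
  every output byte.
* Cycle clocks are initialized staggered (site key modulo cycle length) so
  the initial tissue does not divide in lockstep.

## What the simulations do and do not show

Everything in this package runs on synthetic tissue generated by the model
itself; there is no external data. The homeostasis runs used for the
steady-state checks are 8x8-unit lattices (~97,000 sites, about 10^5
agents) run for 2000 steps with three seeds; the pouchitis gradient runs
use a 10x3-unit lattice with a reduced unit template, standing in for runs
that are orders of magnitude larger. The anatomic 3.5 cm x 6 cm pouch
(219 x 120 units, ~40 million sites) is constructible for size accounting
and configuration echo, but the dynamics here are exercised at desk scale.
Consequences: passing tests demonstrate internal consistency (homeostasis,
gradients, wound closure, the distal-dominant metaplasia gradient and its
mechanism), not calibration against histology beyond the 4:1 population
ratio; finite-size effects at unit counts this small (especially the closed
axial ends) are larger than they would be at anatomic scale.

Out of scope by design: adaptive immunity and T-cell lineages, microbial
population dynamics, fluid dynamics of stool, force-based cell mechanics,
goblet/Paneth and other secretory lineages, dynamic load balancing, and
real message-passing transport (the decomposition contract is exercised
with logical workers).
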