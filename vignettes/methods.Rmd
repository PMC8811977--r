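---
title: "forestflux: model, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{forestflux: model, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

forestflux implements a gain–loss (stock-flow) forest carbon budget: the
total ecosystem carbon (TEC) of each grid cell is partitioned into 14
pools, and the model tracks the explicit annual fluxes between them rather
than differencing inventories. The five live pools are foliage,
merchantable stem, other wood, coarse root and fine root; the nine dead
organic matter (DOM) pools are snag stems, snag branches, aboveground
medium (down deadwood), aboveground fast/very fast (litter), aboveground
slow, belowground fast/very fast, and belowground slow (soil).

The annual base step applies flows in a fixed order chosen to match the
convention of carbon-budget models in this family:

1. snag fall (SnagStem → AbovegroundMedium, SnagBranch → AbovegroundFast);
2. decay/emission of snags and down deadwood;
3. emission from the belowground slow (soil) pool;
4. live → DOM biomass turnover;
5. decay/emission of the fast and very fast pools;
6. emission from aboveground slow;
7. transfer aboveground slow → belowground slow;
8. growth of live pools.

The ordering is load-bearing: turnover (step 4) uses pre-growth stocks, so
permuting steps 4 and 8 changes the DOM inputs at every age. A regression
test pins the full 8-step order against an independently written scalar
oracle.

**Growth.** Merchantable volume by age follows the Von Bertalanffy curve
$y = a(1 - e^{-b\,\mathrm{age}})^3$ with per-species $a$ (asymptote,
m³/ha) and $b$ (1/yr) from the packaged 28-species table, which also
carries each type-group's range mean annual temperature and mean historical
fire return interval (MRI). A deterministic reference simulation expands
volume to the five live components and derives the NPP schedule
$NPP(a) = \sum_i [S_i(a) - S_i(a-1)] + \sum_i S_i(a-1)\,T_i$ and
allocation proportions $pNPP_i(a) = (G_i + S_i(a-1) T_i)/NPP(a)$. By
construction the engine's growth step exactly regrows the reference live
stocks (round-trip identity, tested to 1e-6 relative).

**Decay.** Each DOM pool decays at
$EDR = BDR \cdot e^{(T - T_{ref})\ln(Q_{10}) \cdot 0.1}$ with
$T_{ref} = 10\,°C$; $Q_{10} = 2.65$ for the aboveground very fast and
aboveground slow pools and $2.00$ for all others — deliberately including
the belowground slow (soil) pool, reflecting evidence for a substantial
temperature sensitivity of soil decomposition. A proportion `p_air` of
each decay flux is emitted to the atmosphere (heterotrophic respiration);
the remainder moves to the slow pool of the same stratum.

**Climate multipliers.** Growth is scaled per cell-year by the anomaly of
a Miami-type climate NPP estimate,
$NPP_t = \min[f(MAP), f(MAT)]$ with
$f(MAP) = 0.551\,MAP^{1.055}/e^{0.000306\,MAP}$ and
$f(MAT) = 2540/(1 + e^{1.584 - 0.0622\,MAT})$, divided by the same
quantity computed from 30-year normals — the normals are run through the
identical pipeline, so units cancel and the multiplier is exactly 1 when
climate equals normals. Decay is scaled by
$DM = Q_{10}^{(T_{mean}-T_{norm})/10}$ with the same fast/slow Q10
mapping as EDR.

**Spin-up and initialization.** DOM pools start from zero at age zero and
run for 3000 years with stand-replacing wildfire applied deterministically
every MRI years. At the end, the mature stand is disturbed once by
high-severity fire and once by clearcut, and each post-disturbance stand
is run 300 more years to produce the two stock-by-age ("state attribute")
tables. Landscape cells are initialized by (species, last disturbance,
age) lookup, ages clamped to 300.

**Landscape dynamics.** The STSM schedules transitions by annual
probability, target area (sampling without replacement, optionally
weighted by a 3×3 like-neighbour kernel), or exogenous event masks (fire
perimeters). Burned cells draw severity from a per-stratum multinomial
split. High-severity fire converts forest to a distinct post-fire
shrubland class that remembers its originating species and recovers to
forest with annual probability 0.064; medium/low severity keep class and
age. Clearcut resets age to zero; selection harvest does not. Insect
transitions cause live→DOM mortality only. Urbanization and agricultural
expansion emit and export part of the live carbon, move the rest to DOM,
and freeze the cell (see Limitations).

**Accounting.** NEP = NPP − Rh; NBP = NEP − combustion − harvest export,
positive = sink; land-conversion removals are ledgered in the transition
year. The driver enforces ΔTEC = NBP to 1e-9 relative every year and
aborts on violation.

## Parameters

| Parameter | Units | Default | Notes |
|---|---|---|---|
| a, b, range temperature, MRI | m³/ha, 1/yr, °C, yr | packaged, per species | inventory-derived growth/regime table |
| expansion factors | t biomass per m³ | softwood/hardwood sets | **placeholder**, override for science use |
| carbon fraction | – | 0.5 | single scalar per species |
| live turnover T | 1/yr | foliage 0.10 (hardwood 0.95), stem 0.0045, other wood 0.04, coarse root 0.02, fine root 0.64 | **placeholder** CBM-style values |
| snag fall | 1/yr | stem 0.032, branch 0.10 | |
| BDR | 1/yr @10 °C | very fast 0.355/0.50, fast 0.1435, medium 0.0374, snags 0.0187/0.0718, AG slow 0.015, BG slow 0.005 | **placeholder**; see below |
| p_air | – | 0.83 (slow pools 1.0) | partitions Rh vs slow-pool build-up |
| AG→BG slow transfer | 1/yr | 0.006 | |
| Q10 | – | 2.65 fast / 2.00 others | fixed mapping, overridable per pool |
| severity split | – | 0.30/0.35/0.35 | per stratum |
| recovery probability | 1/yr | 0.064 | post-fire shrub → forest |
| disturbance matrices | proportions | packaged CSV | **placeholder** flow proportions |

The belowground slow BDR (0.005/yr, a ~200-year soil turnover time at
10 °C) was chosen once, a priori, from the soil-carbon turnover literature
range together with the requirement of the stated experimental design that
a 3000-year spin-up reach steady state across the packaged species'
temperature range (coldest group 2.47 °C, giving an e-folding tail of
~1.4e-4 over 3000 years). It was not tuned against any test result.
Parameters marked **placeholder** are plausible defaults shipped so the
package runs end-to-end; the upstream databases they stand in for are out
of scope, and serious applications must supply their own CSVs (all
readers accept a `path`).

## The synthetic world

The fixture generator emulates the *structure* of the real inputs — a
co-registered state-class/age/last-disturbance grid, annual temperature
and precipitation grids around normals with optional warming trend, and
annual fire-perimeter masks — as pure functions of a spec and a seed. The
default demo is a 100×100 grid (1-km cells, 100 ha), four species spanning
softwoods and hardwoods, uniform ages 0–150, 10% non-forest, 0.5%/yr
burned fraction, 0.5%/yr clearcut and 0.2%/yr selection harvest — rates
of the order of magnitude of recent U.S. forest statistics. What it does
*not* emulate: spatial autocorrelation of real landscapes, realistic fire
shapes/spread, species-climate co-location, or ownership patterns. A green
test therefore establishes the correctness of the mechanics and
accounting, not the realism of any national-scale number.

## Numerical choices

- Integer age grid 0–300; older stands use the age-300 schedule row.
- pNPP where NPP = 0 carries forward the last positive-NPP age; age 0
  uses the first positive age (division-by-zero guard in the printed
  formula).
- Selection minimum age = ceiling of half the clearcut age (conservative
  rounding; the convention is otherwise unspecified).
- "Peak merchantable volume" for the 60% harvest threshold is the age-300
  maximum, not the asymptote; the difference is negligible for the
  packaged b values.
- Effective outflow proportions (EDR × DM) are capped at 1; capping is
  counted in the ledger (`clipped`) and surfaced once per run, never
  silent, and no pool can go negative.
- Disturbance flows are computed simultaneously from the pre-transition
  state; source-pool outflows are removed as totals so that a fully
  vacated pool is exactly zero (no floating-point residue).
- NPP anomalies are not clamped; the outflow cap is the only guard.
- Fires during spin-up occur at exact MRI multiples (stochastic intervals
  would defeat reproducibility; a seeded stochastic mode exists). The
  stand state just before the final fire seeds both state attribute
  tables.
- Spin-up and reference runs use the species' range mean temperature with
  multipliers of 1; per-cell climate applies only after initialization.
- All stochastic operations take explicit seeds derived from one master
  seed by a documented splitting rule (`derive_seed`).
- Nodata climate cells get multipliers of 1 and are counted.

## Design decisions taken where the design was open

- Slow pools emit 100% of decayed carbon (`p_air = 1`): a slow pool
  transferring to itself is a no-op, and routing soil decay to litter
  would invert the pool hierarchy.
- Turnover destinations (foliage→AG very fast, stem→snag stem, other
  wood→snag branch, coarse root→BG fast, fine root→BG very fast) are code
  constants rather than CSV columns; they define the pool topology, and a
  wrong destination is better caught in review than in data.
- Post-fire shrubland remembers its species in the landscape's species
  vector; recovery restores the exact prior type-group.
- Medium/low-severity fire keeps forest age and resets only
  time-since-transition.
- Converted cells (urbanization/agriculture) keep their residual DOM but
  stop all dynamics ("frozen"): removals are ledgered once, ΔTEC = NBP
  stays exact, and no post-conversion decay is claimed that the model
  cannot attribute.
- Grids are plain matrices with ESRI ASCII text I/O and configs are JSON:
  the deployment target has no GIS stack, and cell areas come from
  configuration, never from map projection.

## Limitations

- Harvested-wood-product fate, CH4/CO speciation of combustion, CO2
  fertilization, and lateral aquatic fluxes are out of scope.
- Frozen conversion cells do not respire; landscapes with heavy
  urbanization will understate Rh slightly.
- Insect/drought transitions run only where event masks are supplied; no
  projection mode.
- The shipped flow parameters are placeholders (above); absolute pool
  magnitudes from the defaults are illustrative only.
- Single-threaded; the demo scale (10⁴ cells × decades) runs in seconds,
  but continental grids would need tiling.
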