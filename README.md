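# forestflux

Spatially explicit, desk-scale simulation of forest ecosystem carbon using
the **gain–loss (stock-flow) method**: instead of differencing successive
inventories, the model tracks explicit annual carbon fluxes between 14
pools in every grid cell — five live pools (foliage, merchantable stem,
other wood, coarse roots, fine roots) and nine dead organic matter (DOM)
pools covering snags, down deadwood, litter and soil, named by decay speed
and position (e.g. *Aboveground Very Fast*, *Belowground Slow*).

It is aimed at carbon modellers and landscape ecologists who want a
transparent, fully scriptable stand-to-landscape carbon budget engine with
a state-and-transition model (STSM) of land-use change and disturbance on
top: wildfire with stochastic severity, clearcut and selection harvest,
insect mortality, urbanization, agricultural expansion, post-fire
recovery and reforestation scenarios.

## The model in brief

- **Growth.** Merchantable stem volume follows the Von Bertalanffy curve
  *y = a(1 − e^(−b·age))³* (m³/ha); biomass expansion factors and a carbon
  fraction convert volume to carbon in the five live pools. A reference
  stand simulation turns this into a net-primary-productivity schedule
  *NPP(a) = Σ G + Σ S(a−1)·T* (net growth plus biomass turnover) with
  allocation proportions *pNPP = (G + S·T)/NPP* per live pool.
- **Decay.** Each DOM pool has a base decay rate (BDR) at a 10 °C
  reference; the effective rate is *EDR = BDR·e^((T−T_ref)·ln(Q10)·0.1)*
  with Q10 = 2.65 for the fast pools (Aboveground Very Fast, Aboveground
  Slow) and 2.00 for all others, including the belowground slow (soil)
  pool. A proportion of each decay flux is emitted as heterotrophic
  respiration (Rh); the rest moves to the same-stratum slow pool.
- **Climate.** Annual growth is scaled by an NPP anomaly
  *NPP_anom = min[f(MAP), f(MAT)] / μNPP(normals)* with
  *f(MAP) = 0.551·MAP^1.055 / e^(0.000306·MAP)* and
  *f(MAT) = 2540 / (1 + e^(1.584 − 0.0622·MAT))*; decay is scaled by
  *DM = Q10^((T_mean − T_norm)/10)*.
- **Spin-up.** DOM pools start at zero and are spun up for 3000 years with
  stand-replacing wildfire at each species' mean fire return interval;
  fire- and clearcut-initialized stock-by-age tables then initialize
  landscape carbon.
- **Accounting.** NEP = NPP − Rh; NBP = NEP − combustion − harvest export
  (positive NBP = sink); the model enforces ΔTEC = NBP to 1e-9 relative
  every timestep.

Fluxes are applied in a fixed 8-step annual order (snag fall; deadwood
decay; soil emission; biomass turnover; fast-pool decay; aboveground-slow
emission and transfer; growth), with disturbance-triggered flows applied
at the end of each timestep from transition-specific proportional flow
matrices.

## Worked example

```r
library(forestflux)
params <- load_parameters()   # packaged species/flow/disturbance tables

# Douglas-fir growth curve (a = 597.10 m3/ha, b = 0.03/yr)
df <- params$species[params$species$species_name == "Forest: Douglas-fir Group", ]
round(merchantable_volume(df, c(50, 100, 300)), 1)
#> [1] 280.0 512.3 596.9          # m3/ha, approaching the asymptote
min_harvest_age(df)
#> $clearcut_age  [1] 62          # first age reaching 60% of peak volume
#> $selection_age [1] 31

# 3000-year DOM spin-up (fire every 300 years) + stock-by-age tables
tabs <- build_state_attribute_tables("Forest: Douglas-fir Group", params)
round(sum(tabs$fire$stocks[101, ]), 1)
#> [1] 381.2                      # tons C/ha total at age 100 after fire

# a 50 x 50 synthetic landscape, 10 years with fire + harvest + climate
spec <- fixture_spec(nrow = 50, ncol = 50, seed = 42)
ls  <- initialize_landscape(make_landscape(spec),
                            tt <- build_all_tables(params, spec$species))
res <- run_scenario(ls, params, tt,
                    scenario_config(years = 10, clearcut_fraction = 0.005,
                                    selection_fraction = 0.002, seed = 1),
                    climate = make_climate(spec, 10),
                    fire_events = make_fire_events(spec, 10, ls))
round(res$annual[1:3, c("year", "npp", "rh", "nep", "combustion", "harvest", "nbp")], 1)
#>   year      npp       rh     nep combustion harvest      nbp
#> 1    1 692577.0 627478.6 65098.4    23342.1 39889.5   1866.7
#> 2    2 695014.0 625920.3 69093.7    61077.7 41981.1 -33965.0
#> 3    3 692041.1 625908.4 66132.7    13791.8 49693.6   2647.3
signif(aggregate_outputs(res)$mean_annual, 3)
#>   npp_tg_c rh_tg_c nep_tg_c combustion_tg_c harvest_tg_c nbp_tg_c
#> 1    0.694   0.625   0.0687          0.0214       0.0459  0.00135
```

Units: per-cell stocks are tons C/ha; the `annual`/`accounts` tables are
tons C (cell area × density), and `aggregate_outputs()` adds Tg C views.
Year 2 above shows a fire year flipping the landscape from a small sink
(positive NBP) to a source. `carbon_to_co2(73.5)` → `269.5` converts a
carbon mass to CO2 via 44/12.

## Command line

```sh
Rscript inst/cli/forestflux.R fixtures --outdir demo --seed 1   # write a demo dir
Rscript inst/cli/forestflux.R spinup   --species "Forest: Douglas-fir Group" --outdir out
Rscript inst/cli/forestflux.R simulate --config demo/scenario.json --outdir out
Rscript inst/cli/forestflux.R verify   --species "Forest: Douglas-fir Group"
```

See `vignettes/methods.Rmd` for the model description, parameter
defaults (and which of them are placeholders you must override for
science use), numerical choices and known limitations.
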