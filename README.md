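# physiodrought

Drought changes what vegetation *is* (structure: leaf area, biomass) and
what vegetation *does* (physiology: stomatal closure, downregulated
photosynthesis). Remote-sensing streams mix the two. `physiodrought` is an
R package for ecohydrologists and remote-sensing scientists that isolates
the physiological component of drought responses in three gridded
observation streams — relative solar-induced fluorescence (SIFrel),
evapotranspiration derived from midday land-surface temperature, and the
midday/midnight vegetation-optical-depth ratio — and attributes its spatial
pattern to climate and vegetation drivers.

## What it implements

**Two-model decomposition.** Per grid cell, a bagged-tree model predicts
the target anomaly from the LAI anomaly alone, with 24-step block
leave-out so drought periods are predicted by models that never saw them
(the structural component); a second model on LAI plus hydro-meteorological
anomalies, trained on the whole growing season and screened by out-of-bag
R², gives the full prediction. The physiological component is

    physiological(t) = full(t) − structural(t)

exactly, at every step. Multiple-linear-regression and exact
interventional-Shapley variants of the decomposition are included.

**Surface energy balance (ET from LST).** Daily latent heat flux from the
midday surface–air temperature gradient:

    ET = (1 − Cp·ρ·(LSTmax − Tamax)·(1.4·ga) / (1.4·Rsmax)) · Rnmean

with Cp = 1005 J kg⁻¹ K⁻¹, ρ = 1.23 kg m⁻³ and a cover-weighted
aerodynamic conductance ga (0.06 / 0.0345 / 0.002 m s⁻¹ for tree / short
vegetation / soil), plus its exact algebraic inverse.

**Drought machinery.** Growing-season masking (Ta > 5 °C and monthly SIF
climatology > 0.2 mW m⁻² sr⁻¹ nm⁻¹), severe-cell selection by ranking 40
years of monthly soil-moisture yearly minima, 8-daily peak detection,
development/recovery durations, 24-step trajectories, and a −1.5 SD
severity variant.

**Preprocessing.** 16-day moving-window aggregation to 8-daily with a 20%
gap rule, monthly climatology + LOWESS trend removal (reconstruction
identity exact), 7/21/72-cm weighted 1-m soil moisture, cover/irrigation/
VOD-consistency masks, aridity index.

**Statistics.** Composite trajectories with every-third-cell spatial
standard errors, aridity-class bin medians, physiological/total anomaly
ratios, and seasonal bootstrap significance (1000 members, ±16 days,
95% interval, 60% bin-dot rule).

**Synthetic generator with known truth.** Gridded met + observation
streams with a bucket soil-moisture model, an imposed drought year, a
lagged structural (LAI) response and a latent physiological factor
φ ∈ (0, 1] imprinted multiplicatively on SIF and ET and through the
day/night asymmetry on VOD — so every stage of the pipeline is testable
against ground truth without downloads.

## Worked example

```r
library(physiodrought)

cfg <- sim_config(n_cells = 40, seed = 42)   # 5 years, drought in 2020
ds  <- simulate_dataset(cfg)

pl <- run_decomposition_pipeline(ds, "sifrel")
print(pl$decomp)
#> <decomposition_result> sifrel_anom: 40 cells (40 kept), median OOB R2 0.783

ev <- pl$events
sum(ev$selected[cfg$drought_cells])          # all 20 imposed droughts found
#> [1] 20

rs <- recovery_statistics(pl$decomp, pl$events, ds$truth$imprint$sifrel,
                          cells = cfg$drought_cells)
round(rs$median_r, 3)                        # recovery of the latent signal
#> [1] 0.921

ptr <- physio_total_ratio(pl$decomp, ev$peak_step)
round(ptr$ratio, 3)                          # physiological share of the response
#> [1] 0.906
```

Reading the output: all 40 cells pass the out-of-bag screening (median
OOB R² 0.78); every cell with an imposed precipitation suppression is
recovered by the 40-year ranking rule; the recovered physiological series
correlates with the true latent imprint at a median per-cell r of 0.92
inside drought windows; and roughly 90% of the drought-window SIFrel
anomaly is attributed to physiology rather than canopy-structure change
under these generator settings.

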