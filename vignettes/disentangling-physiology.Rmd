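---
title: "Disentangling structural and physiological vegetation drought responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling structural and physiological vegetation drought responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physiodrought)
```

## The problem

When drought hits an ecosystem, the remote-sensing signal changes for two
distinct reasons. *Structural* change — leaves are shed, canopies thin, leaf
area index (LAI) declines — alters every optical and microwave observable.
*Physiological* change — stomatal closure, downregulation of photosynthesis —
alters fluxes and fluorescence without necessarily changing canopy
structure, and it happens faster. Separating the two matters because only
the physiological part tells us how plants regulate water use under stress.

`physiodrought` implements a complete, testable pipeline for this
separation, working from three observation streams whose combination is
sensitive to physiology:

* **relative SIF** (solar-induced chlorophyll fluorescence normalised by
  near-infrared radiance), a proxy for photosynthetic activity;
* **ET** (evapotranspiration as latent heat flux, W m⁻²), estimated from
  midday land-surface temperature through a simplified surface energy
  balance;
* the **VOD ratio** (midday over midnight vegetation optical depth), whose
  day–night asymmetry carries stomatal-regulation information because
  midday canopy water content drops when transpiration outpaces root-zone
  supply while midnight VOD tracks the refilled state.

## The two-model decomposition

For each grid cell and stream, two bagged-decision-tree (random-forest)
regressions are fitted to growing-season anomalies:

1. a **structure-only model** predicting the target anomaly from the LAI
   anomaly alone, with scheduled *block leave-out*: the record is tiled
   into 24-step (192-day) blocks from its first step, and each block is
   predicted by an ensemble trained with that block excluded. Drought
   periods are therefore predicted by models that never saw them, from
   structure–target relations learnt in other periods;
2. a **full model** on LAI plus hydro-meteorological anomalies (air
   temperature, shortwave radiation, VPD, 1-m soil moisture,
   precipitation), trained on the whole growing season. Its out-of-bag
   R² screens cells: cells at or below the configured threshold
   (0 by default; 0.1 and 0.2 as stricter variants) are not interpreted.

The physiological component is the difference `full − structural`, exactly,
at every step — an identity the code maintains by construction and the test
suite asserts at 1e-12. Two variant decompositions are provided: an
ordinary-least-squares version in which the physiological part is the sum
of the fitted met terms, and a Shapley version in which it is the sum of
exact interventional Shapley contributions of the met predictors of the
full model (the efficiency axiom — base value plus contributions equals the
prediction — holds by construction of the exact subset enumeration).

The asymmetry between the two models (leave-out for structure, whole-record
training for the full model) follows the method's published description;
a configuration toggle applies leave-out to the full model too, but doing
so removes the drought period from the met–target relation entirely and
collapses the recovered signal, so the asymmetric default stands.

## The surface energy balance

Daily ET is obtained from the midday surface–air temperature gradient as

$$ET = \left(1 - \frac{C_p\,\rho\,(LST_{max} - Ta_{max})\,(1.4\,g_a)}{1.4\,Rs_{max}}\right) Rn_{mean}$$

with $C_p = 1005$ J kg⁻¹ K⁻¹, $\rho = 1.23$ kg m⁻³, $g_a$ a cover-weighted
aerodynamic conductance (0.06 m s⁻¹ tree, 0.0345 m s⁻¹ short vegetation,
0.002 m s⁻¹ bare soil), $Rs_{max}$ the maximum hourly net shortwave and
$Rn_{mean}$ the daily mean net radiation. The diurnal-amplitude factor 1.4
appears on both $g_a$ and $Rs_{max}$ as printed and cancels algebraically;
it is kept explicit (and exposed as `amp_factor`) for sensitivity checks.
Negative ET over strongly heated surfaces is clipped at zero and the
clipping counted, since the model omits ground heat flux and energy-balance
closure. The exact algebraic inverse (`invert_lst()`) lets the synthetic
generator encode a known ET into an LST stream; forward and inverse
round-trip to 1e-9 over the valid domain ($0 < ET \le Rn$, $Rs_{max} > 0$).

## Drought detection

Droughts are anchored in soil moisture. A cell qualifies as severely
drought-affected when the lowest of its 40 yearly minima of monthly
growing-season soil moisture falls inside the study window (rank ties go to
the later year); the peak is then the minimum 8-daily soil moisture over
in-season steps (earliest step on ties), with an anomaly-based variant.
Development and recovery durations count consecutive negative
soil-moisture-anomaly steps walking back and forward from the peak;
trajectories are the 24 steps `peak − 12 … peak + 11` (the peak as the 13th
element, so the displayed window is exactly 24 steps ≈ 3 months per side),
and a stream enters composites only with ≥ 20 valid steps. A stricter
severity variant requires the peak to lie 1.5 standard deviations below the
40-year seasonal (calendar-month) mean.

## Anomaly extraction

All series are reduced to anomalies in a fixed order: subtract the monthly
mean seasonal cycle (each 8-day step assigned to the month of its centre
date — unbiased for windows straddling month edges), then subtract a
locally weighted (LOWESS) trend of the deseasonalized residual with
neighbourhood fraction 0.4. The reconstruction identity
`raw = climatology + trend + anomaly` is exact wherever data exist. Daily
streams are first aggregated to 8-daily using a 16-day moving window with
8-day overlap; windows with more than 20% missing days become missing, and
the same ≥ 80%-valid rule is applied to every windowed statistic in the
package for consistency. Whether deseasonalizing precedes detrending is a
genuine ambiguity; the climatology-first order is fixed here because the
trend estimate is otherwise dominated by the seasonal cycle at this record
length. One-metre soil moisture is the 7/21/72 cm thickness-weighted mean
of the three layers. The aridity index is mean net radiation over mean
precipitation converted to an energy flux with
$\lambda = 2.5 \times 10^6$ J kg⁻¹ (1 mm day⁻¹ ≈ 28.94 W m⁻²); values
above 1 are dry.

## The synthetic generator and what it does (not) emulate

No public gridded dataset accompanies the method, so validation rests on a
synthetic generator with known ground truth (`sim_config()`,
`simulate_dataset()`). Its default conditions are the ones the validation
suite runs at: 200 exchangeable cells spanning aridity 0.5–2, five years of
8-daily data (46 steps/year, restarting each 1 January so calendar
positions repeat exactly), a 40-year monthly soil-moisture extension, a
designated drought year in which precipitation is suppressed to 5% for
12 steps (~3 months) in half the cells, and moderate observational noise
(10% of signal SD on SIF, ET and VOD; 5% on LAI, NIRv and VPD).

Soil moisture evolves by a single-layer 1-m bucket (inflow precipitation,
outflow demand-proportional ET plus fast drainage above field capacity,
hard bounds at 0.02 and porosity 0.45). Precipitation carries gamma
multiplicative step noise (CV 0.35) and a lognormal AR(1) *interannual*
factor (log-SD 0.25). The interannual component is essential, not
decorative: the structure-only model can only extrapolate structure–target
relations to drought conditions if non-drought years sample partially dry
conditions — that is the method's own working premise — and annual
precipitation totals really do vary at roughly this magnitude.

The latent physiological factor is
$$\varphi = \min\!\big(1, (SM / SM_{crit}^{\mathrm{eff}})^a\big)\cdot
\exp(-b\,\max(0, \Delta VPD)),$$
with $SM_{crit}^{\mathrm{eff}}$ capped at the climatological soil moisture
of the step so that $\varphi = 1$ exactly under climatological conditions,
and $\Delta VPD$ the VPD excess over its climatological value. The
functional form is an artifact choice (the method itself assumes none);
defaults $SM_{crit} = 0.27$, $a = 0.9$, $b = 0.15$ were chosen once so
that drought-cell $\varphi$ minima sit near 0.5 across the whole aridity
gradient (measured 0.42–0.62, mean 0.49), and the day/night VOD asymmetry
$\delta = 0.25$ maps $\varphi$ onto the ratio as $1 - \delta(1-\varphi)$.
$\varphi$ multiplies the structural part of SIF and ET; LAI follows soil
moisture with a 3-step (24-day) lag so structure responds more slowly than
physiology, and water limitation modulates LAI by at most 25% below its
seasonal potential — drought LAI anomalies are modest relative to the
seasonal amplitude, as observed. ET demand uses the climatological net
radiation so that the stored "structural" component is genuinely the
LAI-driven part.

Two structural-channel choices deserve emphasis because they decide
whether the decomposition is *identifiable* at all. First, canopy SIF is
near-linear in LAI at the moderate LAI realized here (absorbed-radiation
scaling; saturation sets in well above LAI 4), and the reflected NIR
radiance used to normalise SIF is held constant. A strongly saturating
curve or an LAI-dependent denominator makes the anomaly-space LAI-target
slope season-dependent, and a single-proxy model fitted on pooled
growing-season anomalies then systematically over- or under-predicts the
summer drought dip — a bias that any such decomposition inherits on real
data and that the null-control test below would flag. Second, the
detrending smoother is a plain locally weighted *linear* fit
(`lowess`, no robustness iterations): robust reweighting makes the
anomaly operator nonlinear, so a noisy and a noise-free copy of the same
signal would detrend differently and truth comparisons would be
distorted. Midday LST
is produced by exact inversion of the energy balance from the noisy ET, so
the ET stream entering the decomposition has passed through the full
LST → ET model. With all noise switched off, every stream is reproduced
bit-exactly from the stored truth components, and identical seeds give
byte-identical cubes (each variable draws from its own named sub-stream of
the master seed).

What the generator does **not** emulate: radiative transfer and sun-view
geometry, cloud gaps, spatial autocorrelation between cells (cells are
exchangeable), sub-diurnal soil-moisture dynamics, multi-year droughts, or
human disturbance. Passing tests therefore demonstrate that the pipeline
recovers a known multiplicative physiological signal under realistic noise
and seasonality — not that it is robust to every pathology of real
satellite records.

## Validation statistics and numerical choices

* **Recovery skill** (`recovery_statistics()`): the recovered physiological
  series is compared with the generator's φ-imprint inside 24-step drought
  windows. The imprint is passed through the same climatology-and-trend
  removal as the observations so both sides live in anomaly space, and the
  headline number is the **median per-cell Pearson correlation** across
  drought cells — medians across cells are the field's standard spatial
  aggregation and are insensitive to the cross-cell amplitude differences
  that depress a pooled correlation. On the default ensemble the suite
  requires r > 0.6 for each stream.
* **Null control**: with physiological sensitivity switched off
  (`a = b = 0`) the per-cell 95% bootstrap interval of the drought-window
  mean physiological anomaly must cover zero in ≥ 90% of cells.
* **Bootstrap significance** mirrors the composite-figure convention: per
  cell, 1000 values drawn with replacement from same-season (± 2 steps,
  i.e. ± 16 days) anomalies of non-drought years; the observation is
  flagged outside the 2.5–97.5 percentile range; a spatial bin earns a dot
  when more than 60% of its cells are flagged. With the observation drawn
  from the null itself the flag rate calibrates to ~5% provided the
  seasonal pool is large (a few hundred values); small pools inflate the
  rate, which is why cells with pools under 10 values are left unflagged.
* **Spatial standard errors** for composite trajectories use the
  every-third-cell subsample in both grid directions (offset 0,
  configurable), reducing the effect of spatial autocorrelation in real
  grids; with exchangeable synthetic cells it is simply a 1/9 subsample.
* **Ensemble defaults**: 500 trees, minimum node size 5, per-cell seed =
  master seed + cell index, OOB R² defined as 1 − SSE_oob/SST. The
  problem sizes run by the test suite and acceptance script (200 cells ×
  5 years, three streams, one null ensemble) were chosen as the smallest
  at which the ensemble statistics are stable.
* **Degenerate inputs**: zero-SD severity cells are "not severe"; cells
  with fewer than 10 valid points get a constant trend; rank-deficient MLR
  designs drop collinear columns with a warning; `Rsmax = 0` gives missing
  ET; empty bootstrap pools leave cells unflagged. All are exercised in
  the tests.

## Known limitations

The decomposition inherits the published method's biases: physiological
regulation that expresses itself through LAI within an 8-day step is
counted as structural, and structural change that tree ensembles cannot
extrapolate (extremes beyond the training range) leaks into the
physiological component. The spatial attribution is correlational — Shapley
importance ranks drivers of spatial variability, it does not establish
causation. The energy-balance model omits ground heat flux and assumes
equal daily minimum surface and air temperatures; its absolute ET is
accordingly approximate even though the drought anomalies it carries are
well recovered.
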