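#' Configuration for the synthetic gridded drought experiment
#'
#' Defines the study conditions the generator emulates: a multi-year 8-daily
#' record of hydro-meteorology and vegetation observation streams over a set
#' of exchangeable 0.25-degree-like grid cells, a 40-year monthly
#' soil-moisture climate extension, and one designated drought year in which
#' precipitation is suppressed over a contiguous window in a configured
#' subset of cells. The latent physiological downregulation factor
#' `phi(t) in (0, 1]` is imprinted multiplicatively on SIF and ET and through
#' the day/night asymmetry on VOD, and is stored for recovery tests.
#'
#' @param n_cells number of grid cells (default 200).
#' @param n_years length of the 8-daily study record in years (>= 5).
#' @param seed master integer seed; every stream draws from a named
#'   sub-stream split from it, so outputs are bit-reproducible and adding a
#'   variable does not perturb the others.
#' @param drought_cells indices of cells receiving the precipitation
#'   suppression (default: every other cell).
#' @param drought_length_steps length of the suppression window in 8-day
#'   steps (default 12, i.e. 96 days).
#' @param drought_year_index which study year carries the drought
#'   (default `n_years - 1`, leaving at least one recovery year).
#' @param noise_sd named list of per-stream noise levels: fractions of the
#'   stream's per-cell signal SD for the observation streams (`sif`, `et`,
#'   `vod`, `lai`, `nirv`, `vpd`), and absolute AR(1) SDs in native units
#'   for the met forcings (`ta` in K, `sw` in W m-2). Moderate
#'   observational noise by default; set all to 0 (with `precip_cv = 0`)
#'   for a fully deterministic run.
#' @param precip_cv coefficient of variation of multiplicative gamma noise
#'   on precipitation (0 switches all precipitation noise off, including
#'   the interannual component).
#' @param precip_interannual_sd log-scale SD of the lognormal AR(1)
#'   year-to-year precipitation factor. Interannual variability makes
#'   non-drought years sample partially dry conditions, which is the
#'   premise that lets a structure model trained on non-drought data
#'   extrapolate to droughts.
#' @param aridity_range range (min, max) of the imposed per-cell aridity
#'   index (net radiation over energy-converted precipitation); cells span
#'   it linearly, so wet (<= 1) and dry (> 1) regimes are both present.
#' @param phys_sensitivity numeric `c(a, b)`: soil-moisture exponent `a` and
#'   VPD sensitivity `b` (kPa^-1) of the physiological response
#'   `phi = min(1, (SM / SMcrit_eff)^a) * exp(-b * max(0, VPD anomaly))`.
#'   `a = 0, b = 0` gives `phi == 1` (null-physiology run).
#' @param structural_lag_steps lag (8-day steps) with which LAI follows soil
#'   moisture; the structural response is slower than the physiological one.
#' @param sm_crit critical volumetric soil moisture (m3 m-3) below which
#'   downregulation starts (effective threshold is capped per step at the
#'   climatological soil moisture so that `phi = 1` under climatology).
#' @param vod_asym `delta`: maximum relative midday VOD depression at
#'   `phi = 0`; the day/night ratio is `1 - delta * (1 - phi)`.
#' @param sif_amp amplitude of canopy SIF (mW m-2 sr-1 nm-1 at closed
#'   canopy); chosen so growing-season SIF climatology exceeds the 0.2
#'   season threshold.
#' @param vod_k biomass-to-VOD scaling of nighttime VOD.
#' @param start_year first calendar year of the 8-daily study record.
#'
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 200L,
                       n_years = 5L,
                       seed = 1L,
                       drought_cells = NULL,
                       drought_length_steps = 12L,
                       drought_year_index = NULL,
                       noise_sd = list(),
                       precip_cv = 0.35,
                       precip_interannual_sd = 0.25,
                       aridity_range = c(0.5, 2.0),
                       phys_sensitivity = c(a = 0.9, b = 0.15),
                       structural_lag_steps = 3L,
                       sm_crit = 0.27,
                       vod_asym = 0.25,
                       sif_amp = 1.8,
                       vod_k = 0.4,
                       start_year = 2017L) {
  if (n_cells <= 0 || n_years <= 0) {
    stop("n_cells and n_years must be positive")
  }
  if (n_years < 5) stop("n_years must be >= 5")
  if (is.null(drought_cells)) drought_cells <- seq(1L, n_cells, by = 2L)
  if (length(drought_cells) &&
      (min(drought_cells) < 1 || max(drought_cells) > n_cells)) {
    stop("drought_cells must be a subset of 1..n_cells")
  }
  if (is.null(drought_year_index)) drought_year_index <- n_years - 1L
  noise_defaults <- list(sif = 0.1, et = 0.1, vod = 0.1,
                         lai = 0.05, nirv = 0.05, vpd = 0.05,
                         ta = 1.2, sw = 18)
  noise <- utils::modifyList(noise_defaults, noise_sd)
  if (any(unlist(noise) < 0) || precip_cv < 0) {
    stop("noise levels must be >= 0")
  }
  cfg <- list(
    n_cells = as.integer(n_cells), n_years = as.integer(n_years),
    time_step_days = 8L, seed = as.integer(seed),
    drought_cells = as.integer(drought_cells),
    drought_length_steps = as.integer(drought_length_steps),
    drought_year_index = as.integer(drought_year_index),
    noise_sd = noise, precip_cv = precip_cv,
    precip_interannual_sd = precip_interannual_sd,
    aridity_range = aridity_range,
    phys_sensitivity = c(a = unname(phys_sensitivity[1]),
                         b = unname(phys_sensitivity[2])),
    structural_lag_steps = as.integer(structural_lag_steps),
    sm_crit = sm_crit, vod_asym = vod_asym,
    sif_amp = sif_amp, vod_k = vod_k,
    # soil / energy constants of the bucket and diurnal shapes
    porosity = 0.45, field_capacity = 0.32, wilting = 0.08,
    drought_precip_factor = 0.05,
    albedo = 0.23, lw_loss = 45, pet_frac = 0.8,
    diurnal_ta_amp = 5,
    start_year = as.integer(start_year),
    monthly_record_years = 40L
  )
  class(cfg) <- "sim_config"
  cfg
}

# ---- deterministic seasonal forcing --------------------------------------

doy_of <- function(dates) as.POSIXlt(dates)$yday + 1

season_phase <- function(doy) sin(2 * pi * (doy - 110) / 365.25)

ta_clim_c <- function(doy) 10 + 10 * season_phase(doy)

sw_clim_wm2 <- function(doy) 180 + 120 * season_phase(doy)

# Net radiation from incoming shortwave: constant albedo and a flat
# longwave loss, floored at a small positive value so the SSEB domain
# (Rnmean > 0) always holds.
rn_from_sw <- function(sw, albedo, lw_loss) {
  pmax((1 - albedo) * sw - lw_loss, 5)
}

# ---- bucket soil moisture -------------------------------------------------

# Single-layer 1-m bucket: inflow precipitation, outflow demand-proportional
# evapotranspiration plus fast drainage above field capacity. Water content
# W is mm over 1 m depth; volumetric SM = W / 1000. The first
# `steps_per_cycle` columns of forcing are iterated `spinup_cycles` times to
# initialise W, so with periodic forcing the recorded trajectory is periodic.
run_bucket <- function(p_mm_day, pet_mm_day, dt_days, cfg,
                       spinup_cycles = 8L, steps_per_cycle = NULL) {
  n_cells <- nrow(p_mm_day)
  n_steps <- ncol(p_mm_day)
  if (is.null(steps_per_cycle)) steps_per_cycle <- n_steps
  fc_mm <- cfg$field_capacity * 1000
  wp_mm <- cfg$wilting * 1000
  por_mm <- cfg$porosity * 1000
  step_fun <- function(w, p, pet) {
    beta <- clamp((w - wp_mm) / (fc_mm - wp_mm), 0, 1)
    w <- w + (p - pet * beta) * dt_days
    over <- w > fc_mm
    w[over] <- fc_mm + (w[over] - fc_mm) * exp(-0.5 * dt_days / 8)
    clamp(w, 0.02 * 1000, por_mm)
  }
  w <- rep(fc_mm * 0.8, n_cells)
  cyc <- seq_len(min(steps_per_cycle, n_steps))
  for (k in seq_len(spinup_cycles)) {
    for (t in cyc) w <- step_fun(w, p_mm_day[, t], pet_mm_day[, t])
  }
  sm <- matrix(NA_real_, n_cells, n_steps)
  for (t in seq_len(n_steps)) {
    w <- step_fun(w, p_mm_day[, t], pet_mm_day[, t])
    sm[, t] <- w / 1000
  }
  sm
}

# ---- static cell attributes ----------------------------------------------

cell_static <- function(cfg) {
  n <- cfg$n_cells
  ai <- seq(cfg$aridity_range[1], cfg$aridity_range[2], length.out = n)
  tree <- clamp(0.75 - 0.3 * ai, 0.05, 0.75)
  grass <- clamp(0.15 + 0.15 * ai, 0, 0.6)
  shrub <- rep(0.10, n)
  soil <- pmax(1 - tree - grass - shrub, 0)
  ncol_grid <- ceiling(sqrt(n))
  row <- (seq_len(n) - 1) %/% ncol_grid
  col <- (seq_len(n) - 1) %% ncol_grid
  data.frame(
    cell = seq_len(n),
    lat = 40 + 0.25 * row, lon = 0.25 * col,
    grid_row = row + 1L, grid_col = col + 1L,
    tree_frac = tree, shrub_frac = shrub, grass_frac = grass,
    soil_frac = soil, irrigation_frac = 0.02,
    aridity_imposed = ai
  )
}

# Lognormal AR(1) year-to-year precipitation factors (mean 1) for the full
# monthly record; the study years use the final columns so the 8-daily and
# monthly records share one interannual history.
yearly_precip_factors <- function(cfg) {
  n <- cfg$n_cells
  ny <- cfg$monthly_record_years
  if (cfg$precip_cv <= 0 || cfg$precip_interannual_sd <= 0) {
    return(matrix(1, n, ny))
  }
  s <- cfg$precip_interannual_sd
  lf <- with_seed(split_seed(cfg$seed, "precip_yearly"),
                  matrix(ar1_noise(n * ny, 0.3, s), n))
  exp(lf - s^2 / 2)
}

# ---- met generation -------------------------------------------------------

#' Generate synthetic hydro-meteorology
#'
#' Produces the 8-daily meteorological cubes the downstream pipeline needs
#' (air temperature, shortwave radiation, VPD, precipitation, three
#' soil-moisture layers plus their 1-m truth, wind, surface pressure, and
#' the daily-summary fields `ta_max_k`, `rs_max`, `rn_mean` used by the
#' surface energy balance), a 40-year monthly soil-moisture record for
#' drought ranking, and a small hourly sub-grid from which the daily
#' summaries can be recomputed. Each variable is a seasonal cycle plus
#' AR(1)/gamma noise; soil moisture evolves by a bucket model. In drought
#' cells, precipitation is multiplied by `drought_precip_factor` over
#' `drought_length_steps` consecutive steps of the drought year, which
#' drives the 40-year record soil-moisture minimum there.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `met_set`; see Details in the package vignette.
#' @export
generate_met <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  static <- cell_static(cfg)
  n <- cfg$n_cells

  # 8-daily calendar, 46 steps restarting each 1 January so calendar
  # positions align exactly across years (periodic forcing)
  years <- cfg$start_year + seq_len(cfg$n_years) - 1L
  dates <- as.Date(unlist(lapply(years, function(y) {
    as.Date(sprintf("%d-01-01", y)) + seq(0, 360, by = 8)
  })), origin = "1970-01-01")
  nt <- length(dates)
  doy <- doy_of(dates)
  yr <- as.integer(format(dates, "%Y"))
  steps_per_year <- 46L

  # deterministic seasonal forcing, identical across cells for Ta/SW
  ta_det <- matrix(rep(ta_clim_c(doy), each = n), n)
  sw_det <- matrix(rep(sw_clim_wm2(doy), each = n), n)
  rn_det <- rn_from_sw(sw_det, cfg$albedo, cfg$lw_loss)

  ta <- ta_det + with_seed(split_seed(cfg$seed, "ta"),
                           matrix(ar1_noise(n * nt, 0.6,
                                            cfg$noise_sd$ta), n))
  sw <- pmax(sw_det + with_seed(split_seed(cfg$seed, "sw"),
                                matrix(ar1_noise(n * nt, 0.5,
                                                 cfg$noise_sd$sw), n)), 20)
  rn <- rn_from_sw(sw, cfg$albedo, cfg$lw_loss)

  # imposed aridity fixes each cell's mean precipitation
  rn_cell_mean <- rowMeans(rn_det)
  p_mean <- rn_cell_mean / (mm_day_to_wm2(1) * static$aridity_imposed)
  p_season <- outer(p_mean, 1 + 0.3 * season_phase(doy))
  p_noise <- if (cfg$precip_cv > 0) {
    shape <- 1 / cfg$precip_cv^2
    with_seed(split_seed(cfg$seed, "precip8"),
              matrix(stats::rgamma(n * nt, shape = shape, rate = shape), n))
  } else {
    matrix(1, n, nt)
  }
  yfac <- yearly_precip_factors(cfg)
  yfac_study <- yfac[, ncol(yfac) - cfg$n_years + seq_len(cfg$n_years),
                     drop = FALSE]
  year_idx <- match(yr, years)
  precip <- p_season * p_noise * yfac_study[, year_idx, drop = FALSE]

  # drought: contiguous precipitation suppression starting early June
  dyear <- years[cfg$drought_year_index]
  start_step <- which(yr == dyear & doy >= 153)[1]
  suppress_steps <- seq(start_step,
                        min(start_step + cfg$drought_length_steps - 1L, nt))
  precip[cfg$drought_cells, suppress_steps] <-
    precip[cfg$drought_cells, suppress_steps] * cfg$drought_precip_factor

  pet <- cfg$pet_frac * rn / mm_day_to_wm2(1)
  sm <- run_bucket(precip, pet, 8, cfg, steps_per_cycle = steps_per_year)

  # deterministic no-drought reference used to define climatological
  # soil moisture and VPD (phi must be 1 under climatology)
  pet_det <- cfg$pet_frac * rn_det / mm_day_to_wm2(1)
  sm_ref <- run_bucket(p_season, pet_det, 8, cfg,
                       steps_per_cycle = steps_per_year)

  beta <- clamp((sm - cfg$wilting) / (cfg$field_capacity - cfg$wilting), 0, 1)
  beta_ref <- clamp((sm_ref - cfg$wilting) /
                      (cfg$field_capacity - cfg$wilting), 0, 1)
  rh <- clamp(0.70 - 0.35 * (1 - beta), 0.15, 0.95)
  rh_ref <- clamp(0.70 - 0.35 * (1 - beta_ref), 0.15, 0.95)
  vpd <- esat_kpa(ta) * (1 - rh) *
    (1 + with_seed(split_seed(cfg$seed, "vpd"),
                   matrix(ar1_noise(n * nt, 0.4, cfg$noise_sd$vpd), n)))
  vpd <- pmax(vpd, 0.01)
  vpd_ref <- esat_kpa(ta_det) * (1 - rh_ref)

  # three soil layers with deterministic offsets that cancel in the
  # thickness-weighted 1-m mean (weights 0.07 / 0.21 / 0.72)
  off <- c(0.02, 0.01)
  off3 <- -(0.07 * off[1] + 0.21 * off[2]) / 0.72
  layer1 <- clamp(sm + off[1], 0.01, cfg$porosity)
  layer2 <- clamp(sm + off[2], 0.01, cfg$porosity)
  layer3 <- sm - (0.07 * (layer1 - sm) + 0.21 * (layer2 - sm)) / 0.72
  stopifnot(abs(off3) < 0.1)

  # daily-summary fields implied by the diurnal shapes (cosine air
  # temperature peaking at 14h; half-sine daylight shortwave 6-18h)
  ta_max_k <- ta + 273.15 + cfg$diurnal_ta_amp
  rs_max <- pi * (1 - cfg$albedo) * sw
  rn_mean <- rn

  # 40-year monthly soil-moisture record ending with the study years
  mrec <- monthly_sm_record(cfg, static, p_mean, rn_cell_mean, yfac)

  mk <- function(v, units, name) grid_cube(v, dates, static, units, name)
  met <- list(
    ta = mk(ta, "degC", "ta"),
    sw = mk(sw, "W m-2", "sw_in"),
    rn = mk(rn, "W m-2", "rn"),
    vpd = mk(vpd, "kPa", "vpd"),
    precip = mk(precip, "mm day-1", "precip"),
    sm = mk(sm, "m3 m-3", "sm_1m"),
    sm_layer1 = mk(layer1, "m3 m-3", "sm_layer1"),
    sm_layer2 = mk(layer2, "m3 m-3", "sm_layer2"),
    sm_layer3 = mk(layer3, "m3 m-3", "sm_layer3"),
    wind = mk(matrix(3 + 0.5 * rep(season_phase(doy), each = n), n),
              "m s-1", "wind"),
    pressure = mk(matrix(101.3, n, nt), "kPa", "pressure"),
    ta_max_k = mk(ta_max_k, "K", "ta_max"),
    rs_max = mk(rs_max, "W m-2", "rs_max"),
    rn_mean = mk(rn_mean, "W m-2", "rn_mean"),
    rn_clim = mk(rn_det, "W m-2", "rn_climatological"),
    vpd_ref = mk(vpd_ref, "kPa", "vpd_climatological"),
    sm_ref = mk(sm_ref, "m3 m-3", "sm_climatological"),
    sm_monthly_40yr = mrec,
    hourly = hourly_subgrid(ta, sw, dates, static, cfg),
    static = static,
    suppress_steps = suppress_steps,
    drought_year = dyear,
    dates = dates
  )
  class(met) <- "met_set"
  met
}

# Monthly 40-year soil-moisture record from the same bucket at monthly
# steps; the drought year repeats the precipitation suppression so the
# record minimum of drought cells falls there.
monthly_sm_record <- function(cfg, static, p_mean, rn_cell_mean, yfac) {
  n <- cfg$n_cells
  years_all <- (cfg$start_year + cfg$n_years - cfg$monthly_record_years):
    (cfg$start_year + cfg$n_years - 1L)
  mdates <- as.Date(sprintf("%d-%02d-15", rep(years_all, each = 12), 1:12))
  doy_m <- doy_of(mdates)
  nt <- length(mdates)
  p_season <- outer(p_mean, 1 + 0.3 * season_phase(doy_m)) *
    yfac[, rep(seq_along(years_all), each = 12), drop = FALSE]
  p_noise <- if (cfg$precip_cv > 0) {
    shape <- 1 / (cfg$precip_cv / sqrt(2))^2  # monthly means are less noisy
    with_seed(split_seed(cfg$seed, "precip_monthly"),
              matrix(stats::rgamma(n * nt, shape = shape, rate = shape), n))
  } else {
    matrix(1, n, nt)
  }
  precip <- p_season * p_noise
  dyear <- cfg$start_year + cfg$drought_year_index - 1L
  dmonths <- which(rep(years_all, each = 12) == dyear &
                     rep(1:12, length(years_all)) %in% 6:9)
  precip[cfg$drought_cells, dmonths] <-
    precip[cfg$drought_cells, dmonths] * cfg$drought_precip_factor
  rn_det <- rn_from_sw(
    matrix(rep(sw_clim_wm2(doy_m), each = n), n), cfg$albedo, cfg$lw_loss)
  pet <- cfg$pet_frac * rn_det / mm_day_to_wm2(1)
  sm <- run_bucket(precip, pet, 30.44, cfg, steps_per_cycle = 12L)
  grid_cube(sm, mdates, cell_static(cfg), "m3 m-3", "sm_monthly")
}

# Hourly met for a small sub-grid (first up to 3 cells, first study year):
# one representative diurnal cycle per 8-daily step, built from the exact
# shapes whose analytic daily summaries the generator reports, so
# daily_met_summaries() recovers ta_max/rs_max/rn_mean bit-exactly.
hourly_subgrid <- function(ta, sw, dates, static, cfg) {
  cells <- seq_len(min(3L, nrow(ta)))
  steps <- which(format(dates, "%Y") == format(dates[1], "%Y"))
  hours <- 0:23
  nh <- length(hours)
  shape_ta <- cos(2 * pi * (hours - 14) / 24)
  shape_sw <- pmax(0, sin(pi * (hours - 6) / 12))
  ta_h <- matrix(NA_real_, length(cells), length(steps) * nh)
  rs_h <- ta_h
  rn_h <- ta_h
  for (k in seq_along(steps)) {
    idx <- (k - 1) * nh + seq_len(nh)
    ta_h[, idx] <- outer(ta[cells, steps[k]] + 273.15,
                         cfg$diurnal_ta_amp * shape_ta, `+`)
    rs_h[, idx] <- outer(pi * (1 - cfg$albedo) * sw[cells, steps[k]],
                         shape_sw)
    # hourly net radiation consistent with the daily mean used downstream:
    # net shortwave minus a flat longwave loss
    rn_h[, idx] <- rs_h[, idx] - cfg$lw_loss
  }
  list(ta_k = ta_h, rs = rs_h, rn = rn_h,
       dates = dates[steps], cells = static$cell[cells], hours = hours)
}

# ---- observations ---------------------------------------------------------

#' Generate observation streams with a known latent physiological signal
#'
#' Builds LAI (lagged structural response to soil moisture), NIRv, canopy
#' SIF and near-infrared radiance (hence relative SIF), midday LST (by
#' exact inversion of the surface energy balance from the true latent heat
#' flux, so [estimate_et()] can recover it), and midday/midnight VOD whose
#' ratio encodes the physiological factor `phi`. The returned `truth`
#' element stores `phi`, the structural part of each stream, and the
#' additive phi-imprint (`structural * (phi - 1)`, and `delta * (phi - 1)`
#' for the VOD ratio) used by parameter-recovery tests.
#'
#' @param met a `met_set` from [generate_met()].
#' @param cfg the same [sim_config()].
#' @return a list of class `obs_set` with cubes `lai`, `nirv`, `sif`,
#'   `nir_rad`, `sifrel`, `lst`, `vod_day`, `vod_night`, `et_true`, and a
#'   `truth` element of class `truth_cube`.
#' @export
generate_observations <- function(met, cfg) {
  stopifnot(inherits(met, "met_set"), inherits(cfg, "sim_config"))
  for (v in c("sm", "vpd", "rn_mean", "ta_max_k", "rs_max")) {
    if (is.null(met[[v]])) stop("missing met variable: ", v)
  }
  n <- cfg$n_cells
  dates <- met$dates
  nt <- length(dates)
  doy <- doy_of(dates)
  static <- met$static

  sm <- met$sm$values
  beta <- clamp((sm - cfg$wilting) / (cfg$field_capacity - cfg$wilting), 0, 1)

  # latent physiological downregulation; the effective soil-moisture
  # threshold is capped at the climatological value so phi = 1 whenever
  # soil moisture and VPD sit at climatology
  a <- cfg$phys_sensitivity["a"]
  b <- cfg$phys_sensitivity["b"]
  sm_crit_eff <- pmin(cfg$sm_crit, met$sm_ref$values)
  phi <- if (a == 0) matrix(1, n, nt) else {
    pmin((pmax(sm, 1e-6) / sm_crit_eff)^a, 1)
  }
  vpd_anom <- pmax(0, met$vpd$values - met$vpd_ref$values)
  phi <- phi * exp(-b * vpd_anom)

  # structural response: LAI follows soil moisture with a lag
  lag <- cfg$structural_lag_steps
  beta_lag <- cbind(beta[, rep(1, lag), drop = FALSE],
                    beta[, seq_len(nt - lag), drop = FALSE])
  laimax <- 1.5 + 2.0 * clamp((2 - static$aridity_imposed) / 1.5, 0, 1)
  season_lai <- pmax(0, season_phase(doy))
  lai_pot <- 0.4 + outer(laimax - 0.4, season_lai)
  # water limitation modulates LAI by up to 25% below potential: drought
  # LAI anomalies are modest relative to the seasonal amplitude, and the
  # lagged partial response is what a ~3-month drought can express
  lai_sig <- lai_pot * (0.75 + 0.25 * beta_lag)
  lai <- pmax(lai_sig + with_seed(split_seed(cfg$seed, "lai"),
                                  scaled_noise(lai_sig, cfg$noise_sd$lai)),
              0.05)

  nirv_sig <- 0.08 + 0.28 * (1 - exp(-0.6 * lai))
  nirv <- nirv_sig + with_seed(split_seed(cfg$seed, "nirv"),
                               scaled_noise(nirv_sig, cfg$noise_sd$nirv))

  # SIF: structural part scales with absorbed radiation, near-linear in
  # LAI at the moderate values realized here (saturation only sets in
  # well above LAI 4); multiplied by phi
  sif_struct <- cfg$sif_amp * 0.16 * lai
  sif <- pmax(sif_struct * phi +
                with_seed(split_seed(cfg$seed, "sif"),
                          scaled_noise(sif_struct * phi, cfg$noise_sd$sif)),
              0)
  # constant reflected NIR radiance: the ratio keeps the irradiance
  # filtering role while the SIFrel structural channel stays a
  # season-homogeneous linear function of LAI (see vignette)
  nir_rad <- matrix(42, n, nt)
  sifrel <- sif / nir_rad

  # ET: atmospheric demand times canopy conductance term times phi; the
  # demand uses the climatological net radiation so the structural part
  # stays purely LAI-driven (seasonal demand is absorbed by the
  # climatology in anomaly space)
  rn_mean <- met$rn_mean$values
  demand <- 0.75 * met$rn_clim$values
  et_struct <- demand * pmin(0.15 + 0.2 * lai, 0.95)
  et_true <- pmin(et_struct * phi, 0.95 * rn_mean)
  et_obs <- et_true + with_seed(split_seed(cfg$seed, "et"),
                                scaled_noise(et_true, cfg$noise_sd$et))
  et_obs <- clamp(et_obs, 0.02 * rn_mean, 0.98 * rn_mean)

  # midday LST carries the ET signal through the energy balance inverse
  ga <- mix_ga(static)
  lst <- invert_lst(et_obs, met$ta_max_k$values, met$rs_max$values,
                    rn_mean, matrix(ga, n, nt))

  # VOD: nighttime scales with biomass; daytime is depressed when phi < 1
  biomass <- 0.5 + 0.25 * lai
  vod_night_sig <- cfg$vod_k * biomass
  vod_night <- pmax(vod_night_sig +
                      with_seed(split_seed(cfg$seed, "vod_night"),
                                scaled_noise(vod_night_sig,
                                             cfg$noise_sd$vod)),
                    0.01)
  ratio_sig <- 1 - cfg$vod_asym * (1 - phi)
  vod_day_sig <- vod_night * ratio_sig
  vod_day <- pmax(vod_day_sig +
                    with_seed(split_seed(cfg$seed, "vod_day"),
                              scaled_noise(vod_day_sig, cfg$noise_sd$vod)),
                  0.01)

  mk <- function(v, units, name) grid_cube(v, dates, static, units, name)
  truth <- structure(list(
    phi = mk(phi, "1", "phi"),
    soil_moisture = mk(sm, "m3 m-3", "sm_truth"),
    structural = list(
      sif = mk(sif_struct, "mW m-2 sr-1 nm-1", "sif_structural"),
      sifrel = mk(sif_struct / nir_rad, "1", "sifrel_structural"),
      et = mk(et_struct, "W m-2", "et_structural"),
      vod_ratio = mk(matrix(1, n, nt), "1", "vod_ratio_structural")
    ),
    imprint = list(
      sifrel = mk(sif_struct / nir_rad * (phi - 1), "1", "sifrel_imprint"),
      et = mk(et_struct * (phi - 1), "W m-2", "et_imprint"),
      vod_ratio = mk(cfg$vod_asym * (phi - 1), "1", "vod_ratio_imprint")
    )
  ), class = "truth_cube")

  obs <- list(
    lai = mk(lai, "m2 m-2", "lai"),
    nirv = mk(nirv, "1", "nirv"),
    sif = mk(sif, "mW m-2 sr-1 nm-1", "sif"),
    nir_rad = mk(nir_rad, "mW m-2 sr-1 nm-1", "nir_radiance"),
    sifrel = mk(sifrel, "1", "sifrel"),
    lst = mk(lst, "K", "lst_midday"),
    vod_day = mk(vod_day, "1", "vod_day"),
    vod_night = mk(vod_night, "1", "vod_night"),
    et_true = mk(et_true, "W m-2", "et_true"),
    truth = truth
  )
  class(obs) <- "obs_set"
  obs
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [generate_met()] and
#' [generate_observations()] under one configuration.
#'
#' @param cfg a [sim_config()].
#' @return list of class `sim_dataset` with elements `met`, `obs`,
#'   `static`, `truth`, `config`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  met <- generate_met(cfg)
  obs <- generate_observations(met, cfg)
  structure(list(met = met, obs = obs, static = met$static,
                 truth = obs$truth, config = cfg),
            class = "sim_dataset")
}
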