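#' End-to-end decomposition pipeline on a synthetic dataset
#'
#' Convenience driver used by the validation suite: derives the observation
#' stream (relative SIF, energy-balance ET from midday LST, or the VOD
#' day/night ratio), extracts anomalies for the stream, the structure proxy
#' and the hydro-meteorological predictors, builds the growing-season mask,
#' detects drought events, and runs the two-model decomposition.
#'
#' @param ds a `sim_dataset` from [simulate_dataset()].
#' @param target `"sifrel"`, `"et"`, or `"vod_ratio"`.
#' @param cfg a [decomposition_config()].
#' @param structure_proxy `"lai"` (default) or `"nirv"`.
#' @return list with `decomp` (`decomposition_result`), `events`,
#'   `growing_mask`, `anoms` (named list of `anomaly_cube`s), `target_cube`
#'   and `aridity`.
#' @export
run_decomposition_pipeline <- function(ds, target = c("sifrel", "et",
                                                      "vod_ratio"),
                                       cfg = decomposition_config(),
                                       structure_proxy = c("lai", "nirv")) {
  target <- match.arg(target)
  structure_proxy <- match.arg(structure_proxy)
  met <- ds$met
  obs <- ds$obs

  target_cube <- switch(
    target,
    sifrel = obs$sifrel,
    et = {
      ga <- mix_ga(ds$static)
      n <- nrow(obs$lst$values)
      nt <- ncol(obs$lst$values)
      et <- estimate_et(obs$lst$values, met$ta_max_k$values,
                        met$rs_max$values, met$rn_mean$values,
                        matrix(ga, n, nt))
      grid_cube(et, obs$lst$time, obs$lst$cells, "W m-2", "et_sseb")
    },
    vod_ratio = vod_ratio(obs$vod_day, obs$vod_night)
  )

  structure_cube <- if (structure_proxy == "lai") obs$lai else obs$nirv

  anoms <- list(
    target = compute_anomalies(target_cube),
    structure = compute_anomalies(structure_cube),
    ta = compute_anomalies(met$ta),
    sw = compute_anomalies(met$sw),
    vpd = compute_anomalies(met$vpd),
    sm = compute_anomalies(met$sm),
    precip = compute_anomalies(met$precip)
  )

  sif_clim <- monthly_climatology(obs$sif)
  gmask <- growing_season_mask(met$ta, sif_clim)

  study_years <- as.integer(unique(format(met$dates, "%Y")))
  events <- detect_drought_events(
    met$sm, anoms$sm$anomaly, met$sm_monthly_40yr, gmask, study_years)

  met_anom_cubes <- list(ta = anoms$ta$anomaly, sw = anoms$sw$anomaly,
                         vpd = anoms$vpd$anomaly, sm = anoms$sm$anomaly,
                         precip = anoms$precip$anomaly)
  decomp <- decompose_stream(anoms$target$anomaly,
                             anoms$structure$anomaly,
                             met_anom_cubes, gmask, cfg)

  aridity <- aridity_index(met$rn, met$precip)

  list(decomp = decomp, events = events, growing_mask = gmask,
       anoms = anoms, met_anom_cubes = met_anom_cubes,
       target_cube = target_cube, aridity = aridity)
}

#' Recovery skill of the physiological component against synthetic truth
#'
#' Compares the recovered physiological series with the known phi-imprint
#' of the generator inside drought windows (24 steps around each peak).
#' The imprint is passed through the same climatology + trend removal as
#' the observations so both sides live in anomaly space; the headline
#' statistic is the median per-cell Pearson correlation across kept,
#' drought-affected cells (the pooled correlation across all window steps
#' is also reported).
#'
#' @param decomp a `decomposition_result`.
#' @param events events table from [detect_drought_events()].
#' @param imprint_cube `grid_cube` of the true phi-imprint for the stream
#'   (from the dataset's `truth$imprint`).
#' @param cells optional cell indices to restrict to (e.g. the configured
#'   drought cells); default all.
#' @param window step offsets around the peak.
#' @param min_steps minimum valid window steps per cell.
#' @return list with `median_r`, `pooled_r`, `per_cell_r`, `n_cells`.
#' @export
recovery_statistics <- function(decomp, events, imprint_cube,
                                cells = NULL, window = -12:11,
                                min_steps = 6L) {
  imp <- compute_anomalies(imprint_cube)$anomaly$values
  nt <- ncol(imp)
  if (is.null(cells)) cells <- seq_len(nrow(imp))
  use <- intersect(cells, which(decomp$kept & events$selected &
                                  !is.na(events$peak_step)))
  per_cell <- rep(NA_real_, length(use))
  rec_all <- c()
  tru_all <- c()
  for (k in seq_along(use)) {
    i <- use[k]
    w <- events$peak_step[i] + window
    w <- w[w >= 1 & w <= nt]
    rec <- decomp$physiological[i, w]
    tru <- imp[i, w]
    ok <- !is.na(rec) & !is.na(tru)
    if (sum(ok) < min_steps) next
    per_cell[k] <- stats::cor(rec[ok], tru[ok])
    rec_all <- c(rec_all, rec[ok])
    tru_all <- c(tru_all, tru[ok])
  }
  list(median_r = stats::median(per_cell, na.rm = TRUE),
       pooled_r = if (length(rec_all) > 2) {
         stats::cor(rec_all, tru_all)
       } else NA_real_,
       per_cell_r = per_cell, n_cells = sum(!is.na(per_cell)))
}
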