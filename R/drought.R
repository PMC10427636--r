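#' Growing-season mask
#'
#' A step is in the growing season of its cell iff air temperature exceeds
#' 5 degC and the cell's monthly SIF climatology for that month exceeds
#' 0.2 mW m-2 sr-1 nm-1 (both strict). Using the SIF mean seasonal cycle
#' rather than instantaneous SIF keeps post-drought anomalies inside the
#' season. Missing temperature counts as out of season.
#'
#' @param ta `grid_cube` of air temperature; units attribute `"K"` or
#'   `"degC"` decides the conversion.
#' @param sif_clim cells x 12 monthly climatology of raw SIF
#'   (mW m-2 sr-1 nm-1), as from [monthly_climatology()].
#' @param ta_threshold_c,sif_threshold season thresholds.
#' @return logical cells x steps matrix.
#' @export
growing_season_mask <- function(ta, sif_clim, ta_threshold_c = 5,
                                sif_threshold = 0.2) {
  ta_c <- if (identical(ta$units, "K")) ta$values - 273.15 else ta$values
  mo <- as.integer(format(ta$time, "%m"))
  sif_m <- sif_clim[, mo, drop = FALSE]
  mask <- (ta_c > ta_threshold_c) & (sif_m > sif_threshold)
  mask[is.na(mask)] <- FALSE
  mask
}

#' Select severely drought-affected cells by 40-year ranking
#'
#' For each cell, yearly minima of the monthly soil-moisture record
#' (optionally restricted to growing-season months) are ranked; the cell is
#' selected iff its lowest yearly minimum falls inside the study window.
#' Rank ties between a study year and an earlier year resolve to the later
#' year (inclusive reading of the study window). Cells with fewer than
#' `min_years` valid years are excluded.
#'
#' @param sm_monthly `grid_cube` of monthly soil moisture spanning the full
#'   (e.g. 40-year) record.
#' @param study_years integer vector of study-period calendar years.
#' @param months months (1-12) considered, e.g. growing-season months;
#'   default all.
#' @param min_years minimum valid years per cell.
#' @param rank 1 selects on the record minimum; 2 reports cells whose
#'   second-lowest minimum is also in the study window (used to exclude
#'   multi-drought cells in robustness checks).
#' @return logical vector over cells.
#' @export
select_drought_cells <- function(sm_monthly, study_years,
                                 months = 1:12, min_years = 30L,
                                 rank = 1L) {
  yr <- as.integer(format(sm_monthly$time, "%Y"))
  mo <- as.integer(format(sm_monthly$time, "%m"))
  use <- mo %in% months
  years <- sort(unique(yr))
  n <- nrow(sm_monthly$values)
  ymin <- matrix(NA_real_, n, length(years))
  for (k in seq_along(years)) {
    idx <- which(use & yr == years[k])
    if (length(idx)) {
      v <- apply(sm_monthly$values[, idx, drop = FALSE], 1, function(z) {
        if (all(is.na(z))) NA_real_ else min(z, na.rm = TRUE)
      })
      ymin[, k] <- v
    }
  }
  out <- logical(n)
  for (i in seq_len(n)) {
    ok <- which(!is.na(ymin[i, ]))
    if (length(ok) < min_years) next
    ord <- ok[order(ymin[i, ok], -years[ok])]  # ties -> latest year first
    if (length(ord) >= rank) {
      out[i] <- years[ord[rank]] %in% study_years
    }
  }
  out
}

#' Drought peak per cell
#'
#' The time step of minimum 8-daily soil moisture over in-season steps
#' (`variant = "absolute"`), or of minimum soil-moisture anomaly
#' (`variant = "anomaly"`). Ties resolve to the earliest step. Cells with
#' no valid in-season value get `NA`.
#'
#' @param sm `grid_cube` of 8-daily soil moisture (absolute values).
#' @param growing_mask logical cells x steps matrix.
#' @param sm_anom optional `grid_cube` of soil-moisture anomalies
#'   (required for the anomaly variant).
#' @param variant `"absolute"` or `"anomaly"`.
#' @return integer vector of peak step indices (`NA` where no event).
#' @export
find_peak <- function(sm, growing_mask, sm_anom = NULL,
                      variant = c("absolute", "anomaly")) {
  variant <- match.arg(variant)
  vals <- if (variant == "absolute") sm$values else {
    if (is.null(sm_anom)) stop("sm_anom required for the anomaly variant")
    sm_anom$values
  }
  vals[!growing_mask] <- NA
  unname(apply(vals, 1, function(z) {
    if (all(is.na(z))) NA_integer_ else which.min(z)
  }))
}

#' Drought development and recovery durations
#'
#' Counts consecutive steps with negative soil-moisture anomaly walking
#' backward from the peak (development, peak included) and forward from the
#' peak (recovery), stopping at the first step with anomaly at or above
#' zero. A missing step during the walk stops it and flags the duration as
#' censored, as does running off the record.
#'
#' @param sm_anom numeric anomaly series of one cell.
#' @param peak_step peak index into `sm_anom`.
#' @return list with `dev_duration`, `recov_duration` (steps), and
#'   `censored` (logical length 2: development, recovery side).
#' @export
drought_durations <- function(sm_anom, peak_step) {
  n <- length(sm_anom)
  censored <- c(dev = FALSE, recov = FALSE)
  dev <- 0L
  t <- peak_step
  while (t >= 1) {
    v <- sm_anom[t]
    if (is.na(v)) { censored["dev"] <- TRUE; break }
    if (v >= 0) break
    dev <- dev + 1L
    t <- t - 1L
  }
  if (t < 1) censored["dev"] <- TRUE
  recov <- 0L
  t <- peak_step + 1L
  while (t <= n) {
    v <- sm_anom[t]
    if (is.na(v)) { censored["recov"] <- TRUE; break }
    if (v >= 0) break
    recov <- recov + 1L
    t <- t + 1L
  }
  if (t > n) censored["recov"] <- TRUE
  list(dev_duration = dev, recov_duration = recov, censored = censored)
}

#' Extract the 24-step trajectory window around a drought peak
#'
#' Steps `peak - 12` to `peak + 11` (about 3 months either side at 8-day
#' resolution, 24 steps total, peak as the 13th element); parts outside the
#' record are missing-padded. A stream enters composites only when at least
#' `min_valid` of the 24 steps are valid.
#'
#' @param series numeric series of one cell (typically an anomaly).
#' @param peak_step peak index.
#' @param before,after steps before/after the peak (defaults 12 and 11).
#' @return list with `values` (length `before + after + 1`), `offsets`
#'   (step offsets relative to the peak), and `valid_count`.
#' @export
extract_trajectory <- function(series, peak_step, before = 12L,
                               after = 11L) {
  offsets <- seq(-before, after)
  idx <- peak_step + offsets
  vals <- rep(NA_real_, length(idx))
  inside <- idx >= 1 & idx <= length(series)
  vals[inside] <- series[idx[inside]]
  list(values = vals, offsets = offsets,
       valid_count = sum(!is.na(vals)))
}

#' Severity filter: -1.5 SD below the long-record seasonal mean
#'
#' A detected peak is severe iff the soil moisture at the peak lies below
#' the 40-year seasonal mean minus 1.5 standard deviations, where the
#' seasonal statistics use the calendar month of the peak from the monthly
#' long record (the same monthly grouping as the climatology).
#'
#' @param sm_peak soil moisture value at the peak (per cell).
#' @param peak_month calendar month (1-12) of each peak.
#' @param sm_monthly `grid_cube` of the 40-year monthly record.
#' @param n_sd threshold in standard deviations (default 1.5).
#' @return logical vector; `FALSE` (not severe) where the seasonal SD is
#'   zero or statistics are unavailable.
#' @export
severity_filter <- function(sm_peak, peak_month, sm_monthly, n_sd = 1.5) {
  mo <- as.integer(format(sm_monthly$time, "%m"))
  n <- nrow(sm_monthly$values)
  out <- logical(n)
  for (i in seq_len(n)) {
    if (is.na(sm_peak[i]) || is.na(peak_month[i])) next
    v <- sm_monthly$values[i, mo == peak_month[i]]
    v <- v[!is.na(v)]
    if (length(v) < 2) next
    s <- stats::sd(v)
    if (s == 0) next
    out[i] <- sm_peak[i] < mean(v) - n_sd * s
  }
  out
}

#' Detect drought events across a gridded dataset
#'
#' Bundles selection, peak finding, durations, and the severity flag into
#' one per-cell events table.
#'
#' @param sm_8daily `grid_cube` of 8-daily soil moisture.
#' @param sm_anom `grid_cube` of its anomalies.
#' @param sm_monthly `grid_cube` of the 40-year monthly record.
#' @param growing_mask logical cells x steps matrix.
#' @param study_years calendar years of the study window.
#' @param season_months months used for yearly minima ranking.
#' @param variant peak detection variant, see [find_peak()].
#' @return data frame with one row per cell: `cell`, `selected`,
#'   `peak_step`, `peak_date`, `dev_duration`, `recov_duration`,
#'   `censored_dev`, `censored_recov`, `severe`.
#' @export
detect_drought_events <- function(sm_8daily, sm_anom, sm_monthly,
                                  growing_mask, study_years,
                                  season_months = 1:12,
                                  variant = "absolute") {
  selected <- select_drought_cells(sm_monthly, study_years,
                                   months = season_months)
  peaks <- find_peak(sm_8daily, growing_mask, sm_anom, variant = variant)
  n <- nrow(sm_8daily$values)
  ev <- data.frame(
    cell = sm_8daily$cells$cell,
    selected = selected,
    peak_step = ifelse(selected, peaks, NA_integer_),
    peak_date = as.Date(NA),
    dev_duration = NA_integer_, recov_duration = NA_integer_,
    censored_dev = NA, censored_recov = NA, severe = NA
  )
  has_peak <- which(selected & !is.na(peaks))
  ev$peak_date[has_peak] <- sm_8daily$time[peaks[has_peak]]
  for (i in has_peak) {
    d <- drought_durations(sm_anom$values[i, ], peaks[i])
    ev$dev_duration[i] <- d$dev_duration
    ev$recov_duration[i] <- d$recov_duration
    ev$censored_dev[i] <- d$censored["dev"]
    ev$censored_recov[i] <- d$censored["recov"]
  }
  sm_peak <- rep(NA_real_, n)
  peak_month <- rep(NA_integer_, n)
  sm_peak[has_peak] <- sm_8daily$values[cbind(has_peak, peaks[has_peak])]
  peak_month[has_peak] <-
    as.integer(format(sm_8daily$time[peaks[has_peak]], "%m"))
  ev$severe <- severity_filter(sm_peak, peak_month, sm_monthly)
  ev
}
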