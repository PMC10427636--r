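#' Aggregate a daily cube to 8-daily with a 16-day moving window
#'
#' Each output step is the mean over the 16-day window centred on the
#' output's 8-day grid (windows overlap by 8 days). A window with more than
#' 20% of its days missing is set to missing. Only windows lying fully
#' inside the record are produced.
#'
#' @param daily a daily-resolution `grid_cube`.
#' @param max_gap_frac maximum tolerated fraction of missing days per
#'   window (default 0.2).
#' @return an 8-daily `grid_cube` stamped at window centres.
#' @export
aggregate_8daily <- function(daily, max_gap_frac = 0.2) {
  step <- time_step_days(daily)
  if (is.na(step) || step > 1) {
    stop("input must be daily resolution")
  }
  nd <- ncol(daily$values)
  starts <- seq(1L, nd - 15L, by = 8L)
  out <- matrix(NA_real_, nrow(daily$values), length(starts))
  for (k in seq_along(starts)) {
    win <- daily$values[, starts[k] + 0:15, drop = FALSE]
    gap <- rowMeans(is.na(win))
    m <- rowMeans(win, na.rm = TRUE)
    m[gap > max_gap_frac] <- NA_real_
    m[gap == 1] <- NA_real_
    out[, k] <- m
  }
  grid_cube(out, daily$time[starts + 8L], daily$cells,
            daily$units, daily$name)
}

#' Monthly climatology of a cube
#'
#' Mean seasonal cycle per calendar month (January to December); each step
#' is assigned to the month of its centre date.
#'
#' @param x a `grid_cube` spanning at least one full year.
#' @return a cells x 12 matrix; `NA` where a month has no data.
#' @export
monthly_climatology <- function(x) {
  mo <- as.integer(format(x$time, "%m"))
  out <- matrix(NA_real_, nrow(x$values), 12)
  for (m in 1:12) {
    idx <- which(mo == m)
    if (length(idx)) {
      v <- rowMeans(x$values[, idx, drop = FALSE], na.rm = TRUE)
      v[!is.finite(v)] <- NA_real_
      out[, m] <- v
    }
  }
  colnames(out) <- month.abb
  out
}

#' Locally weighted trend of a deseasonalized cube
#'
#' Per-cell LOWESS (locally weighted linear smooth) with neighbourhood
#' fraction `window_frac`, evaluated at every time step (linear
#' interpolation between fitted points, nearest value beyond the ends).
#' Cells with fewer than `min_points` valid values get a constant trend at
#' the cell mean, with a warning.
#'
#' @param x a `grid_cube` of deseasonalized values.
#' @param window_frac neighbourhood fraction (default 0.4).
#' @param min_points minimum valid points for a local fit.
#' @return a `grid_cube` holding the trend component.
#' @export
lowess_trend <- function(x, window_frac = 0.4, min_points = 10L) {
  nt <- ncol(x$values)
  out <- matrix(NA_real_, nrow(x$values), nt)
  short_cells <- 0L
  for (i in seq_len(nrow(x$values))) {
    y <- x$values[i, ]
    ok <- which(!is.na(y))
    if (length(ok) == 0) next
    if (length(ok) < min_points) {
      out[i, ] <- mean(y[ok])
      short_cells <- short_cells + 1L
      next
    }
    # iter = 0: plain locally weighted linear fit. Robustness iterations
    # would make the operator nonlinear (weights depend on the residual
    # scale), so noisy and noise-free versions of the same signal would
    # be detrended differently.
    lo <- stats::lowess(ok, y[ok], f = window_frac, iter = 0)
    out[i, ] <- stats::approx(lo$x, lo$y, xout = seq_len(nt),
                              rule = 2)$y
  }
  if (short_cells > 0) {
    warning(short_cells, " cell(s) had fewer than ", min_points,
            " valid points; trend set to cell mean")
  }
  grid_cube(out, x$time, x$cells, x$units, paste0(x$name, "_trend"))
}

#' Split a cube into climatology, trend, and anomaly
#'
#' Removes the monthly mean seasonal cycle first, then a locally weighted
#' trend of the deseasonalized residual:
#' `anomaly = raw - climatology(month) - trend`. The decomposition is
#' returned whole so the reconstruction identity can be checked.
#'
#' @param x an 8-daily `grid_cube`.
#' @param window_frac LOWESS neighbourhood fraction.
#' @return an object of class `anomaly_cube`: list with `anomaly` and
#'   `trend` (`grid_cube`s), `climatology` (cells x 12), `raw` (the input),
#'   and `month` (per-step month index).
#' @export
compute_anomalies <- function(x, window_frac = 0.4) {
  clim <- monthly_climatology(x)
  mo <- as.integer(format(x$time, "%m"))
  deseas <- x$values - clim[, mo, drop = FALSE]
  trend <- lowess_trend(
    grid_cube(deseas, x$time, x$cells, x$units, x$name),
    window_frac = window_frac)
  anom <- deseas - trend$values
  structure(list(
    anomaly = grid_cube(anom, x$time, x$cells, x$units,
                        paste0(x$name, "_anom")),
    trend = trend,
    climatology = clim,
    raw = x,
    month = mo
  ), class = "anomaly_cube")
}

#' @export
print.anomaly_cube <- function(x, ...) {
  cat("<anomaly_cube> of", x$raw$name, "\n")
  print(x$anomaly)
  invisible(x)
}

#' Thickness-weighted 1-m soil moisture
#'
#' Weighted mean of three soil layers with weights proportional to layer
#' thicknesses of 7, 21, and 72 cm (weights 0.07, 0.21, 0.72). Missing in
#' any layer propagates.
#'
#' @param layer1,layer2,layer3 aligned `grid_cube`s (top to bottom).
#' @return a `grid_cube` of 1-m soil moisture.
#' @export
soil_moisture_1m <- function(layer1, layer2, layer3) {
  stopifnot(identical(dim(layer1$values), dim(layer2$values)),
            identical(dim(layer1$values), dim(layer3$values)))
  w <- c(7, 21, 72) / 100
  v <- w[1] * layer1$values + w[2] * layer2$values + w[3] * layer3$values
  grid_cube(v, layer1$time, layer1$cells, layer1$units, "sm_1m")
}

#' Cell mask from static fields and the VOD day/night criterion
#'
#' Keeps a cell iff vegetation cover (tree + shrub + grass) is at least
#' `min_cover`, irrigation fraction is at most `max_irrigation`, and — for
#' VOD-ratio analyses only (`vod_criterion = TRUE`) — its growing-season
#' mean midday VOD does not exceed the midnight mean (midday > midnight
#' indicates incomplete overnight root-zone refilling, which biases the
#' ratio). Cells with missing static fields are dropped.
#'
#' @param static data frame with `tree_frac`, `shrub_frac`, `grass_frac`,
#'   `irrigation_frac`.
#' @param vod_day,vod_night optional `grid_cube`s (required when
#'   `vod_criterion` is `TRUE`).
#' @param growing_mask optional logical cells x steps matrix restricting
#'   the VOD means to growing-season steps.
#' @param min_cover,max_irrigation thresholds (fractions).
#' @param vod_criterion apply the VOD day/night test.
#' @return logical vector, `TRUE` for kept cells.
#' @export
build_mask <- function(static, vod_day = NULL, vod_night = NULL,
                       growing_mask = NULL,
                       min_cover = 0.05, max_irrigation = 0.10,
                       vod_criterion = FALSE) {
  cover <- static$tree_frac + static$shrub_frac + static$grass_frac
  keep <- !is.na(cover) & cover >= min_cover &
    !is.na(static$irrigation_frac) &
    static$irrigation_frac <= max_irrigation
  if (vod_criterion) {
    if (is.null(vod_day) || is.null(vod_night)) {
      stop("vod_day and vod_night required for the VOD criterion")
    }
    d <- vod_day$values
    n <- vod_night$values
    if (!is.null(growing_mask)) {
      d[!growing_mask] <- NA
      n[!growing_mask] <- NA
    }
    keep <- keep & (rowMeans(d, na.rm = TRUE) <=
                      rowMeans(n, na.rm = TRUE))
  }
  keep[is.na(keep)] <- FALSE
  keep
}

#' Aridity index from net radiation and precipitation
#'
#' `AI = mean(Rn) / (lambda-converted mean precipitation)`: multi-year mean
#' net radiation divided by mean precipitation expressed as an equivalent
#' latent heat flux via the latent heat of vaporization
#' (1 mm day-1 ~ 28.94 W m-2 at lambda = 2.5e6 J kg-1). Values above 1
#' label dry cells, at or below 1 wet cells.
#'
#' @param rn `grid_cube` of net radiation, W m-2.
#' @param precip `grid_cube` of precipitation, mm day-1.
#' @param lambda latent heat of vaporization, J kg-1.
#' @return per-cell aridity index; `Inf` (with a warning) where mean
#'   precipitation is zero.
#' @export
aridity_index <- function(rn, precip, lambda = 2.5e6) {
  rn_mean <- rowMeans(rn$values, na.rm = TRUE)
  p_mean <- rowMeans(precip$values, na.rm = TRUE)
  p_flux <- p_mean * lambda / 86400
  ai <- rn_mean / p_flux
  if (any(p_mean == 0, na.rm = TRUE)) {
    warning(sum(p_mean == 0, na.rm = TRUE),
            " cell(s) with zero precipitation; aridity set to Inf")
  }
  ai
}

#' Tree- versus short-vegetation dominance
#'
#' Classifies each cell by the ratio tree / (shrub + grass) against a 0.5
#' threshold.
#'
#' @param static data frame with cover fraction columns.
#' @param threshold dominance threshold on the ratio.
#' @return character vector, `"tree"` or `"short"`.
#' @export
dominant_vegetation <- function(static, threshold = 0.5) {
  ratio <- static$tree_frac / (static$shrub_frac + static$grass_frac)
  ifelse(ratio > threshold, "tree", "short")
}
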