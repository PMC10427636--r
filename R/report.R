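#' Composite drought trajectory across cells
#'
#' Mean anomaly per trajectory step across cells (unweighted), with a
#' spatial standard error computed from the every-third-cell subsample in
#' both grid directions: the SE per step is the standard deviation of the
#' subsample anomalies divided by the square root of the subsample size.
#' Cells contribute only when at least `min_valid` of their 24 window
#' steps are valid.
#'
#' @param traj matrix of trajectories (cells x window steps), e.g. rows
#'   from [extract_trajectory()].
#' @param cells data frame with `grid_row` and `grid_col` giving each
#'   cell's position on the lat/lon grid.
#' @param min_valid minimum valid steps per cell (default 20 of 24).
#' @param every subsampling stride (default 3).
#' @param offset 0-based start offset of the subsample in both directions.
#' @return list with `mean`, `se` (per-step vectors), `n_cells`,
#'   `n_subsample`.
#' @export
composite_trajectory <- function(traj, cells, min_valid = 20L,
                                 every = 3L, offset = 0L) {
  valid <- rowSums(!is.na(traj)) >= min_valid
  used <- traj[valid, , drop = FALSE]
  if (nrow(used) == 0) {
    return(list(mean = numeric(0), se = numeric(0),
                n_cells = 0L, n_subsample = 0L))
  }
  sub_sel <- valid &
    ((cells$grid_row - 1L) %% every == offset) &
    ((cells$grid_col - 1L) %% every == offset)
  sub <- traj[sub_sel, , drop = FALSE]
  se <- if (nrow(sub) > 1) {
    apply(sub, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
    })
  } else {
    rep(NA_real_, ncol(used))
  }
  list(mean = colMeans(used, na.rm = TRUE), se = se,
       n_cells = nrow(used), n_subsample = nrow(sub))
}

#' Aridity classes with near-equal cell counts
#'
#' Quantile-based class edges over the kept cells, so each class holds a
#' similar number of cells.
#'
#' @param aridity per-cell aridity index.
#' @param n_classes number of classes.
#' @return integer class index per cell (1 = wettest), with the class
#'   edges as attribute `"edges"`.
#' @export
aridity_classes <- function(aridity, n_classes = 6L) {
  qs <- stats::quantile(aridity, probs = seq(0, 1, length.out =
                                               n_classes + 1),
                        na.rm = TRUE, type = 7)
  qs[1] <- -Inf
  qs[length(qs)] <- Inf
  cls <- as.integer(cut(aridity, qs, labels = FALSE,
                        include.lowest = TRUE))
  attr(cls, "edges") <- qs
  cls
}

#' Median anomalies per aridity class and drought phase
#'
#' Pools anomaly values over cells and steps within each class x phase bin
#' and reports the median, mirroring the box summaries of composite
#' drought figures.
#'
#' @param values matrix (cells x steps) of anomalies (total or
#'   physiological).
#' @param peak_step per-cell drought peak index (`NA` skips the cell).
#' @param classes per-cell class index, e.g. from [aridity_classes()].
#' @param phases named list of step-offset vectors relative to the peak
#'   (default: development `-12..-1`, peak `0`, recovery `1..11`).
#' @return data frame with `class`, `phase`, `median`, `n`.
#' @export
bin_medians <- function(values, peak_step, classes,
                        phases = list(development = -12:-1, peak = 0L,
                                      recovery = 1:11)) {
  nt <- ncol(values)
  out <- list()
  for (cl in sort(unique(classes[!is.na(classes)]))) {
    cells_cl <- which(classes == cl & !is.na(peak_step))
    for (ph in names(phases)) {
      pool <- c()
      for (i in cells_cl) {
        steps <- peak_step[i] + phases[[ph]]
        steps <- steps[steps >= 1 & steps <= nt]
        pool <- c(pool, values[i, steps])
      }
      pool <- pool[!is.na(pool)]
      out[[length(out) + 1]] <- data.frame(
        class = cl, phase = ph,
        median = if (length(pool)) stats::median(pool) else NA_real_,
        n = length(pool))
    }
  }
  do.call(rbind, out)
}

#' Ratio of physiological to total drought anomaly
#'
#' Per cell, the ratio of the drought-window median physiological anomaly
#' to the drought-window median total anomaly; cells with negligible total
#' anomaly (`|median| < eps`) are skipped. The class (and overall) value is
#' the median ratio across cells.
#'
#' @param decomp a `decomposition_result`.
#' @param peak_step per-cell peak index.
#' @param classes per-cell class index (`NULL` for a single overall
#'   value).
#' @param window step offsets around the peak defining the drought period.
#' @param eps negligible-total threshold.
#' @return data frame with `class`, `ratio`, `n_cells`.
#' @export
physio_total_ratio <- function(decomp, peak_step, classes = NULL,
                               window = -12:11, eps = 1e-8) {
  n <- length(decomp$kept)
  nt <- ncol(decomp$total)
  if (is.null(classes)) classes <- rep(1L, n)
  ratio <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!decomp$kept[i] || is.na(peak_step[i])) next
    steps <- peak_step[i] + window
    steps <- steps[steps >= 1 & steps <= nt]
    tot <- stats::median(decomp$total[i, steps], na.rm = TRUE)
    phy <- stats::median(decomp$physiological[i, steps], na.rm = TRUE)
    if (is.na(tot) || abs(tot) < eps) next
    ratio[i] <- phy / tot
  }
  out <- list()
  for (cl in sort(unique(classes[!is.na(classes)]))) {
    r <- ratio[classes == cl]
    r <- r[!is.na(r)]
    out[[length(out) + 1]] <- data.frame(
      class = cl,
      ratio = if (length(r)) stats::median(r) else NA_real_,
      n_cells = length(r))
  }
  do.call(rbind, out)
}

#' Bootstrap significance of drought-window anomalies
#'
#' Per cell, draws `n_samples` values with replacement from same-season
#' anomalies of non-drought years (calendar positions within
#' `halfwidth_steps` 8-day steps of the peak's position, excluding the
#' drought year) and flags the observed value as significant when it lies
#' outside the sample's 2.5-97.5 percentile range. Cells with a null pool
#' smaller than `min_pool` stay unflagged.
#'
#' @param values matrix (cells x steps) of the anomaly being tested.
#' @param dates time axis of the columns.
#' @param observed per-cell observed statistic (e.g. drought-window mean
#'   physiological anomaly).
#' @param peak_step per-cell peak index.
#' @param exclude_years calendar years excluded from the null pool
#'   (typically the drought year).
#' @param n_samples bootstrap sample size (default 1000).
#' @param halfwidth_steps seasonal tolerance in 8-day steps (default 2,
#'   i.e. +-16 days).
#' @param seed integer seed.
#' @param min_pool minimum pool size.
#' @return data frame with `cell` index, `flag`, `lo`, `hi`, `pool_n`.
#' @export
bootstrap_significance <- function(values, dates, observed, peak_step,
                                   exclude_years, n_samples = 1000L,
                                   halfwidth_steps = 2L, seed = 1L,
                                   min_pool = 10L) {
  doy <- as.POSIXlt(dates)$yday + 1
  yr <- as.integer(format(dates, "%Y"))
  n <- nrow(values)
  out <- data.frame(cell = seq_len(n), flag = FALSE,
                    lo = NA_real_, hi = NA_real_, pool_n = 0L)
  tol <- halfwidth_steps * 8 + 4  # +-2 steps with half-step slack
  for (i in seq_len(n)) {
    if (is.na(observed[i]) || is.na(peak_step[i])) next
    d0 <- doy[peak_step[i]]
    circ <- pmin(abs(doy - d0), 365.25 - abs(doy - d0))
    pool <- values[i, circ <= tol & !(yr %in% exclude_years)]
    pool <- pool[!is.na(pool)]
    out$pool_n[i] <- length(pool)
    if (length(pool) < min_pool) next
    samp <- with_seed(seed + i,
                      sample(pool, n_samples, replace = TRUE))
    q <- stats::quantile(samp, c(0.025, 0.975), names = FALSE)
    out$lo[i] <- q[1]
    out$hi[i] <- q[2]
    out$flag[i] <- observed[i] < q[1] | observed[i] > q[2]
  }
  out
}

#' Significance dots per bin
#'
#' A bin is dotted when more than `threshold` of its cells carry a
#' significant anomaly flag.
#'
#' @param flags per-cell logical significance flags.
#' @param classes per-cell class index.
#' @param threshold fraction of flagged cells required (strict, default
#'   0.6).
#' @return data frame with `class`, `frac_significant`, `dot`.
#' @export
bin_significance_dots <- function(flags, classes, threshold = 0.6) {
  out <- list()
  for (cl in sort(unique(classes[!is.na(classes)]))) {
    f <- flags[classes == cl]
    f <- f[!is.na(f)]
    frac <- if (length(f)) mean(f) else NA_real_
    out[[length(out) + 1]] <- data.frame(
      class = cl, frac_significant = frac,
      dot = !is.na(frac) && frac > threshold)
  }
  do.call(rbind, out)
}
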