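#' Midday/midnight VOD ratio
#'
#' Elementwise ratio of midday to midnight vegetation optical depth. Under
#' pre-dawn equilibrium the ratio cancels most structural (biomass)
#' variation and carries the day-night water-content asymmetry associated
#' with stomatal regulation. Missing where midnight VOD is not positive.
#'
#' @param day,night aligned `grid_cube`s of midday and midnight VOD.
#' @return a `grid_cube` of the unitless ratio.
#' @export
vod_ratio <- function(day, night) {
  stopifnot(identical(dim(day$values), dim(night$values)))
  r <- day$values / night$values
  r[!is.finite(r) | night$values <= 0] <- NA_real_
  grid_cube(r, day$time, day$cells, "1", "vod_ratio")
}

#' Configuration of the two-model decomposition
#'
#' @param leaveout_steps length of the scheduled leave-out blocks in 8-day
#'   steps (24, i.e. 192 days, in the main analysis; 12 and 6 as
#'   robustness variants). Blocks tile the record from its first step; the
#'   structure-only model predicts each block from a model trained with
#'   that block excluded.
#' @param oob_threshold cells whose full-model out-of-bag R2 does not
#'   exceed this are not kept (0, 0.1 or 0.2).
#' @param n_trees,min_node_size bagged-ensemble parameters.
#' @param min_train minimum training steps required after block exclusion.
#' @param full_leaveout if `TRUE` the full model also uses block leave-out
#'   prediction; by default it trains on the whole growing season and
#'   predicts in-sample, mirroring the asymmetric description of the
#'   method.
#' @param seed master seed; each cell uses `seed + cell index`.
#' @return list of class `decomposition_config`.
#' @export
decomposition_config <- function(leaveout_steps = 24L, oob_threshold = 0,
                                 n_trees = 500L, min_node_size = 5L,
                                 min_train = 20L, full_leaveout = FALSE,
                                 seed = 1L) {
  if (!oob_threshold %in% c(0, 0.1, 0.2)) {
    stop("oob_threshold must be 0, 0.1 or 0.2")
  }
  structure(list(leaveout_steps = as.integer(leaveout_steps),
                 oob_threshold = oob_threshold,
                 n_trees = as.integer(n_trees),
                 min_node_size = as.integer(min_node_size),
                 min_train = as.integer(min_train),
                 full_leaveout = full_leaveout,
                 seed = as.integer(seed)),
            class = "decomposition_config")
}

ranger_fit <- function(x, y, cfg, seed) {
  ranger::ranger(
    x = x, y = y,
    num.trees = cfg$n_trees, min.node.size = cfg$min_node_size,
    seed = seed, num.threads = 1,
    oob.error = TRUE, write.forest = TRUE
  )
}

# Block leave-out predictions: each calendar block is predicted by an
# ensemble trained on all other usable steps.
block_leaveout_predict <- function(x, y, steps, block_id, cfg, seed) {
  pred <- rep(NA_real_, length(y))
  for (b in unique(block_id)) {
    test <- which(block_id == b)
    train <- which(block_id != b)
    if (length(train) < cfg$min_train) next
    fit <- ranger::ranger(
      x = x[train, , drop = FALSE], y = y[train],
      num.trees = cfg$n_trees, min.node.size = cfg$min_node_size,
      seed = seed + b, num.threads = 1,
      oob.error = FALSE, write.forest = TRUE)
    pred[test] <- stats::predict(fit, x[test, , drop = FALSE],
                                 num.threads = 1)$predictions
  }
  pred
}

#' Structure-only model of one cell (leave-out predictions)
#'
#' Bagged-tree regression of the target anomaly on the structure proxy
#' (LAI, or NIRv) as the only predictor, with scheduled block leave-out:
#' the prediction for every block comes from an ensemble trained with that
#' block excluded, so drought-period structure predictions never see
#' drought-period data.
#'
#' @param target_anom,structure_anom numeric vectors over usable steps.
#' @param step_index calendar step index of each usable step (defines the
#'   leave-out block tiling from the record start).
#' @param cfg a [decomposition_config()].
#' @param seed integer seed for this cell.
#' @return numeric vector of held-out structural predictions (`NA` where a
#'   block had insufficient training data).
#' @export
fit_structure_model <- function(target_anom, structure_anom, step_index,
                                cfg = decomposition_config(), seed = 1L) {
  block_id <- (step_index - 1L) %/% cfg$leaveout_steps
  block_leaveout_predict(data.frame(structure = structure_anom),
                         target_anom, step_index, block_id, cfg, seed)
}

#' Full model of one cell (structure + hydro-meteorology)
#'
#' Bagged-tree regression on the structure proxy plus hydro-meteorological
#' anomaly predictors, trained on the whole growing season; out-of-bag
#' predictions give the screening R2 (`1 - SSE_oob / SST`). Predictions are
#' issued in-sample (or with block leave-out when the config says so).
#'
#' @param target_anom numeric target vector over usable steps.
#' @param predictors data frame of structure + met anomalies (same rows).
#' @param step_index calendar step index of each row.
#' @param cfg a [decomposition_config()].
#' @param seed integer seed for this cell.
#' @return list with `prediction`, `oob_r2`, and the fitted `model`.
#' @export
fit_full_model <- function(target_anom, predictors, step_index,
                           cfg = decomposition_config(), seed = 1L) {
  fit <- ranger_fit(predictors, target_anom, cfg, seed)
  sst <- sum((target_anom - mean(target_anom))^2)
  oob <- fit$predictions
  ok <- !is.na(oob)
  oob_r2 <- if (sst > 0 && any(ok)) {
    1 - sum((target_anom[ok] - oob[ok])^2) / sst
  } else {
    NA_real_
  }
  pred <- if (cfg$full_leaveout) {
    block_id <- (step_index - 1L) %/% cfg$leaveout_steps
    block_leaveout_predict(predictors, target_anom, step_index, block_id,
                           cfg, seed)
  } else {
    stats::predict(fit, predictors, num.threads = 1)$predictions
  }
  list(prediction = pred, oob_r2 = oob_r2, model = fit)
}

#' Physiological component as full minus structural prediction
#'
#' @param struct_pred,full_pred aligned prediction vectors or matrices.
#' @return their difference; missing wherever either side is missing.
#' @export
physiological_component <- function(struct_pred, full_pred) {
  full_pred - struct_pred
}

#' Two-model decomposition of a gridded observation stream
#'
#' For every cell: (i) a structure-only bagged-tree model with scheduled
#' block leave-out yields the structural prediction of the target anomaly;
#' (ii) a full model on structure plus hydro-meteorological anomalies,
#' trained on the whole growing season, yields the full prediction and an
#' out-of-bag R2; (iii) the physiological component is full minus
#' structural. Cells whose out-of-bag R2 does not exceed the configured
#' threshold are flagged `kept = FALSE`.
#'
#' @param target_anom `grid_cube` of target anomalies (relative SIF, ET, or
#'   VOD ratio).
#' @param structure_anom `grid_cube` of the structure-proxy anomalies (LAI,
#'   or NIRv as a variant).
#' @param met_anoms named list of `grid_cube`s of hydro-meteorological
#'   anomalies (e.g. Ta, shortwave, VPD, soil moisture, precipitation).
#' @param growing_mask logical cells x steps matrix; only in-season steps
#'   with complete data are used.
#' @param cfg a [decomposition_config()].
#' @return object of class `decomposition_result`: matrices `total`,
#'   `structural`, `full`, `physiological` (cells x steps), vector
#'   `oob_r2`, logical `kept`, plus `time`, `cells`, `config`.
#' @export
decompose_stream <- function(target_anom, structure_anom, met_anoms,
                             growing_mask, cfg = decomposition_config()) {
  n <- nrow(target_anom$values)
  nt <- ncol(target_anom$values)
  met_mat <- lapply(met_anoms, function(cc) cc$values)
  shape_ok <- vapply(met_mat, function(m) all(dim(m) == c(n, nt)), TRUE)
  stopifnot(all(shape_ok), all(dim(structure_anom$values) == c(n, nt)))

  structural <- matrix(NA_real_, n, nt)
  full <- matrix(NA_real_, n, nt)
  total <- matrix(NA_real_, n, nt)
  oob_r2 <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    y <- target_anom$values[i, ]
    xs <- structure_anom$values[i, ]
    xm <- vapply(met_mat, function(m) m[i, ], numeric(nt))
    usable <- which(growing_mask[i, ] & !is.na(y) & !is.na(xs) &
                      rowSums(is.na(xm)) == 0)
    if (length(usable) < cfg$min_train + cfg$leaveout_steps) next
    preds <- data.frame(structure = xs[usable],
                        xm[usable, , drop = FALSE])
    seed_i <- cfg$seed + i
    sp <- fit_structure_model(y[usable], xs[usable], usable, cfg, seed_i)
    fm <- fit_full_model(y[usable], preds, usable, cfg, seed_i)
    structural[i, usable] <- sp
    full[i, usable] <- fm$prediction
    total[i, usable] <- y[usable]
    oob_r2[i] <- fm$oob_r2
  }
  physio <- physiological_component(structural, full)
  structure(list(
    total = total, structural = structural, full = full,
    physiological = physio,
    oob_r2 = oob_r2,
    kept = !is.na(oob_r2) & oob_r2 > cfg$oob_threshold,
    time = target_anom$time, cells = target_anom$cells,
    config = cfg, target = target_anom$name
  ), class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf(
    "<decomposition_result> %s: %d cells (%d kept), median OOB R2 %.3f\n",
    x$target, length(x$kept), sum(x$kept),
    stats::median(x$oob_r2, na.rm = TRUE)))
  invisible(x)
}

#' Multiple-linear-regression decomposition of one cell
#'
#' Ordinary least squares of the target anomaly on the structure proxy and
#' hydro-meteorological anomalies over all usable steps; the physiological
#' component is the sum of the fitted met terms evaluated at each step.
#' Collinear columns dropped by the fit contribute zero, with a warning.
#'
#' @param target_anom numeric vector.
#' @param structure_anom numeric vector.
#' @param met_anoms data frame of met anomaly columns (same rows).
#' @return list with `physiological` (vector), `structural`
#'   (intercept + structure term), `coefficients`.
#' @export
mlr_decomposition <- function(target_anom, structure_anom, met_anoms) {
  df <- data.frame(y = target_anom, structure = structure_anom, met_anoms)
  fit <- stats::lm(y ~ ., data = df)
  beta <- stats::coef(fit)
  if (anyNA(beta)) {
    warning("collinear predictors dropped: ",
            paste(names(beta)[is.na(beta)], collapse = ", "))
    beta[is.na(beta)] <- 0
  }
  met_names <- names(met_anoms)
  physio <- as.matrix(met_anoms) %*% beta[met_names]
  structural <- beta[1] + beta["structure"] * structure_anom
  list(physiological = as.numeric(physio),
       structural = as.numeric(structural),
       coefficients = beta)
}

#' Exact interventional Shapley values
#'
#' Enumerates all predictor subsets and computes, for every row of `x`,
#' the exact Shapley contribution of each predictor with the
#' interventional value function
#' `v(S) = mean_b f(x_S, background_b)`. The efficiency axiom holds by
#' construction: contributions sum to `f(x) - mean_b f(background_b)`.
#' Intended for the small predictor sets used here (cost grows as `2^p`).
#'
#' @param predict_fn function taking a data frame and returning numeric
#'   predictions (e.g. wrapping a fitted ensemble).
#' @param x data frame of rows to explain.
#' @param background data frame of background rows used to marginalise
#'   absent predictors.
#' @return list with `shap` (rows x predictors matrix), `base` (scalar
#'   mean background prediction), and `prediction` (`f(x)`).
#' @export
shapley_values <- function(predict_fn, x, background) {
  p <- ncol(x)
  if (p > 12) stop("exact enumeration limited to 12 predictors")
  nx <- nrow(x)
  nb <- nrow(background)
  n_sub <- 2^p
  # value function for every subset (bitmask order)
  v <- matrix(NA_real_, nx, n_sub)
  base_block <- background[rep(seq_len(nb), times = nx), , drop = FALSE]
  x_rep <- x[rep(seq_len(nx), each = nb), , drop = FALSE]
  for (s in 0:(n_sub - 1)) {
    members <- which(bitwAnd(s, bitwShiftL(1L, 0:(p - 1))) > 0)
    z <- base_block
    if (length(members)) z[, members] <- x_rep[, members, drop = FALSE]
    pred <- predict_fn(z)
    v[, s + 1] <- colMeans(matrix(pred, nb, nx))
  }
  wts <- factorial(0:(p - 1)) * factorial(p - 1 - (0:(p - 1))) /
    factorial(p)
  shap <- matrix(0, nx, p, dimnames = list(NULL, colnames(x)))
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    for (s in 0:(n_sub - 1)) {
      if (bitwAnd(s, bit) > 0) next
      size <- sum(bitwAnd(s, bitwShiftL(1L, 0:(p - 1))) > 0)
      shap[, j] <- shap[, j] +
        wts[size + 1] * (v[, s + bit + 1] - v[, s + 1])
    }
  }
  list(shap = shap, base = v[1, 1], prediction = v[, n_sub])
}

#' Shapley-value decomposition of one cell
#'
#' Fits the full bagged-tree model (structure + met) and takes the sum of
#' the exact Shapley contributions of the met predictors per step as the
#' physiological component.
#'
#' @param target_anom numeric target vector over usable steps.
#' @param structure_anom numeric structure-proxy vector.
#' @param met_anoms data frame of met anomaly columns.
#' @param cfg a [decomposition_config()].
#' @param seed integer seed.
#' @param n_background background rows (sampled from the data) used to
#'   marginalise the value function.
#' @return list with `physiological`, `structural` (structure Shapley term
#'   plus base), `shap` matrix, `base`, `model`.
#' @export
shapley_decomposition <- function(target_anom, structure_anom, met_anoms,
                                  cfg = decomposition_config(), seed = 1L,
                                  n_background = 30L) {
  preds <- data.frame(structure = structure_anom, met_anoms)
  fit <- ranger_fit(preds, target_anom, cfg, seed)
  bg_idx <- with_seed(seed, sample.int(nrow(preds),
                                       min(n_background, nrow(preds))))
  sv <- shapley_values(
    function(z) stats::predict(fit, z, num.threads = 1)$predictions,
    preds, preds[bg_idx, , drop = FALSE])
  met_names <- names(met_anoms)
  list(physiological = rowSums(sv$shap[, met_names, drop = FALSE]),
       structural = sv$base + sv$shap[, "structure"],
       shap = sv$shap, base = sv$base, prediction = sv$prediction,
       model = fit)
}
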