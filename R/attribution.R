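#' Assemble the spatial driver table
#'
#' One row per kept, drought-affected cell: static drivers (aridity, tree
#' cover fraction), drought durations, hydro-meteorological anomalies
#' averaged over the 3-month drought development window
#' (`peak - 12 .. peak`) — and, for recovery targets, additionally over the
#' recovery window (`peak + 1 .. peak + 11`) — and as response the window
#' mean of one stream's physiological anomaly. Rows with any missing
#' driver or response are dropped.
#'
#' @param decomp a `decomposition_result`.
#' @param events events table from [detect_drought_events()].
#' @param met_anoms named list of `grid_cube`s of met anomalies.
#' @param static data frame with `aridity` and `tree_frac` per cell (same
#'   order as the cubes).
#' @param period `"development"` or `"recovery"`: which window defines the
#'   response (recovery responses also carry recovery-window drivers).
#' @return data frame of drivers plus `response` and `cell`.
#' @export
build_driver_table <- function(decomp, events, met_anoms, static,
                               period = c("development", "recovery")) {
  period <- match.arg(period)
  n <- length(decomp$kept)
  nt <- ncol(decomp$physiological)
  win_mean <- function(mat, i, steps) {
    steps <- steps[steps >= 1 & steps <= nt]
    if (!length(steps)) return(NA_real_)
    v <- mat[i, steps]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  rows <- list()
  for (i in seq_len(n)) {
    if (!decomp$kept[i]) next
    pk <- events$peak_step[i]
    if (is.na(pk)) next
    dev_steps <- (pk - 12):pk
    rec_steps <- (pk + 1):(pk + 11)
    resp_steps <- if (period == "development") dev_steps else rec_steps
    row <- list(
      cell = decomp$cells$cell[i],
      aridity = static$aridity[i],
      tree_frac = static$tree_frac[i],
      dev_duration = events$dev_duration[i],
      response = win_mean(decomp$physiological, i, resp_steps)
    )
    for (nm in names(met_anoms)) {
      row[[paste0(nm, "_dev")]] <-
        win_mean(met_anoms[[nm]]$values, i, dev_steps)
    }
    if (period == "recovery") {
      row$recov_duration <- events$recov_duration[i]
      for (nm in names(met_anoms)) {
        row[[paste0(nm, "_recov")]] <-
          win_mean(met_anoms[[nm]]$values, i, rec_steps)
      }
    }
    rows[[length(rows) + 1]] <- row
  }
  tab <- do.call(rbind, lapply(rows, as.data.frame))
  if (is.null(tab)) return(data.frame())
  tab[stats::complete.cases(tab), , drop = FALSE]
}

#' Driver importance by exact Shapley values on a spatial ensemble model
#'
#' Fits a bagged-tree regression of the response on all drivers across
#' cells, reports a k-fold cross-validation R2, and ranks drivers by the
#' mean absolute exact Shapley value (in response units, unnormalised).
#'
#' @param table driver table from [build_driver_table()].
#' @param seed integer seed (folds, ensemble, background sample).
#' @param n_trees ensemble size.
#' @param folds number of cross-validation folds over cells.
#' @param n_background background rows for the Shapley value function.
#' @param min_rows minimum rows required.
#' @return list of class `importance_result`: data frame `importance`
#'   (driver, mean_abs_shap, rank), `cv_r2`, the fitted `model`, and the
#'   per-row `shap` matrix.
#' @export
shapley_importance <- function(table, seed = 1L, n_trees = 300L,
                               folds = 5L, n_background = 30L,
                               min_rows = 50L) {
  if (nrow(table) < min_rows) {
    stop("need at least ", min_rows, " rows for attribution, got ",
         nrow(table))
  }
  drivers <- setdiff(names(table), c("cell", "response"))
  x <- table[, drivers, drop = FALSE]
  y <- table$response
  cfg <- list(n_trees = as.integer(n_trees), min_node_size = 5L)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), nrow(x))))
  pred_cv <- rep(NA_real_, nrow(x))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fit_f <- ranger::ranger(x = x[!test, , drop = FALSE], y = y[!test],
                            num.trees = n_trees, min.node.size = 5,
                            seed = seed + f, num.threads = 1,
                            oob.error = FALSE)
    pred_cv[test] <- stats::predict(fit_f, x[test, , drop = FALSE],
                                    num.threads = 1)$predictions
  }
  cv_r2 <- 1 - sum((y - pred_cv)^2) / sum((y - mean(y))^2)

  fit <- ranger::ranger(x = x, y = y, num.trees = n_trees,
                        min.node.size = 5, seed = seed, num.threads = 1,
                        oob.error = TRUE)
  bg <- with_seed(seed, x[sample.int(nrow(x), min(n_background,
                                                  nrow(x))), ,
                          drop = FALSE])
  sv <- shapley_values(
    function(z) stats::predict(fit, z, num.threads = 1)$predictions,
    x, bg)
  mabs <- colMeans(abs(sv$shap))
  imp <- data.frame(driver = drivers, mean_abs_shap = mabs)
  imp <- imp[order(-imp$mean_abs_shap), ]
  imp$rank <- seq_len(nrow(imp))
  rownames(imp) <- NULL
  structure(list(importance = imp, cv_r2 = cv_r2, model = fit,
                 shap = sv$shap, base = sv$base,
                 prediction = sv$prediction, method = "shapley"),
            class = "importance_result")
}

#' Driver importance by absolute Spearman correlation
#'
#' Rank correlation between each driver and the response across cells;
#' drivers are ranked by `|rho|`. Constant drivers (undefined correlation)
#' rank last.
#'
#' @param table driver table from [build_driver_table()].
#' @param min_rows minimum rows required.
#' @return list of class `importance_result` with data frame `importance`
#'   (driver, abs_rho, rank).
#' @export
spearman_importance <- function(table, min_rows = 10L) {
  if (nrow(table) < min_rows) {
    stop("need at least ", min_rows, " rows, got ", nrow(table))
  }
  drivers <- setdiff(names(table), c("cell", "response"))
  rho <- vapply(drivers, function(d) {
    v <- table[[d]]
    if (length(unique(v)) < 2) return(NA_real_)
    abs(stats::cor(v, table$response, method = "spearman"))
  }, numeric(1))
  imp <- data.frame(driver = drivers, abs_rho = rho)
  imp <- imp[order(-imp$abs_rho, na.last = TRUE), ]
  imp$rank <- seq_len(nrow(imp))
  rownames(imp) <- NULL
  structure(list(importance = imp, method = "spearman"),
            class = "importance_result")
}

#' Top-k agreement between two importance rankings
#'
#' @param a,b `importance_result`s.
#' @param k compare the top `k` drivers (default 5).
#' @return integer: number of drivers shared by the two top-k sets.
#' @export
importance_overlap <- function(a, b, k = 5L) {
  top <- function(r) utils::head(r$importance$driver, k)
  length(intersect(top(a), top(b)))
}

#' @export
print.importance_result <- function(x, ...) {
  cat("<importance_result> method:", x$method)
  if (!is.null(x$cv_r2)) cat(sprintf(", CV R2 = %.3f", x$cv_r2))
  cat("\n")
  print(x$importance)
  invisible(x)
}
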