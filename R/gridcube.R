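#' Gridded (cell x time) data cube
#'
#' The basic container used throughout the package: one variable on a set of
#' grid cells at a fixed temporal step. Values are held as a numeric matrix
#' with one row per cell and one column per time step; `NA` marks missing
#' observations. Cell metadata (ids, coordinates, static attributes) travel
#' with the cube so that masking and spatial subsampling can be done without
#' external bookkeeping.
#'
#' @param values numeric matrix, cells in rows, time steps in columns.
#' @param time vector of `Date`s (strictly increasing, fixed step), one per
#'   column of `values`.
#' @param cells data frame with at least a `cell` id column; typically also
#'   `lat`, `lon` and any static attributes. One row per row of `values`.
#' @param units unit string for the variable (free text, CF-style).
#' @param name variable name.
#'
#' @return an object of class `grid_cube`.
#' @export
grid_cube <- function(values, time, cells = NULL, units = "", name = "") {
  values <- as.matrix(values)
  time <- as.Date(time)
  if (ncol(values) != length(time)) {
    stop("`values` must have one column per time step")
  }
  if (length(time) > 1 && any(diff(as.numeric(time)) <= 0)) {
    stop("`time` must be strictly increasing")
  }
  if (is.null(cells)) {
    cells <- data.frame(cell = seq_len(nrow(values)))
  }
  if (nrow(cells) != nrow(values)) {
    stop("`cells` must have one row per row of `values`")
  }
  structure(
    list(values = values, time = time, cells = cells,
         units = units, name = name),
    class = "grid_cube"
  )
}

#' @export
print.grid_cube <- function(x, ...) {
  cat(sprintf(
    "<grid_cube> %s [%s]: %d cells x %d steps (%s .. %s), %.1f%% missing\n",
    if (nzchar(x$name)) x$name else "unnamed",
    x$units, nrow(x$values), ncol(x$values),
    format(x$time[1]), format(x$time[length(x$time)]),
    100 * mean(is.na(x$values))
  ))
  invisible(x)
}

#' @export
dim.grid_cube <- function(x) dim(x$values)

#' Number of days between consecutive time steps of a cube
#' @param x a `grid_cube`.
#' @return integer step length in days (1 for daily, 8 for 8-daily, ...).
#' @export
time_step_days <- function(x) {
  if (length(x$time) < 2) return(NA_integer_)
  as.integer(round(stats::median(diff(as.numeric(x$time)))))
}

#' Subset a cube by cells and/or time steps
#' @param x a `grid_cube`.
#' @param cells row indices (or logical mask) of cells to keep.
#' @param steps column indices (or logical mask) of time steps to keep.
#' @return a `grid_cube`.
#' @export
cube_subset <- function(x, cells = NULL, steps = NULL) {
  if (is.null(cells)) cells <- seq_len(nrow(x$values))
  if (is.null(steps)) steps <- seq_len(ncol(x$values))
  grid_cube(x$values[cells, steps, drop = FALSE], x$time[steps],
            x$cells[cells, , drop = FALSE], x$units, x$name)
}

#' Apply a function cell-wise over a cube
#' @keywords internal
cube_map <- function(x, f, ...) {
  out <- t(apply(x$values, 1, f, ...))
  if (nrow(out) != nrow(x$values)) out <- t(out)
  grid_cube(out, x$time, x$cells, x$units, x$name)
}

#' Write a cube as long-format CSV (cell, date, value)
#'
#' Plain-text serialisation used for all on-disk exchange; the companion
#' reader restores the cube including cell metadata (stored alongside as
#' `<path>.cells.csv` when `cells` has more than the id column).
#'
#' @param x a `grid_cube`.
#' @param path output CSV path.
#' @export
write_cube_csv <- function(x, path) {
  long <- data.frame(
    cell = rep(x$cells$cell, times = ncol(x$values)),
    date = rep(x$time, each = nrow(x$values)),
    value = as.vector(x$values)
  )
  utils::write.csv(long, path, row.names = FALSE)
  if (ncol(x$cells) > 1) {
    utils::write.csv(x$cells, paste0(path, ".cells.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a cube from long-format CSV written by [write_cube_csv()]
#' @param path CSV path.
#' @param units,name variable metadata to attach.
#' @return a `grid_cube`.
#' @export
read_cube_csv <- function(path, units = "", name = "") {
  long <- utils::read.csv(path)
  time <- sort(unique(as.Date(long$date)))
  ids <- unique(long$cell)
  values <- matrix(NA_real_, length(ids), length(time))
  i <- match(long$cell, ids)
  j <- match(as.Date(long$date), time)
  values[cbind(i, j)] <- long$value
  cells_path <- paste0(path, ".cells.csv")
  cells <- if (file.exists(cells_path)) {
    utils::read.csv(cells_path)
  } else {
    data.frame(cell = ids)
  }
  grid_cube(values, time, cells[match(ids, cells$cell), , drop = FALSE],
            units, name)
}
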