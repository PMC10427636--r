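# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# A small but complete synthetic dataset (40 cells, 5 years).
small_sim <- function() {
  if (is.null(.fixtures$small)) {
    cfg <- sim_config(n_cells = 40L, seed = 42L)
    .fixtures$small <- list(cfg = cfg, ds = simulate_dataset(cfg))
  }
  .fixtures$small
}

# Noise-free variant of the same conditions (encoding checks).
noisefree_sim <- function() {
  if (is.null(.fixtures$noisefree)) {
    cfg <- sim_config(
      n_cells = 12L, seed = 42L, precip_cv = 0,
      noise_sd = list(sif = 0, et = 0, vod = 0, lai = 0, nirv = 0, ta = 0, sw = 0,
                      vpd = 0))
    .fixtures$noisefree <- list(cfg = cfg, ds = simulate_dataset(cfg))
  }
  .fixtures$noisefree
}

# Daily constant-valued cube over n cells and dates.
constant_daily_cube <- function(value = 5, n_cells = 3, n_days = 64,
                                start = as.Date("2019-01-01")) {
  grid_cube(matrix(value, n_cells, n_days),
            seq(start, by = 1, length.out = n_days),
            units = "x", name = "const")
}
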