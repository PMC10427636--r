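test_that("growing season needs warm temperatures and an active SIF climatology", {
  tm <- as.Date(c("2020-01-10", "2020-06-10", "2020-07-10"))
  ta <- grid_cube(matrix(c(4, 10, 10), 1, 3), tm, units = "degC")
  clim <- matrix(0, 1, 12)
  clim[1, 6] <- 0.5
  clim[1, 7] <- 0.2   # exactly at the threshold -> out (strict)
  mask <- growing_season_mask(ta, clim)
  expect_equal(as.vector(mask), c(FALSE, TRUE, FALSE))

  # temperature in K is converted before thresholding
  ta_k <- grid_cube(matrix(c(4, 10, 10) + 273.15, 1, 3), tm, units = "K")
  expect_equal(growing_season_mask(ta_k, clim), mask)

  # missing temperature counts as out of season
  ta2 <- grid_cube(matrix(c(NA, 10, 10), 1, 3), tm, units = "degC")
  expect_false(growing_season_mask(ta2, clim)[1, 1])
})

test_that("40-year ranking selects cells with study-period record minima", {
  # 40 years x 12 months, 3 cells: record minimum planted in year 39
  # (study), year 7 (not study), and a tie between years 10 and 39
  years <- 1982:2021
  tm <- as.Date(sprintf("%d-%02d-15", rep(years, each = 12), 1:12))
  base <- 0.30 + 0.02 * sin(2 * pi * (1:12) / 12)
  v <- matrix(rep(base, length(years)), 3, length(tm), byrow = TRUE)
  v[1, (39 - 1) * 12 + 7] <- 0.10
  v[2, (7 - 1) * 12 + 7] <- 0.10
  v[3, (10 - 1) * 12 + 7] <- 0.10
  v[3, (39 - 1) * 12 + 7] <- 0.10  # exact tie; later year wins
  smm <- grid_cube(v, tm, cells = data.frame(cell = 1:3))
  sel <- select_drought_cells(smm, study_years = 2018:2021)
  expect_equal(sel, c(TRUE, FALSE, TRUE))

  # fewer than 30 valid years excludes the cell
  v4 <- v[1, , drop = FALSE]
  v4[1, 1:(15 * 12)] <- NA
  smm4 <- grid_cube(v4, tm)
  expect_false(select_drought_cells(smm4, 2018:2021))
})

test_that("peak detection takes the in-season minimum with stated tie-breaks", {
  tm <- seq(as.Date("2020-04-01"), by = 8, length.out = 50)
  v <- 0.3 + 0.05 * sin(seq_len(50) / 5)
  v[37] <- 0.1
  sm <- grid_cube(rbind(v, v), tm, cells = data.frame(cell = 1:2))
  sm$values[2, 20] <- 0.1  # equal minima at 20 and 37 -> earlier wins
  mask <- matrix(TRUE, 2, 50)
  pk <- find_peak(sm, mask)
  expect_equal(pk, c(37L, 20L))

  # masked-out steps cannot host the peak
  mask2 <- mask
  mask2[1, 37] <- FALSE
  expect_false(find_peak(sm, mask2)[1] == 37L)

  # all-missing series yields no event
  sm$values[1, ] <- NA
  expect_true(is.na(find_peak(sm, mask)[1]))
})

test_that("durations count consecutive negative anomalies around the peak", {
  # hand-counted: [+, -, -, peak(-), -, +] -> development 3, recovery 1
  d <- drought_durations(c(0.1, -0.1, -0.2, -0.3, -0.1, 0.2), 4)
  expect_equal(d$dev_duration, 3L)
  expect_equal(d$recov_duration, 1L)
  expect_false(any(d$censored))

  # non-negative anomalies adjacent to the peak on both sides
  d2 <- drought_durations(c(0.1, 0.0, -0.3, 0.0, 0.1), 3)
  expect_equal(d2$dev_duration, 1L)
  expect_equal(d2$recov_duration, 0L)

  # all-negative window censors both sides at the record edge
  d3 <- drought_durations(rep(-0.1, 5), 3)
  expect_true(all(d3$censored))

  # missing value stops the walk and flags censoring
  d4 <- drought_durations(c(NA, -0.2, -0.3, -0.1, 0.2), 3)
  expect_equal(d4$dev_duration, 2L)
  expect_true(d4$censored["dev"])
})

test_that("trajectories are 24 steps with the peak 13th, padded at edges", {
  series <- seq_len(100)
  tr <- extract_trajectory(series, 50)
  expect_length(tr$values, 24)
  expect_equal(tr$offsets, -12:11)
  expect_equal(tr$values[13], 50)  # offset 0
  expect_equal(tr$valid_count, 24L)

  edge <- extract_trajectory(series, 5)
  expect_true(all(is.na(edge$values[1:8])))  # offsets -12..-5 precede start
  expect_equal(edge$valid_count, 16L)
})

test_that("severity requires 1.5 SD below the long-record seasonal mean", {
  years <- 1982:2021
  tm <- as.Date(sprintf("%d-%02d-15", rep(years, each = 12), 1:12))
  set.seed(5)
  v <- matrix(0.30 + rnorm(3 * length(tm), 0, 0.02), 3, length(tm))
  v[3, ] <- 0.30  # zero SD cell
  smm <- grid_cube(v, tm, cells = data.frame(cell = 1:3))
  mo <- 7L
  stats_v <- v[1, rep(1:12, length(years)) == mo]
  z2 <- mean(stats_v) - 2.0 * sd(stats_v)
  z1 <- mean(stats_v) - 1.0 * sd(stats_v)
  sev <- severity_filter(c(z2, z1, 0.30), rep(mo, 3), smm)
  expect_equal(sev, c(TRUE, FALSE, FALSE))
})

test_that("end-to-end: configured drought cells are selected and peak inside suppression", {
  s <- small_sim()
  ds <- s$ds
  sif_clim <- monthly_climatology(ds$obs$sif)
  gmask <- growing_season_mask(ds$met$ta, sif_clim)
  anoms <- compute_anomalies(ds$met$sm)
  ev <- detect_drought_events(ds$met$sm, anoms$anomaly,
                              ds$met$sm_monthly_40yr, gmask,
                              study_years = 2017:2021)
  dc <- s$cfg$drought_cells
  expect_true(all(ev$selected[dc]))
  expect_true(all(ev$peak_step[dc] %in% ds$met$suppress_steps))
  # severe at the default generator strength in nearly all drought cells
  expect_gte(mean(ev$severe[dc]), 0.9)
  # anomaly-variant peaks stay in the drought year
  pk_anom <- find_peak(ds$met$sm, gmask, anoms$anomaly,
                       variant = "anomaly")
  yr_of <- function(p) as.integer(format(ds$met$dates[p], "%Y"))
  expect_true(mean(yr_of(pk_anom[dc]) == ds$met$drought_year) >= 0.9)
})

test_that("second-rank exclusion is a pure subset of the selection", {
  s <- small_sim()
  smm <- s$ds$met$sm_monthly_40yr
  sel1 <- select_drought_cells(smm, 2017:2021, rank = 1)
  sel2 <- select_drought_cells(smm, 2017:2021, rank = 2)
  robust <- sel1 & !sel2
  expect_true(all(which(robust) %in% which(sel1)))
})
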