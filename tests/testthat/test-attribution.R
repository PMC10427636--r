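# A self-contained driver-table fixture: a decomposition-like object and
# events with planted spatial structure.
make_attr_fixture <- function(n = 120, seed = 21, planted = TRUE) {
  set.seed(seed)
  nt <- 100
  aridity <- runif(n, 0.4, 2.2)
  tree <- runif(n, 0.05, 0.7)
  phys <- matrix(rnorm(n * nt, 0, 0.02), n, nt)
  peak <- rep(50L, n)
  resp_core <- if (planted) {
    -0.5 * aridity + 0.8 * tree
  } else {
    rnorm(n)
  }
  for (i in seq_len(n)) {
    phys[i, 38:50] <- phys[i, 38:50] + resp_core[i]
  }
  decomp <- structure(list(
    physiological = phys, total = phys, structural = 0 * phys,
    full = phys, oob_r2 = rep(0.5, n), kept = rep(TRUE, n),
    time = seq(as.Date("2020-01-01"), by = 8, length.out = nt),
    cells = data.frame(cell = seq_len(n)),
    config = decomposition_config(), target = "synthetic"
  ), class = "decomposition_result")
  events <- data.frame(cell = seq_len(n), selected = TRUE,
                       peak_step = peak, dev_duration = 5L,
                       recov_duration = 4L)
  tm <- decomp$time
  met <- list(
    vpd = grid_cube(matrix(rnorm(n * nt), n, nt), tm,
                    cells = decomp$cells),
    sm = grid_cube(matrix(rnorm(n * nt), n, nt), tm,
                   cells = decomp$cells))
  static <- data.frame(aridity = aridity, tree_frac = tree)
  list(decomp = decomp, events = events, met = met, static = static,
       resp_core = resp_core)
}

test_that("driver table rows, windows, and bookkeeping are correct", {
  fx <- make_attr_fixture()
  tab <- build_driver_table(fx$decomp, fx$events, fx$met, fx$static)
  expect_equal(nrow(tab), 120)  # kept cells minus dropped rows (none)
  expect_true(all(c("aridity", "tree_frac", "dev_duration",
                    "vpd_dev", "sm_dev", "response") %in% names(tab)))
  # window averaging cross-checked by direct slicing on one cell
  i <- 7
  w <- (fx$events$peak_step[i] - 12):fx$events$peak_step[i]
  expect_equal(tab$response[tab$cell == i],
               mean(fx$decomp$physiological[i, w]))
  expect_equal(tab$vpd_dev[tab$cell == i],
               mean(fx$met$vpd$values[i, w]))

  rec <- build_driver_table(fx$decomp, fx$events, fx$met, fx$static,
                            period = "recovery")
  expect_true(all(c("recov_duration", "vpd_recov") %in% names(rec)))
  wr <- (fx$events$peak_step[i] + 1):(fx$events$peak_step[i] + 11)
  expect_equal(rec$response[rec$cell == i],
               mean(fx$decomp$physiological[i, wr]))

  # a cell that is not kept drops out
  fx$decomp$kept[3] <- FALSE
  expect_equal(nrow(build_driver_table(fx$decomp, fx$events, fx$met,
                                       fx$static)), 119)
})

test_that("planted drivers are recovered as top-ranked by Shapley importance", {
  fx <- make_attr_fixture()
  tab <- build_driver_table(fx$decomp, fx$events, fx$met, fx$static)
  imp <- shapley_importance(tab, seed = 1L)
  top2 <- imp$importance$driver[1:2]
  expect_setequal(top2, c("aridity", "tree_frac"))
  expect_gt(imp$cv_r2, 0.35)
  # Shapley efficiency on the attribution model
  pred <- predict(imp$model, tab[, setdiff(names(tab),
                                           c("cell", "response"))],
                  num.threads = 1)$predictions
  expect_equal(imp$base + rowSums(imp$shap), pred, tolerance = 1e-6)
})

test_that("a pure-noise response has no cross-validated skill", {
  fx <- make_attr_fixture(planted = FALSE, seed = 22)
  tab <- build_driver_table(fx$decomp, fx$events, fx$met, fx$static)
  imp <- shapley_importance(tab, seed = 1L)
  expect_lt(imp$cv_r2, 0.1)
})

test_that("permuting a driver never increases its importance", {
  fx <- make_attr_fixture()
  tab <- build_driver_table(fx$decomp, fx$events, fx$met, fx$static)
  imp <- shapley_importance(tab, seed = 1L)
  before <- imp$importance$mean_abs_shap[imp$importance$driver ==
                                           "aridity"]
  tab2 <- tab
  set.seed(2)
  tab2$aridity <- sample(tab2$aridity)
  imp2 <- shapley_importance(tab2, seed = 1L)
  after <- imp2$importance$mean_abs_shap[imp2$importance$driver ==
                                           "aridity"]
  expect_lt(after, before)
})

test_that("Spearman ranking agrees with Shapley on planted drivers", {
  fx <- make_attr_fixture()
  tab <- build_driver_table(fx$decomp, fx$events, fx$met, fx$static)
  sp <- spearman_importance(tab)
  # monotone noiseless relation scores |rho| near 1 for aridity + tree mix
  expect_true(all(c("aridity", "tree_frac") %in%
                    sp$importance$driver[1:2]))
  # constant drivers rank last
  expect_equal(sp$importance$driver[nrow(sp$importance)] %in%
                 c("dev_duration"), TRUE)
  sh <- shapley_importance(tab, seed = 1L)
  expect_gte(importance_overlap(sh, sp, k = 5), 3)
})

test_that("row minima are enforced", {
  fx <- make_attr_fixture(n = 30)
  tab <- build_driver_table(fx$decomp, fx$events, fx$met, fx$static)
  expect_error(shapley_importance(tab), "at least 50")
  expect_error(spearman_importance(tab[1:5, ]), "at least 10")
})
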