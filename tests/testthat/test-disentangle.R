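test_that("VOD ratio divides elementwise and guards non-positive nights", {
  tm <- seq(as.Date("2020-06-01"), by = 8, length.out = 3)
  day <- grid_cube(matrix(c(0.5, 0.55, 0.5), 1, 3), tm)
  night <- grid_cube(matrix(c(0.5, 0.50, 0), 1, 3), tm)
  r <- vod_ratio(day, night)
  expect_equal(r$values[1, 1:2], c(1.0, 1.1))
  expect_true(is.na(r$values[1, 3]))
})

test_that("structure model recovers a known monotone relation out of sample", {
  set.seed(11)
  n <- 184
  x <- as.numeric(arima.sim(list(ar = 0.5), n, sd = 1))
  y <- 2 * x  # noise-free known relation
  pred <- fit_structure_model(y, x, seq_len(n),
                              decomposition_config(), seed = 3L)
  ok <- !is.na(pred)
  rmse <- sqrt(mean((pred[ok] - y[ok])^2))
  expect_lt(rmse / sd(y), 0.10)
})

test_that("a target independent of structure has no held-out skill", {
  set.seed(12)
  r2s <- replicate(5, {
    n <- 184
    x <- rnorm(n)
    y <- rnorm(n)
    pred <- fit_structure_model(y, x, seq_len(n),
                                decomposition_config(), seed = 7L)
    ok <- !is.na(pred)
    1 - sum((y[ok] - pred[ok])^2) / sum((y[ok] - mean(y[ok]))^2)
  })
  expect_lt(mean(r2s), 0.05)
})

test_that("model fits are deterministic given the seed", {
  set.seed(13)
  n <- 150
  x <- rnorm(n)
  y <- x + rnorm(n, 0, 0.2)
  p1 <- fit_structure_model(y, x, seq_len(n), seed = 5L)
  p2 <- fit_structure_model(y, x, seq_len(n), seed = 5L)
  expect_identical(p1, p2)
  met <- data.frame(vpd = rnorm(n))
  f1 <- fit_full_model(y, data.frame(structure = x, met), seq_len(n),
                       seed = 5L)
  f2 <- fit_full_model(y, data.frame(structure = x, met), seq_len(n),
                       seed = 5L)
  expect_identical(f1$prediction, f2$prediction)
  expect_identical(f1$oob_r2, f2$oob_r2)
})

test_that("full model screens cells by out-of-bag skill", {
  set.seed(14)
  n <- 184
  x <- rnorm(n)
  met <- data.frame(vpd = rnorm(n), sm = rnorm(n))
  y_signal <- x + 0.8 * met$vpd + rnorm(n, 0, 0.1)
  y_noise <- rnorm(n)
  f_sig <- fit_full_model(y_signal, data.frame(structure = x, met),
                          seq_len(n), seed = 2L)
  f_noise <- fit_full_model(y_noise, data.frame(structure = x, met),
                            seq_len(n), seed = 2L)
  expect_gt(f_sig$oob_r2, 0.8)
  expect_lt(f_noise$oob_r2, 0.1)
})

test_that("decomposition identity holds exactly and thresholds are monotone", {
  s <- small_sim()
  ds <- s$ds
  pl <- run_decomposition_pipeline(ds, "sifrel")
  d <- pl$decomp
  ok <- !is.na(d$physiological)
  expect_equal(d$physiological[ok], (d$full - d$structural)[ok],
               tolerance = 1e-12)
  # raising the threshold never adds kept cells
  kept0 <- !is.na(d$oob_r2) & d$oob_r2 > 0
  kept01 <- !is.na(d$oob_r2) & d$oob_r2 > 0.1
  kept02 <- !is.na(d$oob_r2) & d$oob_r2 > 0.2
  expect_true(all(which(kept02) %in% which(kept01)))
  expect_true(all(which(kept01) %in% which(kept0)))
})

test_that("null-structure target assigns nothing to physiology under MLR", {
  set.seed(15)
  n <- 200
  lai <- rnorm(n)
  met <- data.frame(vpd = rnorm(n), sm = rnorm(n))
  y <- 0.9 * lai + rnorm(n, 0, 0.05)
  dec <- mlr_decomposition(y, lai, met)
  expect_lt(max(abs(dec$physiological)), 0.1 * sd(y))
})

test_that("MLR decomposition matches a closed-form least-squares oracle", {
  set.seed(16)
  n <- 250
  lai <- as.numeric(arima.sim(list(ar = 0.4), n))
  met <- data.frame(vpd = rnorm(n), sw = rnorm(n))
  y <- 0.5 * lai + 0.3 * met$vpd - 0.2 * met$sw + rnorm(n, 0, 0.05)
  dec <- mlr_decomposition(y, lai, met)
  # independent oracle: normal equations solved directly
  X <- cbind(1, lai, met$vpd, met$sw)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  physio_oracle <- beta[3] * met$vpd + beta[4] * met$sw
  expect_equal(dec$physiological, physio_oracle, tolerance = 1e-9)

  # collinear column is dropped with a warning, contributing zero
  met2 <- data.frame(vpd = met$vpd, vpd_copy = met$vpd)
  expect_warning(dec2 <- mlr_decomposition(y, lai, met2), "collinear")
  expect_true(all(is.finite(dec2$physiological)))
})

test_that("exact Shapley values satisfy efficiency and a linear-model oracle", {
  set.seed(17)
  n <- 60
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  beta <- c(a = 1.5, b = -2, c = 0.5)
  f_lin <- function(z) as.matrix(z) %*% beta
  bg <- x[1:20, ]
  sv <- shapley_values(function(z) as.numeric(f_lin(z)), x, bg)
  # linear closed form: phi_j = beta_j * (x_j - mean(background_j))
  for (j in names(beta)) {
    expect_equal(sv$shap[, j], beta[j] * (x[[j]] - mean(bg[[j]])),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # efficiency: contributions + base = prediction
  expect_equal(rowSums(sv$shap) + sv$base, as.numeric(f_lin(x)),
               tolerance = 1e-9)
})

test_that("Shapley decomposition is faithful on ensemble models", {
  set.seed(18)
  n <- 160
  lai <- as.numeric(arima.sim(list(ar = 0.5), n))
  met <- data.frame(vpd = rnorm(n), sm = rnorm(n))
  y <- lai + 0.8 * met$vpd + rnorm(n, 0, 0.1)
  dec <- shapley_decomposition(y, lai, met, seed = 4L)
  pred <- predict(dec$model, data.frame(structure = lai, met),
                  num.threads = 1)$predictions
  # efficiency against the actual ensemble prediction
  expect_equal(dec$base + rowSums(dec$shap), pred, tolerance = 1e-6)
  # met-driven part correlates with the planted met term
  expect_gt(cor(dec$physiological, 0.8 * met$vpd), 0.7)

  # structure-only target: met contributions are comparatively small
  y2 <- lai + rnorm(n, 0, 0.05)
  dec2 <- shapley_decomposition(y2, lai, met, seed = 4L)
  expect_lt(mean(abs(dec2$physiological)), 0.2 * sd(y2))
})
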