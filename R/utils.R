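clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Saturation vapour pressure (kPa) over water, Magnus form; ta_c in deg C.
esat_kpa <- function(ta_c) 0.6108 * exp(17.27 * ta_c / (ta_c + 237.3))

# Latent heat of vaporization (J kg-1) used for precipitation unit
# conversion; 1 mm day-1 of water evaporated corresponds to
# lambda / 86400 W m-2 (~28.94 W m-2).
LAMBDA_VAPORIZATION <- 2.5e6

mm_day_to_wm2 <- function(p_mm_day) p_mm_day * LAMBDA_VAPORIZATION / 86400 / 1000 * 1000

# Named RNG sub-streams split deterministically from one master seed, so
# that adding a variable to a simulation does not perturb the draws of the
# others. Seeds are derived by hashing the stream name; all below 2^31.
split_seed <- function(master_seed, name) {
  h <- sum(utf8ToInt(name) * (31^(seq_along(utf8ToInt(name)) %% 8)))
  (as.integer(master_seed) %% 100000L) * 20011L + as.integer(h %% 99991L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# First-order autoregressive noise with marginal standard deviation sd.
ar1_noise <- function(n, rho, sd) {
  if (sd <= 0 || n == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - rho^2)
  as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), rho,
                           method = "recursive"))
}

# Fraction-of-signal noise: sd is `frac` times the cell's signal SD.
scaled_noise <- function(signal_mat, frac) {
  if (frac <= 0) return(array(0, dim(signal_mat)))
  sds <- apply(signal_mat, 1, stats::sd, na.rm = TRUE)
  sds[!is.finite(sds) | sds == 0] <- mean(sds[is.finite(sds) & sds > 0])
  matrix(stats::rnorm(length(signal_mat)), nrow(signal_mat)) * frac * sds
}
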