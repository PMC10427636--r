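#' Simplified surface energy balance: LST to daily evapotranspiration
#'
#' Converts the midday surface-air temperature gradient into an evaporative
#' fraction of daily net radiation:
#'
#' \deqn{ET = \left(1 - \frac{C_p \rho (LST_{max} - Ta_{max}) (1.4 g_a)}
#'   {1.4 Rs_{max}}\right) Rn_{mean}}
#'
#' with ET the daily latent heat flux (W m-2), `LSTmax` the midday land
#' surface temperature (K), `Tamax` the maximum hourly air temperature (K),
#' `Rsmax` the maximum hourly net shortwave radiation (W m-2), `Rnmean` the
#' daily mean net radiation (W m-2), and `ga` a cover-weighted aerodynamic
#' conductance (m s-1). Daily minimum surface and air temperatures are
#' assumed equal, so only the maxima enter. The diurnal-amplitude factor
#' 1.4 multiplies both `ga` and `Rsmax` as printed and is exposed for
#' sensitivity tests.
#'
#' @param lst_max,ta_max temperatures in K (scalars, vectors or matrices).
#' @param rs_max maximum hourly net shortwave radiation, W m-2 (> 0).
#' @param rn_mean daily mean net radiation, W m-2.
#' @param ga aerodynamic conductance, m s-1 (> 0); see [mix_ga()].
#' @param cp specific heat capacity of air, J kg-1 K-1.
#' @param rho density of air, kg m-3.
#' @param amp_factor diurnal-amplitude multiplier applied to both `ga`
#'   and `rs_max`.
#' @param clip clip the result to `[0, rn_mean]` where `rn_mean > 0`
#'   (negative values arise over strongly heated surfaces); clipping
#'   events are counted in the `"clipped"` attribute.
#'
#' @return latent heat flux, W m-2, same shape as the inputs; `NA` where
#'   `rs_max` is 0 (division guard) or any input is missing.
#' @export
estimate_et <- function(lst_max, ta_max, rs_max, rn_mean, ga,
                        cp = 1005, rho = 1.23, amp_factor = 1.4,
                        clip = TRUE) {
  if (any(ga <= 0, na.rm = TRUE)) stop("ga must be positive")
  rs <- ifelse(rs_max == 0, NA_real_, rs_max)
  et <- (1 - cp * rho * (lst_max - ta_max) * (amp_factor * ga) /
           (amp_factor * rs)) * rn_mean
  n_clip <- 0L
  if (clip) {
    pos <- !is.na(et) & !is.na(rn_mean) & rn_mean > 0
    bad <- pos & (et < 0 | et > rn_mean)
    n_clip <- sum(bad)
    et[pos] <- clamp(et[pos], 0, rn_mean[pos])
  }
  attr(et, "clipped") <- n_clip
  et
}

#' Invert the surface energy balance for midday LST
#'
#' Exact algebraic inverse of [estimate_et()]: returns the `LSTmax` that
#' reproduces a given latent heat flux. Used by the synthetic generator to
#' encode a known ET into the LST stream.
#'
#' @param et_true target latent heat flux, W m-2, with
#'   `0 < et_true <= rn_mean`.
#' @inheritParams estimate_et
#' @return `lst_max` in K.
#' @export
invert_lst <- function(et_true, ta_max, rs_max, rn_mean, ga,
                       cp = 1005, rho = 1.23, amp_factor = 1.4) {
  if (any(et_true > rn_mean + 1e-9, na.rm = TRUE)) {
    stop("et_true must not exceed rn_mean")
  }
  if (any(rn_mean <= 0, na.rm = TRUE)) {
    stop("rn_mean must be positive on the inversion domain")
  }
  # the amp_factor cancels between numerator and denominator
  ta_max + (1 - et_true / rn_mean) * (amp_factor * rs_max) /
    (cp * rho * (amp_factor * ga))
}

#' Cover-weighted aerodynamic conductance
#'
#' Mixes the canonical conductances of tree (0.06 m s-1), short vegetation
#' (grass + shrub, 0.0345 m s-1), and bare soil (0.002 m s-1) by their
#' fractional covers; residual uncovered fraction is treated as soil.
#'
#' @param static data frame with `tree_frac`, `shrub_frac`, `grass_frac`
#'   columns (fractions in `[0, 1]` summing to at most 1).
#' @param ga_tree,ga_short,ga_soil component conductances, m s-1.
#' @return per-cell conductance, m s-1.
#' @export
mix_ga <- function(static, ga_tree = 0.06, ga_short = 0.0345,
                   ga_soil = 0.002) {
  tree <- static$tree_frac
  short <- static$shrub_frac + static$grass_frac
  if (any(tree + short > 1 + 1e-6, na.rm = TRUE)) {
    stop("cover fractions sum to more than 1")
  }
  soil <- pmax(1 - tree - short, 0)
  ga_tree * tree + ga_short * short + ga_soil * soil
}

#' Daily summaries of hourly meteorology
#'
#' Reduces hourly air temperature, net shortwave radiation, and net
#' radiation to the per-day fields the energy balance needs: maximum hourly
#' air temperature, maximum hourly net shortwave, and daily mean net
#' radiation. Days with fewer than 80% valid hours are set missing.
#'
#' @param hourly list with matrices `ta_k`, `rs`, `rn` (cells x hours,
#'   hours blocked in days of 24) and a `dates` vector, as produced by the
#'   generator's hourly sub-grid.
#' @param min_valid_frac minimum fraction of valid hours per day.
#' @return list of matrices `ta_max`, `rs_max`, `rn_mean`
#'   (cells x days).
#' @export
daily_met_summaries <- function(hourly, min_valid_frac = 0.8) {
  nh <- 24L
  n_days <- ncol(hourly$ta_k) %/% nh
  reduce <- function(mat, f) {
    out <- matrix(NA_real_, nrow(mat), n_days)
    for (d in seq_len(n_days)) {
      block <- mat[, (d - 1) * nh + seq_len(nh), drop = FALSE]
      valid <- rowMeans(!is.na(block))
      v <- apply(block, 1, f, na.rm = TRUE)
      v[!is.finite(v)] <- NA_real_
      v[valid < min_valid_frac] <- NA_real_
      out[, d] <- v
    }
    out
  }
  list(ta_max = reduce(hourly$ta_k, max),
       rs_max = reduce(hourly$rs, max),
       rn_mean = reduce(hourly$rn, mean))
}
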