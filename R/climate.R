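# Climate-driven growth and decay multipliers.
#
# Annual growth is scaled by an NPP anomaly: a Miami-type climate NPP
# estimate (minimum of a precipitation-limited and a temperature-limited
# term) divided by the same estimate under 30-year climate normals. Decay
# of DOM pools is scaled by Q10 multipliers of the annual temperature
# anomaly relative to the normals. Units of the NPP functions (g C/m2/yr
# scale) cancel in the anomaly ratio.

#' Precipitation-limited NPP term
#'
#' `f(MAP) = 0.551 * MAP^1.055 / exp(0.000306 * MAP)` with MAP total annual
#' precipitation in mm. Unimodal in MAP (argmax near 1.055/0.000306 mm).
#'
#' @param map Total annual precipitation (mm), `>= 0`. Vectorised.
#' @return NPP estimate (g C/m2/yr scale).
#' @export
npp_precip <- function(map) {
  if (any(map < 0)) stop("MAP must be >= 0")
  0.551 * map^1.055 / exp(0.000306 * map)
}

#' Temperature-limited NPP term
#'
#' Logistic in mean annual temperature: `f(MAT) = 2540 / (1 + exp(1.584 -
#' 0.0622 * MAT))`; strictly increasing, bounded above by 2540.
#'
#' @param mat Mean annual temperature (degrees C). Vectorised.
#' @return NPP estimate (g C/m2/yr scale).
#' @export
npp_temp <- function(mat) {
  2540 / (1 + exp(1.584 - 0.0622 * mat))
}

#' Climate NPP estimate (minimum rule)
#'
#' `NPP_t = min(f(MAP), f(MAT))`, elementwise.
#'
#' @param map Total annual precipitation (mm).
#' @param mat Mean annual temperature (degrees C).
#' @return NPP estimate (g C/m2/yr scale).
#' @export
npp_climate <- function(map, mat) {
  pmin(npp_precip(map), npp_temp(mat))
}

#' NPP anomaly (growth multiplier)
#'
#' Ratio of the annual climate NPP estimate to the normal-period estimate;
#' multiplies the age-specific NPP schedule. Cells with `mu_npp = 0` (or
#' nodata, NA) get a multiplier of 1 and are counted in the returned
#' attribute `n_flagged`.
#'
#' @param npp_t Annual climate NPP estimate ([npp_climate()]).
#' @param mu_npp Normal-period climate NPP estimate (same units).
#' @return Multiplier(s), dimensionless, with attribute `n_flagged`.
#' @export
npp_anomaly <- function(npp_t, mu_npp) {
  bad <- !is.finite(mu_npp) | mu_npp <= 0 | !is.finite(npp_t)
  out <- ifelse(bad, 1, npp_t / mu_npp)
  if (any(bad)) attr(out, "n_flagged") <- sum(bad)
  out
}

#' Spatial decay multiplier
#'
#' `DM = Q10^((T_mean - T_norm)/10)`: the Q10 scaling of decay for the
#' departure of the annual mean temperature from the 30-year normal.
#' Multiplies the effective decay rate (`MDR = EDR * DM`). Satisfies
#' `DM(+d) * DM(-d) = 1` and `DM = 1` at normals.
#'
#' @param t_mean Annual mean temperature (degrees C).
#' @param t_norm 30-year normal mean temperature (degrees C).
#' @param q10 Q10 coefficient (> 0); 2.65 for the fast pools (Aboveground
#'   Very Fast and Aboveground Slow), 2.00 for all other DOM pools
#'   including the belowground slow (soil) pool.
#' @return Multiplier(s), dimensionless.
#' @export
decay_multiplier <- function(t_mean, t_norm, q10 = 2.0) {
  if (any(q10 <= 0)) stop("q10 must be > 0")
  q10^((t_mean - t_norm) / 10)
}

#' Per-cell multiplier grids for one year
#'
#' Applies the NPP anomaly and decay-multiplier pipeline to co-registered
#' climate grids. Nodata (NA) climate propagates to multipliers of 1.
#'
#' @param mat,map Annual mean temperature / total precipitation grids
#'   (matrices).
#' @param mat_norm,map_norm 30-year normal grids (same shape).
#' @param q10_fast,q10_slow Q10 coefficients for the two decay-multiplier
#'   classes.
#' @return List of matrices `npp_anom`, `dm_fast`, `dm_slow`.
#' @export
climate_multipliers <- function(mat, map, mat_norm, map_norm,
                                q10_fast = 2.65, q10_slow = 2.0) {
  stopifnot(all(dim(mat) == dim(map)), all(dim(mat) == dim(mat_norm)),
            all(dim(mat) == dim(map_norm)))
  mu <- npp_climate(ifelse(is.na(map_norm), 0, pmax(map_norm, 0)),
                    ifelse(is.na(mat_norm), 0, mat_norm))
  mu[is.na(map_norm) | is.na(mat_norm)] <- NA
  nt <- npp_climate(ifelse(is.na(map), 0, pmax(map, 0)),
                    ifelse(is.na(mat), 0, mat))
  nt[is.na(map) | is.na(mat)] <- NA
  anom <- npp_anomaly(nt, mu)
  dmf <- decay_multiplier(mat, mat_norm, q10_fast)
  dms <- decay_multiplier(mat, mat_norm, q10_slow)
  dmf[!is.finite(dmf)] <- 1
  dms[!is.finite(dms)] <- 1
  shape <- function(x) matrix(as.numeric(x), nrow(mat), ncol(mat))
  list(npp_anom = shape(anom), dm_fast = shape(dmf), dm_slow = shape(dms))
}
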