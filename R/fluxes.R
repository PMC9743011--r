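# Closed-form static-chamber gas flux and HPFM temperature correction.
#
# Flux: F_A = dC/dt * (P * M * V) / (R * A * T), with dC/dt in mole fraction
# per hour (ppm interpreted as mole fraction x 1e-6), giving g m-2 h-1.
# Negative fluxes mean the soil acts as a sink.

#' Static chamber geometry and gas constants
#'
#' Defaults match an opaque soil chamber of base area 43.4 cm2 and volume
#' 0.634 dm3 used for ethylene efflux, at standard pressure and 20 degrees C.
#' The gas constant is fixed at 8.314 J K-1 mol-1.
#'
#' @param area_m2 Chamber base area, m2.
#' @param volume_m3 Chamber volume, m3.
#' @param temperature_k Chamber temperature, K.
#' @param pressure_pa Atmospheric pressure, Pa.
#' @param molar_mass_g Molar mass of the gas, g mol-1 (ethylene: 28.05).
#' @return List of class `"chamber_geometry"`.
#' @export
chamber_geometry <- function(area_m2 = 43.4e-4, volume_m3 = 0.634e-3,
                             temperature_k = 293.15, pressure_pa = 101325,
                             molar_mass_g = 28.05) {
  vals <- c(area_m2, volume_m3, temperature_k, pressure_pa, molar_mass_g)
  if (any(vals <= 0)) stop("all chamber parameters must be positive", call. = FALSE)
  structure(list(area_m2 = area_m2, volume_m3 = volume_m3,
                 temperature_k = temperature_k, pressure_pa = pressure_pa,
                 molar_mass_g = molar_mass_g, gas_constant = 8.314),
            class = "chamber_geometry")
}

#' Concentration accumulation rate from a chamber time series
#'
#' Ordinary least-squares slope of concentration against time over the full
#' recorded series (typically 6-8 min), converted to mole fraction per hour.
#' An optional deadband trims the first seconds after chamber placement.
#'
#' @param time Times since chamber closure.
#' @param conc_ppm Concentrations, ppm.
#' @param time_unit Unit of `time`: `"s"`, `"min"` or `"h"`.
#' @param deadband Initial period (in `time_unit`) to discard.
#' @return List of class `"chamber_slope"`: `slope_ppm_h`, `slope_molfrac_h`
#'   (mol mol-1 h-1), `intercept_ppm`, `r_squared`, `n`.
#' @export
fit_slope <- function(time, conc_ppm, time_unit = c("s", "min", "h"),
                      deadband = 0) {
  time_unit <- match.arg(time_unit)
  stopifnot(length(time) == length(conc_ppm))
  keep <- time >= deadband
  time <- time[keep]
  conc_ppm <- conc_ppm[keep]
  if (length(time) < 3L) stop("need at least three time points", call. = FALSE)
  if (diff(range(time)) <= 0) stop("all times identical", call. = FALSE)
  hours <- time / c(s = 3600, min = 60, h = 1)[[time_unit]]
  fit <- stats::lm(conc_ppm ~ hours)
  slope <- unname(stats::coef(fit)[2])
  ss_tot <- sum((conc_ppm - mean(conc_ppm))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(list(slope_ppm_h = slope, slope_molfrac_h = slope * 1e-6,
                 intercept_ppm = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(time)),
            class = "chamber_slope")
}

#' Chamber gas flux
#'
#' Converts a concentration accumulation rate into an areal mass flux:
#' `F_A = dC/dt * (P * M * V) / (R * A * T)` in g m-2 h-1. The flux is
#' signed: a falling concentration gives a negative flux (the soil acting as
#' a sink).
#'
#' @param slope A [fit_slope()] result, or a numeric accumulation rate in
#'   mol mol-1 h-1.
#' @param geom A [chamber_geometry()].
#' @return Flux, g m-2 h-1.
#' @export
#' @examples
#' gas_flux(1e-6, chamber_geometry())
gas_flux <- function(slope, geom = chamber_geometry()) {
  stopifnot(inherits(geom, "chamber_geometry"))
  dcdt <- if (inherits(slope, "chamber_slope")) slope$slope_molfrac_h else slope
  dcdt * (geom$pressure_pa * geom$molar_mass_g * geom$volume_m3) /
    (geom$gas_constant * geom$area_m2 * geom$temperature_k)
}

#' Temperature correction of HPFM hydraulic conductance
#'
#' Corrects a measured root hydraulic conductance for the viscosity effect of
#' measurement temperature using the manufacturer's relation
#' `K_r = K_raw * (0.554 + 0.0225 * T) / (0.554 + 0.0225 * T_c)`, with
#' temperatures in degrees C. At a soil temperature of 2 C against a 22 C
#' calibration the correction reduces the raw conductance by about 43%.
#'
#' @param k_raw Measured conductance, g MPa-1 s-1.
#' @param temp_c Measurement temperature, degrees C.
#' @param calib_temp_c Calibration temperature, degrees C.
#' @return Corrected conductance, with attributes `factor` (the multiplier)
#'   and `percent_change` (100 * (factor - 1)).
#' @export
#' @examples
#' hpfm_correct(1, temp_c = 2, calib_temp_c = 22)
hpfm_correct <- function(k_raw, temp_c, calib_temp_c = 22) {
  denom <- 0.554 + 0.0225 * calib_temp_c
  numer <- 0.554 + 0.0225 * temp_c
  if (denom <= 0 || numer <= 0) stop("correction factor not positive", call. = FALSE)
  f <- numer / denom
  structure(k_raw * f, factor = f, percent_change = 100 * (f - 1))
}
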