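#' Heterotrophic respiration rate from a headspace CO2 reading
#'
#' Converts one accumulated headspace CO2 concentration into a respiration
#' rate in ug C-CO2 per g dry soil per hour via the ideal gas law:
#' `co2_ppm * (P * V) / (R * T) * (1 / dry_soil_g) * 12 * (1 / interval_h)`.
#' `P*V/(R*T)` is moles of headspace air, so ppm (umol CO2 per mol air)
#' converts to umol CO2, and 12 ug C per umol C converts to carbon mass.
#'
#' @param co2_ppm Headspace CO2 concentration (umol per mol air, >= 0).
#' @param pressure_atm Atmospheric pressure P (atm).
#' @param headspace_volume_l Jar headspace volume V (L).
#' @param temperature_k Incubation temperature T (K, > 250).
#' @param dry_soil_g Dry soil mass (g).
#' @param interval_h Hours since the jar was last flushed, t.
#' @param gas_constant Ideal gas constant R (L atm / K / mol), default
#'   0.0821.
#' @return Respiration rate(s) in ug C-CO2 per g dry soil per hour.
#' @export
respiration_rate <- function(co2_ppm, pressure_atm, headspace_volume_l,
                             temperature_k, dry_soil_g, interval_h,
                             gas_constant = 0.0821) {
  args <- list(pressure_atm = pressure_atm,
               headspace_volume_l = headspace_volume_l,
               temperature_k = temperature_k, dry_soil_g = dry_soil_g,
               interval_h = interval_h, gas_constant = gas_constant)
  for (nm in names(args))
    if (any(!is.finite(args[[nm]])) || any(args[[nm]] <= 0))
      stop("'", nm, "' must be strictly positive", call. = FALSE)
  if (any(co2_ppm < 0)) stop("'co2_ppm' must be >= 0", call. = FALSE)
  if (any(temperature_k <= 250))
    stop("'temperature_k' must exceed 250 K", call. = FALSE)
  co2_ppm * (pressure_atm * headspace_volume_l) /
    (gas_constant * temperature_k) / dry_soil_g * 12 / interval_h
}

#' Mean respiration rate over the stabilized window
#'
#' Arithmetic mean of the rates measured within the stabilized portion of
#' the incubation (default day 20 to day 193), which is the quantity fed to
#' the Q10 calculation.
#'
#' @param day Numeric vector of incubation days.
#' @param rate Matching respiration rates.
#' @param window_start_day,window_end_day Inclusive window bounds.
#' @return Mean rate over measurements inside the window.
#' @export
mean_stabilized_rate <- function(day, rate, window_start_day = 20,
                                 window_end_day = 193) {
  if (length(day) != length(rate))
    stop("'day' and 'rate' must have equal length", call. = FALSE)
  keep <- day >= window_start_day & day <= window_end_day
  if (!any(keep))
    stop("no measurements inside the stabilized window [",
         window_start_day, ", ", window_end_day, "]", call. = FALSE)
  mean(rate[keep])
}

#' Temperature sensitivity (Q10) of respiration
#'
#' `Q10 = (k_high / k_low)^(10 / (t_high_c - t_low_c))`: the factor by
#' which respiration increases per 10 degrees C of warming, computed from
#' rates at two incubation temperatures (defaults 15 and 4 degrees C, so
#' the exponent is 10/11).
#'
#' @param k_high Rate at the warmer temperature (> 0).
#' @param k_low Rate at the cooler temperature (> 0).
#' @param t_high_c,t_low_c The two incubation temperatures (degrees C).
#' @return Q10 value(s).
#' @export
q10 <- function(k_high, k_low, t_high_c = 15, t_low_c = 4) {
  if (any(k_high <= 0) || any(k_low <= 0))
    stop("rates must be strictly positive", call. = FALSE)
  if (t_high_c == t_low_c)
    stop("the two temperatures must differ", call. = FALSE)
  (k_high / k_low)^(10 / (t_high_c - t_low_c))
}
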