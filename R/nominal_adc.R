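# Nominal (reference) ADC model for PVP solutions.
#
# Calibrated diffusion phantoms ship with per-concentration polynomial fits
# of ADC against temperature; those coefficient tables are vendor documents,
# so the package provides a synthetic default with the right qualitative
# shape and lets users supply their own coefficients.

PVP_FRACTIONS <- c(0, 0.10, 0.20, 0.30, 0.40, 0.50)

#' Default synthetic ADC(T) model for PVP concentrations
#'
#' Builds a per-concentration quadratic model `ADC(T) = a0 + a1*T + a2*T^2`
#' (units mm^2/s, T in degrees Celsius) anchored so that at 20 degrees C the
#' 0% vial sits at 2.0e-3 mm^2/s and the 50% vial at 0.3e-3 mm^2/s, the
#' endpoints of the phantom's nominal range. Intermediate concentrations are
#' log-linearly interpolated in concentration, which keeps ADC strictly
#' decreasing in PVP fraction. Temperature dependence is a linear +2% per
#' degree C relative slope (a2 = 0), a realistic magnitude for aqueous
#' diffusivity near room temperature.
#'
#' @param adc_20_water ADC of the 0% vial at 20 C (mm^2/s).
#' @param adc_20_pvp50 ADC of the 50% vial at 20 C (mm^2/s).
#' @param slope_per_c relative temperature slope per degree C.
#' @return An object of class `nominal_adc_model`: list with `coefficients`
#'   (data.frame pvp_fraction, a0, a1, a2) and `valid_range` (degrees C).
#' @export
default_adc_model <- function(adc_20_water = 2.0e-3,
                              adc_20_pvp50 = 0.3e-3,
                              slope_per_c = 0.02) {
  stopifnot(adc_20_water > adc_20_pvp50, adc_20_pvp50 > 0)
  adc20 <- exp(log(adc_20_water) +
                 (PVP_FRACTIONS / 0.5) * log(adc_20_pvp50 / adc_20_water))
  coef <- data.frame(
    pvp_fraction = PVP_FRACTIONS,
    a0 = adc20 * (1 - slope_per_c * 20),
    a1 = adc20 * slope_per_c,
    a2 = 0
  )
  structure(list(coefficients = coef, valid_range = c(15, 24)),
            class = "nominal_adc_model")
}

#' Construct an ADC(T) model from explicit coefficients
#'
#' @param coefficients data.frame with columns `pvp_fraction`, `a0`, `a1`,
#'   `a2`; one row per concentration.
#' @param valid_range length-2 numeric, temperature validity range in C.
#' @return A `nominal_adc_model`.
#' @export
adc_model <- function(coefficients, valid_range = c(15, 24)) {
  need <- c("pvp_fraction", "a0", "a1", "a2")
  if (!is.data.frame(coefficients) || !all(need %in% names(coefficients)))
    stopf("coefficients must be a data.frame with columns %s",
          paste(need, collapse = ", "))
  if (anyDuplicated(coefficients$pvp_fraction))
    stopf("duplicate pvp_fraction rows in coefficient table")
  structure(list(coefficients = coefficients[need],
                 valid_range = as.numeric(valid_range)),
            class = "nominal_adc_model")
}

#' Nominal ADC of a PVP concentration at a given temperature
#'
#' Evaluates the per-concentration quadratic `a0 + a1*T + a2*T^2`.
#'
#' @param model a `nominal_adc_model`.
#' @param pvp_fraction mass fraction; must be present in the model table.
#' @param temperature_c temperature in degrees Celsius, inside the model's
#'   validity range.
#' @return ADC in mm^2/s (vectorized over `pvp_fraction`).
#' @export
nominal_adc <- function(model, pvp_fraction, temperature_c) {
  stopifnot(inherits(model, "nominal_adc_model"))
  if (!is_scalar_number(temperature_c))
    stopf("temperature_c must be a single finite number")
  rng <- model$valid_range
  if (temperature_c < rng[1] || temperature_c > rng[2])
    stopf("temperature %.2f C outside model validity range [%g, %g]",
          temperature_c, rng[1], rng[2])
  idx <- match(pvp_fraction, model$coefficients$pvp_fraction)
  if (anyNA(idx))
    stopf("pvp_fraction %s not in model table",
          paste(pvp_fraction[is.na(idx)], collapse = ", "))
  cf <- model$coefficients[idx, , drop = FALSE]
  adc <- cf$a0 + cf$a1 * temperature_c + cf$a2 * temperature_c^2
  if (any(adc <= 0)) stopf("model yields non-positive ADC at %g C", temperature_c)
  adc
}
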