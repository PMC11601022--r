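# Physical relations between gas composition, temperature, humidity,
# speed of sound and molar mass, plus BTPS conversion factors.

#' Universal gas constant, J/(mol K)
#' @keywords internal
.R_GAS <- 8.31446

# Species constants. Molar masses in g/mol from standard atomic weights
# (CIAAW 2021); molar heat capacities Cp in J/(mol K) at ~300 K from the
# NIST WebBook (ideal-gas values; SF6 from Chase 1998 JANAF tables).
.GAS_SPECIES <- data.frame(
  species    = c("n2", "o2", "co2", "ar", "sf6", "h2o"),
  molar_mass = c(28.014, 31.998, 44.009, 39.948, 146.055, 18.015),
  cp         = c(29.124, 29.378, 37.129, 20.786, 97.0, 33.60),
  stringsAsFactors = FALSE
)

#' Gas species constants
#'
#' Molar masses (g/mol) and molar heat capacities at constant pressure
#' (J/(mol K), ideal gas, ~300 K) for the species handled by the package:
#' N2, O2, CO2, Ar, SF6 and water vapour.
#'
#' @return A data frame with columns `species`, `molar_mass` and `cp`.
#' @export
gas_species_constants <- function() .GAS_SPECIES

#' Construct a gas mixture
#'
#' A gas mixture is a named vector of mole fractions over the species
#' N2, O2, CO2, Ar, SF6 and H2O. Fractions must lie in \[0, 1\] and sum to 1
#' within 1e-9.
#'
#' @param n2,o2,co2,ar,sf6,h2o Mole fractions (dimensionless).
#' @return An object of class `gas_mixture`.
#' @examples
#' gas_mixture(n2 = 1)
#' dry_air()
#' @export
gas_mixture <- function(n2 = 0, o2 = 0, co2 = 0, ar = 0, sf6 = 0, h2o = 0) {
  x <- c(n2 = n2, o2 = o2, co2 = co2, ar = ar, sf6 = sf6, h2o = h2o)
  validate_gas_mixture(x)
  structure(x, class = "gas_mixture")
}

validate_gas_mixture <- function(x) {
  if (length(x) != 6L || any(!is.finite(x)))
    stop_mbw("gas mixture must have 6 finite mole fractions", "mbw_invalid_mixture")
  if (any(x < -1e-12) || any(x > 1 + 1e-12))
    stop_mbw("mole fractions must lie in [0, 1]", "mbw_invalid_mixture")
  if (abs(sum(x) - 1) > 1e-9)
    stop_mbw(sprintf("mole fractions sum to %.12f, not 1", sum(x)),
             "mbw_invalid_mixture")
  invisible(x)
}

#' Standard dry air mixture
#'
#' @return A `gas_mixture` with the standard dry-air composition
#'   (78.08% N2, 20.95% O2, 0.04% CO2, 0.93% Ar).
#' @export
dry_air <- function() {
  gas_mixture(n2 = 0.7808, o2 = 0.2095, co2 = 0.0004, ar = 0.0093)
}

#' Tracer gas supply mixture
#'
#' Dry air with a given SF6 mole fraction; the remaining species are scaled
#' down proportionally. The washin supply of the test is typically 4% SF6.
#'
#' @param sf6 SF6 mole fraction (default 0.04).
#' @return A `gas_mixture`.
#' @export
tracer_mixture <- function(sf6 = 0.04) {
  air <- unclass(dry_air()) * (1 - sf6)
  gas_mixture(n2 = air[["n2"]], o2 = air[["o2"]], co2 = air[["co2"]],
              ar = air[["ar"]], sf6 = sf6)
}

#' Add water vapour to a mixture
#'
#' Replaces any existing water content and rescales the dry fractions so the
#' water mole fraction equals `rh * svp(temperature) / pressure`.
#'
#' @param mix A `gas_mixture`.
#' @param rh Relative humidity, fraction in \[0, 1\].
#' @param temperature Gas temperature, K.
#' @param pressure Total pressure, Pa.
#' @return A `gas_mixture` including water vapour.
#' @export
humidify <- function(mix, rh, temperature, pressure = 101325) {
  validate_gas_mixture(unclass(mix))
  xh <- rh * saturation_vapor_pressure(temperature) / pressure
  dry <- unclass(mix)
  dry["h2o"] <- 0
  dry <- dry / sum(dry)
  out <- dry * (1 - xh)
  out["h2o"] <- xh
  structure(out, class = "gas_mixture")
}

#' Mixture molar mass
#'
#' Mole-fraction-weighted mean of the species molar masses.
#'
#' @param mix A `gas_mixture`.
#' @return Molar mass in g/mol.
#' @examples
#' mixture_molar_mass(gas_mixture(n2 = 1))   # 28.014
#' mixture_molar_mass(tracer_mixture(0.04))  # ~33.65
#' @export
mixture_molar_mass <- function(mix) {
  x <- unclass(mix)
  validate_gas_mixture(x)
  sum(x * .GAS_SPECIES$molar_mass)
}

#' Mixture adiabatic index
#'
#' gamma = Cp/Cv of the mixture, with Cp the mole-fraction-weighted molar heat
#' capacity and Cv = Cp - R (ideal-gas mixing).
#'
#' @param mix A `gas_mixture`.
#' @return Dimensionless adiabatic index.
#' @examples
#' mixture_adiabatic_index(gas_mixture(n2 = 1)) # 1.400
#' @export
mixture_adiabatic_index <- function(mix) {
  x <- unclass(mix)
  validate_gas_mixture(x)
  cp <- sum(x * .GAS_SPECIES$cp)
  cp / (cp - .R_GAS)
}

#' Speed of sound in a gas mixture
#'
#' c = sqrt(gamma * R * T / MM), with MM in kg/mol. This is the relation an
#' ultrasonic flowmeter inverts to report a molar-mass signal.
#'
#' @param mix A `gas_mixture`.
#' @param temperature Gas temperature, K (> 0).
#' @return Speed of sound in m/s.
#' @examples
#' speed_of_sound(dry_air(), 293.15) # ~343 m/s
#' @export
speed_of_sound <- function(mix, temperature) {
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop_mbw("temperature must be positive", "mbw_domain_error")
  mm_kg <- mixture_molar_mass(mix) / 1000
  sqrt(mixture_adiabatic_index(mix) * .R_GAS * temperature / mm_kg)
}

#' Saturation vapour pressure of water
#'
#' Magnus-type formula (Alduchov & Eskridge 1996 coefficients), accurate to
#' well below sensor noise between 270 and 320 K.
#'
#' @param temperature Temperature in K, within \[270, 320\].
#' @return Saturation vapour pressure in Pa.
#' @examples
#' saturation_vapor_pressure(310.15) # ~6.27 kPa
#' @export
saturation_vapor_pressure <- function(temperature) {
  if (any(!is.finite(temperature)) ||
      any(temperature < 270) || any(temperature > 320))
    stop_mbw("temperature out of supported range [270, 320] K",
             "mbw_domain_error")
  t_c <- temperature - 273.15
  610.94 * exp(17.625 * t_c / (t_c + 243.04))
}

#' Ambient / sensor conditions
#'
#' @param temperature Sensor-side gas temperature, K.
#' @param pressure Ambient pressure, Pa.
#' @param relative_humidity Ambient relative humidity, fraction in \[0, 1\].
#' @param body_temperature Body (or lung-model medium) temperature, K.
#' @return An object of class `ambient_conditions`.
#' @export
ambient_conditions <- function(temperature = 296.15, pressure = 101325,
                               relative_humidity = 0.3,
                               body_temperature = 310.15) {
  if (temperature < 270 || temperature > 320 ||
      body_temperature < 270 || body_temperature > 320)
    stop_mbw("temperatures must lie in [270, 320] K", "mbw_domain_error")
  if (pressure < 50e3 || pressure > 110e3)
    stop_mbw("pressure must lie in [50, 110] kPa", "mbw_domain_error")
  if (relative_humidity < 0 || relative_humidity > 1)
    stop_mbw("relative humidity must lie in [0, 1]", "mbw_domain_error")
  structure(list(temperature = temperature, pressure = pressure,
                 relative_humidity = relative_humidity,
                 body_temperature = body_temperature),
            class = "ambient_conditions")
}

#' BTPS conversion factor
#'
#' Multiplicative factor converting a volume measured at sensor conditions to
#' body temperature, ambient pressure, saturated (BTPS). For inspirations the
#' gas is assumed at ambient temperature and humidity at the sensor; for
#' expirations it is assumed saturated at the sensor temperature (expired gas
#' leaves the body saturated at body temperature and partially cools on the
#' way to the sensor).
#'
#' @param cond An `ambient_conditions` object.
#' @param direction `"inspiration"` or `"expiration"`.
#' @return Dimensionless factor (> 1 when the sensor is cooler/drier than
#'   the body).
#' @export
btps_factor <- function(cond, direction = c("inspiration", "expiration")) {
  direction <- match.arg(direction)
  p <- cond$pressure
  p_body <- saturation_vapor_pressure(cond$body_temperature)
  p_sensor <- if (direction == "inspiration")
    cond$relative_humidity * saturation_vapor_pressure(cond$temperature)
  else
    saturation_vapor_pressure(cond$temperature)
  (cond$body_temperature / cond$temperature) * (p - p_sensor) / (p - p_body)
}

# Vectorised molar mass / adiabatic index over a composition matrix whose
# columns follow .GAS_SPECIES order. Used by the simulator; skips per-row
# validation for speed.
.mm_matrix <- function(comp) as.numeric(comp %*% .GAS_SPECIES$molar_mass)
.gamma_matrix <- function(comp) {
  cp <- as.numeric(comp %*% .GAS_SPECIES$cp)
  cp / (cp - .R_GAS)
}
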