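# Waveguide dosimetry arithmetic: dBm power conversions, the S-parameter
# power budget, peak field across a parallel-plate gap, linear field
# interpolation along the exposure section, and the specific absorption rate
# SAR = sigma * E^2 / rho.

#' Convert dBm to milliwatts (and back)
#'
#' `P[mW] = 10^(dBm/10)`; `mw_to_dbm()` is the exact inverse.
#'
#' @param p_dbm Power in dBm.
#' @return Power in mW.
#' @examples
#' dbm_to_mw(23 - 0.8)  # source power minus cable loss
#' @export
dbm_to_mw <- function(p_dbm) 10^(p_dbm / 10)

#' @rdname dbm_to_mw
#' @param p_mw Power in mW (> 0).
#' @export
mw_to_dbm <- function(p_mw) {
  if (any(p_mw <= 0)) stop_input("power must be > 0 for dBm conversion")
  10 * log10(p_mw)
}

#' S-parameter power budget
#'
#' Splits the power entering the waveguide into reflected
#' (`p_in * 10^(s11/10)`), transmitted (`p_in * 10^(s21/10)`) and absorbed
#' (the remainder) components. Reflected + transmitted + absorbed equals
#' `p_in` exactly by construction.
#'
#' @param p_in Input power in mW (>= 0).
#' @param s11 Reflection coefficient in dB (<= 0).
#' @param s21 Transmission coefficient in dB (<= 0).
#' @return A list with `reflected`, `transmitted` and `absorbed` in mW. A
#'   negative absorbed power (inconsistent S-parameters) triggers a warning.
#' @examples
#' power_budget(166, s11 = -11.88, s21 = -10.73)  # 20 GHz, buffer-filled
#' @export
power_budget <- function(p_in, s11, s21) {
  if (p_in < 0) stop_input("p_in must be >= 0")
  if (s11 > 0 || s21 > 0) stop_input("S-parameters are given in dB and must be <= 0")
  reflected <- p_in * 10^(s11 / 10)
  transmitted <- p_in * 10^(s21 / 10)
  absorbed <- p_in - reflected - transmitted
  if (absorbed < 0) {
    warning("inconsistent S-parameters: absorbed power is negative")
  }
  list(reflected = reflected, transmitted = transmitted, absorbed = absorbed)
}

#' Nominal peak field across the plate gap
#'
#' Peak voltage of a matched transmission line carrying power `p` divided by
#' the plate separation: `E = sqrt(2 (p/1000) Z) / gap`.
#'
#' @param p Power in mW.
#' @param impedance Line impedance in ohms (default 50).
#' @param gap Plate separation in metres (default 1 mm).
#' @return Peak field in V/m.
#' @examples
#' peak_field_nominal(166)  # about 4.1 kV/m
#' @export
peak_field_nominal <- function(p, impedance = 50, gap = 1e-3) {
  if (impedance <= 0 || gap <= 0) stop_input("impedance and gap must be > 0")
  if (any(p < 0)) stop_input("power must be >= 0")
  sqrt(2 * (p / 1000) * impedance) / gap
}

#' Exposure configuration
#'
#' Bundles the RF settings from which the field at the measurement point and
#' the SAR are computed.
#'
#' @param frequency_ghz Carrier frequency in GHz.
#' @param source_power_dbm Signal-generator output in dBm.
#' @param cable_loss_db Coaxial cable loss in dB (subtracted from the source
#'   power; positive number).
#' @param s11,s21 Measured reflection/transmission parameters in dB (<= 0).
#' @param gap Plate separation in metres.
#' @param line_impedance Line impedance in ohms.
#' @param measurement_position Fractional position of the O.D. measurement
#'   along the exposure section, in \[0, 1\] (0 = entry, 1 = exit).
#' @return A classed list.
#' @export
exposure_setting <- function(frequency_ghz, source_power_dbm,
                             cable_loss_db = 0.8, s11, s21, gap = 1e-3,
                             line_impedance = 50,
                             measurement_position = 0.5) {
  if (gap <= 0 || line_impedance <= 0) {
    stop_input("gap and line_impedance must be > 0")
  }
  if (s11 > 0 || s21 > 0) stop_input("S-parameters must be <= 0 dB")
  if (measurement_position < 0 || measurement_position > 1) {
    stop_input("measurement_position must be in [0, 1]")
  }
  structure(list(frequency_ghz = frequency_ghz,
                 source_power_dbm = source_power_dbm,
                 cable_loss_db = cable_loss_db, s11 = s11, s21 = s21,
                 gap = gap, line_impedance = line_impedance,
                 measurement_position = measurement_position),
            class = "exposure_setting")
}

#' Medium properties for SAR
#'
#' @param conductivity Electrical conductivity sigma in S/m (> 0).
#' @param density Mass density rho in kg/m^3 (> 0; water by default).
#' @return A classed list.
#' @export
medium_props <- function(conductivity = 0.8, density = 1000) {
  if (conductivity <= 0 || density <= 0) {
    stop_input("conductivity and density must be > 0")
  }
  structure(list(conductivity = conductivity, density = density),
            class = "medium_props")
}

#' Field at the measurement position
#'
#' The field at the entry of the exposure section is computed from the power
#' remaining after reflection, `p_in (1 - 10^(s11/10))`, and the field at the
#' exit from the transmitted power `p_in 10^(s21/10)`; the field at the
#' measurement point interpolates linearly between them (in field by default,
#' optionally in power).
#'
#' @param setting An [exposure_setting()].
#' @param basis Interpolation basis, `"field"` (default) or `"power"`.
#' @return Peak field in V/m at the measurement position.
#' @export
field_at_measurement <- function(setting, basis = c("field", "power")) {
  stopifnot(inherits(setting, "exposure_setting"))
  basis <- match.arg(basis)
  p_in <- dbm_to_mw(setting$source_power_dbm - setting$cable_loss_db)
  p_entry <- p_in * (1 - 10^(setting$s11 / 10))
  p_exit <- p_in * 10^(setting$s21 / 10)
  pos <- setting$measurement_position
  if (basis == "field") {
    e_entry <- peak_field_nominal(p_entry, setting$line_impedance, setting$gap)
    e_exit <- peak_field_nominal(p_exit, setting$line_impedance, setting$gap)
    (1 - pos) * e_entry + pos * e_exit
  } else {
    peak_field_nominal((1 - pos) * p_entry + pos * p_exit,
                       setting$line_impedance, setting$gap)
  }
}

#' Specific absorption rate
#'
#' `SAR = sigma * E^2 / rho` in W/kg, using the field value exactly as
#' tabulated (no peak-to-RMS conversion).
#'
#' @param medium A [medium_props()].
#' @param e_peak Field in V/m (>= 0).
#' @return SAR in W/kg.
#' @examples
#' sar(medium_props(0.8, 1000), 1000)  # 800 W/kg
#' @export
sar <- function(medium, e_peak) {
  stopifnot(inherits(medium, "medium_props"))
  if (any(e_peak < 0)) stop_input("field must be >= 0")
  medium$conductivity * e_peak^2 / medium$density
}

#' Round SAR for tabular reporting
#'
#' @param sar_value SAR in W/kg.
#' @return `sar_value` rounded to the nearest 100 W/kg.
#' @export
sar_rounded <- function(sar_value) round(sar_value / 100) * 100

#' Ratio of a SAR value to an exposure guideline
#'
#' @param sar_value SAR in W/kg (>= 0).
#' @param guideline Guideline in W/kg; 0.08 is the whole-body time-averaged
#'   limit, 100 the brief local occupational limit.
#' @return The dimensionless ratio.
#' @export
guideline_ratio <- function(sar_value, guideline = 0.08) {
  if (any(sar_value < 0)) stop_input("sar_value must be >= 0")
  sar_value / guideline
}

#' Full dosimetry report for one exposure setting
#'
#' @param setting An [exposure_setting()].
#' @param medium A [medium_props()].
#' @return A list with the waveguide input power, the power budget, the
#'   nominal peak field, the field at the measurement position, and SAR
#'   (exact and rounded to the nearest 100 W/kg) with guideline ratios.
#' @export
dosimetry_report <- function(setting, medium = medium_props()) {
  p_in <- dbm_to_mw(setting$source_power_dbm - setting$cable_loss_db)
  budget <- power_budget(p_in, setting$s11, setting$s21)
  e_nom <- peak_field_nominal(p_in, setting$line_impedance, setting$gap)
  e_meas <- field_at_measurement(setting)
  s <- sar(medium, e_meas)
  list(frequency_ghz = setting$frequency_ghz,
       p_waveguide_mw = p_in,
       budget = budget,
       e_nominal_v_m = e_nom,
       e_measurement_v_m = e_meas,
       sar_w_kg = s,
       sar_rounded_w_kg = sar_rounded(s),
       vs_whole_body_guideline = guideline_ratio(s, 0.08),
       vs_local_guideline = guideline_ratio(s, 100))
}
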