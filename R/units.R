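# Dimensional quantities and the closed unit table.
#
# Every numeric attribute read from a NeuroML/LEMS document is converted to SI
# on entry and kept in SI throughout the simulator. The unit table is explicit
# and closed: an unknown unit is an error, never silently treated as SI.

# unit name -> c(factor to SI, dimension label)
.fb_unit_table <- local({
  u <- list(
    # time
    "s"          = list(1,        "time"),
    "ms"         = list(1e-3,     "time"),
    "us"         = list(1e-6,     "time"),
    "min"        = list(60,       "time"),
    "hour"       = list(3600,     "time"),
    # voltage
    "V"          = list(1,        "voltage"),
    "mV"         = list(1e-3,     "voltage"),
    # current
    "A"          = list(1,        "current"),
    "mA"         = list(1e-3,     "current"),
    "uA"         = list(1e-6,     "current"),
    "nA"         = list(1e-9,     "current"),
    "pA"         = list(1e-12,    "current"),
    # conductance
    "S"          = list(1,        "conductance"),
    "mS"         = list(1e-3,     "conductance"),
    "uS"         = list(1e-6,     "conductance"),
    "nS"         = list(1e-9,     "conductance"),
    "pS"         = list(1e-12,    "conductance"),
    # capacitance
    "F"          = list(1,        "capacitance"),
    "uF"         = list(1e-6,     "capacitance"),
    "nF"         = list(1e-9,     "capacitance"),
    "pF"         = list(1e-12,    "capacitance"),
    # length
    "m"          = list(1,        "length"),
    "cm"         = list(1e-2,     "length"),
    "um"         = list(1e-6,     "length"),
    # resistance / resistivity
    "ohm"        = list(1,        "resistance"),
    "kohm"       = list(1e3,      "resistance"),
    "Mohm"       = list(1e6,      "resistance"),
    "ohm_m"      = list(1,        "resistivity"),
    "ohm_cm"     = list(1e-2,     "resistivity"),
    "kohm_cm"    = list(10,       "resistivity"),
    # specific capacitance (F/m^2)
    "F_per_m2"   = list(1,        "specificCapacitance"),
    "uF_per_cm2" = list(1e-2,     "specificCapacitance"),
    # conductance density (S/m^2)
    "S_per_m2"   = list(1,        "conductanceDensity"),
    "mS_per_cm2" = list(10,       "conductanceDensity"),
    "S_per_cm2"  = list(1e4,      "conductanceDensity"),
    # rate / frequency
    "Hz"         = list(1,        "per_time"),
    "per_s"      = list(1,        "per_time"),
    "per_ms"     = list(1e3,      "per_time"),
    # voltage per time (Izhikevich-style phenomenological slopes)
    "mV_per_ms"  = list(1,        "voltage_per_time"),
    # conductance per voltage (izhikevich2007 k parameter)
    "nS_per_mV"  = list(1e-6,     "conductance_per_voltage"),
    "uS_per_mV"  = list(1e-3,     "conductance_per_voltage"),
    "pA_per_ms"  = list(1e-9,     "current_per_time")
  )
  u
})

#' Convert a NeuroML quantity string to SI
#'
#' Parses strings of the form `"<number><unit>"` (whitespace between number and
#' unit optional, e.g. `"10 mV"`, `"-20mV"`, `"0.3 mS_per_cm2"`) and returns the
#' magnitude in SI units. The supported unit table is closed: an unknown unit
#' raises an `UnknownUnit` error rather than being passed through.
#'
#' @param text quantity string, or a bare number (treated as dimensionless).
#' @param expect_dim optional dimension label; a mismatch raises
#'   `DimensionMismatch`.
#' @return a double: the magnitude in SI units, with attribute `"dimension"`.
#' @examples
#' to_si("10 mV")          # 0.01
#' to_si("0.3 mS_per_cm2") # 3
#' @export
to_si <- function(text, expect_dim = NULL) {
  if (is.numeric(text)) {
    return(structure(as.double(text), dimension = "none"))
  }
  text <- trimws(text)
  m <- regmatches(text, regexec(
    "^([+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s*([A-Za-z_][A-Za-z0-9_]*)?$",
    text
  ))[[1]]
  if (length(m) == 0L) {
    fb_abort("UnknownUnit", sprintf("cannot parse quantity string '%s'", text))
  }
  num <- as.double(m[2])
  unit <- if (is.na(m[3]) || m[3] == "") "" else m[3]
  if (unit == "") return(structure(num, dimension = "none"))
  ent <- .fb_unit_table[[unit]]
  if (is.null(ent)) {
    fb_abort("UnknownUnit", sprintf("unknown unit '%s' in '%s'", unit, text))
  }
  if (!is.null(expect_dim) && !identical(ent[[2]], expect_dim)) {
    fb_abort("DimensionMismatch", sprintf(
      "quantity '%s' has dimension '%s', expected '%s'", text, ent[[2]], expect_dim
    ))
  }
  structure(num * ent[[1]], dimension = ent[[2]])
}

#' @keywords internal
#' Format an SI magnitude in a preferred unit, preserving 6 significant digits.
fb_format_quantity <- function(si_value, unit) {
  ent <- .fb_unit_table[[unit]]
  if (is.null(ent)) fb_abort("UnknownUnit", sprintf("unknown unit '%s'", unit))
  sprintf("%.6g %s", si_value / ent[[1]], unit)
}

#' @keywords internal
fb_unit_dimension <- function(unit) {
  ent <- .fb_unit_table[[unit]]
  if (is.null(ent)) fb_abort("UnknownUnit", sprintf("unknown unit '%s'", unit))
  ent[[2]]
}
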