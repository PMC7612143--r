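# Physical constants: single source of truth for all unit conversions.
.RGAS  <- 0.0083145    # gas constant, kJ mol^-1 K^-1
.NAVO  <- 6.02214e23   # Avogadro, mol^-1
.DEBYE <- 3.33564e-30  # C m per debye
.EPS0  <- 8.8542e-12   # vacuum permittivity, F m^-1

# Element-keyed van der Waals radii in nm, used when a structure file does
# not carry explicit radii. Unknown elements fall back to carbon.
.VDW_RADII   <- c(H = 0.12, C = 0.17, N = 0.155, O = 0.152, S = 0.18)
.VDW_DEFAULT <- 0.17

.vdwRadius <- function(element) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

#' Convert an energy in kBT units to kJ/mol
#'
#' Multiplies by R*T, i.e. kBT expressed per mole. At 310 K one kBT is
#' about 2.58 kJ/mol.
#'
#' @param value energy in kBT units.
#' @param temperature temperature in K (default 310).
#' @return energy in kJ/mol.
#' @examples
#' kbtToKJmol(11, 310)  # ~28 kJ/mol
#' @export
kbtToKJmol <- function(value, temperature = 310) {
  stopifnot(is.numeric(value), is.numeric(temperature))
  if (any(temperature <= 0)) stop("temperature must be > 0")
  value * .RGAS * temperature
}
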