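#' Physical constants and unit conversions (Hartree atomic units)
#'
#' All tensors in this package are stored in Hartree atomic units; unit
#' conversions happen only at the wavelength boundary. The speed of light is
#' `c_au = 137.035999084` a.u. (the inverse fine-structure constant) and one
#' nanometre is `18.897261246` bohr.
#'
#' @format `rayoa_constants` is a named list with elements `c_au`
#'   (speed of light, a.u.) and `bohr_per_nm` (bohr per nanometre).
#' @export
rayoa_constants <- list(
  c_au = 137.035999084,
  bohr_per_nm = 18.897261246
)

#' Convert an incident wavelength to angular frequency in atomic units
#'
#' The angular frequency of the incident light, `omega = 2 * pi * c / lambda`
#' with both `c` and `lambda` expressed in Hartree atomic units. This is the
#' frequency factor carried by the electric dipole-electric quadrupole
#' invariant.
#'
#' @param wavelength_nm Incident wavelength in nanometres (> 0).
#' @return Angular frequency in atomic units (scalar, > 0).
#' @examples
#' wavelength_to_omega(532)
#' @export
wavelength_to_omega <- function(wavelength_nm) {
  if (!is.numeric(wavelength_nm) || any(!is.finite(wavelength_nm)) ||
      any(wavelength_nm <= 0)) {
    abort("`wavelength_nm` must be a positive finite number.",
          class = "rayoa_invalid_wavelength")
  }
  2 * pi * rayoa_constants$c_au / (wavelength_nm * rayoa_constants$bohr_per_nm)
}
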