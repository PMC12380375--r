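#' Convert between wavelength and wavenumber
#'
#' Spectroscopic grids are commonly tabulated in wavenumbers (cm^-1) while the
#' simulation code works in wavelengths (um). The two are related by
#' `nu[cm^-1] = 1e4 / lambda[um]`; the conversion is an involution, so the same
#' formula maps either direction.
#'
#' @param lambda_um wavelength(s) in micrometres, > 0
#' @param nu_cm wavenumber(s) in cm^-1, > 0
#' @return the converted quantity
#' @examples
#' wavelength_to_wavenumber(1)    # 10000 cm^-1
#' wavenumber_to_wavelength(1250) # 8 um
#' @export
wavelength_to_wavenumber <- function(lambda_um) {
  if (any(lambda_um <= 0)) .stopf("wavelength must be positive")
  1e4 / lambda_um
}

#' @rdname wavelength_to_wavenumber
#' @export
wavenumber_to_wavelength <- function(nu_cm) {
  if (any(nu_cm <= 0)) .stopf("wavenumber must be positive")
  1e4 / nu_cm
}
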