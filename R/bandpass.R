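#' Annular numerical-aperture bandpass filter
#'
#' Describes the passband of an objective with outer numerical aperture
#' `na_out` and centre obscuration `na_in` (a Cassegrain-style mirror
#' objective has `na_in > 0`). The spatial-frequency cutoffs are
#' `fl = na_in / lambda` and `fu = na_out / lambda` (cycles per um).
#'
#' @param na_in inner numerical aperture, 0 <= na_in < na_out
#' @param na_out outer numerical aperture
#' @param wavelength wavelength in um
#' @return an object of class `aperture_filter` with cutoffs `fl`, `fu`
#' @export
aperture_filter <- function(na_in, na_out, wavelength) {
  if (na_in < 0 || na_out <= na_in) .stopf("need 0 <= na_in < na_out")
  if (wavelength <= 0) .stopf("wavelength must be positive")
  structure(list(na_in = na_in, na_out = na_out, wavelength = wavelength,
                 fl = na_in / wavelength, fu = na_out / wavelength),
            class = "aperture_filter")
}

#' @export
print.aperture_filter <- function(x, ...) {
  cat(sprintf("<aperture_filter> NA %g..%g, passband [%g, %g] um^-1 at lambda %g um\n",
              x$na_in, x$na_out, x$fl, x$fu, x$wavelength))
  invisible(x)
}

# centred frequency axis of an R-pixel grid over fov (spacing 1/fov)
.freq_axis <- function(n_pixels, fov) {
  (seq_len(n_pixels) - 1 - floor(n_pixels / 2)) / fov
}

#' Apply an annular bandpass to a 2-D spatial field
#'
#' Forward 2-D Fourier transform, annular mask keeping frequencies
#' fl <= |f| <= fu (frequency spacing 1/fov), inverse transform. Models the
#' band-limiting of the collection objective in the imaging path.
#'
#' @param field a spatial-domain [complex_field_2d()]
#' @param filter an [aperture_filter()]
#' @return the band-limited [complex_field_2d()]
#' @export
apply_bandpass_2d <- function(field, filter) {
  if (!inherits(field, "complex_field_2d")) .stopf("field must be a complex_field_2d")
  if (!inherits(filter, "aperture_filter")) .stopf("filter must be an aperture_filter")
  if (anyNA(field$samples)) field$samples[is.na(field$samples)] <- 0 + 0i  # masked interior
  r <- nrow(field$samples)
  fr <- .freq_axis(r, field$fov)
  rho <- sqrt(outer(fr^2, fr^2, "+"))
  mask <- rho >= filter$fl & rho <= filter$fu
  if (!any(mask)) .stopf("empty passband: no frequency sample in [%g, %g] um^-1",
                         filter$fl, filter$fu)
  sh <- c(seq(floor(r / 2) + 1, r), seq_len(floor(r / 2)))  # ifftshift
  spec <- fft(field$samples[sh, sh])
  spec <- spec * (mask[sh, sh])
  out <- fft(spec, inverse = TRUE)[sh, sh] / r^2
  complex_field_2d(out, field$fov, field$wavelength)
}

#' Count of frequency samples inside an annular passband
#'
#' @param n_pixels grid resolution per side
#' @param fov spatial field of view in um
#' @param filter an [aperture_filter()]
#' @return number of grid frequencies with fl <= |f| <= fu
#' @export
passband_pixel_count <- function(n_pixels, fov, filter) {
  fr <- .freq_axis(n_pixels, fov)
  rho <- sqrt(outer(fr^2, fr^2, "+"))
  sum(rho >= filter$fl & rho <= filter$fu)
}

#' Apply an annular bandpass to a 1-D reciprocal radial profile
#'
#' Radial mask keeping fl <= q <= fu; the 1-D equivalent of
#' [apply_bandpass_2d()] for circularly symmetric fields, typically followed
#' by [inverse_hankel()].
#'
#' @param field a reciprocal-domain [radial_field_1d()]
#' @param filter an [aperture_filter()]
#' @return the masked [radial_field_1d()]
#' @export
apply_bandpass_1d <- function(field, filter) {
  if (!inherits(field, "radial_field_1d")) .stopf("field must be a radial_field_1d")
  if (field$domain != "reciprocal")
    .stopf("apply_bandpass_1d expects a reciprocal-domain field")
  keep <- field$r >= filter$fl & field$r <= filter$fu
  if (!any(keep)) .stopf("empty passband: no radial sample in [%g, %g] um^-1",
                         filter$fl, filter$fu)
  out <- field
  out$samples[!keep] <- 0 + 0i
  out
}
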