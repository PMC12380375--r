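#' Monochromatic plane wave
#'
#' E(r) = E0 * e_hat * exp(i k s . r) with k = 2*pi/lambda. The polarization
#' e_hat is a complex unit 3-vector (Conj(e) . e = 1) orthogonal to the real
#' unit propagation direction.
#'
#' @param amplitude complex scalar amplitude E0 (arbitrary units)
#' @param wavelength vacuum wavelength in um
#' @param direction real unit 3-vector of propagation (default +z)
#' @param polarization complex unit 3-vector, orthogonal to `direction`
#'   (default x)
#' @return an object of class `plane_wave`
#' @export
plane_wave <- function(amplitude = 1 + 0i, wavelength = 1,
                       direction = c(0, 0, 1), polarization = c(1, 0, 0)) {
  if (wavelength <= 0) .stopf("wavelength must be positive")
  direction <- as.numeric(direction)
  if (length(direction) != 3 || abs(sqrt(sum(direction^2)) - 1) > 1e-9)
    .stopf("direction must be a real unit 3-vector")
  polarization <- as.complex(polarization)
  if (length(polarization) != 3 ||
      abs(Re(sum(Conj(polarization) * polarization)) - 1) > 1e-9)
    .stopf("polarization must satisfy Conj(e) . e = 1")
  if (Mod(sum(polarization * direction)) > 1e-9)
    .stopf("polarization must be orthogonal to the propagation direction")
  structure(list(amplitude = as.complex(amplitude), wavelength = wavelength,
                 direction = direction, polarization = polarization),
            class = "plane_wave")
}

#' Complex field sampled on a square 2-D grid
#'
#' Stores complex field samples on an R x R regular grid covering a physical
#' field of view `fov` (um). Row-major image convention: x increases along
#' columns, y along rows, and the physical coordinates are centred on the
#' grid, so the FOV centre sits at pixel (R/2 + 1, R/2 + 1) for even R.
#'
#' @param samples complex matrix, at least 2 x 2, all values finite
#' @param fov physical side length in um
#' @param wavelength wavelength in um
#' @return an object of class `complex_field_2d`
#' @export
complex_field_2d <- function(samples, fov, wavelength) {
  samples <- as.matrix(samples)
  if (nrow(samples) != ncol(samples) || nrow(samples) < 2)
    .stopf("samples must be a square matrix with R >= 2")
  if (!all(is.finite(Re(samples)) & is.finite(Im(samples))))
    .stopf("field samples must be finite")
  if (fov <= 0) .stopf("fov must be positive")
  if (wavelength <= 0) .stopf("wavelength must be positive")
  structure(list(samples = samples, fov = fov, wavelength = wavelength),
            class = "complex_field_2d")
}

#' Pixel-centre coordinates of a 2-D field grid
#'
#' @param field a [complex_field_2d()] object
#' @return list with vectors `x` and `y` (um), centred on the grid
#' @export
field_coords <- function(field) {
  r <- nrow(field$samples)
  ax <- (seq_len(r) - 1 - floor(r / 2)) * field$fov / r
  list(x = ax, y = ax)
}

#' @export
print.complex_field_2d <- function(x, ...) {
  cat(sprintf("<complex_field_2d> %d x %d, FOV %g um, lambda %g um, max|E| = %g\n",
              nrow(x$samples), ncol(x$samples), x$fov, x$wavelength,
              max(Mod(x$samples), na.rm = TRUE)))
  invisible(x)
}

#' Complex field on a 1-D radial grid
#'
#' One-dimensional representation of a circularly symmetric field: complex
#' samples at increasing nonnegative radial positions. The `domain` tag says
#' whether the radius is spatial (um) or reciprocal (spatial frequency,
#' um^-1); the order-0 Hankel transform maps between the two.
#'
#' @param samples complex vector, length >= 2
#' @param r radial sample positions, nonnegative increasing; length of
#'   `samples`
#' @param domain `"spatial"` or `"reciprocal"`
#' @param wavelength wavelength in um
#' @param grid sampling scheme tag: `"bessel0"` for the Bessel-zero grid of
#'   the discrete Hankel transform (required by [inverse_hankel()]),
#'   `"uniform"` or `"other"`
#' @return an object of class `radial_field_1d` with `r_max = max(r)`
#' @export
radial_field_1d <- function(samples, r, domain = c("spatial", "reciprocal"),
                            wavelength = 1, grid = "other") {
  domain <- match.arg(domain)
  samples <- as.complex(samples)
  r <- as.numeric(r)
  if (length(samples) < 2) .stopf("need at least 2 radial samples")
  if (length(r) != length(samples)) .stopf("r and samples must have equal length")
  if (any(r < 0) || any(diff(r) <= 0)) .stopf("radial positions must be nonnegative and increasing")
  if (wavelength <= 0) .stopf("wavelength must be positive")
  structure(list(samples = samples, r = r, r_max = max(r), domain = domain,
                 wavelength = wavelength, grid = grid),
            class = "radial_field_1d")
}

#' @export
print.radial_field_1d <- function(x, ...) {
  cat(sprintf("<radial_field_1d> %d samples, %s domain, r_max %g %s, lambda %g um\n",
              length(x$samples), x$domain, x$r_max,
              if (x$domain == "spatial") "um" else "um^-1", x$wavelength))
  invisible(x)
}
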