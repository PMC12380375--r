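#' Tabulated optical constants of a material
#'
#' Container for the complex refractive index n(nu) = m(nu) + i*kappa(nu)
#' sampled on a strictly increasing spectral grid. The grid may be tagged as
#' wavenumbers (`"cm-1"`) or wavelengths (`"um"`).
#'
#' @param grid strictly increasing spectral grid
#' @param m real refractive index at each grid point
#' @param kappa extinction coefficient at each grid point (>= 0)
#' @param unit `"cm-1"` or `"um"`
#' @return an object of class `optical_constants`
#' @export
optical_constants <- function(grid, m, kappa, unit = c("cm-1", "um")) {
  unit <- match.arg(unit)
  if (length(grid) != length(m) || length(grid) != length(kappa))
    .stopf("grid, m and kappa must have equal length")
  if (any(diff(grid) <= 0)) .stopf("spectral grid must be strictly increasing")
  if (any(kappa < 0)) .stopf("extinction coefficient kappa must be >= 0")
  structure(list(grid = as.numeric(grid), m = as.numeric(m),
                 kappa = as.numeric(kappa), unit = unit),
            class = "optical_constants")
}

#' @export
print.optical_constants <- function(x, ...) {
  cat(sprintf("<optical_constants> %d points on [%g, %g] %s; m in [%g, %g]; kappa in [%g, %g]\n",
              length(x$grid), min(x$grid), max(x$grid), x$unit,
              min(x$m), max(x$m), min(x$kappa), max(x$kappa)))
  invisible(x)
}

# discrete principal-value Hilbert transform on a uniform grid:
# (1/pi) PV int f(w') / (w' - w) dw', singular node excluded (the symmetric
# trapezoid pairing makes the exclusion second-order accurate)
.hilbert_pv <- function(f, grid) {
  n <- length(grid)
  if (n < 8) .stopf("Kramers-Kronig transform needs at least 8 grid points")
  dg <- diff(grid)
  if (max(dg) - min(dg) > 1e-9 * mean(dg)) .stopf("Kramers-Kronig transform requires a uniform grid")
  h <- mean(dg)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- grid - grid[i]
    d[i] <- 1  # excluded below
    w <- f / d
    w[i] <- 0
    out[i] <- sum(w) * h / pi
  }
  out
}

#' Kramers-Kronig transforms between real and imaginary spectral parts
#'
#' Any causal response function chi(omega) = chi1 + i*chi2 obeys the
#' Kramers-Kronig relations: chi1 is the principal-value Hilbert transform of
#' chi2, and chi2 is minus the Hilbert transform of chi1. These link the
#' dispersive (real) and absorptive (imaginary) parts of the refractive index,
#' and are exposed here as spectral utilities.
#'
#' The principal value is evaluated by a discrete Hilbert sum on the uniform
#' grid with the singular node excluded; accuracy relies on the input decaying
#' towards the grid edges (a band-limited resonance well inside the grid).
#' Constant offsets are invisible to the transform.
#'
#' @param imag_spectrum,real_spectrum numeric spectrum sampled on `grid`
#' @param grid uniform, strictly increasing spectral grid (any consistent unit)
#' @return the transformed spectrum on the same grid
#' @examples
#' # single-pole resonance: chi = 1/(w0 - w - i g/2) has
#' # chi1 = (w0-w)/D, chi2 = (g/2)/D with D = (w0-w)^2 + g^2/4
#' w <- seq(-60, 60, length.out = 2048) + 100
#' chi2 <- 0.5 / ((100 - w)^2 + 0.25)
#' chi1 <- kk_real_from_imag(chi2, w)
#' @export
kk_real_from_imag <- function(imag_spectrum, grid) {
  .hilbert_pv(imag_spectrum, grid)
}

#' @rdname kk_real_from_imag
#' @export
kk_imag_from_real <- function(real_spectrum, grid) {
  -.hilbert_pv(real_spectrum, grid)
}

#' Beer-Lambert absorbance of a homogeneous sample
#'
#' A(nu) = rho * b * eps(nu), with concentration rho (M), path length b (cm)
#' and molar absorptivity eps (M^-1 cm^-1). The output is exactly bilinear in
#' (rho * b) and eps.
#'
#' @param rho concentration in M (>= 0)
#' @param b path length in cm (>= 0)
#' @param eps molar absorptivity spectrum in M^-1 cm^-1
#' @return absorbance spectrum (dimensionless)
#' @seealso [molar_absorptivity_from_kappa()] for the link to the extinction
#'   coefficient.
#' @export
beer_lambert_absorbance <- function(rho, b, eps) {
  if (length(rho) != 1 || length(b) != 1) .stopf("rho and b must be scalars")
  if (rho < 0) .stopf("concentration rho must be >= 0")
  if (b < 0) .stopf("path length b must be >= 0")
  rho * b * eps
}

#' Molar absorptivity implied by an extinction-coefficient spectrum
#'
#' eps(nu) = 4*pi*nu*kappa(nu) / (2.303 * rho): the molar absorptivity that,
#' inserted into the Beer-Lambert law, reproduces the absorbance of a medium
#' with extinction coefficient kappa at concentration rho. `nu_cm` is in cm^-1
#' and `b` in the Beer-Lambert law is then in cm.
#'
#' @param nu_cm wavenumber grid in cm^-1
#' @param kappa extinction coefficient at each grid point
#' @param rho concentration in M (> 0)
#' @return molar absorptivity spectrum in M^-1 cm^-1
#' @export
molar_absorptivity_from_kappa <- function(nu_cm, kappa, rho) {
  if (rho <= 0) .stopf("concentration rho must be > 0")
  4 * pi * nu_cm * kappa / (2.303 * rho)
}

#' Absorbance image from sample and background intensities
#'
#' A = -log10(I / I0) elementwise; the standard spectroscopic-imaging
#' definition. Pixels with non-positive background are flagged as invalid
#' (`NA`) rather than propagating infinities.
#'
#' @param i_sample intensity image (matrix or array) of the sample
#' @param i_background intensity image of the source, same shape
#' @return absorbance image of the same shape, `NA` where the background is
#'   not positive
#' @export
absorbance_from_intensities <- function(i_sample, i_background) {
  if (!identical(dim(i_sample), dim(i_background)) ||
      length(i_sample) != length(i_background))
    .stopf("sample and background images must have the same shape")
  bad <- !(i_background > 0)
  a <- -log10(i_sample / i_background)
  a[bad] <- NA_real_
  a
}
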