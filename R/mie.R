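#' Homogeneous dielectric sphere
#'
#' @param a radius in um (> 0)
#' @param n complex refractive index m + i*kappa (Re(n) > 0, Im(n) >= 0)
#' @param center (x, y) position of the sphere centre in um
#' @return an object of class `mie_sphere`
#' @export
mie_sphere <- function(a, n, center = c(0, 0)) {
  n <- as.complex(n)
  if (a <= 0) .stopf("sphere radius must be positive")
  if (Re(n) <= 0) .stopf("real refractive index must be positive")
  if (Im(n) < 0) .stopf("extinction coefficient must be >= 0")
  if (length(center) != 2) .stopf("center must be (x, y)")
  structure(list(a = a, n = n, center = as.numeric(center)), class = "mie_sphere")
}

# ---- spherical Bessel machinery (vectorized over argument) ----------------

# j_t(z), t = 0..nmax, by normalized downward recurrence; rows = order,
# columns = argument. The normalization pivot is whichever of j0, j1 is
# larger, so arguments near a zero of sin (e.g. z = 2*pi) stay accurate.
.sph_jn_mat <- function(nmax, z) {
  z <- as.complex(z)
  ns <- length(z)
  nstart <- nmax + ceiling(12 + max(Mod(z)))
  jm <- rep(0 + 0i, ns)
  j <- rep(1e-30 + 0i, ns)
  out <- matrix(0i, nmax + 1, ns)
  for (t in seq(nstart, 0)) {
    jmm <- (2 * t + 3) / z * j - jm
    if (t <= nmax) out[t + 1, ] <- jmm
    jm <- j
    j <- jmm
    big <- Mod(j) > 1e250
    if (any(big)) {
      j[big] <- j[big] * 1e-250
      jm[big] <- jm[big] * 1e-250
      out[, big] <- out[, big] * 1e-250
    }
  }
  j0t <- sin(z) / z
  j1t <- sin(z) / z^2 - cos(z) / z
  use1 <- Mod(j0t) < Mod(j1t)
  piv <- ifelse(use1, out[min(2, nmax + 1), ], out[1, ])
  scale <- ifelse(use1, j1t, j0t) / piv
  sweep(out, 2, scale, "*")
}

# y_t(z) by upward recurrence (stable); rows = order, columns = argument
.sph_yn_mat <- function(nmax, z) {
  z <- as.complex(z)
  out <- matrix(0i, nmax + 1, length(z))
  out[1, ] <- -cos(z) / z
  if (nmax >= 1) out[2, ] <- -cos(z) / z^2 - sin(z) / z
  if (nmax >= 2) for (t in 2:nmax) out[t + 1, ] <- (2 * t - 1) / z * out[t, ] - out[t - 1, ]
  out
}

# derivative w.r.t. the argument from f'_t = f_{t-1} - (t+1)/z f_t,
# given the order-(-1) row value f_m1
.sph_deriv <- function(f, z, f_m1) {
  nmax <- nrow(f) - 1
  fm <- rbind(f_m1, f[-(nmax + 1), , drop = FALSE])
  tfac <- matrix(0:nmax + 1, nmax + 1, length(z)) /
    matrix(z, nmax + 1, length(z), byrow = TRUE)
  fm - tfac * f
}

# Legendre polynomials P_t(mu), rows = points, cols = order 0..nmax
.legendre_mat <- function(mu, nmax) {
  p <- matrix(0, length(mu), nmax + 1)
  p[, 1] <- 1
  if (nmax >= 1) p[, 2] <- mu
  if (nmax >= 2) for (t in 2:nmax)
    p[, t + 1] <- ((2 * t - 1) * mu * p[, t] - (t - 1) * p[, t - 1]) / t
  p
}

.mie_nmax <- function(x) ceiling(x + 4 * x^(1 / 3) + 2)

#' Scalar Mie series coefficients of a sphere
#'
#' Expands the field scattered by a homogeneous sphere in scalar partial
#' waves: ES = sum_t B_t h1_t(kr) P_t(cos(theta)). The coefficient B_t
#' enforces continuity of the scalar field and of its radial derivative at
#' the sphere boundary between the exterior (incident + scattered) and
#' interior expansions, giving
#' \deqn{B_t = (2t+1) i^t \frac{j_t(ka) j_t'(kna) n - j_t(kna) j_t'(ka)}
#'   {j_t(kna) h_t'(ka) - h_t(ka) j_t'(kna) n}}
#' with x = ka the size parameter. The series is truncated at
#' ceiling(x + 4 x^(1/3) + 2) orders and then trimmed where the relative
#' coefficient magnitude falls below `tail_tol`. An index-matched sphere
#' (n = 1) has identically zero coefficients.
#'
#' @param sphere a [mie_sphere()]
#' @param wavelength vacuum wavelength in um
#' @param tail_tol relative magnitude below which trailing orders are dropped
#' @return an object of class `mie_series` with elements `B` (complex vector,
#'   orders 0..n_terms), `size_parameter`, `a`, `n`, `wavelength`
#' @export
mie_coefficients <- function(sphere, wavelength, tail_tol = 1e-14) {
  if (!inherits(sphere, "mie_sphere")) .stopf("sphere must be a mie_sphere")
  if (wavelength <= 0) .stopf("wavelength must be positive")
  B <- drop(.mie_B_mat(sphere$a, sphere$n, wavelength))
  bmax <- max(Mod(B))
  if (bmax > 0) {
    keep <- which(Mod(B) / bmax > tail_tol)
    B <- B[seq_len(max(keep))]
  }
  structure(list(B = B, size_parameter = 2 * pi * sphere$a / wavelength,
                 n_terms = length(B) - 1, a = sphere$a, n = sphere$n,
                 wavelength = wavelength),
            class = "mie_series")
}

# coefficients for many spheres at once: columns = spheres, rows = order
.mie_B_mat <- function(a, n, wavelength, nmax = NULL) {
  k <- 2 * pi / wavelength
  x <- k * a
  y <- n * k * a
  if (is.null(nmax)) nmax <- .mie_nmax(max(x))
  jx <- .sph_jn_mat(nmax, x)
  jy <- .sph_jn_mat(nmax, y)
  hx <- jx + 1i * .sph_yn_mat(nmax, x)
  djx <- .sph_deriv(jx, x, cos(x) / x)
  djy <- .sph_deriv(jy, y, cos(y) / y)
  dhx <- .sph_deriv(hx, x, exp(1i * x) / x)
  tt <- 0:nmax
  ct <- (2 * tt + 1) * (1i)^tt
  nm <- matrix(n, nmax + 1, length(a), byrow = TRUE)
  ct * (jx * djy * nm - jy * djx) / (jy * dhx - hx * djy * nm)
}

# far-field angular profile on a reciprocal radial grid q (um^-1).
# Plane-detector convention: the angle maps as sin(theta) = lambda*q with
# obliquity factor cos(theta); beyond the propagating band edge q = 1/lambda
# the far field is zero (evanescent components do not reach the detector).
.mie_far_profile <- function(B, q, wavelength) {
  k <- 2 * pi / wavelength
  s2 <- (wavelength * q)^2
  mu <- sqrt(pmax(1 - s2, 0))
  inband <- s2 <= 1
  nmax <- length(B) - 1
  p <- .legendre_mat(mu, nmax)
  f <- drop(p %*% (B * (-1i)^(0:nmax))) * mu / (1i * k)
  f[!inband] <- 0
  f
}

#' Radial far-field profile of a sphere
#'
#' Evaluates the scattered far field of a sphere as a 1-D radial profile in
#' the reciprocal domain. Because the scalar Mie field has no azimuthal
#' dependence, this single radial line carries the full 2-D far field. The
#' reciprocal coordinate q is spatial frequency (um^-1); the scattering angle
#' maps as sin(theta) = lambda*q, the profile carries the flat-detector
#' obliquity factor cos(theta), and frequencies beyond the propagating band
#' edge q = 1/lambda are zero.
#'
#' @param sphere a [mie_sphere()]
#' @param wavelength vacuum wavelength in um
#' @param n_samples number of radial samples (>= 64)
#' @param q_max reciprocal extent in um^-1
#' @param grid `"bessel0"` (default; ready for [inverse_hankel()]) or
#'   `"uniform"`
#' @return a reciprocal-domain [radial_field_1d()]
#' @export
far_field_radial <- function(sphere, wavelength, n_samples = 320,
                             q_max = 2 / wavelength, grid = c("bessel0", "uniform")) {
  grid <- match.arg(grid)
  if (n_samples < 64) .stopf("far_field_radial needs n_samples >= 64")
  ser <- mie_coefficients(sphere, wavelength)
  if (grid == "bessel0") {
    plan <- hankel_plan(n_samples, q_max)
    q <- plan$q
  } else {
    q <- seq_len(n_samples) / n_samples * q_max
  }
  radial_field_1d(.mie_far_profile(ser$B, q, wavelength), q, "reciprocal",
                  wavelength, grid = if (grid == "bessel0") "bessel0" else "uniform")
}

#' 2-D far-field image of a sphere
#'
#' Samples the radial far-field profile on the reciprocal grid conjugate to a
#' spatial image with side `fov` and resolution `n_pixels` (frequency spacing
#' 1/fov). The returned object's `fov` is the conjugate spatial field of
#' view; [near_field_from_far_2d()] transforms it to the spatial domain.
#'
#' @inheritParams far_field_radial
#' @param n_pixels image resolution per side
#' @param fov conjugate spatial field of view in um
#' @return a [complex_field_2d()] holding the reciprocal-domain image
#'   (zero-frequency at the grid centre)
#' @export
far_field_2d <- function(sphere, wavelength, n_pixels = 256, fov = 32) {
  ser <- mie_coefficients(sphere, wavelength)
  fidx <- (seq_len(n_pixels) - 1 - floor(n_pixels / 2)) / fov
  qq <- sqrt(outer(fidx^2, fidx^2, "+"))
  samples <- matrix(.mie_far_profile(ser$B, as.vector(qq), wavelength),
                    n_pixels, n_pixels)
  complex_field_2d(samples, fov, wavelength)
}

#' Spatial near field from a 2-D reciprocal-domain image
#'
#' Inverse 2-D discrete Fourier transform of a centred reciprocal-domain
#' image (as produced by [far_field_2d()]), normalized as a Riemann sum of
#' the continuous inverse transform so the result is resolution-independent.
#'
#' @param far a [complex_field_2d()] in the reciprocal domain
#' @return a spatial-domain [complex_field_2d()] with the same `fov`
#' @export
near_field_from_far_2d <- function(far) {
  r <- nrow(far$samples)
  sh <- c(seq(floor(r / 2) + 1, r), seq_len(floor(r / 2)))  # ifftshift
  fr <- far$samples[sh, sh]
  near <- fft(fr, inverse = TRUE) / far$fov^2
  complex_field_2d(near[sh, sh], far$fov, far$wavelength)
}

#' Scattered or total Mie field on a 2-D plane
#'
#' Direct partial-wave evaluation of the field of a sphere on a plane through
#' (or offset from) its centre. The incident plane wave propagates along +z;
#' the `"horizontal"` plane is z = `z_plane` (coordinates x, y), on which the
#' total field of a centred sphere depends only on the distance from the
#' axis; the `"vertical"` plane is y = 0 (coordinates x, z). Points inside
#' the sphere are masked `NA` (the interior field is out of scope).
#'
#' @param sphere a [mie_sphere()] (its `center` shifts the sphere in the
#'   plane coordinates)
#' @param wavelength vacuum wavelength in um
#' @param n_pixels image resolution per side
#' @param fov physical side length in um
#' @param plane `"horizontal"` or `"vertical"`
#' @param z_plane z offset of the horizontal plane in um
#' @param total if `TRUE` add the incident wave exp(i k z)
#' @return a [complex_field_2d()]
#' @export
scattered_field_2d <- function(sphere, wavelength, n_pixels = 128, fov = 16,
                               plane = c("horizontal", "vertical"),
                               z_plane = 0, total = FALSE) {
  plane <- match.arg(plane)
  ser <- mie_coefficients(sphere, wavelength)
  ax <- (seq_len(n_pixels) - 1 - floor(n_pixels / 2)) * fov / n_pixels
  if (plane == "horizontal") {
    px <- outer(rep(1, n_pixels), ax) - sphere$center[1]  # x along columns
    py <- outer(ax, rep(1, n_pixels)) - sphere$center[2]  # y along rows
    pz <- matrix(z_plane, n_pixels, n_pixels)
    zinc <- pz
  } else {
    px <- outer(rep(1, n_pixels), ax) - sphere$center[1]
    pz <- outer(ax, rep(1, n_pixels))                     # z along rows
    py <- matrix(0, n_pixels, n_pixels)
    zinc <- pz
    pz <- pz - 0  # sphere centred at z = 0
  }
  rr <- sqrt(px^2 + py^2 + pz^2)
  es <- matrix(.mie_scattered_points(ser, as.vector(rr), as.vector(pz), wavelength),
               n_pixels, n_pixels)
  out <- es
  if (total) out <- out + exp(2i * pi / wavelength * zinc)
  out[rr < sphere$a] <- NA_complex_
  # complex_field_2d requires finite values; carry the interior mask explicitly
  f <- complex_field_2d(ifelse(is.na(out), 0 + 0i, out), fov, wavelength)
  f$mask <- rr < sphere$a
  f$samples[f$mask] <- NA_complex_
  f
}

# scattered scalar field at points with spherical radius rr and axial
# coordinate zz (cos(theta) = z / r); vectorized partial-wave sum
.mie_scattered_points <- function(ser, rr, zz, wavelength) {
  k <- 2 * pi / wavelength
  nmax <- length(ser$B) - 1
  r <- pmax(rr, 1e-9)
  mu <- zz / r
  kr <- k * r
  jx <- .sph_jn_mat(nmax, kr)
  hx <- jx + 1i * .sph_yn_mat(nmax, kr)
  p <- .legendre_mat(mu, nmax)  # points x order
  drop(rowSums(p * t(hx * ser$B)))
}

#' Spatial radial profile of the scattered near field
#'
#' Reconstructs the scattered field on the detector plane as a function of
#' radius by the order-0 discrete Hankel transform of the radial far field,
#' then resamples it at the requested radii with a cubic spline (zero beyond
#' the transform's spatial extent). This is the 1-D shortcut to the 2-D
#' far-field/Fourier pipeline, exact for circularly symmetric fields.
#'
#' @param sphere a [mie_sphere()]
#' @param radii spatial radii (um) at which to evaluate
#' @param wavelength vacuum wavelength in um
#' @param n_samples,q_max discrete Hankel transform size and reciprocal extent
#' @return complex vector of scattered-field values at `radii`
#' @export
radial_near_profile <- function(sphere, radii, wavelength,
                                n_samples = 320, q_max = 2.5 / wavelength) {
  ff <- far_field_radial(sphere, wavelength, n_samples, q_max)
  nf <- inverse_hankel(ff)
  re <- splinefun(nf$r, Re(nf$samples))
  im <- splinefun(nf$r, Im(nf$samples))
  out <- complex(real = re(radii), imaginary = im(radii))
  out[radii > nf$r_max] <- 0 + 0i
  out
}

#' Field of two spheres and its right-half radial extraction
#'
#' Superposes the scattered fields of a central sphere (at the origin) and a
#' perturbing sphere displaced along -x by `separation`, under one incident
#' plane wave (single scattering; no multiple-scattering coupling). Returns
#' the total 2-D field in the plane through both centres and the 1-D
#' extraction along the +x half-line through the central sphere -- the side
#' facing away from the perturber, which keeps the input structure of
#' single-sphere radial representations.
#'
#' The 1-D extraction is built from the band-limited Hankel near-field
#' profile (the training representation), evaluated at `radii`:
#' E(r) = 1 + f_c(r) + f_o(r + separation).
#'
#' @param sphere_center central [mie_sphere()] at the origin
#' @param sphere_offset perturbing [mie_sphere()]
#' @param separation centre-to-centre distance in um (>= sum of radii)
#' @param wavelength vacuum wavelength in um
#' @param n_pixels,fov 2-D grid specification
#' @param radii radial samples of the 1-D extraction (default 320 uniform
#'   points on [0, fov/2])
#' @return list with `field` (total [complex_field_2d()], horizontal plane)
#'   and `half_line` (spatial [radial_field_1d()] of the total field)
#' @export
two_sphere_field <- function(sphere_center, sphere_offset, separation,
                             wavelength, n_pixels = 128, fov = 16,
                             radii = NULL) {
  if (separation < sphere_center$a + sphere_offset$a)
    .stopf("spheres overlap: separation %g < %g", separation,
           sphere_center$a + sphere_offset$a)
  if (is.null(radii)) radii <- seq(0, fov / 2, length.out = 320)
  s1 <- mie_sphere(sphere_center$a, sphere_center$n, c(0, 0))
  s2 <- mie_sphere(sphere_offset$a, sphere_offset$n, c(-separation, 0))
  f1 <- scattered_field_2d(s1, wavelength, n_pixels, fov, "horizontal")
  f2 <- scattered_field_2d(s2, wavelength, n_pixels, fov, "horizontal")
  tot <- f1$samples + f2$samples + 1  # incident exp(ikz) = 1 on z = 0
  msk <- f1$mask | f2$mask
  fld <- complex_field_2d(ifelse(msk, 0 + 0i, tot), fov, wavelength)
  fld$mask <- msk
  fld$samples[msk] <- NA_complex_
  fc <- radial_near_profile(sphere_center, radii, wavelength)
  fo <- radial_near_profile(sphere_offset, radii + separation, wavelength)
  half <- radial_field_1d(1 + fc + fo, radii, "spatial",
                          wavelength, grid = "uniform")
  list(field = fld, half_line = half)
}
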