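# Order-0 quasi-discrete Hankel transform on the Bessel-zero grid
# (Fourier-Bessel double-truncation scheme). With ordinary-frequency
# convention g(q) = 2*pi * int f(r) J0(2*pi*q*r) r dr, sampling at
# r_m = c_m * R / C and q_k = c_k * Q / C (c_j the j-th zero of J0,
# C = c_{N+1}, 2*pi*R*Q = C) gives the reciprocal pair
#   g(q_k) = sum_m f(r_m) J0(c_k c_m / C) / (pi Q^2 J1(c_m)^2)
#   f(r_m) = sum_k g(q_k) J0(c_k c_m / C) / (pi R^2 J1(c_k)^2)
# which is self-inverse up to conditioning.

# first n zeros of J0 by Newton refinement of the McMahon expansion
.j0_zeros <- function(n) {
  z <- (seq_len(n) - 0.25) * pi
  for (i in 1:50) {
    dz <- besselJ(z, 0) / (-besselJ(z, 1))
    z <- z - dz
    if (max(abs(dz)) < 1e-14) break
  }
  z
}

#' Plan an order-0 discrete Hankel transform
#'
#' Precomputes the Bessel-zero sampling grids and transform matrices for the
#' order-0 quasi-discrete Hankel transform with `n` samples and reciprocal
#' extent `q_max` (um^-1). The spatial extent is fixed by the scheme's
#' sampling theorem: `r_max = c[n+1] / (2*pi*q_max)`.
#'
#' @param n number of radial samples (>= 2)
#' @param q_max reciprocal-domain extent in um^-1
#' @return a list with spatial radii `r`, reciprocal radii `q`, the two
#'   transform matrices and the extents; class `hankel_plan`
#' @export
hankel_plan <- function(n, q_max) {
  if (n < 2) .stopf("hankel plan needs n >= 2")
  if (q_max <= 0) .stopf("q_max must be positive")
  cz <- .j0_zeros(n + 1)
  cc <- cz[seq_len(n)]
  C <- cz[n + 1]
  r_max <- C / (2 * pi * q_max)
  q <- cc * q_max / C
  r <- cc * r_max / C
  j1 <- besselJ(cc, 1)
  core <- outer(cc, cc, function(a, b) besselJ(a * b / C, 0))
  inv <- core / (pi * r_max^2 * matrix(j1^2, n, n, byrow = TRUE))
  fwd <- core / (pi * q_max^2 * matrix(j1^2, n, n, byrow = TRUE))
  structure(list(n = n, q = q, r = r, q_max = q_max, r_max = r_max,
                 to_spatial = inv, to_reciprocal = fwd),
            class = "hankel_plan")
}

.plan_for_field <- function(field) {
  n <- length(field$samples)
  if (!identical(field$grid, "bessel0"))
    .stopf("discrete Hankel transform requires samples on the Bessel-zero grid (grid = \"bessel0\")")
  # the grid's full extent lies beyond the last sample: q_max = q_n * C / c_n
  cz <- .j0_zeros(n + 1)
  ext <- field$r_max * cz[n + 1] / cz[n]
  if (field$domain == "reciprocal") hankel_plan(n, q_max = ext)
  else hankel_plan(n, q_max = cz[n + 1] / (2 * pi * ext))
}

#' Order-0 inverse discrete Hankel transform (reciprocal to spatial)
#'
#' Maps a circularly symmetric reciprocal-domain radial profile to the spatial
#' domain; the radial analogue of an inverse 2-D Fourier transform. Input
#' samples must lie on the Bessel-zero grid of [hankel_plan()] (as produced by
#' [far_field_radial()] with `grid = "bessel0"`). The spatial extent follows
#' from the scheme's sampling theorem.
#'
#' @param field a reciprocal-domain [radial_field_1d()] on the Bessel-zero grid
#' @return a spatial-domain [radial_field_1d()] on the matching grid
#' @seealso [forward_hankel()] for the spatial-to-reciprocal direction.
#' @export
inverse_hankel <- function(field) {
  if (!inherits(field, "radial_field_1d")) .stopf("field must be a radial_field_1d")
  if (field$domain != "reciprocal")
    .stopf("inverse_hankel expects a reciprocal-domain field (got '%s')", field$domain)
  plan <- .plan_for_field(field)
  out <- drop(plan$to_spatial %*% field$samples)
  radial_field_1d(out, plan$r, "spatial", field$wavelength, grid = "bessel0")
}

#' Order-0 forward discrete Hankel transform (spatial to reciprocal)
#'
#' @param field a spatial-domain [radial_field_1d()] on the Bessel-zero grid
#' @return a reciprocal-domain [radial_field_1d()]
#' @export
forward_hankel <- function(field) {
  if (!inherits(field, "radial_field_1d")) .stopf("field must be a radial_field_1d")
  if (field$domain != "spatial")
    .stopf("forward_hankel expects a spatial-domain field (got '%s')", field$domain)
  plan <- .plan_for_field(field)
  out <- drop(plan$to_reciprocal %*% field$samples)
  radial_field_1d(out, plan$q, "reciprocal", field$wavelength, grid = "bessel0")
}
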