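# Independent oracles and shared fixtures for the test suite.
# Everything here is deliberately implemented apart from the package's own
# numerics: spherical Bessel functions come from base R's half-integer
# besselJ/besselY (real arguments) and from the closed forms j0, j1 plus
# upward recurrence (complex arguments), so the per-order continuity solve
# below shares no code with mie_coefficients().

# spherical bessel j_t for t = 0..nmax by closed form + upward recurrence;
# adequate for |z| comfortably above nmax (checked against base besselJ)
oracle_sph_j <- function(nmax, z) {
  out <- complex(length.out = nmax + 1)
  out[1] <- sin(z) / z
  if (nmax >= 1) out[2] <- sin(z) / z^2 - cos(z) / z
  if (nmax >= 2) for (t in 2:nmax) out[t + 1] <- (2 * t - 1) / z * out[t] - out[t - 1]
  out
}

oracle_sph_y <- function(nmax, z) {
  out <- complex(length.out = nmax + 1)
  out[1] <- -cos(z) / z
  if (nmax >= 1) out[2] <- -cos(z) / z^2 - sin(z) / z
  if (nmax >= 2) for (t in 2:nmax) out[t + 1] <- (2 * t - 1) / z * out[t] - out[t - 1]
  out
}

# per-order 2x2 boundary-matching solve: continuity of the scalar field and
# its radial derivative at r = a between (incident + scattered) outside and
# the interior expansion; returns the scattered coefficients
oracle_mie_B <- function(a, n, wavelength, nmax) {
  k <- 2 * pi / wavelength
  x <- k * a
  y <- n * k * a
  jx <- sqrt(pi / (2 * x)) * besselJ(x, 0:nmax + 0.5)       # base R, real arg
  yx <- sqrt(pi / (2 * x)) * besselY(x, 0:nmax + 0.5)
  hx <- complex(real = jx, imaginary = yx)
  jy <- oracle_sph_j(nmax, y)
  dfun <- function(f, fm1, z) fm1 - (0:nmax + 1) / z * f
  jxm1 <- c(cos(x) / x, jx[-(nmax + 1)])
  jym1 <- c(cos(y) / y, jy[-(nmax + 1)])
  hxm1 <- c(exp(1i * x) / x, hx[-(nmax + 1)])
  djx <- dfun(jx, jxm1, x)
  djy <- dfun(jy, jym1, y)
  dhx <- dfun(hx, hxm1, x)
  B <- complex(length.out = nmax + 1)
  for (i in seq_len(nmax + 1)) {
    ct <- (2 * (i - 1) + 1) * (1i)^(i - 1)
    m2 <- matrix(c(hx[i], dhx[i], -jy[i], -n * djy[i]), 2, 2)
    B[i] <- solve(m2, -ct * c(jx[i], djx[i]))[1]
  }
  B
}

# Fresnel amplitude coefficients at an interface n1 -> n2 (normal incidence)
fresnel_normal <- function(n1, n2) {
  list(r = (n1 - n2) / (n1 + n2), t = 2 * n1 / (n1 + n2))
}

# single-film (n1 | nf, thickness d | n2) reflectance, normal incidence
thin_film_R <- function(n1, nf, n2, d, wavelength) {
  r12 <- (n1 - nf) / (n1 + nf)
  r23 <- (nf - n2) / (nf + n2)
  beta <- 2 * pi / wavelength * nf * d
  r <- (r12 + r23 * exp(2i * beta)) / (1 + r12 * r23 * exp(2i * beta))
  Mod(r)^2
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

# small shared fixtures
fix_sphere <- function() mie_sphere(1, 1.5 + 0.03i)

fix_hologram <- function(n_pixels = 64, frames = 32) {
  fld <- scattered_field_2d(fix_sphere(), 1, n_pixels, 16, "horizontal",
                            total = TRUE)
  s <- fld$samples
  s[fld$mask] <- 0 + 0i
  list(field = s,
       ig = simulate_interferogram(s, 1 + 0i, (seq_len(frames) - 1) * 2 / frames, 1))
}
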