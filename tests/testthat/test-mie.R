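test_that("series coefficients match the per-order boundary-matching oracle", {
  for (a in c(0.5, 1, 2)) {
    for (n in c(1.2 + 0i, 1.5 + 0.03i, 2 + 0.05i)) {
      ser <- mie_coefficients(mie_sphere(a, n), 1)
      nmax <- ser$n_terms
      B_o <- oracle_mie_B(a, n, 1, nmax)
      expect_lt(max(Mod(ser$B - B_o)) / max(Mod(B_o)), 1e-10,
                label = sprintf("a=%g n=%s", a, format(n)))
    }
  }
})

test_that("index-matched sphere does not scatter", {
  ser <- mie_coefficients(mie_sphere(1, 1 + 0i), 1)
  expect_lt(max(Mod(ser$B)), 1e-12)
  fld <- scattered_field_2d(mie_sphere(1, 1 + 0i), 1, 32, 8, "horizontal",
                            total = TRUE)
  inc <- exp(0i)  # plane z = 0
  expect_lt(max(Mod(fld$samples - inc), na.rm = TRUE), 1e-12)
  ff <- far_field_radial(mie_sphere(1, 1 + 0i), 1, 64, 2)
  expect_lt(max(Mod(ff$samples)), 1e-12)
})

test_that("doubling the wavelength halves the size parameter and truncation", {
  s1 <- mie_coefficients(mie_sphere(1, 1.5 + 0.03i), 1)
  s2 <- mie_coefficients(mie_sphere(1, 1.5 + 0.03i), 2)
  expect_equal(s1$size_parameter, 2 * s2$size_parameter)
  expect_gt(s1$n_terms, s2$n_terms)
})

test_that("horizontal-plane total field is radially symmetric", {
  fld <- scattered_field_2d(fix_sphere(), 1, 64, 16, "horizontal", total = TRUE)
  cx <- field_coords(fld)
  rr <- round(sqrt(outer(cx$y^2, cx$x^2, "+")), 9)
  groups <- split(as.vector(fld$samples), as.vector(rr))
  dev <- vapply(groups, function(g) {
    g <- g[!is.na(g)]
    if (length(g) < 2) 0 else max(Mod(g - g[1]))
  }, numeric(1))
  expect_lt(max(dev), 1e-8)
})

test_that("scattered amplitude decays as 1/(kr) in the far zone", {
  ser <- mie_coefficients(fix_sphere(), 1)
  mu <- 0.3
  e1 <- chemholo:::.mie_scattered_points(ser, 500, 500 * mu, 1)
  e2 <- chemholo:::.mie_scattered_points(ser, 1000, 1000 * mu, 1)
  expect_equal(Mod(e1) / Mod(e2), 2, tolerance = 0.02)
})

test_that("points inside the sphere are masked", {
  fld <- scattered_field_2d(mie_sphere(2, 1.5 + 0i), 1, 64, 8, "horizontal")
  cx <- field_coords(fld)
  rr <- sqrt(outer(cx$y^2, cx$x^2, "+"))
  expect_true(all(is.na(fld$samples[rr < 2])))
  expect_true(!anyNA(fld$samples[rr > 2.5]))
})

test_that("1-D radial far field equals the radial extraction of the 2-D image", {
  s <- fix_sphere()
  f2 <- far_field_2d(s, 1, 128, 16)
  cut <- f2$samples[65, 65:128]          # +x row from the centre
  q <- (0:63) / 16
  ser <- mie_coefficients(s, 1)
  prof <- chemholo:::.mie_far_profile(ser$B, q, 1)
  expect_lt(max(Mod(cut - prof)) / max(Mod(prof)), 1e-10)
})

test_that("far-field profile is linear in the series coefficients", {
  ser <- mie_coefficients(fix_sphere(), 1)
  q <- seq(0.01, 0.9, length.out = 50)
  f1 <- chemholo:::.mie_far_profile(ser$B, q, 1)
  f2 <- chemholo:::.mie_far_profile(3.7 * ser$B, q, 1)
  expect_equal(f2, 3.7 * f1, tolerance = 1e-12)
})

test_that("Hankel transform round-trips band-limited radial profiles", {
  plan <- hankel_plan(256, 4)
  # gaussian is self-reciprocal under the order-0 transform
  g <- radial_field_1d(exp(-pi * plan$q^2), plan$q, "reciprocal", 1, "bessel0")
  sp <- inverse_hankel(g)
  expect_lt(max(Mod(sp$samples - exp(-pi * sp$r^2))), 1e-12)
  set.seed(7)
  for (rep in 1:5) {
    # random smooth band-limited profile
    w <- runif(3, 0.3, 1.5)
    amp <- rnorm(3)
    prof <- amp[1] * exp(-(plan$q / w[1])^2) +
      amp[2] * exp(-((plan$q - 0.5) / w[2])^2) +
      amp[3] * exp(-((plan$q - 1) / w[3])^2)
    f <- radial_field_1d(prof + 0i, plan$q, "reciprocal", 1, "bessel0")
    rt <- forward_hankel(inverse_hankel(f))
    expect_lt(max(Mod(rt$samples - f$samples)) / max(Mod(f$samples)), 1e-8)
  }
  expect_error(inverse_hankel(sp), "reciprocal")
  expect_error(forward_hankel(g), "spatial")
})

test_that("1-D Hankel path agrees with the 2-D Fourier path", {
  # a = 2 um, m = 1.4, kappa = 0.02 sphere on the 256 px / 32 um geometry;
  # the residual (~8e-4 of the peak) is Cartesian-grid quadrature error at
  # the aperture rim, see the methods vignette
  s <- mie_sphere(2, 1.4 + 0.02i)
  f2 <- near_field_from_far_2d(far_field_2d(s, 1, 256, 32))
  cut <- f2$samples[129, 129:256]
  r2 <- (0:127) * 32 / 256
  nf <- inverse_hankel(far_field_radial(s, 1, 256, q_max = 4))
  sr <- splinefun(r2, Re(cut))
  si <- splinefun(r2, Im(cut))
  sel <- nf$r < 15.5
  ref <- complex(real = sr(nf$r[sel]), imaginary = si(nf$r[sel]))
  relmax <- max(Mod(nf$samples[sel] - ref)) / max(Mod(cut))
  expect_lt(relmax, 1.5e-3)
})

test_that("two-sphere field reduces to one sphere at large separation", {
  s <- fix_sphere()
  radii <- seq(0, 8, length.out = 320)
  ts <- two_sphere_field(s, s, 128, 1, n_pixels = 32, fov = 16, radii = radii)
  single <- 1 + radial_near_profile(s, radii, 1)
  expect_lt(max(Mod(ts$half_line$samples - single)), 1e-6)
})

test_that("two identical spheres produce a mirror-symmetric field", {
  s <- mie_sphere(1, 1.5 + 0.01i)
  ts <- two_sphere_field(s, s, 4, 1, n_pixels = 64, fov = 16)
  v <- ts$field$samples
  v[is.na(v)] <- 0 + 0i
  # swapping the identical spheres mirrors the field about the mid-plane
  # x = -2: pixel column j (x = (j - 33) / 4) maps to column 50 - j
  for (j in c(2, 10, 20, 33, 45)) {
    expect_lt(max(Mod(v[, j] - v[, 50 - j])), 1e-8)
  }
})

test_that("closer spheres perturb the right-half extraction more", {
  s <- mie_sphere(1, 1.5 + 0.01i)
  radii <- seq(0, 8, length.out = 160)
  single <- 1 + radial_near_profile(s, radii, 1)
  pert <- function(sep) {
    ts <- two_sphere_field(s, s, sep, 1, n_pixels = 32, fov = 16, radii = radii)
    max(Mod(ts$half_line$samples - single))
  }
  expect_gt(pert(2), pert(8))
  expect_error(two_sphere_field(s, s, 1.5, 1), "overlap")
})
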