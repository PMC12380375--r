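test_that("homogeneous stack transmits with accumulated phase and no reflection", {
  lam <- 2
  stk <- layer_stack(c(1.2 + 0i, 1.2 + 0i, 1.2 + 0i), c(0, 1))
  sol <- solve_layered(stk, plane_wave(1 + 0i, lam))
  expect_lt(max(Mod(sol$D[, 1])), 1e-12)
  # field at z equals field at z + lambda/n
  e1 <- field_at(sol, 0, 0, 0.2)
  e2 <- field_at(sol, 0, 0, 0.2 + lam / 1.2)
  expect_lt(max(Mod(e1 - e2)), 1e-12)
  # transmitted amplitude preserved
  expect_equal(Mod(sol$U[1, 3]), 1, tolerance = 1e-12)
})

test_that("two semi-infinite layers reproduce the Fresnel coefficients", {
  for (n2 in c(1.5 + 0i, 2.4 + 0i, 1.33 + 0i)) {
    sol <- solve_layered(layer_stack(c(1 + 0i, n2), 0), plane_wave(1 + 0i, 1))
    fr <- fresnel_normal(1, n2)
    expect_equal(sol$D[1, 1], fr$r, tolerance = 1e-12)
    expect_equal(sol$U[1, 2], fr$t, tolerance = 1e-12)
  }
})

test_that("oblique incidence matches Fresnel for s and p polarization", {
  n1 <- 1; n2 <- 1.7
  th <- 35 * pi / 180
  dir <- c(sin(th), 0, cos(th))
  stk <- layer_stack(c(n1 + 0i, n2 + 0i), 0)
  th2 <- asin(n1 * sin(th) / n2)
  rs <- (n1 * cos(th) - n2 * cos(th2)) / (n1 * cos(th) + n2 * cos(th2))
  rp <- (n2 * cos(th) - n1 * cos(th2)) / (n2 * cos(th) + n1 * cos(th2))
  sol_s <- solve_layered(stk, plane_wave(1 + 0i, 1, dir, c(0, 1, 0)), "s")
  expect_equal(Mod(sol_s$D[2, 1]), abs(rs), tolerance = 1e-10)
  sol_p <- solve_layered(stk, plane_wave(1 + 0i, 1, dir, c(0, 1, 0)), "p")
  expect_equal(sqrt(sum(Mod(sol_p$D[, 1])^2)), abs(rp), tolerance = 1e-10)
  rt <- reflectance_transmittance(sol_s)
  expect_equal(rt$R + rt$T, 1, tolerance = 1e-10)
})

test_that("quarter-wave film reflectance matches the thin-film closed form", {
  lam <- 1; nf <- 1.38; d <- lam / (4 * nf)
  sol <- solve_layered(layer_stack(c(1 + 0i, nf + 0i, 1.5 + 0i), c(0, d)),
                       plane_wave(1 + 0i, lam))
  rt <- reflectance_transmittance(sol)
  expect_equal(rt$R, thin_film_R(1, nf, 1.5, d, lam), tolerance = 1e-10)
  expect_equal(rt$R + rt$T, 1, tolerance = 1e-10)
})

test_that("randomized lossless stacks conserve energy and satisfy Gauss's law", {
  set.seed(42)
  for (rep in 1:10) {
    nl <- sample(2:6, 1)
    n <- complex(real = runif(nl, 1, 2.5))
    bnd <- cumsum(c(0, runif(nl - 2, 0.2, 3)))[seq_len(nl - 1)]
    th <- runif(1, 0, 0.4)
    dir <- c(sin(th), 0, cos(th))
    sol <- solve_layered(layer_stack(n, bnd),
                         plane_wave(1 + 0i, runif(1, 0.8, 2), dir, c(0, 1, 0)), "s")
    rt <- reflectance_transmittance(sol)
    expect_equal(rt$R + rt$T, 1, tolerance = 1e-10)
    expect_lt(sol$residual, 1e-10)
    # transversality of every partial wave
    for (l in seq_len(nl)) {
      su <- c(sol$sx, sol$sy, sol$sz[l])
      sd <- c(sol$sx, sol$sy, -sol$sz[l])
      expect_lt(Mod(sum(su * sol$U[, l])), 1e-10)
      expect_lt(Mod(sum(sd * sol$D[, l])), 1e-10)
    }
  }
})

test_that("field_at is continuous across boundaries and decays in absorbers", {
  stk <- layer_stack(c(1 + 0i, 1.4 + 0.02i, 1.4 + 0i), c(0, 3))
  sol <- solve_layered(stk, plane_wave(1 + 0i, 1))
  for (zb in c(0, 3)) {
    below <- field_at(sol, 0.3, -0.2, zb - 1e-12)
    above <- field_at(sol, 0.3, -0.2, zb + 1e-12)
    expect_lt(max(Mod(below - above)[1:2]), 1e-10)  # tangential components
  }
  # index-matched real parts: transmitted amplitude ratio ~ exp(-k kappa d)
  # up to the tiny residual reflections at the extinction jump (r ~ kappa/2n)
  stk2 <- layer_stack(c(1.4 + 0i, 1.4 + 0.02i, 1.4 + 0i), c(0, 3))
  sol2 <- solve_layered(stk2, plane_wave(1 + 0i, 1))
  ratio <- Mod(sol2$U[1, 3]) / Mod(sol2$U[1, 1])
  expect_equal(ratio, exp(-2 * pi * 0.02 * 3), tolerance = 2e-4)
})

test_that("equal-OPL stacks agree at the exit face but split at the detector", {
  lam <- 1.5
  sa <- solve_layered(layer_stack(c(1, 3 + 0.05i, 1), c(0, 2)), plane_wave(1 + 0i, lam))
  sb <- solve_layered(layer_stack(c(1, 1 + 0.05i, 1), c(0, 6)), plane_wave(1 + 0i, lam))
  d_exit <- wrap_pi(Arg(field_at(sa, 0, 0, 2 + 1e-9)[1]) -
                    Arg(field_at(sb, 0, 0, 6 + 1e-9)[1]))
  d_det <- wrap_pi(Arg(field_at(sa, 0, 0, 8)[1]) - Arg(field_at(sb, 0, 0, 8)[1]))
  expect_lt(abs(d_exit), 0.05)                      # same optical path inside
  geo <- wrap_pi(2 * pi / lam * (6 - 2))            # air-path difference
  expect_equal(d_det, geo, tolerance = 0.06)
  expect_gt(abs(d_det), 10 * abs(d_exit))
})

test_that("degenerate geometries are rejected cleanly", {
  expect_error(solve_layered(layer_stack(c(1 + 0i, 1.5 + 0i), 0),
                             plane_wave(1 + 0i, 1, c(1, 0, 0), c(0, 1, 0))),
               "grazing")
  expect_error(layer_stack(c(1 + 0i, 1.5 + 0i, 1 + 0i), c(2, 1)), "increasing")
  expect_error(reflectance_transmittance(
    solve_layered(layer_stack(c(1, 1.5 + 0.1i), 0), plane_wave(1 + 0i, 1))),
    "lossless")
})
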