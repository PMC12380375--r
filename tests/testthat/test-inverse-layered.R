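test_that("candidate grid is half-open with exact optical path products", {
  prob <- layered_inverse_problem(2, 10, 1 + 0i, 1, m_range = c(1, 2),
                                  epsilon = 0.5)
  cand <- grid_candidates(prob)
  expect_equal(cand$m, c(1.0, 1.5))
  expect_equal(cand$m * cand$d, rep(2, 2), tolerance = 1e-12)
  prob2 <- layered_inverse_problem(2, 10, 1 + 0i, 1, m_range = c(1, 2),
                                   epsilon = 0.25)
  expect_equal(nrow(grid_candidates(prob2)), 2 * nrow(cand))
  expect_error(grid_candidates(
    layered_inverse_problem(2, 1e7, 1 + 0i, 1, m_range = c(1, 2),
                            epsilon = 1e-9)), "too fine")
})

test_that("noiseless inversion recovers the embedded layer exactly", {
  m <- 1.65; d <- 1.67; kap <- 0.03; dt <- 4
  z_det <- d + dt
  meas <- simulate_layered_measurement(m, d, kap, z_det, 1)
  prob <- layered_inverse_problem(m * d, z_det, meas, 1)
  est <- fit_layered(prob)
  expect_equal(est$m_hat, m, tolerance = 1e-12)
  expect_equal(est$d_hat, d, tolerance = 1e-12)
  expect_equal(est$kappa_hat, kap, tolerance = 1e-12)
  expect_lt(est$cost, 1e-10)
})

test_that("a measurement generated from a candidate wins with zero cost", {
  prob0 <- layered_inverse_problem(2.7555, 6, 1 + 0i, 1)
  cand <- grid_candidates(prob0)
  pick <- cand[317, ]
  meas <- simulate_layered_measurement(pick$m, pick$d, 0, 6, 1)
  md <- fit_md(layered_inverse_problem(2.7555, 6, meas, 1), kappa = 0)
  expect_equal(md$m_hat, pick$m)
  expect_lt(md$cost, 1e-12)
})

test_that("equal-OPL candidates are distinguished through the air path", {
  # two (m, d) pairs of identical optical path length produce different
  # detector phases once dt > 0, so the scan has a unique sharp minimum
  meas <- simulate_layered_measurement(1.5, 2, 0, 8, 1)
  prob <- layered_inverse_problem(3, 8, meas, 1, m_range = c(1.1, 2.0),
                                  epsilon = 0.01)
  md <- fit_md(prob)
  expect_equal(md$m_hat, 1.5, tolerance = 1e-12)
  others <- md$scan$cost[abs(md$scan$m - 1.5) > 0.05]
  expect_gt(min(others), 100 * md$cost + 1e-6)
})

test_that("kappa cost is monotone around the optimum", {
  m <- 1.65; d <- 1.67; kap <- 0.03
  meas <- simulate_layered_measurement(m, d, kap, 6, 1)
  prob <- layered_inverse_problem(m * d, 6, meas, 1)
  kp <- fit_kappa(prob, m, d)
  expect_equal(kp$kappa_hat, kap, tolerance = 1e-12)
  scan <- kp$scan
  below <- scan$cost[scan$kappa <= kap]
  above <- scan$cost[scan$kappa >= kap]
  expect_true(all(diff(below) <= 1e-12))
  expect_true(all(diff(above) >= -1e-12))
  # a transparent layer comes back with kappa = 0
  meas0 <- simulate_layered_measurement(1.4, 2, 0, 6, 1)
  est0 <- fit_layered(layered_inverse_problem(2.8, 6, meas0, 1))
  expect_equal(est0$kappa_hat, 0)
})

test_that("random noiseless on-grid truths are recovered exactly", {
  set.seed(21)
  eps <- 5e-3
  opl <- 2.4
  for (rep in 1:12) {
    mi <- 1.1 + sample.int(round(0.9 / eps) - 1, 1) * eps
    ki <- sample.int(20, 1) * eps
    d <- opl / mi
    z_det <- opl / 1.1 + 2   # beyond the thickest candidate
    meas <- simulate_layered_measurement(mi, d, ki, z_det, 1)
    est <- fit_layered(layered_inverse_problem(opl, z_det, meas, 1,
                                               epsilon = eps))
    expect_equal(est$m_hat, mi, tolerance = 1e-9)
    expect_equal(est$kappa_hat, ki, tolerance = 1e-9)
  }
})

test_that("noise leaves m and d at grid precision while kappa degrades", {
  tab <- noise_robustness_experiment(sigma_grid = c(0, 0.02, 0.1),
                                     n_reps = 3, n_pixels = 32, seed = 5,
                                     epsilon = 2e-3)
  expect_equal(tab$err_m[1], 0)
  expect_equal(tab$err_d[1], 0)
  expect_equal(tab$err_kappa[1], 0)
  # m, d stay near grid precision; kappa error grows with sigma
  expect_lt(max(tab$err_m), 5e-3)
  expect_gt(tab$err_kappa[3], tab$err_kappa[1])
  expect_gt(tab$err_kappa[3], tab$err_m[3])
  # determinism
  tab2 <- noise_robustness_experiment(sigma_grid = c(0, 0.02, 0.1),
                                      n_reps = 3, n_pixels = 32, seed = 5,
                                      epsilon = 2e-3)
  expect_identical(tab, tab2)
})
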