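# wrap a phase difference to (-pi, pi]
.wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

#' Simulate the detector-plane field behind a single embedded layer
#'
#' Coupled-wave simulation of a 3-layer stack (air / target / air) at normal
#' incidence: the target layer with index m + i*kappa and thickness d starts
#' at `z_base`, and the x-polarized field is evaluated at the fixed detector
#' position `z_detector` beyond the stack.
#'
#' @param m,d,kappa real index, thickness (um) and extinction coefficient of
#'   the target layer
#' @param z_detector absolute detector position in um (must lie beyond the
#'   layer)
#' @param wavelength wavelength in um
#' @param z_base position of the lower layer boundary (default 0)
#' @param amplitude incident amplitude
#' @return complex scalar: the x-component of the transmitted field at the
#'   detector
#' @export
simulate_layered_measurement <- function(m, d, kappa, z_detector, wavelength,
                                         z_base = 0, amplitude = 1 + 0i) {
  if (z_detector <= z_base + d)
    .stopf("detector at z = %g must lie beyond the layer (top at %g)",
           z_detector, z_base + d)
  stk <- layer_stack(c(1, complex(real = m, imaginary = kappa), 1),
                     c(z_base, z_base + d))
  sol <- solve_layered(stk, plane_wave(amplitude, wavelength))
  field_at(sol, 0, 0, z_detector)[1]
}

#' Inverse problem for a layer of known optical path length
#'
#' Bundles the prior knowledge and the measurement for the grid-search
#' inversion of a flat layer embedded in air: the layer's optical path
#' length P = m * d, the fixed detector position, the (pixel-averaged)
#' measured complex field, and the search ranges. The candidate family is
#' m_i * d_i = P, enumerated over m with precision `epsilon`.
#'
#' @param opl optical path length P = m * d of the target layer (um)
#' @param z_detector absolute detector position (um)
#' @param measured measured complex field value at the detector
#' @param wavelength wavelength in um
#' @param m_range search interval for the real index (m_min >= 1)
#' @param epsilon grid precision for m (> 0)
#' @param kappa_range search interval for the extinction coefficient
#' @param z_base position of the lower layer boundary (default 0)
#' @param incident incident [plane_wave()]
#' @return an object of class `layered_inverse_problem`
#' @export
layered_inverse_problem <- function(opl, z_detector, measured, wavelength,
                                    m_range = c(1.1, 2.0), epsilon = 1e-3,
                                    kappa_range = c(0, 0.1), z_base = 0,
                                    incident = plane_wave(1 + 0i, wavelength)) {
  if (opl <= 0) .stopf("optical path length must be positive")
  if (epsilon <= 0) .stopf("epsilon must be positive")
  if (m_range[1] < 1 || m_range[2] <= m_range[1]) .stopf("need 1 <= m_min < m_max")
  if (z_detector <= z_base + opl / m_range[1])
    .stopf("detector must lie beyond the thickest candidate layer (z > %g)",
           z_base + opl / m_range[1])
  structure(list(opl = opl, z_detector = z_detector, measured = measured,
                 wavelength = wavelength, m_range = m_range, epsilon = epsilon,
                 kappa_range = kappa_range, z_base = z_base, incident = incident),
            class = "layered_inverse_problem")
}

#' Candidate (m, d) pairs of a layered inverse problem
#'
#' Enumerates N = (m_max - m_min) / epsilon candidates on the half-open grid
#' m_i = m_min + i * epsilon, i = 0..N-1, each with thickness d_i = P / m_i
#' so that m_i * d_i equals the known optical path length exactly.
#'
#' @param problem a [layered_inverse_problem()]
#' @return data frame with columns `m` and `d`
#' @export
grid_candidates <- function(problem) {
  n <- round((problem$m_range[2] - problem$m_range[1]) / problem$epsilon)
  if (n < 1) .stopf("empty candidate grid")
  if (n > 1e7) .stopf("candidate grid too fine: N = %g > 1e7", n)
  m <- problem$m_range[1] + (seq_len(n) - 1) * problem$epsilon
  data.frame(m = m, d = problem$opl / m)
}

#' Phase-matching grid search for the layer's (m, d)
#'
#' Simulates the detector-plane field for every candidate (m_i, d_i) with
#' m_i d_i = P and scores the wrapped phase mismatch
#' Theta_i = |wrap(phi(m_i, d_i) - phi_measured)|. Candidates share the
#' optical path through the layer but differ in the geometric air path to
#' the fixed detector, which breaks the (m, d) degeneracy. Ties break to the
#' smaller m. The extinction coefficient barely moves the phase; pass the
#' current estimate in `kappa` when iterating.
#'
#' @param problem a [layered_inverse_problem()]
#' @param kappa extinction coefficient used in the candidate simulations
#' @return list with `m_hat`, `d_hat`, `cost` (phase mismatch at the argmin,
#'   radians) and the full `scan` data frame
#' @export
fit_md <- function(problem, kappa = 0) {
  cand <- grid_candidates(problem)
  phi0 <- Arg(problem$measured)
  cost <- vapply(seq_len(nrow(cand)), function(i) {
    ef <- simulate_layered_measurement(cand$m[i], cand$d[i], kappa,
                                       problem$z_detector, problem$wavelength,
                                       problem$z_base,
                                       problem$incident$amplitude)
    abs(.wrap_phase(Arg(ef) - phi0))
  }, numeric(1))
  best <- which.min(cost)
  list(m_hat = cand$m[best], d_hat = cand$d[best], cost = cost[best],
       scan = cbind(cand, cost = cost))
}

#' Amplitude-matching grid search for the layer's extinction coefficient
#'
#' With (m, d) fixed, scans kappa over the problem's `kappa_range` at the
#' same grid precision and minimizes the amplitude mismatch
#' | |E(kappa)| - |E_measured| |, which is monotone in |kappa - kappa_true|
#' near the optimum for a single absorbing layer.
#'
#' @param problem a [layered_inverse_problem()]
#' @param m_hat,d_hat fixed layer parameters from [fit_md()]
#' @return list with `kappa_hat`, `cost` and the full `scan` data frame
#' @export
fit_kappa <- function(problem, m_hat, d_hat) {
  kr <- problem$kappa_range
  n <- round((kr[2] - kr[1]) / problem$epsilon) + 1
  if (n < 1) .stopf("empty kappa grid")
  kap <- kr[1] + (seq_len(n) - 1) * problem$epsilon
  a0 <- Mod(problem$measured)
  cost <- vapply(kap, function(kk) {
    ef <- simulate_layered_measurement(m_hat, d_hat, kk,
                                       problem$z_detector, problem$wavelength,
                                       problem$z_base,
                                       problem$incident$amplitude)
    abs(Mod(ef) - a0)
  }, numeric(1))
  best <- which.min(cost)
  list(kappa_hat = kap[best], cost = cost[best],
       scan = data.frame(kappa = kap, cost = cost))
}

#' Full layered inversion: alternate phase and amplitude fits
#'
#' Runs [fit_md()] (phase) and [fit_kappa()] (amplitude) alternately. The
#' first phase fit assumes kappa = 0; subsequent passes reuse the current
#' kappa estimate, which removes the small phase bias a strongly absorbing
#' layer would otherwise impose on (m, d). Stops early once the estimate is
#' stationary.
#'
#' @param problem a [layered_inverse_problem()]
#' @param n_passes maximum number of alternations (default 3)
#' @return an object of class `layered_estimate` with `m_hat`, `d_hat`,
#'   `kappa_hat`, the final phase `cost` and the pass history
#' @export
fit_layered <- function(problem, n_passes = 3) {
  kap <- 0
  hist <- list()
  md <- NULL
  for (p in seq_len(n_passes)) {
    md <- fit_md(problem, kappa = kap)
    kp <- fit_kappa(problem, md$m_hat, md$d_hat)
    hist[[p]] <- c(m = md$m_hat, d = md$d_hat, kappa = kp$kappa_hat,
                   cost_phase = md$cost, cost_amp = kp$cost)
    if (p > 1 && hist[[p]]["m"] == hist[[p - 1]]["m"] &&
        hist[[p]]["kappa"] == hist[[p - 1]]["kappa"]) break
    kap <- kp$kappa_hat
  }
  last <- hist[[length(hist)]]
  structure(list(m_hat = unname(last["m"]), d_hat = unname(last["d"]),
                 kappa_hat = unname(last["kappa"]),
                 cost = unname(last["cost_phase"]),
                 history = do.call(rbind, hist)),
            class = "layered_estimate")
}

#' @export
print.layered_estimate <- function(x, ...) {
  cat(sprintf("<layered_estimate> m = %g, d = %g um, kappa = %g (phase cost %.3e rad)\n",
              x$m_hat, x$d_hat, x$kappa_hat, x$cost))
  invisible(x)
}

#' Noise robustness of the layered inversion
#'
#' Repeats the full inversion on measurements corrupted by zero-mean
#' Gaussian detector noise. For each noise level sigma (quoted as a fraction
#' of the incident amplitude), `n_pixels` pixel readings of the flat-sample
#' detector field receive independent real and imaginary noise, the pixels
#' are averaged (the sample is flat, so averaging is exact), and the
#' inversion runs on the averaged value. Relative absolute errors of m, d
#' and kappa are averaged over `n_reps` repetitions.
#'
#' @param m_true,d_true,kappa_true ground-truth layer parameters
#' @param dt distance from the upper layer boundary to the detector (um)
#' @param wavelength wavelength in um
#' @param sigma_grid nonnegative noise standard deviations (fraction of the
#'   incident amplitude)
#' @param n_reps repetitions per noise level
#' @param n_pixels detector pixels averaged per measurement
#' @param seed RNG seed
#' @param m_range,epsilon,kappa_range passed to [layered_inverse_problem()]
#' @return data frame with one row per sigma: mean relative absolute errors
#'   `err_m`, `err_d`, `err_kappa`
#' @export
noise_robustness_experiment <- function(m_true = 1.65, d_true = 1.67,
                                        kappa_true = 0.03, dt = 4,
                                        wavelength = 1,
                                        sigma_grid = c(0, 0.001, 0.01, 0.05, 0.1),
                                        n_reps = 5, n_pixels = 64, seed = 1,
                                        m_range = c(1.1, 2.0), epsilon = 1e-3,
                                        kappa_range = c(0, 0.1)) {
  if (any(sigma_grid < 0)) .stopf("noise levels must be nonnegative")
  set.seed(seed)
  z_det <- d_true + dt
  e_true <- simulate_layered_measurement(m_true, d_true, kappa_true, z_det,
                                         wavelength)
  amp_in <- 1
  rows <- lapply(sigma_grid, function(sg) {
    errs <- vapply(seq_len(n_reps), function(rep) {
      noise <- complex(real = rnorm(n_pixels, 0, sg * amp_in),
                       imaginary = rnorm(n_pixels, 0, sg * amp_in))
      meas <- mean(e_true + noise)
      prob <- layered_inverse_problem(m_true * d_true, z_det, meas, wavelength,
                                      m_range, epsilon, kappa_range)
      est <- fit_layered(prob)
      c(abs(est$m_hat - m_true) / m_true,
        abs(est$d_hat - d_true) / d_true,
        abs(est$kappa_hat - kappa_true) / max(kappa_true, .Machine$double.eps))
    }, numeric(3))
    data.frame(sigma = sg, err_m = mean(errs[1, ]), err_d = mean(errs[2, ]),
               err_kappa = mean(errs[3, ]))
  })
  do.call(rbind, rows)
}
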