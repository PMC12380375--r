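test_that("interferogram constructor enforces its invariants", {
  fr <- array(1, c(4, 4, 3))
  expect_s3_class(interferogram(fr, (0:2) * 0.1, 1), "interferogram")
  expect_error(interferogram(fr[, , 1:2, drop = FALSE], (0:1) * 0.1, 1), "M >= 3")
  expect_error(interferogram(fr, c(0, 0.1, 0.25), 1), "uniformly")
  expect_error(interferogram(-fr, (0:2) * 0.1, 1), ">= 0")
})

test_that("simulated frames are sinusoidal in the offset with period lambda", {
  es <- matrix(c(0.3 + 0.2i, -0.1 + 0.4i, 0.05 - 0.3i, 0.2 + 0i), 2)
  ig <- simulate_interferogram(es, 1 + 0i, (0:9) * 0.11, 1)
  expect_true(all(ig$frames >= 0))
  # a frame at Delta and Delta + lambda are identical
  f1 <- simulate_interferogram(es, 1 + 0i, c(0, 1, 2), 1)
  expect_lt(max(abs(f1$frames[, , 1] - f1$frames[, , 2])), 1e-12)
  # zero object field: every frame is the constant |ER|^2
  ig0 <- simulate_interferogram(matrix(0 + 0i, 2, 2), 2 + 0i, (0:3) * 0.2, 1)
  expect_equal(max(abs(ig0$frames - 4)), 0)
})

test_that("difference images cancel the DC terms exactly", {
  h <- fix_hologram(16, 8)
  d <- difference_images(h$ig)
  expect_equal(dim(d)[3], 7)
  # telescoping sum equals last - first
  expect_equal(rowSums(d, dims = 2), h$ig$frames[, , 8] - h$ig$frames[, , 1],
               tolerance = 1e-12)
  ig0 <- simulate_interferogram(matrix(0 + 0i, 2, 2), 1 + 0i, (0:3) * 0.2, 1)
  expect_equal(max(abs(difference_images(ig0))), 0)
})

test_that("reconstruction recovers random complex fields at machine precision", {
  set.seed(11)
  es <- matrix(complex(real = rnorm(256, 0, 0.3),
                       imaginary = rnorm(256, 0, 0.3)), 16)
  for (m in c(3, 5, 32)) {
    ig <- simulate_interferogram(es, 1 + 0i, (0:(m - 1)) * 2 / m, 1)
    rec <- reconstruct_field(ig, 1 + 0i)
    expect_lt(mean(Mod(rec$es - es)), 1e-12)
    expect_true(all(rec$residual >= 0))
  }
})

test_that("any consecutive window of >= 3 frames reconstructs identically", {
  set.seed(12)
  es <- matrix(complex(real = rnorm(64, 0, 0.5),
                       imaginary = rnorm(64, 0, 0.5)), 8)
  ig <- simulate_interferogram(es, 1 + 0i, (0:31) * 2 / 32, 1)
  r_all <- reconstruct_field(ig, 1 + 0i)$es
  r_first3 <- reconstruct_field(ig, 1 + 0i, n_frames_used = 3)$es
  r_mid <- reconstruct_field(ig, 1 + 0i, n_frames_used = 5, frame_offset = 13)$es
  expect_lt(max(Mod(r_first3 - r_all)), 1e-10)
  expect_lt(max(Mod(r_mid - r_all)), 1e-10)
  # the sinusoid-fitting route agrees
  expect_lt(max(Mod(reconstruct_sinfit(ig, 1 + 0i) - es)), 1e-12)
})

test_that("ill-posed reconstructions are rejected", {
  set.seed(13)
  es <- matrix(complex(real = rnorm(16), imaginary = rnorm(16)), 4)
  ig <- simulate_interferogram(es, 1 + 0i, (0:4) * 0.2, 1)
  expect_error(reconstruct_field(ig, 1 + 0i, n_frames_used = 2), "underdetermined")
  expect_error(reconstruct_field(ig, 0 + 0i), "nonzero")
  ig_bad <- simulate_interferogram(es, 1 + 0i, (0:4) * 0.5, 1)  # delta = lambda/2
  expect_error(reconstruct_field(ig_bad, 1 + 0i), "singular")
})

test_that("reconstruction error grows linearly with intensity noise", {
  set.seed(14)
  es <- matrix(complex(real = rnorm(256, 0, 0.4),
                       imaginary = rnorm(256, 0, 0.4)), 16)
  ig <- simulate_interferogram(es, 1 + 0i, (0:7) * 0.11, 1)
  sig <- c(1e-4, 1e-3, 1e-2, 1e-1)
  mae <- vapply(sig, function(s) {
    igN <- ig
    igN$frames <- ig$frames + array(rnorm(length(ig$frames), 0, s),
                                    dim = dim(ig$frames))
    igN$frames <- pmax(igN$frames, 0)
    mean(Mod(reconstruct_field(igN, 1 + 0i)$es - es))
  }, numeric(1))
  fit <- lm(log10(mae) ~ log10(sig))
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.1)
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("fringe amplitude is larger near the sphere surface than at centre", {
  h <- fix_hologram(64, 32)
  # pixel A: image centre (on the sphere axis); pixel B: just outside the
  # surface, 0.25 um beyond the 1 um radius
  centre <- c(33, 33)
  off <- 33 - round((1.25 / sqrt(2)) / (16 / 64))
  amp <- function(px) {
    tr <- h$ig$frames[px[1], px[2], ]
    max(tr) - min(tr)
  }
  expect_gt(amp(c(off, off)), amp(centre))
})

test_that("interferogram stacks survive the float-TIFF round trip", {
  h <- fix_hologram(16, 5)
  tf <- tempfile(fileext = ".tif")
  suppressWarnings(write_interferogram_tiff(h$ig, tf))
  ig2 <- load_experimental_stack(tf, h$ig$step, h$ig$wavelength)
  expect_equal(dim(ig2$frames), dim(h$ig$frames))
  expect_lt(max(abs(ig2$frames - h$ig$frames)) / max(h$ig$frames), 1e-6)
  # reconstruction from the reloaded stack still works
  rec <- reconstruct_field(ig2, 1 + 0i, n_frames_used = 3)
  expect_lt(mean(Mod(rec$es - h$field)), 1e-5)
  expect_error(load_experimental_stack(tf, 0.1), "metadata")
  expect_error(load_experimental_stack("/nonexistent.tif", 0.1, 1), "no such file")
})
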