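test_that("factorial corpus has levels^3 samples and is deterministic", {
  ds1 <- generate_mie_dataset(3, n_radial = 96)
  expect_equal(nrow(ds1$inputs), 27)
  expect_equal(ncol(ds1$inputs), 192)
  expect_equal(colnames(ds1$labels), c("a", "m", "kappa"))
  expect_true(all(ds1$labels[, "a"] >= 1 & ds1$labels[, "a"] <= 2))
  ds2 <- generate_mie_dataset(3, n_radial = 96)
  expect_identical(ds1$inputs, ds2$inputs)
  # corner corpus: 2 levels -> 8 samples at the range corners
  ds3 <- generate_mie_dataset(2, n_radial = 96)
  expect_equal(nrow(ds3$inputs), 8)
  expect_setequal(unique(ds3$labels[, "m"]), c(1.1, 2.0))
  expect_error(generate_mie_dataset(3, ranges = list(a = c(1, 2), m = c(0.9, 2),
                                                     kappa = c(0.01, 0.05))),
               "m > 1")
})

test_that("identical labels give identical inputs", {
  ds <- generate_mie_dataset(2, n_radial = 96)
  dup <- chemholo:::.corpus_far_fields(ds$labels[c(3, 3), ],
                                       chemholo:::.dataset_geometry(96, 1, 16))
  expect_identical(dup[, 1], dup[, 2])
})

test_that("intensity conversion keeps magnitude, drops global phase", {
  ds <- generate_mie_dataset(2, n_radial = 96)
  dsi <- to_intensity(ds)
  l <- 96
  expect_equal(dsi$inputs[, 1:l],
               sqrt(ds$inputs[, 1:l]^2 + ds$inputs[, (l + 1):(2 * l)]^2))
  expect_true(all(dsi$inputs[, (l + 1):(2 * l)] == 0))
  expect_error(to_intensity(dsi), "complex")
  # global phase rotation changes the complex inputs but not the intensity
  rot <- exp(0.7i)
  z <- complex(real = ds$inputs[1, 1:l], imaginary = ds$inputs[1, (l + 1):(2 * l)])
  zr <- z * rot
  expect_gt(max(abs(Re(zr) - Re(z))), 1e-3)
  expect_lt(max(abs(Mod(zr) - Mod(z))), 1e-14)
  # a pure-real field maps to its absolute value
  fake <- ds
  fake$inputs[, (l + 1):(2 * l)] <- 0
  expect_equal(to_intensity(fake)$inputs[, 1:l], abs(fake$inputs[, 1:l]))
})

test_that("9:1 split with 20% validation reproduces the protocol counts", {
  fake <- chemholo:::.mie_dataset(matrix(0, 27000, 2),
                                  cbind(a = runif(27000), m = runif(27000) + 1.1,
                                        kappa = runif(27000)),
                                  "complex", "spatial", 1:2, 1,
                                  list(a = c(0, 1), m = c(1.1, 2.1),
                                       kappa = c(0, 1)))
  sp <- split_dataset(fake, seed = 3)
  expect_equal(nrow(sp$train$inputs), 19440)
  expect_equal(nrow(sp$validation$inputs), 4860)
  expect_equal(nrow(sp$test$inputs), 2700)
  idx <- c(sp$index$train, sp$index$validation, sp$index$test)
  expect_equal(sort(idx), 1:27000)   # disjoint cover, no duplicates
  sp2 <- split_dataset(fake, seed = 3)
  expect_identical(sp$index, sp2$index)
  sp3 <- split_dataset(fake, seed = 4)
  expect_false(identical(sp$index, sp3$index))
})

test_that("relative RMSE follows its two documented readings", {
  expect_equal(unname(relative_rmse(cbind(2), cbind(2))), 0)
  # one sample, truth 2, prediction 2.2
  expect_equal(unname(relative_rmse(cbind(2.2), cbind(2))), 10)
  expect_equal(unname(relative_rmse(cbind(2.2), cbind(2), "as_printed")),
               100 * sqrt(0.2^2 / 2), tolerance = 1e-12)
  # scale consistency: errors scaled by c scale eps_R by c
  set.seed(6)
  t <- matrix(runif(50, 1, 2))
  e <- rnorm(50, 0, 0.01)
  r1 <- relative_rmse(t + e, t)
  r2 <- relative_rmse(t + 3 * e, t)
  expect_equal(unname(r2 / r1), 3, tolerance = 1e-10)
  expect_warning(relative_rmse(cbind(c(1, 1)), cbind(c(1, 0))), "zero true")
})
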