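test_that("spectrum text files round-trip", {
  oc <- optical_constants(seq(900, 1800, by = 100), seq(1.4, 1.49, by = 0.01),
                          seq(0, 0.09, by = 0.01))
  f <- tempfile(fileext = ".txt")
  write_spectrum(oc, f)
  oc2 <- read_spectrum(f)
  expect_equal(oc2$grid, oc$grid)
  expect_equal(oc2$m, oc$m)
  expect_equal(oc2$kappa, oc$kappa)
  expect_equal(oc2$unit, "cm-1")
})

test_that("complex fields round-trip through float TIFF", {
  fld <- scattered_field_2d(fix_sphere(), 1, 32, 8, "horizontal", total = TRUE)
  fld$samples[fld$mask] <- 0 + 0i
  f <- tempfile(fileext = ".tif")
  suppressWarnings(write_field_tiff(fld, f))
  fld2 <- read_field_tiff(f)
  expect_equal(fld2$fov, 8)
  expect_equal(fld2$wavelength, 1)
  expect_lt(max(Mod(fld2$samples - fld$samples)) / max(Mod(fld$samples)), 1e-6)
})

test_that("fixtures are deterministic and carry manifests", {
  d1 <- file.path(tempdir(), "fx1")
  d2 <- file.path(tempdir(), "fx2")
  suppressWarnings({
    make_fixture("hologram_32", d1, seed = 1)
    make_fixture("hologram_32", d2, seed = 1)
  })
  f1 <- file.path(d1, "hologram_32.tif")
  f2 <- file.path(d2, "hologram_32.tif")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  man <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(man$seed, 1)
  expect_equal(man$config$scenario, "hologram_32")
  # the hologram fixture matches its stated schedule
  ig <- load_experimental_stack(f1, 2 / 32, 1)
  expect_equal(dim(ig$frames)[3], 32)
  expect_error(make_fixture("no_such_scenario", tempdir()))
})

test_that("radial-pipeline and layer fixtures write their tables", {
  d <- file.path(tempdir(), "fx3")
  make_fixture("radial_pipeline", d)
  tab <- read.csv(file.path(d, "radial_pipeline.csv"))
  expect_true(all(c("q", "far_re", "near_re") %in% names(tab)))
  expect_equal(nrow(tab), 128)
  d4 <- file.path(tempdir(), "fx4")
  make_fixture("equal_opl_layers", d4)
  tab2 <- read.csv(file.path(d4, "equal_opl_layers.csv"))
  expect_lt(abs(tab2$phase_exit_a - tab2$phase_exit_b), 0.05)
})

test_that("the command line dispatches, reports usage, and fails cleanly", {
  expect_equal(cli_dispatch("--help"), 0L)
  expect_output(cli_dispatch(c("simulate-mie", "--help")), "usage")
  expect_equal(suppressMessages(cli_dispatch(c("unknown-cmd"))), 2L)
  # invalid wavelength: nonzero exit, no partial output
  out <- tempfile(fileext = ".tif")
  code <- suppressMessages(cli_dispatch(c("simulate-mie", "--a", "1", "--m", "1.5",
                                          "--kappa", "0.03", "--wavelength-um",
                                          "-1", "--out", out)))
  expect_equal(code, 2L)
  expect_false(file.exists(out))
})

test_that("simulate-hologram then reconstruct works end to end", {
  dir <- file.path(tempdir(), "cli-e2e")
  dir.create(dir, showWarnings = FALSE)
  stack <- file.path(dir, "h.tif")
  rec <- file.path(dir, "es.tif")
  suppressWarnings(suppressMessages({
    c1 <- cli_dispatch(c("simulate-hologram", "--a", "1", "--m", "1.5",
                         "--kappa", "0.03", "--pixels", "32", "--frames", "8",
                         "--out", stack))
    c2 <- cli_dispatch(c("reconstruct", "--stack", stack, "--wavelength-um", "1",
                         "--step-um", "0.25", "--frames", "3", "--out", rec))
  }))
  expect_equal(c1, 0L)
  expect_equal(c2, 0L)
  es <- read_field_tiff(rec)
  ref <- scattered_field_2d(fix_sphere(), 1, 32, 16, "horizontal", total = TRUE)
  ref$samples[ref$mask] <- 0 + 0i
  expect_lt(mean(Mod(es$samples - ref$samples)), 1e-4)
  expect_true(file.exists(file.path(dir, "manifest.json")))
})
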