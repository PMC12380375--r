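#' Deterministic fixture scenarios
#'
#' Generates the named benchmark configurations of the package as on-disk
#' artifacts (fields and hologram stacks as float TIFF with JSON sidecars,
#' tables as CSV) plus a reproducibility manifest. The same scenario and
#' seed always produce byte-identical files.
#'
#' Scenarios:
#' * `sphere_field` -- total field of an a = 1 um sphere, n = 1.5 + 0.03i,
#'   lambda = 1 um, FOV 16 um, 128 px (horizontal plane).
#' * `equal_opl_layers` -- two 3-layer stacks of equal optical path length
#'   (n = 3 + 0.05i, d = 2 um vs n = 1 + 0.05i, d = 6 um, lambda = 1.5 um):
#'   detector-plane fields demonstrating the phase split beyond the stack.
#' * `radial_pipeline` -- radial far field and Hankel near field of an
#'   a = 2 um, m = 1.4, kappa = 0.02 sphere (FOV 32 um grid geometry).
#' * `hologram_32` -- 32-frame phase-stepped hologram of the `sphere_field`
#'   scene, total path difference 2 um.
#' * `training_corpus` -- a reduced single-sphere training corpus
#'   (levels^3 samples; level count via `overrides$levels`, default 5).
#' * `two_spheres` -- two identical a = 1 um, m = 1.5, kappa = 0.01 spheres
#'   at 4 um separation: 2-D field and right-half extraction.
#'
#' @param scenario one of the names above
#' @param dir output directory (created if needed)
#' @param seed RNG seed recorded in the manifest (scenarios are themselves
#'   deterministic)
#' @param overrides named list of scenario-specific overrides
#' @return character vector of written artifact paths (invisibly)
#' @export
make_fixture <- function(scenario = c("sphere_field", "equal_opl_layers",
                                      "radial_pipeline", "hologram_32",
                                      "training_corpus", "two_spheres"),
                         dir, seed = 1, overrides = list()) {
  scenario <- match.arg(scenario)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  files <- character(0)
  cfg <- list(scenario = scenario, overrides = overrides)
  add <- function(f) files <<- c(files, f)

  if (scenario == "sphere_field") {
    sph <- mie_sphere(1, 1.5 + 0.03i)
    fld <- scattered_field_2d(sph, 1, 128, 16, "horizontal", total = TRUE)
    add(write_field_tiff(fld, file.path(dir, "sphere_field.tif")))
  } else if (scenario == "equal_opl_layers") {
    lam <- 1.5
    mk <- function(n_mid, d) {
      stk <- layer_stack(c(1, n_mid, 1), c(0, d))
      solve_layered(stk, plane_wave(1 + 0i, lam))
    }
    za <- seq(2.001, 8, length.out = 200)
    zb <- seq(6.001, 8, length.out = 200)
    sa <- mk(3 + 0.05i, 2)
    sb <- mk(1 + 0.05i, 6)
    tab <- data.frame(
      z = 8,
      phase_exit_a = Arg(field_at(sa, 0, 0, 2.0000001)[1]),
      phase_exit_b = Arg(field_at(sb, 0, 0, 6.0000001)[1]),
      phase_det_a = Arg(field_at(sa, 0, 0, 8)[1]),
      phase_det_b = Arg(field_at(sb, 0, 0, 8)[1]))
    f <- file.path(dir, "equal_opl_layers.csv")
    write.csv(tab, f, row.names = FALSE)
    add(f)
  } else if (scenario == "radial_pipeline") {
    sph <- mie_sphere(2, 1.4 + 0.02i)
    ff <- far_field_radial(sph, 1, 128, q_max = 4)
    nf <- inverse_hankel(ff)
    f <- file.path(dir, "radial_pipeline.csv")
    write.csv(data.frame(q = ff$r, far_re = Re(ff$samples),
                         far_im = Im(ff$samples), r = nf$r,
                         near_re = Re(nf$samples), near_im = Im(nf$samples)),
              f, row.names = FALSE)
    add(f)
  } else if (scenario == "hologram_32") {
    sph <- mie_sphere(1, 1.5 + 0.03i)
    fld <- scattered_field_2d(sph, 1, 128, 16, "horizontal", total = TRUE)
    s <- fld$samples
    s[fld$mask] <- 0 + 0i
    ig <- simulate_interferogram(s, 1 + 0i, deltas = (0:31) * (2 / 32),
                                 wavelength = 1)
    add(write_interferogram_tiff(ig, file.path(dir, "hologram_32.tif")))
    add(file.path(dir, "hologram_32.tif.json"))
  } else if (scenario == "training_corpus") {
    levels <- if (!is.null(overrides$levels)) overrides$levels else 5
    ds <- generate_mie_dataset(levels)
    f <- file.path(dir, "training_corpus.rds")
    saveRDS(ds, f)
    add(f)
    cfg$levels <- levels
  } else if (scenario == "two_spheres") {
    sep <- if (!is.null(overrides$separation)) overrides$separation else 4
    sph <- mie_sphere(1, 1.5 + 0.01i)
    ts <- two_sphere_field(sph, sph, sep, 1, 128, 16)
    add(write_field_tiff(ts$field, file.path(dir, "two_spheres.tif")))
    f <- file.path(dir, "two_spheres_half_line.csv")
    write.csv(data.frame(r = ts$half_line$r, re = Re(ts$half_line$samples),
                         im = Im(ts$half_line$samples)), f, row.names = FALSE)
    add(f)
    cfg$separation <- sep
  }
  write_manifest(dir, cfg, seed, files)
  invisible(files)
}
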