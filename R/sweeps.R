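# ---- sweep corpora ---------------------------------------------------------
# Each sweep enlarges the factorial label grid by a fourth per-sample
# feature (noise level %, numerical aperture, or sphere separation um),
# which is appended to the network inputs.

.sweep_labels <- function(levels_per_feature, ranges) {
  lv <- function(r) seq(r[1], r[2], length.out = levels_per_feature)
  expand.grid(a = lv(ranges$a), m = lv(ranges$m), kappa = lv(ranges$kappa))
}

#' Gaussian-noise sweep corpus
#'
#' Replicates the clean factorial corpus across `n_levels` noise levels
#' spanning `noise_range` (percent). A level of x% adds zero-mean Gaussian
#' noise of standard deviation sigma = (x/100) * RMS(|E|) -- the RMS of the
#' sample's clean complex magnitude over the radial grid, which is ~1 for
#' the unit incident field -- drawn independently for the real and imaginary
#' channels from the same distribution. The level is the sample's sweep
#' feature.
#'
#' @param levels_per_feature factorial levels per label
#' @param n_levels number of noise levels
#' @param noise_range range of noise levels in percent
#' @param ranges,wavelength,n_radial,fov corpus geometry as in
#'   [generate_mie_dataset()]
#' @param seed RNG seed for the noise draws
#' @return a complex `mie_dataset` with `sweep_kind = "noise"`
#' @export
noise_sweep_corpus <- function(levels_per_feature = 10, n_levels = 100,
                               noise_range = c(1, 100),
                               ranges = list(a = c(1, 2), m = c(1.1, 2.0),
                                             kappa = c(0.01, 0.05)),
                               wavelength = 1, n_radial = 320, fov = 16,
                               seed = 1) {
  base <- generate_mie_dataset(levels_per_feature, ranges, wavelength,
                               n_radial, fov)
  nl <- nrow(base$labels)
  lvls <- seq(noise_range[1], noise_range[2], length.out = n_levels)
  l <- n_radial
  re <- base$inputs[, 1:l, drop = FALSE]
  im <- base$inputs[, (l + 1):(2 * l), drop = FALSE]
  rms <- sqrt(rowMeans(re^2 + im^2))
  set.seed(seed)
  inputs <- matrix(0, nl * n_levels, 2 * l)
  sweep_feature <- numeric(nl * n_levels)
  for (j in seq_along(lvls)) {
    sg <- lvls[j] / 100 * rms
    rows <- (j - 1) * nl + seq_len(nl)
    inputs[rows, 1:l] <- re + matrix(rnorm(nl * l), nl, l) * sg
    inputs[rows, (l + 1):(2 * l)] <- im + matrix(rnorm(nl * l), nl, l) * sg
    sweep_feature[rows] <- lvls[j]
  }
  .mie_dataset(inputs, base$labels[rep(seq_len(nl), n_levels), ], "complex",
               base$domain, base$radii, wavelength, ranges,
               sweep_feature = sweep_feature, sweep_kind = "noise")
}

#' Aperture-bandpass sweep corpus
#'
#' Band-limits every sample's far-field profile to the passband of an
#' objective with outer numerical aperture NA (inner aperture 0) before the
#' inverse Hankel transform to the spatial representation; the NA is the
#' sweep feature. An NA too small to pass any frequency sample is clamped to
#' the first sample (with a message).
#'
#' @param n_nas number of numerical apertures
#' @param na_range NA range (the upper end slightly above 1 passes the whole
#'   propagating band)
#' @inheritParams noise_sweep_corpus
#' @return a complex `mie_dataset` with `sweep_kind = "bandpass"`
#' @export
bandpass_sweep_corpus <- function(levels_per_feature = 10, n_nas = 100,
                                  na_range = c(0.02, 1.01),
                                  ranges = list(a = c(1, 2), m = c(1.1, 2.0),
                                                kappa = c(0.01, 0.05)),
                                  wavelength = 1, n_radial = 320, fov = 16) {
  labels <- .sweep_labels(levels_per_feature, ranges)
  geom <- .dataset_geometry(n_radial, wavelength, fov)
  ff <- .corpus_far_fields(labels, geom)
  nl <- nrow(labels)
  nas <- seq(na_range[1], na_range[2], length.out = n_nas)
  inputs <- matrix(0, nl * n_nas, 2 * n_radial)
  sweep_feature <- numeric(nl * n_nas)
  clamped <- 0L
  for (j in seq_along(nas)) {
    fu <- nas[j] / wavelength
    keep <- geom$plan$q <= fu
    if (!any(keep)) {
      keep[1] <- TRUE
      clamped <- clamped + 1L
    }
    nf <- geom$smat %*% (geom$plan$to_spatial %*% (ff * keep)) + 1
    rows <- (j - 1) * nl + seq_len(nl)
    inputs[rows, ] <- cbind(t(Re(nf)), t(Im(nf)))
    sweep_feature[rows] <- nas[j]
  }
  if (clamped > 0)
    message(sprintf("%d aperture(s) below the first frequency sample were clamped", clamped))
  .mie_dataset(inputs, labels[rep(seq_len(nl), n_nas), ], "complex",
               "spatial", geom$radii, wavelength, ranges,
               sweep_feature = sweep_feature, sweep_kind = "bandpass")
}

#' Two-sphere structured-noise sweep corpus
#'
#' Adds a second sphere of the same material at `n_distances` centre
#' separations (um, largest to contact); the structured perturbation is the
#' interference between the two scattered fields. Inputs are the right-half
#' radial extraction through the central sphere,
#' E(r) = 1 + f(r) + f(r + separation); the separation is the sweep feature.
#' Label rows whose sphere radius would overlap at a given separation
#' (separation < 2a) are dropped (with a message).
#'
#' @param n_distances number of separations
#' @param sep_range separation range in um
#' @inheritParams noise_sweep_corpus
#' @return a complex `mie_dataset` with `sweep_kind = "two_sphere"`
#' @export
two_sphere_sweep_corpus <- function(levels_per_feature = 10, n_distances = 100,
                                    sep_range = c(2, 8),
                                    ranges = list(a = c(1, 2), m = c(1.1, 2.0),
                                                  kappa = c(0.01, 0.05)),
                                    wavelength = 1, n_radial = 320, fov = 16) {
  labels <- .sweep_labels(levels_per_feature, ranges)
  geom <- .dataset_geometry(n_radial, wavelength, fov)
  ff <- .corpus_far_fields(labels, geom)
  nf0 <- geom$plan$to_spatial %*% ff       # scattered profile on the plan grid
  base <- geom$smat %*% nf0                # f(r) on the uniform grid
  nl <- nrow(labels)
  seps <- seq(sep_range[2], sep_range[1], length.out = n_distances)
  blocks <- vector("list", length(seps))
  dropped <- 0L
  for (j in seq_along(seps)) {
    smat_off <- .spline_matrix(geom$plan$r, geom$radii + seps[j])
    beyond <- geom$radii + seps[j] > geom$plan$r_max
    smat_off[beyond, ] <- 0
    tot <- 1 + base + smat_off %*% nf0
    ok <- labels$a * 2 <= seps[j]
    dropped <- dropped + sum(!ok)
    blocks[[j]] <- list(inputs = cbind(t(Re(tot))[ok, , drop = FALSE],
                                       t(Im(tot))[ok, , drop = FALSE]),
                        labels = labels[ok, , drop = FALSE],
                        sweep = rep(seps[j], sum(ok)))
  }
  if (dropped > 0)
    message(sprintf("%d overlapping sphere configurations skipped", dropped))
  .mie_dataset(do.call(rbind, lapply(blocks, `[[`, "inputs")),
               do.call(rbind, lapply(blocks, `[[`, "labels")),
               "complex", "spatial", geom$radii, wavelength, ranges,
               sweep_feature = unlist(lapply(blocks, `[[`, "sweep")),
               sweep_kind = "two_sphere")
}

# ---- paired training / per-bin evaluation ---------------------------------

# stratified-by-sweep-value shuffle/split so every sweep bin keeps its 9:1
# test share even in scaled-down corpora
.stratified_split <- function(ds, test_fraction, validation_fraction, seed) {
  set.seed(seed)
  n <- nrow(ds$inputs)
  test <- integer(0)
  for (v in unique(ds$sweep_feature)) {
    rows <- which(ds$sweep_feature == v)
    rows <- rows[sample.int(length(rows))]
    test <- c(test, rows[seq_len(max(1, floor(length(rows) * test_fraction)))])
  }
  pool <- setdiff(sample.int(n), test)
  n_val <- floor(length(pool) * validation_fraction)
  list(train = .dataset_subset(ds, pool[-seq_len(n_val)]),
       validation = .dataset_subset(ds, pool[seq_len(n_val)]),
       test = .dataset_subset(ds, test))
}

#' Paired complex/intensity robustness sweep
#'
#' Trains the shallow network once per representation on a sweep corpus
#' (sweep value as the fourth feature) and evaluates the per-label relative
#' RMSE separately at every sweep value on the held-out test share of that
#' value, averaged over `seeds`. The split is stratified by sweep value.
#'
#' @param corpus a complex sweep `mie_dataset` (from one of the
#'   `*_sweep_corpus()` builders)
#' @param config a [train_config()]
#' @param seeds trial seeds
#' @param metric error reading, see [relative_rmse()]
#' @return a `sweep_report`: data frame with one row per sweep value,
#'   per-label complex and intensity errors (%, averaged over seeds)
#' @export
run_sweep <- function(corpus, config = train_config(), seeds = 1,
                      metric = "relative") {
  if (is.null(corpus$sweep_feature)) .stopf("corpus carries no sweep feature")
  ds_i <- to_intensity(corpus)
  vals <- sort(unique(corpus$sweep_feature))
  acc <- array(0, dim = c(length(vals), 3, 2),
               dimnames = list(NULL, colnames(corpus$labels),
                               c("complex", "intensity")))
  for (sd in seeds) {
    cfg <- config
    cfg$seed <- as.integer(sd)
    for (rep in c("complex", "intensity")) {
      ds <- if (rep == "complex") corpus else ds_i
      sp <- .stratified_split(ds, config$test_fraction,
                              config$validation_fraction, seed = sd)
      model <- train_mie_ann(sp$train, sp$validation, cfg)
      yp <- predict_labels(model, sp$test)
      for (vi in seq_along(vals)) {
        rows <- which(sp$test$sweep_feature == vals[vi])
        acc[vi, , rep] <- acc[vi, , rep] +
          relative_rmse(yp[rows, , drop = FALSE],
                        sp$test$labels[rows, , drop = FALSE], metric)
      }
    }
  }
  acc <- acc / length(seeds)
  rep_df <- data.frame(sweep = vals,
                       complex_a = acc[, "a", "complex"],
                       complex_m = acc[, "m", "complex"],
                       complex_kappa = acc[, "kappa", "complex"],
                       intensity_a = acc[, "a", "intensity"],
                       intensity_m = acc[, "m", "intensity"],
                       intensity_kappa = acc[, "kappa", "intensity"])
  structure(list(report = rep_df, kind = corpus$sweep_kind, seeds = seeds,
                 metric = metric),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("<sweep_report> %s, %d sweep values, %d seed(s)\n",
              x$kind, nrow(x$report), length(x$seeds)))
  agg_c <- rowMeans(x$report[, c("complex_a", "complex_m", "complex_kappa")])
  agg_i <- rowMeans(x$report[, c("intensity_a", "intensity_m", "intensity_kappa")])
  cat(sprintf("  complex <= intensity (label-mean) at %d / %d sweep points\n",
              sum(agg_c <= agg_i), nrow(x$report)))
  invisible(x)
}

#' Gaussian-noise robustness sweep
#'
#' @inheritParams noise_sweep_corpus
#' @inheritParams run_sweep
#' @param ... passed to [noise_sweep_corpus()]
#' @return a `sweep_report`, see [run_sweep()]
#' @export
noise_sweep <- function(levels_per_feature = 10, n_levels = 100,
                        config = train_config(), seeds = 1, ...) {
  run_sweep(noise_sweep_corpus(levels_per_feature, n_levels, ...),
            config, seeds)
}

#' Aperture-bandpass robustness sweep
#'
#' @inheritParams bandpass_sweep_corpus
#' @inheritParams run_sweep
#' @param ... passed to [bandpass_sweep_corpus()]
#' @return a `sweep_report`, see [run_sweep()]
#' @export
bandpass_sweep <- function(levels_per_feature = 10, n_nas = 100,
                           config = train_config(), seeds = 1, ...) {
  run_sweep(bandpass_sweep_corpus(levels_per_feature, n_nas, ...),
            config, seeds)
}

#' Two-sphere structured-noise robustness sweep
#'
#' @inheritParams two_sphere_sweep_corpus
#' @inheritParams run_sweep
#' @param ... passed to [two_sphere_sweep_corpus()]
#' @return a `sweep_report`, see [run_sweep()]
#' @export
two_sphere_sweep <- function(levels_per_feature = 10, n_distances = 100,
                             config = train_config(), seeds = 1, ...) {
  run_sweep(two_sphere_sweep_corpus(levels_per_feature, n_distances, ...),
            config, seeds)
}
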