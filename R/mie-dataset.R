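# cached geometry shared by corpus builders: Hankel plan, spline resampling
# matrix onto the uniform radial grid, Legendre basis at the plan's angular
# samples
.chemholo_cache <- new.env(parent = emptyenv())

# cubic-spline interpolation is linear in the data, so resampling from the
# Bessel-zero grid to the uniform grid is one matrix product
.spline_matrix <- function(x_from, x_to) {
  n <- length(x_from)
  s <- matrix(0, length(x_to), n)
  for (j in seq_len(n)) {
    e <- numeric(n)
    e[j] <- 1
    s[, j] <- spline(x_from, e, xout = x_to, method = "fmm")$y
  }
  s
}

.dataset_geometry <- function(n_radial, wavelength, fov, q_max = 2.5 / wavelength) {
  key <- sprintf("geom_%d_%g_%g_%g", n_radial, wavelength, fov, q_max)
  if (!is.null(.chemholo_cache[[key]])) return(.chemholo_cache[[key]])
  plan <- hankel_plan(n_radial, q_max)
  radii <- seq(0, fov / 2, length.out = n_radial)
  smat <- .spline_matrix(plan$r, radii)
  mu <- sqrt(pmax(1 - (wavelength * plan$q)^2, 0))
  inband <- (wavelength * plan$q) <= 1
  geom <- list(plan = plan, radii = radii, smat = smat, mu = mu,
               inband = inband, wavelength = wavelength, fov = fov)
  .chemholo_cache[[key]] <- geom
  geom
}

# far-field profiles for all label rows: L x n complex matrix on the plan grid
.corpus_far_fields <- function(labels, geom) {
  labels <- as.data.frame(labels)
  nmax <- .mie_nmax(2 * pi * max(labels$a) / geom$wavelength)
  B <- .mie_B_mat(labels$a, complex(real = labels$m, imaginary = labels$kappa),
                  geom$wavelength, nmax)
  p <- .legendre_mat(geom$mu, nmax)
  k <- 2 * pi / geom$wavelength
  (p %*% (B * (-1i)^(0:nmax))) * (geom$mu * geom$inband) / (1i * k)
}

.mie_dataset <- function(inputs, labels, representation, domain, radii,
                         wavelength, ranges, sweep_feature = NULL,
                         sweep_kind = NULL) {
  structure(list(inputs = inputs, labels = as.matrix(labels),
                 representation = representation, domain = domain,
                 radii = radii, wavelength = wavelength, ranges = ranges,
                 sweep_feature = sweep_feature, sweep_kind = sweep_kind),
            class = "mie_dataset")
}

#' @export
print.mie_dataset <- function(x, ...) {
  cat(sprintf("<mie_dataset> %d samples x %d radial points (%s, %s domain)%s\n",
              nrow(x$inputs), length(x$radii), x$representation, x$domain,
              if (is.null(x$sweep_feature)) ""
              else sprintf(", sweep '%s' (%d values)", x$sweep_kind,
                           length(unique(x$sweep_feature)))))
  invisible(x)
}

#' Simulated single-sphere corpus for the inverse Mie problem
#'
#' Builds the factorial training corpus: `levels_per_feature` uniformly
#' spaced values per label over the given ranges (radius a in um, real index
#' m, extinction coefficient kappa), `levels^3` spheres in total, each
#' represented by its 1-D field at `n_radial` points. The default (spatial)
#' representation is the total field -- incident DC term plus the
#' band-limited scattered near field obtained by the order-0 inverse discrete
#' Hankel transform -- resampled on a uniform radial grid spanning half the
#' field of view; `domain = "reciprocal"` keeps the far-field profile on the
#' transform's Bessel-zero grid instead. Channels are the real and imaginary
#' parts; inputs are stored as an n x (2 * n_radial) matrix, first all real
#' then all imaginary columns. Generation is a pure function of the labels
#' and geometry.
#'
#' @param levels_per_feature grid levels per label (>= 2)
#' @param ranges list with elements `a`, `m`, `kappa`, each c(min, max);
#'   m must stay > 1
#' @param wavelength wavelength in um
#' @param n_radial radial points per sample
#' @param fov field of view in um (spatial representation spans fov/2)
#' @param domain `"spatial"` or `"reciprocal"`
#' @return a `mie_dataset` with `representation = "complex"`
#' @export
generate_mie_dataset <- function(levels_per_feature = 30,
                                 ranges = list(a = c(1, 2), m = c(1.1, 2.0),
                                               kappa = c(0.01, 0.05)),
                                 wavelength = 1, n_radial = 320, fov = 16,
                                 domain = c("spatial", "reciprocal")) {
  domain <- match.arg(domain)
  if (levels_per_feature < 2) .stopf("need at least 2 levels per feature")
  if (ranges$m[1] <= 1) .stopf("model validity requires m > 1")
  if (ranges$a[1] <= 0 || ranges$kappa[1] < 0) .stopf("invalid label ranges")
  lv <- function(r) seq(r[1], r[2], length.out = levels_per_feature)
  labels <- expand.grid(a = lv(ranges$a), m = lv(ranges$m),
                        kappa = lv(ranges$kappa))
  geom <- .dataset_geometry(n_radial, wavelength, fov)
  ff <- .corpus_far_fields(labels, geom)
  if (domain == "spatial") {
    field <- geom$smat %*% (geom$plan$to_spatial %*% ff) + 1  # + incident DC
    radii <- geom$radii
  } else {
    field <- ff
    radii <- geom$plan$q
  }
  inputs <- cbind(t(Re(field)), t(Im(field)))
  .mie_dataset(inputs, labels, "complex", domain, radii, wavelength, ranges)
}

#' Convert a complex dataset to its square-root-intensity representation
#'
#' Replaces the two field channels by a single magnitude channel
#' sqrt(Re^2 + Im^2) (the square root of the measured intensity regularizes
#' the numeric range), zeroing the second channel so both representations
#' share one network architecture. A global phase rotation of a complex
#' sample leaves its intensity representation unchanged -- exactly the
#' information discarded by phase-blind measurements.
#'
#' @param ds a complex `mie_dataset`
#' @return the intensity `mie_dataset`
#' @export
to_intensity <- function(ds) {
  if (!inherits(ds, "mie_dataset")) .stopf("ds must be a mie_dataset")
  if (ds$representation != "complex")
    .stopf("to_intensity expects a complex dataset (got '%s')", ds$representation)
  l <- length(ds$radii)
  extra <- if (ncol(ds$inputs) > 2 * l) ds$inputs[, -(1:(2 * l)), drop = FALSE] else NULL
  re <- ds$inputs[, 1:l, drop = FALSE]
  im <- ds$inputs[, (l + 1):(2 * l), drop = FALSE]
  inputs <- cbind(sqrt(re^2 + im^2), matrix(0, nrow(ds$inputs), l))
  if (!is.null(extra)) inputs <- cbind(inputs, extra)
  out <- ds
  out$inputs <- inputs
  out$representation <- "intensity"
  out
}

.dataset_subset <- function(ds, idx) {
  out <- ds
  out$inputs <- ds$inputs[idx, , drop = FALSE]
  out$labels <- ds$labels[idx, , drop = FALSE]
  if (!is.null(ds$sweep_feature)) out$sweep_feature <- ds$sweep_feature[idx]
  out
}

#' Shuffle and split a dataset into train / validation / test
#'
#' The corpus is shuffled and split 9:1 into a training pool and test set
#' (by default), and 20% of the pool is held out for validation: 27,000
#' samples yield 19,440 / 4,860 / 2,700. Floor rounding; the three parts are
#' a disjoint cover of the corpus.
#'
#' @param ds a `mie_dataset`
#' @param test_fraction fraction held out for the final test
#' @param validation_fraction fraction of the remaining pool held out for
#'   validation
#' @param seed RNG seed for the shuffle
#' @return list with datasets `train`, `validation`, `test` and the index
#'   vectors in `$index`
#' @export
split_dataset <- function(ds, test_fraction = 1 / 10,
                          validation_fraction = 1 / 5, seed = 1) {
  if (test_fraction <= 0 || test_fraction >= 1 ||
      validation_fraction <= 0 || validation_fraction >= 1)
    .stopf("fractions must lie in (0, 1)")
  n <- nrow(ds$inputs)
  set.seed(seed)
  idx <- sample.int(n)
  n_test <- floor(n * test_fraction)
  test <- idx[seq_len(n_test)]
  pool <- idx[-seq_len(n_test)]
  n_val <- floor(length(pool) * validation_fraction)
  val <- pool[seq_len(n_val)]
  train <- pool[-seq_len(n_val)]
  list(train = .dataset_subset(ds, train),
       validation = .dataset_subset(ds, val),
       test = .dataset_subset(ds, test),
       index = list(train = train, validation = val, test = test))
}

# input matrix of a dataset, with the sweep feature (if any) appended
.dataset_x <- function(ds) {
  if (is.null(ds$sweep_feature)) ds$inputs
  else cbind(ds$inputs, sweep = ds$sweep_feature)
}

#' Train the inverse-Mie network on a dataset split
#'
#' Fits the dense tanh network to regress (a, m, kappa) from the 1-D field
#' representation. The kappa label is min-max scaled into \[1, 2\] on the
#' training labels (bringing it to the numeric range of a and m) and the
#' scaling is inverted at prediction time. A sweep feature, when present, is
#' appended to the inputs as one extra column.
#'
#' @param train_ds,val_ds training and validation `mie_dataset`s (same
#'   representation)
#' @param config a [train_config()]
#' @return a trained [ann_model()] carrying the label scaling
#' @export
train_mie_ann <- function(train_ds, val_ds, config = train_config()) {
  if (train_ds$representation != val_ds$representation)
    .stopf("train and validation representations differ")
  x <- .dataset_x(train_ds)
  xv <- .dataset_x(val_ds)
  y <- train_ds$labels
  yv <- val_ds$labels
  lbl <- list(scaled = FALSE)
  if (config$kappa_scaling) {
    lo <- min(y[, "kappa"]); hi <- max(y[, "kappa"])
    if (hi > lo) {
      y[, "kappa"] <- 1 + (y[, "kappa"] - lo) / (hi - lo)
      yv[, "kappa"] <- 1 + (yv[, "kappa"] - lo) / (hi - lo)
      lbl <- list(scaled = TRUE, lo = lo, hi = hi)
    }
  }
  model <- ann_train(x, y, xv, yv, config)
  model$label_scale <- lbl
  model$label_names <- colnames(train_ds$labels)
  model$representation <- train_ds$representation
  model
}

#' Predict sphere labels for a dataset
#'
#' @param model a model from [train_mie_ann()]
#' @param ds a `mie_dataset` with the model's representation
#' @return n x 3 matrix of predicted (a, m, kappa) on the physical scale
#' @export
predict_labels <- function(model, ds) {
  if (!is.null(model$representation) && model$representation != ds$representation)
    .stopf("model was trained on %s inputs, dataset is %s",
           model$representation, ds$representation)
  yp <- ann_predict(model, .dataset_x(ds))
  colnames(yp) <- model$label_names
  if (isTRUE(model$label_scale$scaled)) {
    yp[, "kappa"] <- (yp[, "kappa"] - 1) *
      (model$label_scale$hi - model$label_scale$lo) + model$label_scale$lo
  }
  yp
}

#' Relative root-mean-square error per label
#'
#' The error metric of the study, reported in percent. The default reading
#' normalizes each error by its true value before averaging:
#' eps_R = 100 * sqrt(mean(((pred - true) / true)^2)). The `"as_printed"`
#' variant follows the typeset formula literally, dividing the squared error
#' by the true value once: 100 * sqrt(mean((pred - true)^2 / true)); its
#' units are inconsistent and it is provided for comparison only. Zero true
#' labels are excluded with a warning.
#'
#' @param pred,truth n x q matrices
#' @param metric `"relative"` or `"as_printed"`
#' @return named vector of per-column errors in percent
#' @export
relative_rmse <- function(pred, truth, metric = c("relative", "as_printed")) {
  metric <- match.arg(metric)
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  out <- vapply(seq_len(ncol(truth)), function(j) {
    t <- truth[, j]; p <- pred[, j]
    keep <- t != 0
    if (!all(keep)) warning("zero true labels excluded from relative RMSE")
    t <- t[keep]; p <- p[keep]
    if (metric == "relative") 100 * sqrt(mean(((p - t) / t)^2))
    else 100 * sqrt(mean((p - t)^2 / t))
  }, numeric(1))
  names(out) <- colnames(truth)
  out
}

#' Evaluate a trained model on a test dataset
#'
#' @param model a model from [train_mie_ann()]
#' @param test_ds held-out `mie_dataset`
#' @param metric error reading, see [relative_rmse()]
#' @return an `eval_report`: per-label `eps_r` (%), `n_test`, `metric`
#' @export
evaluate_mie_ann <- function(model, test_ds, metric = "relative") {
  yp <- predict_labels(model, test_ds)
  eps <- relative_rmse(yp, test_ds$labels, metric)
  structure(list(eps_r = eps, n_test = nrow(test_ds$labels), metric = metric),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n = %d (%s): %s\n", x$n_test, x$metric,
              paste(sprintf("%s = %.2f%%", names(x$eps_r), x$eps_r),
                    collapse = ", ")))
  invisible(x)
}

#' Paired complex/intensity benchmark of the shallow inverse-Mie network
#'
#' Runs the full protocol: generate the factorial corpus, derive the
#' square-root-intensity twin, and for each seed shuffle/split 9:1 with a
#' 20% validation holdout, train the `hidden`-unit network for both
#' representations on identical splits, and evaluate the per-label relative
#' RMSE on the held-out test set. Returns per-seed errors and their means.
#'
#' @param levels_per_feature factorial levels per label (30 reproduces the
#'   27,000-sample corpus)
#' @param seeds integer vector of trial seeds (split, init and shuffling)
#' @param config a [train_config()]
#' @param wavelength,n_radial,fov corpus geometry
#' @param metric error reading, see [relative_rmse()]
#' @param verbose print one line per trained model
#' @return list with matrices `complex` and `intensity` (rows = seeds,
#'   columns = labels), their column `means`, and the settings
#' @export
mie_ann_benchmark <- function(levels_per_feature = 30, seeds = 1:10,
                              config = train_config(), wavelength = 1,
                              n_radial = 320, fov = 16, metric = "relative",
                              verbose = FALSE) {
  ds_c <- generate_mie_dataset(levels_per_feature, wavelength = wavelength,
                               n_radial = n_radial, fov = fov)
  ds_i <- to_intensity(ds_c)
  res <- list(complex = NULL, intensity = NULL)
  for (sd in seeds) {
    cfg <- config
    cfg$seed <- as.integer(sd)
    for (rep in c("complex", "intensity")) {
      ds <- if (rep == "complex") ds_c else ds_i
      sp <- split_dataset(ds, config$test_fraction, config$validation_fraction,
                          seed = sd)
      model <- train_mie_ann(sp$train, sp$validation, cfg)
      ev <- evaluate_mie_ann(model, sp$test, metric)
      if (verbose)
        message(sprintf("seed %d %-9s: %s", sd, rep,
                        paste(sprintf("%s %.2f%%", names(ev$eps_r), ev$eps_r),
                              collapse = " ")))
      res[[rep]] <- rbind(res[[rep]], ev$eps_r)
    }
  }
  rownames(res$complex) <- rownames(res$intensity) <- paste0("seed", seeds)
  list(complex = res$complex, intensity = res$intensity,
       means = list(complex = colMeans(res$complex),
                    intensity = colMeans(res$intensity)),
       seeds = seeds, levels_per_feature = levels_per_feature, metric = metric)
}
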