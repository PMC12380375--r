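#' Training configuration for the inverse-Mie network
#'
#' Defaults follow the study protocol: 400 epochs at batch size 200, a 9:1
#' train/test split with a further 20% validation holdout, and feature
#' scaling of the extinction-coefficient label. The optimizer is
#' adaptive-moment gradient descent (step 1e-3, reduced x0.3 from epoch 300);
#' inputs are standardized per feature on the training split and validation
#' MSE is checked every 5 epochs with best-weights selection.
#'
#' @param epochs training epochs
#' @param batch minibatch size
#' @param learning_rate Adam step size
#' @param decay_epoch epoch from which the step size is multiplied by
#'   `decay_factor` (0 disables)
#' @param decay_factor multiplicative step reduction
#' @param test_fraction held-out test fraction of the corpus
#' @param validation_fraction validation fraction of the training part
#' @param hidden hidden-layer widths (single number for the shallow net;
#'   a vector such as `c(64, 64, 64)` for deeper presets)
#' @param kappa_scaling scale the kappa label into the numeric range of the
#'   other labels (min-max to \[1, 2\], fitted on training labels)
#' @param standardize z-score the inputs per feature (fitted on training)
#' @param val_every epochs between validation checks
#' @param double_precision run the update loop in double precision (default)
#'   rather than single
#' @param seed base RNG seed for initialization and shuffling
#' @return list of class `train_config`
#' @export
train_config <- function(epochs = 400, batch = 200, learning_rate = 1e-3,
                         decay_epoch = 300, decay_factor = 0.3,
                         test_fraction = 1 / 10, validation_fraction = 1 / 5,
                         hidden = 5, kappa_scaling = TRUE, standardize = TRUE,
                         val_every = 5, double_precision = TRUE, seed = 1) {
  if (epochs < 1 || batch < 1) .stopf("epochs and batch must be positive")
  if (test_fraction <= 0 || test_fraction >= 1 ||
      validation_fraction <= 0 || validation_fraction >= 1)
    .stopf("fractions must lie in (0, 1)")
  structure(list(epochs = as.integer(epochs), batch = as.integer(batch),
                 learning_rate = learning_rate, decay_epoch = as.integer(decay_epoch),
                 decay_factor = decay_factor, test_fraction = test_fraction,
                 validation_fraction = validation_fraction, hidden = hidden,
                 kappa_scaling = kappa_scaling, standardize = standardize,
                 val_every = as.integer(val_every),
                 double_precision = double_precision, seed = as.integer(seed)),
            class = "train_config")
}

#' Initialize a dense tanh regression network
#'
#' Weights are drawn from the Glorot normal distribution, zero mean and
#' standard deviation sqrt(2 / (N_in + N_out)) per layer (the fan counts of
#' that layer's weight matrix); biases start at zero. Hidden activations are
#' hyperbolic tangent, the output is linear.
#'
#' @param layer_sizes integer vector: input width, hidden widths, output
#'   width (e.g. `c(640, 5, 3)` for the shallow inverse-Mie net)
#' @param seed RNG seed for the draw
#' @return an object of class `ann_model`
#' @export
ann_model <- function(layer_sizes, seed = 1) {
  if (length(layer_sizes) < 2) .stopf("need at least input and output sizes")
  set.seed(seed)
  nl <- length(layer_sizes) - 1
  W <- vector("list", nl)
  b <- vector("list", nl)
  for (l in seq_len(nl)) {
    fi <- layer_sizes[l]
    fo <- layer_sizes[l + 1]
    W[[l]] <- matrix(rnorm(fi * fo, 0, sqrt(2 / (fi + fo))), fi, fo)
    b[[l]] <- rep(0, fo)
  }
  structure(list(W = W, b = b, layer_sizes = as.integer(layer_sizes),
                 x_center = NULL, x_scale = NULL, label_scale = NULL,
                 seed = seed),
            class = "ann_model")
}

#' @export
print.ann_model <- function(x, ...) {
  cat(sprintf("<ann_model> %s (tanh hidden, linear output)%s\n",
              paste(x$layer_sizes, collapse = " -> "),
              if (is.null(x$x_center)) " [untrained]" else ""))
  invisible(x)
}

#' Train a dense network by minibatch Adam
#'
#' Runs the seeded minibatch loop (compiled): per-epoch reshuffled batches,
#' adaptive-moment updates, optional step decay, and periodic validation
#' with best-weights selection. Inputs are standardized per feature using
#' training-set statistics when the configuration asks for it; constant
#' features keep unit scale.
#'
#' @param x training inputs, n x p numeric matrix
#' @param y training labels, n x q numeric matrix
#' @param x_val,y_val validation split, same widths
#' @param config a [train_config()]
#' @param model optional pre-initialized [ann_model()]; by default a fresh
#'   Glorot init of sizes `c(p, config$hidden, q)` with `config$seed`
#' @return the trained `ann_model` with training history in `$history`
#' @export
ann_train <- function(x, y, x_val, y_val, config = train_config(), model = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  x_val <- as.matrix(x_val); y_val <- as.matrix(y_val)
  if (nrow(x) != nrow(y)) .stopf("x and y row counts differ")
  if (is.null(model))
    model <- ann_model(c(ncol(x), config$hidden, ncol(y)), seed = config$seed)
  if (config$standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl < 1e-12] <- 1
  } else {
    ctr <- rep(0, ncol(x))
    scl <- rep(1, ncol(x))
  }
  xs <- t(sweep(sweep(x, 2, ctr), 2, scl, "/"))      # features x n
  xvs <- t(sweep(sweep(x_val, 2, ctr), 2, scl, "/"))
  out <- .ann_train_cpp(xs, t(y), xvs, t(y_val), model$W, model$b,
                        config$epochs, config$batch, config$learning_rate,
                        config$decay_epoch, config$decay_factor,
                        config$val_every, config$seed + 104729L,
                        isTRUE(config$double_precision))
  model$W <- out$W
  model$b <- out$b
  model$x_center <- ctr
  model$x_scale <- scl
  model$history <- list(loss = out$loss, best_val = out$best_val)
  model
}

#' Predict with a trained network
#'
#' @param model a trained [ann_model()]
#' @param x inputs, n x p matrix
#' @return n x q matrix of predictions
#' @export
ann_predict <- function(model, x) {
  x <- as.matrix(x)
  if (!is.null(model$x_center))
    x <- sweep(sweep(x, 2, model$x_center), 2, model$x_scale, "/")
  a <- x
  nl <- length(model$W)
  for (l in seq_len(nl)) {
    a <- a %*% model$W[[l]]
    a <- sweep(a, 2, model$b[[l]], "+")
    if (l < nl) a <- tanh(a)
  }
  a
}
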