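#' Phase-stepped interferogram
#'
#' A stack of M intensity frames recorded while the reference-arm optical
#' path offset steps through Delta_1 .. Delta_M in uniform increments delta.
#' Per pixel and offset the recorded intensity is
#' I(m) = |ES|^2 + |ER|^2 + ES ER* e^(-ik Delta_m) + ES* ER e^(+ik Delta_m),
#' a sinusoid in Delta with period lambda.
#'
#' @param frames numeric array R1 x R2 x M (or list of M matrices) of
#'   nonnegative intensities
#' @param deltas reference-arm offsets Delta_m in um, uniformly spaced
#' @param wavelength wavelength in um
#' @return an object of class `interferogram` with `step` delta
#' @export
interferogram <- function(frames, deltas, wavelength) {
  if (is.list(frames)) {
    d <- dim(frames[[1]])
    if (any(!vapply(frames, function(f) identical(dim(f), d), TRUE)))
      .stopf("all frames must have the same shape")
    frames <- array(unlist(frames), dim = c(d, length(frames)))
  }
  if (length(dim(frames)) != 3) .stopf("frames must be an R1 x R2 x M array")
  m <- dim(frames)[3]
  if (m < 3) .stopf("an interferogram needs M >= 3 frames (got %d)", m)
  if (length(deltas) != m) .stopf("need one offset per frame")
  dd <- diff(deltas)
  if (any(abs(dd - dd[1]) > 1e-12)) .stopf("offsets must be uniformly spaced")
  if (dd[1] <= 0) .stopf("offsets must be increasing")
  if (min(frames) < -1e-12 * max(abs(frames))) .stopf("intensities must be >= 0")
  if (wavelength <= 0) .stopf("wavelength must be positive")
  structure(list(frames = frames, deltas = as.numeric(deltas),
                 step = dd[1], wavelength = wavelength),
            class = "interferogram")
}

#' @export
print.interferogram <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<interferogram> %d frames of %d x %d, step %g um, lambda %g um\n",
              d[3], d[1], d[2], x$step, x$wavelength))
  invisible(x)
}

#' Simulate a phase-stepped interferogram
#'
#' Interferes an object field with a collimated reference wave whose phase is
#' stepped through the offsets `deltas`, producing the per-pixel intensities
#' of the detector model (real and nonnegative by construction).
#'
#' @param e_obj object field at the detector: a [complex_field_2d()] or a
#'   complex matrix
#' @param e_ref complex reference amplitude: scalar (collimated reference) or
#'   matrix of the object field's shape
#' @param deltas uniformly spaced reference offsets in um
#' @param wavelength wavelength in um (taken from `e_obj` if it is a field)
#' @return an [interferogram()]
#' @export
simulate_interferogram <- function(e_obj, e_ref, deltas, wavelength = NULL) {
  if (inherits(e_obj, "complex_field_2d")) {
    if (is.null(wavelength)) wavelength <- e_obj$wavelength
    e_obj <- e_obj$samples
    e_obj[is.na(e_obj)] <- 0 + 0i  # masked sphere interior
  }
  if (is.null(wavelength)) .stopf("wavelength required when e_obj is a plain matrix")
  if (anyNA(e_obj)) .stopf("object field contains NA pixels; fill or crop first")
  k <- 2 * pi / wavelength
  d <- dim(e_obj)
  fr <- array(0, dim = c(d, length(deltas)))
  cross <- e_obj * Conj(e_ref)
  dc <- Mod(e_obj)^2 + Mod(e_ref)^2
  for (m in seq_along(deltas)) {
    fr[, , m] <- dc + 2 * Re(cross * exp(-1i * k * deltas[m]))
  }
  interferogram(fr, deltas, wavelength)
}

#' Consecutive difference images of an interferogram
#'
#' D_m = I_(m+1) - I_m for m = 1..M-1. The offset-independent terms
#' |ES|^2 + |ER|^2 cancel exactly, leaving only the two oscillating
#' cross-terms; these differences are the data of the linear reconstruction
#' system.
#'
#' @param ig an [interferogram()]
#' @return array R1 x R2 x (M-1) of difference images
#' @export
difference_images <- function(ig) {
  if (!inherits(ig, "interferogram")) .stopf("ig must be an interferogram")
  m <- dim(ig$frames)[3]
  ig$frames[, , 2:m, drop = FALSE] - ig$frames[, , 1:(m - 1), drop = FALSE]
}

# (M-1) x 2 system matrix of the difference equations:
# D_m = e^(-ik Delta_m) u + e^(+ik Delta_m) u2, where
# u = (e^(-ik delta) - 1) ES ER* and u2 its conjugate channel
.holo_system <- function(deltas, k) {
  m <- length(deltas)
  cbind(exp(-1i * k * deltas[-m]), exp(1i * k * deltas[-m]))
}

#' Reconstruct the complex object field from an interferogram
#'
#' Forms the M-1 consecutive difference images and solves, per pixel, the
#' 2-unknown linear system for the interferometric cross-terms via the
#' Moore-Penrose pseudo-inverse, then divides out the reference:
#' ES = u / (ER (e^(-ik delta) - 1)). With noiseless input the
#' reconstruction error is at machine-precision level. The conjugate channel
#' is redundant and only enters the per-pixel consistency residual.
#'
#' @param ig an [interferogram()]
#' @param e_ref complex reference amplitude (scalar or per-pixel matrix),
#'   nonzero
#' @param n_frames_used reconstruct from the first n frames only (default:
#'   all); must be >= 3
#' @param frame_offset start the window at this frame (1-based, default 1)
#' @return an object of class `reconstructed_field`: `es` (complex matrix),
#'   `e_ref`, and `residual` (per-pixel nonnegative misfit of the difference
#'   system)
#' @export
reconstruct_field <- function(ig, e_ref, n_frames_used = NULL, frame_offset = 1) {
  if (!inherits(ig, "interferogram")) .stopf("ig must be an interferogram")
  m_all <- dim(ig$frames)[3]
  if (is.null(n_frames_used)) n_frames_used <- m_all - frame_offset + 1
  if (n_frames_used < 3)
    .stopf("reconstruction is underdetermined with %d frames: the M-1 difference rows must determine 2 cross-terms, so M >= 3", n_frames_used)
  if (frame_offset < 1 || frame_offset + n_frames_used - 1 > m_all)
    .stopf("frame window [%d, %d] outside 1..%d", frame_offset,
           frame_offset + n_frames_used - 1, m_all)
  if (any(Mod(e_ref) == 0)) .stopf("reference amplitude must be nonzero")
  k <- 2 * pi / ig$wavelength
  kd <- k * ig$step
  if (abs(sin(kd)) < 1e-9)
    .stopf("singular phase stepping: k*delta = %g is a multiple of pi (delta a multiple of lambda/2)", kd)
  idx <- frame_offset:(frame_offset + n_frames_used - 1)
  deltas <- ig$deltas[idx]
  dd <- ig$frames[, , idx[-1], drop = FALSE] - ig$frames[, , idx[-length(idx)], drop = FALSE]
  p <- .holo_system(deltas, k)
  pinv <- solve(Conj(t(p)) %*% p, Conj(t(p)))  # Moore-Penrose inverse (full column rank)
  d1 <- dim(dd)[1]; d2 <- dim(dd)[2]
  dmat <- matrix(dd, d1 * d2, length(idx) - 1)  # pixels x (M-1)
  u <- dmat %*% t(pinv)                         # pixels x 2
  fit <- u %*% t(p)
  residual <- matrix(sqrt(rowSums(Mod(fit - dmat)^2)), d1, d2)
  es <- matrix(u[, 1], d1, d2) / (e_ref * (exp(-1i * kd) - 1))
  structure(list(es = es, e_ref = e_ref, residual = residual,
                 wavelength = ig$wavelength, step = ig$step,
                 n_frames_used = n_frames_used),
            class = "reconstructed_field")
}

#' @export
print.reconstructed_field <- function(x, ...) {
  cat(sprintf("<reconstructed_field> %d x %d from %d frames, max residual %.3e\n",
              nrow(x$es), ncol(x$es), x$n_frames_used, max(x$residual)))
  invisible(x)
}

#' Sinusoid-fitting reconstruction (cross-check path)
#'
#' Fits, per pixel, I(Delta) = a0 + b cos(k Delta) + c sin(k Delta) by linear
#' least squares over all frames and recovers ES = (b + i c) / (2 Conj(ER)).
#' An independent route to the same cross-term used to validate the
#' difference-system reconstruction.
#'
#' @inheritParams reconstruct_field
#' @return complex matrix of the reconstructed object field
#' @export
reconstruct_sinfit <- function(ig, e_ref) {
  if (!inherits(ig, "interferogram")) .stopf("ig must be an interferogram")
  k <- 2 * pi / ig$wavelength
  m <- dim(ig$frames)[3]
  basis <- cbind(1, cos(k * ig$deltas), sin(k * ig$deltas))
  d1 <- dim(ig$frames)[1]; d2 <- dim(ig$frames)[2]
  imat <- t(matrix(ig$frames, d1 * d2, m))  # frames x pixels
  cf <- qr.solve(basis, imat)               # 3 x pixels
  u0 <- complex(real = cf[2, ], imaginary = cf[3, ]) / 2  # ES ER*
  matrix(u0, d1, d2) / Conj(e_ref)
}

#' Load an experimental interferogram stack from a multi-page TIFF
#'
#' Reads a multi-page TIFF (one page per phase step, any sample format the
#' tiff reader supports), casts to double, and attaches the acquisition
#' metadata that the file format does not carry: the step size and the
#' wavelength. Offsets are taken as Delta_m = (m - 1) * step. If a JSON
#' sidecar written by [write_interferogram_tiff()] is present, its affine
#' offset/scale is applied to restore physical intensities; intensities are
#' otherwise taken in the reader's native (arbitrary) units.
#'
#' @param path TIFF file with M >= 3 pages of identical shape
#' @param step phase step delta in um
#' @param wavelength wavelength in um
#' @return an [interferogram()]
#' @export
load_experimental_stack <- function(path, step, wavelength) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  if (missing(step) || missing(wavelength))
    .stopf("step and wavelength metadata are required")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  if (any(!vapply(pages, function(p) identical(dim(p), d), TRUE)))
    .stopf("frame shape mismatch across TIFF pages")
  off <- 0; sc <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar)
    if (!is.null(meta$offset)) { off <- meta$offset; sc <- meta$scale }
  }
  deltas <- (seq_along(pages) - 1) * step
  interferogram(lapply(pages, function(p) {
    storage.mode(p) <- "double"
    p * sc + off
  }), deltas, wavelength)
}

#' Write an interferogram stack to a multi-page float TIFF
#'
#' Stores the frames as 32-bit float pages. TIFF writers expect values in
#' \[0, 1\], so the stack is affinely mapped onto that range and the offset
#' and scale are recorded -- together with step, wavelength and frame count
#' -- in a JSON sidecar `<path>.json`, which
#' [load_experimental_stack()] uses to restore physical values.
#'
#' @param ig an [interferogram()]
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_interferogram_tiff <- function(ig, path) {
  m <- dim(ig$frames)[3]
  off <- min(ig$frames)
  sc <- max(ig$frames) - off
  if (sc <= 0) sc <- 1
  pages <- lapply(seq_len(m), function(i) (ig$frames[, , i] - off) / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(step = ig$step, wavelength = ig$wavelength,
                            n_frames = m, offset = off, scale = sc),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
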