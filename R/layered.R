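#' Stack of homogeneous layers
#'
#' Layers are indexed 1..L along +z. The L-1 internal boundaries sit at
#' strictly increasing z positions; the first and last layers are unbounded.
#' The input field is specified at `z0` inside the first layer.
#'
#' @param n complex refractive index per layer (length L >= 2)
#' @param boundaries z-coordinates of the L-1 internal interfaces (um)
#' @param z0 anchor of the incident field inside layer 1 (default: the first
#'   boundary)
#' @return an object of class `layer_stack`
#' @examples
#' # 2-um slab of n = 1.65 + 0.03i in air, entry face at z = 0
#' layer_stack(c(1, 1.65 + 0.03i, 1), c(0, 2))
#' @export
layer_stack <- function(n, boundaries, z0 = NULL) {
  n <- as.complex(n)
  boundaries <- as.numeric(boundaries)
  if (length(n) < 2) .stopf("a layer stack needs at least 2 layers")
  if (length(boundaries) != length(n) - 1)
    .stopf("L layers need L-1 boundaries (got %d layers, %d boundaries)",
           length(n), length(boundaries))
  if (length(boundaries) > 1 && any(diff(boundaries) <= 0))
    .stopf("boundary positions must be strictly increasing")
  if (is.null(z0)) z0 <- boundaries[1]
  if (z0 > boundaries[1]) .stopf("z0 must lie inside the first layer (z0 <= first boundary)")
  structure(list(n = n, boundaries = boundaries, z0 = z0), class = "layer_stack")
}

#' @export
print.layer_stack <- function(x, ...) {
  cat(sprintf("<layer_stack> %d layers, boundaries at %s um\n",
              length(x$n), paste(signif(x$boundaries, 6), collapse = ", ")))
  invisible(x)
}

# longitudinal direction component per layer: sz = sqrt(n^2 - sx^2 - sy^2),
# branch Im(sz) >= 0 (decaying along +z), ties broken to Re(sz) >= 0
.layer_sz <- function(n, sx, sy) {
  sz <- sqrt(n^2 - sx^2 - sy^2)
  flip <- Im(sz) < 0 | (abs(Im(sz)) < 1e-300 & Re(sz) < 0)
  sz[flip] <- -sz[flip]
  sz
}

#' Coupled-wave solution for a plane wave crossing a layer stack
#'
#' Decomposes the field in every layer into a +z-propagating amplitude
#' (anchored at the layer's lower boundary) and a -z-propagating amplitude
#' (anchored at its upper boundary), with anchored exponentials so absorbing
#' layers stay well-conditioned. The transverse direction components
#' (sx, sy) are fixed by the incident wave and the longitudinal component
#' follows the dispersion relation sz = sqrt(n^2 - sx^2 - sy^2) per layer.
#' Unknown amplitudes satisfy, per internal boundary, continuity of the
#' tangential electric field and of the tangential magnetic field
#' (H proportional to s x E), plus one Gauss-law transversality constraint
#' s . P = 0 per partial wave: 6(L-1) equations for 6(L-1) unknowns, solved
#' directly. The last layer carries no -z-propagating wave.
#'
#' @param stack a [layer_stack()]
#' @param incident a [plane_wave()]; its direction must have a positive z
#'   component (not grazing)
#' @param polarization `NULL` to use the incident wave's polarization vector,
#'   or `"s"` / `"p"` to build the unit vector perpendicular / parallel to
#'   the plane of incidence
#' @return an object of class `layer_solution` with per-layer amplitude
#'   matrices `U` (+z) and `D` (-z), direction data and the boundary-equation
#'   residual
#' @export
solve_layered <- function(stack, incident, polarization = NULL) {
  if (!inherits(stack, "layer_stack")) .stopf("stack must be a layer_stack")
  if (!inherits(incident, "plane_wave")) .stopf("incident must be a plane_wave")
  L <- length(stack$n)
  lam <- incident$wavelength
  k <- 2 * pi / lam
  dir <- incident$direction
  if (abs(dir[3]) <= 1e-12) .stopf("grazing incidence (|dir_z| ~ 0) is not supported")
  if (dir[3] < 0) .stopf("incident wave must propagate towards +z")
  pol <- incident$polarization
  if (!is.null(polarization)) {
    polarization <- match.arg(polarization, c("s", "p"))
    if (abs(dir[1]) < 1e-14 && abs(dir[2]) < 1e-14) {
      pol <- if (polarization == "s") c(0 + 0i, 1 + 0i, 0 + 0i) else c(1 + 0i, 0 + 0i, 0 + 0i)
    } else {
      shat <- c(-dir[2], dir[1], 0)
      shat <- shat / sqrt(sum(shat^2))
      if (polarization == "s") pol <- as.complex(shat)
      else {
        ph <- c(dir[2] * shat[3] - dir[3] * shat[2],
                dir[3] * shat[1] - dir[1] * shat[3],
                dir[1] * shat[2] - dir[2] * shat[1])
        pol <- as.complex(ph / sqrt(sum(ph^2)))
      }
    }
  }
  sx <- stack$n[1] * dir[1]
  sy <- stack$n[1] * dir[2]
  sz <- .layer_sz(stack$n, sx, sy)
  zb <- stack$boundaries
  # anchors: U_l at lower boundary (z0 for layer 1), D_l at upper boundary
  anchU <- c(stack$z0, zb)
  anchD <- c(zb, NA_real_)
  u1 <- incident$amplitude * pol

  # unknown vector blocks: D_1, then (U_l, D_l) for internal layers, then U_L
  unk <- list(list(layer = 1L, type = "D"))
  if (L > 2) for (l in 2:(L - 1)) {
    unk[[length(unk) + 1]] <- list(layer = l, type = "U")
    unk[[length(unk) + 1]] <- list(layer = l, type = "D")
  }
  unk[[length(unk) + 1]] <- list(layer = L, type = "U")
  nu <- length(unk)
  col_of <- function(layer, type) {
    for (i in seq_len(nu))
      if (unk[[i]]$layer == layer && unk[[i]]$type == type) return(3 * (i - 1) + 1)
    NA_integer_
  }

  nE <- 6 * (L - 1)
  A <- matrix(0i, nE, nE)
  rhs <- rep(0i, nE)
  row <- 0L

  # rows contributed by one partial wave at a boundary: (Ex, Ey, Hx, Hy)
  wave_rows <- function(szw) {
    rbind(c(1, 0, 0),                 # Ex
          c(0, 1, 0),                 # Ey
          c(0, -szw, sy),             # (s x E)_x = sy Ez - sz Ey
          c(szw, 0, -sx))             # (s x E)_y = sz Ex - sx Ez
  }

  for (b in seq_len(L - 1)) {
    zbnd <- zb[b]
    lhs_terms <- list(
      list(layer = b, type = "U", phase = exp(1i * k * sz[b] * (zbnd - anchU[b])), szw = sz[b]),
      list(layer = b, type = "D", phase = 1 + 0i, szw = -sz[b]))
    rhs_terms <- list(
      list(layer = b + 1, type = "U", phase = 1 + 0i, szw = sz[b + 1]))
    if (b + 1 < L)
      rhs_terms[[2]] <- list(layer = b + 1, type = "D",
                             phase = exp(1i * k * sz[b + 1] * (anchD[b + 1] - zbnd)),
                             szw = -sz[b + 1])
    for (r in 1:4) {
      row <- row + 1L
      for (tm in lhs_terms) {
        wr <- wave_rows(tm$szw)[r, ] * tm$phase
        if (tm$layer == 1 && tm$type == "U") {
          rhs[row] <- rhs[row] - sum(wr * u1)
        } else {
          cc <- col_of(tm$layer, tm$type)
          A[row, cc:(cc + 2)] <- A[row, cc:(cc + 2)] + wr
        }
      }
      for (tm in rhs_terms) {
        cc <- col_of(tm$layer, tm$type)
        A[row, cc:(cc + 2)] <- A[row, cc:(cc + 2)] - wave_rows(tm$szw)[r, ] * tm$phase
      }
    }
  }
  # Gauss transversality per unknown wave
  for (i in seq_len(nu)) {
    row <- row + 1L
    l <- unk[[i]]$layer
    szw <- if (unk[[i]]$type == "U") sz[l] else -sz[l]
    cc <- 3 * (i - 1) + 1
    A[row, cc:(cc + 2)] <- c(sx, sy, szw)
  }

  sol <- tryCatch(solve(A, rhs), error = function(e)
    .stopf("singular coupled-wave system (degenerate geometry at boundaries %s): %s",
           paste(signif(zb, 6), collapse = ", "), conditionMessage(e)))
  U <- matrix(0i, 3, L); D <- matrix(0i, 3, L)
  U[, 1] <- u1
  for (i in seq_len(nu)) {
    v <- sol[(3 * (i - 1) + 1):(3 * i)]
    if (unk[[i]]$type == "U") U[, unk[[i]]$layer] <- v else D[, unk[[i]]$layer] <- v
  }
  res <- max(Mod(A %*% sol - rhs)) / max(Mod(u1))
  structure(list(stack = stack, wavelength = lam, k = k, sx = sx, sy = sy,
                 sz = sz, U = U, D = D, anchU = anchU, anchD = anchD,
                 residual = res),
            class = "layer_solution")
}

#' @export
print.layer_solution <- function(x, ...) {
  cat(sprintf("<layer_solution> %d layers, lambda %g um, residual %.2e\n",
              length(x$stack$n), x$wavelength, x$residual))
  invisible(x)
}

# layer index containing z (boundaries belong to the upper layer)
.layer_index <- function(stack, z) {
  findInterval(z, stack$boundaries, left.open = TRUE) + 1L
}

#' Evaluate the layered-solution field at a point
#'
#' Sum of the two counter-propagating partial waves of the layer containing
#' `z`, including the common transverse phase exp(i k (sx x + sy y)).
#' Vectorized over `z`.
#'
#' @param solution a [solve_layered()] result
#' @param x,y transverse coordinates in um (scalars)
#' @param z longitudinal coordinate(s) in um
#' @return complex 3 x length(z) matrix of field vectors (a plain length-3
#'   vector if `z` is scalar)
#' @export
field_at <- function(solution, x, y, z) {
  s <- solution
  li <- .layer_index(s$stack, z)
  out <- matrix(0i, 3, length(z))
  tp <- exp(1i * s$k * (s$sx * x + s$sy * y))
  for (j in seq_along(z)) {
    l <- li[j]
    up <- s$U[, l] * exp(1i * s$k * s$sz[l] * (z[j] - s$anchU[l]))
    dn <- if (l < length(s$stack$n))
      s$D[, l] * exp(-1i * s$k * s$sz[l] * (z[j] - s$anchD[l])) else 0i
    out[, j] <- (up + dn) * tp
  }
  if (length(z) == 1) drop(out) else out
}

#' Power reflectance and transmittance of a layer stack
#'
#' Computed from the outermost-layer amplitudes with sz weighting of the
#' longitudinal energy flux. Requires lossless outer layers, otherwise the
#' power bookkeeping is undefined.
#'
#' @param solution a [solve_layered()] result
#' @return list with elements `R` and `T`; for a lossless stack R + T = 1
#' @export
reflectance_transmittance <- function(solution) {
  s <- solution
  L <- length(s$stack$n)
  if (abs(Im(s$stack$n[1])) > 1e-12 || abs(Im(s$stack$n[L])) > 1e-12)
    .stopf("reflectance/transmittance requires lossless outer layers")
  z1 <- s$stack$boundaries[1]
  uin <- s$U[, 1] * exp(1i * s$k * s$sz[1] * (z1 - s$anchU[1]))
  pin <- Re(s$sz[1]) * sum(Mod(uin)^2)
  pr <- Re(s$sz[1]) * sum(Mod(s$D[, 1])^2)
  pt <- Re(s$sz[L]) * sum(Mod(s$U[, L])^2)
  list(R = pr / pin, T = pt / pin)
}
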