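# Synthetic smooth deformation fields with analytic Jacobians, and
# thin-plate-spline landmark registration.
#
# Convention: a deformation_field is defined on the grid of the *target*
# (output) space and maps target coordinates to source coordinates
# (pull-back). Density transfer then multiplies by the Jacobian determinant
# of that map, which conserves integrated counts by change of variables.

#' Deformation field container
#'
#' @param displacement array `c(grid, d)` of displacements (target to source),
#'   in grid units (pixels/voxels).
#' @param jacobian_det array of the determinant of the target-to-source map.
#' @param spacing grid spacing (defaults to 1 unit per cell).
#' @return object of class `deformation_field`.
#' @export
deformation_field <- function(displacement, jacobian_det, spacing = NULL) {
  d <- dim(displacement)
  nd <- d[length(d)]
  stopifnot(nd %in% c(2, 3), length(d) == nd + 1)
  if (any(!is.finite(displacement))) stop("displacement must be finite")
  structure(list(displacement = displacement, jacobian_det = jacobian_det,
                 dim = d[seq_len(nd)], ndim = nd,
                 spacing = spacing %||% rep(1, nd)),
            class = "deformation_field")
}

#' Generate a smooth invertible random deformation field
#'
#' The displacement is a sum of low-frequency sine/cosine components with
#' random coefficients, so the Jacobian is available analytically at every
#' grid point. Amplitude 0 gives the identity (determinant 1 everywhere).
#' Fields whose minimum Jacobian determinant falls to 0.2 or below are
#' rejected with an error (the field would not be safely invertible).
#'
#' @param grid_shape 2 or 3 integers.
#' @param amplitude displacement amplitude in grid units.
#' @param rng_seed integer seed.
#' @param n_modes number of random Fourier modes per displacement component.
#' @param max_freq highest spatial frequency (cycles per grid extent).
#' @return a [deformation_field()].
#' @export
make_deformation <- function(grid_shape, amplitude, rng_seed = 1L,
                             n_modes = 4L, max_freq = 2) {
  nd <- length(grid_shape)
  stopifnot(nd %in% c(2, 3), amplitude >= 0)
  set.seed(derive_seed(rng_seed, "deformation"))
  # coefficients: per output component, n_modes terms a * sin(k.x + phase)
  modes <- lapply(seq_len(nd), function(comp) {
    k <- matrix(stats::runif(n_modes * nd, -max_freq, max_freq), n_modes, nd)
    k <- 2 * pi * sweep(k, 2, grid_shape, `/`)
    list(k = k, phase = stats::runif(n_modes, 0, 2 * pi),
         a = if (amplitude > 0) stats::rnorm(n_modes, 0, 1) else rep(0, n_modes))
  })
  # normalize so max |u| is ~amplitude: scale by sum |a|
  sc <- vapply(modes, function(m) sum(abs(m$a)), numeric(1))
  sc[sc == 0] <- 1
  for (comp in seq_len(nd)) modes[[comp]]$a <- amplitude * modes[[comp]]$a / sc[comp]

  grids <- lapply(grid_shape, function(n) seq_len(n) - 0.5)
  coords <- as.matrix(do.call(expand.grid, grids))
  npt <- nrow(coords)
  u <- matrix(0, npt, nd)
  J <- array(0, c(npt, nd, nd))             # gradient of displacement
  for (comp in seq_len(nd)) {
    m <- modes[[comp]]
    for (i in seq_len(nrow(m$k))) {
      ph <- coords %*% m$k[i, ] + m$phase[i]
      u[, comp] <- u[, comp] + m$a[i] * sin(ph)
      for (ax in seq_len(nd))
        J[, comp, ax] <- J[, comp, ax] + m$a[i] * cos(ph) * m$k[i, ax]
    }
  }
  # det(I + J)
  if (nd == 2) {
    det <- (1 + J[, 1, 1]) * (1 + J[, 2, 2]) - J[, 1, 2] * J[, 2, 1]
  } else {
    a <- 1 + J[, 1, 1]; b <- J[, 1, 2]; cc <- J[, 1, 3]
    d <- J[, 2, 1]; e <- 1 + J[, 2, 2]; f <- J[, 2, 3]
    g <- J[, 3, 1]; hh <- J[, 3, 2]; i <- 1 + J[, 3, 3]
    det <- a * (e * i - f * hh) - b * (d * i - f * g) + cc * (d * hh - e * g)
  }
  if (min(det) <= 0.2)
    stop(sprintf("deformation not safely invertible: min Jacobian determinant %.3f",
                 min(det)))
  deformation_field(array(u, c(grid_shape, nd)), array(det, grid_shape))
}

#' Fit a thin-plate spline to landmark pairs
#'
#' Classic 2D thin-plate spline: affine part plus radial basis
#' `U(r) = r^2 log r`, minimizing bending energy; at `regularization = 0` the
#' map interpolates the landmarks exactly. The Jacobian of the fitted map is
#' evaluated analytically from the spline coefficients.
#'
#' @param source_landmarks,target_landmarks n x 2 matrices (n >= 3,
#'   non-collinear for exact interpolation).
#' @param regularization nonnegative smoothing parameter (0 = interpolation).
#' @return object of class `tps_map` with elements `predict(x)` coordinates
#'   mapped source -> target, and `jacobian(x)` per-point 2 x 2 Jacobians.
#' @export
tps_fit <- function(source_landmarks, target_landmarks, regularization = 0) {
  P <- rbind(source_landmarks); Q <- rbind(target_landmarks)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 2, ncol(Q) == 2, regularization >= 0)
  n <- nrow(P)
  if (n < 3) stop("need at least 3 landmark pairs")
  if (qr(cbind(1, P))$rank < 3 && regularization == 0)
    stop("landmarks are collinear; exact thin-plate interpolation is singular")
  r2 <- as.matrix(stats::dist(P))^2
  K <- ifelse(r2 > 0, r2 * log(pmax(r2, 1e-300)) / 2, 0)   # r^2 log r
  Pm <- cbind(1, P)
  L <- rbind(cbind(K + diag(regularization, n), Pm),
             cbind(t(Pm), matrix(0, 3, 3)))
  rhs <- rbind(Q, matrix(0, 3, 2))
  coef <- solve(L, rhs)
  W <- coef[seq_len(n), , drop = FALSE]      # n x 2 radial weights
  A <- coef[n + 1:3, , drop = FALSE]         # 3 x 2 affine (1, x, y)

  predict_fun <- function(x) {
    x <- rbind(x)
    d2 <- outer(x[, 1], P[, 1], `-`)^2 + outer(x[, 2], P[, 2], `-`)^2
    U <- ifelse(d2 > 0, d2 * log(pmax(d2, 1e-300)) / 2, 0)
    cbind(1, x) %*% A + U %*% W
  }
  jacobian_fun <- function(x) {
    x <- rbind(x)
    dx <- outer(x[, 1], P[, 1], `-`)
    dy <- outer(x[, 2], P[, 2], `-`)
    r2m <- dx^2 + dy^2
    # with U = (r^2/2) log r^2, grad U = (x - p)(log r^2 + 1)
    g <- ifelse(r2m > 0, log(pmax(r2m, 1e-300)) + 1, 0)
    J <- array(0, c(nrow(x), 2, 2))
    J[, 1, 1] <- A[2, 1] + (dx * g) %*% W[, 1]
    J[, 1, 2] <- A[3, 1] + (dy * g) %*% W[, 1]
    J[, 2, 1] <- A[2, 2] + (dx * g) %*% W[, 2]
    J[, 2, 2] <- A[3, 2] + (dy * g) %*% W[, 2]
    J
  }
  structure(list(predict = predict_fun, jacobian = jacobian_fun,
                 weights = W, affine = A, source = P, target = Q,
                 regularization = regularization),
            class = "tps_map")
}

#' Evaluate a thin-plate-spline map as a deformation field
#'
#' Samples the fitted map on a regular grid and returns displacement and
#' analytic Jacobian determinant. To *pull* a density from space A into
#' space B, fit the spline from B landmarks to A landmarks and evaluate on
#' the B grid.
#'
#' @param tps a [tps_fit()] result.
#' @param grid_shape 2 integers.
#' @return a [deformation_field()] (2D).
#' @export
tps_deformation_field <- function(tps, grid_shape) {
  stopifnot(inherits(tps, "tps_map"), length(grid_shape) == 2)
  gx <- seq_len(grid_shape[1]) - 0.5
  gy <- seq_len(grid_shape[2]) - 0.5
  coords <- as.matrix(expand.grid(gx, gy))
  mapped <- tps$predict(coords)
  J <- tps$jacobian(coords)
  det <- J[, 1, 1] * J[, 2, 2] - J[, 1, 2] * J[, 2, 1]
  deformation_field(array(mapped - coords, c(grid_shape, 2)),
                    array(det, grid_shape))
}
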