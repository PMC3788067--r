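# Diffusion acquisition scheme and signal simulation.

#' Diffusion acquisition scheme
#'
#' @param bvals numeric vector of b-values (s/mm^2), one per acquisition.
#' @param bvecs matrix (n x 3) of gradient directions; rows with b > 0 must be
#'   unit vectors (checked to 1e-8). At least one b = 0 acquisition and at
#'   least 6 non-collinear nonzero-b directions are required.
#' @return object of class `diffusion_scheme`.
#' @export
diffusion_scheme <- function(bvals, bvecs) {
  bvecs <- rbind(bvecs)
  stopifnot(length(bvals) == nrow(bvecs), ncol(bvecs) == 3)
  if (!any(bvals == 0)) stop("scheme needs at least one b = 0 acquisition")
  dw <- bvals > 0
  nn <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
  if (any(abs(nn - 1) > 1e-8)) stop("nonzero-b gradient directions must be unit vectors")
  g <- bvecs[dw, , drop = FALSE]
  # non-collinearity: the 6 quadratic forms must span rank 6
  q <- cbind(g[, 1]^2, 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
             g[, 2]^2, 2 * g[, 2] * g[, 3], g[, 3]^2)
  if (sum(dw) < 6 || qr(q)$rank < 6)
    stop("scheme needs at least 6 non-collinear nonzero-b directions")
  structure(list(bvals = as.numeric(bvals), bvecs = unname(bvecs)),
            class = "diffusion_scheme")
}

#' Default 31-direction scheme
#'
#' One b = 0 acquisition plus 31 directions at b = 1200 s/mm^2 (the study's
#' acquisition), spread over the hemisphere by a golden-angle spiral.
#'
#' @param n_dirs number of diffusion-weighted directions.
#' @param b b-value of the weighted acquisitions (s/mm^2).
#' @param n_b0 number of b = 0 acquisitions.
#' @return a [diffusion_scheme()].
#' @export
default_scheme <- function(n_dirs = 31L, b = 1200, n_b0 = 1L) {
  i <- seq_len(n_dirs)
  z <- (i - 0.5) / n_dirs                 # upper hemisphere
  phi <- i * pi * (3 - sqrt(5))
  s <- sqrt(1 - z^2)
  g <- cbind(s * cos(phi), s * sin(phi), z)
  g <- g / sqrt(rowSums(g^2))
  diffusion_scheme(c(rep(0, n_b0), rep(b, n_dirs)),
                   rbind(matrix(0, n_b0, 3), g))
}

#' Simulate diffusion-weighted signal from a tensor field
#'
#' Noiseless signal per voxel and acquisition is `s0 * exp(-b g' D g)`.
#' Rician noise is the magnitude of the complex Gaussian perturbation
#' `sqrt((S + sigma*n1)^2 + (sigma*n2)^2)`.
#'
#' @param tensors a [tensor_field()].
#' @param scheme a [diffusion_scheme()].
#' @param s0 non-diffusion-weighted signal level.
#' @param noise_sigma Rician noise scale in signal units (0 for noiseless).
#' @param rng_seed integer seed.
#' @return object of class `dwi_volume`: `signal` (4D array x,y,z,acq),
#'   `scheme`, `voxel_size`.
#' @export
simulate_dwi <- function(tensors, scheme, s0 = 1000, noise_sigma = 0, rng_seed = 1L) {
  stopifnot(inherits(tensors, "tensor_field"), inherits(scheme, "diffusion_scheme"),
            noise_sigma >= 0)
  d6 <- tensors$d6
  nvox <- nrow(d6); nacq <- length(scheme$bvals)
  g <- scheme$bvecs; b <- scheme$bvals
  # quadratic form coefficients per acquisition (columns), 6 x nacq
  co <- rbind(g[, 1]^2, 2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
              g[, 2]^2, 2 * g[, 2] * g[, 3], g[, 3]^2)
  q <- d6 %*% co                           # nvox x nacq: g' D g
  neg <- which(q < -1e-15, arr.ind = TRUE)
  if (nrow(neg)) {
    v <- lin_to_ijk(neg[1, 1], tensors$dims)
    stop(sprintf("non positive-semidefinite tensor at voxel (%d, %d, %d)",
                 v[1], v[2], v[3]))
  }
  signal <- s0 * exp(-sweep(q, 2, b, `*`))
  if (noise_sigma > 0) {
    set.seed(derive_seed(rng_seed, "rician"))
    n1 <- matrix(stats::rnorm(nvox * nacq), nvox, nacq)
    n2 <- matrix(stats::rnorm(nvox * nacq), nvox, nacq)
    signal <- sqrt((signal + noise_sigma * n1)^2 + (noise_sigma * n2)^2)
  }
  structure(list(signal = array(signal, c(tensors$dims, nacq)), scheme = scheme,
                 voxel_size = tensors$voxel_size, s0 = s0),
            class = "dwi_volume")
}

#' Fit diffusion tensors by log-linear least squares
#'
#' Per voxel, solves `ln S(g, b) = ln S0 - b g' D g` by ordinary least
#' squares over all acquisitions jointly. The signal is clamped at
#' `1e-6 * S0ref` (S0ref = per-voxel mean b0) before the log, since the
#' Rician noise floor can produce values near zero. Voxels with non-finite
#' signal are dropped from the mask with a message.
#'
#' @param dwi a [simulate_dwi()] result (or compatible `dwi_volume`).
#' @param mask logical 3D array of voxels to fit; default all.
#' @return a [tensor_field()] (negative-eigenvalue fits are retained; FA uses
#'   eigenvalues clamped at zero).
#' @export
fit_tensor <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  dims <- dim(dwi$signal)[1:3]
  sig <- matrix(dwi$signal, prod(dims), dim(dwi$signal)[4])
  b <- dwi$scheme$bvals; g <- dwi$scheme$bvecs
  if (length(b) < 7) stop("need at least 7 acquisitions (1 b0 + 6 directions)")
  if (is.null(mask)) mask <- array(TRUE, dims)
  idx <- which(as.logical(mask))
  S <- sig[idx, , drop = FALSE]
  bad <- !is.finite(rowSums(S))
  if (any(bad)) {
    message(sum(bad), " voxel(s) with non-finite signal dropped from mask")
    idx <- idx[!bad]; S <- S[!bad, , drop = FALSE]
  }
  s0ref <- rowMeans(S[, b == 0, drop = FALSE])
  S <- pmax(S, 1e-6 * s0ref)
  X <- cbind(1, -b * g[, 1]^2, -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -b * g[, 2]^2, -2 * b * g[, 2] * g[, 3], -b * g[, 3]^2)
  beta <- qr.coef(qr(X), t(log(S)))        # 7 x n
  d6 <- matrix(0, prod(dims), 6)
  d6[idx, ] <- t(beta[2:7, , drop = FALSE])
  out_mask <- array(FALSE, dims); out_mask[idx] <- TRUE
  tf <- tensor_field(d6, dims, dwi$voxel_size, mask = out_mask)
  tf$s0_fit <- array(0, dims); tf$s0_fit[idx] <- exp(beta[1, ])
  tf
}

#' Reorient a tensor by preservation of principal direction
#'
#' The reoriented tensor keeps its eigenvalues; its first eigenvector is the
#' normalized image of the original first eigenvector under the local affine
#' map, the second is the Gram-Schmidt-corrected image of the original second
#' eigenvector, and the third completes the right-handed frame.
#'
#' @param tensor symmetric 3 x 3 matrix.
#' @param local_affine invertible 3 x 3 Jacobian of the deformation.
#' @return reoriented symmetric 3 x 3 tensor.
#' @export
ppd_reorient <- function(tensor, local_affine) {
  stopifnot(is.matrix(tensor), all(dim(tensor) == 3),
            is.matrix(local_affine), all(dim(local_affine) == 3))
  if (abs(det(local_affine)) < 1e-12) stop("local affine map is singular")
  ee <- eigen((tensor + t(tensor)) / 2, symmetric = TRUE)
  v1 <- unit3(as.vector(local_affine %*% ee$vectors[, 1]))
  w2 <- as.vector(local_affine %*% ee$vectors[, 2])
  v2 <- w2 - sum(w2 * v1) * v1
  v2 <- unit3(v2)
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  V <- cbind(v1, v2, v3)
  D <- V %*% diag(ee$values) %*% t(V)
  (D + t(D)) / 2
}
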