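# Vectorized eigendecomposition of many symmetric 3x3 matrices.
#
# Eigenvalues use the trigonometric solution of the characteristic cubic
# (Smith 1961); the principal eigenvector comes from the Cayley-Hamilton
# identity (A - l2 I)(A - l3 I), whose columns span the l1 eigenspace.
# Near-degenerate voxels fall back to base eigen(), which is the accuracy
# reference but far too slow to call per voxel on whole volumes.

#' Eigenvalues and principal eigenvector of symmetric 3x3 tensors
#'
#' @param d6 n x 6 matrix of tensor components in the order
#'   Dxx, Dxy, Dxz, Dyy, Dyz, Dzz.
#' @return list with `values` (n x 3, sorted descending) and `v1`
#'   (n x 3 unit principal eigenvectors, sign convention: first component of
#'   largest magnitude made nonnegative).
#' @export
eig3_sym <- function(d6) {
  d6 <- rbind(d6)
  n <- nrow(d6)
  a11 <- d6[, 1]; a12 <- d6[, 2]; a13 <- d6[, 3]
  a22 <- d6[, 4]; a23 <- d6[, 5]; a33 <- d6[, 6]
  q <- (a11 + a22 + a33) / 3
  b11 <- a11 - q; b22 <- a22 - q; b33 <- a33 - q
  p2 <- (b11^2 + b22^2 + b33^2 + 2 * (a12^2 + a13^2 + a23^2)) / 6
  p <- sqrt(pmax(p2, 0))
  # det(B)/2 with B = A - qI
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- clamp(r, -1, 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  vals <- unname(cbind(l1, l2, l3))

  # principal eigenvector via columns of (A - l2 I)(A - l3 I)
  c11 <- a11 - l2; c22 <- a22 - l2; c33 <- a33 - l2
  e11 <- a11 - l3; e22 <- a22 - l3; e33 <- a33 - l3
  m11 <- c11 * e11 + a12 * a12 + a13 * a13
  m21 <- a12 * e11 + c22 * a12 + a23 * a13
  m31 <- a13 * e11 + a23 * a12 + c33 * a13
  m12 <- c11 * a12 + a12 * e22 + a13 * a23
  m22 <- a12 * a12 + c22 * e22 + a23 * a23
  m32 <- a13 * a12 + a23 * e22 + c33 * a23
  m13 <- c11 * a13 + a12 * a23 + a13 * e33
  m23 <- a12 * a13 + c22 * a23 + a23 * e33
  m33 <- a13 * a13 + a23 * a23 + c33 * e33
  n1 <- m11^2 + m21^2 + m31^2
  n2 <- m12^2 + m22^2 + m32^2
  n3 <- m13^2 + m23^2 + m33^2
  best <- max.col(cbind(n1, n2, n3), ties.method = "first")
  vx <- ifelse(best == 1, m11, ifelse(best == 2, m12, m13))
  vy <- ifelse(best == 1, m21, ifelse(best == 2, m22, m23))
  vz <- ifelse(best == 1, m31, ifelse(best == 2, m32, m33))
  nv <- sqrt(vx^2 + vy^2 + vz^2)

  scale <- pmax(abs(l1), abs(l3), 1e-300)
  # fall back where the top eigenvalue is (nearly) degenerate or the
  # Cayley-Hamilton product collapsed numerically
  bad <- which((l1 - l2) <= 1e-7 * scale | nv <= 1e-10 * scale^2 | !is.finite(nv))
  ok <- nv > 0
  vx <- ifelse(ok, vx / nv, 1); vy <- ifelse(ok, vy / nv, 0); vz <- ifelse(ok, vz / nv, 0)
  v1 <- unname(cbind(vx, vy, vz))
  for (i in bad) {
    A <- matrix(c(a11[i], a12[i], a13[i],
                  a12[i], a22[i], a23[i],
                  a13[i], a23[i], a33[i]), 3, 3)
    ee <- eigen(A, symmetric = TRUE)
    vals[i, ] <- ee$values
    v1[i, ] <- ee$vectors[, 1]
  }
  # deterministic sign: first component with non-negligible magnitude >= 0
  lead <- ifelse(abs(v1[, 1]) > 1e-8, v1[, 1],
                 ifelse(abs(v1[, 2]) > 1e-8, v1[, 2], v1[, 3]))
  flip <- lead < 0
  v1[flip, ] <- -v1[flip, , drop = FALSE]
  list(values = vals, v1 = v1)
}

#' Fractional anisotropy from eigenvalues
#'
#' Eigenvalues are clamped at zero before applying the standard FA formula
#' (negative eigenvalues can arise from noisy log-linear fits). Exactly equal
#' eigenvalues are short-circuited to FA = 0 so that isotropic tensors give
#' zero without floating-point residue; an all-zero tensor also gives 0.
#'
#' @param values n x 3 matrix of eigenvalues.
#' @return numeric vector of FA values in `[0, 1]`.
#' @export
fa_from_eigenvalues <- function(values) {
  values <- rbind(values)
  l <- pmax(values, 0)
  equal <- l[, 1] == l[, 2] & l[, 2] == l[, 3]
  m <- rowMeans(l)
  num <- (l[, 1] - m)^2 + (l[, 2] - m)^2 + (l[, 3] - m)^2
  den <- l[, 1]^2 + l[, 2]^2 + l[, 3]^2
  fa <- ifelse(equal | den == 0, 0, sqrt(1.5 * num / pmax(den, 1e-300)))
  unname(clamp(fa, 0, 1))
}
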