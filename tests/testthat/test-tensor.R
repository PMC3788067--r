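# Tensor fitting, FA, eigensolver, and PPD reorientation.

test_that("log-linear fit inverts noiseless simulation exactly (property)", {
  d6 <- random_spd_tensors(100, seed = 7)
  dims <- c(100L, 1L, 1L)
  tf <- tensor_field(d6, dims, rep(0.3, 3))
  dwi <- simulate_dwi(tf, default_scheme(), s0 = 1000, noise_sigma = 0)
  fit <- fit_tensor(dwi)
  rel <- sqrt(rowSums((fit$d6 - d6)^2)) / sqrt(rowSums(d6^2))
  expect_lt(max(rel), 1e-8)
})

test_that("FA is exactly 0 for isotropic and 1 for stick tensors", {
  expect_identical(fa_from_eigenvalues(c(7e-4, 7e-4, 7e-4)), 0)
  expect_identical(fa_from_eigenvalues(c(0.1, 0.1, 0.1)), 0)
  expect_equal(fa_from_eigenvalues(c(1.5e-3, 0, 0)), 1)
  # negative eigenvalues clamped before the formula
  expect_equal(fa_from_eigenvalues(c(1e-3, -1e-5, -1e-5)), 1)
  expect_identical(fa_from_eigenvalues(c(0, 0, 0)), 0)
  # isotropic voxel through the full fit still gives FA 0 exactly
  dims <- c(2L, 1L, 1L)
  tf <- tensor_field(matrix(c(7e-4, 0, 0, 7e-4, 0, 7e-4), 2, 6, byrow = TRUE),
                     dims, rep(0.3, 3))
  expect_identical(unique(as.vector(tf$fa)), 0)
})

test_that("vectorized eigensolver matches base eigen on random tensors", {
  d6 <- random_spd_tensors(500, seed = 11)
  ee <- eig3_sym(d6)
  for (i in seq_len(nrow(d6))) {
    ref <- eigen(d6_to_mat(d6[i, ]), symmetric = TRUE)
    expect_equal(ee$values[i, ], ref$values, tolerance = 1e-8)
    expect_gt(abs(sum(ee$v1[i, ] * ref$vectors[, 1])), 1 - 1e-7)
  }
})

test_that("FA is invariant under joint rotation of tensor and scheme", {
  d6 <- random_spd_tensors(20, seed = 3)
  sch <- default_scheme()
  set.seed(4)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  fa1 <- fa_from_eigenvalues(eig3_sym(d6)$values)
  rot <- t(vapply(seq_len(nrow(d6)), function(i) {
    D <- R %*% d6_to_mat(d6[i, ]) %*% t(R)
    c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
  }, numeric(6)))
  fa2 <- fa_from_eigenvalues(eig3_sym(rot)$values)
  expect_equal(fa1, fa2, tolerance = 1e-10)
})

test_that("fit_tensor validates its inputs", {
  dims <- c(2L, 2L, 2L)
  tf <- tensor_field(matrix(c(7e-4, 0, 0, 7e-4, 0, 7e-4), prod(dims), 6,
                            byrow = TRUE), dims, rep(0.3, 3))
  sch <- diffusion_scheme(c(0, rep(1200, 6)), rbind(c(0, 0, 0), rbind(
    c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
    c(1, 1, 0) / sqrt(2), c(0, 1, 1) / sqrt(2), c(1, 0, 1) / sqrt(2))))
  dwi <- simulate_dwi(tf, sch)
  expect_s3_class(fit_tensor(dwi), "tensor_field")
  dwi$signal <- dwi$signal[, , , 1:6]
  dwi$scheme$bvals <- dwi$scheme$bvals[1:6]
  dwi$scheme$bvecs <- dwi$scheme$bvecs[1:6, ]
  expect_error(fit_tensor(dwi), "at least 7")

  dwi2 <- simulate_dwi(tf, sch)
  dwi2$signal[1, 1, 1, 2] <- NaN
  expect_message(fit_tensor(dwi2), "non-finite")
})

test_that("PPD reorientation preserves eigenvalues and maps directions", {
  D <- d6_to_mat(random_spd_tensors(1, seed = 9)[1, ])
  expect_equal(ppd_reorient(D, diag(3)), D, tolerance = 1e-12)

  set.seed(10)
  R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  expect_equal(ppd_reorient(D, R), R %*% D %*% t(R), tolerance = 1e-10)

  # shear applied to a prolate tensor along x: new principal direction is the
  # normalized image of (1,0,0); eigenvalues unchanged
  Dx <- diag(c(1.7e-3, 2.5e-4, 2.5e-4))
  S <- rbind(c(1, 0.4, 0), c(0, 1, 0), c(0, 0, 1))
  Dr <- ppd_reorient(Dx, S)
  er <- eigen(Dr, symmetric = TRUE)
  expect_equal(er$values, c(1.7e-3, 2.5e-4, 2.5e-4), tolerance = 1e-10)
  v1_expect <- S %*% c(1, 0, 0); v1_expect <- v1_expect / sqrt(sum(v1_expect^2))
  expect_gt(abs(sum(er$vectors[, 1] * v1_expect)), 1 - 1e-10)

  # eigenvalue preservation under random invertible affines (property)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3, 3)
    if (abs(det(A)) < 0.1) next
    Dr <- ppd_reorient(D, A)
    expect_equal(eigen(Dr, symmetric = TRUE)$values,
                 eigen(D, symmetric = TRUE)$values, tolerance = 1e-10)
  }
  expect_error(ppd_reorient(D, matrix(0, 3, 3)), "singular")
})
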