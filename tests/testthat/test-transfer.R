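# Deformation fields, thin-plate splines, Jacobian-compensated transfer and
# interface projection.

test_that("make_deformation: identity at amplitude 0, analytic Jacobian checks out", {
  f0 <- make_deformation(c(32, 32), 0)
  expect_true(all(f0$displacement == 0))
  expect_true(all(f0$jacobian_det == 1))

  # analytic determinant vs central finite differences of the displacement
  # (low spatial frequency so the FD oracle itself is accurate to < 1e-3)
  f <- make_deformation(c(96, 96), 1.5, rng_seed = 3)
  u1 <- f$displacement[, , 1]; u2 <- f$displacement[, , 2]
  G <- 96
  i <- 2:(G - 1); j <- 2:(G - 1)
  d11 <- 1 + (u1[i + 1, j] - u1[i - 1, j]) / 2
  d12 <- (u1[i, j + 1] - u1[i, j - 1]) / 2
  d21 <- (u2[i + 1, j] - u2[i - 1, j]) / 2
  d22 <- 1 + (u2[i, j + 1] - u2[i, j - 1]) / 2
  fd_det <- d11 * d22 - d12 * d21
  expect_lt(max(abs(fd_det - f$jacobian_det[i, j])), 1e-3)

  # 3D field too
  f3 <- make_deformation(c(20, 20, 20), 1.0, rng_seed = 4)
  expect_true(min(f3$jacobian_det) > 0.2)

  # excessive amplitude -> non-invertible error reporting the determinant
  expect_error(make_deformation(c(32, 32), 50, rng_seed = 1),
               "not safely invertible")
})

test_that("TPS reproduces affine maps and interpolates landmarks", {
  set.seed(2)
  src <- matrix(runif(24, 5, 95), 12, 2)
  A <- rbind(c(1.3, 0.2), c(-0.1, 0.8)); b <- c(4, -2)
  tgt <- src %*% t(A) + rep(b, each = 12)
  tps <- tps_fit(src, tgt)
  expect_lt(max(abs(tps$weights)), 1e-8)            # nonlinear part vanishes
  expect_lt(max(abs(tps$predict(src) - tgt)), 1e-6) # exact interpolation
  J <- tps$jacobian(rbind(c(30, 60), c(70, 20)))
  expect_equal(J[1, , ], A, tolerance = 1e-8)

  # prediction error at held-out points of a smooth synthetic map
  f <- function(x) cbind(x[, 1] + 3 * sin(x[, 1] / 20) + 0.5 * cos(x[, 2] / 15),
                         x[, 2] + 2 * cos(x[, 2] / 18) + 0.7 * sin(x[, 1] / 25))
  set.seed(3)
  lm_src <- cbind(runif(50, 5, 95), runif(50, 5, 95))
  tps2 <- tps_fit(lm_src, f(lm_src))
  held <- cbind(runif(40, 15, 85), runif(40, 15, 85))
  err <- sqrt(rowSums((tps2$predict(held) - f(held))^2))
  mag <- sqrt(rowSums((f(held) - held)^2))
  expect_lt(max(err) / mean(mag), 0.05)

  expect_error(tps_fit(cbind(1:5, 1:5), cbind(1:5, 2 * (1:5))), "collinear")
  expect_s3_class(tps_deformation_field(tps, c(16, 16)), "deformation_field")
})

test_that("transfer_ddm conserves mass and matches closed forms", {
  blob <- gaussian_blob(64, R = 20)
  # identity: bitwise equality
  id <- deformation_field(array(0, c(64, 64, 2)), array(1, c(64, 64)))
  expect_identical(transfer_ddm(blob, id), blob)

  # uniform 2x magnification: pull-back map y -> y/2, density scaled by 1/4
  G2 <- c(128, 128)
  coords <- as.matrix(expand.grid(seq_len(128) - 0.5, seq_len(128) - 0.5))
  disp <- array(0.5 * coords - coords, c(G2, 2))
  mag <- deformation_field(disp, array(0.25, G2))
  out <- transfer_ddm(blob, mag)
  expect_lt(abs(sum(out) - sum(blob)) / sum(blob), 1e-6)
  # peak density drops by 4
  expect_equal(max(out), max(blob) / 4, tolerance = 1e-4)

  # nonpositive determinant rejected
  badf <- deformation_field(array(0, c(64, 64, 2)), array(-1, c(64, 64)))
  expect_error(transfer_ddm(blob, badf), "nonpositive")

  # random smooth fields: mass conserved within 1%, particle oracle within 2% TV
  for (s in 1:10) {
    f <- make_deformation(c(64, 64), 1.5, rng_seed = s)
    out <- transfer_ddm(blob, f)
    expect_lt(abs(sum(out) - sum(blob)) / sum(blob), 0.01)
    oracle <- particle_push_oracle(blob, f, subdiv = 4L)
    tv <- 0.5 * sum(abs(out / sum(out) - oracle / sum(oracle)))
    expect_lt(tv, 0.02)
  }
})

test_that("chained transfers compose with the composed field", {
  blob <- gaussian_blob(128, R = 40)
  f1 <- make_deformation(c(128, 128), 1.5, rng_seed = 21)
  f2 <- make_deformation(c(128, 128), 1.0, rng_seed = 22)
  seq_out <- transfer_ddm(transfer_ddm(blob, f1), f2)
  # composed pull-back: y -> map1(map2(y)); Jacobians multiply
  coords <- as.matrix(expand.grid(seq_len(128) - 0.5, seq_len(128) - 0.5))
  m2 <- coords + matrix(f2$displacement, 128 * 128, 2)
  u1x <- tracerval:::interp_grid(f1$displacement[, , 1], m2)
  u1y <- tracerval:::interp_grid(f1$displacement[, , 2], m2)
  j1 <- tracerval:::interp_grid(f1$jacobian_det, m2)
  comp <- deformation_field(array(cbind(m2[, 1] + u1x, m2[, 2] + u1y) - coords,
                                  c(128, 128, 2)),
                            array(j1 * as.vector(f2$jacobian_det), c(128, 128)))
  comp_out <- transfer_ddm(blob, comp)
  rel <- sum(abs(seq_out - comp_out)) / sum(blob)
  expect_lt(rel, 0.02)
})

test_that("interface projection conserves mass with deterministic ties", {
  lab <- slab_labels()
  iface <- extract_interface(lab)
  # interface = GM layer z = 7, every voxel 6-adjacent to WM and GM
  expect_true(all(iface$voxels[, 3] == 7))
  expect_equal(iface$normals[1, ], c(0, 0, -1))

  h <- rep(0.3, 3)
  vol <- array(0, dim(lab))
  vol[5, 5, 8] <- 2.5                          # single GM voxel above (5,5,7)
  s <- project_to_interface(vol, iface, h)
  iv <- which(iface$voxels[, 1] == 5 & iface$voxels[, 2] == 5)
  expect_equal(s$values[iv], 2.5)
  expect_equal(sum(s$values), 2.5)

  # a whole GM column lands on its own interface voxel; mass exact
  vol2 <- array(0, dim(lab))
  vol2[6, 4, 7:10] <- c(1, 2, 3, 4)
  s2 <- project_to_interface(vol2, iface, h)
  iv2 <- which(iface$voxels[, 1] == 6 & iface$voxels[, 2] == 4)
  expect_equal(s2$values[iv2], 10)
  expect_equal(sum(s2$values), 10)

  # equidistant tie: midpoint between two interface voxels goes to the
  # smaller linear index
  vol3 <- array(0, dim(lab))
  vol3[7, 7, 9] <- 1
  ties <- project_to_interface(vol3, iface, h)
  expect_equal(sum(ties$values), 1)
  hit <- iface$voxels[ties$values > 0, ]
  expect_equal(unname(hit), c(7, 7, 7))

  expect_error(extract_interface(array(0L, c(4, 4, 4))), "no white/gray")
})
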