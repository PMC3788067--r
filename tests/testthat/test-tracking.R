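# Seed regions, FACT geometry, selection, and the probabilistic tracker.

make_slab_fixture <- function() {
  lab <- slab_labels()
  inj <- array(FALSE, dim(lab)); inj[4:9, 4:9, 7:8] <- TRUE
  iface <- extract_interface(lab)
  list(lab = lab, inj = inj, iface = iface)
}

test_that("seed region honors d_w exactly on the flat slab", {
  fx <- make_slab_fixture()
  h <- rep(0.3, 3)
  wm <- fx$lab == 1L
  s0 <- build_seed_region(fx$inj, fx$iface, wm, 0, h)
  expect_identical(s0$mask, fx$inj)                 # d_w = 0: injection only
  s1 <- build_seed_region(fx$inj, fx$iface, wm, 0.3, h)
  # adds exactly one WM layer under the injection interface voxels
  added <- s1$mask & !s0$mask
  av <- which(added, arr.ind = TRUE)
  expect_true(all(av[, 3] == 6))                    # top WM layer
  expect_equal(sum(added), sum(fx$inj[, , 7]))      # one voxel per column
  s2 <- build_seed_region(fx$inj, fx$iface, wm, 0.6, h)
  # monotone nesting
  expect_true(all(s1$mask[s0$mask]))
  expect_true(all(s2$mask[s1$mask]))
  expect_true(all((s2$mask & !s1$mask) | !s2$mask | s1$mask))
  expect_error(build_seed_region(fx$inj, fx$iface, wm, -0.1, h), "nonnegative")
  expect_error(build_seed_region(array(FALSE, dim(fx$lab)), fx$iface, wm, 0, h),
               "empty")
})

test_that("FACT in a uniform field produces straight spanning streamlines", {
  tf <- uniform_field(c(20L, 8L, 8L), dir = c(1, 0, 0))
  seeds <- as.matrix(expand.grid(10L, 2:7, 2:7))
  ss <- fact_track(tf, seeds)
  expect_length(ss$streamlines, 36)
  for (i in seq_along(ss$streamlines)) {
    s <- ss$streamlines[[i]]
    ctr <- (seeds[i, ] - 0.5) * 0.3
    # maximum perpendicular deviation from the analytic line through the seed
    expect_lt(max(abs(s[, 2] - ctr[2])), 0.15)
    expect_lt(max(abs(s[, 3] - ctr[3])), 0.15)
    # spans the volume along x
    expect_lt(min(s[, 1]), 0.31)
    expect_gt(max(s[, 1]), 20 * 0.3 - 0.31)
  }
})

test_that("seeding requires FA >= start threshold", {
  tf <- uniform_field(c(8L, 8L, 8L), dir = c(1, 0, 0),
                      ev = c(8e-4, 7.6e-4, 7.6e-4))   # FA ~ 0.03
  expect_lt(max(tf$fa), 0.1)
  ss <- fact_track(tf, rbind(c(4L, 4L, 4L)))
  expect_length(ss$streamlines, 0)
  expect_warning(fact_track(tf, matrix(integer(0), 0, 3)), "empty seed")
})

test_that("a 90-degree crossing slab blocks straight passage at stop angle 70", {
  tf <- uniform_field(c(20L, 12L, 12L), dir = c(1, 0, 0))
  dims <- tf$dims; np <- prod(dims)
  # slab x = 13..15 oriented along y (winner-take-all crossing emulation)
  pdm <- matrix(tf$pd, np, 3)
  d6m <- tf$d6
  slab <- as.matrix(expand.grid(13:15, 1:12, 1:12))
  sl <- h_lin(slab, dims)
  ev <- c(1.7e-3, 2.5e-4)
  d6m[sl, ] <- matrix(c(ev[2], 0, 0, ev[1], 0, ev[2]), length(sl), 6, byrow = TRUE)
  tf2 <- tensor_field(d6m, dims, tf$voxel_size)
  seeds <- as.matrix(expand.grid(3L, 3:10, 3:10))
  ss <- fact_track(tf2, seeds)
  # no streamline reaches the far side of the slab
  beyond <- vapply(ss$streamlines, function(s) max(s[, 1]) > 15 * 0.3,
                   logical(1))
  expect_identical(sum(beyond), 0L)
})

test_that("FACT is deterministic", {
  ph <- make_phantom(default_phantom_config())
  iface <- extract_interface(ph$tissue$labels)
  sr <- build_seed_region(ph$tissue$injection, iface, ph$tissue$labels == 1L,
                          0.6, rep(0.3, 3))
  a <- fact_track(ph$tensors, sr)
  b <- fact_track(ph$tensors, sr)
  expect_identical(a$streamlines, b$streamlines)
})

test_that("select_streamlines applies the two-region contract", {
  tf <- uniform_field(c(20L, 8L, 8L), dir = c(1, 0, 0))
  dims <- tf$dims
  ss <- fact_track(tf, rbind(c(10L, 4L, 4L), c(10L, 6L, 6L)))
  ra <- array(FALSE, dims); ra[1:2, , ] <- TRUE
  rb <- array(FALSE, dims); rb[19:20, , ] <- TRUE
  sel <- select_streamlines(ss, ra, rb)
  expect_length(sel$streamlines, 2)           # both span the volume
  rb2 <- array(FALSE, dims); rb2[19:20, 6, 6] <- TRUE
  sel2 <- select_streamlines(ss, ra, rb2)     # only the (.,6,6) line passes
  expect_length(sel2$streamlines, 1)
  ra3 <- array(FALSE, dims); ra3[10, 4, 4] <- TRUE
  rb3 <- array(FALSE, dims); rb3[10, 4, 4] <- TRUE
  sel3 <- select_streamlines(ss, ra3, rb3)    # wholly inside one region: kept
  expect_length(sel3$streamlines, 1)
})

test_that("probabilistic tracker degenerates to straight lines at sigma 0", {
  tf <- uniform_field(c(20L, 8L, 8L), dir = c(1, 0, 0))
  dims <- tf$dims
  seeds <- rbind(c(10L, 4L, 4L))
  p <- tracking_params("prob", n_samples = 25L, distance_correction = FALSE)
  vis <- probabilistic_track(tf, seeds, NULL, NULL, p, orientation_sigma = 0,
                             rng_seed = 1)
  nz <- which(vis > 0, arr.ind = TRUE)
  expect_true(all(nz[, 2] == 4 & nz[, 3] == 4))   # support = the seeded column
  expect_true(all(nz[, 1] >= 1 & nz[, 1] <= 20))
  expect_gt(nrow(nz), 15)
})

test_that("waypoint filtering and distance correction behave as specified", {
  tf <- uniform_field(c(20L, 8L, 8L), dir = c(1, 0, 0))
  dims <- tf$dims
  seeds <- rbind(c(10L, 4L, 4L))
  # waypoint off the line: every sample discarded
  wp <- array(FALSE, dims); wp[10, 8, 8] <- TRUE
  p <- tracking_params("prob", n_samples = 10L, distance_correction = FALSE)
  vis <- probabilistic_track(tf, seeds, wp, NULL, p, orientation_sigma = 0,
                             rng_seed = 1)
  expect_true(all(vis == 0))
  expect_identical(attr(vis, "n_retained"), 0L)

  # on/off ratio equals the mean retained path length
  pon <- tracking_params("prob", n_samples = 10L, distance_correction = TRUE)
  von <- probabilistic_track(tf, seeds, NULL, NULL, pon, 0, rng_seed = 1)
  voff <- probabilistic_track(tf, seeds, NULL, NULL, p, 0, rng_seed = 1)
  ml <- attr(von, "mean_path_length")
  nz <- voff > 0
  expect_true(all(abs(von[nz] / voff[nz] - ml) < 1e-9))
  # mean path length close to the analytic spanning length (6 mm minus the
  # final partial steps of the two directed halves)
  expect_lt(abs(ml - 6) / 6, 0.05)

  # reproducibility and argument validation
  v2 <- probabilistic_track(tf, seeds, NULL, NULL, pon, 0.1, rng_seed = 5)
  v3 <- probabilistic_track(tf, seeds, NULL, NULL, pon, 0.1, rng_seed = 5)
  expect_identical(v2, v3)
  expect_error(probabilistic_track(tf, seeds, NULL, NULL,
                                   tracking_params("prob", n_samples = 0L)),
               "n_samples")
})

test_that("streamline vertices stay inside the volume and steps are bounded", {
  ph <- make_phantom(default_phantom_config())
  iface <- extract_interface(ph$tissue$labels)
  sr <- build_seed_region(ph$tissue$injection, iface, ph$tissue$labels == 1L,
                          0.6, rep(0.3, 3))
  ss <- fact_track(ph$tensors, sr)
  ext <- ph$tensors$dims * 0.3
  for (s in ss$streamlines) {
    expect_gte(nrow(s), 2)
    expect_true(all(s[, 1] >= -1e-9 & s[, 1] <= ext[1] + 1e-9 &
                    s[, 2] >= -1e-9 & s[, 2] <= ext[2] + 1e-9 &
                    s[, 3] >= -1e-9 & s[, 3] <= ext[3] + 1e-9))
    steps <- sqrt(rowSums(diff(s)^2))
    expect_true(all(steps <= ss$step_length + 1e-9))
  }
})

test_that("ROIs reached are non-decreasing in seed depth on the crossing phantom", {
  ph <- make_phantom(default_phantom_config(crossing = TRUE))
  iface <- extract_interface(ph$tissue$labels)
  reached <- lapply(c(0, 0.3, 0.6), function(dw) {
    sr <- build_seed_region(ph$tissue$injection, iface, ph$tissue$labels == 1L,
                            dw, rep(0.3, 3))
    ss <- fact_track(ph$tensors, sr)
    nd <- regional_counts(streamline_interface_ddm(ss, iface), ph$tissue$roi_map)
    names(nd)[nd > 0]
  })
  expect_true(all(reached[[1]] %in% reached[[2]]))
  expect_true(all(reached[[2]] %in% reached[[3]]))
})
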