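# Micrograph pipeline: illumination correction, segmentation, boundary
# fitting, crossing extraction, and DDM gridding.

test_that("black top-hat maps a flat image to zero and removes ramps", {
  flat <- micrograph(matrix(0.6, 128, 128), 0.87)
  out <- tophat_correct(flat, 10)
  expect_true(all(out$image == 0))
  expect_error(tophat_correct(flat, 200), "larger than the image")

  # planted dark fiber on a linear ramp: contrast after correction within 10%
  # of the ramp-free reference
  mk <- function(grad) {
    pl <- data.frame(type = "fiber", x = 64, y = 64, angle = 0.4, length = 40,
                     width = 5, intensity = 0.3)
    make_micrograph(pl, rbind(c(2, 20), c(60, 22), c(126, 24)),
                    size = c(128, 128), illumination_gradient = grad,
                    noise = 0, rng_seed = 1)$micrograph
  }
  c_ramp <- tophat_correct(mk(0.2), 10)
  c_flat <- tophat_correct(mk(0), 10)
  peak_ramp <- max(c_ramp$image); peak_flat <- max(c_flat$image)
  expect_lt(abs(peak_ramp - peak_flat) / peak_flat, 0.1)

  # near idempotence: a second pass (bright-foreground polarity) changes
  # little energy
  once <- c_flat$image
  twice <- tophat_correct(micrograph(once, 0.87), 10, foreground = "bright")$image
  expect_lt(sum((twice - once)^2) / sum(once^2), 0.05)
})

test_that("shape filters keep fibers and reject round clutter", {
  fx <- test_micrograph(21, noise = 0, n_crossing = 3, n_noncrossing = 2,
                        n_clutter = 3, n_speck = 0)
  obj <- segment_fiber_objects(tophat_correct(fx$mg$micrograph, 12))
  expect_equal(nrow(obj$objects), 5)          # 5 fibers survive, 3 discs do not
  expect_true(all(obj$objects$elongation >= 20))

  # lowering the elongation cutoff admits the discs
  obj2 <- segment_fiber_objects(tophat_correct(fx$mg$micrograph, 12),
                                filters = list(area_min = 20, area_max = 1e5,
                                               min_elongation = 5))
  expect_gt(nrow(obj2$objects), nrow(obj$objects))

  # empty image: zero objects, not an error
  blank <- micrograph(matrix(0.7, 256, 256), 0.87)
  obj0 <- segment_fiber_objects(tophat_correct(blank, 12))
  expect_equal(nrow(obj0$objects), 0)
})

test_that("boundary curve fitting is faithful and banded at the stated width", {
  # collinear markers -> straight strip of the requested width
  mk <- cbind(seq(10, 110, length.out = 6), rep(40, 6))
  bc <- fit_boundary_curve(mk, width = 6)
  band <- rasterize_band(bc, c(128, 80))
  rows <- which(apply(band, 1, any))
  for (r in intersect(rows, 15:105)) {
    ys <- range(which(band[r, ]))
    expect_lte(diff(ys) + 1, 7)               # 6 +- 1 px thick
    expect_gte(diff(ys) + 1, 5)
  }

  # markers on a circle: fitted curve deviates < 1 px radially
  th <- seq(0, 2 * pi, length.out = 17)
  circ <- cbind(64 + 30 * cos(th), 64 + 30 * sin(th))
  bcc <- fit_boundary_curve(circ, width = 6)
  rad <- sqrt((bcc$polyline[, 1] - 64)^2 + (bcc$polyline[, 2] - 64)^2)
  expect_lt(max(abs(rad - 30)), 1)

  expect_warning(fit_boundary_curve(rbind(c(1, 1), c(1, 1), c(5, 5), c(9, 9),
                                          c(13, 10))),
                 "duplicate")
})

test_that("crossing extraction matches planted truth on clean images", {
  for (seed in c(31, 32)) {
    fx <- test_micrograph(seed, noise = 0)
    expect_equal(count_pipeline(fx$mg, fx$curve), fx$mg$truth_crossing)
  }
  # objects far from the band are excluded even if segmented
  fx <- test_micrograph(33, noise = 0, n_crossing = 4, n_noncrossing = 6)
  obj <- segment_fiber_objects(tophat_correct(fx$mg$micrograph, 12))
  expect_equal(nrow(obj$objects), 10)
  expect_equal(extract_crossing_fibers(obj, fx$curve)$count, 4)

  # zero planted objects -> pipeline returns 0 (with noise present)
  bnd <- default_boundary(c(512, 512))
  mg0 <- make_micrograph(NULL, bnd, size = c(512, 512), noise = 0.03,
                         rng_seed = 2)
  expect_identical(mg0$truth_crossing, 0L)
  expect_equal(count_pipeline(mg0, fit_boundary_curve(bnd)), 0)
})

test_that("boundary shifts leave counts of long perpendicular fibers stable", {
  fx <- test_micrograph(41, noise = 0.03, n_crossing = 8, n_noncrossing = 4)
  obj <- segment_fiber_objects(tophat_correct(fx$mg$micrograph, 12))
  bs <- boundary_shift_robustness(obj, fx$curve, 20)
  expect_identical(bs$count[bs$shift == 0], bs$count[2])
  expect_lt(attr(bs, "max_relative_change"), 0.05)
  bs0 <- boundary_shift_robustness(obj, fx$curve, 0)
  expect_equal(length(unique(bs0$count)), 1)
  expect_error(boundary_shift_robustness(obj, fx$curve, 5000), "leaves the image")

  # fibers much shorter than the shift: counts drop at both offsets
  bnd <- default_boundary(c(512, 512))
  pl <- plant_micrograph_objects(6, 0, 0, 0, bnd, c(512, 512), rng_seed = 5,
                                 fiber_length = c(18, 24), fiber_width = c(3, 5),
                                 min_sep = 60)
  mg <- make_micrograph(pl, bnd, size = c(512, 512), noise = 0, rng_seed = 5)
  objs <- segment_fiber_objects(tophat_correct(mg$micrograph, 8))
  bss <- boundary_shift_robustness(objs, fit_boundary_curve(bnd), 40)
  expect_lt(bss$count[1], bss$count[2])
  expect_lt(bss$count[3], bss$count[2])
})

test_that("grid_counts conserves mass with the study's unit size", {
  d <- grid_counts(cbind(0, 0), 6660)
  expect_equal(d$unit_size, c(26.015625, 26.015625))   # 6660 / 256
  expect_equal(d$counts[1, 1], 1)
  expect_equal(sum(d$counts), 1)

  set.seed(8)
  pts <- cbind(runif(1000, 0, 6660), runif(1000, 0, 6660))
  dd <- grid_counts(pts, 6660)
  expect_equal(sum(dd$counts), 1000)
  expect_true(all(dd$counts == floor(dd$counts)))
  # permutation invariance
  dd2 <- grid_counts(pts[sample(1000), ], 6660)
  expect_identical(dd$counts, dd2$counts)
  # far-edge clamping
  de <- grid_counts(cbind(6660, 6660), 6660)
  expect_equal(de$counts[256, 256], 1)
  expect_error(grid_counts(cbind(-1, 5), 6660), "outside")

  # soma gridding shares the implementation, with its own provenance
  ds <- count_somas(pts, 6660)
  expect_identical(ds$counts, dd$counts)
  expect_identical(ds$provenance, "bda_soma")
  d0 <- count_somas(matrix(numeric(0), 0, 2), 6660)
  expect_equal(sum(d0$counts), 0)
})

test_that("segmentation is invariant to a constant offset after top-hat", {
  fx <- test_micrograph(51, noise = 0, n_crossing = 5, n_noncrossing = 3)
  img2 <- micrograph(pmax(pmin(fx$mg$micrograph$image - 0.1, 1), 0), 0.87)
  n1 <- nrow(segment_fiber_objects(tophat_correct(fx$mg$micrograph, 12))$objects)
  n2 <- nrow(segment_fiber_objects(tophat_correct(img2, 12))$objects)
  expect_equal(n1, n2)
})
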