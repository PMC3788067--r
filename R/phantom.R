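# Synthetic phantom: tissue labels, ROIs, fiber bundles, tensor field.
#
# The phantom is a flat-slab "cortex": a gray-matter slab on top of white
# matter, with a tracer-injection patch in GM and projection ROIs arranged on
# a ring around it. Each ROI is connected to the injection by a curved white
# matter bundle (down from the injection, radially outward in its own depth
# lane, up into the ROI). An optional crossing bundle occludes the top white
# matter layer under the injection along one pathway, emulating the
# partial-volume crossing-fiber failure mode of single-tensor tracking.

#' Phantom configuration
#'
#' @param grid_shape integer 3-vector of voxel counts.
#' @param voxel_size numeric 3-vector, mm.
#' @param wm_z,gm_z inclusive voxel index ranges (z) of white and gray matter
#'   slabs; everything else is background.
#' @param injection list with integer ranges `x`, `y`, `z` (voxel indices) of
#'   the injection patch (must lie in GM), or `NULL`.
#' @param rois data.frame with columns `id, x1, x2, y1, y2, z1, z2`
#'   (inclusive voxel ranges of projection ROI patches in GM).
#' @param bundles list of bundle specs: each a list with `name`,
#'   `target_roi` (ROI id or `NA`), `waypoints` (k x 3 matrix, mm),
#'   `radius` (mm; scalar or 3-vector for anisotropic cross-sections),
#'   `axon_count`, `soma_count`, optional `bend_radius` (mm).
#' @param crossing optional occluding bundle spec (same fields, `target_roi`
#'   normally `NA`); by convention its `axon_count` exceeds every regular
#'   bundle's so it wins partial-volume contests.
#' @param bundle_ev,wm_ev,gm_ev eigenvalues (mm^2/s) of the prolate bundle
#'   tensor, background white matter and gray matter tensors. Defaults give
#'   FA of about 0.84, 0.15 and 0.13.
#' @param noise_sigma Rician noise scale as a fraction of the b0 signal.
#' @param rng_seed integer seed controlling all phantom randomness.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(64L, 64L, 64L),
                           voxel_size = c(0.3, 0.3, 0.3),
                           wm_z = c(5L, 50L),
                           gm_z = c(51L, 58L),
                           injection = NULL,
                           rois = NULL,
                           bundles = list(),
                           crossing = NULL,
                           bundle_ev = c(1.7e-3, 2.5e-4, 2.5e-4),
                           wm_ev = c(0.88e-3, 0.66e-3, 0.66e-3),
                           gm_ev = c(0.86e-3, 0.69e-3, 0.69e-3),
                           noise_sigma = 1 / 25,
                           rng_seed = 1L) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 8),
            length(voxel_size) == 3, all(voxel_size > 0),
            noise_sigma >= 0)
  if (wm_z[2] + 1 != gm_z[1]) stop("gray matter slab must sit directly on white matter")
  for (b in c(bundles, if (!is.null(crossing)) list(crossing))) {
    if (any(b$radius <= 0)) stop("bundle radius must be positive: ", b$name)
    if (b$axon_count < 0) stop("axon_count must be nonnegative: ", b$name)
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 wm_z = as.integer(wm_z), gm_z = as.integer(gm_z),
                 injection = injection, rois = rois, bundles = bundles,
                 crossing = crossing, bundle_ev = bundle_ev, wm_ev = wm_ev,
                 gm_ev = gm_ev, noise_sigma = noise_sigma,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_config")
}

#' Default ring phantom
#'
#' 64^3 voxels at 0.3 mm isotropic (the study's acquisition voxel size) with a
#' 20 x 20 voxel injection patch and 8 projection ROIs on a ring, whose
#' ground-truth axon counts span three orders of magnitude. Bundle calibers
#' grow sublinearly with axon count (packing density is not constant across
#' tracts) so that all bundles stay resolvable at 0.3 mm.
#'
#' @param crossing if `TRUE`, add an occluding crossing bundle in the top
#'   white matter layer under the injection, across the largest bundle's
#'   descending column.
#' @param noise_sigma Rician noise scale relative to b0 (default 1/25,
#'   i.e. SNR around 25).
#' @param rng_seed integer seed.
#' @return a `phantom_config`.
#' @export
default_phantom_config <- function(crossing = FALSE, noise_sigma = 1 / 25,
                                   rng_seed = 1L) {
  h <- 0.3
  ctr <- c(32, 32) * h                      # grid center (mm), 64 voxels
  theta <- (0:7) * pi / 4
  # calibers alternate around the ring (adjacent columns never overlap) and
  # stay >= ~1 voxel so every true pathway is geometrically traversable at
  # the acquisition resolution
  r_vox <- c(3.4, 1.3, 2.3, 1.15, 2.8, 1.05, 1.8, 1.45)
  counts <- c(2000L, 750L, 300L, 120L, 50L, 20L, 8L, 3L)   # by caliber rank
  lane_z <- c(40, 33, 27.1, 22.2, 18, 14.5, 11.5, 8.8)     # by caliber rank
  rk <- rank(-r_vox, ties.method = "first")
  col_ring <- 7; roi_ring <- 20
  z_top <- (52 - 0.5) * h                   # waypoint z inside GM
  rois <- do.call(rbind, lapply(1:8, function(k) {
    cx <- 32.5 + roi_ring * cos(theta[k]); cy <- 32.5 + roi_ring * sin(theta[k])
    half <- ceiling(r_vox[k]) + 1
    data.frame(id = k,
               x1 = round(cx - half), x2 = round(cx + half) - 1L,
               y1 = round(cy - half), y2 = round(cy + half) - 1L,
               z1 = 51L, z2 = 54L)
  }))
  # snap vertical column centers onto the voxel-center lattice so thin tubes
  # cover the voxels that FACT actually transits
  snap <- function(x) (round(x / h - 0.5) + 0.5) * h
  bundles <- lapply(1:8, function(k) {
    a <- snap(ctr + col_ring * h * c(cos(theta[k]), sin(theta[k])))
    b <- snap(ctr + roi_ring * h * c(cos(theta[k]), sin(theta[k])))
    zl <- (lane_z[rk[k]] - 0.5) * h
    wp <- rbind(c(a, z_top), c(a, zl), c(b, zl), c(b, z_top))
    list(name = paste0("bundle", k), target_roi = k, waypoints = wp,
         radius = r_vox[k] * h, axon_count = counts[rk[k]],
         soma_count = counts[rk[k]], bend_radius = 1.2)
  })
  cross <- NULL
  if (crossing) {
    xocc <- ctr[1] + col_ring * h            # over bundle 1's column (theta = 0)
    zocc <- (50 - 0.5) * h                   # top white-matter layer
    wp <- rbind(c(xocc, 20 * h, zocc), c(xocc, 45 * h, zocc))
    cross <- list(name = "crossing", target_roi = NA, waypoints = wp,
                  radius = c(3.6 * h, 3.6 * h, 0.45 * h),
                  axon_count = 10000L, soma_count = 0L, bend_radius = 1.2)
  }
  phantom_config(injection = list(x = c(22L, 43L), y = c(22L, 43L), z = c(51L, 53L)),
                 rois = rois, bundles = bundles, crossing = cross,
                 noise_sigma = noise_sigma, rng_seed = rng_seed)
}

#' Tensor field container
#'
#' @param d6 matrix (n_voxel x 6) or 4D array of tensor components in the
#'   order Dxx, Dxy, Dxz, Dyy, Dyz, Dzz (mm^2/s).
#' @param dims grid dimensions.
#' @param voxel_size mm.
#' @param mask logical 3D array of valid voxels.
#' @return object of class `tensor_field` with per-voxel `fa` and principal
#'   direction `pd` arrays computed by eigendecomposition.
#' @export
tensor_field <- function(d6, dims, voxel_size, mask = NULL) {
  nvox <- prod(dims)
  if (is.array(d6) && length(dim(d6)) == 4) d6 <- matrix(d6, nvox, 6)
  stopifnot(nrow(d6) == nvox, ncol(d6) == 6)
  if (is.null(mask)) mask <- array(TRUE, dims)
  fa <- numeric(nvox); pd <- matrix(0, nvox, 3)
  idx <- which(as.logical(mask))
  if (length(idx)) {
    ee <- eig3_sym(d6[idx, , drop = FALSE])
    fa[idx] <- fa_from_eigenvalues(ee$values)
    pd[idx, ] <- ee$v1
  }
  structure(list(d6 = d6, dims = as.integer(dims), voxel_size = voxel_size,
                 mask = array(as.logical(mask), dims),
                 fa = array(fa, dims), pd = array(pd, c(dims, 3))),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("tensor_field:", paste(x$dims, collapse = "x"), "voxels,",
      sum(x$mask), "in mask, FA range",
      paste(signif(range(x$fa[x$mask]), 3), collapse = "-"), "\n")
  invisible(x)
}

prolate_d6 <- function(ev, t) {
  # D = l3 I + (l1 - l2) t t' for ev = (l1, l2, l2); general: use l2 = l3
  l1 <- ev[1]; l2 <- ev[2]
  c(l2 + (l1 - l2) * t[1]^2, (l1 - l2) * t[1] * t[2], (l1 - l2) * t[1] * t[3],
    l2 + (l1 - l2) * t[2]^2, (l1 - l2) * t[2] * t[3], l2 + (l1 - l2) * t[3]^2)
}

# rasterize one bundle: returns linear voxel ids (restricted to WM) and unit
# tangents of the nearest centerline sample
rasterize_bundle <- function(bundle, dims, voxel_size, wm_vec) {
  h <- voxel_size
  rad <- bundle$radius
  if (length(rad) == 1) rad <- rep(rad, 3)
  path <- rounded_path(bundle$waypoints, bend_radius = bundle$bend_radius %||% 1.2,
                       step = 0.45 * min(h))
  pts <- path$points
  lims <- dims * h
  out <- pts < 0 | sweep(pts, 2, lims, `>`)
  if (any(out)) stop("bundle leaves the grid: ", bundle$name)
  nvox <- prod(dims)
  dmin <- rep(Inf, nvox)
  near <- integer(nvox)
  rw <- ceiling(rad / h)                     # window half-width in voxels
  offs <- as.matrix(expand.grid(-rw[1]:rw[1], -rw[2]:rw[2], -rw[3]:rw[3]))
  for (i in seq_len(nrow(pts))) {
    v0 <- pos_to_voxel(pts[i, ], h)
    cand <- sweep(offs, 2, as.integer(v0), `+`)
    ok <- in_grid(cand, dims)
    cand <- cand[ok, , drop = FALSE]
    if (!nrow(cand)) next
    cc <- vox_center(cand, h)
    dd <- sqrt(((cc[, 1] - pts[i, 1]) / rad[1])^2 +
               ((cc[, 2] - pts[i, 2]) / rad[2])^2 +
               ((cc[, 3] - pts[i, 3]) / rad[3])^2)
    li <- lin_index(cand, dims)
    upd <- dd < dmin[li]
    dmin[li[upd]] <- dd[upd]
    near[li[upd]] <- i
  }
  sel <- which(dmin <= 1 & wm_vec)
  list(lin = sel, tangents = path$tangents[near[sel], , drop = FALSE])
}

#' Generate the phantom tissue model and ground-truth tensor field
#'
#' White matter voxels inside a bundle receive a prolate tensor aligned with
#' the local centerline tangent; where bundles overlap, the bundle with the
#' larger axon count wins (single-tensor partial-volume emulation). Gray
#' matter gets a low-anisotropy (FA < 0.15) radially oriented tensor,
#' remaining white matter a mildly anisotropic one. Deterministic given the
#' config.
#'
#' @param config a [phantom_config()].
#' @return list with `tissue` (class `tissue_model`: `labels` 0 = background,
#'   1 = WM, 2 = GM; `injection` logical array; `roi_map` integer array;
#'   `bundle_truth` data.frame) and `tensors` (a [tensor_field()]).
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  dims <- config$grid_shape; h <- config$voxel_size
  nvox <- prod(dims)
  zi <- slice.index(array(0L, dims), 3)
  labels <- array(0L, dims)
  labels[zi >= config$wm_z[1] & zi <= config$wm_z[2]] <- 1L
  labels[zi >= config$gm_z[1] & zi <= config$gm_z[2]] <- 2L

  injection <- array(FALSE, dims)
  if (!is.null(config$injection)) {
    inj <- config$injection
    injection[inj$x[1]:inj$x[2], inj$y[1]:inj$y[2], inj$z[1]:inj$z[2]] <- TRUE
    if (any(injection & labels != 2L)) {
      # allowed to dip at most 2 voxels into WM below GM
      bad <- injection & labels != 2L & !(labels == 1L & zi >= config$gm_z[1] - 2)
      if (any(bad)) stop("injection region extends outside GM and adjacent WM")
    }
  }
  roi_map <- array(0L, dims)
  if (!is.null(config$rois)) {
    for (i in seq_len(nrow(config$rois))) {
      r <- config$rois[i, ]
      blk <- roi_map[r$x1:r$x2, r$y1:r$y2, r$z1:r$z2]
      if (any(blk != 0L)) stop("projection ROIs overlap: id ", r$id)
      roi_map[r$x1:r$x2, r$y1:r$y2, r$z1:r$z2] <- r$id
    }
    if (any(roi_map > 0L & injection)) stop("injection overlaps a projection ROI")
    roi_map[labels != 2L] <- 0L              # ROIs are cortical
  }

  # base tensors
  d6 <- matrix(0, nvox, 6)
  zhat <- c(0, 0, 1)
  wm_vec <- as.vector(labels == 1L)
  wm_lin <- which(wm_vec)
  gm_lin <- which(labels == 2L)
  d6[wm_lin, ] <- matrix(prolate_d6(config$wm_ev, zhat), length(wm_lin), 6, byrow = TRUE)
  d6[gm_lin, ] <- matrix(prolate_d6(config$gm_ev, zhat), length(gm_lin), 6, byrow = TRUE)

  # bundles, winner-take-all by axon count
  allb <- config$bundles
  if (!is.null(config$crossing)) allb <- c(allb, list(config$crossing))
  winner <- rep(-Inf, nvox)
  for (b in allb) {
    if (!is.na(b$target_roi) && !is.null(config$rois)) {
      ends <- b$waypoints[c(1, nrow(b$waypoints)), , drop = FALSE]
      ev <- pos_to_voxel(ends[2, ], h)
      if (roi_map[ev[1], ev[2], ev[3]] != b$target_roi)
        stop("bundle endpoint not inside its ROI: ", b$name)
    }
    rb <- rasterize_bundle(b, dims, h, wm_vec)
    upd <- b$axon_count > winner[rb$lin]
    li <- rb$lin[upd]
    winner[li] <- b$axon_count
    tg <- rb$tangents[upd, , drop = FALSE]
    for (j in seq_along(li)) d6[li[j], ] <- prolate_d6(config$bundle_ev, tg[j, ])
  }

  truth <- do.call(rbind, lapply(config$bundles, function(b) {
    data.frame(roi = b$target_roi, axon_count = b$axon_count,
               soma_count = b$soma_count, radius_mm = b$radius[1])
  }))
  if (!is.null(truth)) truth <- truth[order(truth$roi), , drop = FALSE]

  tissue <- structure(list(labels = labels, injection = injection,
                           roi_map = roi_map, bundle_truth = truth,
                           config = config),
                      class = "tissue_model")
  tensors <- tensor_field(d6, dims, h, mask = labels > 0L)
  list(tissue = tissue, tensors = tensors)
}

#' @export
print.tissue_model <- function(x, ...) {
  cat("tissue_model:", paste(dim(x$labels), collapse = "x"),
      "| WM:", sum(x$labels == 1L), "GM:", sum(x$labels == 2L),
      "| injection:", sum(x$injection),
      "| ROIs:", length(setdiff(unique(as.vector(x$roi_map)), 0L)), "\n")
  invisible(x)
}
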