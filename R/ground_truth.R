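# Ground-truth tracer data: interface-crossing fiber centroids in micrograph
# space and labeled-soma positions in gray matter, with per-ROI totals equal
# to the phantom's bundle truth by construction.

#' Generate ground-truth tracer fibers and somas
#'
#' For each projection ROI, places exactly `axon_count` interface-crossing
#' fiber centroids in micrograph-space coordinates under the ROI (uniform in
#' the bundle footprint disc clipped to the ROI), and `soma_count` soma
#' positions inside the ROI's gray matter. The phantom is reciprocal by
#' default (soma_count = axon_count), emulating reciprocal cortico-cortical
#' connections.
#'
#' @param tissue a `tissue_model` from [make_phantom()].
#' @param interface an [extract_interface()] result for the same tissue.
#' @param image_size micrograph-space extent in px (the standard micrograph
#'   is 6660 px across the field of view).
#' @param rng_seed integer seed.
#' @return list with `fiber_centroids` (data.frame roi, x, y in px),
#'   `somas` (data.frame roi, x, y, z in mm), and `px_per_mm`.
#' @export
make_ground_truth_fibers <- function(tissue, interface, image_size = 6660,
                                     rng_seed = 1L) {
  stopifnot(inherits(tissue, "tissue_model"))
  truth <- tissue$bundle_truth
  if (is.null(truth)) stop("tissue model has no bundle truth")
  cfg <- tissue$config
  h <- cfg$voxel_size
  fov_mm <- cfg$grid_shape[1] * h[1]
  px_per_mm <- image_size / fov_mm
  set.seed(derive_seed(rng_seed, "ground_truth"))
  fib <- list(); som <- list()
  iface_roi <- tissue$roi_map[lin_index(interface$voxels, dim(tissue$labels))]
  for (i in seq_len(nrow(truth))) {
    roi <- truth$roi[i]
    ivox <- interface$voxels[iface_roi == roi, , drop = FALSE]
    if (nrow(ivox) == 0) stop("ROI ", roi, " has no interface voxels")
    rr <- cfg$rois[cfg$rois$id == roi, ]
    # bundle footprint: disc of the bundle radius around the ROI center,
    # clipped to the ROI rectangle (all in mm, xy-plane)
    cx <- (rr$x1 + rr$x2) / 2 * h[1]; cy <- (rr$y1 + rr$y2) / 2 * h[2]
    rad <- truth$radius_mm[i]
    n <- truth$axon_count[i]
    draw_xy <- function(n) {
      out <- matrix(numeric(0), 0, 2)
      while (nrow(out) < n) {
        m <- 2 * (n - nrow(out)) + 8
        th <- stats::runif(m, 0, 2 * pi); u <- sqrt(stats::runif(m))
        x <- cx + rad * u * cos(th); y <- cy + rad * u * sin(th)
        ok <- x >= (rr$x1 - 1) * h[1] & x <= rr$x2 * h[1] &
          y >= (rr$y1 - 1) * h[2] & y <= rr$y2 * h[2]
        out <- rbind(out, cbind(x[ok], y[ok]))
      }
      out[seq_len(n), , drop = FALSE]
    }
    if (n > 0) {
      xy <- draw_xy(n)
      fib[[length(fib) + 1]] <- data.frame(roi = roi, x = xy[, 1] * px_per_mm,
                                           y = xy[, 2] * px_per_mm)
    }
    ns <- truth$soma_count[i]
    if (ns > 0) {
      xy <- draw_xy(ns)
      z <- stats::runif(ns, (rr$z1 - 1) * h[3], rr$z2 * h[3])
      som[[length(som) + 1]] <- data.frame(roi = roi, x = xy[, 1], y = xy[, 2], z = z)
    }
  }
  empty_fib <- data.frame(roi = integer(0), x = numeric(0), y = numeric(0))
  empty_som <- data.frame(roi = integer(0), x = numeric(0), y = numeric(0),
                          z = numeric(0))
  list(fiber_centroids = if (length(fib)) do.call(rbind, fib) else empty_fib,
       somas = if (length(som)) do.call(rbind, som) else empty_som,
       px_per_mm = px_per_mm)
}
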