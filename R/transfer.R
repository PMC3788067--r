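# Carrying density distribution maps between spaces: Jacobian-compensated
# resampling, white/gray matter interface extraction, and projection of
# gray-matter densities onto the interface.

#' Extract the white/gray matter interface
#'
#' Interface voxels are the gray matter voxels 6-adjacent to at least one
#' white matter voxel (the deepest cortical layer). Normals point from gray
#' towards white matter.
#'
#' @param labels integer 3D array: 0 background, 1 WM, 2 GM.
#' @return object of class `interface_set`: `voxels` (n x 3, ordered by
#'   linear index), `mask`, `normals` (n x 3), `dims`.
#' @export
extract_interface <- function(labels) {
  dims <- dim(labels)
  gm <- labels == 2L; wm <- labels == 1L
  mask <- gm & dilate6(wm) & !wm
  vox <- which_vox(mask)
  if (nrow(vox) == 0) stop("no white/gray matter interface found")
  normals <- matrix(0, nrow(vox), 3)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  for (i in seq_len(6)) {
    nb <- sweep(vox, 2, offs[i, ], `+`)
    ok <- in_grid(nb, dims)
    iswm <- rep(FALSE, nrow(vox))
    iswm[ok] <- wm[lin_index(nb[ok, , drop = FALSE], dims)]
    normals <- normals + outer(as.numeric(iswm), offs[i, ])
  }
  nn <- sqrt(rowSums(normals^2))
  normals[nn > 0, ] <- normals[nn > 0, , drop = FALSE] / nn[nn > 0]
  structure(list(voxels = vox, mask = mask, normals = normals, dims = dims),
            class = "interface_set")
}

#' Surface density distribution map
#'
#' Density values attached to the voxels of a white/gray matter interface.
#'
#' @param interface an [extract_interface()] result.
#' @param values numeric vector aligned with `interface$voxels` (nonnegative).
#' @param provenance one of `"bda_fiber"`, `"bda_soma"`, `"ds_stream"`,
#'   `"ds_terminal"`, `"prob_stream"`.
#' @return object of class `surface_ddm`.
#' @export
surface_ddm <- function(interface, values, provenance) {
  stopifnot(inherits(interface, "interface_set"),
            length(values) == nrow(interface$voxels), all(values >= 0))
  structure(list(interface = interface, values = as.numeric(values),
                 provenance = provenance),
            class = "surface_ddm")
}

#' @export
print.surface_ddm <- function(x, ...) {
  cat("surface_ddm (", x$provenance, "): ", sum(x$values > 0), "/",
      length(x$values), " interface voxels, total mass ",
      signif(sum(x$values), 6), "\n", sep = "")
  invisible(x)
}

# n-linear interpolation of a cell-centered grid at continuous coords (grid
# units, cell centers at i - 0.5); outside the grid -> 0
interp_grid <- function(arr, coords) {
  d <- dim(arr); nd <- length(d)
  x <- sweep(rbind(coords), 2, rep(0.5, nd), `-`)   # cell-center frame
  i0 <- floor(x); f <- x - i0
  val <- numeric(nrow(x))
  corners <- as.matrix(do.call(expand.grid, rep(list(0:1), nd)))
  for (ci in seq_len(nrow(corners))) {
    idx <- sweep(i0, 2, corners[ci, ], `+`) + 1   # 1-based cell index
    w <- rep(1, nrow(x))
    for (ax in seq_len(nd))
      w <- w * ifelse(corners[ci, ax] == 1, f[, ax], 1 - f[, ax])
    ok <- rep(TRUE, nrow(x))
    for (ax in seq_len(nd)) ok <- ok & idx[, ax] >= 1 & idx[, ax] <= d[ax]
    if (any(ok & w > 0)) {
      sel <- which(ok & w > 0)
      lin <- idx[sel, 1]
      mult <- 1
      for (ax in 2:nd) { mult <- mult * d[ax - 1]; lin <- lin + (idx[sel, ax] - 1) * mult }
      val[sel] <- val[sel] + w[sel] * arr[lin]
    }
  }
  val
}

#' Transfer a density map through a deformation field
#'
#' Resamples the input density at the pulled-back location of every output
#' cell and multiplies by the Jacobian determinant of the (output-to-input)
#' map, so integrated counts are preserved under the change of variables.
#' Chaining two transfers composes with the composed field.
#'
#' @param ddm numeric matrix/array (2D or 3D density), or a `ddm2d` object.
#' @param field a [deformation_field()] defined on the output grid, mapping
#'   output coordinates to input coordinates.
#' @param supersample quadrature points per output cell per axis: each output
#'   cell averages the compensated pull-back over `supersample^d` subpoints
#'   (displacement and determinant interpolated between grid nodes), which
#'   keeps integrated counts accurate under curved fields. 1 = plain
#'   cell-center sampling.
#' @return density in the output space (same class as the input; `ddm2d`
#'   counts become real-valued).
#' @export
transfer_ddm <- function(ddm, field, supersample = 3L) {
  stopifnot(inherits(field, "deformation_field"), supersample >= 1)
  is_ddm2d <- inherits(ddm, "ddm2d")
  arr <- if (is_ddm2d) ddm$counts else ddm
  stopifnot(length(dim(arr)) == field$ndim)
  if (min(field$jacobian_det) <= 0)
    stop("deformation field has nonpositive Jacobian determinant")
  nd <- field$ndim
  grids <- lapply(field$dim, function(n) seq_len(n) - 0.5)
  coords <- as.matrix(do.call(expand.grid, grids))
  ss <- as.integer(supersample)
  if (all(field$displacement == 0) && identical(dim(arr), as.integer(field$dim))) {
    # identity map: no resampling, only determinant compensation
    out <- as.vector(arr) * as.vector(field$jacobian_det)
  } else if (ss == 1L) {
    src <- coords + matrix(field$displacement, nrow(coords), nd)
    out <- interp_grid(arr, src) * as.vector(field$jacobian_det)
  } else {
    off1 <- (seq_len(ss) - 0.5) / ss - 0.5
    offs <- as.matrix(do.call(expand.grid, rep(list(off1), nd)))
    ucomp <- lapply(seq_len(nd), function(ax)
      if (nd == 2) field$displacement[, , ax] else field$displacement[, , , ax])
    out <- 0
    for (q in seq_len(nrow(offs))) {
      p <- sweep(coords, 2, offs[q, ], `+`)
      u <- vapply(ucomp, function(uc) interp_grid(uc, p), numeric(nrow(coords)))
      j <- interp_grid(field$jacobian_det, p)
      out <- out + interp_grid(arr, p + u) * j
    }
    out <- out / nrow(offs)
  }
  out <- array(out, field$dim)
  if (is_ddm2d) {
    res <- ddm
    res$counts <- out
    res$deformed <- TRUE
    res
  } else out
}

#' Project gray-matter densities onto the interface
#'
#' Adds the density of every nonzero gray-matter voxel to the closest
#' interface voxel (Euclidean distance between voxel centers; ties broken by
#' the smallest linear voxel index). Total mass is preserved exactly.
#'
#' @param density_volume 3D array of nonnegative densities (supported in GM).
#' @param interface an [extract_interface()] result.
#' @param voxel_size mm.
#' @param provenance provenance tag of the output.
#' @return a [surface_ddm()].
#' @export
project_to_interface <- function(density_volume, interface, voxel_size,
                                 provenance = "bda_soma") {
  stopifnot(inherits(interface, "interface_set"))
  if (nrow(interface$voxels) == 0) stop("empty interface")
  dims <- interface$dims
  src <- which(density_volume != 0)
  vals <- numeric(nrow(interface$voxels))
  if (length(src)) {
    iface_ctr <- vox_center(interface$voxels, voxel_size)
    src_ijk <- lin_to_ijk(src, dims)
    src_ctr <- vox_center(src_ijk, voxel_size)
    iface_lin <- lin_index(interface$voxels, dims)
    ord <- order(iface_lin)                  # tie-break: smallest linear index
    iface_ctr <- iface_ctr[ord, , drop = FALSE]
    chunk <- max(1L, floor(2e6 / nrow(iface_ctr)))
    for (s in split(seq_along(src), ceiling(seq_along(src) / chunk))) {
      dd <- outer(src_ctr[s, 1], iface_ctr[, 1], `-`)^2 +
        outer(src_ctr[s, 2], iface_ctr[, 2], `-`)^2 +
        outer(src_ctr[s, 3], iface_ctr[, 3], `-`)^2
      nearest <- max.col(-dd, ties.method = "first")
      tgt <- ord[nearest]
      for (j in seq_along(s))
        vals[tgt[j]] <- vals[tgt[j]] + density_volume[src[s[j]]]
    }
  }
  surface_ddm(interface, vals, provenance)
}
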