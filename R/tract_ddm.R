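# Converting tracking output into interface densities: streamline crossing
# counts, streamline-terminal counts, and probabilistic visitation restricted
# to the interface.

#' Streamline crossing density on the interface
#'
#' Counts, per interface voxel, the number of distinct streamlines entering
#' that voxel (multiple entries of one streamline into one voxel count once).
#' Voxel entry is determined from the tracked polyline's per-voxel transit
#' record (segment-based, not vertex membership alone).
#'
#' @param streamlines a `streamline_set`.
#' @param interface an [extract_interface()] result.
#' @return a [surface_ddm()] with provenance `"ds_stream"`.
#' @export
streamline_interface_ddm <- function(streamlines, interface) {
  stopifnot(inherits(streamlines, "streamline_set"),
            inherits(interface, "interface_set"))
  np <- prod(interface$dims)
  counts <- numeric(np)
  for (v in streamlines$visited) {
    u <- unique(v)
    counts[u] <- counts[u] + 1
  }
  iface_lin <- lin_index(interface$voxels, interface$dims)
  surface_ddm(interface, counts[iface_lin], "ds_stream")
}

#' Streamline-terminal density on the interface
#'
#' Terminal points (the final vertex of each directed half of a
#' bidirectionally tracked streamline; both endpoints eligible) that fall in
#' projection-ROI gray matter are assigned to their nearest interface voxel
#' and counted.
#'
#' @param streamlines a `streamline_set`.
#' @param roi_map integer 3D array of projection-ROI ids (0 = none), covering GM.
#' @param interface an [extract_interface()] result.
#' @param voxel_size mm.
#' @return a [surface_ddm()] with provenance `"ds_terminal"`.
#' @export
terminal_ddm <- function(streamlines, roi_map, interface, voxel_size) {
  stopifnot(inherits(streamlines, "streamline_set"),
            inherits(interface, "interface_set"))
  dims <- interface$dims
  term <- do.call(rbind, lapply(streamlines$streamlines, function(s)
    s[c(1, nrow(s)), , drop = FALSE]))
  vals <- numeric(nrow(interface$voxels))
  if (!is.null(term) && nrow(term)) {
    tv <- pos_to_voxel(term, voxel_size)
    ok <- in_grid(tv, dims)
    tv <- tv[ok, , drop = FALSE]; term <- term[ok, , drop = FALSE]
    in_roi <- roi_map[lin_index(tv, dims)] > 0
    term <- term[in_roi, , drop = FALSE]
    if (nrow(term)) {
      ictr <- vox_center(interface$voxels, voxel_size)
      iface_lin <- lin_index(interface$voxels, dims)
      ord <- order(iface_lin)
      ictr <- ictr[ord, , drop = FALSE]
      for (j in seq_len(nrow(term))) {
        dd <- (ictr[, 1] - term[j, 1])^2 + (ictr[, 2] - term[j, 2])^2 +
          (ictr[, 3] - term[j, 3])^2
        k <- ord[which.min(dd)]
        vals[k] <- vals[k] + 1
      }
    }
  }
  surface_ddm(interface, vals, "ds_terminal")
}

#' Restrict a probabilistic visitation map to the interface
#'
#' Keeps the visitation values of interface voxels and discards the rest.
#'
#' @param visitation 3D array from [probabilistic_track()].
#' @param interface an [extract_interface()] result.
#' @return a [surface_ddm()] with provenance `"prob_stream"`.
#' @export
probabilistic_interface_ddm <- function(visitation, interface) {
  stopifnot(inherits(interface, "interface_set"))
  iface_lin <- lin_index(interface$voxels, interface$dims)
  surface_ddm(interface, as.vector(visitation)[iface_lin], "prob_stream")
}
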