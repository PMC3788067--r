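# File interfaces: NIfTI volumes (RNifti), FSL-style bval/bvec text,
# TrackVis .trk streamlines, and TSV tables.

#' Write a volume as NIfTI-1
#'
#' @param arr 3D or 4D array.
#' @param path output file (`.nii` or `.nii.gz`).
#' @param voxel_size mm (length 3).
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(arr, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_size, rep(1, length(dim(arr)) - 3))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path NIfTI file.
#' @return list with `data` (array) and `voxel_size`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), voxel_size = RNifti::pixdim(img)[1:3])
}

#' Write a DWI volume with FSL-style bval/bvec files
#'
#' @param dwi a `dwi_volume`.
#' @param prefix path prefix; writes `<prefix>.nii.gz`, `<prefix>.bval`,
#'   `<prefix>.bvec`.
#' @return the prefix, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_volume"))
  write_nifti_volume(dwi$signal, paste0(prefix, ".nii.gz"), dwi$voxel_size)
  writeLines(paste(format(dwi$scheme$bvals, trim = TRUE), collapse = " "),
             paste0(prefix, ".bval"))
  writeLines(apply(t(dwi$scheme$bvecs), 1, paste, collapse = " "),
             paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' Read a DWI volume written by [write_dwi()]
#'
#' @param prefix path prefix.
#' @return a `dwi_volume`.
#' @export
read_dwi <- function(prefix) {
  vol <- read_nifti_volume(paste0(prefix, ".nii.gz"))
  bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
  bvecs <- t(matrix(scan(paste0(prefix, ".bvec"), quiet = TRUE), nrow = 3,
                    byrow = TRUE))
  structure(list(signal = vol$data, scheme = diffusion_scheme(bvals, bvecs),
                 voxel_size = vol$voxel_size, s0 = NA_real_),
            class = "dwi_volume")
}

#' Write tensor-field maps as NIfTI
#'
#' Writes `<prefix>_tensor.nii.gz` (4D, 6 components in the order
#' Dxx, Dxy, Dxz, Dyy, Dyz, Dzz), `<prefix>_fa.nii.gz` and
#' `<prefix>_pd.nii.gz` (3-vector, RGB convention).
#'
#' @param tf a [tensor_field()].
#' @param prefix path prefix.
#' @return the prefix, invisibly.
#' @export
write_tensor_nifti <- function(tf, prefix) {
  stopifnot(inherits(tf, "tensor_field"))
  write_nifti_volume(array(tf$d6, c(tf$dims, 6)), paste0(prefix, "_tensor.nii.gz"),
                     tf$voxel_size)
  write_nifti_volume(tf$fa, paste0(prefix, "_fa.nii.gz"), tf$voxel_size)
  write_nifti_volume(abs(tf$pd), paste0(prefix, "_pd.nii.gz"), tf$voxel_size)
  invisible(prefix)
}

#' Write streamlines as a TrackVis .trk file
#'
#' Minimal TrackVis version-2 writer; coordinates are stored in mm with the
#' voxel size recorded in the header.
#'
#' @param streamlines a `streamline_set`.
#' @param path output `.trk` path.
#' @return the path, invisibly.
#' @export
write_trk <- function(streamlines, path) {
  stopifnot(inherits(streamlines, "streamline_set"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL); writeBin(as.raw(0), con)
  writeBin(as.integer(streamlines$dims), con, size = 2)
  writeBin(as.numeric(streamlines$voxel_size), con, size = 4)
  writeBin(numeric(3), con, size = 4)                       # origin
  writeBin(0L, con, size = 2)                               # n_scalars
  writeBin(raw(200), con)                                   # scalar names
  writeBin(0L, con, size = 2)                               # n_properties
  writeBin(raw(200), con)                                   # property names
  m <- diag(4); m[1, 1] <- streamlines$voxel_size[1]
  m[2, 2] <- streamlines$voxel_size[2]; m[3, 3] <- streamlines$voxel_size[3]
  writeBin(as.numeric(t(m)), con, size = 4)                 # vox_to_ras
  writeBin(raw(444), con)                                   # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL); writeBin(as.raw(0), con)
  writeBin(raw(4), con)                                     # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4)              # orientation
  writeBin(raw(2), con)                                     # pad1
  writeBin(raw(6), con)                                     # invert/swap flags
  writeBin(length(streamlines$streamlines), con, size = 4)  # n_count
  writeBin(2L, con, size = 4)                               # version
  writeBin(1000L, con, size = 4)                            # hdr_size
  for (s in streamlines$streamlines) {
    writeBin(nrow(s), con, size = 4)
    writeBin(as.numeric(t(s)), con, size = 4)
  }
  invisible(path)
}

#' Read a TrackVis .trk file written by [write_trk()]
#'
#' @param path `.trk` file.
#' @return list with `streamlines` (list of n x 3 matrices), `dims`,
#'   `voxel_size`, `n_count`.
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5, useBytes = TRUE); readBin(con, "raw", 1)
  if (!identical(magic, "TRACK")) stop("not a TrackVis file")
  dims <- readBin(con, "integer", 3, size = 2)
  vox <- readBin(con, "numeric", 3, size = 4)
  seek(con, 988)
  n_count <- readBin(con, "integer", 1, size = 4)
  version <- readBin(con, "integer", 1, size = 4)
  hdr <- readBin(con, "integer", 1, size = 4)
  if (hdr != 1000) stop("unexpected trk header size: ", hdr)
  sl <- vector("list", n_count)
  for (i in seq_len(n_count)) {
    np <- readBin(con, "integer", 1, size = 4)
    sl[[i]] <- matrix(readBin(con, "numeric", 3 * np, size = 4), np, 3,
                      byrow = TRUE)
  }
  list(streamlines = sl, dims = dims, voxel_size = vox, n_count = n_count)
}

#' Write a 2D DDM as a TSV matrix
#'
#' @param ddm a `ddm2d`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ddm_tsv <- function(ddm, path) {
  stopifnot(inherits(ddm, "ddm2d"))
  utils::write.table(ddm$counts, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a surface DDM as TSV (voxel index and density)
#'
#' @param sddm a [surface_ddm()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_surface_ddm_tsv <- function(sddm, path) {
  stopifnot(inherits(sddm, "surface_ddm"))
  df <- data.frame(i = sddm$interface$voxels[, 1], j = sddm$interface$voxels[, 2],
                   k = sddm$interface$voxels[, 3], density = sddm$values)
  utils::write.table(df[df$density > 0, ], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
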