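# Shared helpers: coordinate conversions, seeds, small numerics.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("cannot normalize zero vector")
  v / n
}

#' Derive a stage seed from a master seed
#'
#' All stochastic stages draw their RNG seed deterministically from one master
#' integer so a whole experiment is reproducible from a single value. The
#' derived seed stays below 2^31.
#'
#' @param seed master seed (integer-valued scalar).
#' @param tag character tag naming the stage.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag))
  m <- 2147483647
  h <- 0
  for (cc in utf8ToInt(tag)) h <- (h * 131 + cc) %% m
  s <- (abs(seed) %% m)
  as.integer(((s * 48271) %% m + h) %% (m - 1) + 1)
}

# voxel index (1-based, n x 3) -> physical center position in mm
vox_center <- function(ijk, voxel_size) {
  ijk <- rbind(ijk)
  sweep(ijk - 0.5, 2, voxel_size, `*`)
}

# physical position (mm, n x 3) -> voxel index (1-based); no bounds check
pos_to_voxel <- function(p, voxel_size) {
  p <- rbind(p)
  floor(sweep(p, 2, voxel_size, `/`)) + 1L
}

in_grid <- function(ijk, dims) {
  ijk <- rbind(ijk)
  ijk[, 1] >= 1 & ijk[, 1] <= dims[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= dims[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= dims[3]
}

lin_index <- function(ijk, dims) {
  ijk <- rbind(ijk)
  (ijk[, 3] - 1L) * (dims[1] * dims[2]) + (ijk[, 2] - 1L) * dims[1] + ijk[, 1]
}

lin_to_ijk <- function(lin, dims) {
  lin0 <- lin - 1L
  k <- lin0 %/% (dims[1] * dims[2])
  r <- lin0 %% (dims[1] * dims[2])
  cbind(r %% dims[1] + 1L, r %/% dims[1] + 1L, k + 1L)
}

# which voxels of a logical 3D array, as an n x 3 index matrix
which_vox <- function(mask) {
  w <- which(mask)
  if (length(w) == 0) return(matrix(integer(0), 0, 3))
  lin_to_ijk(w, dim(mask))
}

#' Densify a 3D polyline with rounded corners
#'
#' Replaces each interior corner of a waypoint polyline by a circular arc of
#' the given bend radius (shrunk if the adjacent segments are too short) and
#' resamples the path at approximately `step` spacing. Used to build bundle
#' centerlines whose per-voxel turning angle stays well below tracking stop
#' angles.
#'
#' @param waypoints k x 3 matrix of waypoints (mm).
#' @param bend_radius corner arc radius (mm).
#' @param step resampling step (mm).
#' @return list with `points` (n x 3) and unit `tangents` (n x 3).
#' @keywords internal
rounded_path <- function(waypoints, bend_radius = 1.2, step = 0.1) {
  wp <- rbind(waypoints)
  stopifnot(nrow(wp) >= 2)
  pts <- wp[1, , drop = FALSE]
  if (nrow(wp) > 2) {
    for (i in 2:(nrow(wp) - 1)) {
      a <- wp[i - 1, ]; b <- wp[i, ]; c <- wp[i + 1, ]
      u <- unit3(b - a); v <- unit3(c - b)
      cosg <- clamp(sum(u * v), -1, 1)
      gamma <- acos(cosg)                      # turn angle
      if (gamma < 1e-9) { pts <- rbind(pts, b); next }
      la <- sqrt(sum((b - a)^2)); lc <- sqrt(sum((c - b)^2))
      r <- min(bend_radius, 0.45 * la / tan(gamma / 2), 0.45 * lc / tan(gamma / 2))
      d <- r * tan(gamma / 2)
      p1 <- b - d * u                          # arc entry
      # arc center: offset from p1 perpendicular to u, towards the turn
      nrm <- v - sum(v * u) * u
      nrm <- unit3(nrm)
      ctr <- p1 + r * nrm
      nseg <- max(2L, ceiling(gamma * r / step))
      ang <- seq(0, gamma, length.out = nseg + 1)
      # rotate (p1 - ctr) about axis w = u x nrm
      w <- c(u[2] * nrm[3] - u[3] * nrm[2],
             u[3] * nrm[1] - u[1] * nrm[3],
             u[1] * nrm[2] - u[2] * nrm[1])
      w <- unit3(w)
      x0 <- p1 - ctr
      arc <- t(vapply(ang, function(th) {
        ctr + x0 * cos(th) +
          c(w[2] * x0[3] - w[3] * x0[2],
            w[3] * x0[1] - w[1] * x0[3],
            w[1] * x0[2] - w[2] * x0[1]) * sin(th) +
          w * sum(w * x0) * (1 - cos(th))
      }, numeric(3)))
      pts <- rbind(pts, arc)
    }
  }
  pts <- rbind(pts, wp[nrow(wp), ])
  # resample at ~step spacing along cumulative arclength
  seglen <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  keep <- c(TRUE, seglen > 1e-12)
  pts <- pts[keep, , drop = FALSE]
  s <- c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))))
  total <- s[length(s)]
  ss <- seq(0, total, by = step)
  if (ss[length(ss)] < total) ss <- c(ss, total)
  px <- stats::approx(s, pts[, 1], xout = ss)$y
  py <- stats::approx(s, pts[, 2], xout = ss)$y
  pz <- stats::approx(s, pts[, 3], xout = ss)$y
  dense <- cbind(px, py, pz)
  tg <- rbind(dense[2, ] - dense[1, ],
              (dense[-(1:2), , drop = FALSE] - dense[1:(nrow(dense) - 2), , drop = FALSE]) / 2,
              dense[nrow(dense), ] - dense[nrow(dense) - 1, ])
  tg <- tg / sqrt(rowSums(tg^2))
  list(points = dense, tangents = tg)
}
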