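# Streamline tracking: seed-region construction with white-matter depth
# extension, deterministic FACT propagation, streamline selection, and a
# simplified probabilistic tracker honoring the seed/waypoint/termination
# mask contract.

#' Tracking parameter sets
#'
#' Defaults reproduce the study's configurations: the deterministic ("ds")
#' scheme uses start FA = 0.1, stop FA = 0.2 and stop angle = 70 degrees
#' (note the start threshold is deliberately below the stop threshold: gray
#' matter voxels may seed streamlines that cannot propagate); the
#' probabilistic ("prob") scheme uses 10000 samples per seed voxel,
#' curvature threshold 0.2 (minimum cosine between successive steps),
#' modified Euler integration, step length 0.1 mm and distance correction on.
#'
#' @param scheme `"ds"` or `"prob"`.
#' @param ... overrides for individual fields (`start_fa`, `stop_fa`,
#'   `stop_angle`, `step_length`, `n_samples`, `curvature_threshold`,
#'   `distance_correction`, `modified_euler`).
#' @return object of class `tracking_params`.
#' @export
tracking_params <- function(scheme = c("ds", "prob"), ...) {
  scheme <- match.arg(scheme)
  p <- list(scheme = scheme, start_fa = 0.1, stop_fa = 0.2, stop_angle = 70,
            step_length = 0.1, n_samples = 10000L, curvature_threshold = 0.2,
            distance_correction = TRUE, modified_euler = TRUE)
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(p)))
  p[names(ov)] <- ov
  stopifnot(p$start_fa >= 0, p$start_fa <= 1, p$stop_fa >= 0, p$stop_fa <= 1,
            p$stop_angle > 0, p$stop_angle < 180,
            p$curvature_threshold >= -1, p$curvature_threshold <= 1,
            p$step_length > 0)
  structure(p, class = "tracking_params")
}

#' Build a seed region with white-matter depth extension
#'
#' The seed region at depth `d_w = 0` is the injection gray matter itself; at
#' `d_w > 0` it additionally contains every white matter voxel whose center
#' lies within `d_w` (Euclidean) of an interface voxel beneath the injection
#' region. "Beneath" means interface voxels that belong to, or are 6-adjacent
#' to, the injection mask. At 0.3 mm voxels, `d_w` = 0.3 and 0.6 mm add one
#' and two voxel layers of subjacent white matter.
#'
#' @param injection_mask logical 3D array.
#' @param interface an [extract_interface()] result (or logical array).
#' @param wm_mask logical 3D array of white matter.
#' @param d_w extension depth in mm (>= 0).
#' @param voxel_size mm.
#' @return object of class `seed_region`: `voxels` (n x 3), `mask`, `d_w`.
#' @export
build_seed_region <- function(injection_mask, interface, wm_mask, d_w, voxel_size) {
  if (d_w < 0) stop("d_w must be nonnegative")
  if (!any(injection_mask)) stop("injection mask is empty")
  dims <- dim(injection_mask)
  iface_mask <- if (inherits(interface, "interface_set")) interface$mask else interface
  mask <- injection_mask
  if (d_w > 0) {
    under <- iface_mask & injection_mask
    if (!any(under)) under <- iface_mask & dilate6(injection_mask)
    uvox <- which_vox(under)
    if (nrow(uvox)) {
      rw <- ceiling(d_w / voxel_size)
      offs <- as.matrix(expand.grid(-rw[1]:rw[1], -rw[2]:rw[2], -rw[3]:rw[3]))
      dmm <- sqrt(rowSums(sweep(offs, 2, voxel_size, `*`)^2))
      offs <- offs[dmm <= d_w + 1e-9, , drop = FALSE]
      cand <- unique(do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
        sweep(uvox, 2, offs[i, ], `+`))))
      cand <- cand[in_grid(cand, dims), , drop = FALSE]
      li <- lin_index(cand, dims)
      keep <- wm_mask[li]
      mask[li[keep]] <- TRUE
    }
  }
  structure(list(voxels = which_vox(mask), mask = mask, d_w = d_w),
            class = "seed_region")
}

# 6-neighborhood dilation (including the set itself)
dilate6 <- function(mask) {
  d <- dim(mask); out <- mask
  out[-1, , ] <- out[-1, , ] | mask[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | mask[-1, , ]
  out[, -1, ] <- out[, -1, ] | mask[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | mask[, -1, ]
  out[, , -1] <- out[, , -1] | mask[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | mask[, , -1]
  out
}

streamline_set <- function(streamlines, visited, seed_voxel, provenance,
                           step_length, dims, voxel_size, params = NULL) {
  structure(list(streamlines = streamlines, visited = visited,
                 seed_voxel = seed_voxel, provenance = provenance,
                 step_length = step_length, dims = dims,
                 voxel_size = voxel_size, params = params),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  nv <- if (length(x$streamlines)) range(vapply(x$streamlines, nrow, 1L)) else c(0, 0)
  cat("streamline_set (", x$provenance, "): ", length(x$streamlines),
      " streamlines, ", nv[1], "-", nv[2], " vertices\n", sep = "")
  invisible(x)
}

# one FACT half-track from the center of voxel `v0` along initial direction d0
fact_half <- function(tensors, v0, d0, stop_fa, cos_stop, max_steps = 4000L) {
  dims <- tensors$dims; h <- tensors$voxel_size
  fa <- tensors$fa; pd <- tensors$pd
  np <- prod(dims)
  p <- as.numeric(vox_center(v0, h)); v <- as.integer(v0); d <- d0
  verts <- matrix(NA_real_, max_steps + 2L, 3)
  nvert <- 0L
  visited <- integer(0)
  tiny <- 1e-6 * min(h)
  for (step in seq_len(max_steps)) {
    lo <- (v - 1) * h; hi <- v * h
    tt <- ifelse(d > 1e-12, (hi - p) / d, ifelse(d < -1e-12, (lo - p) / d, Inf))
    t_exit <- max(min(tt), 0)
    if (!is.finite(t_exit)) break
    p_exit <- p + t_exit * d
    v_next <- as.integer(pos_to_voxel(p_exit + tiny * d, h))
    if (all(v_next == v)) {                 # numerical corner case
      ax <- which.min(tt)
      v_next[ax] <- v[ax] + as.integer(sign(d[ax]))
    }
    nvert <- nvert + 1L; verts[nvert, ] <- p_exit
    if (!in_grid(v_next, dims)) break       # left the volume
    li <- lin_index(v_next, dims)
    if (fa[li] < stop_fa) {                 # terminate within the entered voxel
      lo2 <- (v_next - 1) * h; hi2 <- v_next * h
      p2 <- p_exit + tiny * d
      tt2 <- ifelse(d > 1e-12, (hi2 - p2) / d, ifelse(d < -1e-12, (lo2 - p2) / d, Inf))
      t2 <- min(tt2)
      if (is.finite(t2) && t2 > 0) {
        nvert <- nvert + 1L; verts[nvert, ] <- p2 + 0.5 * t2 * d
      }
      visited <- c(visited, li)
      break
    }
    d_next <- c(pd[li], pd[li + np], pd[li + 2L * np])
    if (sum(d_next * d) < 0) d_next <- -d_next
    if (sum(d_next * d) < cos_stop) break   # turning angle exceeds stop angle
    visited <- c(visited, li)
    p <- p_exit + tiny * d
    v <- v_next; d <- d_next
  }
  list(verts = verts[seq_len(nvert), , drop = FALSE], visited = visited)
}

#' Deterministic FACT fiber tracking
#'
#' From the center of each seed voxel with FA >= `start_fa`, streamlines are
#' propagated bidirectionally along the per-voxel principal direction, the
#' direction changing at voxel boundaries (fiber assignment by continuous
#' tracking). Propagation terminates on entering a voxel with
#' FA < `stop_fa` (the streamline ends *within* that voxel), when the turning
#' angle between successive voxel directions exceeds `stop_angle`, or when
#' leaving the volume. Fully deterministic.
#'
#' @param tensors a [tensor_field()].
#' @param seeds a [build_seed_region()] result, or an n x 3 voxel index matrix.
#' @param params [tracking_params()]; the `ds` defaults reproduce the study.
#' @return a `streamline_set` with per-streamline visited voxels.
#' @export
fact_track <- function(tensors, seeds, params = tracking_params("ds")) {
  stopifnot(inherits(tensors, "tensor_field"))
  sv <- if (inherits(seeds, "seed_region")) seeds$voxels else rbind(seeds)
  if (nrow(sv) == 0) {
    warning("empty seed set: returning empty streamline set")
    return(streamline_set(list(), list(), sv, "DS", NA_real_,
                          tensors$dims, tensors$voxel_size, params))
  }
  dims <- tensors$dims; np <- prod(dims)
  li <- lin_index(sv, dims)
  ok <- tensors$fa[li] >= params$start_fa & tensors$mask[li]
  sv <- sv[ok, , drop = FALSE]; li <- li[ok]
  cos_stop <- cos(params$stop_angle * pi / 180)
  sl <- vector("list", nrow(sv)); vis <- vector("list", nrow(sv))
  for (i in seq_len(nrow(sv))) {
    d0 <- c(tensors$pd[li[i]], tensors$pd[li[i] + np], tensors$pd[li[i] + 2L * np])
    a <- fact_half(tensors, sv[i, ], d0, params$stop_fa, cos_stop)
    b <- fact_half(tensors, sv[i, ], -d0, params$stop_fa, cos_stop)
    ctr <- vox_center(sv[i, ], tensors$voxel_size)
    pts <- rbind(a$verts[rev(seq_len(nrow(a$verts))), , drop = FALSE], ctr, b$verts)
    sl[[i]] <- unname(pts)
    vis[[i]] <- unique(c(li[i], a$visited, b$visited))
  }
  streamline_set(sl, vis, sv, "DS",
                 sqrt(sum(tensors$voxel_size^2)), dims, tensors$voxel_size, params)
}

#' Select streamlines penetrating two regions
#'
#' Keeps streamlines whose path visits at least one voxel of `region_a` and
#' one of `region_b` (the study's two-ROI selection: the injection region and
#' the interface directly underneath it).
#'
#' @param streamlines a `streamline_set`.
#' @param region_a,region_b logical 3D arrays (nonempty).
#' @return the filtered `streamline_set`.
#' @export
select_streamlines <- function(streamlines, region_a, region_b) {
  stopifnot(inherits(streamlines, "streamline_set"),
            any(region_a), any(region_b))
  a <- as.vector(region_a); b <- as.vector(region_b)
  keep <- vapply(streamlines$visited,
                 function(v) any(a[v]) && any(b[v]), logical(1))
  out <- streamlines
  out$streamlines <- streamlines$streamlines[keep]
  out$visited <- streamlines$visited[keep]
  out$seed_voxel <- streamlines$seed_voxel[keep, , drop = FALSE]
  out
}

#' Simplified probabilistic tracking
#'
#' Emulates the contract of FSL-style probabilistic tractography on a
#' single-tensor field: `n_samples` streamline samples per seed voxel are
#' propagated bidirectionally with fixed step length; at each step the
#' direction is drawn from a symmetric angular distribution around the local
#' principal direction (tangential Gaussian perturbation with scale
#' `orientation_sigma`, in radians; 0 degenerates to deterministic
#' propagation), optionally corrected by a two-stage (modified Euler)
#' predictor-corrector. A sample terminates when its step direction's cosine
#' with the previous direction falls below `curvature_threshold`, on entering
#' a voxel with FA < `stop_fa`, on entering the termination mask, or on
#' leaving the volume. Samples that never visit the waypoint mask are
#' discarded. The returned voxel value is the number of retained sample
#' visits (each sample counted at most once per voxel), multiplied by the
#' mean retained path length when `distance_correction` is on.
#'
#' @param tensors a [tensor_field()].
#' @param seed a `seed_region` (or n x 3 voxel matrix).
#' @param waypoint,termination logical 3D arrays (`NULL` disables).
#' @param params [tracking_params()], scheme `"prob"`.
#' @param orientation_sigma angular spread (radians, >= 0).
#' @param rng_seed integer seed; results are reproducible given it.
#' @return 3D array of visitation density, with attributes `n_retained`,
#'   `mean_path_length`.
#' @export
probabilistic_track <- function(tensors, seed, waypoint = NULL, termination = NULL,
                                params = tracking_params("prob"),
                                orientation_sigma = 0.2, rng_seed = 1L) {
  stopifnot(inherits(tensors, "tensor_field"), orientation_sigma >= 0)
  if (params$n_samples <= 0) stop("n_samples must be positive")
  sv <- if (inherits(seed, "seed_region")) seed$voxels else rbind(seed)
  if (nrow(sv) == 0) stop("empty seed region")
  dims <- tensors$dims; h <- tensors$voxel_size; np <- prod(dims)
  fa <- as.vector(tensors$fa)
  pdm <- matrix(tensors$pd, np, 3)
  wp <- if (is.null(waypoint)) NULL else as.vector(waypoint)
  tm <- if (is.null(termination)) NULL else as.vector(termination)
  L <- params$step_length
  max_steps <- ceiling(sum(dims * h) / L)
  set.seed(derive_seed(rng_seed, "probtrack"))

  ns <- params$n_samples
  N <- nrow(sv) * ns
  seed_li <- rep(lin_index(sv, dims), each = ns)
  start <- vox_center(sv[rep(seq_len(nrow(sv)), each = ns), , drop = FALSE], h)
  start <- start + sweep(matrix(stats::runif(N * 3) - 0.5, N, 3), 2, h, `*`)
  d0 <- pdm[seed_li, , drop = FALSE]

  hit_wp <- if (is.null(wp)) rep(TRUE, N) else wp[seed_li]
  path_len <- numeric(N)
  vkeys <- vector("list", 2L * max_steps + 2L)
  nk <- 0L
  nk <- nk + 1L; vkeys[[nk]] <- (seq_len(N) - 1) * np + seed_li

  for (sgn in c(1, -1)) {
    pos <- start
    dir <- sgn * d0
    alive <- rep(TRUE, N)
    # samples whose seed voxel is masked out never move
    alive[!tensors$mask[seed_li]] <- FALSE
    for (step in seq_len(max_steps)) {
      ia <- which(alive)
      if (!length(ia)) break
      cur <- dir[ia, , drop = FALSE]
      vox_li <- lin_index(pos_to_voxel(pos[ia, , drop = FALSE], h), dims)
      mean_dir <- pdm[vox_li, , drop = FALSE]
      flip <- rowSums(mean_dir * cur) < 0
      mean_dir[flip, ] <- -mean_dir[flip, , drop = FALSE]
      if (orientation_sigma > 0) {
        eps <- matrix(stats::rnorm(length(ia) * 3), ncol = 3)
        eps <- eps - mean_dir * rowSums(eps * mean_dir)
        d1 <- mean_dir + orientation_sigma * eps
      } else d1 <- mean_dir
      d1 <- d1 / sqrt(rowSums(d1^2))
      ok_curv <- rowSums(d1 * cur) >= params$curvature_threshold
      if (params$modified_euler) {
        pred <- pos[ia, , drop = FALSE] + L * d1
        pv <- pos_to_voxel(pred, h)
        ing <- in_grid(pv, dims)
        d2 <- d1
        if (any(ing)) {
          pli <- lin_index(pv[ing, , drop = FALSE], dims)
          md2 <- pdm[pli, , drop = FALSE]
          fl2 <- rowSums(md2 * d1[ing, , drop = FALSE]) < 0
          md2[fl2, ] <- -md2[fl2, , drop = FALSE]
          use <- fa[pli] >= params$stop_fa
          d2i <- d1[ing, , drop = FALSE]
          d2i[use, ] <- md2[use, , drop = FALSE]
          d2[ing, ] <- d2i
        }
        stp <- d1 + d2
        stp <- stp / sqrt(rowSums(stp^2))
      } else stp <- d1
      newpos <- pos[ia, , drop = FALSE] + L * stp
      nv <- pos_to_voxel(newpos, h)
      ing <- in_grid(nv, dims)
      moved <- ok_curv & ing                 # samples that take the step
      nli <- rep(1L, length(ia))             # placeholder for safe indexing
      nli[ing] <- lin_index(nv[ing, , drop = FALSE], dims)
      idx_enter <- ia[moved]
      if (length(idx_enter)) {
        nk <- nk + 1L
        vkeys[[nk]] <- (idx_enter - 1) * np + nli[moved]
        if (!is.null(wp)) hit_wp[idx_enter] <- hit_wp[idx_enter] | wp[nli[moved]]
        path_len[idx_enter] <- path_len[idx_enter] + L
        pos[idx_enter, ] <- newpos[moved, , drop = FALSE]
        dir[idx_enter, ] <- stp[moved, , drop = FALSE]
      }
      # stop: curvature/volume violations, low-FA entry, termination mask
      stop_now <- !moved |
        (moved & (fa[nli] < params$stop_fa | !tensors$mask[nli]))
      if (!is.null(tm)) stop_now <- stop_now | (moved & tm[nli])
      alive[ia[stop_now]] <- FALSE
    }
  }

  keys <- unique(unlist(vkeys[seq_len(nk)]))
  samp <- floor((keys - 1) / np) + 1
  vox <- keys - (samp - 1) * np
  retained <- hit_wp[samp]
  counts <- numeric(np)
  if (any(retained)) {
    tb <- tabulate(vox[retained], nbins = np)
    counts <- tb
  }
  n_ret <- sum(hit_wp)
  mean_len <- if (n_ret > 0) mean(path_len[hit_wp]) else 0
  val <- if (params$distance_correction) counts * mean_len else counts
  out <- array(val, dims)
  attr(out, "n_retained") <- n_ret
  attr(out, "mean_path_length") <- mean_len
  out
}
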