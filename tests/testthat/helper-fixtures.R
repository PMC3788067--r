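# Shared fixtures and independent oracles for the test suite.

# --- small phantom configs -------------------------------------------------

# one straight bundle along +x through mid-height white matter
straight_bundle_config <- function(radius = 0.45, axon = 100) {
  phantom_config(
    grid_shape = c(32L, 32L, 32L), voxel_size = c(0.3, 0.3, 0.3),
    wm_z = c(3L, 26L), gm_z = c(27L, 30L),
    bundles = list(list(name = "straight", target_roi = NA,
                        waypoints = rbind(c(0.9, 4.65, 4.65), c(8.7, 4.65, 4.65)),
                        radius = radius, axon_count = axon, soma_count = axon)),
    noise_sigma = 0, rng_seed = 1L)
}

# straight bundle along +x crossed mid-way by an orthogonal occluder along y
crossing_pair_config <- function(occluder_axons = 500) {
  cfg <- straight_bundle_config()
  cfg$crossing <- list(name = "occluder", target_roi = NA,
                       waypoints = rbind(c(4.65, 0.9, 4.65), c(4.65, 8.7, 4.65)),
                       radius = 0.45, axon_count = occluder_axons,
                       soma_count = 0, bend_radius = 1.2)
  cfg
}

# uniform prolate tensor field, principal direction along `dir`
uniform_field <- function(dims = c(20L, 8L, 8L), dir = c(1, 0, 0),
                          ev = c(1.7e-3, 2.5e-4, 2.5e-4), voxel = 0.3) {
  dir <- dir / sqrt(sum(dir^2))
  d6 <- c(ev[2] + (ev[1] - ev[2]) * dir[1]^2,
          (ev[1] - ev[2]) * dir[1] * dir[2],
          (ev[1] - ev[2]) * dir[1] * dir[3],
          ev[2] + (ev[1] - ev[2]) * dir[2]^2,
          (ev[1] - ev[2]) * dir[2] * dir[3],
          ev[2] + (ev[1] - ev[2]) * dir[3]^2)
  tensor_field(matrix(d6, prod(dims), 6, byrow = TRUE), dims, rep(voxel, 3))
}

# random symmetric positive definite diffusion-scale tensors (n x 6)
random_spd_tensors <- function(n, seed = 1) {
  set.seed(seed)
  t(vapply(seq_len(n), function(i) {
    Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
    lam <- sort(runif(3, 2e-4, 2e-3), decreasing = TRUE)
    D <- Q %*% diag(lam) %*% t(Q)
    c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
  }, numeric(6)))
}

d6_to_mat <- function(d6) {
  matrix(c(d6[1], d6[2], d6[3], d6[2], d6[4], d6[5], d6[3], d6[5], d6[6]), 3, 3)
}

# --- definitional correlation oracles (independent of stats::cor) ----------

pearson_oracle <- function(x, y) {
  xm <- sum(x) / length(x); ym <- sum(y) / length(y)
  sum((x - xm) * (y - ym)) / sqrt(sum((x - xm)^2) * sum((y - ym)^2))
}

# average ranks computed from scratch
ranks_oracle <- function(x) {
  vapply(seq_along(x), function(i) {
    sum(x < x[i]) + (1 + sum(x == x[i])) / 2
  }, numeric(1))
}

spearman_oracle <- function(x, y) {
  pearson_oracle(ranks_oracle(x), ranks_oracle(y))
}

# --- deformation helpers ---------------------------------------------------

# forward-push particle oracle for transfer_ddm: pushes subdivided cell mass
# through the forward map (numerical inverse of the pull-back field, solved
# for all particles at once by fixed-point iteration) and bins it
particle_push_oracle <- function(input, field, subdiv = 4L) {
  u1 <- field$displacement[, , 1]; u2 <- field$displacement[, , 2]
  interp2 <- function(A, pts) tracerval:::interp_grid(A, pts)
  off <- (seq_len(subdiv) - 0.5) / subdiv
  nz <- which(input != 0, arr.ind = TRUE)
  offs <- as.matrix(expand.grid(off, off))
  x <- cbind(rep(nz[, 1] - 1, each = nrow(offs)) + offs[, 1],
             rep(nz[, 2] - 1, each = nrow(offs)) + offs[, 2])
  w <- rep(input[nz] / subdiv^2, each = nrow(offs))
  y <- x                                       # solve y + u(y) = x
  for (it in 1:80) {
    y_new <- x - cbind(interp2(u1, y), interp2(u2, y))
    if (max(abs(y_new - y)) < 1e-10) { y <- y_new; break }
    y <- y_new
  }
  # cloud-in-cell deposit (bilinear splatting, second-order in the particle
  # position, adjoint of the bilinear interpolation used for the pull-back)
  out <- matrix(0, field$dim[1], field$dim[2])
  fx <- y[, 1] - 0.5; fy <- y[, 2] - 0.5
  i0 <- floor(fx); j0 <- floor(fy)
  ax <- fx - i0; ay <- fy - j0
  for (di in 0:1) for (dj in 0:1) {
    ii <- i0 + di + 1; jj <- j0 + dj + 1
    wq <- w * (if (di == 1) ax else 1 - ax) * (if (dj == 1) ay else 1 - ay)
    ok <- ii >= 1 & ii <= field$dim[1] & jj >= 1 & jj <= field$dim[2] & wq > 0
    for (r in which(ok)) out[ii[r], jj[r]] <- out[ii[r], jj[r]] + wq[r]
  }
  out
}

# smooth compactly supported test density: C^2 bump (1 - (r/R)^2)^3, exactly
# zero outside radius R (no truncation cliff)
gaussian_blob <- function(G = 64, center = NULL, R = 20) {
  center <- center %||% rep(G / 2, 2)
  x <- outer(seq_len(G) - 0.5 - center[1], rep(1, G))
  y <- outer(rep(1, G), seq_len(G) - 0.5 - center[2])
  r2 <- (x^2 + y^2) / R^2
  ifelse(r2 < 1, (1 - r2)^3, 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- micrograph helper -----------------------------------------------------

test_micrograph <- function(seed, noise = 0.03, n_crossing = 10,
                            n_noncrossing = 5, n_clutter = 4, n_speck = 3,
                            size = c(1024, 1024)) {
  bnd <- default_boundary(size)
  pl <- plant_micrograph_objects(n_crossing, n_noncrossing, n_clutter, n_speck,
                                 bnd, size, rng_seed = seed,
                                 fiber_length = c(50, 90), fiber_width = c(3, 6),
                                 min_sep = 110)
  mg <- make_micrograph(pl, bnd, size = size, noise = noise, rng_seed = seed)
  list(mg = mg, boundary = bnd, curve = fit_boundary_curve(bnd))
}

count_pipeline <- function(mg, curve, element_radius = 12) {
  obj <- segment_fiber_objects(tophat_correct(mg$micrograph, element_radius))
  extract_crossing_fibers(obj, curve)$count
}

# linear voxel index (independent of package internals)
h_lin <- function(ijk, dims) {
  ijk <- rbind(ijk)
  (ijk[, 3] - 1) * dims[1] * dims[2] + (ijk[, 2] - 1) * dims[1] + ijk[, 1]
}

# --- slab tissue for seed-region / projection tests ------------------------

slab_labels <- function(dims = c(12L, 12L, 12L), wm_z = 2:6, gm_z = 7:10) {
  lab <- array(0L, dims)
  lab[, , wm_z] <- 1L
  lab[, , gm_z] <- 2L
  lab
}
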