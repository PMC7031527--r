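# Independent oracles and small fixtures used across the suite. These are
# deliberately naive implementations (queue-based flood fill, exhaustive
# voxel enumeration) kept separate from the package's vectorised code paths.

# Breadth-first flood fill: the reference for region_grow
bfs_flood_fill <- function(volume, seed_voxel, threshold, connectivity = 26) {
  d <- dim(volume)
  offs <- if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else as.matrix(expand.grid(-1:1, -1:1, -1:1))[rowSums(abs(expand.grid(-1:1, -1:1, -1:1))) > 0, ]
  above <- volume >= threshold
  visited <- array(FALSE, d)
  queue <- matrix(seed_voxel, 1, 3)
  visited[seed_voxel[1], seed_voxel[2], seed_voxel[3]] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
    for (r in seq_len(nrow(offs))) {
      nb <- cur + offs[r, ]
      if (any(nb < 1) || any(nb > d)) next
      if (!visited[nb[1], nb[2], nb[3]] && above[nb[1], nb[2], nb[3]]) {
        visited[nb[1], nb[2], nb[3]] <- TRUE
        queue <- rbind(queue, nb)
      }
    }
  }
  visited & above
}

# Exhaustive per-voxel ratio-by-threshold: the reference for the analysis ops
brute_ratio_by_threshold <- function(pre, post, field, thresholds, vox = 1) {
  do.call(rbind, lapply(thresholds, function(th) {
    vpre <- 0; vpost <- 0
    d <- dim(pre)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      if (field[i, j, k] >= th) {
        if (pre[i, j, k]) vpre <- vpre + vox^3
        if (post[i, j, k]) vpost <- vpost + vox^3
      }
    }
    data.frame(threshold = th, v_pre_mm3 = vpre, v_post_mm3 = vpost,
               ratio_pct = if (vpre > 0) 100 * vpost / vpre else NA_real_)
  }))
}

# Uniform conducting sphere phantom for solver oracles
sphere_phantom <- function(radius_mm = 50, voxel_size_mm = 4, sigma = 0.1,
                           eps_r = 1, margin = 2) {
  tt <- list("9" = tissue_properties("uniform", c(50, 7500),
                                     c(sigma, sigma), c(eps_r, eps_r)))
  n <- ceiling(2 * (radius_mm + voxel_size_mm) / voxel_size_mm) + 2 * margin
  origin <- rep(-n * voxel_size_mm / 2, 3)
  cc <- lapply(1:3, function(ax) origin[ax] + (seq_len(n) - 0.5) * voxel_size_mm)
  r <- sqrt(outer(outer(cc[[1]]^2, cc[[2]]^2, `+`), cc[[3]]^2, `+`))
  labs <- array(0L, rep(n, 3))
  labs[r < radius_mm] <- 9L
  voxel_phantom(labs, voxel_size_mm, origin, tt, "sphere")
}

# radius (mm) of each voxel center from the world origin, and cylindrical
# radius about the z axis, for a phantom grid
phantom_radii <- function(phantom) {
  d <- dim(phantom$labels)
  cc <- lapply(1:3, function(ax)
    phantom$origin_mm[ax] + (seq_len(d[ax]) - 0.5) * phantom$voxel_size_mm)
  rho2 <- outer(cc[[1]]^2, cc[[2]]^2, `+`)
  list(r = sqrt(outer(rho2, cc[[3]]^2, `+`)),
       rho = array(rep(sqrt(rho2), d[3]), d))
}

# Eddy-current closed form for a homogeneous sphere in uniform sinusoidal
# B_z: |J| = sigma * pi * f * |B| * rho (rho = cylindrical radius). Derived
# from E = -j w A with A = (B x r)/2 and phi = 0 (A is tangential to the
# sphere, so the insulating boundary condition is already met).
eddy_J_exact <- function(sigma, f_hz, B_tesla, rho_m) {
  sigma * pi * f_hz * B_tesla * rho_m
}

# deterministic random binary mask fixtures on small grids
random_mask <- function(dims, p = 0.3, seed = 1) {
  set.seed(seed)
  array(stats::runif(prod(dims)) < p, dims)
}

# coarse 4 mm layered head for fast geometric tests (layers chosen so no
# layer is thinner than the voxel)
coarse_head <- function() {
  build_layered_head(voxel_size_mm = 4,
                     layer_thicknesses_mm = c(skin = 4, skull = 8, grey = 6))
}
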