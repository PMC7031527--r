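# Internal helpers shared across modules.

MU0 <- 4e-7 * pi     # vacuum permeability, H/m
EPS0 <- 8.8541878128e-12  # vacuum permittivity, F/m

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression with a locally seeded RNG, restoring the caller's state
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

unit_vector <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < .Machine$double.eps) stopf("cannot normalise a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Rowwise cross product for n x 3 matrices
cross3_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(m) sqrt(rowSums(m^2))

#' Coordinates (mm) of voxel centers for a grid
#'
#' Voxel (i, j, k) (1-based) owns the half-open cube
#' [origin + (i-1) vs, origin + i vs) per axis; its center is at
#' origin + (i - 1/2) vs.
#' @noRd
voxel_center_coords <- function(dims, voxel_size, origin) {
  lapply(1:3, function(ax) origin[ax] + (seq_len(dims[ax]) - 0.5) * voxel_size)
}

#' All voxel centers as an n x 3 matrix (mm), in array storage order
#' @noRd
voxel_center_matrix <- function(dims, voxel_size, origin) {
  cc <- voxel_center_coords(dims, voxel_size, origin)
  cbind(rep(cc[[1]], times = dims[2] * dims[3]),
        rep(rep(cc[[2]], each = dims[1]), times = dims[3]),
        rep(cc[[3]], each = dims[1] * dims[2]))
}

#' Trilinear interpolation of a 3D array at arbitrary points
#'
#' @param arr 3D numeric array sampled at voxel centers.
#' @param pts n x 3 matrix of query points in continuous voxel-center
#'   coordinates (1 = center of first voxel). Points outside are clamped.
#' @noRd
trilinear <- function(arr, pts) {
  d <- dim(arr)
  px <- pmin(pmax(pts[, 1], 1), d[1])
  py <- pmin(pmax(pts[, 2], 1), d[2])
  pz <- pmin(pmax(pts[, 3], 1), d[3])
  x0 <- pmin(floor(px), d[1] - 1L); y0 <- pmin(floor(py), d[2] - 1L)
  z0 <- pmin(floor(pz), d[3] - 1L)
  if (d[1] == 1L) x0 <- rep(1, length(px))
  fx <- px - x0; fy <- py - y0; fz <- pz - z0
  idx <- function(i, j, k) arr[cbind(i, j, k)]
  x1 <- pmin(x0 + 1L, d[1]); y1 <- pmin(y0 + 1L, d[2]); z1 <- pmin(z0 + 1L, d[3])
  c000 <- idx(x0, y0, z0); c100 <- idx(x1, y0, z0)
  c010 <- idx(x0, y1, z0); c110 <- idx(x1, y1, z0)
  c001 <- idx(x0, y0, z1); c101 <- idx(x1, y0, z1)
  c011 <- idx(x0, y1, z1); c111 <- idx(x1, y1, z1)
  c00 <- c000 * (1 - fx) + c100 * fx
  c10 <- c010 * (1 - fx) + c110 * fx
  c01 <- c001 * (1 - fx) + c101 * fx
  c11 <- c011 * (1 - fx) + c111 * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Shift a 3D logical/numeric array by an integer offset, zero-filling
#' @noRd
shift_array <- function(arr, off) {
  d <- dim(arr)
  out <- array(if (is.logical(arr)) FALSE else 0, dim = d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[ax]
    if (abs(o) >= d[ax]) return(out)
    if (o >= 0) { dst[[ax]] <- (1 + o):d[ax]; src[[ax]] <- 1:(d[ax] - o) }
    else        { dst[[ax]] <- 1:(d[ax] + o); src[[ax]] <- (1 - o):d[ax] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

neighbour_offsets <- function(connectivity = 26) {
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    g[rowSums(abs(g)) > 0, , drop = FALSE]
  } else stopf("connectivity must be 6 or 26, got %s", connectivity)
}

#' Binary dilation by one step under the given connectivity
#' @noRd
dilate_mask <- function(mask, connectivity = 6) {
  out <- mask
  offs <- neighbour_offsets(connectivity)
  for (r in seq_len(nrow(offs))) out <- out | shift_array(mask, offs[r, ])
  out
}

erode_mask <- function(mask, connectivity = 6) {
  out <- mask
  offs <- neighbour_offsets(connectivity)
  for (r in seq_len(nrow(offs))) out <- out & shift_array(mask, offs[r, ])
  out
}

close_mask <- function(mask, connectivity = 6) {
  erode_mask(dilate_mask(mask, connectivity), connectivity)
}
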