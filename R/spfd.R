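# Scalar-potential finite-difference (SPFD) magneto-quasistatic solver.
#
# In the magneto-quasistatic regime the source magnetic field is unperturbed
# by tissue; the induced electric field is E = -j w A - grad(phi) with the
# scalar potential solving div(sigma* (grad(phi) + j w A)) = 0 inside the
# conductor and J.n = 0 on the conductor-air boundary. Discretisation:
# potentials on voxel-grid nodes (corners), complex conductivity sigma* =
# sigma + j w eps0 eps_r per voxel, edge conductances averaged over the up to
# four voxels sharing each edge. Kirchhoff balance at every node gives a
# complex symmetric sparse system solved by diagonally preconditioned
# conjugate gradients (COCG for the complex-symmetric case).

#' Complex conductivity volume of a phantom at a frequency
#'
#' @param phantom A [voxel_phantom()].
#' @param frequency Hz.
#' @param displacement Include the j w eps0 eps_r term (default TRUE).
#' @return Complex 3D array (S/m), zero in air.
#' @export
phantom_sigma_star <- function(phantom, frequency, displacement = TRUE) {
  labs <- phantom$labels
  out <- array(0 + 0i, dim(labs))
  for (lb in setdiff(sort(unique(as.vector(labs))), 0L)) {
    p <- phantom$tissue_table[[as.character(lb)]]
    s <- if (displacement && frequency > 0) complex_conductivity(p, max(frequency, 50))
         else p$sigma(max(frequency, 50)) + 0i
    out[labs == lb] <- s
  }
  out
}

#' Vector potential of a uniform sinusoidal B field
#'
#' `A = (B0 x r) / 2` for a spatially uniform field `B0`; used with the
#' conducting-sphere eddy-current oracle.
#' @param points_mm n x 3 world points (mm).
#' @param B0 Length-3 field vector (tesla).
#' @return n x 3 A vectors (tesla meter).
#' @export
uniform_field_A <- function(points_mm, B0) {
  P <- rbind(points_mm) * 1e-3
  0.5 * cbind(B0[2] * P[, 3] - B0[3] * P[, 2],
              B0[3] * P[, 1] - B0[1] * P[, 3],
              B0[1] * P[, 2] - B0[2] * P[, 1])
}

# Edge-midpoint coordinate matrices for the three edge families.
# Nodes are voxel corners: node (i,j,k), 1-based, sits at
# origin + (i-1, j-1, k-1) * vs. Edge family ax connects node (i,j,k) to
# node (i+e_ax); its midpoint offsets by vs/2 along ax.
edge_midpoints_mm <- function(dims, vs, origin, ax) {
  nd <- dims + 1L
  ed <- nd; ed[ax] <- dims[ax]
  cx <- origin[1] + (seq_len(ed[1]) - 1) * vs + if (ax == 1) vs / 2 else 0
  cy <- origin[2] + (seq_len(ed[2]) - 1) * vs + if (ax == 2) vs / 2 else 0
  cz <- origin[3] + (seq_len(ed[3]) - 1) * vs + if (ax == 3) vs / 2 else 0
  list(dims = ed,
       pts = cbind(rep(cx, times = ed[2] * ed[3]),
                   rep(rep(cy, each = ed[1]), times = ed[3]),
                   rep(cz, each = ed[1] * ed[2])))
}

# Edge conductances S_e = (h/4) * sum of sigma* over adjacent voxels,
# h in meters. Returns complex array of dims ed (see edge_midpoints_mm).
edge_conductance <- function(sigma_star, vs_m, ax) {
  d <- dim(sigma_star)
  perp <- setdiff(1:3, ax)
  # pad sigma with a zero shell on the two perpendicular axes, then average
  # the 4 voxels around each edge
  pd <- d; pd[perp] <- pd[perp] + 2L
  pad <- array(0 + 0i, pd)
  idx <- lapply(1:3, function(a) if (a %in% perp) 1 + seq_len(d[a]) else seq_len(d[a]))
  pad[idx[[1]], idx[[2]], idx[[3]]] <- sigma_star
  sub <- function(o1, o2) {
    sel <- lapply(1:3, function(a) {
      if (a == perp[1]) o1 + seq_len(d[a] + 1L)
      else if (a == perp[2]) o2 + seq_len(d[a] + 1L)
      else seq_len(d[a])
    })
    pad[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
  }
  (sub(0, 0) + sub(1, 0) + sub(0, 1) + sub(1, 1)) * (vs_m / 4)
}

#' Assemble the SPFD linear system
#'
#' Builds the Kirchhoff node balance `L phi = b` over nodes touching
#' conducting tissue, with `L[nm] = -S_e`, `L[nn] = sum_e S_e` and
#' `b[n] = j w h sum_e (+/-) S_e A_e`, where `A_e` is the source vector
#' potential component along each incident edge at its midpoint. Air voxels
#' carry zero conductance, which realises the insulating boundary (J.n = 0)
#' naturally.
#'
#' @param phantom A [voxel_phantom()].
#' @param A_fun Function `(points_mm) -> n x 3` vector potential (T m) of the
#'   unit-amplitude source, e.g. built from [vector_potential_A()] or
#'   [uniform_field_A()].
#' @param frequency Hz (>= 0; at 0 the right-hand side vanishes).
#' @param displacement Include displacement currents in sigma*.
#' @return List of class `spfd_system`: real/imag sparse operators, complex
#'   right-hand side, node index maps and grid metadata.
#' @export
assemble_spfd <- function(phantom, A_fun, frequency, displacement = TRUE) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  dims <- dim(phantom$labels)
  vs <- phantom$voxel_size_mm
  vs_m <- vs * 1e-3
  sigma_star <- phantom_sigma_star(phantom, frequency, displacement)
  if (!any(Mod(sigma_star) > 0)) stopf("phantom has no conducting voxels")
  nd <- dims + 1L
  n_nodes <- prod(nd)
  node_id <- function(i, j, k) (as.numeric(k) - 1) * nd[1] * nd[2] +
    (as.numeric(j) - 1) * nd[1] + as.numeric(i)
  omega <- 2 * pi * frequency

  e_n1 <- list(); e_n2 <- list(); e_S <- list(); e_A <- list()
  for (ax in 1:3) {
    S <- edge_conductance(sigma_star, vs_m, ax)
    em <- edge_midpoints_mm(dims, vs, phantom$origin_mm, ax)
    keep <- which(Mod(S) > 0)
    if (length(keep) == 0) next
    ijk <- arrayInd(keep, em$dims)
    off <- c(0L, 0L, 0L); off[ax] <- 1L
    e_n1[[ax]] <- node_id(ijk[, 1], ijk[, 2], ijk[, 3])
    e_n2[[ax]] <- node_id(ijk[, 1] + off[1], ijk[, 2] + off[2], ijk[, 3] + off[3])
    e_S[[ax]] <- S[keep]
    e_A[[ax]] <- if (omega > 0) A_fun(em$pts[keep, , drop = FALSE])[, ax]
                 else numeric(length(keep))
  }
  n1 <- unlist(e_n1); n2 <- unlist(e_n2)
  Sk <- unlist(e_S); Ak <- unlist(e_A)
  if (length(n1) == 0) stopf("phantom has no conducting edges")
  active <- sort(unique(c(n1, n2)))
  remap <- integer(n_nodes); remap[active] <- seq_along(active)
  m1 <- remap[n1]; m2 <- remap[n2]
  # duplicate (i, j) triplets are summed by sparseMatrix; diagonal entries
  # accumulate +S from every incident edge, off-diagonals get -S
  ii <- c(m1, m2, m1, m2); jj <- c(m2, m1, m1, m2)
  ss <- c(-Sk, -Sk, Sk, Sk)
  na <- length(active)
  Lr <- Matrix::sparseMatrix(i = ii, j = jj, x = Re(ss), dims = c(na, na))
  Li <- Matrix::sparseMatrix(i = ii, j = jj, x = Im(ss), dims = c(na, na))
  rhs_active <- complex(na)
  if (omega > 0) {
    # EMF drive: current n1 -> n2 includes -j w h A term; Kirchhoff balance
    # moves +j w h S A to node n1's RHS and -j w h S A to node n2's
    contrib <- (1i * omega * vs_m) * Sk * Ak
    rr <- rowsum(cbind(Re(contrib), Im(contrib)), group = m1, reorder = TRUE)
    rows <- as.integer(rownames(rr))
    rhs_active[rows] <- rhs_active[rows] + complex(real = rr[, 1], imaginary = rr[, 2])
    rr <- rowsum(cbind(Re(contrib), Im(contrib)), group = m2, reorder = TRUE)
    rows <- as.integer(rownames(rr))
    rhs_active[rows] <- rhs_active[rows] - complex(real = rr[, 1], imaginary = rr[, 2])
  }
  structure(list(Lr = Lr, Li = Li, b = rhs_active, active_nodes = active,
                 node_dims = nd, dims = dims, voxel_size_mm = vs,
                 origin_mm = phantom$origin_mm, frequency = frequency,
                 sigma_star = sigma_star, omega = omega,
                 has_imag = any(abs(Im(ss)) > 0)),
            class = "spfd_system")
}

# complex sparse matvec via the real/imag parts
spfd_matvec <- function(sys, x) {
  xr <- Re(x); xi <- Im(x)
  if (sys$has_imag) {
    complex(real = as.numeric(sys$Lr %*% xr - sys$Li %*% xi),
            imaginary = as.numeric(sys$Lr %*% xi + sys$Li %*% xr))
  } else {
    complex(real = as.numeric(sys$Lr %*% xr),
            imaginary = as.numeric(sys$Lr %*% xi))
  }
}

#' Solve the SPFD system
#'
#' Conjugate-gradient iteration for the complex symmetric operator (COCG:
#' unconjugated inner products) with diagonal preconditioning and a zero
#' initial guess. The potential is determined up to an additive constant per
#' connected component; the right-hand side is compatible by construction,
#' so the iteration converges in the quotient space.
#'
#' @param system An `spfd_system` from [assemble_spfd()].
#' @param tolerance Relative residual (2-norm) stopping criterion.
#' @param max_iterations Iteration cap.
#' @return List with complex `phi` over active nodes, `residual` (relative),
#'   `iterations`, `residual_history`.
#' @export
solve_spfd <- function(system, tolerance = 1e-12, max_iterations = 20000) {
  stopifnot(inherits(system, "spfd_system"))
  if (!(tolerance > 0 && tolerance < 1)) stopf("tolerance must be in (0, 1)")
  b <- system$b
  bnorm <- sqrt(sum(Mod(b)^2))
  if (bnorm == 0) {
    return(list(phi = complex(length(b)), residual = 0, iterations = 0,
                residual_history = numeric(0)))
  }
  dg <- complex(real = Matrix::diag(system$Lr), imaginary = Matrix::diag(system$Li))
  x <- complex(length(b))
  r <- b
  z <- r / dg
  p <- z
  rz <- sum(r * z)  # unconjugated
  hist <- numeric(0)
  it <- 0
  repeat {
    it <- it + 1
    Ap <- spfd_matvec(system, p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    res <- sqrt(sum(Mod(r)^2)) / bnorm
    hist <- c(hist, res)
    if (res <= tolerance) break
    if (it >= max_iterations)
      stopf("SPFD solver did not converge in %d iterations (residual %.3g); history tail: %s",
            max_iterations, res,
            paste(signif(utils::tail(hist, 5), 3), collapse = ", "))
    z <- r / dg
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  list(phi = x, residual = res, iterations = it, residual_history = hist)
}

#' Derive E, J and B volumes from the solved potential
#'
#' `E = -j w A - grad(phi)` at voxel centers (corner-difference gradient),
#' `J = sigma* E`, `B` is the unperturbed source field (the head does not
#' alter it in this regime, by model assumption).
#'
#' @param solution Output of [solve_spfd()].
#' @param system The `spfd_system` that produced it.
#' @param A_fun Source vector-potential function (as in [assemble_spfd()]).
#' @param B_fun Optional function `(points_mm) -> n x 3` source B (tesla); if
#'   supplied, per-voxel-center B vectors are stored.
#' @return Object of class `field_solution`: complex component arrays `Ex`,
#'   `Ey`, `Ez`, `Jx`, `Jy`, `Jz` (and optionally `Bx`, `By`, `Bz`),
#'   magnitude arrays `J_mag` (A/m^2) and `E_mag`, the node potential array
#'   `phi`, frequency and solver stats.
#' @export
fields_from_potential <- function(solution, system, A_fun, B_fun = NULL) {
  dims <- system$dims
  nd <- system$node_dims
  vs_m <- system$voxel_size_mm * 1e-3
  phi <- array(0 + 0i, nd)
  phi[system$active_nodes] <- solution$phi
  # corner-difference gradient at voxel centers: average the 4 parallel edge
  # differences of each voxel
  gr <- function(ax) {
    idx <- function(o) {
      sel <- lapply(1:3, function(a) {
        n <- dims[a]
        if (a == ax) (1:n) + o[a] else (1:n) + o[a]
      })
      phi[sel[[1]], sel[[2]], sel[[3]], drop = FALSE]
    }
    perp <- setdiff(1:3, ax)
    acc <- array(0 + 0i, dims)
    for (o1 in 0:1) for (o2 in 0:1) {
      off_lo <- c(0L, 0L, 0L); off_lo[perp[1]] <- o1; off_lo[perp[2]] <- o2
      off_hi <- off_lo; off_hi[ax] <- 1L
      acc <- acc + (idx(off_hi) - idx(off_lo))
    }
    acc / (4 * vs_m)
  }
  centers <- voxel_center_matrix(dims, system$voxel_size_mm, system$origin_mm)
  Ac <- A_fun(centers)
  jw <- 1i * system$omega
  E <- list(x = array(-jw * Ac[, 1], dims) - gr(1),
            y = array(-jw * Ac[, 2], dims) - gr(2),
            z = array(-jw * Ac[, 3], dims) - gr(3))
  sg <- system$sigma_star
  J <- list(x = sg * E$x, y = sg * E$y, z = sg * E$z)
  out <- list(frequency = system$frequency,
              Ex = E$x, Ey = E$y, Ez = E$z,
              Jx = J$x, Jy = J$y, Jz = J$z,
              E_mag = sqrt(Mod(E$x)^2 + Mod(E$y)^2 + Mod(E$z)^2),
              J_mag = sqrt(Mod(J$x)^2 + Mod(J$y)^2 + Mod(J$z)^2),
              phi = phi, voxel_size_mm = system$voxel_size_mm,
              origin_mm = system$origin_mm,
              solver_stats = list(iterations = solution$iterations,
                                  residual = solution$residual))
  if (!is.null(B_fun)) {
    Bc <- B_fun(centers)
    out$Bx <- array(Bc[, 1], dims); out$By <- array(Bc[, 2], dims)
    out$Bz <- array(Bc[, 3], dims)
    out$B_mag <- array(row_norms(Bc), dims)
  }
  structure(out, class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("Field solution at %g Hz: max |J| %.3g mA/m^2, solver %d iterations (residual %.2g)\n",
              x$frequency, 1e3 * max(x$J_mag), x$solver_stats$iterations,
              x$solver_stats$residual))
  invisible(x)
}

#' Discrete charge-conservation check
#'
#' Recomputes the net current into every node directly from the edge
#' conductances and the solved potentials/EMFs (independent flux sum, not the
#' solver's own residual vector) and reports
#' `max |net current| / (h^2 max |J|)` -- the dimensionless divergence
#' metric that should vanish to solver tolerance on interior nodes.
#'
#' @param solution [solve_spfd()] output.
#' @param system The assembled `spfd_system`.
#' @param A_fun The source vector-potential function.
#' @param J_max Maximum current density magnitude (A/m^2) used for
#'   normalisation (e.g. from [fields_from_potential()]).
#' @return The conservation metric (dimensionless).
#' @export
divergence_metric <- function(solution, system, A_fun, J_max) {
  nd <- system$node_dims
  vs_m <- system$voxel_size_mm * 1e-3
  phi <- array(0 + 0i, nd)
  phi[system$active_nodes] <- solution$phi
  net <- array(0 + 0i, nd)
  for (ax in 1:3) {
    S <- edge_conductance(system$sigma_star, vs_m, ax)
    em <- edge_midpoints_mm(system$dims, system$voxel_size_mm, system$origin_mm, ax)
    ed <- em$dims
    A_edge <- array(0, ed)
    keep <- which(Mod(S) > 0)
    if (length(keep) == 0) next
    A_edge[keep] <- A_fun(em$pts[keep, , drop = FALSE])[, ax]
    lo <- lapply(1:3, function(a) seq_len(ed[a]))
    hi <- lo; hi[[ax]] <- lo[[ax]] + 1L
    phi1 <- phi[lo[[1]], lo[[2]], lo[[3]], drop = FALSE]
    phi2 <- phi[hi[[1]], hi[[2]], hi[[3]], drop = FALSE]
    # current flowing node1 -> node2 along each edge
    Ie <- S * (phi1 - phi2 - 1i * system$omega * vs_m * A_edge)
    net[lo[[1]], lo[[2]], lo[[3]]] <- net[lo[[1]], lo[[2]], lo[[3]]] - Ie
    net[hi[[1]], hi[[2]], hi[[3]]] <- net[hi[[1]], hi[[2]], hi[[3]]] + Ie
  }
  max(Mod(net)) / (vs_m^2 * J_max)
}

#' Solve the induced-field problem over a harmonic band
#'
#' One SPFD solve per harmonic frequency, with that frequency's interpolated
#' tissue properties. When `fast_mode = TRUE` and the phantom's properties
#' are verified frequency-independent (non-dispersive, negligible
#' displacement term), a single unit-frequency solve is scaled analytically
#' (phi and E are proportional to omega).
#'
#' @param phantom A [voxel_phantom()].
#' @param A_fun Unit-current vector-potential function `(points_mm) -> n x 3`.
#' @param harmonics A [harmonic_set()]; fields are computed per unit current
#'   (scale by the harmonic amplitudes when recomposing time courses).
#' @param tolerance,max_iterations Solver controls.
#' @param fast_mode Attempt the single-solve omega-scaling shortcut.
#' @param displacement Include displacement currents.
#' @param progress Emit a message per frequency.
#' @return List of `field_solution` objects, one per frequency.
#' @export
solve_band <- function(phantom, A_fun, harmonics, tolerance = 1e-12,
                       max_iterations = 20000, fast_mode = FALSE,
                       displacement = TRUE, progress = FALSE) {
  stopifnot(inherits(harmonics, "harmonic_set"))
  freqs <- harmonics$frequencies
  if (length(freqs) == 0) stopf("harmonic set is empty")
  if (fast_mode) {
    disp_ok <- !displacement
    if (!disp_ok) {
      # displacement currents make sigma* frequency-dependent; fast mode is
      # only exact when they are absent
      eps_max <- max(vapply(phantom$tissue_table, function(p)
        max(p$eps_r_tab), numeric(1)))
      disp_ok <- eps_max * EPS0 * 2 * pi * max(freqs) <
        1e-12 * min(vapply(phantom$tissue_table, function(p)
          min(p$sigma_S_per_m[p$sigma_S_per_m > 0]), numeric(1)))
    }
    dispersive <- any(vapply(phantom$tissue_table, function(p) {
      diff(range(p$sigma_S_per_m)) > 0 || diff(range(p$eps_r_tab)) > 0
    }, logical(1)))
    if (dispersive || !disp_ok) {
      warnf("fast mode requires non-dispersive, displacement-free properties; using full solves")
      fast_mode <- FALSE
    }
  }
  if (fast_mode) {
    f_ref <- freqs[1]
    sys <- assemble_spfd(phantom, A_fun, f_ref, displacement = FALSE)
    sol <- solve_spfd(sys, tolerance, max_iterations)
    ref <- fields_from_potential(sol, sys, A_fun)
    lapply(freqs, function(f) {
      s <- f / f_ref
      out <- ref
      out$frequency <- f
      for (nm in c("Ex", "Ey", "Ez", "Jx", "Jy", "Jz", "phi")) out[[nm]] <- ref[[nm]] * s
      out$E_mag <- ref$E_mag * s; out$J_mag <- ref$J_mag * s
      out
    })
  } else {
    lapply(freqs, function(f) {
      if (progress) message(sprintf("SPFD solve at %g Hz", f))
      sys <- assemble_spfd(phantom, A_fun, f, displacement = displacement)
      sol <- solve_spfd(sys, tolerance, max_iterations)
      fields_from_potential(sol, sys, A_fun)
    })
  }
}

#' Nearest-neighbour label resampling of a phantom to a new voxel size
#'
#' Used to run the solver at a coarser resolution than the phantom grid.
#' @param phantom A [voxel_phantom()].
#' @param new_voxel_size_mm Target isotropic voxel size.
#' @export
resample_phantom <- function(phantom, new_voxel_size_mm) {
  if (abs(new_voxel_size_mm - phantom$voxel_size_mm) < 1e-12) return(phantom)
  d <- dim(phantom$labels)
  extent <- d * phantom$voxel_size_mm
  td <- pmax(8L, as.integer(ceiling(extent / new_voxel_size_mm)))
  src_idx <- lapply(1:3, function(ax) {
    x <- ((seq_len(td[ax]) - 0.5) * new_voxel_size_mm) / phantom$voxel_size_mm + 0.5
    pmin(pmax(round(x), 1), d[ax])
  })
  labs <- phantom$labels[src_idx[[1]], src_idx[[2]], src_idx[[3]]]
  voxel_phantom(labs, new_voxel_size_mm, phantom$origin_mm,
                phantom$tissue_table, name = paste0(phantom$name, "_resampled"))
}
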