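# SPFD solver: assembly structure, scaling laws, the conducting-sphere
# eddy-current oracle, conservation and band solving.

uniform_A <- function(B0) function(pts) uniform_field_A(pts, B0)

test_that("assembled operator rows sum to zero (charge conservation by construction)", {
  ph <- sphere_phantom(radius_mm = 20, voxel_size_mm = 4)
  sys <- assemble_spfd(ph, uniform_A(c(0, 0, 1e-3)), 1000, displacement = FALSE)
  rs <- Matrix::rowSums(sys$Lr)
  expect_lt(max(abs(rs)), 1e-15 * max(abs(sys$Lr@x)))
  # RHS is compatible (sums to zero over each component)
  expect_lt(Mod(sum(sys$b)), 1e-12 * sqrt(sum(Mod(sys$b)^2)))
})

test_that("scaling the conductivity leaves phi unchanged and scales J", {
  phA <- sphere_phantom(radius_mm = 20, voxel_size_mm = 4, sigma = 0.1)
  phB <- sphere_phantom(radius_mm = 20, voxel_size_mm = 4, sigma = 0.2)
  Af <- uniform_A(c(0, 0.2e-3, 1e-3))
  sysA <- assemble_spfd(phA, Af, 500, displacement = FALSE)
  sysB <- assemble_spfd(phB, Af, 500, displacement = FALSE)
  solA <- solve_spfd(sysA); solB <- solve_spfd(sysB)
  expect_lt(max(Mod(solA$phi - solB$phi)), 1e-9 * max(Mod(solA$phi)))
  fA <- fields_from_potential(solA, sysA, Af)
  fB <- fields_from_potential(solB, sysB, Af)
  expect_equal(fB$J_mag, 2 * fA$J_mag, tolerance = 1e-9)
})

test_that("the static limit and the zero-source solve are exactly zero", {
  ph <- sphere_phantom(radius_mm = 20, voxel_size_mm = 4)
  Af <- uniform_A(c(0, 0, 1e-3))
  sys0 <- assemble_spfd(ph, Af, 0, displacement = FALSE)
  expect_true(all(Mod(sys0$b) == 0))
  sol0 <- solve_spfd(sys0)
  expect_equal(sol0$iterations, 0)
  expect_true(all(Mod(sol0$phi) == 0))
  f0 <- fields_from_potential(sol0, sys0, Af)
  expect_true(all(f0$J_mag == 0))
  # air voxels never carry current
  ph2 <- sphere_phantom(radius_mm = 20, voxel_size_mm = 4)
  sys <- assemble_spfd(ph2, Af, 1000, displacement = FALSE)
  f <- fields_from_potential(solve_spfd(sys), sys, Af)
  expect_true(all(f$J_mag[ph2$labels == 0L] == 0))
})

test_that("a phantom with no conducting voxels is refused", {
  tt <- list("9" = tissue_properties("x", c(50, 7500), c(1, 1), c(1, 1)))
  labs <- array(0L, c(8, 8, 8))
  ph <- voxel_phantom(labs, 4, tissue_table = tt)
  expect_error(assemble_spfd(ph, uniform_A(c(0, 0, 1e-3)), 100),
               "no conducting")
})

test_that("reversing the source negates the induced fields exactly", {
  ph <- sphere_phantom(radius_mm = 20, voxel_size_mm = 4)
  Ap <- uniform_A(c(0, 0, 1e-3)); Am <- uniform_A(c(0, 0, -1e-3))
  sp <- assemble_spfd(ph, Ap, 750, displacement = FALSE)
  sm <- assemble_spfd(ph, Am, 750, displacement = FALSE)
  fp <- fields_from_potential(solve_spfd(sp), sp, Ap)
  fm <- fields_from_potential(solve_spfd(sm), sm, Am)
  expect_equal(fm$Jx, -fp$Jx, tolerance = 1e-10)
  expect_equal(fm$Jz, -fp$Jz, tolerance = 1e-10)
})

test_that("tightening the tolerance never worsens the achieved residual", {
  ph <- sphere_phantom(radius_mm = 24, voxel_size_mm = 3)
  sys <- assemble_spfd(ph, uniform_A(c(0.3e-3, 0, 1e-3)), 1000,
                       displacement = FALSE)
  r1 <- solve_spfd(sys, tolerance = 1e-6)$residual
  r2 <- solve_spfd(sys, tolerance = 5e-7)$residual
  expect_lte(r2, r1)
  expect_lte(r1, 1e-6)
  expect_error(solve_spfd(sys, tolerance = 2), "tolerance")
})

test_that("the solver reproduces the conducting-sphere eddy-current profile", {
  # sigma = 0.1 S/m sphere, radius 50 mm, uniform 1 mT B_z at 1 kHz:
  # |J| = sigma pi f B rho; checked at 4 mm here (finer grids in the
  # acceptance suite, converging monotonically)
  errs <- vapply(c(8, 4), function(vs) {
    ph <- sphere_phantom(radius_mm = 50, voxel_size_mm = vs)
    Af <- uniform_A(c(0, 0, 1e-3))
    sys <- assemble_spfd(ph, Af, 1000, displacement = FALSE)
    sol <- solve_spfd(sys)
    f <- fields_from_potential(sol, sys, Af)
    rr <- phantom_radii(ph)
    inside <- ph$labels == 9L & rr$r < 45
    Jex <- eddy_J_exact(0.1, 1000, 1e-3, rr$rho[inside] * 1e-3)
    sqrt(sum((f$J_mag[inside] - Jex)^2) / sum(Jex^2))
  }, numeric(1))
  expect_lt(errs[2], 0.05)
  expect_lt(errs[2], errs[1])  # grid refinement reduces the oracle error
})

test_that("charge is conserved to solver precision (independent flux sum)", {
  ph <- sphere_phantom(radius_mm = 30, voxel_size_mm = 3)
  Af <- uniform_A(c(0, 0.4e-3, 0.9e-3))
  sys <- assemble_spfd(ph, Af, 2000, displacement = FALSE)
  sol <- solve_spfd(sys, tolerance = 1e-12)
  f <- fields_from_potential(sol, sys, Af)
  expect_lt(divergence_metric(sol, sys, Af, max(f$J_mag)), 1e-8)
})

test_that("solve_band returns one solution per harmonic and a fast-mode shortcut", {
  tt_const <- list("9" = tissue_properties("c", c(50, 7500), c(0.2, 0.2),
                                           c(1, 1)))
  labs <- sphere_phantom(radius_mm = 20, voxel_size_mm = 4)$labels
  ph <- voxel_phantom(labs, 4, tissue_table = tt_const)
  h <- harmonic_set(c(100, 200, 300), c(1, 0.5, 0.25) + 0i, fundamental = 100)
  Af <- uniform_A(c(0, 0, 1e-3))
  full <- solve_band(ph, Af, h, displacement = FALSE)
  expect_length(full, 3)
  expect_equal(vapply(full, `[[`, numeric(1), "frequency"), c(100, 200, 300))
  fast <- solve_band(ph, Af, h, displacement = FALSE, fast_mode = TRUE)
  for (k in 1:3) {
    denom <- max(full[[k]]$J_mag)
    expect_lt(max(abs(fast[[k]]$J_mag - full[[k]]$J_mag)) / denom, 1e-6)
  }
  expect_error(solve_band(ph, Af, harmonic_set(numeric(0), complex(0))),
               "at least one")
  # dispersive properties refuse the shortcut
  ph_disp <- sphere_phantom(radius_mm = 20, voxel_size_mm = 4)
  expect_warning(solve_band(ph_disp, Af, h, fast_mode = TRUE,
                            displacement = TRUE),
                 "fast mode")
})

test_that("displacement currents scale |J| by the complex-conductivity magnitude", {
  # uniform sphere in uniform B_z: phi = 0, E = -j w A independent of the
  # material, so J = sigma* E and |J| scales by |sigma*| / sigma exactly
  ph <- sphere_phantom(radius_mm = 20, voxel_size_mm = 4, sigma = 0.1,
                       eps_r = 1e5)
  Af <- uniform_A(c(0, 0, 1e-3))
  s_on <- assemble_spfd(ph, Af, 7500, displacement = TRUE)
  s_off <- assemble_spfd(ph, Af, 7500, displacement = FALSE)
  expect_true(s_on$has_imag)
  f_on <- fields_from_potential(solve_spfd(s_on), s_on, Af)
  f_off <- fields_from_potential(solve_spfd(s_off), s_off, Af)
  tan_loss <- 2 * pi * 7500 * 8.8541878128e-12 * 1e5 / 0.1
  inside <- ph$labels == 9L
  ratio <- f_on$J_mag[inside] / f_off$J_mag[inside]
  expect_equal(stats::median(ratio), sqrt(1 + tan_loss^2), tolerance = 0.01)
})
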