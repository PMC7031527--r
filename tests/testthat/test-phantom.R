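# Synthetic phantom generator: layered head, tissue properties, lesions,
# ground-truth evolution, MRI-like rendering, NIfTI round trips.

test_that("layered head shells match analytic sphere-shell volumes", {
  ph <- build_layered_head(radius_mm = 90, voxel_size_mm = 2,
                           layer_thicknesses_mm = c(skin = 4, skull = 7, csf = 3))
  # bounds: skin 86-90, skull 79-86, csf 76-79, white core < 76
  shell <- function(r1, r0) 4 / 3 * pi * (r1^3 - r0^3)
  vox <- 2^3
  expect_equal(sum(ph$labels == 1L) * vox, shell(90, 86), tolerance = 0.05)
  expect_equal(sum(ph$labels == 2L) * vox, shell(86, 79), tolerance = 0.05)
  expect_equal(sum(ph$labels == 3L) * vox, shell(79, 76), tolerance = 0.05)
  expect_equal(sum(ph$labels == 5L) * vox, 4 / 3 * pi * 76^3, tolerance = 0.05)
  # no grey layer requested -> label absent; grid dims follow construction
  expect_false(any(ph$labels == 4L))
  expect_equal(dim(ph$labels), rep(ceiling(2 * 90 / 2) + 4, 3))
})

test_that("a zero-thickness layer is absent and thin layers are refused", {
  ph <- build_layered_head(voxel_size_mm = 2,
                           layer_thicknesses_mm = c(skin = 4, skull = 7,
                                                    csf = 0, grey = 4))
  expect_false(any(ph$labels == 3L))
  expect_error(build_layered_head(voxel_size_mm = 5), "thinnest layer")
})

test_that("phantom constructor validates labels, grid and properties", {
  expect_error(voxel_phantom(array(0L, c(4, 4, 4)), 1), "at least 8")
  labs <- array(0L, c(8, 8, 8)); labs[4, 4, 4] <- 99L
  expect_error(voxel_phantom(labs, 1), "without tissue properties")
})

test_that("edema takes constant conductivity 1.7 S/m and grey-matter permittivity", {
  tab <- default_tissue_table()
  ed <- tab[["6"]]; gm <- tab[["4"]]
  expect_equal(ed$sigma(50), 1.7)
  expect_equal(ed$sigma(7500), 1.7)
  expect_equal(ed$sigma(632), 1.7)
  expect_equal(ed$eps_r_tab, gm$eps_r_tab)
  expect_equal(ed$eps_r(1000), gm$eps_r(1000))
  # complex conductivity follows sigma + j 2 pi f eps0 eps_r directly; with
  # a non-dispersive permittivity (CSF) the imaginary part grows with f
  f <- c(50, 500, 7500)
  expect_equal(Im(complex_conductivity(ed, f)),
               2 * pi * f * 8.8541878128e-12 * ed$eps_r(f), tolerance = 1e-12)
  expect_equal(Re(complex_conductivity(ed, f)), rep(1.7, 3))
  csf <- tab[["3"]]
  expect_true(all(diff(Im(complex_conductivity(csf, f))) > 0))
  expect_error(tissue_properties("bad", c(50, 7500), c(-1, 1), c(1, 1)),
               "non-negative")
  expect_error(tissue_properties("short", c(100, 7500), c(1, 1), c(1, 1)),
               "cover")
})

test_that("lesion generation is reproducible, monotone in size, and ellipsoidal at zero irregularity", {
  ph <- build_layered_head(voxel_size_mm = 2)
  les <- generate_lesion(ph, c(48, 0, 0), c(24, 20, 18), irregularity = 0,
                         seed = 5)
  vol <- sum(les) * 8
  expect_equal(vol, 4 / 3 * pi * 24 * 20 * 18, tolerance = 0.05)
  les2 <- generate_lesion(ph, c(48, 0, 0), c(24, 20, 18), irregularity = 0,
                          seed = 5)
  expect_identical(les, les2)
  irr1 <- generate_lesion(ph, c(48, 0, 0), c(15, 12, 12), irregularity = 0.2,
                          seed = 9)
  irr2 <- generate_lesion(ph, c(48, 0, 0), c(15, 12, 12), irregularity = 0.2,
                          seed = 9)
  expect_identical(irr1, irr2)
  small <- generate_lesion(ph, c(48, 0, 0), c(10, 8, 8), irregularity = 0,
                           seed = 5)
  expect_gt(sum(les), sum(small))
  expect_error(generate_lesion(ph, c(0, 0, 200), c(10, 10, 10)),
               "not inside the brain")
  expect_error(generate_lesion(ph, c(70, 0, 0), c(12, 10, 10),
                               irregularity = 0, seed = 1, strict = TRUE),
               "outside the brain")
})

test_that("lesion evolution obeys the Bernoulli retention expectation", {
  # uniform field: retention probability is exactly (M/100) exp(a B)
  dims <- c(24, 24, 16)
  pre <- array(TRUE, dims)  # 9216 voxels
  field <- array(2, dims)   # 2 mT everywhere
  post <- evolve_lesion(pre, field, M_true = 80, a_true = -0.1,
                        growth_rate_untreated = 0, seed = 11)
  p <- 0.8 * exp(-0.2)
  se <- sqrt(p * (1 - p) / prod(dims))
  expect_lt(abs(sum(post) / prod(dims) - p), 3 * se)
  # null law: expected post volume equals pre volume
  post0 <- evolve_lesion(pre, field, M_true = 100, a_true = 0,
                         growth_rate_untreated = 0, seed = 12)
  se0 <- sqrt(0.5 / prod(dims))  # bound on binomial SE
  expect_lt(abs(sum(post0) / prod(dims) - 1), 3 * se0)
  # determinism and config validation
  expect_identical(post, evolve_lesion(pre, field, M_true = 80, a_true = -0.1,
                                       growth_rate_untreated = 0, seed = 11))
  expect_error(evolve_lesion(pre, field, M_true = -5), "positive")
  expect_error(evolve_lesion(pre, field, growth_rate_untreated = -1),
               "non-negative")
})

test_that("below-floor lesion regions grow at the untreated rate", {
  dims <- c(20, 20, 20)
  pre <- array(FALSE, dims); pre[6:15, 6:15, 6:15] <- TRUE
  field <- array(0.1, dims)  # everywhere below the floor
  post <- evolve_lesion(pre, field, M_true = 80, a_true = -0.5,
                        growth_rate_untreated = 0.2, exposure_floor_mT = 1,
                        seed = 3)
  expect_true(all(post[pre]))          # unexposed voxels persist
  added <- sum(post) - sum(pre)
  n <- sum(pre)
  se <- sqrt(0.2 * 0.8 * n)
  expect_lt(abs(added - 0.2 * n), 4 * se)
})

test_that("MRI-like rendering is deterministic with the requested contrast", {
  ph <- build_layered_head(voxel_size_mm = 4,
                           layer_thicknesses_mm = c(skin = 4, skull = 8,
                                                    grey = 6))
  les <- generate_lesion(ph, c(40, 0, 0), c(12, 10, 10), irregularity = 0,
                         seed = 2)
  r0 <- render_mri_like(ph, les, noise_sd = 0, seed = 1)
  expect_true(all(r0$volume[les] == max(r0$volume)))
  expect_length(unique(as.vector(r0$volume)), length(unique(as.vector(ph$labels))) + 1)
  r1 <- render_mri_like(ph, les, noise_sd = 25, seed = 7)
  r2 <- render_mri_like(ph, les, noise_sd = 25, seed = 7)
  expect_identical(r1$volume, r2$volume)
  expect_equal(r1$cnr, (900 - 400) / 25, tolerance = 1e-3)
  expect_error(render_mri_like(ph, les, noise_sd = -1), "non-negative")
})

test_that("phantom and mask volumes survive a NIfTI round trip", {
  ph <- build_layered_head(voxel_size_mm = 4,
                           layer_thicknesses_mm = c(skin = 4, skull = 8,
                                                    grey = 6))
  les <- generate_lesion(ph, c(40, 0, 0), c(12, 10, 10), irregularity = 0.2,
                         seed = 4)
  tmp <- withr::local_tempdir()
  write_phantom_nifti(ph$labels, ph, file.path(tmp, "labels.nii.gz"))
  back <- read_labels_nifti(file.path(tmp, "labels.nii.gz"))
  expect_identical(array(as.integer(back), dim(back)), ph$labels)
  expect_lt(max(abs(attr(back, "affine") - phantom_affine(ph))), 1e-6)
  write_mask(les, ph, file.path(tmp, "mask.nii.gz"))
  mback <- read_mask(file.path(tmp, "mask.nii.gz"))
  expect_equal(sum(mback), sum(les))
  expect_identical(array(mback, dim(mback)), les)
  expect_warning(write_mask(array(FALSE, dim(ph$labels)), ph,
                            file.path(tmp, "empty.nii.gz")), "empty")
  expect_true(file.exists(file.path(tmp, "empty.nii.gz")))
})

test_that("the shipped tissue table CSV round-trips through the reader", {
  path <- system.file("extdata", "tissue_properties_default.csv",
                      package = "pemfdose")
  tab <- read_tissue_table(path)
  ref <- default_tissue_table()
  expect_setequal(names(tab), names(ref))
  for (lb in names(ref)) {
    expect_equal(tab[[lb]]$sigma_S_per_m, ref[[lb]]$sigma_S_per_m)
    expect_equal(tab[[lb]]$eps_r_tab, ref[[lb]]$eps_r_tab)
    expect_identical(tab[[lb]]$name, ref[[lb]]$name)
  }
  expect_error(suppressWarnings(read_tissue_table(tempfile())),
               "cannot open|No such|does not exist")
})
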