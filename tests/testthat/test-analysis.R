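# Exposure summaries, slicing, ratio tables, threshold curves and the
# exponential dose-response fit.

test_that("exposure summary reports extremes, mode and locations", {
  d <- c(10, 10, 10)
  mask <- array(FALSE, d); mask[3:8, 3:8, 3:8] <- TRUE
  uni <- array(1.5, d)
  s <- exposure_summary(uni, mask, bin_width = 0.05, voxel_size_mm = 2)
  expect_equal(s$min_value, 1.5)
  expect_equal(s$max_value, 1.5)
  expect_equal(s$mode_value, 1.525)  # center of the [1.5, 1.55) bin
  expect_equal(sum(s$counts), sum(mask))
  expect_equal(s$volume_mm3, sum(mask) * 8)
  expect_error(exposure_summary(uni, array(FALSE, d)), "empty")

  # gradient over a wedge-shaped mask: the mode is the bin covering the
  # largest cross-section, verified against exhaustive counting
  set.seed(4)
  grad <- array(rep(seq(0.52, 2.48, length.out = d[1]), times = prod(d[2:3])), d)
  wedge <- array(FALSE, d)
  for (i in 1:10) wedge[i, 1:i, 1:5] <- TRUE
  s2 <- exposure_summary(grad, wedge, bin_width = 0.1)
  vals <- grad[wedge]
  lo <- floor(min(vals) / 0.1) * 0.1
  counts <- table(floor((vals - lo) / 0.1))
  best <- as.integer(names(which.max(counts)))
  expect_equal(s2$mode_value, lo + (best + 0.5) * 0.1, tolerance = 1e-9)
  expect_equal(grad[s2$min_voxel[1], s2$min_voxel[2], s2$min_voxel[3]],
               min(vals))
  expect_equal(grad[s2$max_voxel[1], s2$max_voxel[2], s2$max_voxel[3]],
               max(vals))
})

test_that("coil-frame slicing recovers symmetric sphere cross-sections", {
  # 2 mm voxels with 4 mm slabs along a grid-aligned d axis: every slab
  # holds exactly two voxel layers, so slab areas average adjacent layers
  ph <- build_layered_head(voxel_size_mm = 2)
  sphere <- generate_lesion(ph, c(48, 0, 0), c(20, 20, 20), irregularity = 0,
                            seed = 1)
  coil <- place_coil(ph, sphere, standoff_mm = 5)
  fr <- coil_frame(coil)
  sl <- coil_frame_slices(sphere, sphere, ph, fr, plane = "d", spacing_mm = 4)
  expect_equal(sl$area_pre_mm2, sl$area_post_mm2)  # identical masks
  areas <- sl$area_pre_mm2[sl$area_pre_mm2 > 0]
  # maximal at the central slice, decaying towards both ends
  peak <- which.max(areas)
  expect_true(all(diff(areas[seq_len(peak)]) >= -1e-6 * max(areas)))
  expect_true(all(diff(areas[peak:length(areas)]) <= 1e-6 * max(areas)))
  # central cross-section close to the analytic great-circle area
  expect_equal(max(areas), pi * 20^2, tolerance = 0.1)
  expect_error(coil_frame_slices(sphere, sphere, ph, fr, plane = "q"),
               "should be one of|'arg'")
  expect_error(coil_frame_slices(sphere, sphere, ph, fr, spacing_mm = 1),
               "exceed the voxel size")
})

test_that("range-table ratios follow the hand-counted construction", {
  d <- c(12, 12, 12)
  field <- array(0, d)
  field[1:6, , ] <- 1.8   # 864 voxels in [1.7, 2)
  field[7:12, , ] <- 2.5  # 864 voxels in [2, Inf)
  pre <- array(FALSE, d); post <- array(FALSE, d)
  pre[1:5, 1:10, 1:2] <- TRUE            # 100 pre voxels in [1.7, 2)
  idx <- which(field == 1.8 & !pre)[1:47]
  post[idx] <- TRUE                      # 47 post voxels in [1.7, 2)
  tab <- ratio_by_range(pre, post, field, range_edges = c(1, 1.3, 1.7, 2, Inf),
                        voxel_size_mm = 1)
  expect_equal(tab$ratio[tab$range_low == 1.7], 0.47)
  expect_true(is.na(tab$ratio[tab$range_low == 1]))    # the "slash" marker
  expect_true(is.na(tab$ratio[tab$range_low == 1.3]))
  expect_equal(tab$v_pre_mm3[tab$range_low == 1.7], 100)
  # identical masks give unit ratios wherever occupied
  tab2 <- ratio_by_range(pre, pre, field, c(1, 1.7, 2, Inf))
  expect_equal(tab2$ratio[tab2$v_pre_mm3 > 0], 1)
})

test_that("range volumes conserve the total exposed pre-treatment volume", {
  set.seed(9)
  for (rep in 1:5) {
    d <- c(16, 16, 16)
    pre <- random_mask(d, 0.3, seed = rep)
    post <- random_mask(d, 0.25, seed = rep + 100)
    if (!any(pre)) next
    field <- array(runif(prod(d), 0, 3), d)
    edges <- c(0, sort(runif(3, 0.5, 2.5)), Inf)
    tab <- ratio_by_range(pre, post, field, edges)
    expect_equal(sum(tab$v_pre_mm3), sum(pre))
    expect_equal(sum(tab$v_post_mm3), sum(post))
  }
})

test_that("threshold ratios equal brute-force enumeration and range tail sums", {
  for (rep in 1:3) {
    d <- c(12, 11, 10)
    pre <- random_mask(d, 0.35, seed = rep + 7)
    post <- random_mask(d, 0.3, seed = rep + 70)
    set.seed(rep)
    field <- array(runif(prod(d), 0, 2.5), d)
    edges <- c(0.5, 1, 1.5, 2, Inf)
    curve <- suppressMessages(
      ratio_by_threshold(pre, post, field, edges[-length(edges)]))
    oracle <- brute_ratio_by_threshold(pre, post, field, edges[-length(edges)])
    keep <- oracle$v_pre_mm3 > 0
    expect_equal(curve$v_pre_mm3, oracle$v_pre_mm3[keep])
    expect_equal(curve$v_post_mm3, oracle$v_post_mm3[keep])
    expect_equal(curve$ratio_pct, oracle$ratio_pct[keep])
    # tail-sum identity: threshold volumes are cumulative range volumes
    tab <- ratio_by_range(pre, post, field, edges)
    for (k in seq_along(edges[-length(edges)])) {
      expect_equal(sum(tab$v_pre_mm3[k:nrow(tab)]),
                   oracle$v_pre_mm3[k])
      expect_equal(sum(tab$v_post_mm3[k:nrow(tab)]),
                   oracle$v_post_mm3[k])
    }
  }
})

test_that("the lowest threshold reproduces the whole-mask volume ratio", {
  d <- c(10, 10, 10)
  pre <- random_mask(d, 0.4, seed = 5)
  post <- random_mask(d, 0.3, seed = 6)
  field <- array(runif(prod(d), 1, 2), d)
  r <- ratio_by_threshold(pre, post, field, min(field))
  expect_equal(r$ratio_pct, 100 * sum(post) / sum(pre))
})

test_that("the exponential fit recovers exact and null laws", {
  x <- seq(1, 2.2, by = 0.1)
  exact <- data.frame(threshold = x, ratio_pct = 79.38 * exp(-0.1 * x))
  fit <- fit_dose_response(exact)
  expect_lt(abs(fit$M - 79.38), 1e-6)
  expect_lt(abs(fit$a + 0.1), 1e-9)
  expect_equal(unname(coef(fit)), c(fit$M, fit$a))
  expect_equal(predict(fit, data.frame(threshold = 1.4)),
               fit$M * exp(1.4 * fit$a))
  expect_lt(max(abs(residuals(fit))), 1e-6)

  set.seed(2)
  flat <- data.frame(threshold = x, ratio_pct = 70 + rnorm(length(x), 0, 0.5))
  f0 <- fit_dose_response(flat)
  expect_lt(abs(f0$a), 2 * sqrt(f0$cov[2, 2]))

  expect_error(fit_dose_response(exact[1:2, ]), "at least 3")
  expect_error(fit_dose_response(data.frame(threshold = c(1, 1, 1),
                                            ratio_pct = c(50, 60, 70))),
               "distinct")
})

test_that("pooling preserves case identity and sharpens the fit", {
  x <- seq(1, 2, by = 0.125)
  gen <- function(id, seed) {
    set.seed(seed)
    data.frame(threshold = x,
               ratio_pct = 80 * exp(-0.3 * x) * exp(rnorm(length(x), 0, 0.05)),
               case = id)
  }
  one <- gen("AA", 1)
  pooled <- pool_cases(list(one, gen("BB", 2), gen("CC", 3)))
  expect_identical(pool_cases(list(one)), one)
  expect_setequal(unique(pooled$case), c("AA", "BB", "CC"))
  expect_equal(nrow(pooled), 3 * length(x))
  f1 <- fit_dose_response(one)
  f3 <- fit_dose_response(pooled)
  expect_lt(f3$cov[2, 2], f1$cov[2, 2])
  expect_error(pool_cases(list()), "no cases")
})

test_that("a strictly decreasing retention law yields a non-increasing expected ratio curve", {
  # average the threshold curves over replicates of a steep-gradient fixture
  d <- c(16, 16, 16)
  field <- array(rep(seq(0.5, 3, length.out = d[1]), times = prod(d[2:3])), d)
  pre <- array(TRUE, d)
  thr <- seq(0.6, 2.4, by = 0.3)
  curves <- sapply(1:10, function(s) {
    post <- evolve_lesion(pre, field, M_true = 95, a_true = -0.6,
                          growth_rate_untreated = 0, seed = s)
    ratio_by_threshold(pre, post, field, thr)$ratio_pct
  })
  avg <- rowMeans(curves)
  expect_true(all(diff(avg) < 0))
})

test_that("full-pipeline parameter recovery hits the generator truth", {
  rec <- suppressWarnings(dose_response_recovery(seed = 42))
  expect_gt(rec$n_lesion_voxels, 5000)
  expect_lt(abs(rec$fit$M - rec$M_true) / rec$M_true, 0.15)
  expect_lt(abs(rec$fit$a - rec$a_true) / abs(rec$a_true), 0.15)
})
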