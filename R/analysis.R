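# Post-processing of lesion exposure: histograms over lesion voxels,
# coil-frame slicing, exposure-conditioned pre/post volume ratios
# (range tables and lower-bound-threshold curves) and the pooled
# exponential dose-response fit f(x) = M exp(a x).

#' Exposure summary over a lesion mask
#'
#' Field-magnitude extremes, their voxel locations, and a fixed-bin-width
#' histogram whose modal bin center is the robustness metric used for
#' coil-misplacement sensitivity.
#'
#' @param field_volume Numeric array of field magnitudes at the signal peak
#'   (mT or mA/m^2); may be NA outside the mask.
#' @param mask Logical array, congruent, nonempty.
#' @param bin_width Histogram bin width (default 0.05, i.e. 0.05 mT).
#' @param voxel_size_mm Voxel edge (mm) used to report volume.
#' @return List of class `exposure_summary`: `values`, `breaks`, `counts`,
#'   `mode_value`, `min_value`, `max_value`, `min_voxel`, `max_voxel`
#'   (1-based index triples), `n_voxels`, `volume_mm3`.
#' @export
exposure_summary <- function(field_volume, mask, bin_width = 0.05,
                             voxel_size_mm = 1) {
  if (!all(dim(field_volume) == dim(mask)))
    stopf("field volume and mask grids are not congruent")
  idx <- which(mask)
  if (length(idx) == 0) stopf("mask is empty")
  v <- field_volume[idx]
  if (anyNA(v)) stopf("field volume has NA values inside the mask")
  lo <- floor(min(v) / bin_width) * bin_width
  hi <- ceiling(max(v) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  counts <- tabulate(pmin(floor((v - lo) / bin_width) + 1L, length(breaks) - 1L),
                     nbins = length(breaks) - 1L)
  mode_bin <- which.max(counts)
  i_min <- idx[which.min(v)]; i_max <- idx[which.max(v)]
  structure(list(values = v, breaks = breaks, counts = counts,
                 mode_value = (breaks[mode_bin] + breaks[mode_bin + 1]) / 2,
                 min_value = min(v), max_value = max(v),
                 min_voxel = arrayInd(i_min, dim(mask))[1, ],
                 max_voxel = arrayInd(i_max, dim(mask))[1, ],
                 n_voxels = length(v),
                 volume_mm3 = length(v) * voxel_size_mm^3),
            class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat(sprintf("Exposure over %d voxels (%.0f mm^3): min %.3g, mode %.3g, max %.3g\n",
              x$n_voxels, x$volume_mm3, x$min_value, x$mode_value, x$max_value))
  invisible(x)
}

#' Slice pre/post lesion masks along a coil-frame direction
#'
#' Cuts both masks into slabs of `spacing_mm` perpendicular to the chosen
#' coil-frame axis (`d` = depth from the coil plane, `f` longitudinal, `t`
#' transversal) and reports per-slab cross-section areas plus contour
#' polylines of the slab occupancy in the two in-plane frame coordinates.
#' Offsets for the `d` axis are measured from the coil plane.
#'
#' @param mask_pre,mask_post Logical arrays on the phantom grid.
#' @param phantom The congruent [voxel_phantom()].
#' @param frame A [coil_frame()].
#' @param plane `"d"`, `"f"` or `"t"`.
#' @param spacing_mm Distance between consecutive slices (default 5 mm);
#'   must exceed the voxel size.
#' @return data.frame with `offset_mm` (slab center), `area_pre_mm2`,
#'   `area_post_mm2`; contour polylines in attribute `contours` (a list per
#'   slab with `pre`/`post` lists of xy matrices in frame coordinates).
#' @export
coil_frame_slices <- function(mask_pre, mask_post, phantom, frame,
                              plane = c("d", "f", "t"), spacing_mm = 5) {
  plane <- match.arg(plane)
  if (spacing_mm <= phantom$voxel_size_mm)
    stopf("slice spacing must exceed the voxel size")
  axis_vec <- switch(plane, d = frame$d_axis, f = frame$f_axis, t = frame$t_axis)
  in1 <- switch(plane, d = frame$f_axis, f = frame$d_axis, t = frame$d_axis)
  in2 <- switch(plane, d = frame$t_axis, f = frame$t_axis, t = frame$f_axis)
  vs <- phantom$voxel_size_mm
  vol <- vs^3
  centers <- voxel_center_matrix(dim(mask_pre), vs, phantom$origin_mm)
  rel <- sweep(centers, 2, frame$origin)
  proj <- as.numeric(rel %*% axis_vec)
  u <- as.numeric(rel %*% in1); w <- as.numeric(rel %*% in2)
  ipre <- which(mask_pre); ipost <- which(mask_post)
  if (length(ipre) + length(ipost) == 0) stopf("both masks are empty")
  rng <- range(proj[c(ipre, ipost)])
  k0 <- floor(rng[1] / spacing_mm); k1 <- ceiling(rng[2] / spacing_mm)
  slabs <- seq(k0, k1 - 1)
  contour_for <- function(sel) {
    if (length(sel) == 0) return(list())
    gx <- seq(floor(min(u[sel]) / vs) * vs, ceiling(max(u[sel]) / vs) * vs, by = vs)
    gy <- seq(floor(min(w[sel]) / vs) * vs, ceiling(max(w[sel]) / vs) * vs, by = vs)
    if (length(gx) < 3 || length(gy) < 3) return(list())
    occ <- matrix(0, length(gx), length(gy))
    iu <- pmin(pmax(round((u[sel] - gx[1]) / vs) + 1L, 1L), length(gx))
    iw <- pmin(pmax(round((w[sel] - gy[1]) / vs) + 1L, 1L), length(gy))
    occ[cbind(iu, iw)] <- 1
    cl <- grDevices::contourLines(gx, gy, occ, levels = 0.5)
    lapply(cl, function(c0) cbind(c0$x, c0$y))
  }
  out <- data.frame(offset_mm = (slabs + 0.5) * spacing_mm,
                    area_pre_mm2 = NA_real_, area_post_mm2 = NA_real_)
  contours <- vector("list", length(slabs))
  for (s in seq_along(slabs)) {
    lo <- slabs[s] * spacing_mm; hi <- lo + spacing_mm
    selp <- ipre[proj[ipre] >= lo & proj[ipre] < hi]
    sels <- ipost[proj[ipost] >= lo & proj[ipost] < hi]
    out$area_pre_mm2[s] <- length(selp) * vol / spacing_mm
    out$area_post_mm2[s] <- length(sels) * vol / spacing_mm
    contours[[s]] <- list(pre = contour_for(selp), post = contour_for(sels))
  }
  attr(out, "contours") <- contours
  attr(out, "plane") <- plane
  out
}

#' Pre/post volume ratios by exposure range
#'
#' Partitions exposure into contiguous half-open ranges `[low, high)` (the
#' last may be unbounded) and reports, per range, the pre-treatment lesion
#' volume whose exposure falls in the range, the post-treatment lesion
#' volume lying in head regions with exposure in the range, and their ratio
#' (`NA` marks ranges containing neither, the "slash" convention; a ratio
#' above 1 means the lesion enlarged there).
#'
#' @param mask_pre,mask_post Logical arrays.
#' @param field_volume Exposure magnitudes at the signal peak (mT or
#'   mA/m^2), congruent, defined (non-NA) over both masks.
#' @param range_edges Increasing edges; default the clinical B ranges
#'   `c(1, 1.3, 1.7, 2, Inf)` mT.
#' @param voxel_size_mm Voxel edge (mm).
#' @return data.frame of class `ratio_table` with columns `range_low`,
#'   `range_high`, `v_pre_mm3`, `v_post_mm3`, `ratio`.
#' @export
ratio_by_range <- function(mask_pre, mask_post, field_volume,
                           range_edges = c(1, 1.3, 1.7, 2, Inf),
                           voxel_size_mm = 1) {
  if (!all(dim(mask_pre) == dim(field_volume)) ||
      !all(dim(mask_post) == dim(field_volume)))
    stopf("masks and field volume are not congruent")
  if (!any(mask_pre)) stopf("pre-treatment mask is empty")
  if (is.unsorted(range_edges, strictly = TRUE))
    stopf("range edges must be strictly increasing")
  vol <- voxel_size_mm^3
  fpre <- field_volume[mask_pre]; fpost <- field_volume[mask_post]
  if (anyNA(fpre) || anyNA(fpost))
    stopf("field volume has NA values over the masks")
  n <- length(range_edges) - 1
  out <- data.frame(range_low = range_edges[-length(range_edges)],
                    range_high = range_edges[-1],
                    v_pre_mm3 = NA_real_, v_post_mm3 = NA_real_,
                    ratio = NA_real_)
  for (r in seq_len(n)) {
    np <- sum(fpre >= out$range_low[r] & fpre < out$range_high[r])
    ns <- sum(fpost >= out$range_low[r] & fpost < out$range_high[r])
    out$v_pre_mm3[r] <- np * vol
    out$v_post_mm3[r] <- ns * vol
    out$ratio[r] <- if (np == 0 && ns == 0) NA_real_ else ns / np
  }
  class(out) <- c("ratio_table", "data.frame")
  out
}

#' Pre/post volume ratios above lower-bound exposure thresholds
#'
#' For each threshold: `Volume_pre` is the pre-treatment lesion volume
#' exposed at or above the threshold; `Volume_post` is the post-treatment
#' lesion volume lying in regions exposed at or above the threshold; the
#' ratio is reported in percent. Thresholds with zero `Volume_pre` are
#' dropped with a message.
#'
#' @inheritParams ratio_by_range
#' @param thresholds Increasing exposure thresholds.
#' @param case_id Optional case label attached to the rows (for pooling).
#' @return data.frame with `threshold`, `v_pre_mm3`, `v_post_mm3`,
#'   `ratio_pct`, `case`.
#' @export
ratio_by_threshold <- function(mask_pre, mask_post, field_volume, thresholds,
                               voxel_size_mm = 1, case_id = "case") {
  if (!any(mask_pre)) stopf("pre-treatment mask is empty")
  vol <- voxel_size_mm^3
  fpre <- field_volume[mask_pre]; fpost <- field_volume[mask_post]
  if (anyNA(fpre) || anyNA(fpost))
    stopf("field volume has NA values over the masks")
  vpre <- vapply(thresholds, function(th) sum(fpre >= th), numeric(1)) * vol
  vpost <- vapply(thresholds, function(th) sum(fpost >= th), numeric(1)) * vol
  keep <- vpre > 0
  if (any(!keep))
    message(sprintf("dropping %d threshold(s) with no exposed pre-treatment volume",
                    sum(!keep)))
  data.frame(threshold = thresholds[keep], v_pre_mm3 = vpre[keep],
             v_post_mm3 = vpost[keep],
             ratio_pct = 100 * vpost[keep] / vpre[keep],
             case = case_id, stringsAsFactors = FALSE)
}

#' Pool per-case threshold/ratio series
#'
#' Concatenates the per-case series as raw points (no averaging), preserving
#' case identifiers, ready for [fit_dose_response()].
#' @param cases List of data.frames from [ratio_by_threshold()].
#' @export
pool_cases <- function(cases) {
  if (length(cases) == 0) stopf("no cases to pool")
  do.call(rbind, cases)
}

#' Exponential dose-response fit f(x) = M exp(a x)
#'
#' Nonlinear least squares of the percent volume ratio against the exposure
#' threshold, pooled over cases with equal weight per point. The fit is
#' seeded deterministically by log-linear regression of the positive ratios.
#'
#' @param data data.frame with columns `threshold` and `ratio_pct` (and
#'   optionally `case`), e.g. from [ratio_by_threshold()] or [pool_cases()].
#' @return Object of class `dose_response_fit` with components `M`, `a`,
#'   `cov` (2x2 covariance of (M, a)), `n_points`, `data` and the underlying
#'   `nls` fit. Methods: `print`, `summary`, `coef`, `predict`, `plot`,
#'   `residuals`.
#' @examples
#' d <- data.frame(threshold = seq(1, 2.2, by = 0.2),
#'                 ratio_pct = 79.38 * exp(-0.1 * seq(1, 2.2, by = 0.2)))
#' fit <- fit_dose_response(d)
#' coef(fit)
#' @export
fit_dose_response <- function(data) {
  need <- c("threshold", "ratio_pct")
  if (!all(need %in% names(data)))
    stopf("data must have columns: %s", paste(need, collapse = ", "))
  data <- data[is.finite(data$threshold) & is.finite(data$ratio_pct), ]
  if (nrow(data) < 3) stopf("dose-response fit needs at least 3 points")
  if (length(unique(data$threshold)) < 2)
    stopf("dose-response fit needs at least 2 distinct thresholds")
  pos <- data$ratio_pct > 0
  if (sum(pos) >= 2) {
    lm0 <- stats::lm(log(ratio_pct) ~ threshold, data = data[pos, ])
    start <- list(M = exp(stats::coef(lm0)[[1]]), a = stats::coef(lm0)[[2]])
  } else {
    start <- list(M = max(data$ratio_pct, 1), a = -0.1)
  }
  fit <- minpack.lm::nlsLM(ratio_pct ~ M * exp(a * threshold), data = data,
                           start = start,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  structure(list(M = cf[["M"]], a = cf[["a"]], cov = stats::vcov(fit),
                 n_points = nrow(data), data = data, fit = fit),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit: ratio(x) = %.2f * exp(%.4f x)  [%d points]\n",
              x$M, x$a, x$n_points))
  invisible(x)
}

#' @export
summary.dose_response_fit <- function(object, ...) {
  se <- sqrt(diag(object$cov))
  cat(sprintf("Exponential dose-response fit over %d pooled points\n",
              object$n_points))
  cat(sprintf("  M = %.3f (SE %.3f)  [percent ratio at zero exposure]\n",
              object$M, se[1]))
  cat(sprintf("  a = %.4f (SE %.4f) [per exposure unit]\n", object$a, se[2]))
  half <- if (object$a < 0) (log(50 / object$M)) / object$a else NA_real_
  if (is.finite(half) && half > 0)
    cat(sprintf("  50%% volume ratio at exposure ~ %.2f\n", half))
  invisible(object)
}

#' @export
coef.dose_response_fit <- function(object, ...) c(M = object$M, a = object$a)

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$threshold else newdata$threshold
  object$M * exp(object$a * x)
}

#' @export
residuals.dose_response_fit <- function(object, ...) {
  object$data$ratio_pct - predict(object)
}

#' @export
plot.dose_response_fit <- function(x, xlab = "Exposure threshold",
                                   ylab = "Volume ratio post/pre (%)", ...) {
  d <- x$data
  cases <- if ("case" %in% names(d)) factor(d$case) else factor(rep(1, nrow(d)))
  graphics::plot(d$threshold, d$ratio_pct, pch = as.integer(cases),
                 xlab = xlab, ylab = ylab, ...)
  xs <- seq(min(d$threshold), max(d$threshold), length.out = 200)
  graphics::lines(xs, x$M * exp(x$a * xs))
  if (nlevels(cases) > 1)
    graphics::legend("topright", legend = levels(cases),
                     pch = seq_len(nlevels(cases)), bty = "n")
  invisible(x)
}
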