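# Synthetic head phantom: labeled multi-tissue voxel grid, random ischemic
# lesions, an MRI-like rendered volume, and ground-truth lesion evolution
# under a known dose-response law. These stand in for the patient MRI data
# and the licensed anatomical models the clinical workflow uses; they are
# synthetic by construction and labelled as such.

#' Labeled voxel phantom
#'
#' @param labels 3D integer array of tissue labels; 0 is air/background and
#'   every nonzero label must appear in `tissue_table`. Grid dimensions must
#'   be at least 8 per axis.
#' @param voxel_size_mm Isotropic voxel size (mm, > 0).
#' @param origin_mm World coordinate (mm) of the outer corner of voxel
#'   (1,1,1); voxel (i,j,k) owns the half-open cube
#'   `[origin + (i-1) vs, origin + i vs)` per axis.
#' @param tissue_table Named list of [tissue_properties()] keyed by label.
#' @param name Phantom name.
#' @return Object of class `voxel_phantom`.
#' @export
voxel_phantom <- function(labels, voxel_size_mm, origin_mm = NULL,
                          tissue_table = default_tissue_table(),
                          name = "phantom") {
  if (length(dim(labels)) != 3) stopf("labels must be a 3D array")
  if (any(dim(labels) < 8)) stopf("grid dimensions must be at least 8 per axis")
  if (voxel_size_mm <= 0) stopf("voxel_size_mm must be positive")
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(as.character(present), names(tissue_table))
  if (length(missing) > 0)
    stopf("labels without tissue properties: %s", paste(missing, collapse = ", "))
  if (is.null(origin_mm)) origin_mm <- -dim(labels) * voxel_size_mm / 2
  structure(list(labels = labels, voxel_size_mm = voxel_size_mm,
                 origin_mm = as.numeric(origin_mm),
                 tissue_table = tissue_table, name = name),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("Voxel phantom '%s': %d x %d x %d at %g mm, %d tissue labels\n",
              x$name, d[1], d[2], d[3], x$voxel_size_mm,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' 4x4 grid-to-world affine of a phantom (mm)
#' @param phantom A [voxel_phantom()].
#' @export
phantom_affine <- function(phantom) {
  vs <- phantom$voxel_size_mm
  aff <- diag(c(vs, vs, vs, 1))
  # maps 0-based voxel index of a center: origin + (i + 0.5) vs
  aff[1:3, 4] <- phantom$origin_mm + vs / 2
  aff
}

phantom_head_center <- function(phantom) {
  idx <- which(phantom$labels > 0)
  if (length(idx) == 0) return(phantom$origin_mm + dim(phantom$labels) *
                                 phantom$voxel_size_mm / 2)
  mask <- array(FALSE, dim(phantom$labels)); mask[idx] <- TRUE
  mask_centroid_mm(mask, phantom)
}

#' Centroid (mm) of a binary mask on a phantom grid
#' @param mask Logical 3D array.
#' @param phantom The congruent [voxel_phantom()].
#' @export
mask_centroid_mm <- function(mask, phantom) {
  idx <- which(mask)
  if (length(idx) == 0) stopf("mask is empty")
  d <- dim(mask)
  ijk <- arrayInd(idx, d)
  colMeans(sweep(ijk - 0.5, 2, c(0, 0, 0), `+`)) * phantom$voxel_size_mm +
    phantom$origin_mm
}

#' Volume (mm^3) of a binary mask
#' @inheritParams mask_centroid_mm
#' @param voxel_size_mm Voxel edge length (mm).
#' @export
mask_volume_mm3 <- function(mask, voxel_size_mm) sum(mask) * voxel_size_mm^3

#' Build a concentric layered spherical head phantom
#'
#' Outside-in layers: skin, skull, CSF, grey matter, with a white-matter
#' core filling the remainder. A zero-thickness layer is simply absent.
#'
#' @param radius_mm Outer (scalp) radius.
#' @param layer_thicknesses_mm Named numeric vector with entries among
#'   `skin`, `skull`, `csf`, `grey` (mm); defaults
#'   `c(skin = 4, skull = 7, csf = 3, grey = 4)`. Their sum must be smaller
#'   than the radius.
#' @param voxel_size_mm Isotropic voxel size; must not exceed the thinnest
#'   nonzero layer.
#' @param tissue_table Label -> properties map (labels 1..5 as in
#'   [default_tissue_table()]).
#' @param margin_voxels Air margin around the sphere.
#' @return A [voxel_phantom()] centered at the world origin.
#' @export
build_layered_head <- function(radius_mm = 90,
                               layer_thicknesses_mm = c(skin = 4, skull = 7,
                                                        csf = 3, grey = 4),
                               voxel_size_mm = 2,
                               tissue_table = default_tissue_table(),
                               margin_voxels = 2) {
  lt <- c(skin = 0, skull = 0, csf = 0, grey = 0)
  lt[names(layer_thicknesses_mm)] <- layer_thicknesses_mm
  if (any(lt < 0)) stopf("layer thicknesses must be non-negative")
  if (sum(lt) >= radius_mm) stopf("layer thicknesses must sum to less than the radius")
  thin <- min(lt[lt > 0])
  if (length(thin) && voxel_size_mm > thin)
    stopf("voxel size %g mm exceeds the thinnest layer (%g mm); refine the grid",
          voxel_size_mm, thin)
  n <- ceiling(2 * radius_mm / voxel_size_mm) + 2 * margin_voxels
  dims <- rep(n, 3)
  origin <- rep(-n * voxel_size_mm / 2, 3)
  cc <- voxel_center_coords(dims, voxel_size_mm, origin)
  r2 <- outer(outer(cc[[1]]^2, cc[[2]]^2, `+`), cc[[3]]^2, `+`)
  r <- sqrt(r2)
  # boundaries outside-in: skin outer = radius, then cumulative inner radii
  bounds <- radius_mm - cumsum(c(0, lt))
  labels <- array(0L, dims)
  layer_labels <- c(skin = 1L, skull = 2L, csf = 3L, grey = 4L)
  for (i in seq_along(lt)) {
    if (lt[i] == 0) next
    labels[r < bounds[i] & r >= bounds[i + 1]] <- layer_labels[names(lt)[i]]
  }
  labels[r < bounds[length(bounds)]] <- 5L  # white matter core
  voxel_phantom(labels, voxel_size_mm, origin, tissue_table,
                name = sprintf("layered_head_r%g", radius_mm))
}

#' Generate a random ischemic lesion mask inside the brain
#'
#' An ellipsoid with band-limited radial irregularity: the surface radius
#' along each direction is modulated by a smooth random field, then the mask
#' is clipped to grey/white-matter voxels. Reproducible by seed.
#'
#' @param phantom A [voxel_phantom()].
#' @param centroid_mm Lesion center (world mm); must be inside the brain.
#' @param principal_radii_mm Length-3 semi-axes (mm), each > voxel size.
#' @param irregularity Relative amplitude of the radial modulation
#'   (0 = exact ellipsoid).
#' @param seed Integer seed.
#' @param brain_labels Labels the lesion may occupy (default grey/white,
#'   4:5).
#' @param strict Error (rather than clip with a warning) if the nominal
#'   lesion extends outside the brain labels.
#' @return Logical 3D array congruent with the phantom.
#' @export
generate_lesion <- function(phantom, centroid_mm, principal_radii_mm,
                            irregularity = 0.2, seed = 1,
                            brain_labels = c(4L, 5L), strict = FALSE) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (any(principal_radii_mm <= phantom$voxel_size_mm))
    stopf("principal radii must exceed the voxel size")
  d <- dim(phantom$labels)
  cen_vox <- (centroid_mm - phantom$origin_mm) / phantom$voxel_size_mm + 0.5
  lab_at <- phantom$labels[rbind(pmin(pmax(round(cen_vox), 1), d))]
  if (!(lab_at %in% brain_labels))
    stopf("lesion centroid (label %d) is not inside the brain labels", lab_at)
  cc <- voxel_center_coords(d, phantom$voxel_size_mm, phantom$origin_mm)
  dx <- (cc[[1]] - centroid_mm[1]) / principal_radii_mm[1]
  dy <- (cc[[2]] - centroid_mm[2]) / principal_radii_mm[2]
  dz <- (cc[[3]] - centroid_mm[3]) / principal_radii_mm[3]
  rho <- sqrt(outer(outer(dx^2, dy^2, `+`), dz^2, `+`))
  if (irregularity > 0) {
    # smooth random radial modulation: low-order random field in direction
    # space, evaluated via a random trigonometric expansion
    mod <- with_seed(seed, {
      nterms <- 6L
      w <- matrix(stats::rnorm(3 * nterms), nterms, 3)
      ph <- stats::runif(nterms, 0, 2 * pi)
      amp <- stats::rnorm(nterms)
      ux <- outer(outer(dx, 0 * dy, `+`), 0 * dz, `+`)
      uy <- outer(outer(0 * dx, dy, `+`), 0 * dz, `+`)
      uz <- outer(outer(0 * dx, 0 * dy, `+`), dz, `+`)
      den <- pmax(rho, 1e-9)
      ux <- ux / den; uy <- uy / den; uz <- uz / den
      s <- 0
      for (i in seq_len(nterms))
        s <- s + amp[i] * cos(w[i, 1] * ux + w[i, 2] * uy + w[i, 3] * uz + ph[i])
      s / stats::sd(s)
    })
    thresh <- 1 + irregularity * mod
  } else thresh <- 1
  mask <- rho <= thresh
  inside_brain <- array(phantom$labels %in% brain_labels, dim = d)
  escaped <- sum(mask & !inside_brain)
  if (escaped > 0) {
    if (strict) stopf("lesion extends outside the brain labels (%d voxels)", escaped)
    warnf("lesion clipped to brain labels (%d voxels removed)", escaped)
  }
  mask & inside_brain
}

#' Evolve a lesion under a known exposure-dependent retention law
#'
#' Synthetic ground truth for validating the dose-response analysis. Each
#' pre-treatment lesion voxel with peak exposure `B` (mT) at or above
#' `exposure_floor_mT` is retained independently with probability
#' `min(1, (M_true/100) exp(a_true B))`; voxels below the floor are retained
#' and the low-exposure part of the lesion additionally grows by an expected
#' fraction `growth_rate_untreated` into adjacent low-exposure brain tissue,
#' emulating the natural expansion of an untreated ischemic region.
#'
#' @param pre_mask Logical 3D array.
#' @param field_mT Numeric array of peak `|B|` (mT), congruent with the mask.
#' @param M_true,a_true Ground-truth law parameters: retention percent at
#'   zero field and exponential rate per mT. Defaults mirror the fitted
#'   clinical values (M = 79.38, a = -0.1); `M_true` must be positive and
#'   rates non-negative where required.
#' @param growth_rate_untreated Expected fractional growth of the
#'   below-floor lesion volume (default 0.1).
#' @param exposure_floor_mT Exposure below which tissue is treated as
#'   unexposed (default 0; no growth component unless some voxels fall
#'   below).
#' @param brain_mask Logical array of voxels growth may occupy (default:
#'   everywhere outside the pre mask).
#' @param seed Integer seed.
#' @param close_post Apply one morphological closing to the result (off by
#'   default: closing perturbs the exact Bernoulli retention expectation).
#' @return Logical post-treatment mask.
#' @export
evolve_lesion <- function(pre_mask, field_mT, M_true = 79.38, a_true = -0.1,
                          growth_rate_untreated = 0.1, exposure_floor_mT = 0,
                          brain_mask = NULL, seed = 1, close_post = FALSE) {
  if (!all(dim(pre_mask) == dim(field_mT)))
    stopf("field volume and mask grids are not congruent")
  if (M_true <= 0) stopf("M_true must be positive")
  if (growth_rate_untreated < 0) stopf("growth_rate_untreated must be non-negative")
  idx <- which(pre_mask)
  if (length(idx) == 0) stopf("pre-treatment mask is empty")
  b <- field_mT[idx]
  if (anyNA(b)) stopf("field volume has NA values over the lesion")
  with_seed(seed, {
    exposed <- b >= exposure_floor_mT
    p <- pmin(1, (M_true / 100) * exp(a_true * b))
    keep <- logical(length(idx))
    keep[exposed] <- stats::runif(sum(exposed)) < p[exposed]
    keep[!exposed] <- TRUE
    post <- array(FALSE, dim(pre_mask))
    post[idx[keep]] <- TRUE
    n_low <- sum(!exposed)
    if (n_low > 0 && growth_rate_untreated > 0) {
      n_add <- stats::rbinom(1, n_low, min(1, growth_rate_untreated))
      if (n_add > 0) {
        low <- array(FALSE, dim(pre_mask)); low[idx[!exposed]] <- TRUE
        allowed <- if (is.null(brain_mask)) !pre_mask else (brain_mask & !pre_mask)
        allowed <- allowed & (field_mT < exposure_floor_mT)
        grown <- low
        added <- integer(0)
        while (length(added) < n_add) {
          ring <- dilate_mask(grown, 6) & !grown
          cand <- which(ring & allowed)
          if (length(cand) == 0) break
          take <- min(length(cand), n_add - length(added))
          added <- c(added, sample(cand, take))
          grown <- grown | ring
        }
        post[added] <- TRUE
      }
    }
    if (close_post) post <- close_mask(post, 6)
    post
  })
}

#' Render an MRI-like grey-scale volume of the phantom
#'
#' Per-voxel Gaussian noise around a per-label mean intensity; the ischemic
#' lesion is strongly hyperintense (its mean must strictly exceed every
#' tissue mean). Reports the lesion contrast-to-noise ratio against grey
#' matter.
#'
#' @param phantom A [voxel_phantom()].
#' @param lesion_mask Logical array (or NULL for no lesion).
#' @param intensity_table Named numeric vector: mean intensity per label
#'   (names "0".."5") plus `"lesion"`.
#' @param noise_sd Gaussian noise SD (>= 0; 0 gives a piecewise-constant
#'   volume).
#' @param seed Integer seed.
#' @return List with `volume` (numeric array) and `cnr`
#'   (`(I_lesion - I_grey)/noise_sd`, `Inf` when noiseless).
#' @export
render_mri_like <- function(phantom, lesion_mask = NULL,
                            intensity_table = c("0" = 0, "1" = 300, "2" = 120,
                                                "3" = 180, "4" = 400, "5" = 330,
                                                lesion = 900),
                            noise_sd = 30, seed = 1) {
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    stopf("noise_sd must be a non-negative number")
  tissue_means <- intensity_table[setdiff(names(intensity_table), "lesion")]
  if (intensity_table[["lesion"]] <= max(tissue_means))
    stopf("lesion intensity must be strictly the highest")
  vol <- array(0, dim(phantom$labels))
  for (lb in names(intensity_table)) {
    if (lb == "lesion") next
    vol[phantom$labels == as.integer(lb)] <- intensity_table[[lb]]
  }
  if (!is.null(lesion_mask)) vol[lesion_mask] <- intensity_table[["lesion"]]
  if (noise_sd > 0) {
    vol <- vol + with_seed(seed, array(stats::rnorm(length(vol), 0, noise_sd),
                                       dim(vol)))
  }
  grey <- intensity_table[["4"]] %||% max(tissue_means)
  cnr <- if (noise_sd > 0) (intensity_table[["lesion"]] - grey) / noise_sd else Inf
  list(volume = vol, cnr = cnr)
}

#' Write / read a volume on a phantom grid as NIfTI
#'
#' `write_phantom_nifti` stores any congruent array (labels, masks, field
#' magnitudes) with the phantom's affine; `read_mask_nifti` reads a binary
#' mask back as a logical array.
#' @param vol 3D array (logical masks are stored as 0/1 integers).
#' @param phantom The [voxel_phantom()] providing grid geometry.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_phantom_nifti <- function(vol, phantom, path) {
  if (is.logical(vol)) {
    if (!any(vol)) warnf("writing an empty mask to %s", path)
    vol <- array(as.integer(vol), dim(vol))
  }
  img <- RNifti::asNifti(vol)
  vs <- phantom$voxel_size_mm
  img <- RNifti::`pixdim<-`(img, c(vs, vs, vs))
  img <- RNifti::`sform<-`(img, structure(phantom_affine(phantom), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_phantom_nifti
#' @export
read_mask_nifti <- function(path) {
  if (!file.exists(path)) stopf("mask file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img) != 0, dim(img))
  attr(arr, "affine") <- structure(RNifti::xform(img), class = NULL)
  arr
}

#' @rdname write_phantom_nifti
#' @export
read_labels_nifti <- function(path) {
  if (!file.exists(path)) stopf("label file not found: %s", path)
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(as.vector(img))), dim(img))
  attr(arr, "affine") <- structure(RNifti::xform(img), class = NULL)
  arr
}
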