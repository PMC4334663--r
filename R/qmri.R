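#' Quantitative volumetric map
#'
#' A 3-D voxel array with a voxel-to-world affine (RAS mm) and a map type.
#'
#' @param values 3-D numeric array.
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @param map_type One of `"MT"` (p.u.), `"R1"` (1/s), `"R2star"` (1/s), or
#'   another label for generic volumes (probability maps, atlases).
#' @return A `quantitative_map` object.
#' @export
quantitative_map <- function(values, affine, map_type = "generic") {
  if (length(dim(values)) != 3L) stop_input("values must be a 3-D array")
  if (!all(is.finite(values))) stop_input("map values must be finite")
  if (!is.matrix(affine) || any(dim(affine) != 4L)) {
    stop_input("affine must be a 4x4 matrix")
  }
  if (abs(det(affine)) < 1e-12) stop_input("affine must be invertible")
  structure(list(values = values, affine = affine, map_type = map_type),
            class = "quantitative_map")
}

#' @export
print.quantitative_map <- function(x, ...) {
  cat("<quantitative_map> ", x$map_type, ", ",
      paste(dim(x$values), collapse = " x "), " voxels\n", sep = "")
  invisible(x)
}

# voxel sizes (mm per voxel step) from the affine columns
affine_voxel_sizes <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

check_orthogonal_affine <- function(affine) {
  a <- affine[1:3, 1:3]
  g <- crossprod(a)
  off <- g - diag(diag(g))
  if (max(abs(off)) > 1e-6 * max(diag(g))) {
    stop_geometry("sheared/oblique affines are not supported for smoothing")
  }
  invisible(TRUE)
}

# world coordinates (n_vox x 3) of all voxel centres, 0-based indices
voxel_world_coords <- function(dim3, affine) {
  idx <- as.matrix(expand.grid(i = 0:(dim3[1] - 1), j = 0:(dim3[2] - 1),
                               k = 0:(dim3[3] - 1)))
  xyz <- cbind(idx, 1) %*% t(affine)
  xyz[, 1:3, drop = FALSE]
}

#' Estimate R2* from multi-echo signals by log-linear regression
#'
#' Per voxel, ordinary least squares of `log(signal)` on echo time; R2* is
#' minus the slope and the amplitude is `exp(intercept)`. Voxels with any
#' non-positive signal are flagged invalid and returned as `NaN`.
#'
#' @param signals echoes x voxels matrix of signal intensities.
#' @param echo_times_s Echo times in seconds (>= 3, increasing).
#' @return A list: `r2star` (1/s per voxel), `s0` (amplitude), `valid`
#'   (logical mask of voxels fitted).
#' @export
#' @examples
#' te <- default_echo_times()
#' s <- 100 * exp(-19 * te)
#' fit_r2star(matrix(s, ncol = 1), te)$r2star
fit_r2star <- function(signals, echo_times_s) {
  signals <- as.matrix(signals)
  te <- as.numeric(echo_times_s)
  if (length(te) < 3L) stop_input("need at least 3 echoes")
  if (any(diff(te) <= 0)) stop_input("echo times must be strictly increasing")
  if (nrow(signals) != length(te)) {
    stop_input("signals must have one row per echo")
  }
  valid <- colSums(signals <= 0 | !is.finite(signals)) == 0L
  r2 <- rep(NaN, ncol(signals))
  s0 <- rep(NaN, ncol(signals))
  if (any(valid)) {
    x <- cbind(1, te)
    beta <- solve(crossprod(x), crossprod(x, log(signals[, valid, drop = FALSE])))
    r2[valid] <- -beta[2, ]
    s0[valid] <- exp(beta[1, ])
  }
  list(r2star = r2, s0 = s0, valid = valid)
}

#' Default multi-echo grid
#'
#' Eight equidistant echo times from 2.39 to 18.91 ms (spacing 2.36 ms),
#' in seconds.
#' @return Numeric vector of 8 echo times (s).
#' @export
default_echo_times <- function() seq(2.39, 18.91, by = 2.36) / 1000

#' Smooth a quantitative map with a Gaussian kernel
#'
#' Separable Gaussian convolution with `sd = fwhm / 2.3548` per axis,
#' converted to voxels through the affine scales. Edges use renormalised
#' (unit-mass) convolution, so constant maps are unchanged and total mass
#' over a constant-padded field is preserved.
#'
#' @param map A [quantitative_map()].
#' @param fwhm_mm Full width at half maximum in mm (default 3; 0 = identity).
#' @return The smoothed [quantitative_map()].
#' @export
smooth_map <- function(map, fwhm_mm = 3) {
  check_scalar(fwhm_mm, "fwhm_mm")
  if (fwhm_mm < 0) stop_config("fwhm_mm must be >= 0")
  if (fwhm_mm == 0) return(map)
  check_orthogonal_affine(map$affine)
  vox <- affine_voxel_sizes(map$affine)
  vals <- map$values
  ones <- array(1, dim(vals))
  for (ax in 1:3) {
    sd_vox <- fwhm_mm / 2.3548 / vox[ax]
    k <- gauss_kernel(sd_vox)
    if (length(k) > 1L) {
      vals <- conv_axis(vals, k, ax)
      ones <- conv_axis(ones, k, ax)
    }
  }
  out <- map
  out$values <- vals / ones
  out
}

gauss_kernel <- function(sd_vox) {
  r <- ceiling(4 * sd_vox)
  if (r < 1) return(1)
  x <- (-r):r
  k <- exp(-x^2 / (2 * sd_vox^2))
  k / sum(k)
}

# zero-padded 1-D convolution of a 3-D array along axis `ax`
conv_axis <- function(arr, k, ax) {
  d <- dim(arr)
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  r <- (length(k) - 1L) / 2L
  n <- nrow(m)
  padded <- rbind(matrix(0, r, ncol(m)), m, matrix(0, r, ncol(m)))
  out <- matrix(0, n, ncol(m))
  for (s in seq_along(k)) {
    out <- out + k[s] * padded[s:(s + n - 1L), , drop = FALSE]
  }
  res <- array(out, da)
  aperm(res, order(perm))
}

#' Threshold a tissue-probability map into a binary mask
#'
#' Grey matter uses a probability threshold of 0.2, white matter a stricter
#' 0.8; both strict `>` inequalities.
#'
#' @param prob_map A [quantitative_map()] with values in \[0, 1\].
#' @param mode `"GM"` or `"WM"` (sets the default threshold).
#' @param threshold Override threshold in (0, 1).
#' @return Logical 3-D array; attribute `"n_voxels"` holds the voxel count.
#' @export
make_tissue_mask <- function(prob_map, mode = c("GM", "WM"), threshold = NULL) {
  mode <- match.arg(mode)
  p <- prob_map$values
  if (min(p) < 0 || max(p) > 1) stop_input("probability map outside [0, 1]")
  thr <- threshold %||% if (mode == "GM") 0.2 else 0.8
  if (thr <= 0 || thr >= 1) stop_config("threshold must be in (0, 1)")
  mask <- p > thr
  if (!any(mask)) warn(paste0("empty ", mode, " mask at threshold ", thr))
  attr(mask, "n_voxels") <- sum(mask)
  mask
}

#' Region-of-interest definitions and masks
#'
#' An ROI is either a sphere (world-space centre + radius, default 5 mm) or
#' a label in an atlas volume. `roi_mask()` rasterises it on a given grid:
#' sphere membership is by voxel-centre containment (centre within the
#' radius), atlas membership by label equality.
#'
#' @param label ROI name.
#' @param centre_mm Sphere centre (world mm), for spherical ROIs.
#' @param radius_mm Sphere radius (mm), default 5.
#' @param atlas A [quantitative_map()] holding integer labels, for atlas ROIs.
#' @param atlas_label Integer label value within `atlas`.
#' @return `roi_definition()` returns an `roi_definition`; `roi_mask()` a
#'   logical 3-D array.
#' @export
roi_definition <- function(label, centre_mm = NULL, radius_mm = 5,
                           atlas = NULL, atlas_label = NULL) {
  if (is.null(centre_mm) == is.null(atlas)) {
    stop_config("provide exactly one of centre_mm (sphere) or atlas (label)")
  }
  if (!is.null(centre_mm)) {
    check_vec3(centre_mm, "centre_mm")
    if (radius_mm <= 0) stop_config("radius_mm must be positive")
  } else if (is.null(atlas_label)) {
    stop_config("atlas ROIs need atlas_label")
  }
  structure(list(label = label, centre_mm = centre_mm, radius_mm = radius_mm,
                 atlas = atlas, atlas_label = atlas_label),
            class = "roi_definition")
}

#' @rdname roi_definition
#' @param roi An `roi_definition`.
#' @param dim3 Grid dimensions (3 integers); defaults to the atlas grid for
#'   atlas ROIs.
#' @param affine Voxel-to-world affine for the grid.
#' @export
roi_mask <- function(roi, dim3 = NULL, affine = NULL) {
  if (!is.null(roi$atlas)) {
    vals <- roi$atlas$values
    if (!any(vals == roi$atlas_label)) {
      stop_input("atlas label ", roi$atlas_label, " absent from atlas volume")
    }
    return(vals == roi$atlas_label)
  }
  if (is.null(dim3) || is.null(affine)) {
    stop_config("sphere ROIs need dim3 and affine")
  }
  xyz <- voxel_world_coords(dim3, affine)
  d2 <- (xyz[, 1] - roi$centre_mm[1])^2 + (xyz[, 2] - roi$centre_mm[2])^2 +
    (xyz[, 3] - roi$centre_mm[3])^2
  array(d2 <= roi$radius_mm^2, dim3)
}

#' Grey-matter-masked ROI average of a quantitative map
#'
#' Arithmetic mean of the map values over the intersection of the ROI mask
#' with the grey-matter mask.
#'
#' @param map A [quantitative_map()].
#' @param roi_mask Logical 3-D ROI mask.
#' @param gm_mask Logical 3-D grey-matter mask (optional: `NULL` averages
#'   over the ROI alone).
#' @param roi_label Name used in the empty-intersection error message.
#' @return Scalar mean.
#' @export
roi_mean <- function(map, roi_mask, gm_mask = NULL, roi_label = "ROI") {
  sel <- roi_mask
  if (!is.null(gm_mask)) sel <- sel & gm_mask
  if (!any(sel)) {
    stop_input("empty ROI after grey-matter masking: ", roi_label)
  }
  mean(map$values[sel])
}

#' Extract per-(map, ROI) grey-matter-masked means
#'
#' Convenience wrapper running smooth -> mask -> average in the pipeline's
#' fixed order over a set of maps and ROI definitions.
#'
#' @param maps Named list of [quantitative_map()]s (names = map types).
#' @param rois List of [roi_definition()]s.
#' @param gm_prob Grey-matter probability [quantitative_map()].
#' @param fwhm_mm Smoothing FWHM applied to each quantitative map (and to the
#'   probability map before thresholding); 0 disables.
#' @return Tibble with `map`, `roi`, `value`.
#' @export
extract_roi_means <- function(maps, rois, gm_prob, fwhm_mm = 3) {
  gm_s <- smooth_map(gm_prob, fwhm_mm)
  gm_s$values <- pmin(pmax(gm_s$values, 0), 1)
  gm <- make_tissue_mask(gm_s, "GM")
  purrr::map_dfr(names(maps), function(mt) {
    m <- smooth_map(maps[[mt]], fwhm_mm)
    purrr::map_dfr(rois, function(roi) {
      rm_ <- roi_mask(roi, dim(m$values), m$affine)
      tibble(map = mt, roi = roi$label,
             value = roi_mean(m, rm_, gm, roi$label))
    })
  })
}

#' Read/write quantitative maps as NIfTI-1
#'
#' @param map A [quantitative_map()] (write) or file path (read).
#' @param path Output path (`.nii` / `.nii.gz`).
#' @param map_type Map type label to attach on read.
#' @return `write_map_nifti()` the path, invisibly; `read_map_nifti()` a
#'   [quantitative_map()].
#' @export
write_map_nifti <- function(map, path) {
  img <- RNifti::asNifti(map$values)
  RNifti::sform(img) <- structure(map$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_map_nifti
#' @export
read_map_nifti <- function(path, map_type = "generic") {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), code = NULL)
  quantitative_map(array(as.numeric(img), dim(img)[1:3]),
                   matrix(as.numeric(aff), 4, 4), map_type)
}
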