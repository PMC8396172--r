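#' Euclidean distance transform of a mask
#'
#' Distance from every set voxel to the nearest unset voxel, computed with a
#' separable exact squared-distance transform.
#'
#' @param mask a `binary_mask` (or 0/1 array).
#' @param units `"mm"` (default) or `"voxel"`.
#' @return numeric array of distances, 0 on background.
#' @export
distance_transform <- function(mask, units = c("mm", "voxel")) {
  units <- match.arg(units)
  v <- if (is.list(mask)) mask$voxels else mask
  storage.mode(v) <- "integer"
  d <- cpp_edt(v)
  if (units == "mm" && is.list(mask)) d <- d * mask$spacing_um / 1000
  d
}

ball_radius_vox <- function(radius_mm, spacing_um) radius_mm * 1000 / spacing_um

dilate_ball <- function(vox, r_vox) {
  if (r_vox <= 0) return(vox)
  inv <- 1L - vox
  storage.mode(inv) <- "integer"
  d <- cpp_edt(inv)  # distance of background voxels to the mask
  out <- array(as.integer(vox == 1L | d <= r_vox), dim(vox))
  out
}

erode_ball <- function(vox, r_vox) {
  if (r_vox <= 0) return(vox)
  v <- vox
  storage.mode(v) <- "integer"
  d <- cpp_edt(v)    # distance of mask voxels to the background
  array(as.integer(d > r_vox), dim(vox))
}

#' Morphological refinement of a candidate mask
#'
#' Morphological closing with a ball structuring element (dilate then erode)
#' fills internal holes left by vasculature and nodules, followed by an
#' opening (erode then dilate) that removes features smaller than the
#' element. `radius_mm = 0` is the identity.
#'
#' @param mask a `binary_mask`.
#' @param radius_mm ball radius in millimetres (default 0.25).
#' @return refined `binary_mask`.
#' @export
morph_refine <- function(mask, radius_mm = 0.25) {
  if (radius_mm < 0) stop("radius_mm must be >= 0")
  ext <- dim(mask$voxels) * mask$spacing_um / 1000
  if (radius_mm > min(ext))
    stop("structuring element radius exceeds the volume extent")
  if (radius_mm == 0) return(mask)
  r <- ball_radius_vox(radius_mm, mask$spacing_um)
  v <- mask$voxels
  v <- erode_ball(dilate_ball(v, r), r)  # closing
  v <- dilate_ball(erode_ball(v, r), r)  # opening
  binary_mask(v, mask$spacing_um, mask$origin_mm)
}

#' Label connected components of a mask
#'
#' @param mask a `binary_mask` or 0/1 array.
#' @param connectivity 26 (default) or 6.
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 26))
  v <- if (is.list(mask)) mask$voxels else mask
  storage.mode(v) <- "integer"
  cpp_label_components(v, as.integer(connectivity))
}

# Gaussian blur of an array, sigma given in voxels (scalar or length 3)
gaussian_blur_vox <- function(arr, sigma_vox) {
  if (length(sigma_vox) == 1) sigma_vox <- rep(sigma_vox, 3)
  if (all(sigma_vox <= 0)) return(arr)
  storage.mode(arr) <- "double"
  cpp_gaussian_blur(arr, sigma_vox)
}
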