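#' CT volume in Hounsfield units
#'
#' The universal image carrier of the package: a 3-D scalar grid in
#' Hounsfield units (HU) with isotropic physical voxel spacing. Axis order is
#' x (left-right), y (ventral-dorsal), z (cranio-caudal); voxel centers lie
#' at `origin_mm + (index - 1) * spacing_um / 1000` millimetres.
#'
#' @param voxels numeric 3-D array of voxel values (HU).
#' @param spacing_um isotropic voxel edge length in micrometres (> 0).
#' @param origin_mm physical position (mm) of the center of voxel (1,1,1).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing_um, origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  if (!is.numeric(spacing_um) || length(spacing_um) != 1 || spacing_um <= 0)
    stop("spacing_um must be a single positive number")
  if (anyNA(voxels) || !all(is.finite(voxels)))
    stop("voxel values must all be finite")
  storage.mode(voxels) <- "double"
  structure(
    list(voxels = voxels, spacing_um = as.numeric(spacing_um),
         origin_mm = as.numeric(origin_mm)),
    class = "ct_volume"
  )
}

#' Binary voxel mask
#'
#' A voxel-aligned binary grid (values 0/1) used for lungs, tumors and
#' detections. Shares the grid conventions of [ct_volume()].
#'
#' @param voxels 3-D array with values in \{0, 1\} (logical arrays accepted).
#' @inheritParams ct_volume
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing_um, origin_mm = c(0, 0, 0)) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 3)
  if (is.logical(voxels)) {
    storage.mode(voxels) <- "integer"
  }
  if (!all(voxels %in% c(0L, 1L)))
    stop("mask voxels must be 0 or 1")
  storage.mode(voxels) <- "integer"
  if (!is.numeric(spacing_um) || length(spacing_um) != 1 || spacing_um <= 0)
    stop("spacing_um must be a single positive number")
  structure(
    list(voxels = voxels, spacing_um = as.numeric(spacing_um),
         origin_mm = as.numeric(origin_mm)),
    class = "binary_mask"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> %d x %d x %d voxels @ %.1f um\n", d[1], d[2], d[3],
              x$spacing_um))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<binary_mask> %d x %d x %d voxels @ %.1f um, %d set (%.2f mm^3)\n",
              d[1], d[2], d[3], x$spacing_um, sum(x$voxels),
              mask_volume_mm3(x)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$voxels)

#' @export
dim.binary_mask <- function(x) dim(x$voxels)

#' Physical volume of one voxel in cubic millimetres
#' @param x a `ct_volume` or `binary_mask` (or a spacing in micrometres).
#' @return voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(x) {
  sp <- if (is.numeric(x)) x else x$spacing_um
  (sp / 1000)^3
}

#' Physical volume of a mask in cubic millimetres
#' @param mask a `binary_mask`.
#' @return total volume of set voxels in mm^3.
#' @export
mask_volume_mm3 <- function(mask) {
  sum(mask$voxels) * voxel_volume_mm3(mask)
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$voxels), dim(b$voxels)))
    stop("grids have different shapes")
  if (abs(a$spacing_um - b$spacing_um) > 1e-6)
    stop("grids have different spacings")
  invisible(TRUE)
}

#' Air/water attenuation calibration
#'
#' Linear attenuation coefficients (1/mm) of water and air used to convert a
#' raw attenuation volume to Hounsfield units. The default
#' `mu_water = 0.02`, `mu_air = 0` is used for all synthetic work; real
#' scanner calibrations can be supplied.
#'
#' @param mu_water linear attenuation of water (1/mm).
#' @param mu_air linear attenuation of air (1/mm).
#' @return An object of class `hu_calibration`.
#' @export
hu_calibration <- function(mu_water = 0.02, mu_air = 0) {
  if (!is.finite(mu_water) || !is.finite(mu_air))
    stop("calibration values must be finite")
  if (mu_air < 0 || mu_water <= mu_air)
    stop("calibration error: need mu_water > mu_air >= 0")
  structure(list(mu_water = mu_water, mu_air = mu_air),
            class = "hu_calibration")
}

#' Convert linear attenuation to Hounsfield units
#'
#' Applies the standard HU normalization
#' `X_HU = 1000 * ((X - mu_air) / (mu_water - mu_air) - 1)`, which maps the
#' water attenuation to 0 HU and the air attenuation to -1000 HU.
#'
#' @param raw a 3-D numeric array of linear attenuation values (1/mm), or a
#'   plain numeric vector/scalar.
#' @param cal an [hu_calibration()].
#' @param spacing_um voxel spacing for the returned volume (required when
#'   `raw` is an array and a `ct_volume` is wanted).
#' @return A `ct_volume` when `raw` is a 3-D array and `spacing_um` is given,
#'   otherwise a numeric object of the same shape as `raw`.
#' @export
to_hounsfield <- function(raw, cal = hu_calibration(), spacing_um = NULL) {
  if (!inherits(cal, "hu_calibration")) stop("cal must be an hu_calibration")
  vals <- if (is.list(raw)) raw$voxels else raw
  if (anyNA(vals) || !all(is.finite(vals)))
    stop("calibration error: non-finite attenuation input")
  hu <- 1000 * ((vals - cal$mu_air) / (cal$mu_water - cal$mu_air) - 1)
  if (is.array(hu) && length(dim(hu)) == 3 && !is.null(spacing_um))
    return(ct_volume(hu, spacing_um))
  hu
}

#' Convert Hounsfield units back to linear attenuation
#'
#' Inverse of [to_hounsfield()]: `X = (X_HU/1000 + 1) * (mu_water - mu_air)
#' + mu_air`, so -1000 HU maps to the air attenuation.
#'
#' @param hu numeric HU values (scalar, vector or array).
#' @param cal an [hu_calibration()].
#' @return attenuation values (1/mm) of the same shape.
#' @export
hu_to_attenuation <- function(hu, cal = hu_calibration()) {
  vals <- if (is.list(hu)) hu$voxels else hu
  (vals / 1000 + 1) * (cal$mu_water - cal$mu_air) + cal$mu_air
}

#' Resample a volume or mask to a new isotropic spacing
#'
#' Trilinear interpolation for image volumes; masks are interpolated linearly
#' and re-binarized at 0.5 so the result stays crisp and deterministic. The
#' output grid covers the physical extent of the input
#' (`round(n * spacing / target)` voxels per axis).
#'
#' @param vol a `ct_volume` or `binary_mask`.
#' @param target_um desired isotropic spacing in micrometres.
#' @param fill value used outside the input grid (images only; default is the
#'   input minimum, masks use 0).
#' @return resampled object of the same class.
#' @export
resample_isotropic <- function(vol, target_um, fill = NULL) {
  if (!is.numeric(target_um) || target_um <= 0)
    stop("target_um must be positive")
  d <- dim(vol$voxels)
  if (abs(target_um - vol$spacing_um) < 1e-9) return(vol)
  scale <- vol$spacing_um / target_um
  out_dim <- as.integer(round(d * scale))
  if (any(out_dim < 2))
    stop("target spacing too coarse: an axis would collapse below 2 voxels")
  is_mask <- inherits(vol, "binary_mask")
  v <- vol$voxels
  if (is_mask) storage.mode(v) <- "double"
  if (is.null(fill)) fill <- if (is_mask) 0 else min(v)
  # output voxel i (0-based) center maps to input coordinate i / scale
  A <- diag(3) / scale
  warped <- cpp_affine_warp(v, out_dim, A, c(0, 0, 0), fill)
  if (is_mask) {
    binary_mask(array(as.integer(warped >= 0.5), out_dim), target_um,
                vol$origin_mm)
  } else {
    ct_volume(warped, target_um, vol$origin_mm)
  }
}

#' Read a CT volume from a NIfTI file
#'
#' Reads a NIfTI-1 image (`.nii` / `.nii.gz`) with isotropic voxels into a
#' [ct_volume()]. Anisotropic headers are rejected unless
#' `resample_to` names a target spacing, in which case the volume is first
#' loaded on its native grid (finest axis spacing) and resampled explicitly
#' -- never accepted silently.
#'
#' @param path file path to a NIfTI image.
#' @param resample_to optional isotropic spacing (micrometres) to resample an
#'   anisotropic input to.
#' @return a `ct_volume`.
#' @export
read_volume <- function(path, resample_to = NULL) {
  if (dir.exists(path))
    stop("format error: expected a NIfTI file, got a directory ",
         "(DICOM series input is not supported by this reader)")
  if (!file.exists(path)) stop("format error: file not found: ", path)
  img <- RNifti::readNifti(path)
  pix <- RNifti::pixdim(img)[1:3] * 1000  # mm -> um
  arr <- array(as.numeric(img), dim = dim(img)[1:3])
  if (diff(range(pix)) > 0.1) {
    if (is.null(resample_to))
      stop("format error: anisotropic voxels (", paste(round(pix, 2), collapse = " x "),
           " um); pass resample_to= to resample explicitly")
    # load at the finest spacing then resample each axis: approximate by
    # warping straight to the target isotropic grid
    d <- dim(arr)
    out_dim <- as.integer(round(d * pix / resample_to))
    A <- diag(resample_to / pix)
    warped <- cpp_affine_warp(arr, out_dim, A, c(0, 0, 0), min(arr))
    return(ct_volume(warped, resample_to))
  }
  ct_volume(arr, mean(pix))
}

#' Write a CT volume (or mask) to a NIfTI file
#'
#' @param vol a `ct_volume` or `binary_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  v <- vol$voxels
  storage.mode(v) <- "double"
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- rep(vol$spacing_um / 1000, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from a NIfTI file
#' @param path file path; voxels are binarized at 0.5.
#' @return a `binary_mask`.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(array(as.integer(v$voxels >= 0.5), dim(v$voxels)),
              v$spacing_um, v$origin_mm)
}

#' Run configuration
#'
#' A small container for a pipeline run: the RNG seed (identical seed and
#' configuration give identical synthetic outputs), file paths, and named
#' per-stage parameter lists that override stage defaults. Can be loaded
#' from a JSON file, so runs are reproducible from a single record.
#'
#' @param seed integer RNG seed.
#' @param paths named list of input/output paths.
#' @param ... named per-stage parameter lists (e.g.
#'   `lungseg = list(hu_threshold = -175)`).
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1L, paths = list(), ...) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer")
  stages <- list(...)
  if (length(stages) && is.null(names(stages)))
    stop("stage parameters must be named")
  structure(list(seed = as.integer(seed), paths = paths, stages = stages),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#' @param path JSON file with fields `seed`, optionally `paths` and
#'   per-stage parameter objects.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  seed <- x$seed %||% 1L
  paths <- x$paths %||% list()
  stages <- x[setdiff(names(x), c("seed", "paths"))]
  do.call(run_config, c(list(seed = seed, paths = paths), stages))
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> seed %d, %d path(s), stages: %s\n", x$seed,
              length(x$paths),
              if (length(x$stages)) paste(names(x$stages), collapse = ", ")
              else "(defaults)"))
  invisible(x)
}

# Evaluate a function with a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
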