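#' Circular cone-beam acquisition geometry
#'
#' Describes a circular cone-beam scan: point source rotating in the axial
#' (x-y) plane about the isocenter, flat detector perpendicular to the
#' central ray. Detector pixels are indexed by (u, v) with u in-plane and v
#' axial.
#'
#' @param n_views number of projection angles.
#' @param angular_range_deg total rotation (360 for a full scan).
#' @param source_object_mm source-to-isocenter distance.
#' @param source_detector_mm source-to-detector distance.
#' @param detector_rows,detector_cols detector size (v, u).
#' @param detector_pitch_mm detector pixel pitch (isotropic).
#' @return an object of class `cone_beam_geometry`.
#' @export
cone_beam_geometry <- function(n_views = 360, angular_range_deg = 360,
                               source_object_mm = 200,
                               source_detector_mm = 400,
                               detector_rows = 192, detector_cols = 192,
                               detector_pitch_mm = 0.2) {
  if (!(source_detector_mm > source_object_mm && source_object_mm > 0))
    stop("need source_detector_mm > source_object_mm > 0")
  if (n_views < 1) stop("n_views must be >= 1")
  structure(list(
    n_views = as.integer(n_views),
    angular_range_deg = angular_range_deg,
    source_object_mm = source_object_mm,
    source_detector_mm = source_detector_mm,
    detector_rows = as.integer(detector_rows),
    detector_cols = as.integer(detector_cols),
    detector_pitch_mm = detector_pitch_mm
  ), class = "cone_beam_geometry")
}

#' @export
print.cone_beam_geometry <- function(x, ...) {
  cat(sprintf(
    "<cone_beam_geometry> %d views / %.0f deg, SOD %.0f mm, SDD %.0f mm, detector %d x %d @ %.3f mm\n",
    x$n_views, x$angular_range_deg, x$source_object_mm, x$source_detector_mm,
    x$detector_cols, x$detector_rows, x$detector_pitch_mm))
  invisible(x)
}

#' Magnification-matched geometry for a volume
#'
#' Convenience constructor: detector pitch equal to the voxel size times the
#' cone-beam magnification, and a detector just large enough to cover the
#' projected volume at every angle.
#'
#' @param vol a `ct_volume` to be scanned.
#' @param n_views number of views.
#' @param source_object_mm,source_detector_mm distances in mm.
#' @param margin extra detector pixels on each side.
#' @return a `cone_beam_geometry`.
#' @export
geometry_for_volume <- function(vol, n_views = 360, source_object_mm = 200,
                                source_detector_mm = 400, margin = 4) {
  vox <- vol$spacing_um / 1000
  d <- dim(vol$voxels)
  mag <- source_detector_mm / source_object_mm
  pitch <- vox * mag
  r_xy <- vox * sqrt(d[1]^2 + d[2]^2) / 2
  hz <- vox * d[3] / 2
  mag_max <- source_detector_mm / (source_object_mm - r_xy)
  nu <- 2 * ceiling(r_xy * mag_max / pitch) + 2 * margin
  nv <- 2 * ceiling(sqrt(hz^2 + r_xy^2) * mag_max / pitch) + 2 * margin
  cone_beam_geometry(n_views = n_views, angular_range_deg = 360,
                     source_object_mm = source_object_mm,
                     source_detector_mm = source_detector_mm,
                     detector_rows = nv, detector_cols = nu,
                     detector_pitch_mm = pitch)
}

geometry_angles <- function(geom) {
  (seq_len(geom$n_views) - 1) / geom$n_views *
    geom$angular_range_deg * pi / 180
}

check_geometry_covers <- function(geom, vol) {
  vox <- vol$spacing_um / 1000
  d <- dim(vol$voxels)
  r_xy <- vox * sqrt(d[1]^2 + d[2]^2) / 2
  hz <- vox * d[3] / 2
  if (r_xy >= geom$source_object_mm)
    stop("geometry does not cover the volume: object reaches the source orbit")
  mag_max <- geom$source_detector_mm / (geom$source_object_mm - r_xy)
  u_need <- r_xy * mag_max
  v_need <- hz * mag_max
  u_have <- geom$detector_cols * geom$detector_pitch_mm / 2
  v_have <- geom$detector_rows * geom$detector_pitch_mm / 2
  if (u_need > u_have || v_need > v_have)
    stop("geometry does not cover the volume: detector too small for the cone")
  invisible(TRUE)
}

#' Cone-beam forward projection
#'
#' Computes divergent-ray line integrals of the volume's linear attenuation
#' for every view of the geometry (ray-driven, trilinear sampling at
#' half-voxel steps). HU values are converted back to attenuation (1/mm)
#' with the supplied calibration, so an all-air (-1000 HU) volume projects
#' to zero. The operator is linear in the attenuation volume.
#'
#' @param vol a `ct_volume` in HU (or, with `input = "attenuation"`, a
#'   volume already holding attenuation per mm).
#' @param geom a `cone_beam_geometry`.
#' @param cal an [hu_calibration()].
#' @param input `"hu"` (default) or `"attenuation"`.
#' @return an object of class `projection_set`: list with `views`
#'   (array `nu x nv x n_views` of unitless line integrals), `geometry`,
#'   and the native grid of the projected volume.
#' @export
forward_project <- function(vol, geom, cal = hu_calibration(),
                            input = c("hu", "attenuation")) {
  input <- match.arg(input)
  check_geometry_covers(geom, vol)
  att <- if (input == "hu") hu_to_attenuation(vol$voxels, cal) else vol$voxels
  storage.mode(att) <- "double"
  views <- cpp_forward_project(att, vol$spacing_um / 1000,
                               geometry_angles(geom),
                               geom$source_object_mm, geom$source_detector_mm,
                               geom$detector_cols, geom$detector_rows,
                               geom$detector_pitch_mm, geom$detector_pitch_mm)
  structure(list(views = views, geometry = geom,
                 native_dim = dim(vol$voxels),
                 native_spacing_um = vol$spacing_um),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$views)
  cat(sprintf("<projection_set> %d views of %d x %d (u x v)\n", d[3], d[1], d[2]))
  invisible(x)
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' Insert tumors into measured projections
#'
#' Projection-domain compositing: the tumor-only volume is forward projected
#' and added to the original views, while the projection of the parenchyma
#' volume (the original tissue inside the tumor footprints) is subtracted:
#' `views' = views + A(tumor) - A(parenchyma)`. With `tumor == parenchyma`
#' the output is bit-identical to the input.
#'
#' Both volumes are HU-encoded on the scan grid with -1000 HU (zero
#' attenuation) outside the tumor footprints.
#'
#' @param orig a `projection_set` of the original scan.
#' @param tumor_vol `ct_volume`: the synthesized tumor tissue.
#' @param parenchyma_vol `ct_volume`: the displaced original tissue.
#' @param cal an [hu_calibration()].
#' @return a new `projection_set`.
#' @export
insert_tumors_in_projections <- function(orig, tumor_vol, parenchyma_vol,
                                         cal = hu_calibration()) {
  check_same_grid(tumor_vol, parenchyma_vol)
  if (!identical(dim(tumor_vol$voxels), orig$native_dim) ||
      abs(tumor_vol$spacing_um - orig$native_spacing_um) > 1e-6)
    stop("geometry mismatch: volumes are not on the scan grid")
  pt <- forward_project(tumor_vol, orig$geometry, cal)
  pp <- forward_project(parenchyma_vol, orig$geometry, cal)
  delta <- pt$views - pp$views
  out <- orig
  out$views <- orig$views + delta
  out
}

# row-wise ramp filtering of one projection stack, virtual-detector pitch du
fdk_filter_views <- function(views, du, window = c("ramlak", "hann")) {
  window <- match.arg(window)
  d <- dim(views)
  nu <- d[1]
  M <- 2^ceiling(log2(4 * nu))
  # Ram-Lak kernel sampled at du; the 1/2 makes it the fan/cone-beam convolver
  g <- numeric(M)
  g[1] <- 1 / (4 * du^2)
  n_odd <- seq(1, nu, by = 2)
  g[1 + n_odd] <- -1 / (pi * n_odd * du)^2
  g[M + 1 - n_odd] <- -1 / (pi * n_odd * du)^2
  g <- g / 2
  K <- fft(g)
  if (window == "hann") {
    m <- 0:(M - 1)
    fnorm <- pmin(m, M - m) / M          # 0 .. 0.5
    K <- K * (0.5 * (1 + cos(2 * pi * fnorm)))
  }
  mat <- matrix(views, nrow = nu)
  padded <- rbind(mat, matrix(0, M - nu, ncol(mat)))
  filt <- Re(stats::mvfft(stats::mvfft(padded) * K, inverse = TRUE)) / M
  array(filt[1:nu, ], d) * du
}

#' FDK cone-beam reconstruction
#'
#' Feldkamp-Davis-Kress weighted filtered backprojection for circular
#' cone-beam data: projections are rescaled to a virtual detector through
#' the isocenter, cosine-weighted, row-filtered with a Ram-Lak ramp
#' (optionally Hann-windowed), and backprojected with the standard
#' distance weighting. The result is returned in HU via the calibration.
#'
#' @param proj a `projection_set`.
#' @param out_dim output grid dimensions (defaults to the native grid of the
#'   projected volume, when known).
#' @param vox_mm output voxel size in mm (defaults to the native spacing).
#' @param cal an [hu_calibration()].
#' @param window `"ramlak"` (default) or `"hann"`.
#' @param output `"hu"` (default) or `"attenuation"`.
#' @return a `ct_volume`.
#' @export
fdk_reconstruct <- function(proj, out_dim = NULL, vox_mm = NULL,
                            cal = hu_calibration(),
                            window = c("ramlak", "hann"),
                            output = c("hu", "attenuation")) {
  window <- match.arg(window)
  output <- match.arg(output)
  geom <- proj$geometry
  if (is.null(out_dim)) out_dim <- proj$native_dim
  if (is.null(vox_mm)) vox_mm <- proj$native_spacing_um / 1000
  if (is.null(out_dim) || is.null(vox_mm))
    stop("out_dim and vox_mm are required when the native grid is unknown")
  if (geom$n_views < ceiling(pi / 2 * max(out_dim[1:2])))
    warning("few views for this grid size; expect angular-undersampling streaks")
  sod <- geom$source_object_mm
  sdd <- geom$source_detector_mm
  scale_v <- sod / sdd
  du_v <- geom$detector_pitch_mm * scale_v
  dv_v <- du_v
  # cosine weighting on the virtual detector
  nu <- geom$detector_cols; nv <- geom$detector_rows
  up <- (seq_len(nu) - (nu + 1) / 2) * du_v
  vp <- (seq_len(nv) - (nv + 1) / 2) * dv_v
  W <- sod / sqrt(sod^2 + outer(up^2, vp^2, `+`))
  weighted <- proj$views * as.vector(W)
  filtered <- fdk_filter_views(weighted, du_v, window)
  angles <- geometry_angles(geom)
  dbeta <- geom$angular_range_deg * pi / 180 / geom$n_views
  att <- cpp_fdk_backproject(filtered, as.integer(out_dim), vox_mm, angles,
                             sod, du_v, dv_v) * dbeta
  if (output == "attenuation")
    return(ct_volume(att, vox_mm * 1000))
  ct_volume(to_hounsfield(att, cal), vox_mm * 1000)
}

#' Edge-preserving bilateral filtration
#'
#' Bilateral filter used after reconstruction to reduce noise: each voxel is
#' replaced by a weighted mean of its neighbours, with weights that decay
#' with both spatial distance and HU difference, so homogeneous regions are
#' smoothed while step edges are preserved.
#'
#' @param vol a `ct_volume`.
#' @param sigma_spatial_mm spatial kernel scale in millimetres.
#' @param sigma_range_hu intensity kernel scale in HU.
#' @return filtered `ct_volume`.
#' @export
bilateral_filter <- function(vol, sigma_spatial_mm = 0.2,
                             sigma_range_hu = 150) {
  if (sigma_spatial_mm <= 0 || sigma_range_hu <= 0)
    stop("sigmas must be positive")
  s_vox <- sigma_spatial_mm * 1000 / vol$spacing_um
  radius <- max(1L, min(5L, as.integer(ceiling(2.5 * s_vox))))
  out <- cpp_bilateral(vol$voxels, s_vox, sigma_range_hu, radius)
  ct_volume(out, vol$spacing_um, vol$origin_mm)
}
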