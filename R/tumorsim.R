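#' Random size distribution of augmented tumors
#'
#' Target volumes follow a log-normal law calibrated so that the median and
#' the 90th percentile match the configured values, truncated (clipped) to
#' `size_range_mm3`. The defaults give a median of 0.65 mm^3 with 90% of
#' tumors below 10 mm^3 across an overall range of 0.03--70 mm^3.
#'
#' @param n number of draws.
#' @param size_range_mm3 clipping range, mm^3.
#' @param median_mm3 target median volume.
#' @param p90_mm3 target 90th-percentile volume.
#' @return numeric vector of volumes in mm^3.
#' @export
sample_tumor_volumes <- function(n, size_range_mm3 = c(0.03, 70),
                                 median_mm3 = 0.65, p90_mm3 = 10) {
  sdlog <- log(p90_mm3 / median_mm3) / qnorm(0.9)
  v <- exp(rnorm(n, log(median_mm3), sdlog))
  pmin(pmax(v, size_range_mm3[1]), size_range_mm3[2])
}

# uniform random rotation matrix (quaternion method)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Augment a tumor template
#'
#' Applies a random rigid rotation (uniform over SO(3)), a random shear
#' (each off-diagonal element uniform in +/- `shear_max`) and an isotropic
#' scale chosen so that the output volume matches a draw from the calibrated
#' size distribution (see [sample_tumor_volumes()]). The mask is warped with
#' trilinear interpolation and re-binarized at 0.5.
#'
#' @param template a `tumor_template`.
#' @param size_range_mm3 admissible output volume range.
#' @param median_mm3,p90_mm3 size-distribution calibration.
#' @param shear_max maximal off-diagonal shear magnitude.
#' @param target_mm3 fix the output volume instead of drawing it.
#' @param max_attempts retries for a degenerate transform.
#' @return list with `mask` (`binary_mask`), `affine` (3x3 matrix mapping
#'   template physical coordinates to output physical coordinates),
#'   `target_mm3`, `template_id`.
#' @export
augment_tumor <- function(template, size_range_mm3 = c(0.03, 70),
                          median_mm3 = 0.65, p90_mm3 = 10, shear_max = 0.2,
                          target_mm3 = NULL, max_attempts = 100) {
  tvol <- mask_volume_mm3(template$mask)
  if (is.null(target_mm3))
    target_mm3 <- sample_tumor_volumes(1, size_range_mm3, median_mm3, p90_mm3)
  for (attempt in seq_len(max_attempts)) {
    R <- random_rotation()
    Sh <- diag(3)
    Sh[row(Sh) != col(Sh)] <- runif(6, -shear_max, shear_max)
    M0 <- R %*% Sh
    dt <- det(M0)
    if (dt <= 1e-6) next
    s <- (target_mm3 / (tvol * dt))^(1 / 3)
    A <- s * M0
    return(warp_mask_affine(template$mask, A, template$id, target_mm3))
  }
  stop("degenerate affine transform after ", max_attempts, " attempts")
}

# warp a binary mask by physical-coordinate affine A (about the mask center)
warp_mask_affine <- function(mask, A, template_id = NA, target_mm3 = NA) {
  vox <- mask$voxels
  d <- dim(vox)
  sp <- mask$spacing_um / 1000
  ctr_in <- (d - 1) / 2
  # transformed bounding box (voxel units; physical scale cancels)
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  tc <- t(A %*% t(sweep(corners, 2, ctr_in)))
  half_out <- apply(abs(tc), 2, max)
  out_d <- pmax(3L, as.integer(ceiling(2 * half_out + 3)))
  ctr_out <- (out_d - 1) / 2
  Ainv <- solve(A)
  t_off <- as.vector(ctr_in - Ainv %*% ctr_out)
  v <- vox; storage.mode(v) <- "double"
  w <- cpp_affine_warp(v, out_d, Ainv, t_off, 0)
  out <- array(as.integer(w >= 0.5), out_d)
  list(mask = binary_mask(out, mask$spacing_um),
       affine = A, target_mm3 = target_mm3, template_id = template_id)
}

#' Retexture a tumor mask
#'
#' Fills the mask interior with Gaussian noise of the requested mean and
#' standard deviation (lightly smoothed, then renormalized to the exact
#' target statistics), and converts the binary mask into soft blend weights
#' by Gaussian-smoothing it with `edge_sigma_mm`. The soft edge removes
#' abrupt gray-value steps when the tumor is composited into a scan;
#' `edge_sigma_mm = 0` returns the binary mask unchanged.
#'
#' @param mask a `binary_mask` (tumor footprint, local grid).
#' @param target_mean_hu,target_sd_hu intensity statistics of the filling.
#' @param edge_sigma_mm Gaussian edge softening of the blend weights.
#' @param smooth_sigma_vox light texture correlation (voxels).
#' @return list with `intensity` (HU array over the local grid), `weights`
#'   (soft mask in \[0, 1\]) and `mask`.
#' @export
retexture_tumor <- function(mask, target_mean_hu = 30, target_sd_hu = 40,
                            edge_sigma_mm = 0.15, smooth_sigma_vox = 0.6) {
  if (target_sd_hu < 0) stop("target_sd_hu must be >= 0")
  vox <- mask$voxels
  if (sum(vox) == 0) stop("mask is empty")
  d <- dim(vox)
  tex <- array(rnorm(prod(d), target_mean_hu, target_sd_hu), d)
  if (smooth_sigma_vox > 0 && target_sd_hu > 0) {
    tex <- gaussian_blur_vox(tex, smooth_sigma_vox)
    inside <- vox == 1L
    m <- mean(tex[inside]); s <- sd(tex[inside])
    if (is.finite(s) && s > 0)
      tex <- (tex - m) / s * target_sd_hu + target_mean_hu
  }
  if (edge_sigma_mm > 0) {
    sig_vox <- edge_sigma_mm * 1000 / mask$spacing_um
    w <- gaussian_blur_vox(array(as.double(vox), d), sig_vox)
    w <- pmin(pmax(w, 0), 1)
    dim(w) <- d
  } else {
    w <- array(as.double(vox), d)
  }
  list(intensity = tex, weights = w, mask = mask)
}

#' Sample a tumor placement inside the lung mask
#'
#' Candidate centers are drawn with probability proportional to the inverse
#' Euclidean distance to the nearest boundary of the working lung mask (the
#' lung mask minus already-placed tumors), reproducing the preference of
#' murine lung tumors for lung boundaries and for the neighbourhood of
#' other tumors. A draw is accepted only if at most `max_outside_frac` of
#' the tumor's voxels fall outside the lung mask and none overlap a placed
#' tumor.
#'
#' @param lung_mask `binary_mask` of the lung on the scan grid.
#' @param tumor_mask `binary_mask` of the (augmented) tumor, local grid.
#' @param placed list of earlier placements (as returned by this function);
#'   their voxels are removed from the working mask.
#' @param max_outside_frac maximal fraction of tumor voxels outside the
#'   lung mask.
#' @param max_trials sampling budget.
#' @param d_clamp_vox lower clamp on the boundary distance (voxels), so
#'   boundary voxels keep finite weight.
#' @return list with `center_ijk` (1-based voxel index of the tumor center),
#'   `voxels` (linear indices of tumor voxels on the scan grid),
#'   `centroid_mm`, `volume_mm3`, `outside_frac`, plus the local-grid
#'   `offsets` used.
#' @export
sample_tumor_location <- function(lung_mask, tumor_mask, placed = list(),
                                  max_outside_frac = 0.1, max_trials = 200,
                                  d_clamp_vox = 0.5) {
  shape <- dim(lung_mask$voxels)
  sp <- lung_mask$spacing_um / 1000
  if (sum(lung_mask$voxels) == 0) stop("lung mask is empty")
  work <- lung_mask$voxels
  for (pl in placed) work[pl$voxels] <- 0L
  if (sum(work) == 0) stop("placement error: working mask exhausted")
  # volume borders count as mask boundary: compute the EDT under zero padding
  padded <- array(0L, shape + 2L)
  padded[2:(shape[1] + 1), 2:(shape[2] + 1), 2:(shape[3] + 1)] <- work
  dt <- cpp_edt(padded)[2:(shape[1] + 1), 2:(shape[2] + 1), 2:(shape[3] + 1)]
  inside <- which(work == 1L)
  wgt <- 1 / pmax(dt[inside], d_clamp_vox)
  cw <- cumsum(wgt)
  # tumor voxel offsets relative to the (rounded) template centroid
  tv <- which(tumor_mask$voxels == 1L)
  td <- dim(tumor_mask$voxels)
  tijk <- arrayInd(tv, td)
  ctr <- round(colMeans(tijk))
  offs <- sweep(tijk, 2, ctr)
  n_tum <- nrow(offs)
  occupied <- array(FALSE, shape)
  for (pl in placed) occupied[pl$voxels] <- TRUE
  lungv <- lung_mask$voxels == 1L
  for (trial in seq_len(max_trials)) {
    u <- runif(1, 0, cw[length(cw)])
    pick <- inside[findInterval(u, cw) + 1]
    cijk <- arrayInd(pick, shape)
    abs_ijk <- sweep(offs, 2, as.integer(cijk), `+`)
    in_grid <- abs_ijk[, 1] >= 1 & abs_ijk[, 1] <= shape[1] &
      abs_ijk[, 2] >= 1 & abs_ijk[, 2] <= shape[2] &
      abs_ijk[, 3] >= 1 & abs_ijk[, 3] <= shape[3]
    if (!all(in_grid)) next  # partially off the scan: treat as unplaceable here
    lin <- abs_ijk[, 1] + (abs_ijk[, 2] - 1) * shape[1] +
      (abs_ijk[, 3] - 1) * shape[1] * shape[2]
    outside_frac <- mean(!lungv[lin])
    if (outside_frac > max_outside_frac) next
    if (any(occupied[lin])) next
    return(list(center_ijk = as.integer(cijk), voxels = lin,
                centroid_mm = (colMeans(abs_ijk) - 1) * sp,
                volume_mm3 = n_tum * sp^3,
                outside_frac = outside_frac,
                offsets = offs))
  }
  stop("placement error: no admissible position after ", max_trials,
       " trials")
}

#' Place and retexture several tumors in a lung
#'
#' Convenience wrapper: augments one template per requested tumor, samples
#' admissible non-overlapping locations (each accepted tumor is carved out
#' of the working mask, creating fresh high-probability boundaries), and
#' returns per-tumor voxel sets, textures and blend weights on the scan
#' grid.
#'
#' @param lung_mask `binary_mask` of the lung.
#' @param bank list of `tumor_template`s.
#' @param n_tumors number of tumors to place.
#' @param augment_args list of arguments passed to [augment_tumor()].
#' @param retexture_args list of arguments passed to [retexture_tumor()].
#' @param max_trials per-tumor placement budget.
#' @return list of placements; each carries `voxels`, `weights_idx` (linear
#'   indices of the soft-edge support), `weights`, `intensity`, `centroid_mm`,
#'   `volume_mm3`, `template_id`, `affine`.
#' @export
place_tumors <- function(lung_mask, bank, n_tumors = 2, augment_args = list(),
                         retexture_args = list(), max_trials = 200) {
  shape <- dim(lung_mask$voxels)
  placed <- list()
  out <- list()
  for (i in seq_len(n_tumors)) {
    tpl <- bank[[sample.int(length(bank), 1)]]
    aug <- do.call(augment_tumor, c(list(template = tpl), augment_args))
    tex <- do.call(retexture_tumor,
                   c(list(mask = aug$mask,
                          target_mean_hu = tpl$mean_hu,
                          target_sd_hu = tpl$sd_hu), retexture_args))
    loc <- sample_tumor_location(lung_mask, aug$mask, placed,
                                 max_trials = max_trials)
    # map the local soft-weight support onto the scan grid
    td <- dim(aug$mask$voxels)
    sup <- which(tex$weights > 1e-4)
    sijk <- arrayInd(sup, td)
    ctr <- round(colMeans(arrayInd(which(aug$mask$voxels == 1L), td)))
    abs_ijk <- sweep(sijk, 2, as.integer(ctr)) +
      matrix(loc$center_ijk, nrow(sijk), 3, byrow = TRUE)
    ok <- abs_ijk[, 1] >= 1 & abs_ijk[, 1] <= shape[1] &
      abs_ijk[, 2] >= 1 & abs_ijk[, 2] <= shape[2] &
      abs_ijk[, 3] >= 1 & abs_ijk[, 3] <= shape[3]
    abs_ijk <- abs_ijk[ok, , drop = FALSE]
    lin <- abs_ijk[, 1] + (abs_ijk[, 2] - 1) * shape[1] +
      (abs_ijk[, 3] - 1) * shape[1] * shape[2]
    pl <- list(voxels = loc$voxels, weights_idx = lin,
               weights = tex$weights[sup][ok],
               intensity = tex$intensity[sup][ok],
               centroid_mm = loc$centroid_mm,
               volume_mm3 = loc$volume_mm3,
               outside_frac = loc$outside_frac,
               template_id = tpl$id, affine = aug$affine,
               target_mm3 = aug$target_mm3)
    placed <- c(placed, list(pl))
    out <- c(out, list(pl))
  }
  out
}

# HU-encoded volume whose attenuation is w * att(values); empty voxels sit
# at -1000 HU (zero attenuation), so it can be forward projected directly
weighted_hu_volume <- function(shape, spacing_um, idx, w, values_hu,
                               cal = hu_calibration()) {
  att <- array(0, shape)
  att[idx] <- w * hu_to_attenuation(values_hu, cal)
  ct_volume(to_hounsfield(att, cal), spacing_um)
}

#' Build the tumor and parenchyma volumes for projection-domain insertion
#'
#' For placements from [place_tumors()]: the tumor volume carries the
#' soft-weighted synthetic tumor tissue, the parenchyma volume the
#' soft-weighted original tissue under the tumor footprints. Adding the
#' projection of the first and subtracting that of the second composites
#' the tumors into the scan (see [insert_tumors_in_projections()]).
#'
#' @param image original `ct_volume`.
#' @param placements list from [place_tumors()].
#' @param cal an [hu_calibration()].
#' @return list with `tumor_vol`, `parenchyma_vol` (both `ct_volume`) and
#'   `label` (`binary_mask` union of tumor footprints).
#' @export
insertion_volumes <- function(image, placements, cal = hu_calibration()) {
  shape <- dim(image$voxels)
  att_t <- array(0, shape)
  att_p <- array(0, shape)
  lab <- array(0L, shape)
  for (pl in placements) {
    att_t[pl$weights_idx] <- att_t[pl$weights_idx] +
      pl$weights * hu_to_attenuation(pl$intensity, cal)
    att_p[pl$weights_idx] <- att_p[pl$weights_idx] +
      pl$weights * hu_to_attenuation(image$voxels[pl$weights_idx], cal)
    lab[pl$voxels] <- 1L
  }
  list(tumor_vol = ct_volume(to_hounsfield(att_t, cal), image$spacing_um),
       parenchyma_vol = ct_volume(to_hounsfield(att_p, cal), image$spacing_um),
       label = binary_mask(lab, image$spacing_um))
}

#' Voxel-domain tumor compositing
#'
#' Direct alpha blend on the reconstruction grid:
#' `new = (1 - w) * original + w * tumor_texture` per voxel (exact for any
#' air/water calibration because HU is affine in attenuation). Serves as the
#' reference against which projection-domain insertion is validated.
#'
#' @param image original `ct_volume`.
#' @param placements list from [place_tumors()].
#' @return composited `ct_volume`.
#' @export
compose_voxel <- function(image, placements) {
  out <- image$voxels
  for (pl in placements) {
    out[pl$weights_idx] <- (1 - pl$weights) * out[pl$weights_idx] +
      pl$weights * pl$intensity
  }
  ct_volume(out, image$spacing_um, image$origin_mm)
}

#' Final augmentation and cropping of a training set
#'
#' Applies one random magnification factor drawn uniformly from
#' `1 + c(-1, 1) * mag` jointly to image and labels (so their alignment is
#' preserved), then crops both to the bounding box of the lung mask padded
#' by `pad` voxels on each side (clamped at the volume borders).
#'
#' @param vol `ct_volume`.
#' @param labels `binary_mask` of tumor labels.
#' @param lung_mask `binary_mask` of the lungs.
#' @param mag magnification half-range (default 0.1 for +/- 10\%).
#' @param pad crop padding in voxels.
#' @return list with cropped/magnified `image`, `labels`, `lung_mask`,
#'   and the applied `magnification`.
#' @export
finalize_training_set <- function(vol, labels, lung_mask, mag = 0.1,
                                  pad = 30) {
  check_same_grid(vol, labels)
  check_same_grid(vol, lung_mask)
  m <- runif(1, 1 - mag, 1 + mag)
  d <- dim(vol$voxels)
  if (abs(m - 1) > 1e-12) {
    ctr <- (d - 1) / 2
    A <- diag(3) / m
    t_off <- ctr - ctr / m
    img <- cpp_affine_warp(vol$voxels, d, A, t_off, min(vol$voxels))
    lb <- cpp_affine_warp(array(as.double(labels$voxels), d), d, A, t_off, 0)
    lg <- cpp_affine_warp(array(as.double(lung_mask$voxels), d), d, A, t_off, 0)
    labels <- binary_mask(array(as.integer(lb >= 0.5), d), vol$spacing_um)
    lung_mask <- binary_mask(array(as.integer(lg >= 0.5), d), vol$spacing_um)
    vol <- ct_volume(img, vol$spacing_um)
  }
  idx <- which(lung_mask$voxels == 1L)
  if (!length(idx)) stop("empty lung mask after magnification")
  ijk <- arrayInd(idx, d)
  lo <- pmax(1L, apply(ijk, 2, min) - as.integer(pad))
  hi <- pmin(d, apply(ijk, 2, max) + as.integer(pad))
  cr <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  list(image = ct_volume(cr(vol$voxels), vol$spacing_um),
       labels = binary_mask(cr(labels$voxels), vol$spacing_um),
       lung_mask = binary_mask(cr(lung_mask$voxels), vol$spacing_um),
       magnification = m, crop_lo = lo, crop_hi = hi)
}

#' Generate a dataset of simulated tumor-bearing scans
#'
#' Runs the full simulation pipeline per set: pick a base phantom scan,
#' augment and place tumors, composite them into the image (through the
#' projection domain -- forward projection, projection editing, FDK
#' reconstruction and bilateral filtration -- or directly in the voxel
#' domain), apply the final magnification + crop, and record everything in
#' a manifest. The default recipe generates 60 sets
#' of 2 tumors each, 13 sets flagged for training validation.
#'
#' @param phantoms list of base scans; each element needs `image`
#'   (`ct_volume`) and a lung mask under `lung_mask_truth` or `lung_mask`.
#' @param bank list of `tumor_template`s.
#' @param n_sets number of simulated sets.
#' @param tumors_per_set tumors placed per set.
#' @param n_validation sets flagged as validation.
#' @param method `"projection"` (full pipeline) or `"voxel"` (direct blend).
#' @param geom optional `cone_beam_geometry` (defaults to a
#'   magnification-matched geometry per phantom).
#' @param n_views views for the default geometry.
#' @param bilateral apply bilateral filtration after reconstruction.
#' @param mag magnification half-range for [finalize_training_set()].
#' @param pad crop padding (voxels).
#' @param augment_args,retexture_args forwarded to [place_tumors()].
#' @param seed RNG seed; the run is fully deterministic given it.
#' @return object of class `sim_dataset`: list with `sets` (each: `image`,
#'   `labels`, `lung_mask`, `validation`) and `manifest` (data.frame).
#' @export
generate_simulated_dataset <- function(phantoms, bank, n_sets = 60,
                                       tumors_per_set = 2, n_validation = 13,
                                       method = c("projection", "voxel"),
                                       geom = NULL, n_views = 180,
                                       bilateral = (method == "projection"),
                                       mag = 0.1, pad = 30,
                                       augment_args = list(),
                                       retexture_args = list(),
                                       seed = NULL) {
  method <- match.arg(method)
  if (!length(bank)) stop("tumor bank is empty")
  if (n_validation > n_sets) stop("n_validation must not exceed n_sets")
  force(bilateral)
  with_seed(seed, {
    val_ids <- sample.int(n_sets, n_validation)
    sets <- vector("list", n_sets)
    rows <- list()
    for (i in seq_len(n_sets)) {
      ph_idx <- (i - 1L) %% length(phantoms) + 1L
      ph <- phantoms[[ph_idx]]
      image <- ph$image
      lung <- ph$lung_mask_truth %||% ph$lung_mask
      pls <- tryCatch(
        place_tumors(lung, bank, tumors_per_set, augment_args,
                     retexture_args),
        error = function(e) stop("set ", i, ": ", conditionMessage(e))
      )
      if (method == "projection") {
        g <- geom %||% geometry_for_volume(image, n_views = n_views)
        pr <- forward_project(image, g)
        iv <- insertion_volumes(image, pls)
        pr2 <- insert_tumors_in_projections(pr, iv$tumor_vol,
                                            iv$parenchyma_vol)
        rec <- fdk_reconstruct(pr2)
        if (bilateral) rec <- bilateral_filter(rec)
        composite <- rec
        labels <- iv$label
      } else {
        composite <- compose_voxel(image, pls)
        labels <- insertion_volumes(image, pls)$label
      }
      fin <- finalize_training_set(composite, labels, lung, mag = mag,
                                   pad = pad)
      sets[[i]] <- list(image = fin$image, labels = fin$labels,
                        lung_mask = fin$lung_mask,
                        validation = i %in% val_ids)
      for (j in seq_along(pls)) {
        pl <- pls[[j]]
        rows[[length(rows) + 1]] <- data.frame(
          set = i, validation = i %in% val_ids, phantom = ph_idx, tumor = j,
          template_id = pl$template_id, volume_mm3 = pl$volume_mm3,
          centroid_x_mm = pl$centroid_mm[1], centroid_y_mm = pl$centroid_mm[2],
          centroid_z_mm = pl$centroid_mm[3], outside_frac = pl$outside_frac,
          magnification = fin$magnification)
      }
    }
    structure(list(sets = sets, manifest = do.call(rbind, rows)),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("<sim_dataset> %d sets (%d validation), %d tumors\n",
              length(x$sets), sum(vapply(x$sets, `[[`, logical(1),
                                         "validation")),
              nrow(x$manifest)))
  invisible(x)
}
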