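#' Threshold an HU volume for lung candidates
#'
#' First pass of the lung segmentation: everything below the HU threshold
#' (default -175 HU, which removes bone and soft tissue) becomes candidate
#' lung/air material.
#'
#' @param vol a `ct_volume` in HU.
#' @param hu_threshold threshold; voxels strictly below it are kept.
#' @return a `binary_mask`.
#' @export
threshold_lung_candidates <- function(vol, hu_threshold = -175) {
  binary_mask(array(as.integer(vol$voxels < hu_threshold), dim(vol$voxels)),
              vol$spacing_um, vol$origin_mm)
}

#' Analyze connected regions of a candidate mask
#'
#' Labels the 26-connected regions of `mask` and computes, per region: the
#' physical volume, the mean HU over the region, whether the region touches
#' (or is 26-adjacent to) the border-connected background-air component, and
#' the distance between the two k-means cluster centers of its voxel
#' coordinates. The background-air component is defined as the union of
#' 6-connected sub-threshold components that contain volume-border voxels.
#'
#' The k-means split (k = 2, seeded, multiple restarts) probes whether a
#' region consists of two distinct similar-size bodies, as the two lungs do;
#' splits where the smaller cluster holds under 25\% of the voxels are not
#' considered "groups of similar size" and score a center distance of 0.
#'
#' @param mask a `binary_mask` of candidate regions.
#' @param vol the `ct_volume` the mask came from.
#' @param kmeans_sample maximum number of voxel coordinates fed to k-means
#'   (larger regions are subsampled deterministically).
#' @return list of `region_candidate` objects with fields `id`, `voxels`
#'   (linear indices), `volume_mm3`, `mean_hu`, `touches_border`,
#'   `kmeans_center_distance_mm`, `centroid_mm`.
#' @export
analyze_regions <- function(mask, vol, kmeans_sample = 20000) {
  check_same_grid(mask, vol)
  shape <- dim(mask$voxels)
  sp <- mask$spacing_um / 1000
  lab <- label_components(mask, 26)
  k <- max(lab)
  if (k == 0) return(list())

  # border-connected air: 6-connected components of the mask touching the
  # volume border (the cradle air and surrounding background)
  lab6 <- label_components(mask, 6)
  border <- array(0L, shape)
  border[1, , ] <- 1L; border[shape[1], , ] <- 1L
  border[, 1, ] <- 1L; border[, shape[2], ] <- 1L
  border[, , 1] <- 1L; border[, , shape[3]] <- 1L
  border_ids6 <- setdiff(unique(lab6[border == 1L & lab6 > 0L]), 0L)
  bg_air <- array(as.integer(lab6 %in% border_ids6), shape)
  touching <- cpp_labels_touching(lab, bg_air)

  idx_all <- which(lab > 0)
  ids_all <- lab[idx_all]
  hu_all <- vol$voxels[idx_all]
  ijk_all <- arrayInd(idx_all, shape)
  lapply(seq_len(k), function(id) {
    sel <- ids_all == id
    vox <- idx_all[sel]
    coords <- ijk_all[sel, , drop = FALSE]
    n <- length(vox)
    if (n > kmeans_sample) {
      pick <- as.integer(seq(1, n, length.out = kmeans_sample))
      coords_km <- coords[pick, , drop = FALSE]
    } else coords_km <- coords
    kmd <- kmeans_center_distance(coords_km) * sp
    structure(list(
      id = id,
      voxels = vox,
      volume_mm3 = n * sp^3,
      mean_hu = mean(hu_all[sel]),
      touches_border = id %in% touching,
      kmeans_center_distance_mm = kmd,
      centroid_mm = colMeans(coords - 1) * sp
    ), class = "region_candidate")
  })
}

# distance (voxel units) between the two k-means centers of coords;
# 0 when the split is too unbalanced to represent two similar-size bodies
kmeans_center_distance <- function(coords, balance_min = 0.25, restarts = 10) {
  n <- nrow(coords)
  if (n < 4) return(0)
  km <- with_seed(1234, suppressWarnings(
    kmeans(coords, centers = 2, nstart = restarts, iter.max = 50)
  ))
  if (min(km$size) / n < balance_min) return(0)
  sqrt(sum((km$centers[1, ] - km$centers[2, ])^2))
}

#' Select the lung region(s) among candidates
#'
#' Applies the three rejection criteria: (1) a region connected to the
#' background air around the animal is rejected (this removes the air-filled
#' cradle), (2) the region mean HU must lie within \[-600, -175\] (rejects
#' pure-air regions, which are far darker), (3) the region volume must lie
#' within \[`min_vol`, `max_vol`\] mm^3. If more than two candidates survive,
#' the two with the largest k-means center distance (two distinct centers of
#' mass, as expected of lungs) are kept; with one or two survivors all are
#' kept.
#'
#' @param candidates list from [analyze_regions()].
#' @param shape grid dimensions of the parent volume.
#' @param spacing_um voxel spacing of the parent volume.
#' @param hu_range closed HU interval for the region mean.
#' @param min_vol,max_vol region volume bounds, mm^3.
#' @return a `binary_mask` that is the union of the selected region(s).
#' @export
select_lung_region <- function(candidates, shape, spacing_um,
                               hu_range = c(-600, -175),
                               min_vol = 200, max_vol = 1200) {
  keep <- Filter(function(cand) {
    !cand$touches_border &&
      cand$mean_hu >= hu_range[1] && cand$mean_hu <= hu_range[2] &&
      cand$volume_mm3 >= min_vol && cand$volume_mm3 <= max_vol
  }, candidates)
  if (length(keep) == 0)
    stop("no lung found: no candidate region satisfies the selection criteria")
  if (length(keep) > 2) {
    ord <- order(vapply(keep, `[[`, numeric(1), "kmeans_center_distance_mm"),
                 vapply(keep, `[[`, numeric(1), "volume_mm3"),
                 decreasing = TRUE)
    keep <- keep[ord[1:2]]
  }
  out <- array(0L, shape)
  for (cand in keep) out[cand$voxels] <- 1L
  binary_mask(out, spacing_um)
}

#' Segment the lungs from an HU volume
#'
#' The full rule-based pipeline: HU thresholding
#' ([threshold_lung_candidates()]), morphological closing/opening
#' ([morph_refine()]), connected-region analysis ([analyze_regions()]) and
#' criterion-based selection ([select_lung_region()]).
#'
#' @param vol a `ct_volume` in HU.
#' @param hu_threshold threshold for the first pass (default -175 HU).
#' @param radius_mm structuring-element radius for the morphological step.
#' @param hu_range mean-HU acceptance interval for regions.
#' @param min_vol,max_vol region volume bounds in mm^3.
#' @return a `binary_mask` of the segmented lungs.
#' @export
segment_lungs <- function(vol, hu_threshold = -175, radius_mm = 0.25,
                          hu_range = c(-600, -175),
                          min_vol = 200, max_vol = 1200) {
  cand_mask <- threshold_lung_candidates(vol, hu_threshold)
  refined <- morph_refine(cand_mask, radius_mm)
  cands <- analyze_regions(refined, vol)
  select_lung_region(cands, dim(vol$voxels), vol$spacing_um,
                     hu_range = hu_range, min_vol = min_vol,
                     max_vol = max_vol)
}
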