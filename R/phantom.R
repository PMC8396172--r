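#' Generate a digital mouse-thorax phantom
#'
#' Builds a synthetic micro-CT volume of a mouse thorax in Hounsfield units
#' together with ground-truth tissue masks. The phantom contains: background
#' air at -1000 HU, an elliptical soft-tissue body (100--300 HU), two lung
#' lobes as deformed ellipsoids at about -500 HU carrying branching
#' vessel-like bright structures (0--150 HU), a spine and ribs at >= 300 HU,
#' an air-filled cradle channel connected to the volume border, and an
#' optional intestinal gas pocket. Gaussian noise of configurable standard
#' deviation is added last.
#'
#' All anatomical criteria downstream (lung volume 200--1200 mm^3 per
#' region) are physical, so the phantom can be generated at any spacing; the
#' default 150 um keeps runtimes small while honoring the mm^3 rules.
#'
#' @param spacing_um isotropic voxel spacing in micrometres.
#' @param shape integer grid dimensions (x, y, z).
#' @param lung_volume_mm3 target total lung volume (both lobes), mm^3.
#' @param noise_sd standard deviation of additive Gaussian noise, HU.
#' @param include_lungs set `FALSE` for a lung-free (solid body) phantom.
#' @param include_air_pocket include a small sub-lung gas pocket.
#' @param include_cradle include the air-filled cradle below the animal.
#' @param n_vessel_levels branching depth of each lung's vessel tree.
#' @param seed optional RNG seed for a reproducible phantom.
#' @return An object of class `thorax_phantom`: a list with elements `image`
#'   (`ct_volume`), `lung_mask_truth`, `bone_mask`, `vessel_mask`,
#'   `body_mask` (all `binary_mask`).
#' @export
generate_thorax <- function(spacing_um = 150, shape = c(160, 160, 200),
                            lung_volume_mm3 = 600, noise_sd = 25,
                            include_lungs = TRUE, include_air_pocket = TRUE,
                            include_cradle = TRUE, n_vessel_levels = 5,
                            seed = NULL) {
  with_seed(seed, {
    sp <- spacing_um / 1000  # mm
    nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
    ext <- shape * sp
    # physical coordinates of voxel centers, centered on the grid
    xs <- (seq_len(nx) - (nx + 1) / 2) * sp
    ys <- (seq_len(ny) - (ny + 1) / 2) * sp
    zs <- (seq_len(nz) - (nz + 1) / 2) * sp
    X <- array(rep(xs, times = ny * nz), shape)
    Y <- array(rep(rep(ys, each = nx), times = nz), shape)
    Z <- array(rep(zs, each = nx * ny), shape)

    img <- array(-1000, shape)

    # --- body: elliptical cylinder with rounded caps --------------------
    ax <- 0.40 * ext[1]; ay <- 0.36 * ext[2]
    zhalf <- 0.46 * ext[3]
    taper <- pmax(0, (abs(Z) - 0.8 * zhalf) / (0.2 * zhalf))
    body <- (X / ax)^2 + (Y / ay)^2 <= (1 - 0.4 * taper^2) & abs(Z) <= zhalf
    # smooth low-frequency soft-tissue variation, kept within 100-300 HU
    tissue <- 190 + 55 * sin(2 * pi * X / (1.6 * ax)) *
      cos(2 * pi * Y / (1.7 * ay)) + 35 * sin(2 * pi * Z / (1.1 * ext[3]))
    img[body] <- pmin(295, pmax(105, tissue[body]))

    lung <- array(FALSE, shape)
    vessel_mask <- array(0L, shape)
    if (include_lungs) {
      # --- lungs: two deformed ellipsoidal lobes ------------------------
      vol_lobe <- lung_volume_mm3 / 2
      a <- (vol_lobe / (4 / 3 * pi * 0.85 * 1.8))^(1 / 3)
      b <- 0.85 * a; cax <- 1.8 * a
      xoff <- a + 0.22 * a  # lobe centers at +/- xoff, small mediastinal gap
      y0 <- -0.08 * ay; z0 <- 0
      if (xoff + a > 0.92 * ax || b + abs(y0) > 0.92 * ay || cax > 0.9 * zhalf)
        stop("infeasible geometry: requested lung volume does not fit the body")
      ph <- runif(4, 0, 2 * pi)
      for (s in c(-1, 1)) {
        u <- (X - s * xoff) / a
        v <- (Y - y0) / b
        w <- (Z - z0) / cax
        rho <- sqrt(u^2 + v^2 + w^2)
        th <- atan2(v, u)
        deform <- 1 + 0.07 * sin(3 * th + ph[1]) +
          0.05 * sin(2.2 * pi * w + ph[2]) * cos(2 * th + ph[3])
        lobe <- rho <= deform
        lung <- lung | lobe
      }
      img[lung] <- -500

      # --- vessel trees: recursive random branching ---------------------
      segs <- list()
      for (s in c(-1, 1)) {
        start <- c(s * (xoff - 0.6 * a), y0, z0 + 0.25 * cax)
        dir0 <- c(s * 0.25, 0.1, -0.9)
        dir0 <- dir0 / sqrt(sum(dir0^2))
        segs <- c(segs, grow_vessel_tree(start, dir0, len = 0.55 * cax,
                                         radius = 0.33, level = n_vessel_levels))
      }
      for (sg in segs) {
        vox <- rasterize_capsule(sg$p0, sg$p1, sg$r, xs, ys, zs, shape)
        if (length(vox)) {
          keep <- vox[lung[vox]]
          if (length(keep)) {
            img[keep] <- sg$hu
            vessel_mask[keep] <- 1L
          }
        }
      }
    }

    # --- bone: spine + ribs --------------------------------------------
    bone <- array(FALSE, shape)
    ysp <- 0.78 * ay
    spine <- (X^2 + (Y - ysp)^2) <= 1.3^2 & abs(Z) <= zhalf
    bone <- bone | (spine & body)
    rib_r <- 0.88 * sqrt((ax * ay))
    n_ribs <- max(3L, as.integer(floor(1.6 * zhalf / 2.4)))
    rib_z <- seq(-0.75 * zhalf, 0.75 * zhalf, length.out = n_ribs)
    rr <- sqrt((X / ax * rib_r)^2 + (Y / ay * rib_r)^2)
    rib_shell <- abs(rr - rib_r * 0.93) <= 0.28
    for (zk in rib_z) bone <- bone | (rib_shell & abs(Z - zk) <= 0.35 & body)
    if (include_lungs) bone <- bone & !lung
    img[bone] <- 620

    # --- intestinal gas pocket (rejected downstream: too small, too dark)
    if (include_air_pocket) {
      pocket <- (X - 0.25 * ax)^2 + (Y + 0.3 * ay)^2 +
        (Z + 0.86 * zhalf)^2 <= 1.1^2
      pocket <- pocket & body & !lung & !bone
      img[pocket] <- -1000
    }

    # --- cradle: arc shell below the animal with an air channel ---------
    if (include_cradle) {
      yc <- -0.05 * ext[2]
      rc <- sqrt(X^2 + (Y - yc)^2)
      r_in <- 1.04 * ay - yc      # leaves an air gap around the body
      wall <- rc >= r_in & rc <= r_in + 0.6 & Y < yc - 0.35 * r_in
      wall <- wall & !body
      img[wall] <- 60
    }

    if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)

    structure(list(
      image = ct_volume(img, spacing_um),
      lung_mask_truth = binary_mask(array(as.integer(lung), shape), spacing_um),
      bone_mask = binary_mask(array(as.integer(bone), shape), spacing_um),
      vessel_mask = binary_mask(vessel_mask, spacing_um),
      body_mask = binary_mask(array(as.integer(body), shape), spacing_um)
    ), class = "thorax_phantom")
  })
}

#' @export
print.thorax_phantom <- function(x, ...) {
  d <- dim(x$image$voxels)
  cat(sprintf("<thorax_phantom> %d x %d x %d @ %.0f um\n", d[1], d[2], d[3],
              x$image$spacing_um))
  cat(sprintf("  lung volume %.1f mm^3, vessels %.1f mm^3, bone %.1f mm^3\n",
              mask_volume_mm3(x$lung_mask_truth),
              mask_volume_mm3(x$vessel_mask), mask_volume_mm3(x$bone_mask)))
  invisible(x)
}

# recursive random branching; returns list of segments (p0, p1, r, hu)
grow_vessel_tree <- function(p0, dir, len, radius, level) {
  if (level <= 0 || radius < 0.06) return(list())
  p1 <- p0 + dir * len
  seg <- list(p0 = p0, p1 = p1, r = radius, hu = runif(1, 0, 150))
  kids <- list()
  n_child <- if (level > 1) 2 else 0
  for (i in seq_len(n_child)) {
    pert <- rnorm(3, 0, 0.55)
    nd <- dir + pert
    nd <- nd / sqrt(sum(nd^2))
    kids <- c(kids, grow_vessel_tree(p1, nd, len * runif(1, 0.6, 0.8),
                                     radius * runif(1, 0.6, 0.8), level - 1))
  }
  c(list(seg), kids)
}

# voxel indices (linear) within distance r of the segment p0-p1
rasterize_capsule <- function(p0, p1, r, xs, ys, zs, shape) {
  lo <- pmin(p0, p1) - r; hi <- pmax(p0, p1) + r
  ix <- which(xs >= lo[1] & xs <= hi[1])
  iy <- which(ys >= lo[2] & ys <= hi[2])
  iz <- which(zs >= lo[3] & zs <= hi[3])
  if (!length(ix) || !length(iy) || !length(iz)) return(integer())
  g <- expand.grid(x = ix, y = iy, z = iz)
  px <- xs[g$x]; py <- ys[g$y]; pz <- zs[g$z]
  d <- p1 - p0
  l2 <- sum(d^2)
  if (l2 == 0) {
    dist2 <- (px - p0[1])^2 + (py - p0[2])^2 + (pz - p0[3])^2
  } else {
    t <- ((px - p0[1]) * d[1] + (py - p0[2]) * d[2] + (pz - p0[3]) * d[3]) / l2
    t <- pmin(1, pmax(0, t))
    dist2 <- (px - (p0[1] + t * d[1]))^2 + (py - (p0[2] + t * d[2]))^2 +
      (pz - (p0[3] + t * d[3]))^2
  }
  keep <- dist2 <= r^2
  if (!any(keep)) return(integer())
  g <- g[keep, ]
  g$x + (g$y - 1) * shape[1] + (g$z - 1) * shape[1] * shape[2]
}

#' Generate a bank of synthetic tumor templates
#'
#' Creates blobby single-component tumor masks emulating a bank of manually
#' segmented lung tumors. Each template is the union of several overlapping
#' random ellipsoids, Gaussian-smoothed and re-thresholded, then rescaled so
#' its physical volume matches a draw from the requested size range. The
#' templates are synthetic stand-ins for real tumor segmentations; their
#' intensity statistics (`mean_hu`, `sd_hu`) are configurable.
#'
#' @param n_templates number of templates (>= 1).
#' @param size_range_mm3 two-element volume range in mm^3; template volumes
#'   are drawn log-uniformly across it.
#' @param spacing_um voxel spacing of the template grids.
#' @param mean_hu,sd_hu default soft-tissue-like intensity statistics.
#' @param seed optional RNG seed.
#' @return list of `tumor_template` objects (fields `mask`, `mean_hu`,
#'   `sd_hu`, `id`).
#' @export
generate_tumor_bank <- function(n_templates = 7,
                                size_range_mm3 = c(0.03, 70),
                                spacing_um = 150, mean_hu = 30, sd_hu = 40,
                                seed = NULL) {
  if (n_templates < 1) stop("n_templates must be >= 1")
  vox_mm3 <- (spacing_um / 1000)^3
  if (min(size_range_mm3) < 2 * vox_mm3)
    stop("size_range infeasible at this spacing: smallest volume below 2 voxels")
  with_seed(seed, {
    lapply(seq_len(n_templates), function(id) {
      target <- exp(runif(1, log(size_range_mm3[1]), log(size_range_mm3[2])))
      mask <- make_blob_mask(target, spacing_um)
      structure(list(mask = mask, mean_hu = mean_hu, sd_hu = sd_hu, id = id),
                class = "tumor_template")
    })
  })
}

# a single connected blob whose physical volume matches target_mm3 within
# one voxel: the mask is the top-n superlevel set of a smooth metaball field
make_blob_mask <- function(target_mm3, spacing_um, max_iter = 5) {
  sp <- spacing_um / 1000
  r_eq <- (3 * target_mm3 / (4 * pi))^(1 / 3)  # mm
  # generous local grid around the blob
  half <- max(3L, as.integer(ceiling(2.2 * r_eq / sp)))
  n <- 2L * half + 1L
  xs <- (seq_len(n) - half - 1) * sp
  X <- array(rep(xs, times = n * n), c(n, n, n))
  Y <- array(rep(rep(xs, each = n), times = n), c(n, n, n))
  Z <- array(rep(xs, each = n * n), c(n, n, n))
  ne <- sample(3:6, 1)
  field <- array(0, c(n, n, n))
  for (i in seq_len(ne)) {
    ctr <- runif(3, -0.45, 0.45) * r_eq
    ax <- runif(3, 0.5, 1.0) * r_eq
    q <- ((X - ctr[1]) / ax[1])^2 + ((Y - ctr[2]) / ax[2])^2 +
      ((Z - ctr[3]) / ax[3])^2
    field <- pmax(field, 1 - q)  # metaball-ish: positive inside
  }
  field <- gaussian_blur_vox(field, 0.8)
  n_target <- max(2L, as.integer(round(target_mm3 / sp^3)))
  take <- n_target
  ord <- order(field, decreasing = TRUE)
  vox <- array(0L, c(n, n, n))
  for (it in seq_len(max_iter)) {
    vox[] <- 0L
    vox[ord[seq_len(min(take, length(ord)))]] <- 1L
    vox <- keep_largest_component(vox)
    deficit <- n_target - sum(vox)
    if (deficit <= 1L) break
    take <- take + deficit
  }
  binary_mask(vox, spacing_um)
}

keep_largest_component <- function(vox, connectivity = 26) {
  lab <- cpp_label_components(vox, as.integer(connectivity))
  if (max(lab) <= 1) return(vox)
  tab <- tabulate(lab[lab > 0])
  array(as.integer(lab == which.max(tab)), dim(vox))
}

#' Generate a controllable synthetic prediction map
#'
#' Builds a float probability volume in \[0, 1\] emulating a detector output,
#' with exact, constructed detection behaviour: one high-score blob per
#' labeled tumor (unless listed in `miss_ids`), plus exactly `n_false_pos`
#' spurious blobs inside the lung mask placed far enough from every label
#' that they can be neither direct nor near hits. This makes the evaluation
#' stage testable without any trained network.
#'
#' @param labels a `binary_mask` of true tumor labels (26-connected
#'   components are the individual tumors, numbered in scan order).
#' @param lung_mask `binary_mask` of the lung.
#' @param n_false_pos number of spurious blobs to add.
#' @param miss_ids integer ids of label components to leave undetected.
#' @param fp_volume_mm3 volume of each spurious blob (>= 0.15).
#' @param score_range range of blob peak scores.
#' @param blur_sigma_vox edge softening of each blob, voxels.
#' @param seed optional RNG seed.
#' @param max_trials rejection-sampling budget for spurious blob placement.
#' @return a `ct_volume` whose voxels hold probabilities in \[0, 1\].
#' @export
generate_prediction_map <- function(labels, lung_mask, n_false_pos = 0,
                                    miss_ids = integer(),
                                    fp_volume_mm3 = 0.4,
                                    score_range = c(0.65, 0.95),
                                    blur_sigma_vox = 0.5, seed = NULL,
                                    max_trials = 5000) {
  check_same_grid(labels, lung_mask)
  with_seed(seed, {
    sp <- labels$spacing_um / 1000
    shape <- dim(labels$voxels)
    prob <- array(0, shape)
    lab <- label_components(labels)
    k <- max(lab)
    stats_list <- component_stats(lab, labels$spacing_um)
    # blob per detected label: the component itself, slightly dilated
    for (id in seq_len(k)) {
      if (id %in% miss_ids) next
      blob <- array(as.integer(lab == id), shape)
      blob <- dilate_ball(blob, 1)
      sc <- runif(1, score_range[1], score_range[2])
      prob <- pmax(prob, blob * sc)
    }
    # spurious blobs: inside lung, no overlap or near-hit possible
    if (n_false_pos > 0) {
      r_fp <- (3 * fp_volume_mm3 / (4 * pi))^(1 / 3)
      r_fp_vox <- r_fp / sp
      lung_in <- distance_transform(lung_mask, "voxel") > (r_fp_vox + 1)
      ok_idx <- which(lung_in)
      if (!length(ok_idx))
        stop("insufficient free lung space for requested false positives")
      placed <- 0
      trials <- 0
      cen <- lapply(stats_list, `[[`, "centroid_mm")
      rad <- vapply(stats_list, `[[`, numeric(1), "r_eq_mm")
      occupied <- labels$voxels == 1L
      while (placed < n_false_pos && trials < max_trials) {
        trials <- trials + 1
        pick <- ok_idx[sample.int(length(ok_idx), 1)]
        ijk <- arrayInd(pick, shape)
        ctr_mm <- (ijk - 1) * sp
        far <- all(vapply(seq_len(k), function(id) {
          sqrt(sum((ctr_mm - cen[[id]])^2)) > 1.6 * rad[id] + r_fp
        }, logical(1)))
        if (k == 0) far <- TRUE
        if (!far) next
        blob_idx <- sphere_voxels(ijk, r_fp_vox, shape)
        # keep a 2-voxel moat so spurious blobs never merge or touch labels
        excl_idx <- sphere_voxels(ijk, r_fp_vox + 2, shape)
        if (any(occupied[excl_idx]) || any(prob[excl_idx] > 0)) next
        sc <- runif(1, score_range[1], score_range[2])
        prob[blob_idx] <- sc
        occupied[blob_idx] <- TRUE
        placed <- placed + 1
      }
      if (placed < n_false_pos)
        stop("insufficient free lung space for requested false positives")
    }
    if (blur_sigma_vox > 0) {
      hard <- prob
      soft <- gaussian_blur_vox(prob, blur_sigma_vox)
      # keep cores at full score so thresholding stays exact
      prob <- pmax(soft, hard * 0.999)
    }
    prob <- pmin(pmax(prob, 0), 1)
    dim(prob) <- shape
    ct_volume(prob, labels$spacing_um)
  })
}

# linear indices of voxels within r_vox of center index (1-based ijk)
sphere_voxels <- function(ijk, r_vox, shape) {
  r <- ceiling(r_vox)
  rng <- lapply(1:3, function(a) {
    seq(max(1, ijk[a] - r), min(shape[a], ijk[a] + r))
  })
  g <- expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]])
  d2 <- (g$x - ijk[1])^2 + (g$y - ijk[2])^2 + (g$z - ijk[3])^2
  g <- g[d2 <= r_vox^2, ]
  g$x + (g$y - 1) * shape[1] + (g$z - 1) * shape[1] * shape[2]
}

# per-component centroid (mm), volume (mm^3) and equivalent sphere radius
component_stats <- function(lab, spacing_um) {
  k <- max(lab)
  if (k == 0) return(list())
  sp <- spacing_um / 1000
  shape <- dim(lab)
  idx <- which(lab > 0)
  ids <- lab[idx]
  ijk <- arrayInd(idx, shape)
  lapply(seq_len(k), function(id) {
    sel <- ids == id
    sub <- ijk[sel, , drop = FALSE]
    vol <- nrow(sub) * sp^3
    list(centroid_mm = colMeans(sub - 1) * sp,
         volume_mm3 = vol,
         r_eq_mm = (3 * vol / (4 * pi))^(1 / 3),
         voxels = idx[sel])
  })
}
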