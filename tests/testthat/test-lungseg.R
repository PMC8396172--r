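test_that("HU thresholding keeps exactly the sub-threshold voxels", {
  v <- array(100, c(3, 3, 3))
  v[1, 1, 1] <- -500   # lung-like: kept
  v[2, 2, 2] <- 300    # bone: excluded
  v[c(2, 3, 4, 5)] <- -400
  vol <- ct_volume(v, 150)
  m <- threshold_lung_candidates(vol, -175)
  expect_equal(sum(m$voxels), sum(v < -175))  # direct count oracle
  expect_equal(m$voxels[1, 1, 1], 1L)
  expect_equal(m$voxels[2, 2, 2], 0L)
})

test_that("region analysis reports volumes, HU, border contact and k-means split", {
  shape <- c(40, 40, 40)
  sp_um <- 250
  v <- array(500, shape)  # dense body everywhere (not candidate material)
  m <- array(0L, shape)
  # two disjoint interior cubes of known size
  m[5:10, 5:10, 5:10] <- 1L; v[5:10, 5:10, 5:10] <- -400
  m[25:34, 25:34, 25:34] <- 1L; v[25:34, 25:34, 25:34] <- -300
  cands <- analyze_regions(binary_mask(m, sp_um), ct_volume(v, sp_um))
  expect_length(cands, 2)
  vols <- sort(vapply(cands, `[[`, numeric(1), "volume_mm3"))
  expect_equal(vols, sort(c(6^3, 10^3) * (sp_um / 1000)^3))
  expect_equal(sort(vapply(cands, `[[`, numeric(1), "mean_hu")), c(-400, -300))
  expect_false(any(vapply(cands, `[[`, logical(1), "touches_border")))

  # a dumbbell made of two equal blobs: k-means centers sit near the blob
  # centroids, so their distance matches the construction
  m2 <- array(0L, shape)
  m2[4:9, 18:23, 18:23] <- 1L
  m2[30:35, 18:23, 18:23] <- 1L
  m2[4:35, 20:21, 20:21] <- 1L  # thin bridge making it one component
  c2 <- analyze_regions(binary_mask(m2, sp_um), ct_volume(v, sp_um))
  expect_length(c2, 1)
  d_expect <- (mean(30:35) - mean(4:9)) * sp_um / 1000
  expect_lt(abs(c2[[1]]$kmeans_center_distance_mm - d_expect),
            0.25 * d_expect)

  # a single compact cube has a small center separation
  m3 <- array(0L, shape)
  m3[15:26, 15:26, 15:26] <- 1L
  c3 <- analyze_regions(binary_mask(m3, sp_um), ct_volume(v, sp_um))
  diam <- 12 * sqrt(3) * sp_um / 1000
  expect_lt(c3[[1]]$kmeans_center_distance_mm, 0.6 * diam)

  # border-touching air is flagged
  m4 <- array(0L, shape)
  m4[1:6, 1:6, 1:6] <- 1L
  c4 <- analyze_regions(binary_mask(m4, sp_um), ct_volume(v, sp_um))
  expect_true(c4[[1]]$touches_border)
})

test_that("selection applies the three rejection criteria", {
  mk <- function(volume_mm3, mean_hu, touches = FALSE, kmd = 1, id = 1) {
    structure(list(id = id, voxels = id, volume_mm3 = volume_mm3,
                   mean_hu = mean_hu, touches_border = touches,
                   kmeans_center_distance_mm = kmd,
                   centroid_mm = c(0, 0, 0)),
              class = "region_candidate")
  }
  shape <- c(2, 2, 2)
  # pure air (mean -800) is rejected even at valid volume
  expect_error(select_lung_region(list(mk(500, -800)), shape, 150),
               "no lung found")
  # 150 mm^3 is below the 200 mm^3 floor
  expect_error(select_lung_region(list(mk(150, -400)), shape, 150),
               "no lung found")
  # border-connected (cradle air) is rejected
  expect_error(select_lung_region(list(mk(500, -400, touches = TRUE)),
                                  shape, 150), "no lung found")
  # valid candidate is kept
  sel <- select_lung_region(list(mk(500, -400, id = 1)), shape, 150)
  expect_equal(sum(sel$voxels), 1)
  # with more than two survivors, the two largest k-means separations win
  cands <- list(mk(500, -400, kmd = 0.2, id = 1),
                mk(500, -400, kmd = 5, id = 2),
                mk(500, -400, kmd = 3, id = 3))
  sel3 <- select_lung_region(cands, shape, 150)
  expect_equal(which(sel3$voxels == 1L), c(2L, 3L))
})

test_that("segment_lungs recovers the phantom lungs and honors its contracts", {
  ph <- small_phantom()
  seg <- segment_lungs(ph$image)
  expect_gte(dice_coefficient(seg, ph$lung_mask_truth), 0.90)
  vol <- mask_volume_mm3(seg)
  expect_gte(vol, 200)
  expect_lte(vol, 1200)

  # the selected mask never meets the border-connected air component
  thr <- threshold_lung_candidates(ph$image)
  lab6 <- label_components(thr, 6)
  shape <- dim(thr$voxels)
  border_labs <- unique(c(lab6[1, , ], lab6[shape[1], , ], lab6[, 1, ],
                          lab6[, shape[2], ], lab6[, , 1], lab6[, , shape[3]]))
  border_labs <- setdiff(border_labs, 0L)
  bg_air <- array(as.integer(lab6 %in% border_labs), shape)
  expect_equal(sum(seg$voxels * bg_air), 0)

  # idempotence up to boundary jitter: blanking non-lung tissue to +300 HU
  # re-segments to essentially the same mask
  v2 <- ph$image$voxels
  v2[seg$voxels == 0L] <- 300
  seg2 <- segment_lungs(ct_volume(v2, ph$image$spacing_um))
  expect_gte(dice_coefficient(seg2, seg), 0.99)

  # a lung-free phantom raises an explicit error
  solid <- generate_thorax(spacing_um = 300, shape = c(60, 60, 72),
                           lung_volume_mm3 = 230, include_lungs = FALSE,
                           seed = 12)
  expect_error(segment_lungs(solid$image), "no lung found")
})

test_that("lowering the threshold keeps the selected mean HU below -175", {
  ph <- small_phantom()
  for (thr in c(-175, -300, -450)) {
    seg <- tryCatch(segment_lungs(ph$image, hu_threshold = thr),
                    error = function(e) NULL)
    if (is.null(seg)) next
    expect_lte(mean(ph$image$voxels[seg$voxels == 1L]), -175)
  }
})
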