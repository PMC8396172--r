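# small helper: wrap voxel sets on a common grid into detection/label lists
mk_grid <- function(shape = c(40, 40, 40), spacing_um = 500) {
  list(shape = shape, spacing_um = spacing_um,
       sp = spacing_um / 1000)
}

mk_sphere_mask <- function(g, center, r_vox) {
  m <- array(0L, g$shape)
  m[murilung:::sphere_voxels(center, r_vox, g$shape)] <- 1L
  binary_mask(m, g$spacing_um)
}

test_that("post-processing rejects outside-mask and sub-volume components", {
  g <- mk_grid()
  lung <- mk_sphere_mask(g, c(20, 20, 20), 14)
  prob <- array(0, g$shape)
  # inside blob above threshold, 0.20 mm^3 (voxel = 0.125 mm^3 -> 2 voxels)
  keep_idx <- murilung:::sphere_voxels(c(20, 20, 20), 1.05, g$shape)
  expect_gte(length(keep_idx) * g$sp^3, 0.2)
  prob[keep_idx] <- 0.9
  # a single-voxel component: 0.125 mm^3 < 0.15 -> rejected
  prob[34, 20, 20] <- 0.9  # also outside lung (r=14 from center 20)
  prob[20, 20, 26] <- 0.9  # inside lung, 1 voxel = 0.125 mm^3
  dets <- postprocess(prob, lung, threshold = 0.5, min_volume_mm3 = 0.15)
  expect_length(dets, 1)
  expect_gte(dets[[1]]$volume_mm3, 0.15)

  # threshold 0 on a strictly positive map spans the whole lung
  pos <- array(0.01, g$shape)
  d0 <- postprocess(pos, lung, threshold = 0, min_volume_mm3 = 0.15)
  expect_length(d0, 1)
  expect_equal(length(d0[[1]]$voxels), sum(lung$voxels))
  expect_error(postprocess(pos, lung, threshold = 1.5), "threshold")
})

test_that("direct and near hits are matched per the 1.5-radius rule", {
  g <- mk_grid(c(80, 80, 80), 250)
  lung <- mk_sphere_mask(g, c(40, 40, 40), 36)
  # one label of radius 6 voxels = 1.5 mm equivalent radius
  label <- mk_sphere_mask(g, c(40, 40, 40), 6)
  labs <- labeled_tumors(label)
  r <- labs[[1]]$r_eq_mm
  expect_lt(abs(r - 1.5), 0.1)

  det_at <- function(dist_mm) {
    off <- round(dist_mm / g$sp)
    prob <- array(0, g$shape)
    prob[murilung:::sphere_voxels(c(40 + off, 40, 40), 1.5, g$shape)] <- 0.9
    postprocess(prob, lung, 0.5)
  }
  # direct overlap
  cc <- match_detections(det_at(0), labs)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(1L, 0L, 0L))
  # near hit at 1.4 r without overlap
  d14 <- det_at(1.4 * r)
  expect_length(intersect(d14[[1]]$voxels, labs[[1]]$voxels), 0)
  cc14 <- match_detections(d14, labs)
  expect_equal(c(cc14$tp, cc14$fp, cc14$fn), c(1L, 0L, 0L))
  # miss at 2.0 r
  cc20 <- match_detections(det_at(2 * r), labs)
  expect_equal(c(cc20$tp, cc20$fp, cc20$fn), c(0L, 1L, 1L))

  # two detections on one label add no extra TP or FP
  prob <- array(0, g$shape)
  prob[murilung:::sphere_voxels(c(37, 40, 40), 1.5, g$shape)] <- 0.9
  prob[murilung:::sphere_voxels(c(43, 40, 40), 1.5, g$shape)] <- 0.9
  dets2 <- postprocess(prob, lung, 0.5)
  expect_length(dets2, 2)
  cc2 <- match_detections(dets2, labs)
  expect_equal(c(cc2$tp, cc2$fp, cc2$fn), c(1L, 0L, 0L))
})

test_that("precision, recall and Dice reproduce the reported arithmetic", {
  expect_equal(round(precision(confusion_counts(138, 84, 69)), 3), 0.622)
  expect_equal(round(recall(confusion_counts(148, 120, 59)), 3), 0.715)
  expect_equal(round(detection_dice(confusion_counts(138, 84, 69)), 3), 0.643)
  expect_equal(round(detection_dice(confusion_counts(147, 91, 60)), 3), 0.661)
  expect_warning(p0 <- precision(confusion_counts(0, 0, 5)), "precision")
  expect_equal(p0, 0)
  expect_warning(r0 <- recall(confusion_counts(0, 3, 0)), "recall")
  expect_equal(r0, 0)
  expect_equal(detection_dice(confusion_counts(10, 0, 0)), 1)
})

test_that("detection Dice equals the harmonic mean of precision and recall", {
  set.seed(81)
  for (i in 1:20) {
    cc <- confusion_counts(sample(1:200, 1), sample(0:100, 1),
                           sample(0:100, 1))
    p <- precision(cc); r <- recall(cc)
    expect_gte(p, 0); expect_lte(p, 1)
    expect_gte(r, 0); expect_lte(r, 1)
    expect_equal(detection_dice(cc), 2 * p * r / (p + r), tolerance = 1e-12)
  }
})

test_that("threshold sweep finds the precision-recall intersection", {
  g <- mk_grid(c(50, 50, 50), 500)
  lung <- mk_sphere_mask(g, c(25, 25, 25), 22)
  # one label; one true detection scored 0.9; false blobs at graded scores
  # so FP falls (precision rises) while recall drops once 0.9 is passed
  label <- mk_sphere_mask(g, c(25, 25, 25), 2.2)
  prob <- array(0, g$shape)
  prob[murilung:::sphere_voxels(c(25, 25, 25), 2.2, g$shape)] <- 0.9
  fp_centers <- list(c(14, 25, 25), c(36, 25, 25), c(25, 14, 25),
                     c(25, 36, 25))
  sc <- c(0.2, 0.4, 0.6, 0.8)
  for (i in seq_along(fp_centers))
    prob[murilung:::sphere_voxels(fp_centers[[i]], 1.6, g$shape)] <- sc[i]
  sw <- threshold_sweep(list(prob), list(label), list(lung),
                        thresholds = seq(0, 1, by = 0.01))
  expect_equal(nrow(sw$curve), 101)
  # precision rises with threshold until recall collapses; the optimum lies
  # where P and R cross, between the last FP score and the TP score
  expect_true(sw$intersected)
  expect_gte(sw$optimal_threshold, 0.2)
  expect_lte(sw$optimal_threshold, 0.95)
  # monotone staircase: TP and FP never increase with threshold
  expect_true(all(diff(sw$curve$tp) <= 0))
  expect_true(all(diff(sw$curve$fp) <= 0))
  expect_true(all(diff(sw$curve$recall) <= 0))

  # a perfect map keeps P = R = 1 over the plateau
  perf <- array(0, g$shape)
  perf[murilung:::sphere_voxels(c(25, 25, 25), 2.2, g$shape)] <- 0.9
  swp <- threshold_sweep(list(perf), list(label), list(lung),
                         thresholds = seq(0, 0.8, by = 0.1))
  expect_true(swp$intersected)
  row <- swp$curve[swp$curve$threshold == 0.5, ]
  expect_equal(row$precision, 1)
  expect_equal(row$recall, 1)
})

test_that("ROC-like curve yields AUC 1 for perfect and ~0.5 for random maps", {
  g <- mk_grid(c(40, 40, 40), 500)
  lung <- mk_sphere_mask(g, c(20, 20, 20), 17)
  label <- mk_sphere_mask(g, c(20, 20, 20), 2)
  perf <- array(0, g$shape)
  perf[murilung:::sphere_voxels(c(20, 20, 20), 2, g$shape)] <- 0.9
  roc <- roc_like_curve(list(perf), list(label), list(lung),
                        thresholds = seq(0, 1, 0.05))
  expect_equal(roc$auc, 1)

  # label-independent random blob maps score no better than chance under
  # the pseudo-FPR normalization. Unlike a classical ROC, a chance detector
  # here yields an AUC near half its chance recall (well below 0.5), so the
  # Monte-Carlo check asserts the ordering: far below the perfect detector,
  # above zero, and on average no better than the diagonal.
  set.seed(82)
  lidx <- which(lung$voxels == 1L)
  aucs <- replicate(15, {
    prob <- array(0, g$shape)
    for (b in 1:25) {
      ctr <- arrayInd(sample(lidx, 1), g$shape)
      sv <- murilung:::sphere_voxels(ctr, 1.6, g$shape)
      prob[sv] <- pmax(prob[sv], runif(1))
    }
    ctr_l <- arrayInd(sample(lidx, 1), g$shape)
    lab <- array(0L, g$shape)
    lab[murilung:::sphere_voxels(ctr_l, 4, g$shape)] <- 1L
    roc_like_curve(list(prob), list(binary_mask(lab, g$spacing_um)),
                   list(lung), thresholds = seq(0, 1, 0.05))$auc
  })
  expect_gt(mean(aucs), 0.05)
  expect_lt(mean(aucs), 0.55)

  # single-threshold curve reduces to the two-endpoint trapezoid
  roc1 <- roc_like_curve(list(perf), list(label), list(lung),
                         thresholds = c(0.5, 0.95))
  expect_equal(roc1$auc, 1)  # point (0,1) with anchors
})

test_that("size-binned detection rates count per-bin fractions", {
  g <- mk_grid(c(60, 60, 60), 500)
  lung <- mk_sphere_mask(g, c(30, 30, 30), 27)
  # labels of graded sizes: radii in voxels -> volumes spanning the bins
  centers <- list(c(15, 15, 15), c(45, 15, 15), c(15, 45, 15), c(45, 45, 30))
  radii <- c(1.05, 1.35, 2.0, 3.2)  # ~0.2, ~0.4, ~2-4, ~15 mm^3
  lab <- array(0L, g$shape)
  for (i in seq_along(centers))
    lab[murilung:::sphere_voxels(centers[[i]], radii[i], g$shape)] <- 1L
  labels <- binary_mask(lab, g$spacing_um)
  labs <- labeled_tumors(labels)
  vols <- sort(vapply(labs, `[[`, numeric(1), "volume_mm3"))

  # detect all: every non-empty bin at rate 1
  prob <- array(0, g$shape)
  prob[lab == 1L] <- 0.9
  dets <- postprocess(prob, lung, 0.5)
  rates <- size_binned_rates(labs, dets)
  expect_true(all(rates$rate[rates$n_labels > 0] == 1))
  expect_true(all(is.na(rates$rate[rates$n_labels == 0])))

  # detect only the largest: its bin at 1, smallest bins at 0
  prob2 <- array(0, g$shape)
  prob2[murilung:::sphere_voxels(centers[[4]], radii[4], g$shape)] <- 0.9
  rates2 <- size_binned_rates(labs, postprocess(prob2, lung, 0.5))
  expect_equal(rates2$rate[rates2$lo == 5], 1)
  expect_true(all(rates2$rate[rates2$n_labels > 0 & rates2$lo < 5] == 0))
  expect_equal(sum(rates2$n_labels), 4)
})

test_that("constructed confusion counts are recovered exactly end to end", {
  ph <- proj_phantom()
  lung <- ph$lung_mask_truth
  shape <- dim(lung$voxels)
  dt <- distance_transform(lung, "voxel")
  deep <- which(dt > 6)
  set.seed(83)
  lab <- array(0L, shape)
  picks <- deep[round(seq(50, length(deep) - 50, length.out = 3))]
  for (p in picks) lab[murilung:::sphere_voxels(arrayInd(p, shape), 3.5,
                                                shape)] <- 1L
  labels <- binary_mask(lab, lung$spacing_um)
  k <- max(label_components(labels))
  expect_equal(k, 3)
  pm <- generate_prediction_map(labels, lung, n_false_pos = 3, miss_ids = 2,
                                seed = 84)
  cc <- evaluate_detections(pm, labels, lung, threshold = 0.5)
  expect_equal(c(cc$tp, cc$fp, cc$fn), c(2L, 3L, 1L))
})
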