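#' Confusion counts for a detection task
#'
#' @param tp,fp,fn non-negative integer counts of true positives, false
#'   positives and false negatives.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative")
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d, FP %d, FN %d (precision %.3f, recall %.3f, Dice %.3f)\n",
              x$tp, x$fp, x$fn, precision(x), recall(x), detection_dice(x)))
  invisible(x)
}

#' Detection precision
#'
#' `precision = TP / (TP + FP)`; defined as 0 (with a warning) when no
#' detections exist.
#'
#' @param c a `confusion_counts`.
#' @return rate in \[0, 1\].
#' @export
precision <- function(c) {
  if (c$tp + c$fp == 0) {
    warning("no detections: precision defined as 0")
    return(0)
  }
  c$tp / (c$tp + c$fp)
}

#' Detection recall (sensitivity)
#'
#' `recall = TP / (TP + FN)`; defined as 0 (with a warning) when no labels
#' exist.
#'
#' @param c a `confusion_counts`.
#' @return rate in \[0, 1\].
#' @export
recall <- function(c) {
  if (c$tp + c$fn == 0) {
    warning("no labels: recall defined as 0")
    return(0)
  }
  c$tp / (c$tp + c$fn)
}

#' Detection Dice score
#'
#' `D = 2 TP / (2 TP + FP + FN)`, the harmonic mean of precision and
#' recall.
#'
#' @param c a `confusion_counts`.
#' @return score in \[0, 1\].
#' @export
detection_dice <- function(c) {
  denom <- 2 * c$tp + c$fp + c$fn
  if (denom == 0) stop("undefined Dice: all counts zero")
  2 * c$tp / denom
}

#' Post-process a probability map into detection components
#'
#' Rejects everything outside the lung mask, binarizes at the decision
#' threshold, labels 26-connected components, and drops components whose
#' physical volume is below `min_volume_mm3` (default 0.15 mm^3, the
#' smallest nodule reliably imaged).
#'
#' @param prob_map `ct_volume` (or array) of probabilities in \[0, 1\].
#' @param lung_mask `binary_mask`.
#' @param threshold decision threshold in \[0, 1\]; voxels strictly above it
#'   are detections.
#' @param min_volume_mm3 minimum component volume.
#' @return list of `detection_component`s: `voxels` (linear indices),
#'   `volume_mm3`, `centroid_mm`, `peak_score`.
#' @export
postprocess <- function(prob_map, lung_mask, threshold,
                        min_volume_mm3 = 0.15) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  pv <- if (is.list(prob_map)) prob_map$voxels else prob_map
  shape <- dim(pv)
  if (!identical(shape, dim(lung_mask$voxels)))
    stop("prob map and lung mask are on different grids")
  sp <- lung_mask$spacing_um / 1000
  inmask <- pv * (lung_mask$voxels == 1L)
  det <- array(as.integer(inmask > threshold), shape)
  lab <- cpp_label_components(det, 26L)
  stats <- component_stats(lab, lung_mask$spacing_um)
  out <- Filter(function(s) s$volume_mm3 >= min_volume_mm3, stats)
  lapply(out, function(s) {
    structure(list(voxels = s$voxels, volume_mm3 = s$volume_mm3,
                   centroid_mm = s$centroid_mm,
                   peak_score = max(pv[s$voxels])),
              class = "detection_component")
  })
}

#' Extract labeled tumors from a label mask
#'
#' @param labels `binary_mask`; 26-connected components are individual
#'   tumors.
#' @return list of `labeled_tumor`s: `voxels`, `centroid_mm`, `volume_mm3`,
#'   `r_eq_mm` (equivalent sphere radius `(3V / 4 pi)^(1/3)`).
#' @export
labeled_tumors <- function(labels) {
  lab <- label_components(labels, 26)
  stats <- component_stats(lab, labels$spacing_um)
  lapply(stats, function(s) structure(s, class = "labeled_tumor"))
}

#' Match detections against labeled tumors
#'
#' A label counts as detected (one TP, however many detections hit it) if
#' any detection overlaps it (direct hit) or any detection's centroid lies
#' within 1.5 times the label's equivalent radius of the label centroid
#' (near hit). Detections matching no label are false positives; undetected
#' labels are false negatives. A detection overlapping two labels credits
#' both and is no FP.
#'
#' @param dets list from [postprocess()].
#' @param labels list from [labeled_tumors()] or a `binary_mask`.
#' @param near_factor near-hit radius multiplier (default 1.5).
#' @return a `confusion_counts`.
#' @export
match_detections <- function(dets, labels, near_factor = 1.5) {
  if (inherits(labels, "binary_mask")) labels <- labeled_tumors(labels)
  n_lab <- length(labels)
  n_det <- length(dets)
  if (n_lab == 0)
    return(confusion_counts(0, n_det, 0))
  lab_hit <- logical(n_lab)
  det_hit <- logical(n_det)
  for (li in seq_len(n_lab)) {
    L <- labels[[li]]
    lv <- L$voxels
    for (di in seq_len(n_det)) {
      D <- dets[[di]]
      direct <- length(intersect(D$voxels, lv)) > 0
      near <- sqrt(sum((D$centroid_mm - L$centroid_mm)^2)) <=
        near_factor * L$r_eq_mm
      if (direct || near) {
        lab_hit[li] <- TRUE
        det_hit[di] <- TRUE
      }
    }
  }
  confusion_counts(sum(lab_hit), sum(!det_hit), sum(!lab_hit))
}

#' Evaluate one or many prediction maps at a threshold
#'
#' @param prob_maps a probability volume or list of them.
#' @param labels a `binary_mask` or list of them.
#' @param lung_masks a `binary_mask` or list of them.
#' @param threshold decision threshold.
#' @param min_volume_mm3 minimum detection volume.
#' @return aggregated `confusion_counts` over all maps.
#' @export
evaluate_detections <- function(prob_maps, labels, lung_masks, threshold,
                                min_volume_mm3 = 0.15) {
  if (!is.list(prob_maps) || inherits(prob_maps, "ct_volume"))
    prob_maps <- list(prob_maps)
  if (inherits(labels, "binary_mask")) labels <- list(labels)
  if (inherits(lung_masks, "binary_mask")) lung_masks <- list(lung_masks)
  tp <- fp <- fn <- 0L
  for (i in seq_along(prob_maps)) {
    dets <- postprocess(prob_maps[[i]], lung_masks[[i]], threshold,
                        min_volume_mm3)
    cc <- match_detections(dets, labels[[i]])
    tp <- tp + cc$tp; fp <- fp + cc$fp; fn <- fn + cc$fn
  }
  confusion_counts(tp, fp, fn)
}

#' Sweep the decision threshold
#'
#' Evaluates precision and recall over a threshold grid and reports the
#' operating point where the two curves intersect (the threshold of best
#' combined performance), located by linear interpolation of `P - R`
#' between adjacent grid points. If the curves never cross, the threshold
#' maximizing the detection Dice is returned with a warning.
#'
#' @inheritParams evaluate_detections
#' @param thresholds numeric grid (default `seq(0, 1, by = 0.01)`).
#' @return object of class `threshold_sweep`: data.frame `curve`
#'   (threshold, tp, fp, fn, precision, recall, dice), `optimal_threshold`,
#'   `intersected` flag.
#' @export
threshold_sweep <- function(prob_maps, labels, lung_masks,
                            thresholds = seq(0, 1, by = 0.01),
                            min_volume_mm3 = 0.15) {
  if (length(thresholds) < 2) stop("need at least 2 thresholds")
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(t) {
    cc <- evaluate_detections(prob_maps, labels, lung_masks, t,
                              min_volume_mm3)
    p <- if (cc$tp + cc$fp == 0) 0 else cc$tp / (cc$tp + cc$fp)
    r <- if (cc$tp + cc$fn == 0) 0 else cc$tp / (cc$tp + cc$fn)
    d <- if (2 * cc$tp + cc$fp + cc$fn == 0) 0 else
      2 * cc$tp / (2 * cc$tp + cc$fp + cc$fn)
    data.frame(threshold = t, tp = cc$tp, fp = cc$fp, fn = cc$fn,
               precision = p, recall = r, dice = d)
  })
  curve <- do.call(rbind, rows)
  diff_pr <- curve$precision - curve$recall
  opt <- NA_real_
  intersected <- FALSE
  for (i in seq_len(nrow(curve) - 1)) {
    a <- diff_pr[i]; b <- diff_pr[i + 1]
    if (a == 0) { opt <- curve$threshold[i]; intersected <- TRUE; break }
    if (a * b < 0) {
      w <- a / (a - b)
      opt <- curve$threshold[i] +
        w * (curve$threshold[i + 1] - curve$threshold[i])
      intersected <- TRUE
      break
    }
  }
  if (!intersected && diff_pr[nrow(curve)] == 0 &&
      curve$recall[nrow(curve)] > 0) {
    opt <- curve$threshold[nrow(curve)]
    intersected <- TRUE
  }
  if (!intersected) {
    warning("precision and recall never intersect; returning argmax Dice")
    opt <- curve$threshold[which.max(curve$dice)]
  }
  structure(list(curve = curve, optimal_threshold = opt,
                 intersected = intersected),
            class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat(sprintf("<threshold_sweep> %d points, optimal threshold %.3f (%s)\n",
              nrow(x$curve), x$optimal_threshold,
              if (x$intersected) "P = R intersection" else "argmax Dice"))
  invisible(x)
}

#' ROC-like curve and AUC for the detection task
#'
#' A detection task has no true negatives, so a textbook false-positive
#' rate does not exist. The curve reported here uses TPR = recall per
#' threshold against a pseudo-FPR, the false-positive count normalized by
#' its maximum over the sweep. The AUC is the trapezoidal area under the
#' monotone (upper-hull) staircase through the points plus the (0,0) and
#' (1,1) anchors. Because of the pseudo-FPR normalization these AUC values
#' are comparable between runs of this package, but not to AUCs computed
#' with other FPR conventions.
#'
#' @inheritParams threshold_sweep
#' @return object of class `roc_like`: data.frame `curve` (threshold, tpr,
#'   pseudo_fpr) and `auc`.
#' @export
roc_like_curve <- function(prob_maps, labels, lung_masks,
                           thresholds = seq(0, 1, by = 0.01),
                           min_volume_mm3 = 0.15) {
  sw <- threshold_sweep(prob_maps, labels, lung_masks, thresholds,
                        min_volume_mm3)
  curve <- sw$curve
  max_fp <- max(curve$fp)
  pfpr <- if (max_fp == 0) rep(0, nrow(curve)) else curve$fp / max_fp
  pts <- data.frame(threshold = curve$threshold, tpr = curve$recall,
                    pseudo_fpr = pfpr)
  hx <- c(0, pts$pseudo_fpr, 1)
  hy <- c(0, pts$tpr, 1)
  ord <- order(hx, hy)
  hx <- hx[ord]; hy <- hy[ord]
  hy <- cummax(hy)  # monotone staircase upper hull
  auc <- sum(diff(hx) * (head(hy, -1) + tail(hy, -1)) / 2)
  structure(list(curve = pts, auc = auc), class = "roc_like")
}

#' @export
print.roc_like <- function(x, ...) {
  cat(sprintf("<roc_like> %d points, AUC %.3f (pseudo-FPR normalization)\n",
              nrow(x$curve), x$auc))
  invisible(x)
}

#' Detection rate by tumor size bin
#'
#' Fraction of labeled tumors detected (direct or near hit) per volume bin.
#' Default bin edges follow the reporting convention 0.15, 0.25, 0.5, 1,
#' 5 mm^3 with an open top bin. Bins containing no labels are reported as
#' `NA`.
#'
#' @param labels list from [labeled_tumors()] or a `binary_mask`.
#' @param dets list from [postprocess()].
#' @param bin_edges_mm3 ascending lower bin edges; the last bin is open.
#' @param near_factor near-hit radius multiplier.
#' @return data.frame with `bin`, `lo`, `hi`, `n_labels`, `n_detected`,
#'   `rate`.
#' @export
size_binned_rates <- function(labels, dets,
                              bin_edges_mm3 = c(0.15, 0.25, 0.5, 1, 5),
                              near_factor = 1.5) {
  if (inherits(labels, "binary_mask")) labels <- labeled_tumors(labels)
  if (is.unsorted(bin_edges_mm3)) stop("bin edges must be ascending")
  edges <- c(bin_edges_mm3, Inf)
  n_bins <- length(bin_edges_mm3)
  det_per_label <- vapply(labels, function(L) {
    any(vapply(dets, function(D) {
      length(intersect(D$voxels, L$voxels)) > 0 ||
        sqrt(sum((D$centroid_mm - L$centroid_mm)^2)) <=
          near_factor * L$r_eq_mm
    }, logical(1)))
  }, logical(1))
  vols <- vapply(labels, `[[`, numeric(1), "volume_mm3")
  out <- lapply(seq_len(n_bins), function(b) {
    sel <- vols >= edges[b] & vols < edges[b + 1]
    n <- sum(sel)
    data.frame(bin = b, lo = edges[b], hi = edges[b + 1], n_labels = n,
               n_detected = sum(det_per_label[sel]),
               rate = if (n == 0) NA_real_ else sum(det_per_label[sel]) / n)
  })
  do.call(rbind, out)
}
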