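#' Training configuration for the V-Net detector
#'
#' Defaults follow the full-scale training recipe: Adam with initial learning
#' rate 0.01 and first-moment decay 0.9, batch size 3, learning rate reduced
#' by 10\% every 100 steps, 96^3 patches sampled so that 80\% contain tumor,
#' intensities divided by 1000, volumes resampled to 100 um, 5-fold cross
#' validation. Compact values (2 stages, 32^3 patches, a few hundred steps)
#' make CPU runs practical.
#'
#' @param strategy one of `"sim_only"`, `"real_only"`, `"combined"`,
#'   `"transfer"`.
#' @param k_folds folds for cross validation (>= 2).
#' @param epochs optimization steps (one batch per step).
#' @param lr0 initial learning rate (> 0).
#' @param beta1 Adam first-moment decay (the "momentum").
#' @param beta2 Adam second-moment decay.
#' @param batch_size patches per step.
#' @param lr_decay multiplicative decay factor.
#' @param lr_decay_every steps between decays.
#' @param patch cubic patch edge length (voxels).
#' @param p_tumor_patch probability that a sampled patch must intersect a
#'   tumor label.
#' @param norm_divisor intensity normalization divisor (HU).
#' @param resample_um target isotropic spacing before patching; `NULL`
#'   leaves volumes on their native grid.
#' @param flip_coronal augment with random left-right flips.
#' @param val_every steps between validation soft-Dice evaluations (0 = off).
#' @return an object of class `train_config`.
#' @export
train_config <- function(strategy = c("sim_only", "real_only", "combined",
                                      "transfer"),
                         k_folds = 5, epochs = 5000, lr0 = 0.01, beta1 = 0.9,
                         beta2 = 0.999, batch_size = 3, lr_decay = 0.9,
                         lr_decay_every = 100, patch = 96,
                         p_tumor_patch = 0.8, norm_divisor = 1000,
                         resample_um = 100, flip_coronal = TRUE,
                         val_every = 0) {
  strategy <- match.arg(strategy)
  if (p_tumor_patch < 0 || p_tumor_patch > 1)
    stop("p_tumor_patch must be in [0, 1]")
  if (k_folds < 2) stop("k_folds must be >= 2")
  if (lr0 <= 0) stop("lr0 must be > 0")
  structure(as.list(environment()), class = "train_config")
}

#' Split scan ids into cross-validation folds
#'
#' Balanced random partition: every scan appears in exactly one test set,
#' test sets are pairwise disjoint, and sizes differ by at most one.
#'
#' @param scan_ids vector of scan identifiers.
#' @param k number of folds.
#' @param seed optional RNG seed.
#' @return an object of class `fold_split`: list with one element per fold,
#'   each holding `train` and `test` id vectors.
#' @export
make_folds <- function(scan_ids, k = 5, seed = NULL) {
  n <- length(scan_ids)
  if (n < k) stop("need at least k scans")
  with_seed(seed, {
    perm <- sample(scan_ids)
    # contiguous balanced blocks over the permuted ids (sizes differ by <= 1)
    grp <- rep(seq_len(k), times = diff(floor(seq(0, n, length.out = k + 1))))
    folds <- lapply(seq_len(k), function(f) {
      test <- perm[grp == f]
      list(train = setdiff(scan_ids, test), test = test)
    })
    structure(folds, class = "fold_split")
  })
}

#' Dice coefficient between two masks or soft maps
#'
#' `D = 2 |P . T| / (|P| + |T|)`; for soft inputs the intersection is the
#' sum of elementwise products. When both inputs are empty, D is defined as
#' 1 (perfect agreement of two empty segmentations).
#'
#' @param pred,target arrays, `binary_mask`s, or numeric vectors of equal
#'   shape; `pred` may be a soft map in \[0, 1\].
#' @return the Dice coefficient in \[0, 1\].
#' @export
dice_coefficient <- function(pred, target) {
  p <- if (is.list(pred)) pred$voxels else pred
  t <- if (is.list(target)) target$voxels else target
  if (!identical(dim(p), dim(t))) stop("shapes must match")
  sp <- sum(p); st <- sum(t)
  if (sp == 0 && st == 0) return(1)
  2 * sum(p * t) / (sp + st)
}

# soft Dice loss (1 - D) and its gradient w.r.t. the soft prediction.
# The squared-denominator formulation agrees with the cardinality form on
# binary maps and has zero gradient at a perfect prediction.
soft_dice_loss <- function(prob, target, eps = 1e-6) {
  inter <- sum(prob * target)
  denom <- sum(prob^2) + sum(target^2) + eps
  D <- (2 * inter + eps) / denom
  dD <- (2 * target * denom - (2 * inter + eps) * 2 * prob) / denom^2
  list(loss = 1 - D, dice = D, dprob = -dD)
}

#' Sample a training patch
#'
#' With probability `p_tumor_patch` the returned patch is guaranteed to
#' intersect at least one label voxel (a random label voxel with a random
#' in-patch offset); otherwise the patch position is uniform. Intensities
#' are divided by the normalization divisor, and with probability 0.5 both
#' patch and label are flipped left-right (augmentation in the coronal
#' plane). Requesting a tumor patch from an empty label map falls back to a
#' uniform patch.
#'
#' @param image 3-D HU array (or `ct_volume`).
#' @param label 3-D 0/1 array (or `binary_mask`).
#' @param cfg a [train_config()].
#' @return list with `x` (normalized patch), `y` (label patch), `corner`,
#'   `flipped`.
#' @export
sample_patch <- function(image, label, cfg) {
  img <- if (is.list(image)) image$voxels else image
  lab <- if (is.list(label)) label$voxels else label
  d <- dim(img)
  p <- cfg$patch
  if (any(d < p)) stop("volume smaller than patch size")
  want_tumor <- runif(1) < cfg$p_tumor_patch
  lab_idx <- NULL
  if (want_tumor) {
    lab_idx <- which(lab == 1L)
    if (!length(lab_idx)) want_tumor <- FALSE
  }
  if (want_tumor) {
    v <- arrayInd(lab_idx[sample.int(length(lab_idx), 1)], d)
    corner <- integer(3)
    for (a in 1:3) {
      lo <- max(1L, v[a] - p + 1L)
      hi <- min(v[a], d[a] - p + 1L)
      corner[a] <- if (hi <= lo) lo else sample(lo:hi, 1)
    }
  } else {
    corner <- vapply(1:3, function(a) sample.int(d[a] - p + 1L, 1),
                     integer(1))
  }
  ix <- corner[1]:(corner[1] + p - 1)
  iy <- corner[2]:(corner[2] + p - 1)
  iz <- corner[3]:(corner[3] + p - 1)
  x <- img[ix, iy, iz] / cfg$norm_divisor
  y <- lab[ix, iy, iz]
  flipped <- FALSE
  if (cfg$flip_coronal && runif(1) < 0.5) {
    x <- x[p:1, , ]
    y <- y[p:1, , ]
    flipped <- TRUE
  }
  list(x = x, y = y, corner = corner, flipped = flipped)
}

# assemble a batch of patches into (p,p,p,1,n) / label arrays
make_batch <- function(sets, cfg) {
  n <- cfg$batch_size
  p <- cfg$patch
  xb <- array(0, c(p, p, p, 1, n))
  yb <- array(0, c(p, p, p, 1, n))
  for (i in seq_len(n)) {
    s <- sets[[sample.int(length(sets), 1)]]
    pt <- sample_patch(s$image, s$labels, cfg)
    xb[, , , 1, i] <- pt$x
    yb[, , , 1, i] <- pt$y
  }
  list(x = xb, y = yb)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0)
}

adam_step <- function(params, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# one optimization run over `sets`; returns updated net + loss history
train_single <- function(net, sets, cfg, val_sets = NULL) {
  state <- adam_init(net$params)
  history <- data.frame(step = integer(), loss = numeric(),
                        dice = numeric())
  val_hist <- NULL
  for (step in seq_len(cfg$epochs)) {
    lr <- cfg$lr0 * cfg$lr_decay^(floor((step - 1) / cfg$lr_decay_every))
    b <- make_batch(sets, cfg)
    fwd <- vnet_forward(net, b$x, training = TRUE)
    for (nm in names(fwd$buffers)) net$buffers[[nm]] <- fwd$buffers[[nm]]
    l <- soft_dice_loss(fwd$prob, b$y)
    grads <- vnet_backward(net, fwd, l$dprob)
    upd <- adam_step(net$params, grads, state, lr, cfg$beta1, cfg$beta2)
    net$params <- upd$params
    state <- upd$state
    history <- rbind(history,
                     data.frame(step = step, loss = l$loss, dice = l$dice))
    if (cfg$val_every > 0 && !is.null(val_sets) &&
        step %% cfg$val_every == 0) {
      vd <- mean(vapply(val_sets, function(s) {
        pt <- sample_patch(s$image, s$labels, cfg)
        xa <- array(pt$x, c(dim(pt$x), 1, 1))
        pr <- vnet_forward(net, xa, training = FALSE)$prob
        soft_dice_loss(pr, array(pt$y, dim(xa)))$dice
      }, numeric(1)))
      val_hist <- rbind(val_hist, data.frame(step = step, val_dice = vd))
    }
  }
  list(net = net, history = history, validation = val_hist)
}

#' Train V-Net detector(s) under one of four strategies
#'
#' * `sim_only`: a single network trained on the simulated training sets.
#' * `real_only`: one network per cross-validation fold of the real sets.
#' * `combined`: per-fold networks whose training data are each fold's real
#'   training sets plus the full simulated training set.
#' * `transfer`: the `sim_only` network is used as initialization and
#'   retrained per fold on real data.
#'
#' "Real" sets may be any labeled image/label pairs; in fully synthetic
#' work, phantom-derived sets stand in for real scans. Each set is a list
#' with elements `image` (`ct_volume` or array) and `labels`
#' (`binary_mask` or array). Volumes are resampled to `cfg$resample_um`
#' first when that field is non-`NULL`.
#'
#' @param sim_sets list of simulated training sets (may carry a logical
#'   `validation` element; validation sets are excluded from training).
#' @param real_sets list of real (or stand-in) sets.
#' @param cfg a [train_config()].
#' @param spec a [vnet_spec()].
#' @param seed RNG seed governing initialization, folds and sampling.
#' @param init_net optional pre-built or pre-trained `vnet` to start from.
#' @return an object of class `vnet_fit`: list with `models` (one per fold,
#'   or a single model for `sim_only`), `folds`, `histories`, `cfg`, `spec`.
#' @export
vnet_train <- function(sim_sets = NULL, real_sets = NULL, cfg = train_config(),
                       spec = vnet_spec(), seed = NULL, init_net = NULL) {
  check_patch_size(spec, cfg$patch)
  prep <- function(sets) {
    lapply(sets, function(s) {
      img <- s$image; lab <- s$labels
      if (!is.null(cfg$resample_um)) {
        if (inherits(img, "ct_volume")) img <- resample_isotropic(img, cfg$resample_um)
        if (inherits(lab, "binary_mask")) lab <- resample_isotropic(lab, cfg$resample_um)
      }
      list(image = if (is.list(img)) img$voxels else img,
           labels = if (is.list(lab)) lab$voxels else lab,
           validation = isTRUE(s$validation))
    })
  }
  with_seed(seed, {
    sim <- if (!is.null(sim_sets)) prep(sim_sets) else NULL
    real <- if (!is.null(real_sets)) prep(real_sets) else NULL
    sim_train <- Filter(function(s) !s$validation, sim %||% list())
    sim_val <- Filter(function(s) s$validation, sim %||% list())
    need_real <- cfg$strategy %in% c("real_only", "combined", "transfer")
    if (need_real && is.null(real))
      stop("config error: strategy '", cfg$strategy, "' requires real sets")
    if (cfg$strategy %in% c("sim_only", "combined", "transfer") &&
        length(sim_train) == 0)
      stop("config error: strategy '", cfg$strategy, "' requires simulated sets")

    new_net <- function() init_net %||% build_vnet(spec)
    if (cfg$strategy == "sim_only") {
      r <- train_single(new_net(), sim_train, cfg,
                        if (length(sim_val)) sim_val else NULL)
      return(structure(list(models = list(r$net), folds = NULL,
                            histories = list(r$history), cfg = cfg,
                            spec = spec),
                       class = "vnet_fit"))
    }
    folds <- make_folds(seq_along(real), cfg$k_folds)
    base <- if (cfg$strategy == "transfer") {
      if (!is.null(init_net)) init_net
      else train_single(build_vnet(spec), sim_train, cfg)$net
    } else NULL
    models <- list()
    histories <- list()
    for (f in seq_along(folds)) {
      train_ids <- folds[[f]]$train
      sets_f <- real[train_ids]
      if (cfg$strategy == "combined") sets_f <- c(sets_f, sim_train)
      net0 <- switch(cfg$strategy,
                     real_only = new_net(),
                     combined = new_net(),
                     transfer = base)
      r <- train_single(net0, sets_f, cfg)
      models[[f]] <- r$net
      histories[[f]] <- r$history
    }
    structure(list(models = models, folds = folds, histories = histories,
                   cfg = cfg, spec = spec),
              class = "vnet_fit")
  })
}

#' @export
print.vnet_fit <- function(x, ...) {
  cat(sprintf("<vnet_fit> strategy %s, %d model(s)\n", x$cfg$strategy,
              length(x$models)))
  if (length(x$histories)) {
    h <- x$histories[[1]]
    cat(sprintf("  first model: %d steps, final training Dice %.3f\n",
                nrow(h), h$dice[nrow(h)]))
  }
  invisible(x)
}

#' Stitched sliding-window prediction
#'
#' Extracts overlapping cubic patches with the given stride (edge patches
#' clamped to the volume), runs each through the network, and averages
#' overlapping predictions, so every voxel's value is the mean over all
#' patches covering it. A volume smaller than the patch is padded with air
#' and predicted in one piece.
#'
#' @param net a trained `vnet`.
#' @param vol a `ct_volume` (resampled to the training spacing beforehand if
#'   needed) or 3-D array of HU values.
#' @param patch cubic patch edge length.
#' @param stride stride between patch corners (default 12).
#' @param norm_divisor intensity normalization divisor.
#' @return a `ct_volume` of probabilities in \[0, 1\].
#' @export
sliding_window_predict <- function(net, vol, patch, stride = 12,
                                   norm_divisor = 1000) {
  arr <- if (is.list(vol)) vol$voxels else vol
  spacing <- if (is.list(vol)) vol$spacing_um else NA_real_
  d <- dim(arr)
  padded <- FALSE
  if (any(d < patch)) {
    message("volume smaller than patch; predicting one padded patch")
    nd <- pmax(d, patch)
    big <- array(-1000, nd)
    big[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
    arr2 <- big
    padded <- TRUE
  } else arr2 <- arr
  d2 <- dim(arr2)
  starts <- lapply(1:3, function(a) {
    s <- unique(c(seq(1L, d2[a] - patch + 1L, by = stride),
                  d2[a] - patch + 1L))
    s
  })
  acc <- array(0, d2)
  cnt <- array(0, d2)
  for (sz in starts[[3]]) for (sy in starts[[2]]) for (sx in starts[[1]]) {
    ix <- sx:(sx + patch - 1); iy <- sy:(sy + patch - 1)
    iz <- sz:(sz + patch - 1)
    x <- array(arr2[ix, iy, iz] / norm_divisor, c(patch, patch, patch, 1, 1))
    pr <- vnet_forward(net, x, training = FALSE)$prob
    acc[ix, iy, iz] <- acc[ix, iy, iz] + pr[, , , 1, 1]
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  out <- acc / cnt
  if (padded) out <- out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]),
                         drop = FALSE]
  dim(out) <- d
  if (is.na(spacing)) return(out)
  ct_volume(out, spacing)
}

#' Predict tumor probabilities for a volume
#'
#' @param object a `vnet_fit`.
#' @param vol a `ct_volume` in HU.
#' @param model_index which fold model to use.
#' @param stride sliding-window stride.
#' @param ... unused.
#' @return a `ct_volume` of probabilities.
#' @export
predict.vnet_fit <- function(object, vol, model_index = 1, stride = 12, ...) {
  cfg <- object$cfg
  v <- vol
  if (!is.null(cfg$resample_um) && inherits(vol, "ct_volume") &&
      abs(vol$spacing_um - cfg$resample_um) > 1e-6)
    v <- resample_isotropic(vol, cfg$resample_um)
  sliding_window_predict(object$models[[model_index]], v, cfg$patch, stride,
                         cfg$norm_divisor)
}
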