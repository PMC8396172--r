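test_that("parameter count matches a closed-form oracle for a 1-stage net", {
  k <- 3; c1 <- 4
  spec <- vnet_spec(n_stages = 1, channels = c1, convs_per_stage = 2,
                    kernel = k)
  net <- build_vnet(spec, seed = 1)
  unit <- function(cin, cout, kk) kk^3 * cin * cout + cout + 2 * cout + cout
  expected <- unit(1, c1, k) +      # input conv + BN + PReLU
    2 * unit(c1, c1, k) +           # stage block (2 convs)
    (c1 * 1 + 1)                    # final 1x1x1 conv
  expect_equal(net$n_parameters, expected)

  # parameter count is invariant to patch size (fully convolutional):
  # the count depends only on the spec, never on any input
  net2 <- build_vnet(spec, seed = 99)
  expect_equal(net2$n_parameters, expected)
})

test_that("network output matches input shape and admissibility is enforced", {
  spec <- vnet_spec(n_stages = 2, channels = c(2, 4), convs_per_stage = 1,
                    kernel = 3)
  net <- build_vnet(spec, seed = 2)
  x <- array(rnorm(16^3), c(16, 16, 16, 1, 1))
  out <- vnet_forward(net, x)
  expect_equal(dim(out$prob), c(16, 16, 16, 1, 1))
  expect_true(all(out$prob > 0 & out$prob < 1))
  expect_error(check_patch_size(spec, 15), "divisible")

  # constant-zero weights produce a constant output field
  net0 <- net
  for (nm in names(net0$params))
    if (grepl("\\.w$|\\.b$|bn_b", nm)) net0$params[[nm]][] <- 0
  out0 <- vnet_forward(net0, x)
  expect_lt(diff(range(out0$prob)), 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  spec <- vnet_spec(n_stages = 2, channels = c(2, 3), convs_per_stage = 1,
                    kernel = 3, dropout_rate = 0)
  net <- build_vnet(spec, seed = 3)
  set.seed(4)
  x <- array(rnorm(8^3 * 2), c(8, 8, 8, 1, 2))
  y <- array(as.double(runif(8^3 * 2) < 0.3), c(8, 8, 8, 1, 2))
  fwd <- vnet_forward(net, x, training = TRUE)
  l <- murilung:::soft_dice_loss(fwd$prob, y)
  grads <- vnet_backward(net, fwd, l$dprob)
  eps <- 1e-5
  for (nm in c("in.w", "enc2.conv1.w", "down1.w", "up1.w", "dec1.conv1.w",
               "enc1.conv1.bn_g", "dec1.conv1.alpha", "out.b")) {
    i <- sample(length(net$params[[nm]]), 1)
    lo <- hi <- net
    hi$params[[nm]][i] <- hi$params[[nm]][i] + eps
    lo$params[[nm]][i] <- lo$params[[nm]][i] - eps
    fh <- murilung:::soft_dice_loss(vnet_forward(hi, x, TRUE)$prob, y)$loss
    fl <- murilung:::soft_dice_loss(vnet_forward(lo, x, TRUE)$prob, y)$loss
    num <- (fh - fl) / (2 * eps)
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("soft Dice loss is bounded with vanishing gradient at P = T", {
  set.seed(5)
  for (i in 1:5) {
    p <- runif(100)
    t <- as.double(runif(100) < 0.4)
    l <- murilung:::soft_dice_loss(p, t)
    expect_gte(l$loss, 0)
    expect_lte(l$loss, 1)
  }
  t <- as.double(runif(200) < 0.5)
  l <- murilung:::soft_dice_loss(t, t)
  expect_equal(l$loss, 0, tolerance = 1e-5)
  expect_lt(max(abs(l$dprob[t == 1])), 1e-4)
})

test_that("Dice coefficient follows its defining identities", {
  a <- array(0L, c(4, 4, 4)); a[1:2, 1, 1] <- 1L
  b <- a
  expect_equal(dice_coefficient(a, b), 1)
  c_ <- array(0L, c(4, 4, 4)); c_[3:4, 4, 4] <- 1L
  expect_equal(dice_coefficient(a, c_), 0)
  d <- array(0L, c(4, 4, 4)); d[2:3, 1, 1] <- 1L  # |P|=|T|=2, overlap 1
  expect_equal(dice_coefficient(a, d), 0.5)
  empty <- array(0L, c(4, 4, 4))
  expect_equal(dice_coefficient(empty, empty), 1)
  expect_error(dice_coefficient(a, array(0L, c(3, 3, 3))), "match")
})

test_that("fold splits partition the scans with balanced sizes", {
  f <- make_folds(1:10, k = 5, seed = 6)
  sizes <- vapply(f, function(x) length(x$test), integer(1))
  expect_true(all(sizes == 2))
  tests <- unlist(lapply(f, `[[`, "test"))
  expect_setequal(tests, 1:10)
  expect_equal(length(tests), 10)  # pairwise disjoint

  f36 <- make_folds(1:36, k = 5, seed = 7)
  sizes36 <- vapply(f36, function(x) length(x$test), integer(1))
  expect_true(all(sizes36 %in% c(7, 8)))
  expect_setequal(unlist(lapply(f36, `[[`, "test")), 1:36)
  for (fold in f36) {
    expect_length(intersect(fold$train, fold$test), 0)
    expect_setequal(c(fold$train, fold$test), 1:36)
  }
  expect_error(make_folds(1:3, k = 5), "at least")
})

test_that("patch sampler honors bias, normalization and flip involution", {
  set.seed(8)
  d <- c(48, 48, 48)
  img <- array(-1000, d)
  lab <- array(0L, d)
  lab[40:42, 40:42, 40:42] <- 1L
  cfg <- train_config(strategy = "sim_only", patch = 16, p_tumor_patch = 0.8,
                      resample_um = NULL, flip_coronal = FALSE, k_folds = 2)
  hits <- replicate(2000, sum(sample_patch(img, lab, cfg)$y) > 0)
  ci <- 2.576 * sqrt(0.8 * 0.2 / 2000)
  # random-corner patches almost never hit the small label, so the hit rate
  # is governed by the bias probability
  expect_lt(abs(mean(hits) - 0.8), ci + (16 / 33)^3 * 0.2)

  # -1000 HU maps to -1.0 after normalization
  p <- sample_patch(img, lab, cfg)
  expect_equal(min(p$x), -1)
  expect_equal(max(abs(p$x[p$y == 0] + 1)), 0)

  # flipping twice restores the original patch
  x <- array(rnorm(16^3), c(16, 16, 16))
  expect_identical(x[16:1, , ][16:1, , ], x)

  # empty label map falls back to a random patch without error
  p0 <- sample_patch(img, array(0L, d), cfg)
  expect_equal(dim(p0$x), c(16, 16, 16))
})

test_that("sliding-window stitching averages overlapping patches correctly", {
  spec <- vnet_spec(n_stages = 1, channels = 2, convs_per_stage = 1,
                    kernel = 3)
  net <- build_vnet(spec, seed = 9)
  # constant model: zero weights, bias b -> sigmoid(bn(b)) constant
  for (nm in names(net$params)) net$params[[nm]][] <- 0
  net$params[["out.b"]] <- 0.7
  vol <- ct_volume(array(rnorm(24^3, -500, 100), c(24, 24, 24)), 150)
  pr <- sliding_window_predict(net, vol, patch = 8, stride = 5)
  expect_lt(diff(range(pr$voxels)), 1e-12)
  expect_equal(pr$voxels[1], 1 / (1 + exp(-0.7)), tolerance = 1e-9)

  # stride = patch tiles the volume without averaging artifacts
  pr2 <- sliding_window_predict(net, vol, patch = 8, stride = 8)
  expect_equal(dim(pr2$voxels), c(24, 24, 24))

  # coverage counts: a 1-D analogue computed by brute force matches the
  # starts pattern used by the stitcher
  n <- 24; p <- 8; s <- 5
  starts <- unique(c(seq(1, n - p + 1, by = s), n - p + 1))
  cover <- integer(n)
  for (st in starts) cover[st:(st + p - 1)] <- cover[st:(st + p - 1)] + 1L
  expect_true(all(cover >= 1))
  # the stitched output divides by exactly this coverage; with a model
  # emitting patch-dependent constants the mean equals sum/cover
  expect_equal(sum(cover), length(starts) * p)

  # smaller-than-patch volumes are padded and predicted whole
  tiny <- ct_volume(array(0, c(5, 5, 5)), 150)
  expect_message(pr3 <- sliding_window_predict(net, tiny, patch = 8,
                                               stride = 8), "padded")
  expect_equal(dim(pr3$voxels), c(5, 5, 5))
})

test_that("training improves the fit and strategies wire their data", {
  ph <- proj_phantom()
  bank <- generate_tumor_bank(2, size_range_mm3 = c(3, 8), spacing_um = 200,
                              mean_hu = 100, sd_hu = 30, seed = 71)
  aa <- list(size_range_mm3 = c(3, 8), median_mm3 = 5, p90_mm3 = 7.5)
  ds <- generate_simulated_dataset(list(ph), bank, n_sets = 4,
                                   tumors_per_set = 2, n_validation = 0,
                                   method = "voxel", augment_args = aa,
                                   seed = 72)
  spec <- vnet_spec(n_stages = 2, channels = c(3, 6), convs_per_stage = 1,
                    kernel = 3, dropout_rate = 0.01)
  cfg <- train_config(strategy = "sim_only", epochs = 30, batch_size = 2,
                      patch = 16, resample_um = NULL, k_folds = 2)
  fit <- vnet_train(sim_sets = ds$sets, cfg = cfg, spec = spec, seed = 73)
  h <- fit$histories[[1]]
  expect_gt(mean(tail(h$dice, 5)), mean(head(h$dice, 5)))

  # determinism: identical loss curves under one seed
  fit2 <- vnet_train(sim_sets = ds$sets, cfg = cfg, spec = spec, seed = 73)
  expect_identical(fit$histories[[1]]$loss, fit2$histories[[1]]$loss)

  # transfer with zero retraining epochs keeps the sim-only weights
  cfg0 <- train_config(strategy = "transfer", epochs = 0, batch_size = 2,
                       patch = 16, resample_um = NULL, k_folds = 2)
  ft <- vnet_train(sim_sets = ds$sets, real_sets = ds$sets[1:2], cfg = cfg0,
                   spec = spec, seed = 74)
  expect_length(ft$models, 2)
  expect_identical(ft$models[[1]]$params, ft$models[[2]]$params)

  # strategy/data mismatches are config errors
  cfgr <- train_config(strategy = "real_only", epochs = 1, patch = 16,
                       resample_um = NULL, k_folds = 2)
  expect_error(vnet_train(sim_sets = ds$sets, cfg = cfgr, spec = spec),
               "config error")
  expect_error(vnet_train(real_sets = ds$sets,
                          cfg = train_config(strategy = "sim_only",
                                             patch = 16, k_folds = 2,
                                             resample_um = NULL),
                          spec = spec),
               "config error")
})

test_that("flip-symmetric models give flip-equivariant stitched predictions", {
  spec <- vnet_spec(n_stages = 1, channels = 2, convs_per_stage = 1,
                    kernel = 3)
  net <- build_vnet(spec, seed = 10)
  for (nm in names(net$params)) net$params[[nm]][] <- 0
  net$params[["out.b"]] <- 0.3   # constant model is trivially flip-symmetric
  vol <- array(rnorm(16^3), c(16, 16, 16))
  p1 <- sliding_window_predict(net, vol, patch = 8, stride = 4)
  p2 <- sliding_window_predict(net, vol[16:1, , ], patch = 8, stride = 4)
  expect_equal(p1[16:1, , ], p2, tolerance = 1e-12)
})
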