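# Segmenter contracts: architecture arithmetic, deep-supervision targets and
# loss decomposition, training behaviour at desk scale, feature extraction.

test_that("stage widths double and spatial dims halve through the network", {
  cfg <- unet_config(n_stages = 4L, base_channels = 8L, seed = 1L)
  expect_equal(stage_channels(cfg), c(8L, 16L, 32L, 64L))
  m <- build_unet(cfg)
  expect_equal(ncol(m$params$enc$s1$W), 1 * 27)
  expect_equal(nrow(m$params$enc$s1$W), 8)
  expect_equal(nrow(m$params$down$s4$W), 64)

  x <- array(rnorm(32^3), c(32, 32, 32, 1))
  fw <- mlnet3d:::unet_fw(m$params, cfg, x)
  dims <- t(vapply(fw$feats, function(f) dim(f)[1:3], integer(3)))
  expect_equal(dims[, 1], c(32L, 16L, 8L, 4L))
  chans <- vapply(fw$feats, function(f) dim(f)[4], integer(1))
  expect_equal(chans, c(8L, 16L, 32L, 64L))

  m2 <- build_unet(cfg)
  expect_identical(m$params, m2$params)  # seeded initialisation

  small <- array(0, c(4, 4, 4, 1))
  expect_error(mlnet3d:::unet_fw(m$params, cfg, small), "smaller")
  expect_error(unet_config(ds_weights = c(0.5, 0.5, 0.1, 0.1)), NA)  # renormalised
})

# independent trilinear oracle at endpoint-aligned sample positions
trilinear_oracle <- function(f, cx, cy, cz) {
  out <- array(0, c(length(cx), length(cy), length(cz)))
  d <- dim(f)
  for (i in seq_along(cx)) for (j in seq_along(cy)) for (k in seq_along(cz)) {
    p <- c(cx[i], cy[j], cz[k])
    i0 <- pmin(pmax(floor(p), 0), d - 2); w <- p - i0
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      wt <- (if (a) w[1] else 1 - w[1]) * (if (b) w[2] else 1 - w[2]) *
            (if (cc) w[3] else 1 - w[3])
      acc <- acc + wt * f[i0[1] + a + 1, i0[2] + b + 1, i0[3] + cc + 1]
    }
    out[i, j, k] <- acc
  }
  out
}

test_that("downsample_targets follows hand-computed trilinear values", {
  m <- array(0, c(4, 4, 4)); m[1:2, , ] <- 1  # axis-aligned half-filled
  lv <- downsample_targets(m, 2)
  expect_identical(lv[[1]], m)
  co <- (0:1) * 3 / 1  # 2 output points, endpoint aligned on 4 input voxels
  expect_equal(lv[[2]], trilinear_oracle(m, co, co, co), tolerance = 1e-12)

  ones <- array(1, c(6, 6, 6))
  lvo <- downsample_targets(ones, 3)
  for (l in lvo) expect_true(all(abs(l - 1) < 1e-12))

  rnd <- array(round(runif(8^3)), c(8, 8, 8))
  lvr <- downsample_targets(rnd, 4)
  expect_identical(lvr[[1]], rnd)
  for (l in lvr) expect_true(all(l >= 0 & l <= 1))
  expect_equal(dim(lvr[[3]]), c(2, 2, 2))
  expect_error(downsample_targets(rnd, 0), ">= 1")
})

test_that("deep-supervision loss decomposes into weighted per-stage terms", {
  set.seed(2)
  dims <- list(c(8, 8, 8), c(4, 4, 4), c(2, 2, 2))
  preds <- lapply(dims, function(d) array(runif(prod(d)), c(d, 1)))
  targs <- lapply(dims, function(d) array(round(runif(prod(d))), d))
  w <- c(4, 2, 1) / 7
  manual <- sum(vapply(1:3, function(s)
    w[s] * mlnet3d:::seg_stage_loss(as.numeric(preds[[s]]),
                                    as.numeric(targs[[s]])), numeric(1)))
  expect_equal(deep_supervision_loss(preds, targs, w), manual, tolerance = 1e-12)

  # one-hot weights reduce to the single full-resolution stage loss
  w1 <- c(1, 0, 0)
  expect_equal(deep_supervision_loss(preds, targs, w1),
               mlnet3d:::seg_stage_loss(as.numeric(preds[[1]]),
                                        as.numeric(targs[[1]])),
               tolerance = 1e-12)

  # perfect binary prediction sits at the analytic minimum
  perfect <- lapply(targs, function(t) array(t, c(dim(t), 1)))
  expect_lt(deep_supervision_loss(perfect, targs, w), 1e-3)
  expect_gte(deep_supervision_loss(preds, targs, w), 0)

  bad <- preds; bad[[2]] <- array(runif(27), c(3, 3, 3, 1))
  expect_error(deep_supervision_loss(bad, targs, w), "shape mismatch")
})

test_that("training reduces the loss, checkpoints the best Dice, reproduces", {
  fx <- tiny_seg_fit()
  log <- fx$fit$log$epochs
  expect_lt(log$train_loss[nrow(log)], log$train_loss[1])
  expect_equal(fx$fit$log$checkpoint_dice, max(log$val_dice))
  expect_equal(log$val_dice[fx$fit$log$checkpoint_epoch],
               max(log$val_dice))

  cfg2 <- fx$config
  fit2 <- train_segmenter(fx$cohort[1:6], cfg2, epochs = 2L,
                          val_cases = fx$cohort[11:12], lr = 2e-3)
  fit3 <- train_segmenter(fx$cohort[1:6], cfg2, epochs = 2L,
                          val_cases = fx$cohort[11:12], lr = 2e-3)
  expect_identical(fit2$log$epochs, fit3$log$epochs)
  expect_error(train_segmenter(list(), cfg2, val_cases = fx$cohort[1:2]),
               "empty training set")
})

test_that("predict_mask and extract_features obey their contracts", {
  fx <- tiny_seg_fit()
  model <- fx$fit$model
  case <- fx$cohort[[11]]
  pm <- predict_mask(model, case$image)
  expect_true(all(pm$data %in% c(0, 1)))
  expect_equal(dim(pm$data), dim(case$mask$data))

  zero <- volume_image(array(0, c(16, 16, 16, 1)), c(2, 2, 2))
  expect_s3_class(predict_mask(model, zero), "binary_mask")

  py1 <- extract_features(model, case$image)
  py2 <- extract_features(model, case$image)
  expect_identical(py1$features, py2$features)
  expect_equal(py1$factors, c(1L, 2L, 4L, 8L))
  dims <- t(vapply(py1$features, function(f) dim(f)[1:3], integer(3)))
  expect_equal(dims[, 1], c(16L, 8L, 4L, 2L))

  other <- extract_features(model, fx$cohort[[12]]$image)
  expect_false(identical(py1$features, other$features))

  two_ch <- volume_image(array(0, c(16, 16, 16, 2)), c(2, 2, 2))
  one_model_cfg <- model$config
  expect_equal(one_model_cfg$input_channels, 1L)
  # a 2-channel model refuses a 1-channel volume
  cfg2 <- unet_config(base_channels = 4L, input_channels = 2L, seed = 1L)
  m2 <- build_unet(cfg2)
  one_ch <- volume_image(array(0, c(16, 16, 16)), c(2, 2, 2))
  expect_error(predict_mask(m2, one_ch), "channel mismatch")
})

test_that("cross-validation folds partition the cohort with balanced sizes", {
  cohort <- tiny_cohort(n = 9, seed = 20)
  cfg <- unet_config(base_channels = 2L, seed = 3L)
  cv <- crossval_segmentation(cohort, k = 3L, cfg, epochs = 1L, lr = 2e-3)
  expect_setequal(cv$per_case$patient_id,
                  vapply(cohort, function(x) x$patient_id, ""))
  expect_equal(nrow(cv$per_case), 9)  # every case validated exactly once
  sizes <- table(cv$folds)
  expect_lte(diff(range(sizes)), 1)
  expect_length(cv$fold_dice, 3)
  expect_error(crossval_segmentation(cohort, k = 1L, cfg), "k must be")
})
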