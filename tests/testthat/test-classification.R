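# Classifier family: wiring arithmetic, variant algebra, SAM, training
# contracts and score sets.

fake_pyramid <- function(dims = c(16, 16, 16), base = 4L, seed = 1) {
  withr::with_seed(seed, {
    ch <- base * 2L^(0:3)
    f <- lapply(1:4, function(s) {
      d <- pmax(1L, as.integer(dims / 2^(s - 1)))
      array(rnorm(prod(d) * ch[s]), c(d, ch[s]))
    })
    structure(list(features = f, channels = ch, factors = 2L^(0:3)),
              class = "feature_pyramid")
  })
}

test_that("injection wiring: block input channels = backbone width + stage channels", {
  py <- fake_pyramid()
  cfg <- classifier_config("mlnet", input_channels = 1L, base_width = 8L, seed = 2L)
  m <- build_classifier(cfg, py$channels)
  # block-1 conv input channels: stem width 8 + stage-1 features 4
  expect_equal(m$block_in_channels, c(8L + 4L, 8L + 8L, 16L + 16L, 32L + 32L))
  expect_equal(ncol(m$params$blocks$b1$conv1$W), (8 + 4) * 27)

  cfg3 <- classifier_config("stage3", input_channels = 1L, base_width = 8L, seed = 2L)
  m3 <- build_classifier(cfg3, py$channels)
  expect_equal(m3$block_in_channels, c(8L, 8L, 16L + 16L, 32L))  # only block 3 injected

  expect_error(build_classifier(cfg, integer(0)), "channel spec")
})

test_that("plain variant ignores the pyramid entirely", {
  py <- fake_pyramid()
  cfg <- classifier_config("plain_resnet10", input_channels = 1L, seed = 4L)
  m <- build_classifier(cfg)
  x <- array(rnorm(16^3), c(16, 16, 16, 1))
  inj <- mlnet3d:::prepare_injection(py, c(16L, 16L, 16L),
                                     classifier_config("mlnet"))
  expect_identical(mlnet3d:::cls_fw(m, x, NULL)$prob,
                   mlnet3d:::cls_fw(m, x, inj)$prob)
})

test_that("variant algebra: mlnet restricted to stage N equals stageN", {
  py <- fake_pyramid()
  cfgN <- classifier_config("stage2", input_channels = 1L, seed = 6L)
  mN <- build_classifier(cfgN, py$channels)
  cfgM <- classifier_config("mlnet", input_channels = 1L, seed = 6L)
  cfgM$injected_stages <- 2L
  mM <- build_classifier(cfgM, py$channels)
  expect_identical(mN$params, mM$params)
  x <- array(rnorm(16^3), c(16, 16, 16, 1))
  injN <- mlnet3d:::prepare_injection(py, c(16L, 16L, 16L), cfgN)
  injM <- mlnet3d:::prepare_injection(py, c(16L, 16L, 16L), cfgM)
  expect_identical(mlnet3d:::cls_fw(mN, x, injN)$prob,
                   mlnet3d:::cls_fw(mM, x, injM)$prob)
})

test_that("injection changes channels only, never spatial dimensions", {
  py <- fake_pyramid()
  cfg <- classifier_config("mlnet", input_channels = 1L, seed = 2L)
  inj <- mlnet3d:::prepare_injection(py, c(16L, 16L, 16L), cfg)
  # block input resolutions: stem 8^3, blocks at 8,8,4,2
  expect_equal(dim(inj[[1]])[1:3], c(8L, 8L, 8L))
  expect_equal(dim(inj[[2]])[1:3], c(8L, 8L, 8L))
  expect_equal(dim(inj[[3]])[1:3], c(4L, 4L, 4L))
  expect_equal(dim(inj[[4]])[1:3], c(2L, 2L, 2L))
  expect_equal(dim(inj[[2]])[4], py$channels[2])
})

test_that("SAM worked 1-D update and rho = 0 reduction are exact", {
  # L(w) = w^2 at w = 1, rho = 0.5, plain gradient step 0.1:
  # ascend to 1 + 0.5 * 2/2 = 1.5, gradient there 3, update 1 - 0.3 = 0.7
  params <- list(lin = list(W = matrix(1)))
  grad_fn <- function(p) list(loss = p$lin$W[1]^2,
                              grads = list(lin = list(W = matrix(2 * p$lin$W[1]))))
  sgd <- function(p, g) mlnet3d:::par_map2(p, g, function(a, b) a - 0.1 * b)
  out <- sam_update(params, grad_fn, rho = 0.5, base_step = sgd)
  expect_equal(out$params$lin$W[1], 0.7, tolerance = 1e-15)

  out0 <- sam_update(params, grad_fn, rho = 0, base_step = sgd)
  expect_equal(out0$params$lin$W[1], 1 - 0.1 * 2, tolerance = 1e-15)

  # zero gradient falls back to the plain base step
  gz <- function(p) list(loss = 0, grads = list(lin = list(W = matrix(0))))
  outz <- sam_update(params, gz, rho = 0.5, base_step = sgd)
  expect_equal(outz$params$lin$W[1], 1)

  # with rho = 0, SAM + Adam equals a bare Adam step bitwise
  set.seed(8)
  p2 <- list(a = list(W = matrix(rnorm(4), 2), b = rnorm(2)))
  g2 <- list(a = list(W = matrix(rnorm(4), 2), b = rnorm(2)))
  st <- adam_init(p2)
  ref <- adam_step(p2, g2, st, lr = 0.01)$params
  st2 <- adam_init(p2)
  base <- function(pp, gg) { u <- adam_step(pp, gg, st2, lr = 0.01); st2 <<- u$state; u$params }
  out2 <- sam_update(p2, function(p) list(loss = 0, grads = g2), 0, base)
  expect_identical(out2$params, ref)
})

test_that("weighted BCE reduces to plain BCE at weight 1 (hand-computed batch)", {
  probs <- c(0.9, 0.2, 0.6); labels <- c(1, 0, 1)
  manual <- -c(log(0.9), log(0.8), log(0.6))
  got <- vapply(1:3, function(i) mlnet3d:::wbce(probs[i], labels[i], 1), 1)
  expect_equal(got, manual, tolerance = 1e-9)
  # and the positive-class weight scales only positive-label terms
  got2 <- vapply(1:3, function(i) mlnet3d:::wbce(probs[i], labels[i], 2), 1)
  expect_equal(got2, manual * c(2, 1, 2), tolerance = 1e-9)
})

test_that("classifier training is seeded, early-stops, and errors on one class", {
  fx <- cls_fixture()
  cfg <- classifier_config("stage1", input_channels = 1L, base_width = 4L,
                           learning_rate = 1e-3, max_epochs = 3L, seed = 11L)
  fit1 <- train_classifier(fx$cohort[1:8], fx$cohort[9:12], fx$pyramids, cfg,
                           target = "emvi")
  fit2 <- train_classifier(fx$cohort[1:8], fx$cohort[9:12], fx$pyramids, cfg,
                           target = "emvi")
  expect_identical(fit1$log$epochs, fit2$log$epochs)
  expect_identical(fit1$model$params, fit2$model$params)
  log <- fit1$log
  expect_lte(log$stop_epoch, log$checkpoint_epoch + cfg$patience)
  expect_equal(log$epochs$val_loss[log$checkpoint_epoch], log$best_val_loss)

  one_class <- Filter(function(cs) cs$emvi_label == 1L, fx$cohort)
  expect_error(train_classifier(one_class, fx$cohort[1:2], fx$pyramids, cfg,
                                target = "emvi"),
               "single-class")
  expect_error(train_classifier(list(), fx$cohort[1:2], fx$pyramids, cfg),
               "nonempty")

  scores <- predict_scores(fit1$model, fx$cohort[9:12], fx$pyramids, "emvi")
  expect_true(all(scores$score >= 0 & scores$score <= 1))
  scores2 <- predict_scores(fit1$model, fx$cohort[9:12], fx$pyramids, "emvi")
  expect_identical(scores$score, scores2$score)
  expect_error(predict_scores(fit1$model, fx$cohort[9:12], NULL, "emvi"),
               "pyramid")
})

test_that("run_ablation emits one score set per variant on shared splits", {
  fx <- cls_fixture()
  splits <- list(train = fx$cohort[1:8], internal = fx$cohort[9:11],
                 external = fx$cohort[12:14])
  cfg <- classifier_config(input_channels = 1L, base_width = 2L,
                           learning_rate = 1e-3, max_epochs = 1L, seed = 21L)
  abl <- run_ablation(splits, fx$pyramids, cfg, target = "cr",
                      variants = c("plain_resnet10", "stage4"))
  expect_named(abl, c("plain_resnet10", "stage4"))
  ids <- vapply(splits$external, function(x) x$patient_id, "")
  for (v in names(abl)) {
    expect_s3_class(abl[[v]]$external, "score_set")
    expect_identical(abl[[v]]$external$patient_id, ids)
  }
})
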