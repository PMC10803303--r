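# MLNet and its ablation family.
#
# Backbone: a 3D ResNet10-style network — stem conv (stride 2), four
# two-conv blocks with widths doubling per block (stride-2 first conv in
# blocks 2-4), global average pooling and a single logistic unit; 10 weight
# layers in total. The plain variant keeps identity/projection shortcuts.
# The injecting variants (mlnet, stage1..stage4) REMOVE the shortcut and
# instead concatenate the segmenter's stage-s feature map, trilinearly
# resampled to the block-s input resolution, to that block's input (stage 1,
# the finest, feeds the earliest block). The original image is always an
# input through the stem.

CLS_VARIANTS <- c("plain_resnet10", "mlnet", "stage1", "stage2", "stage3", "stage4")

#' Classifier configuration
#'
#' @param variant one of `"plain_resnet10"`, `"mlnet"`, `"stage1"` ..
#'   `"stage4"`; determines the injected stages (mlnet: all four; stageN:
#'   \{N\}; plain: none).
#' @param input_channels image channels fed to the stem (1 or 2).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size gradient-accumulation batch size (default 4).
#' @param patience early-stopping patience in epochs (default 10).
#' @param class_weight positive-class weight of the binary cross-entropy, or
#'   `NULL` to use the training split's negative/positive count ratio.
#' @param sam_rho SAM perturbation radius (default 0.05; 0 disables SAM).
#' @param base_width stem/block-1 channel width (doubling per block).
#' @param max_epochs epoch cap (default 100).
#' @param augment_flips random axis flips of image and features during
#'   training (label-invariant; standard small-cohort regularisation).
#' @param weight_decay decoupled weight decay applied after each step.
#' @param seed integer seed.
#' @return a `classifier_config` object.
#' @export
classifier_config <- function(variant = "mlnet", input_channels = 1L,
                              learning_rate = 1e-4, batch_size = 4L,
                              patience = 10L, class_weight = NULL,
                              sam_rho = 0.05, base_width = 8L,
                              max_epochs = 100L, augment_flips = TRUE,
                              weight_decay = 1e-4, seed = 1L) {
  variant <- match.arg(variant, CLS_VARIANTS)
  injected <- switch(variant,
                     plain_resnet10 = integer(0),
                     mlnet = 1:4,
                     stage1 = 1L, stage2 = 2L, stage3 = 3L, stage4 = 4L)
  stopifnot(learning_rate > 0, patience >= 1, sam_rho >= 0, batch_size >= 1)
  structure(list(variant = variant, injected_stages = injected,
                 input_channels = as.integer(input_channels),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 patience = as.integer(patience), class_weight = class_weight,
                 sam_rho = sam_rho, base_width = as.integer(base_width),
                 max_epochs = as.integer(max_epochs),
                 augment_flips = isTRUE(augment_flips),
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Build a classifier
#'
#' @param config a [classifier_config].
#' @param pyramid_channels integer vector of feature-pyramid channel counts
#'   per stage; required entries for every injected stage.
#' @return a `cls_model` (config, parameters, channel bookkeeping).
#' @export
build_classifier <- function(config, pyramid_channels = integer(0)) {
  stopifnot(inherits(config, "classifier_config"))
  inj <- config$injected_stages
  if (length(inj) > 0 && (length(pyramid_channels) < max(inj) ||
                          any(is.na(pyramid_channels[inj]))))
    stop("injected stage without a pyramid channel spec")
  w <- config$base_width * 2L^(0:3)
  plain <- config$variant == "plain_resnet10"
  with_seed(config$seed, {
    p <- list(stem = conv_param(config$input_channels, w[1]),
              n_stem = inorm_param(w[1]), blocks = list())
    cin <- w[1]
    block_in <- integer(4)
    for (s in 1:4) {
      extra <- if (s %in% inj) pyramid_channels[s] else 0L
      block_in[s] <- cin + extra
      bl <- list(conv1 = conv_param(cin + extra, w[s]), n1 = inorm_param(w[s]),
                 conv2 = conv_param(w[s], w[s]), n2 = inorm_param(w[s]))
      if (plain && (cin + extra != w[s] || s > 1))
        bl$proj <- conv_param(cin + extra, w[s], k = 1L)
      p$blocks[[paste0("b", s)]] <- bl
      cin <- w[s]
    }
    p$fc <- dense_param(2L * w[4], 1L)  # head reads GAP (+) GMP per channel
    structure(list(config = config, params = p, widths = w,
                   block_in_channels = block_in,
                   pyramid_channels = pyramid_channels),
              class = "cls_model")
  })
}

# Resample the injected stages of a pyramid onto the classifier's block
# input resolutions for a given image size, standardising each channel per
# case (decoder activations vary in scale across stages; standardisation
# keeps the four concatenation sites equally conditioned). Returns a list
# indexed by stage.
prepare_injection <- function(pyramid, input_dims, config) {
  inj <- config$injected_stages
  if (length(inj) == 0) return(NULL)
  if (is.null(pyramid)) stop("missing feature pyramid for injecting variant ",
                             config$variant)
  stem_dims <- as.integer(ceiling(input_dims / 2))
  block_dims <- list(stem_dims, stem_dims,
                     as.integer(ceiling(stem_dims / 2)),
                     as.integer(ceiling(stem_dims / 4)))
  out <- vector("list", 4)
  has_prob <- TRUE  # extract_features appends the stage probability last
  for (s in inj) {
    f <- feat_resize_fw(pyramid$features[[s]], block_dims[[s]])$y
    d <- dim(f)
    m <- matrix(f, prod(d[1:3]), d[4])
    # standardise the activation channels; the final channel is the stage's
    # predicted probability and keeps its [0, 1] calibration
    std_cols <- if (has_prob && d[4] > 1) seq_len(d[4] - 1L) else seq_len(d[4])
    mu <- colMeans(m[, std_cols, drop = FALSE])
    sdv <- pmax(apply(m[, std_cols, drop = FALSE], 2, sd), 1e-6)
    m[, std_cols] <- sweep(sweep(m[, std_cols, drop = FALSE], 2, mu), 2, sdv, `/`)
    out[[s]] <- array(m, d)
  }
  structure(out, class = "prepared_injection", input_dims = input_dims)
}

cls_fw <- function(model, x, injection) {
  cfg <- model$config
  if (dim(x)[4] != cfg$input_channels)
    stop("channel mismatch between input and classifier config")
  p <- model$params
  plain <- cfg$variant == "plain_resnet10"
  cache <- list()
  cv <- conv_fw(p$stem, x, stride = 2L)
  no <- inorm_fw(p$n_stem, cv$y)
  rl <- relu_fw(no$y)
  cache$stem <- list(conv = cv$cache, norm = no$cache, relu = rl$cache)
  h <- rl$y
  for (s in 1:4) {
    key <- paste0("b", s)
    bl <- p$blocks[[key]]
    st <- list()
    hin <- h
    if (s %in% cfg$injected_stages) {
      f <- injection[[s]]
      if (is.null(f)) stop("missing prepared features for stage ", s)
      cc <- concat_fw(h, f)
      st$cat <- cc$cache
      hin <- cc$y
    }
    stride <- if (s == 1) 1L else 2L
    c1 <- conv_fw(bl$conv1, hin, stride = stride)
    n1 <- inorm_fw(bl$n1, c1$y)
    r1 <- relu_fw(n1$y)
    c2 <- conv_fw(bl$conv2, r1$y)
    n2 <- inorm_fw(bl$n2, c2$y)
    st <- c(st, list(conv1 = c1$cache, n1 = n1$cache, r1 = r1$cache,
                     conv2 = c2$cache, n2 = n2$cache, stride = stride))
    pre <- n2$y
    if (plain) {
      if (!is.null(bl$proj)) {
        pj <- conv_fw(bl$proj, hin, stride = stride, pad = 0L)
        st$proj <- pj$cache
        pre <- pre + pj$y
      } else pre <- pre + hin
    }
    r2 <- relu_fw(pre)
    st$r2 <- r2$cache
    cache$blocks[[key]] <- st
    h <- r2$y
    cache$block_outs[[key]] <- h
  }
  gp <- gap_fw(h)
  gm <- gmp_fw(h)
  fc <- dense_fw(p$fc, c(gp$y, gm$y))
  cache$gap <- gp$cache
  cache$gmp <- gm$cache
  cache$fc <- fc$cache
  list(logit = fc$y, prob = sigmoid(fc$y), cache = cache,
       block_out = h)
}

cls_bw <- function(model, fw, dlogit, stop_at_block = NULL) {
  p <- model$params
  cfg <- model$config
  plain <- cfg$variant == "plain_resnet10"
  g <- par_zero(p)
  fb <- dense_bw(p$fc, fw$cache$fc, dlogit)
  g$fc$W <- fb$dW; g$fc$b <- fb$db
  C <- length(fb$dx) / 2
  dh <- gap_bw(fw$cache$gap, fb$dx[seq_len(C)]) +
        gmp_bw(fw$cache$gmp, fb$dx[C + seq_len(C)])
  for (s in 4:1) {
    if (!is.null(stop_at_block) && s == stop_at_block)
      return(list(dact = dh))
    key <- paste0("b", s)
    bl <- p$blocks[[key]]
    st <- fw$cache$blocks[[key]]
    d <- relu_bw(st$r2, dh)
    dskip <- NULL
    if (plain) dskip <- d
    nb <- inorm_bw(bl$n2, st$n2, d)
    g$blocks[[key]]$n2$gamma <- nb$dgamma; g$blocks[[key]]$n2$beta <- nb$dbeta
    cb <- conv_bw(bl$conv2, st$conv2, nb$dx)
    g$blocks[[key]]$conv2$W <- cb$dW; g$blocks[[key]]$conv2$b <- cb$db
    d <- relu_bw(st$r1, cb$dx)
    nb <- inorm_bw(bl$n1, st$n1, d)
    g$blocks[[key]]$n1$gamma <- nb$dgamma; g$blocks[[key]]$n1$beta <- nb$dbeta
    cb <- conv_bw(bl$conv1, st$conv1, nb$dx)
    g$blocks[[key]]$conv1$W <- cb$dW; g$blocks[[key]]$conv1$b <- cb$db
    din <- cb$dx
    if (plain) {
      if (!is.null(bl$proj)) {
        pb <- conv_bw(bl$proj, st$proj, dskip)
        g$blocks[[key]]$proj$W <- pb$dW; g$blocks[[key]]$proj$b <- pb$db
        din <- din + pb$dx
      } else din <- din + dskip
    }
    if (!is.null(st$cat)) din <- concat_bw(st$cat, din)$da  # drop pyramid grad
    dh <- din
  }
  d <- relu_bw(fw$cache$stem$relu, dh)
  nb <- inorm_bw(p$n_stem, fw$cache$stem$norm, d)
  g$n_stem$gamma <- nb$dgamma; g$n_stem$beta <- nb$dbeta
  cb <- conv_bw(p$stem, fw$cache$stem$conv, nb$dx)
  g$stem$W <- cb$dW; g$stem$b <- cb$db
  g
}

# flip a 4D feature array along the flagged spatial axes
flip4d <- function(a, fl) {
  d <- dim(a)
  a[if (fl[1]) d[1]:1 else 1:d[1],
    if (fl[2]) d[2]:1 else 1:d[2],
    if (fl[3]) d[3]:1 else 1:d[3], , drop = FALSE]
}

flip_injection <- function(inj, fl) {
  if (is.null(inj)) return(NULL)
  out <- inj
  for (s in seq_along(inj)) if (!is.null(inj[[s]])) out[[s]] <- flip4d(inj[[s]], fl)
  out
}

# weighted binary cross-entropy and its logit gradient
wbce <- function(prob, label, w_pos) {
  -(w_pos * label * log(prob + 1e-12) + (1 - label) * log(1 - prob + 1e-12))
}
wbce_grad_logit <- function(prob, label, w_pos) {
  w_pos * label * (prob - 1) + (1 - label) * prob
}

#' Train a classifier with SAM-wrapped Adam and early stopping
#'
#' Class-weighted binary cross-entropy (positive-class weight defaulting to
#' the training split's negative/positive ratio), Adam base steps wrapped in
#' the two-step SAM procedure, stopping when the internal-validation loss
#' has not improved for `patience` epochs, and returning the
#' best-validation-loss checkpoint.
#'
#' @param train_cases,internal_val_cases nonempty `case_record` lists.
#' @param pyramids named list (by patient id) of `feature_pyramid`s or
#'   prepared injections; may be `NULL` for the plain variant.
#' @param config a [classifier_config].
#' @param target `"emvi"` or `"cr"`.
#' @return list with `model` (best checkpoint) and `log` (per-epoch losses,
#'   `stop_epoch`, `checkpoint_epoch`).
#' @export
train_classifier <- function(train_cases, internal_val_cases, pyramids, config,
                             target = c("emvi", "cr")) {
  target <- match.arg(target)
  if (length(train_cases) == 0L || length(internal_val_cases) == 0L)
    stop("training and internal validation sets must be nonempty")
  lab_of <- function(cs) if (target == "emvi") cs$emvi_label else cs$cr_label
  y_tr <- vapply(train_cases, lab_of, 1L)
  if (length(unique(y_tr)) < 2L)
    stop("single-class training set: class weight undefined")
  w_pos <- if (is.null(config$class_weight)) sum(y_tr == 0) / sum(y_tr == 1)
           else config$class_weight
  need_inj <- length(config$injected_stages) > 0
  prep <- function(cases) lapply(cases, function(cs) {
    x <- prep_input(cs$image, config$input_channels)
    inj <- NULL
    if (need_inj) {
      py <- pyramids[[cs$patient_id]]
      if (is.null(py)) stop("missing pyramid for case ", cs$patient_id)
      inj <- if (inherits(py, "prepared_injection")) py
             else prepare_injection(py, dim(x)[1:3], config)
    }
    list(x = x, inj = inj, y = lab_of(cs))
  })
  tr <- prep(train_cases)
  va <- prep(internal_val_cases)
  pch <- if (need_inj) {
    py1 <- pyramids[[train_cases[[1]]$patient_id]]
    if (inherits(py1, "prepared_injection"))
      vapply(seq_len(4), function(s) if (is.null(py1[[s]])) NA_integer_
             else dim(py1[[s]])[4], 1L)
    else py1$channels
  } else integer(0)
  model <- build_classifier(config, pch)
  with_seed(config$seed + 7L, {
    params <- model$params
    st <- adam_init(params)
    base_step <- function(pp, gg) {
      upd <- adam_step(pp, gg, st, lr = config$learning_rate)
      st <<- upd$state
      upd$params
    }
    batch_grad_fn <- function(idx, flips) function(pp) {
      m2 <- model; m2$params <- pp
      loss <- 0; gacc <- NULL
      for (b in seq_along(idx)) {
        j <- idx[b]
        fl <- flips[[b]]
        xj <- if (any(fl)) flip4d(tr[[j]]$x, fl) else tr[[j]]$x
        ij <- if (any(fl)) flip_injection(tr[[j]]$inj, fl) else tr[[j]]$inj
        fw <- cls_fw(m2, xj, ij)
        loss <- loss + wbce(fw$prob, tr[[j]]$y, w_pos)
        gi <- cls_bw(m2, fw, wbce_grad_logit(fw$prob, tr[[j]]$y, w_pos))
        gacc <- if (is.null(gacc)) gi else par_map2(gacc, gi, `+`)
      }
      list(loss = loss / length(idx),
           grads = par_map(gacc, function(x) x / length(idx)))
    }
    val_loss <- function(pp) {
      m2 <- model; m2$params <- pp
      mean(vapply(va, function(cs)
        wbce(cls_fw(m2, cs$x, cs$inj)$prob, cs$y, w_pos), numeric(1)))
    }
    log <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
    best <- list(loss = Inf, params = params, epoch = 0L)
    stop_epoch <- config$max_epochs
    for (ep in seq_len(config$max_epochs)) {
      ord <- sample(length(tr))
      ep_losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        idx <- ord[i:min(i + config$batch_size - 1L, length(ord))]
        flips <- lapply(idx, function(.)
          if (config$augment_flips) runif(3) < 0.5 else c(FALSE, FALSE, FALSE))
        res <- sam_update(params, batch_grad_fn(idx, flips), config$sam_rho,
                          base_step)
        params <- res$params
        if (config$weight_decay > 0)
          params <- par_map(params, function(x) x * (1 - config$weight_decay))
        ep_losses <- c(ep_losses, res$loss)
        i <- i + config$batch_size
      }
      vl <- val_loss(params)
      log <- rbind(log, data.frame(epoch = ep, train_loss = mean(ep_losses),
                                   val_loss = vl))
      if (vl < best$loss - 1e-9) best <- list(loss = vl, params = params, epoch = ep)
      if (ep - best$epoch >= config$patience) { stop_epoch <- ep; break }
    }
    model$params <- best$params
    list(model = model,
         log = structure(list(epochs = log, stop_epoch = stop_epoch,
                              checkpoint_epoch = best$epoch,
                              best_val_loss = best$loss, class_weight = w_pos),
                         class = "cls_train_log"))
  })
}

#' Score cases with a trained classifier
#'
#' One logistic probability per case; deterministic in inference mode.
#'
#' @param model a trained `cls_model`.
#' @param cases list of `case_record` objects.
#' @param pyramids named list of pyramids/prepared injections (required for
#'   injecting variants).
#' @param target `"emvi"` or `"cr"` (labels copied into the score set).
#' @return a [score_set].
#' @export
predict_scores <- function(model, cases, pyramids = NULL,
                           target = c("emvi", "cr")) {
  target <- match.arg(target)
  cfg <- model$config
  lab_of <- function(cs) if (target == "emvi") cs$emvi_label else cs$cr_label
  probs <- vapply(cases, function(cs) {
    x <- prep_input(cs$image, cfg$input_channels)
    inj <- NULL
    if (length(cfg$injected_stages) > 0) {
      py <- pyramids[[cs$patient_id]]
      if (is.null(py)) stop("missing pyramid for case ", cs$patient_id)
      inj <- if (inherits(py, "prepared_injection")) py
             else prepare_injection(py, dim(x)[1:3], cfg)
    }
    cls_fw(model, x, inj)$prob
  }, numeric(1))
  score_set(vapply(cases, function(cs) cs$patient_id, ""),
            pmin(pmax(probs, 0), 1),
            vapply(cases, lab_of, 1L))
}

#' Train and score every ablation variant on shared splits
#'
#' Trains plain_resnet10, mlnet and stage1..stage4 on identical splits and
#' seeds and scores each on the internal-validation and external lists.
#'
#' @param splits list with `train`, `internal`, `external` case lists.
#' @param pyramids named list of pyramids/prepared injections covering all
#'   cases.
#' @param base_config a [classifier_config]; its variant field is replaced
#'   per run.
#' @param target `"emvi"` or `"cr"`.
#' @param variants variants to run (default all six).
#' @return named list per variant: `internal` and `external` [score_set]s
#'   plus the training `log`.
#' @export
run_ablation <- function(splits, pyramids, base_config,
                         target = c("emvi", "cr"), variants = CLS_VARIANTS,
                         keep_models = FALSE) {
  target <- match.arg(target)
  out <- list()
  for (v in variants) {
    cfg <- base_config
    cfg$variant <- v
    cfg$injected_stages <- switch(v, plain_resnet10 = integer(0), mlnet = 1:4,
                                  stage1 = 1L, stage2 = 2L, stage3 = 3L,
                                  stage4 = 4L)
    fit <- train_classifier(splits$train, splits$internal, pyramids, cfg, target)
    out[[v]] <- list(
      internal = predict_scores(fit$model, splits$internal, pyramids, target),
      external = predict_scores(fit$model, splits$external, pyramids, target),
      log = fit$log)
    if (keep_models) out[[v]]$model <- fit$model
  }
  out
}
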