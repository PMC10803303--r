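# Miniature deep-supervised 3D U-Net.
#
# Encoder: one 3x3x3 conv per stage, stride-2 convs between stages, channel
# width doubling per stage. Decoder: trilinear upsampling, concatenation
# with the encoder skip, one conv per stage. Every decoder stage (the
# bottleneck counts as the coarsest) carries a 1x1x1 auxiliary head whose
# sigmoid output is supervised against the trilinearly downsampled ground
# truth; the training loss is the ds-weighted sum of soft-Dice +
# cross-entropy over the stages. The per-stage pre-head activations form
# the feature pyramid injected into the classifier.

#' Configuration of the miniature segmenter
#'
#' @param n_stages number of resolution stages S (>= 2, default 4).
#' @param base_channels channels at the finest stage (doubling per stage).
#' @param input_channels 1 (DWI) or 2 (DWI + T2W).
#' @param ds_weights deep-supervision weights, one per stage, summing to 1;
#'   default proportional to `2^(1-s)` (finest stage weighted most).
#' @param seed integer seed for parameter initialisation.
#' @return a `unet_config` object.
#' @export
unet_config <- function(n_stages = 4L, base_channels = 8L, input_channels = 1L,
                        ds_weights = NULL, seed = 1L) {
  stopifnot(n_stages >= 2L, base_channels >= 2L, input_channels %in% c(1L, 2L))
  if (is.null(ds_weights)) ds_weights <- 2^(1 - seq_len(n_stages))
  ds_weights <- ds_weights / sum(ds_weights)
  stopifnot(length(ds_weights) == n_stages, all(ds_weights >= 0),
            abs(sum(ds_weights) - 1) < 1e-9)
  structure(list(n_stages = as.integer(n_stages),
                 base_channels = as.integer(base_channels),
                 input_channels = as.integer(input_channels),
                 ds_weights = ds_weights, seed = as.integer(seed)),
            class = "unet_config")
}

#' Stage channel widths of a segmenter configuration
#' @param config a [unet_config].
#' @return integer vector, `base_channels * 2^(s-1)` per stage.
#' @export
stage_channels <- function(config) config$base_channels * 2L^(seq_len(config$n_stages) - 1L)

#' Build a deep-supervised 3D U-Net
#'
#' Parameter initialisation is He-scaled and fully determined by the config
#' seed.
#'
#' @param config a [unet_config].
#' @return a `unet_model` (config plus parameter list).
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "unet_config"))
  S <- config$n_stages
  ch <- stage_channels(config)
  with_seed(config$seed, {
    p <- list(enc = list(), down = list(), dec = list(), head = list(),
              n_enc = list(), n_down = list(), n_dec = list())
    p$enc[["s1"]] <- conv_param(config$input_channels, ch[1])
    p$n_enc[["s1"]] <- inorm_param(ch[1])
    for (s in 2:S) {
      p$down[[paste0("s", s)]] <- conv_param(ch[s - 1], ch[s])
      p$n_down[[paste0("s", s)]] <- inorm_param(ch[s])
      p$enc[[paste0("s", s)]] <- conv_param(ch[s], ch[s])
      p$n_enc[[paste0("s", s)]] <- inorm_param(ch[s])
    }
    for (s in seq_len(S - 1)) {
      p$dec[[paste0("s", s)]] <- conv_param(ch[s + 1] + ch[s], ch[s])
      p$n_dec[[paste0("s", s)]] <- inorm_param(ch[s])
    }
    for (s in seq_len(S))
      p$head[[paste0("s", s)]] <- conv_param(ch[s], 1L, k = 1L)
    structure(list(config = config, params = p), class = "unet_model")
  })
}

# per-volume z-score normalisation, channel-wise; the fixed preprocessing
prep_input <- function(volume, input_channels) {
  stopifnot(inherits(volume, "volume_image"))
  nc <- dim(volume$data)[4]
  if (nc < input_channels)
    stop(sprintf("channel mismatch: model expects %d channels, volume has %d",
                 input_channels, nc))
  x <- volume$data[, , , seq_len(input_channels), drop = FALSE]
  for (c in seq_len(input_channels)) {
    v <- x[, , , c]
    s <- sd(v)
    x[, , , c] <- if (s > 0) (v - mean(v)) / s else v - mean(v)
  }
  x
}

# Full forward pass; returns stage logits, features and the backprop cache.
unet_fw <- function(params, config, x) {
  S <- config$n_stages
  if (min(dim(x)[1:3]) < 2^(S - 1))
    stop(sprintf("input volume smaller than %d voxels per axis", 2^(S - 1)))
  if (dim(x)[4] != config$input_channels)
    stop("channel mismatch between input and model config")
  cache <- list(enc = list(), down = list(), dec = list(), head = list())
  enc_out <- vector("list", S)
  h <- x
  for (s in seq_len(S)) {
    key <- paste0("s", s)
    st <- list()
    if (s > 1) {
      cv <- conv_fw(params$down[[key]], h, stride = 2L)
      no <- inorm_fw(params$n_down[[key]], cv$y)
      rl <- relu_fw(no$y)
      st$down <- list(conv = cv$cache, norm = no$cache, relu = rl$cache)
      h <- rl$y
    }
    cv <- conv_fw(params$enc[[key]], h)
    no <- inorm_fw(params$n_enc[[key]], cv$y)
    rl <- relu_fw(no$y)
    st$enc <- list(conv = cv$cache, norm = no$cache, relu = rl$cache)
    h <- rl$y
    enc_out[[s]] <- h
    cache$enc[[key]] <- st
  }
  feats <- vector("list", S)
  feats[[S]] <- enc_out[[S]]
  h <- enc_out[[S]]
  for (s in rev(seq_len(S - 1))) {
    key <- paste0("s", s)
    up <- feat_resize_fw(h, dim(enc_out[[s]])[1:3])
    cc <- concat_fw(up$y, enc_out[[s]])
    cv <- conv_fw(params$dec[[key]], cc$y)
    no <- inorm_fw(params$n_dec[[key]], cv$y)
    rl <- relu_fw(no$y)
    cache$dec[[key]] <- list(up = up$cache, cat = cc$cache, conv = cv$cache,
                             norm = no$cache, relu = rl$cache)
    h <- rl$y
    feats[[s]] <- h
  }
  logits <- vector("list", S)
  for (s in seq_len(S)) {
    key <- paste0("s", s)
    hd <- conv_fw(params$head[[key]], feats[[s]], pad = 0L)
    cache$head[[key]] <- hd$cache
    logits[[s]] <- hd$y
  }
  list(logits = logits, feats = feats, cache = cache)
}

# Backward pass from per-stage logit gradients; returns the gradient list.
unet_bw <- function(params, config, fw, dlogits) {
  S <- config$n_stages
  g <- par_zero(params)
  dfeat <- vector("list", S)
  for (s in seq_len(S)) {
    key <- paste0("s", s)
    bw <- conv_bw(params$head[[key]], fw$cache$head[[key]], dlogits[[s]])
    g$head[[key]]$W <- bw$dW; g$head[[key]]$b <- bw$db
    dfeat[[s]] <- bw$dx
  }
  denc <- vector("list", S)
  dh <- NULL  # gradient flowing into decoder stage s+1 output
  for (s in seq_len(S - 1)) {
    key <- paste0("s", s)
    d <- dfeat[[s]]
    if (!is.null(dh)) d <- d + dh
    st <- fw$cache$dec[[key]]
    d <- relu_bw(st$relu, d)
    nb <- inorm_bw(params$n_dec[[key]], st$norm, d)
    g$n_dec[[key]]$gamma <- nb$dgamma; g$n_dec[[key]]$beta <- nb$dbeta
    cb <- conv_bw(params$dec[[key]], st$conv, nb$dx)
    g$dec[[key]]$W <- cb$dW; g$dec[[key]]$b <- cb$db
    sp <- concat_bw(st$cat, cb$dx)
    denc[[s]] <- sp$db
    dh <- feat_resize_bw(st$up, sp$da)
  }
  dbott <- dfeat[[S]]
  if (!is.null(dh)) dbott <- dbott + dh
  denc[[S]] <- dbott
  # encoder, coarsest to finest
  dnext <- NULL
  for (s in rev(seq_len(S))) {
    key <- paste0("s", s)
    d <- denc[[s]]
    if (!is.null(dnext)) d <- d + dnext
    st <- fw$cache$enc[[key]]
    d <- relu_bw(st$enc$relu, d)
    nb <- inorm_bw(params$n_enc[[key]], st$enc$norm, d)
    g$n_enc[[key]]$gamma <- nb$dgamma; g$n_enc[[key]]$beta <- nb$dbeta
    cb <- conv_bw(params$enc[[key]], st$enc$conv, nb$dx)
    g$enc[[key]]$W <- cb$dW; g$enc[[key]]$b <- cb$db
    d <- cb$dx
    if (s > 1) {
      d <- relu_bw(st$down$relu, d)
      nb <- inorm_bw(params$n_down[[key]], st$down$norm, d)
      g$n_down[[key]]$gamma <- nb$dgamma; g$n_down[[key]]$beta <- nb$dbeta
      cb <- conv_bw(params$down[[key]], st$down$conv, nb$dx)
      g$down[[key]]$W <- cb$dW; g$down[[key]]$b <- cb$db
      dnext <- cb$dx
    } else dnext <- NULL
  }
  g
}

#' Downsample a ground-truth mask for deep supervision
#'
#' Level s is the mask trilinearly interpolated at scale `2^(1-s)` (the
#' network's per-stage halving schedule, `n -> ceiling(n/2)` per level);
#' level 1 is the original mask, all values stay in \[0, 1\].
#'
#' @param mask a [binary_mask] (or 0/1 3D array).
#' @param S number of levels (>= 1).
#' @return list of S arrays of decreasing resolution.
#' @export
downsample_targets <- function(mask, S) {
  if (S < 1) stop("S must be >= 1")
  m <- mask_data(mask)
  out <- vector("list", S)
  out[[1]] <- m
  dims <- dim(m)
  cur <- m
  if (S > 1) for (s in 2:S) {
    nd <- pmax(1L, as.integer(ceiling(dims / 2)))
    cur <- resize_field(cur, dims, nd)
    cur <- pmin(pmax(cur, 0), 1)
    out[[s]] <- cur
    dims <- nd
  }
  out
}

# soft-Dice + voxel cross-entropy at one stage, on probabilities
seg_stage_loss <- function(p, t, eps = 1e-5) {
  sd_loss <- 1 - (2 * sum(p * t) + eps) / (sum(p) + sum(t) + eps)
  ce <- -mean(t * log(p + 1e-7) + (1 - t) * log(1 - p + 1e-7))
  sd_loss + ce
}

#' Deep-supervision segmentation loss
#'
#' The weighted combination over stages of the per-stage soft-Dice +
#' cross-entropy loss between a predicted probability map and the
#' downsampled soft target.
#'
#' @param preds list of per-stage predicted probability arrays.
#' @param targets list of per-stage soft targets (from [downsample_targets]).
#' @param w deep-supervision weights (nonnegative, summing to 1).
#' @return scalar loss (nonnegative up to the Dice smoothing epsilon).
#' @export
deep_supervision_loss <- function(preds, targets, w) {
  stopifnot(length(preds) == length(targets), length(w) == length(preds))
  for (s in seq_along(preds))
    if (!identical(dim(preds[[s]])[1:3], dim(targets[[s]])[1:3]))
      stop("shape mismatch between prediction and target at stage ", s)
  sum(vapply(seq_along(preds), function(s)
    w[s] * seg_stage_loss(as.numeric(preds[[s]]), as.numeric(targets[[s]])),
    numeric(1)))
}

# gradient of the weighted stage losses with respect to the stage logits
seg_loss_grad <- function(logits, targets, w, eps = 1e-5) {
  lapply(seq_along(logits), function(s) {
    z <- logits[[s]]
    t <- as.numeric(targets[[s]])
    p <- sigmoid(as.numeric(z))
    n <- length(p)
    A <- 2 * sum(p * t) + eps
    B <- sum(p) + sum(t) + eps
    dsd_dp <- -(2 * t * B - A) / B^2
    dz <- w[s] * (dsd_dp * p * (1 - p) + (p - t) / n)
    array(dz, dim(z))
  })
}

#' Train the segmenter
#'
#' Adam on the deep-supervision loss, case-by-case with gradient
#' accumulation over mini-batches; the checkpoint kept is the epoch with the
#' best (highest) validation Dice. Fully reproducible under the config seed.
#'
#' @param cases training `case_record` list.
#' @param config a [unet_config].
#' @param epochs number of epochs.
#' @param val_cases held-out cases used for Dice checkpointing.
#' @param lr Adam learning rate.
#' @param batch_size gradient-accumulation batch size.
#' @return list with `model` (best checkpoint) and `log` (per-epoch
#'   `train_loss`, `val_dice`, and `checkpoint_epoch`).
#' @export
train_segmenter <- function(cases, config, epochs = 15L, val_cases,
                            lr = 1e-3, batch_size = 2L) {
  if (length(cases) == 0L) stop("empty training set")
  if (missing(val_cases) || length(val_cases) == 0L) stop("empty validation set")
  model <- build_unet(config)
  xs <- lapply(cases, function(cs) prep_input(cs$image, config$input_channels))
  ts <- lapply(cases, function(cs) downsample_targets(cs$mask, config$n_stages))
  with_seed(config$seed + 1L, {
    params <- model$params
    st <- adam_init(params)
    log <- data.frame(epoch = integer(), train_loss = numeric(), val_dice = numeric())
    best <- list(dice = -Inf, params = params, epoch = 0L)
    for (ep in seq_len(epochs)) {
      ord <- sample(length(cases))
      losses <- numeric(0)
      i <- 1L
      while (i <= length(ord)) {
        idx <- ord[i:min(i + batch_size - 1L, length(ord))]
        gacc <- NULL
        for (j in idx) {
          fw <- unet_fw(params, config, xs[[j]])
          preds <- lapply(fw$logits, function(z) array(sigmoid(z), dim(z)))
          losses <- c(losses, deep_supervision_loss(preds, ts[[j]], config$ds_weights))
          dz <- seg_loss_grad(fw$logits, ts[[j]], config$ds_weights)
          gi <- unet_bw(params, config, fw, dz)
          gacc <- if (is.null(gacc)) gi else par_map2(gacc, gi, `+`)
        }
        gacc <- par_map(gacc, function(x) x / length(idx))
        upd <- adam_step(params, gacc, st, lr = lr)
        params <- upd$params; st <- upd$state
        i <- i + batch_size
      }
      model$params <- params
      vd <- mean(vapply(val_cases, function(cs)
        dice(predict_mask(model, cs$image), cs$mask), numeric(1)))
      log <- rbind(log, data.frame(epoch = ep, train_loss = mean(losses),
                                   val_dice = vd))
      if (vd > best$dice) best <- list(dice = vd, params = params, epoch = ep)
    }
    model$params <- best$params
    list(model = model,
         log = structure(list(epochs = log, checkpoint_epoch = best$epoch,
                              checkpoint_dice = best$dice),
                         class = "seg_train_log"))
  })
}

#' Predict a binary tumour mask
#'
#' Forward pass in inference mode; foreground where the finest-stage
#' probability is at least 0.5, on the input grid.
#'
#' @param model a trained `unet_model`.
#' @param volume a [volume_image] with at least the model's input channels.
#' @return a [binary_mask].
#' @export
predict_mask <- function(model, volume) {
  stopifnot(inherits(model, "unet_model"))
  x <- prep_input(volume, model$config$input_channels)
  fw <- unet_fw(model$params, model$config, x)
  p <- sigmoid(fw$logits[[1]])
  binary_mask(array(as.numeric(p >= 0.5), dim(p)[1:3]), volume$spacing)
}

#' Extract the multi-stage feature pyramid
#'
#' The decoder-path activations feeding the deep-supervision heads, with
#' each stage's predicted foreground probability appended as a final
#' channel (the stage-s feature volume is everything the trained segmenter
#' infers at that scale). Stage 1 is finest; deterministic in inference
#' mode.
#'
#' @inheritParams predict_mask
#' @return a `feature_pyramid`: list of per-stage arrays plus channel counts
#'   and downsampling factors `2^(s-1)`.
#' @export
extract_features <- function(model, volume) {
  stopifnot(inherits(model, "unet_model"))
  x <- prep_input(volume, model$config$input_channels)
  fw <- unet_fw(model$params, model$config, x)
  feats <- lapply(seq_along(fw$feats), function(s) {
    f <- fw$feats[[s]]
    p <- sigmoid(fw$logits[[s]])
    array(c(f, p), c(dim(f)[1:3], dim(f)[4] + 1L))
  })
  structure(list(features = feats,
                 channels = vapply(feats, function(f) dim(f)[4], 1L),
                 factors = 2L^(seq_along(feats) - 1L)),
            class = "feature_pyramid")
}

#' K-fold cross-validated segmentation
#'
#' Patient-level folds whose validation sets partition the cohort (sizes
#' differing by at most one); each fold trains on the remainder and reports
#' the mean Dice over its validation cases.
#'
#' @param cohort list of `case_record` objects (>= k cases).
#' @param k number of folds (default 4).
#' @param config a [unet_config].
#' @param epochs,lr forwarded to [train_segmenter].
#' @return list with `per_case` data frame (patient, fold, dice), `fold_dice`,
#'   `mean_dice`, `sd_dice`, and the fold `models`.
#' @export
crossval_segmentation <- function(cohort, k = 4L, config, epochs = 12L, lr = 1e-3) {
  if (k < 2L) stop("k must be >= 2")
  n <- length(cohort)
  if (n < k) stop("cohort smaller than k")
  folds <- with_seed(config$seed + 99L, sample(rep_len(seq_len(k), n)))
  per_case <- NULL
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- cohort[folds != f]
    va <- cohort[folds == f]
    cfg <- config
    cfg$seed <- config$seed + f
    fit <- train_segmenter(tr, cfg, epochs = epochs, val_cases = va, lr = lr)
    models[[f]] <- fit$model
    dv <- vapply(va, function(cs) dice(predict_mask(fit$model, cs$image), cs$mask),
                 numeric(1))
    per_case <- rbind(per_case, data.frame(
      patient_id = vapply(va, function(cs) cs$patient_id, ""),
      fold = f, dice = dv, stringsAsFactors = FALSE))
  }
  fold_dice <- vapply(seq_len(k), function(f)
    mean(per_case$dice[per_case$fold == f]), numeric(1))
  list(per_case = per_case, fold_dice = fold_dice,
       mean_dice = mean(per_case$dice), sd_dice = sd(per_case$dice),
       folds = folds, models = models)
}
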