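# Grad-CAM++ attention maps for the 3D classifiers.
#
# Per-channel weights follow the positive-gradient weighting of Grad-CAM++
# generalised to three spatial axes; the weighted activation sum is clamped
# to nonnegative, trilinearly upsampled to the input grid and
# max-normalised. One numerical choice: gradients are divided by their
# global absolute maximum before the alpha computation, which makes the
# normalised map exactly invariant to a positive rescaling of the logits.

#' Grad-CAM++ attention map for one case
#'
#' @param model a trained `cls_model`.
#' @param case a `case_record` (or [volume_image]).
#' @param pyramid the case's `feature_pyramid` or prepared injection
#'   (required for injecting variants).
#' @param target_block residual block whose activations are attributed;
#'   default is the last injected block (block 4 for the plain variant).
#' @return an `attention_map`: 3D array in \[0, 1\] on the input spatial
#'   grid (all zero when the logit has no gradient at the target layer).
#' @export
gradcam_pp <- function(model, case, pyramid = NULL, target_block = NULL) {
  stopifnot(inherits(model, "cls_model"))
  cfg <- model$config
  vol <- if (inherits(case, "case_record")) case$image else case
  x <- prep_input(vol, cfg$input_channels)
  inj <- NULL
  if (length(cfg$injected_stages) > 0) {
    if (is.null(pyramid)) stop("missing pyramid for injecting variant")
    inj <- if (inherits(pyramid, "prepared_injection")) pyramid
           else prepare_injection(pyramid, dim(x)[1:3], cfg)
  }
  if (is.null(target_block))
    target_block <- if (length(cfg$injected_stages) > 0) max(cfg$injected_stages) else 4L
  stopifnot(target_block %in% 1:4)
  fw <- cls_fw(model, x, inj)
  A <- fw$cache$block_outs[[paste0("b", target_block)]]
  if (length(dim(A)) != 4L || min(dim(A)[1:3]) < 1L)
    stop("target layer has no spatial extent")
  g <- cls_bw(model, fw, 1, stop_at_block = target_block)$dact
  d <- dim(A); nvox <- prod(d[1:3]); K <- d[4]
  gmax <- max(abs(g))
  zero_map <- function() structure(array(0, dim(x)[1:3]), class = "attention_map")
  if (gmax == 0) return(zero_map())
  gm <- matrix(g / gmax, nvox, K)
  Am <- matrix(A, nvox, K)
  sumAg3 <- colSums(Am * gm^3)                 # sum over all three spatial axes
  denom <- 2 * gm^2 + matrix(sumAg3, nvox, K, byrow = TRUE)
  alpha <- ifelse(denom != 0, gm^2 / denom, 0)
  w <- colSums(alpha * pmax(gm, 0))
  M <- pmax(Am %*% w, 0)
  up <- feat_resize_fw(array(M, c(d[1:3], 1L)), dim(x)[1:3])$y
  up <- pmax(up[, , , 1], 0)
  mx <- max(up)
  if (mx == 0) return(zero_map())
  structure(up / mx, class = "attention_map")
}

# binary dilation by a Chebyshev-ball (cube) of the given voxel margin
dilate_mask <- function(m, margin) {
  if (margin == 0) return(m != 0)
  d <- dim(m)
  out <- array(FALSE, d)
  src <- m != 0
  for (dx in -margin:margin) for (dy in -margin:margin) for (dz in -margin:margin) {
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    out[xs, ys, zs] <- out[xs, ys, zs] | src[xs - dx, ys - dy, zs - dz]
  }
  out
}

#' Fraction of top-attention voxels inside the (dilated) tumour mask
#'
#' Quantifies whether attention concentrates on tumoural and peri-tumoural
#' regions: among the strictly positive attention voxels at or above the
#' requested quantile, the fraction lying inside the mask dilated by
#' `margin` voxels.
#'
#' @param map an `attention_map` (or 3D array).
#' @param mask a [binary_mask] (or 0/1 array) on the same grid.
#' @param quantile attention quantile in (0, 1) defining the top voxels.
#' @param margin peri-tumoural dilation margin in voxels (default 2).
#' @return fraction in \[0, 1\] (`NA` when the map is all zero).
#' @export
attention_overlap <- function(map, mask, quantile = 0.9, margin = 2L) {
  m <- if (inherits(map, "attention_map")) unclass(map) else map
  g <- mask_data(mask)
  if (!identical(dim(m), dim(g))) stop("map and mask grids do not match")
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  if (sum(g) == 0) stop("empty mask")
  pos <- m > 0
  if (!any(pos)) return(NA_real_)
  thr <- stats::quantile(m[pos], quantile, type = 7)
  top <- pos & m >= thr
  dil <- dilate_mask(g, margin)
  sum(top & dil) / sum(top)
}
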