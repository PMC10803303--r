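# Layer primitives for the miniature 3D networks.
#
# Feature maps are numeric arrays of dim (nx, ny, nz, C). Convolutions run
# through the compiled im2col/GEMM kernels; the cheap pointwise layers stay
# in R. Every layer exposes a _fw returning list(y, cache) and a _bw taking
# the upstream gradient and the cache.

he_init <- function(cout, fan_in) {
  matrix(rnorm(cout * fan_in, 0, sqrt(2 / fan_in)), nrow = cout)
}

conv_param <- function(cin, cout, k = 3L) {
  list(W = he_init(cout, cin * k^3), b = numeric(cout), k = as.integer(k))
}

conv_fw <- function(p, x, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- (p$k - 1L) %/% 2L
  dims <- dim(x)
  y <- conv3d_fw_cpp(x, dims[1:3], dims[4], p$W, p$b, p$k, stride, pad)
  list(y = y, cache = list(x = x, stride = stride, pad = pad))
}

conv_bw <- function(p, cache, dy) {
  dims <- dim(cache$x)
  conv3d_bw_cpp(cache$x, dims[1:3], dims[4], p$W, dy, p$k, cache$stride, cache$pad)
}

inorm_param <- function(C) list(gamma = rep(1, C), beta = numeric(C))

inorm_fw <- function(p, x, eps = 1e-5) {
  d <- dim(x); nvox <- prod(d[1:3]); C <- d[4]
  xm <- matrix(x, nvox, C)
  if (nvox == 1L) {  # a single spatial voxel: normalisation would zero it
    y <- sweep(sweep(xm, 2, p$gamma, `*`), 2, p$beta, `+`)
    return(list(y = array(y, d), cache = list(x = xm, d = d, affine = TRUE)))
  }
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xhat, 2, p$gamma, `*`), 2, p$beta, `+`)
  list(y = array(y, d), cache = list(xhat = xhat, istd = istd, d = d))
}

inorm_bw <- function(p, cache, dy) {
  d <- cache$d; nvox <- prod(d[1:3]); C <- d[4]
  dym <- matrix(dy, nvox, C)
  if (isTRUE(cache$affine)) {
    return(list(dx = array(sweep(dym, 2, p$gamma, `*`), d),
                dgamma = colSums(dym * cache$x), dbeta = colSums(dym)))
  }
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  m1 <- colMeans(dym)
  m2 <- colMeans(dym * cache$xhat)
  dx <- sweep(dym, 2, m1) - sweep(cache$xhat, 2, m2, `*`)
  dx <- sweep(dx, 2, p$gamma * cache$istd, `*`)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

relu_fw <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bw <- function(cache, dy) dy * cache

sigmoid <- function(x) 1 / (1 + exp(-x))

# global average pool: (nx,ny,nz,C) -> length-C vector
gap_fw <- function(x) {
  d <- dim(x)
  list(y = colMeans(matrix(x, prod(d[1:3]), d[4])), cache = d)
}
gap_bw <- function(cache, dy) {
  nvox <- prod(cache[1:3])
  array(rep(dy / nvox, each = nvox), cache)
}

# global max pool: gradient flows to the (first) argmax voxel per channel
gmp_fw <- function(x) {
  d <- dim(x)
  m <- matrix(x, prod(d[1:3]), d[4])
  idx <- max.col(t(m), ties.method = "first")
  list(y = m[cbind(idx, seq_len(d[4]))], cache = list(d = d, idx = idx))
}
gmp_bw <- function(cache, dy) {
  d <- cache$d; nvox <- prod(d[1:3])
  dm <- matrix(0, nvox, d[4])
  dm[cbind(cache$idx, seq_len(d[4]))] <- dy
  array(dm, d)
}

dense_param <- function(nin, nout = 1L)
  list(W = matrix(rnorm(nout * nin, 0, sqrt(1 / nin)), nout, nin), b = numeric(nout))

dense_fw <- function(p, x) list(y = drop(p$W %*% x + p$b), cache = x)
dense_bw <- function(p, cache, dy) {
  dym <- matrix(dy, nrow = nrow(p$W))
  list(dx = drop(crossprod(p$W, dym)),
       dW = dym %*% t(matrix(cache, nrow = length(cache))),
       db = rowSums(dym))
}

# channel concatenation of feature maps sharing the spatial grid
concat_fw <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(identical(da[1:3], db[1:3]))
  list(y = array(c(a, b), c(da[1:3], da[4] + db[4])), cache = c(da[4], db[4]))
}
concat_bw <- function(cache, dy) {
  d <- dim(dy); na <- prod(d[1:3]) * cache[1]
  list(da = array(dy[seq_len(na)], c(d[1:3], cache[1])),
       db = array(dy[-seq_len(na)], c(d[1:3], cache[2])))
}

# endpoint-aligned trilinear resize of a feature map to new spatial dims
resize_coords <- function(n_in, n_out) {
  if (n_out == 1L) return(0)
  (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
}

feat_resize_fw <- function(x, out_dims) {
  d <- dim(x)
  co <- lapply(1:3, function(a) resize_coords(d[a], out_dims[a]))
  y <- resize3d_fw_cpp(x, d[1:3], d[4], co[[1]], co[[2]], co[[3]])
  list(y = y, cache = list(d = d, co = co))
}

feat_resize_bw <- function(cache, dy) {
  resize3d_bw_cpp(dy, cache$d[1:3], cache$d[4],
                  cache$co[[1]], cache$co[[2]], cache$co[[3]])
}

# ---- parameter-list utilities -------------------------------------------

# Structural entries (like the conv kernel size `k`) are carried inside the
# parameter lists but must not enter optimiser arithmetic.
par_skip <- function(nm) nm == "k"

par_map2 <- function(a, b, f) {
  out <- a
  for (nm in names(a)) {
    if (par_skip(nm)) next
    if (is.list(a[[nm]])) out[[nm]] <- par_map2(a[[nm]], b[[nm]], f)
    else out[[nm]] <- f(a[[nm]], b[[nm]])
  }
  out
}

par_map <- function(a, f) {
  out <- a
  for (nm in names(a)) {
    if (par_skip(nm)) next
    if (is.list(a[[nm]])) out[[nm]] <- par_map(a[[nm]], f)
    else out[[nm]] <- f(a[[nm]])
  }
  out
}

par_zero <- function(a) par_map(a, function(x) x * 0)

par_norm <- function(g) {
  acc <- 0
  walk <- function(a) for (nm in names(a)) {
    if (par_skip(nm)) next
    if (is.list(a[[nm]])) walk(a[[nm]]) else acc <<- acc + sum(a[[nm]]^2)
  }
  walk(g)
  sqrt(acc)
}

# ---- optimisers ----------------------------------------------------------

#' Initialise Adam optimiser state for a parameter list
#' @param params nested parameter list.
#' @return Adam state (first/second moment accumulators and step counter).
#' @export
adam_init <- function(params) list(m = par_zero(params), v = par_zero(params), t = 0L)

#' One Adam step
#'
#' @param params,grads nested parameter and gradient lists of the same shape.
#' @param state state from [adam_init].
#' @param lr learning rate.
#' @param beta1,beta2,eps standard Adam constants.
#' @return list with updated `params` and `state`.
#' @export
adam_step <- function(params, grads, state, lr = 1e-4,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- par_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- par_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- par_map2(state$m, state$v,
                  function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- par_map2(params, upd, `-`)
  list(params = params, state = state)
}

#' Sharpness-aware minimisation update
#'
#' The two-step SAM procedure: evaluate the gradient at the current
#' parameters, ascend by `rho` along its normalised direction, re-evaluate
#' the gradient at the perturbed point, and apply the base optimiser step
#' from the ORIGINAL parameters using the perturbed gradient. With `rho = 0`
#' (or a zero first gradient) this reduces exactly to the base step.
#'
#' @param params nested parameter list.
#' @param grad_fn function(params) returning `list(loss=, grads=)`.
#' @param rho perturbation radius (>= 0).
#' @param base_step function(params, grads) returning updated params (e.g. a
#'   closure over [adam_step]).
#' @return list with updated `params`, the `loss` at the original parameters
#'   and the gradient list actually applied.
#' @export
sam_update <- function(params, grad_fn, rho, base_step) {
  stopifnot(rho >= 0)
  g1 <- grad_fn(params)
  gn <- par_norm(g1$grads)
  if (rho == 0 || gn == 0) {
    return(list(params = base_step(params, g1$grads), loss = g1$loss,
                grads = g1$grads))
  }
  adv <- par_map2(params, g1$grads, function(p, g) p + rho * g / gn)
  g2 <- grad_fn(adv)
  list(params = base_step(params, g2$grads), loss = g1$loss, grads = g2$grads)
}
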