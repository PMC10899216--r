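# Internal compute engine: layer forward/backward passes over the C++
# convolution kernels, parameter initialization, structure-walking helpers and
# the Adam optimizer. Feature maps use the internal layout
# dim = c(nx, ny, nz, nc) (x fastest, channel slowest); the public 5D API in
# attention.R / network.R converts at the boundary.

# ---- structure helpers -----------------------------------------------------

# Apply f to every numeric leaf of a nested list (or to pairs/quadruples of
# leaves across structurally identical trees).
map_leaves <- function(x, f) {
  if (is.list(x)) lapply(x, map_leaves, f = f) else f(x)
}

map2_leaves <- function(x, y, f) {
  if (is.list(x)) {
    out <- vector("list", length(x)); names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- map2_leaves(x[[i]], y[[i]], f)
    out
  } else f(x, y)
}

sum_leaves <- function(x, f = length) {
  if (is.list(x)) sum(vapply(x, sum_leaves, 0, f = f)) else f(x)
}

zeros_like <- function(x) map_leaves(x, function(w) { w[] <- 0; w })

# ---- activations -----------------------------------------------------------

#' Exponential linear unit
#'
#' `elu(x) = x` for `x > 0` and `alpha * (exp(x) - 1)` otherwise: identity on
#' the positive side, a smooth saturation to `-alpha` on the negative side,
#' which keeps mean activations near zero and gradients alive for negative
#' inputs (the reason it replaces PReLU throughout this network).
#'
#' @param x numeric scalar, vector or array.
#' @param alpha positive saturation scale (default 1).
#' @return Same shape as `x`.
#' @export
elu <- function(x, alpha = 1) {
  if (alpha <= 0) stopf("alpha must be > 0")
  neg <- x <= 0
  x[neg] <- alpha * (exp(x[neg]) - 1)
  x
}

# Forward + local gradient for the configured activation. For PReLU `a` is a
# per-channel slope vector (channels = last dim of `pre`). The cache keeps the
# activation output so the ELU backward needs no exp (elu'(x) = elu(x) + alpha
# on the negative branch).
act_fw <- function(pre, act, alpha, a = NULL) {
  if (act == "elu") {
    post <- elu(pre, alpha)
    list(post = post, pre = pre, post_kept = post)
  } else { # prelu
    d <- dim(pre); nc <- d[4]
    nv <- prod(d[1:3])
    m <- matrix(pre, nv, nc)
    neg <- m < 0
    m[neg] <- (m * rep(a, each = nv))[neg]
    list(post = array(m, d), pre = pre)
  }
}

act_bw <- function(gpost, cache, act, alpha, a = NULL) {
  pre <- cache$pre
  if (act == "elu") {
    gpre <- gpost
    neg <- which(pre <= 0)
    gpre[neg] <- gpost[neg] * (cache$post_kept[neg] + alpha)
    list(gpre = gpre, ga = NULL)
  } else {
    dd <- dim(pre); nc <- dd[4]; nv <- prod(dd[1:3])
    mpre <- matrix(pre, nv, nc); mg <- matrix(gpost, nv, nc)
    neg <- mpre < 0
    slope <- matrix(rep(a, each = nv), nv, nc)
    slope[!neg] <- 1
    ga <- colSums(mg * mpre * neg)
    list(gpre = array(mg * slope, dd), ga = ga)
  }
}

# ---- conv / deconv layers --------------------------------------------------

conv_fw <- function(x, p, k, stride = 1L, pad = (k - 1L) %/% 2L,
                    act = "none", alpha = 1) {
  pre <- .conv3d_forward_cpp(x, dim(x), p$w, p$b, k, stride, pad)
  if (act == "none") return(list(out = pre, x = x, k = k, stride = stride, pad = pad))
  ac <- act_fw(pre, act, alpha, p$a)
  list(out = ac$post, x = x, pre = ac$pre, post_kept = ac$post_kept,
       k = k, stride = stride, pad = pad)
}

conv_bw <- function(gout, cache, p, act = "none", alpha = 1, need_gx = TRUE) {
  ga <- NULL
  if (act != "none") {
    ab <- act_bw(gout, cache, act, alpha, p$a)
    gout <- ab$gpre
    ga <- ab$ga
  }
  r <- .conv3d_backward_cpp(cache$x, dim(cache$x), p$w, gout,
                            cache$k, cache$stride, cache$pad, need_gx)
  g <- list(w = r$gw, b = r$gb)
  if (!is.null(ga)) g$a <- ga
  list(gx = if (need_gx) r$gx else NULL, g = g)
}

deconv_fw <- function(x, p, act = "none", alpha = 1) {
  pre <- .deconv3d_forward_cpp(x, dim(x), p$w, p$b)
  if (act == "none") return(list(out = pre, x = x))
  ac <- act_fw(pre, act, alpha, p$a)
  list(out = ac$post, x = x, pre = ac$pre, post_kept = ac$post_kept)
}

deconv_bw <- function(gout, cache, p, act = "none", alpha = 1) {
  ga <- NULL
  if (act != "none") {
    ab <- act_bw(gout, cache, act, alpha, p$a)
    gout <- ab$gpre
    ga <- ab$ga
  }
  r <- .deconv3d_backward_cpp(cache$x, dim(cache$x), p$w, gout)
  g <- list(w = r$gw, b = r$gb)
  if (!is.null(ga)) g$a <- ga
  list(gx = r$gx, g = g)
}

# ---- CBAM internals --------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# Channel attention on an internal (nx, ny, nz, nc) tensor.
cam_fw <- function(x, p) {
  d <- dim(x); nv <- prod(d[1:3]); nc <- d[4]
  xm <- matrix(x, nv, nc)
  avg <- colMeans(xm)
  argmax <- integer(nc); mx <- numeric(nc)
  for (c in seq_len(nc)) { i <- which.max(xm[, c]); argmax[c] <- i; mx[c] <- xm[i, c] }
  h_avg <- pmax(drop(crossprod(p$w1, avg)), 0)       # relu(t(w1) %*% avg)
  h_max <- pmax(drop(crossprod(p$w1, mx)), 0)
  o <- drop(crossprod(p$w2, h_avg)) + drop(crossprod(p$w2, h_max)) + 2 * p$b2
  gate <- sigmoid(o)
  y <- array(xm * rep(gate, each = nv), d)
  list(out = y, x = x, xm_avg = avg, xm_max = mx, argmax = argmax,
       h_avg = h_avg, h_max = h_max, gate = gate)
}

cam_bw <- function(gy, cache, p) {
  x <- cache$x
  d <- dim(x); nv <- prod(d[1:3]); nc <- d[4]
  gm <- matrix(gy, nv, nc)
  xm <- matrix(x, nv, nc)
  ggate <- colSums(gm * xm)
  gx <- gm * rep(cache$gate, each = nv)
  go <- ggate * cache$gate * (1 - cache$gate)
  gw2 <- outer(cache$h_avg, go) + outer(cache$h_max, go)
  gb2 <- 2 * go
  gh_avg <- drop(p$w2 %*% go) * (cache$h_avg > 0)
  gh_max <- drop(p$w2 %*% go) * (cache$h_max > 0)
  gw1 <- outer(cache$xm_avg, gh_avg) + outer(cache$xm_max, gh_max)
  gavg <- drop(p$w1 %*% gh_avg)
  gmaxv <- drop(p$w1 %*% gh_max)
  gx <- gx + matrix(rep(gavg / nv, each = nv), nv, nc)
  gx[cbind(cache$argmax, seq_len(nc))] <-
    gx[cbind(cache$argmax, seq_len(nc))] + gmaxv
  list(gx = array(gx, d), g = list(w1 = gw1, w2 = gw2, b2 = gb2))
}

# Spatial attention on an internal (nx, ny, nz, nc) tensor.
sam_fw <- function(x, p) {
  d <- dim(x); nv <- prod(d[1:3]); nc <- d[4]
  xm <- matrix(x, nv, nc)
  mean_map <- rowMeans(xm)
  maxch <- max.col(xm, ties.method = "first")
  max_map <- xm[cbind(seq_len(nv), maxch)]
  t2 <- array(c(mean_map, max_map), c(d[1:3], 2L))
  cv <- conv_fw(t2, p, k = 3L, stride = 1L, pad = 1L)
  gate <- sigmoid(cv$out)                            # (nx, ny, nz, 1)
  gv <- as.vector(gate)
  y <- array(xm * gv, d)
  list(out = y, x = x, t2 = t2, conv_cache = cv, gate = gv, maxch = maxch)
}

sam_bw <- function(gy, cache, p) {
  x <- cache$x
  d <- dim(x); nv <- prod(d[1:3]); nc <- d[4]
  gm <- matrix(gy, nv, nc)
  xm <- matrix(x, nv, nc)
  ggate <- rowSums(gm * xm)
  gx <- gm * cache$gate
  gpre <- array(ggate * cache$gate * (1 - cache$gate), c(d[1:3], 1L))
  cb <- conv_bw(gpre, cache$conv_cache, p)
  gt2 <- cb$gx
  gmean <- as.vector(gt2[, , , 1])
  gmaxm <- as.vector(gt2[, , , 2])
  gx <- gx + gmean / nc
  idx <- cbind(seq_len(nv), cache$maxch)
  gx[idx] <- gx[idx] + gmaxm
  list(gx = array(gx, d), g = list(w = cb$g$w, b = cb$g$b))
}

cbam_fw <- function(x, p) {
  cam <- cam_fw(x, p$cam)
  sam <- sam_fw(cam$out, p$sam)
  list(out = sam$out, cam = cam, sam = sam)
}

cbam_bw <- function(gout, cache, p) {
  sb <- sam_bw(gout, cache$sam, p$sam)
  cbk <- cam_bw(sb$gx, cache$cam, p$cam)
  list(gx = cbk$gx, g = list(cam = cbk$g, sam = sb$g))
}

# ---- initialization --------------------------------------------------------

he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

init_conv <- function(k, cin, cout, prelu = FALSE) {
  p <- list(w = he_init(k^3 * cin, cout, k^3 * cin), b = numeric(cout))
  if (prelu) p$a <- rep(0.25, cout)
  p
}

init_deconv <- function(cin, cout, prelu = FALSE) {
  p <- list(w = he_init(cin, cout * 8L, cin), b = numeric(cout))
  if (prelu) p$a <- rep(0.25, cout)
  p
}

init_cbam <- function(channels, reduction) {
  hidden <- max(1L, channels %/% reduction)
  list(cam = list(w1 = he_init(channels, hidden, channels),
                  w2 = he_init(hidden, channels, hidden),
                  b2 = numeric(channels)),
       sam = list(w = he_init(2L * 27L, 1L, 2L * 27L), b = numeric(1)))
}

# ---- Adam ------------------------------------------------------------------

adam_state <- function(weights) {
  list(m = zeros_like(weights), v = zeros_like(weights), t = 0L)
}

adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- map2_leaves(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- map2_leaves(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mhat <- map_leaves(state$m, function(m) m / bc1)
  vhat <- map_leaves(state$v, function(v) v / bc2)
  upd <- map2_leaves(mhat, vhat, function(m, v) lr * m / (sqrt(v) + eps))
  list(weights = map2_leaves(weights, upd, function(w, u) w - u), state = state)
}
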