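# Public 3D convolutional block attention (channel + spatial) on 5D feature
# maps indexed (batch, channel, depth, height, width).

# (n, c, d, h, w) sample -> internal (nx, ny, nz, nc) and back.
as_internal <- function(x5, n) {
  d <- dim(x5)
  xi <- array(x5[n, , , , ], d[2:5])       # (c, d, h, w)
  aperm(xi, c(4, 3, 2, 1))
}

from_internal <- function(xi) aperm(xi, c(4, 3, 2, 1))  # -> (c, d, h, w)

check_5d <- function(x) {
  if (length(dim(x)) != 5L || any(dim(x) < 1L))
    stopf("expected a 5D array (batch, channel, depth, height, width)")
}

#' Channel-attention parameters
#'
#' The shared two-layer perceptron of the channel attention module: a
#' reduction map `C -> max(1, C/r)` with ReLU and no bias, then an expansion
#' map back to `C` with a bias. Both pooled descriptors (global average and
#' global max over space) pass through the same MLP, so the output bias enters
#' the pre-sigmoid sum twice.
#'
#' @param channels number of input channels C.
#' @param reduction reduction ratio r (default 16, clamped so the hidden width
#'   is at least 1).
#' @param w1,w2,b2 optional explicit weights: `w1` is C x H, `w2` is H x C,
#'   `b2` length C. When omitted they are He-initialized from the current RNG
#'   state (`zero_init = TRUE` gives all-zero weights, a useful fixed point:
#'   every gate is then sigmoid(0) = 0.5).
#' @param zero_init initialize all parameters to zero.
#' @return Object of class `cam_params`.
#' @export
cam_params <- function(channels, reduction = 16L, w1 = NULL, w2 = NULL,
                       b2 = NULL, zero_init = FALSE) {
  hidden <- max(1L, channels %/% reduction)
  if (zero_init) {
    w1 <- matrix(0, channels, hidden); w2 <- matrix(0, hidden, channels)
    b2 <- numeric(channels)
  }
  w1 <- w1 %||% he_init(channels, hidden, channels)
  w2 <- w2 %||% he_init(hidden, channels, hidden)
  b2 <- b2 %||% numeric(channels)
  if (nrow(w1) != channels || ncol(w2) != channels || length(b2) != channels)
    stopf("CAM weight shapes do not match %d channels", channels)
  structure(list(w1 = w1, w2 = w2, b2 = b2, channels = as.integer(channels),
                 reduction = as.integer(reduction)),
            class = "cam_params")
}

#' Spatial-attention parameters
#'
#' One 3 x 3 x 3 convolution mapping the two channel-pooled maps (mean and max
#' over channels) to a single pre-sigmoid map, with padding 1 so the spatial
#' shape is preserved.
#'
#' @param w optional explicit kernel, a 54 x 1 matrix (2 channels x 27 taps,
#'   kx fastest, then ky, kz, then input channel).
#' @param b optional bias (length 1).
#' @param zero_init initialize to zero (gate identically 0.5).
#' @return Object of class `sam_params`.
#' @export
sam_params <- function(w = NULL, b = NULL, zero_init = FALSE) {
  if (zero_init) { w <- matrix(0, 54, 1); b <- 0 }
  w <- w %||% he_init(54L, 1L, 54L)
  b <- b %||% 0
  if (!identical(dim(w), c(54L, 1L)) && !identical(dim(w), c(54, 1)))
    stopf("SAM kernel must be a 54 x 1 matrix")
  structure(list(w = w, b = as.double(b)), class = "sam_params")
}

#' Channel attention gate
#'
#' Global average- and max-pooling over (depth, height, width) give two
#' per-channel descriptors; each passes through the shared MLP; the element
#' sum of the two outputs goes through a sigmoid. The result is a per-channel
#' multiplicative gate in (0, 1).
#'
#' @param x 5D array (batch, channel, depth, height, width).
#' @param params a [cam_params()].
#' @return Gate array of shape (batch, channel, 1, 1, 1).
#' @export
channel_attention <- function(x, params) {
  check_5d(x)
  d <- dim(x)
  if (d[2] != params$channels)
    stopf("input has %d channels but params expect %d", d[2], params$channels)
  gate <- array(0, c(d[1], d[2], 1, 1, 1))
  for (n in seq_len(d[1])) {
    cf <- cam_fw(as_internal(x, n), params)
    gate[n, , 1, 1, 1] <- cf$gate
  }
  gate
}

#' Spatial attention gate
#'
#' Channel-mean and channel-max maps are concatenated (2 channels) and passed
#' through the 3 x 3 x 3 convolution and a sigmoid, producing a per-voxel
#' multiplicative gate in (0, 1) with the input's spatial shape.
#'
#' @param x 5D array (batch, channel, depth, height, width).
#' @param params a [sam_params()].
#' @return Gate array of shape (batch, 1, depth, height, width).
#' @export
spatial_attention <- function(x, params) {
  check_5d(x)
  d <- dim(x)
  gate <- array(0, c(d[1], 1L, d[3], d[4], d[5]))
  for (n in seq_len(d[1])) {
    sf <- sam_fw(as_internal(x, n), params)
    gi <- array(sf$gate, dim(sf$x)[1:3])           # (nx, ny, nz)
    gate[n, 1, , , ] <- aperm(gi, c(3, 2, 1))
  }
  gate
}

#' Sequential channel + spatial attention block
#'
#' Refines features multiplicatively: first the channel gate scales each
#' channel, then the spatial gate (computed from the channel-refined features)
#' scales each voxel. Both gates lie strictly inside (0, 1) for finite inputs,
#' so the block is a contraction: `|output| <= |input|` element-wise, with
#' equality never attained.
#'
#' @param x 5D array (batch, channel, depth, height, width).
#' @param cam a [cam_params()].
#' @param sam a [sam_params()].
#' @return Array of the same shape as `x`.
#' @export
cbam_block <- function(x, cam, sam) {
  check_5d(x)
  d <- dim(x)
  out <- array(0, d)
  for (n in seq_len(d[1])) {
    cf <- cbam_fw(as_internal(x, n), list(cam = cam, sam = sam))
    out[n, , , , ] <- from_internal(cf$out)
  }
  out
}
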