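# Independent oracles and fixture builders shared across tests. These stay
# deliberately naive (per-voxel loops, direct convolution) so they cannot
# share a bug with the vectorized/GEMM implementation they check.

# Direct (loop) 3D convolution on an internal-layout (nx, ny, nz, nc) tensor,
# weight matrix as used by the package (k^3 * cin rows, kx fastest).
naive_conv3d <- function(x, w, b, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- dim(x); cin <- d[4]; cout <- ncol(w)
  od <- c((d[1:3] + 2L * pad - k) %/% stride + 1L, cout)
  out <- array(0, od)
  for (co in seq_len(cout)) for (oz in seq_len(od[3])) {
    for (oy in seq_len(od[2])) for (ox in seq_len(od[1])) {
      acc <- b[co]
      for (ci in seq_len(cin)) for (kz in 1:k) for (ky in 1:k) for (kx in 1:k) {
        ix <- (ox - 1L) * stride - pad + kx
        iy <- (oy - 1L) * stride - pad + ky
        iz <- (oz - 1L) * stride - pad + kz
        if (ix >= 1 && ix <= d[1] && iy >= 1 && iy <= d[2] &&
            iz >= 1 && iz <= d[3]) {
          r <- (ci - 1L) * k^3 + (kz - 1L) * k^2 + (ky - 1L) * k + kx
          acc <- acc + x[ix, iy, iz, ci] * w[r, co]
        }
      }
      out[ox, oy, oz, co] <- acc
    }
  }
  out
}

# Loop-based reference of the full attention block on a 5D (n, c, d, h, w)
# array: scalar arithmetic, no matrix products, no shared code with the
# implementation beyond the parameter objects.
naive_cbam <- function(x, cam, sam) {
  d <- dim(x)
  out <- array(0, d)
  sig <- function(v) 1 / (1 + exp(-v))
  for (n in seq_len(d[1])) {
    xi <- array(x[n, , , , ], d[2:5])                # (c, dep, h, w)
    C <- d[2]
    avg <- numeric(C); mx <- numeric(C)
    for (c in seq_len(C)) {
      avg[c] <- mean(xi[c, , , ])
      mx[c] <- max(xi[c, , , ])
    }
    mlp <- function(v) {
      H <- ncol(cam$w1)
      h <- numeric(H)
      for (j in seq_len(H)) h[j] <- max(0, sum(cam$w1[, j] * v))
      o <- numeric(C)
      for (c in seq_len(C)) o[c] <- sum(cam$w2[, c] * h) + cam$b2[c]
      o
    }
    gate_c <- sig(mlp(avg) + mlp(mx))
    yi <- xi
    for (c in seq_len(C)) yi[c, , , ] <- xi[c, , , ] * gate_c[c]
    # spatial attention: channel mean/max maps -> 3x3x3 conv -> sigmoid
    for (dep in seq_len(d[3])) for (hh in seq_len(d[4])) for (ww in seq_len(d[5])) {
      acc <- sam$b
      for (kz in 1:3) for (ky in 1:3) for (kx in 1:3) {
        dz <- dep + kz - 2L; dy <- hh + ky - 2L; dx <- ww + kx - 2L
        if (dz >= 1 && dz <= d[3] && dy >= 1 && dy <= d[4] &&
            dx >= 1 && dx <= d[5]) {
          mean_v <- mean(yi[, dz, dy, dx])
          max_v <- max(yi[, dz, dy, dx])
          # kernel rows: kx fastest, then ky, kz, then input channel; the
          # conv acts on the internal (x, y, z) axis order, so the depth
          # (z) offset indexes the kz slot and the width (x) offset kx.
          r_mean <- (kz - 1L) * 9L + (ky - 1L) * 3L + kx
          r_max <- 27L + r_mean
          acc <- acc + mean_v * sam$w[r_mean, 1] + max_v * sam$w[r_max, 1]
        }
      }
      out[n, , dep, hh, ww] <- yi[, dep, hh, ww] * sig(acc)
    }
  }
  out
}

# Random small nodule cube (square in-plane) for augmentation tests.
random_cube <- function(seed, shape = c(6L, 10L, 10L)) {
  set.seed(seed)
  img <- gray_volume(array(sample(0:255, prod(shape), TRUE), shape))
  lbl <- array(0, shape)
  n_fg <- sample(3:20, 1)
  idx <- sample(prod(shape), n_fg)
  lbl[idx] <- 1
  nodule_cube(img, lbl, source_case = sprintf("rc%d", seed))
}

# Small deterministic ct_volume.
tiny_volume <- function(shape = c(6L, 8L, 10L), origin = c(-4, -3, -2),
                        spacing = c(0.7, 0.8, 2.5), seed = 1) {
  set.seed(seed)
  ct_volume(array(stats::runif(prod(shape), -1000, 400), shape),
            origin = origin, spacing = spacing, case_id = "tiny")
}
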