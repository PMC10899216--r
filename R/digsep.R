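#' 8-bit gray volume
#'
#' A 3D array of integer gray values in \[0, 255\], the domain on which the
#' pixel-threshold separation operates. `provenance` records how Hounsfield
#' units were mapped to 8 bits (the window bounds), so a gray volume can always
#' be traced back to its HU window.
#'
#' @param voxels 3D integer-valued array indexed (z, y, x), values in \[0, 255\].
#' @param provenance optional list, e.g. `list(window = c(lo, hi))`.
#' @return An object of class `gray_volume`.
#' @export
gray_volume <- function(voxels, provenance = NULL) {
  if (length(dim(voxels)) != 3L) stopf("gray volume must be a 3D array")
  if (any(voxels != floor(voxels)) || min(voxels) < 0 || max(voxels) > 255) {
    stopf("gray values must be integers in [0, 255]; window/quantize first (see hu_to_gray)")
  }
  structure(list(voxels = voxels, provenance = provenance),
            class = "gray_volume")
}

#' @export
print.gray_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<gray_volume> %d x %d x %d (z,y,x), range [%d, %d]\n",
              d[1], d[2], d[3], min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Pixel-threshold separation of a gray volume into digital feature maps
#'
#' Iteratively threshold-binarizes and subtracts the volume at the descending
#' thresholds 128, 64, 32, ... : at step k every voxel still holding a value
#' `>= 2^(8-k)` contributes a digital feature map entry of exactly `2^(8-k)`
#' (otherwise 0), and that map is subtracted from the running volume before
#' the next step. For an 8-bit image this is bit-plane slicing with planes
#' kept at their bit magnitudes; the high planes carry the coarse tissue
#' contrast that drives lung-region texture, which is why segmentation keeps
#' the top four by default.
#'
#' @param gray a [gray_volume()] (or a bare integer array in \[0, 255\]).
#' @param n_planes number of planes to separate, 1 to 8. Default 4: the high
#'   four planes best represent lung-region texture; lower planes remain in
#'   the residual.
#' @return A `digit_map_stack`: list with `planes` (list of 3D arrays, plane k
#'   holding values in `{0, 2^(8-k)}`), `residual` (3D array of the remaining
#'   gray values, in `[0, 2^(8-n_planes) - 1]`), and `n_planes`.
#' @seealso [digsep_reconstruct()], [hu_to_gray()]
#' @examples
#' g <- gray_volume(array(200L, c(1, 1, 1)))
#' s <- digsep_decompose(g, 4)
#' sapply(s$planes, max)  # 128 64 0 0 ; residual 8
#' @export
digsep_decompose <- function(gray, n_planes = 4L) {
  v <- if (inherits(gray, "gray_volume")) gray$voxels else gray
  if (!(n_planes >= 1 && n_planes <= 8)) stopf("n_planes must be in 1..8")
  if (length(dim(v)) != 3L) stopf("expected a 3D array")
  if (any(v != floor(v)) || min(v) < 0 || max(v) > 255) {
    stopf("voxels must be integers in [0, 255]; window/quantize first (see hu_to_gray)")
  }
  current <- v
  planes <- vector("list", n_planes)
  for (k in seq_len(n_planes)) {
    thr <- 2^(8 - k)
    plane <- array(0, dim(v))
    on <- current >= thr
    plane[on] <- thr
    current <- current - plane
    planes[[k]] <- plane
  }
  structure(list(planes = planes, residual = current, n_planes = as.integer(n_planes)),
            class = "digit_map_stack")
}

#' Reassemble a gray volume from its digital feature maps
#'
#' Element-wise sum of all planes plus the residual. Exact inverse of
#' [digsep_decompose()] for every `n_planes` — the subtraction chain conserves
#' the gray values, so no tolerance is involved.
#'
#' @param stack a `digit_map_stack`.
#' @return A [gray_volume()].
#' @export
digsep_reconstruct <- function(stack) {
  if (!inherits(stack, "digit_map_stack")) stopf("expected a digit_map_stack")
  dims <- lapply(stack$planes, dim)
  if (length(unique(lapply(dims, as.integer))) != 1L ||
      !identical(as.integer(dims[[1]]), as.integer(dim(stack$residual)))) {
    stopf("plane/residual shapes disagree")
  }
  out <- stack$residual
  for (p in stack$planes) out <- out + p
  gray_volume(out)
}

#' Window a CT volume from Hounsfield units to 8-bit gray
#'
#' Clips to `[lo, hi]` and maps affinely onto \[0, 255\] with
#' round-half-away-from-zero. The default window (-1000, 400) HU is the same
#' window preprocessing applies, so the threshold separation operates on
#' exactly the content the network sees.
#'
#' @param vol a [ct_volume()] or bare numeric 3D array of HU.
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @return A [gray_volume()] whose provenance records the window.
#' @export
hu_to_gray <- function(vol, lo = -1000, hi = 400) {
  if (lo >= hi) stopf("window requires lo < hi (got %g, %g)", lo, hi)
  v <- if (inherits(vol, "ct_volume")) vol$voxels else vol
  v <- pmin(pmax(v, lo), hi)
  g <- round_half_away((v - lo) / (hi - lo) * 255)
  g <- array(g, dim(v))
  gray_volume(g, provenance = list(window = c(lo, hi)))
}
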