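#' Nodule cube: a training-ready image/label patch
#'
#' A fixed-size (default 16 x 96 x 96) windowed gray image centered on one
#' annotated nodule, with its congruent binary label mask. The label must
#' contain at least one foreground voxel — an empty label would make the cube
#' useless for training and almost always signals a coordinate bug upstream.
#'
#' @param image a [gray_volume()] of shape (depth, height, width).
#' @param label binary 3D array, same shape as `image`.
#' @param source_case case identifier the cube came from.
#' @param nodule_index 1-based index of the nodule within the case.
#' @param provenance list recording crop origin (0-based (z, y, x)) and the
#'   HU window used.
#' @export
nodule_cube <- function(image, label, source_case = "case", nodule_index = 1L,
                        provenance = NULL) {
  if (!inherits(image, "gray_volume")) stopf("image must be a gray_volume")
  if (!identical(dim(image$voxels), dim(label)))
    stopf("image and label shapes differ")
  if (!is_binary_array(label)) stopf("label must be binary (0/1)")
  if (sum(label) < 1) stopf("label has no foreground voxel (case %s, nodule %d)",
                            source_case, nodule_index)
  structure(list(image = image, label = label,
                 source_case = as.character(source_case),
                 nodule_index = as.integer(nodule_index),
                 provenance = provenance),
            class = "nodule_cube")
}

#' @export
print.nodule_cube <- function(x, ...) {
  d <- dim(x$label)
  cat(sprintf("<nodule_cube> %s #%d, %d x %d x %d, %d foreground voxels\n",
              x$source_case, x$nodule_index, d[1], d[2], d[3], sum(x$label)))
  invisible(x)
}

#' Clip a CT volume to an HU window
#'
#' Clamps every voxel into `[lo, hi]`. The default window (-1000, 400) HU
#' removes content irrelevant to lung tissue (air below, bone/contrast above)
#' before windowing to 8 bits. Idempotent; metadata unchanged.
#'
#' @param vol a [ct_volume()].
#' @param lo,hi window bounds in HU.
#' @return The clipped [ct_volume()].
#' @export
clip_hu <- function(vol, lo = -1000, hi = 400) {
  if (lo >= hi) stopf("clip window requires lo < hi")
  vol$voxels <- array(pmin(pmax(vol$voxels, lo), hi), dim(vol$voxels))
  vol
}

#' Blank out everything outside the lung parenchyma
#'
#' Voxels where the mask is 0 are set to `fill` (default -1000 HU, i.e. air),
#' so only the lung parenchyma survives into the network input.
#'
#' @param vol a [ct_volume()].
#' @param mask a [lung_mask()] congruent with `vol`.
#' @param fill replacement HU value outside the mask.
#' @return The masked [ct_volume()].
#' @export
apply_lung_mask <- function(vol, mask, fill = -1000) {
  m <- if (inherits(mask, "lung_mask")) mask$voxels else mask
  if (!identical(dim(vol$voxels), dim(m)))
    stopf("volume (%s) and mask shapes differ", vol$case_id)
  vol$voxels[m == 0] <- fill
  vol
}

#' Rasterize a nodule annotation into a binary mask
#'
#' With contour polygons, each slice is filled by an even-odd point-in-polygon
#' test on voxel centers. Without contours, a solid sphere of world radius
#' `diameter_mm / 2` centered at the annotated center is discretized: a voxel
#' belongs to the mask iff its world center lies within the radius (so on
#' anisotropic grids the voxel footprint is an ellipsoid in index space). If
#' rounding leaves the mask empty but the center is in-bounds, the center
#' voxel is set, so a nodule no larger than one voxel still rasterizes.
#'
#' @param shape target mask shape (depth, height, width).
#' @param annotation a [nodule_annotation()].
#' @param origin,spacing geometry of the target grid ((x, y, z), mm).
#' @return Binary 3D array of `shape`.
#' @export
rasterize_label <- function(shape, annotation, origin = c(0, 0, 0),
                            spacing = c(1, 1, 1)) {
  shape <- as.integer(shape)
  mask <- array(0, shape)
  nz <- shape[1]; ny <- shape[2]; nx <- shape[3]
  if (!is.null(annotation$contours)) {
    for (ct in annotation$contours) {
      z <- as.integer(ct$slice_index)
      if (z < 0 || z >= nz) next
      px <- (ct$xy[, 1] - origin[1]) / spacing[1]   # continuous voxel coords
      py <- (ct$xy[, 2] - origin[2]) / spacing[2]
      ix <- max(0L, floor(min(px))):min(nx - 1L, ceiling(max(px)))
      iy <- max(0L, floor(min(py))):min(ny - 1L, ceiling(max(py)))
      if (length(ix) == 0 || length(iy) == 0) next
      g <- expand.grid(x = ix, y = iy)
      inside <- rep(FALSE, nrow(g))
      n <- length(px)
      j <- n
      for (i in seq_len(n)) {
        cross <- ((py[i] > g$y) != (py[j] > g$y)) &
          (g$x < (px[j] - px[i]) * (g$y - py[i]) / (py[j] - py[i]) + px[i])
        inside <- xor(inside, cross)
        j <- i
      }
      sel <- g[inside, , drop = FALSE]
      if (nrow(sel)) mask[cbind(z + 1L, sel$y + 1L, sel$x + 1L)] <- 1
    }
  } else {
    r <- annotation$diameter_mm / 2
    ctr <- annotation$center_world
    # index ranges that can possibly intersect the sphere
    rng <- function(c0, o0, sp, nvox) {
      lo <- max(0L, floor((c0 - r - o0) / sp))
      hi <- min(nvox - 1L, ceiling((c0 + r - o0) / sp))
      if (lo > hi) integer(0) else lo:hi
    }
    ixs <- rng(ctr[1], origin[1], spacing[1], nx)
    iys <- rng(ctr[2], origin[2], spacing[2], ny)
    izs <- rng(ctr[3], origin[3], spacing[3], nz)
    if (length(ixs) && length(iys) && length(izs)) {
      dx2 <- (origin[1] + ixs * spacing[1] - ctr[1])^2
      dy2 <- (origin[2] + iys * spacing[2] - ctr[2])^2
      dz2 <- (origin[3] + izs * spacing[3] - ctr[3])^2
      d2 <- outer(outer(dz2, dy2, `+`), dx2, `+`)      # (z, y, x)
      sub <- array(0, dim(d2))
      sub[d2 <= r^2] <- 1
      mask[izs + 1L, iys + 1L, ixs + 1L] <- sub
    }
    if (sum(mask) == 0) {
      cidx <- round_half_away((ctr - origin) / spacing)  # (x, y, z), 0-based
      if (all(cidx >= 0) && all(cidx < c(nx, ny, nz))) {
        mask[cidx[3] + 1L, cidx[2] + 1L, cidx[1] + 1L] <- 1
      }
    }
  }
  if (sum(mask) == 0)
    stopf("annotation for case %s rasterizes to an empty mask (outside the volume?)",
          annotation$case_id)
  mask
}

#' Extract a nodule-centered cube from a volume and its label
#'
#' Crops a (16, 96, 96) region (configurable) whose 0-based origin is the
#' annotated center voxel minus half the cube extent, so the nodule center
#' lands at index (8, 48, 48). Regions falling outside the volume are padded
#' with -1000 HU in the image and 0 in the label. The image is then windowed
#' to 8-bit gray with [hu_to_gray()].
#'
#' @param vol a [ct_volume()] (already clipped/masked as desired).
#' @param label binary 3D array congruent with `vol` (e.g. from
#'   [rasterize_label()]).
#' @param annotation the [nodule_annotation()] the cube is centered on.
#' @param cube_shape (depth, height, width) of the crop.
#' @param window HU window `c(lo, hi)` for the 8-bit mapping.
#' @param nodule_index 1-based nodule index recorded in the cube.
#' @return A [nodule_cube()].
#' @export
extract_cube <- function(vol, label, annotation, cube_shape = c(16L, 96L, 96L),
                         window = c(-1000, 400), nodule_index = 1L) {
  dims <- dim(vol$voxels)
  ctr <- world_to_voxel(vol, annotation$center_world)   # 0-based (z, y, x)
  if (any(ctr < 0) || any(ctr >= dims))
    stopf("nodule %d of case %s: center voxel (%d, %d, %d) outside the volume",
          nodule_index, annotation$case_id, ctr[1], ctr[2], ctr[3])
  cube_shape <- as.integer(cube_shape)
  start <- ctr - cube_shape %/% 2L                      # 0-based crop origin
  img <- array(-1000, cube_shape)
  lbl <- array(0, cube_shape)
  src_lo <- pmax(start, 0L)
  src_hi <- pmin(start + cube_shape - 1L, dims - 1L)
  dst_lo <- src_lo - start
  if (all(src_lo <= src_hi)) {
    si <- Map(function(a, b) (a + 1L):(b + 1L), src_lo, src_hi)
    di <- Map(function(a, b, c) (a + 1L):(a + 1L + (c - b)), dst_lo, src_lo,
              src_hi)
    img[di[[1]], di[[2]], di[[3]]] <- vol$voxels[si[[1]], si[[2]], si[[3]]]
    lbl[di[[1]], di[[2]], di[[3]]] <- label[si[[1]], si[[2]], si[[3]]]
  }
  gray <- hu_to_gray(img, window[1], window[2])
  gray$provenance$crop_origin <- start
  nodule_cube(gray, lbl, source_case = vol$case_id, nodule_index = nodule_index,
              provenance = list(crop_origin = start, window = window))
}

#' Preprocess one case into nodule cubes
#'
#' Full per-case chain: HU clip, lung-mask application, label rasterization
#' per annotation (contours if present, else the diameter sphere), and cube
#' extraction around every annotated nodule of the case.
#'
#' @param vol a [ct_volume()].
#' @param mask the case's [lung_mask()], or `NULL` to skip masking.
#' @param annotations list of [nodule_annotation()]; entries whose `case_id`
#'   differs from `vol$case_id` are ignored.
#' @param window HU window `c(lo, hi)`.
#' @param cube_shape (depth, height, width) of each cube.
#' @return List of [nodule_cube()].
#' @export
preprocess_case <- function(vol, mask, annotations, window = c(-1000, 400),
                            cube_shape = c(16L, 96L, 96L)) {
  vol <- clip_hu(vol, window[1], window[2])
  if (!is.null(mask)) vol <- apply_lung_mask(vol, mask, fill = window[1])
  anns <- Filter(function(a) a$case_id == vol$case_id, annotations)
  out <- vector("list", length(anns))
  for (i in seq_along(anns)) {
    lbl <- rasterize_label(dim(vol$voxels), anns[[i]], vol$origin, vol$spacing)
    out[[i]] <- extract_cube(vol, lbl, anns[[i]], cube_shape = cube_shape,
                             window = window, nodule_index = i)
  }
  out
}

#' Preprocess an on-disk dataset into cube files
#'
#' Consumes the directory layout [generate_dataset()] emits (and which mirrors
#' the usual nodule-analysis layout): `volumes/<case>.mhd`,
#' `masks/<case>.mhd`, and an annotation CSV. Writes one MetaImage pair per
#' nodule (`<case>_nodule<k>_img.mhd`, `..._lbl.mhd`, both `MET_UCHAR`) plus a
#' `manifest.csv` (case, nodule, crop origin, foreground voxels).
#'
#' @param volumes_dir directory of case volumes (`.mhd`).
#' @param masks_dir directory of lung masks named like the volumes, or `NULL`.
#' @param annotations_csv annotation CSV path.
#' @param out_dir output directory (created if missing).
#' @param window,cube_shape as in [preprocess_case()].
#' @return The manifest data.frame, invisibly.
#' @export
preprocess_dataset <- function(volumes_dir, masks_dir, annotations_csv, out_dir,
                               window = c(-1000, 400),
                               cube_shape = c(16L, 96L, 96L)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  anns <- read_annotations(annotations_csv)
  vol_files <- list.files(volumes_dir, pattern = "\\.mhd$", full.names = TRUE)
  rows <- list()
  for (vf in vol_files) {
    vol <- read_volume(vf)
    mask <- NULL
    if (!is.null(masks_dir)) {
      mf <- file.path(masks_dir, basename(vf))
      if (file.exists(mf)) {
        mv <- read_volume(mf)
        mask <- lung_mask(array(as.double(mv$voxels > 0.5), dim(mv$voxels)),
                          case_id = vol$case_id)
      }
    }
    cubes <- preprocess_case(vol, mask, anns, window = window,
                             cube_shape = cube_shape)
    for (cube in cubes) {
      stem <- sprintf("%s_nodule%d", cube$source_case, cube$nodule_index)
      write_volume(ct_volume(cube$image$voxels, case_id = stem),
                   file.path(out_dir, paste0(stem, "_img.mhd")), "MET_UCHAR")
      write_volume(ct_volume(cube$label, case_id = stem),
                   file.path(out_dir, paste0(stem, "_lbl.mhd")), "MET_UCHAR")
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = cube$source_case, nodule_index = cube$nodule_index,
        crop_z = cube$provenance$crop_origin[1],
        crop_y = cube$provenance$crop_origin[2],
        crop_x = cube$provenance$crop_origin[3],
        foreground_voxels = sum(cube$label), stringsAsFactors = FALSE)
    }
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(), nodule_index = integer(),
               crop_z = integer(), crop_y = integer(), crop_x = integer(),
               foreground_voxels = integer())
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Load preprocessed cubes back from disk
#'
#' Reads the `manifest.csv` plus image/label MetaImage pairs written by
#' [preprocess_dataset()] (or [augment_dataset()]).
#'
#' @param dir directory holding the cube files and manifest.
#' @return List of [nodule_cube()].
#' @export
load_cubes <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    stem <- sprintf("%s_nodule%d", manifest$case_id[i], manifest$nodule_index[i])
    if (!is.null(manifest$variant) && !is.na(manifest$variant[i]) &&
        nzchar(manifest$variant[i]))
      stem <- paste0(stem, "_", manifest$variant[i])
    img <- read_volume(file.path(dir, paste0(stem, "_img.mhd")))
    lbl <- read_volume(file.path(dir, paste0(stem, "_lbl.mhd")))
    nodule_cube(gray_volume(array(as.integer(img$voxels), dim(img$voxels))),
                array(as.double(lbl$voxels > 0.5), dim(lbl$voxels)),
                source_case = manifest$case_id[i],
                nodule_index = manifest$nodule_index[i])
  })
}

#' HU histogram of a volume
#'
#' Convenience report of the CT-value distribution of a case, used to choose
#' or sanity-check the preprocessing window.
#'
#' @param vol a [ct_volume()].
#' @param breaks number of equal-width bins over the observed HU range.
#' @return data.frame with bin midpoints and counts.
#' @export
hu_histogram <- function(vol, breaks = 50) {
  v <- as.vector(vol$voxels)
  edges <- seq(min(v), max(v), length.out = breaks + 1)
  idx <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), breaks)
  data.frame(hu = (edges[-1] + edges[-length(edges)]) / 2,
             count = tabulate(idx, nbins = breaks))
}
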