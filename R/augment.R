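#' Default augmentation operation set
#'
#' The augmentation families applied to nodule cubes: in-plane quarter
#' rotations, the in-plane transpose, mirrors along x and y, and reversal of
#' slice order along the z axis. Every op is a pure index permutation, applied
#' identically to image and label, so gray-value multisets and label
#' foreground counts are preserved exactly. Scaling is deliberately absent:
#' it degrades segmentation accuracy on nodule cubes and is excluded from the
#' default set.
#'
#' @return Character vector of op names understood by [apply_augment()]:
#'   `rot90_1`, `rot90_2`, `rot90_3`, `transpose_xy`, `mirror_x`, `mirror_y`,
#'   `z_reverse`.
#' @export
augment_ops <- function() {
  c("rot90_1", "rot90_2", "rot90_3", "transpose_xy",
    "mirror_x", "mirror_y", "z_reverse")
}

# One quarter turn counterclockwise in the (y, x) plane of a (z, y, x) array.
rot90_zyx <- function(a) {
  nx <- dim(a)[3]
  aperm(a[, , nx:1, drop = FALSE], c(1, 3, 2))
}

apply_op_array <- function(a, op) {
  d <- dim(a)
  switch(op,
    rot90_1 = rot90_zyx(a),
    rot90_2 = rot90_zyx(rot90_zyx(a)),
    rot90_3 = rot90_zyx(rot90_zyx(rot90_zyx(a))),
    transpose_xy = aperm(a, c(1, 3, 2)),
    mirror_x = a[, , d[3]:1, drop = FALSE],
    mirror_y = a[, d[2]:1, , drop = FALSE],
    z_reverse = a[d[1]:1, , , drop = FALSE],
    stopf("unknown augmentation op '%s'", op)
  )
}

#' Apply one augmentation op to a nodule cube
#'
#' Image and label are transformed by the same index permutation; the cube
#' shape is preserved (rotations and the transpose act on the square 96 x 96
#' in-plane axes).
#'
#' @param cube a [nodule_cube()].
#' @param op one op name from [augment_ops()].
#' @return The transformed [nodule_cube()]; `provenance$augment` records `op`.
#' @export
apply_augment <- function(cube, op) {
  d <- dim(cube$label)
  if (op %in% c("rot90_1", "rot90_3", "transpose_xy") && d[2] != d[3])
    stopf("in-plane rotation/transpose requires square (y, x) extents")
  img <- cube$image
  img$voxels <- apply_op_array(img$voxels, op)
  prov <- cube$provenance
  prov$augment <- c(prov$augment, op)
  nodule_cube(img, apply_op_array(cube$label, op),
              source_case = cube$source_case,
              nodule_index = cube$nodule_index, provenance = prov)
}

#' Enumerate augmented variants of a cube
#'
#' Offline dataset expansion: returns the original cube plus one transformed
#' copy per op (8 variants under the default set).
#'
#' @param cube a [nodule_cube()].
#' @param ops character vector of op names; default [augment_ops()].
#' @return List of [nodule_cube()], the original first.
#' @export
enumerate_augmentations <- function(cube, ops = augment_ops()) {
  if (length(ops) == 0) stopf("ops must be non-empty")
  c(list(cube), lapply(ops, function(op) apply_augment(cube, op)))
}

#' Augment an on-disk cube dataset
#'
#' Reads cubes written by [preprocess_dataset()], writes the enumerated
#' variants (original included) and an extended manifest with a `variant`
#' column (`orig` or the op name).
#'
#' @param in_dir directory holding preprocessed cubes + manifest.
#' @param out_dir output directory.
#' @param ops ops to enumerate; default [augment_ops()].
#' @return The manifest data.frame, invisibly.
#' @export
augment_dataset <- function(in_dir, out_dir, ops = augment_ops()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cubes <- load_cubes(in_dir)
  rows <- list()
  for (cube in cubes) {
    variants <- enumerate_augmentations(cube, ops)
    tags <- c("orig", ops)
    for (i in seq_along(variants)) {
      v <- variants[[i]]
      stem <- sprintf("%s_nodule%d_%s", v$source_case, v$nodule_index, tags[i])
      write_volume(ct_volume(v$image$voxels, case_id = stem),
                   file.path(out_dir, paste0(stem, "_img.mhd")), "MET_UCHAR")
      write_volume(ct_volume(v$label, case_id = stem),
                   file.path(out_dir, paste0(stem, "_lbl.mhd")), "MET_UCHAR")
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = v$source_case, nodule_index = v$nodule_index,
        variant = tags[i], foreground_voxels = sum(v$label),
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
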