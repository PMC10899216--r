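#' CT volume container
#'
#' A 3D scalar grid with the geometric metadata needed to move between world
#' (mm) and voxel coordinates. Axis order of the array is (z, y, x) — the
#' first dimension is the slice (depth) axis — while `origin` and `spacing`
#' are stored (x, y, z) in mm as MetaImage headers print them.
#'
#' @param voxels 3D numeric array indexed (z, y, x); dim = (depth, height, width).
#' @param origin world coordinate (x, y, z) in mm of voxel (0, 0, 0).
#' @param spacing voxel edge lengths (x, y, z) in mm, all > 0.
#' @param case_id identifier string.
#' @return Object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                      case_id = "case") {
  if (length(dim(voxels)) != 3L || length(voxels) == 0L)
    stopf("voxels must be a non-empty 3D array")
  if (length(spacing) != 3L || any(spacing <= 0))
    stopf("spacing must be three positive lengths (mm)")
  if (length(origin) != 3L) stopf("origin must be (x, y, z) in mm")
  structure(list(voxels = voxels, origin = as.double(origin),
                 spacing = as.double(spacing), case_id = as.character(case_id)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ct_volume> '%s' %d x %d x %d (z,y,x), spacing (%g, %g, %g) mm, origin (%g, %g, %g)\n",
              x$case_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Lung parenchyma mask
#'
#' Binary volume congruent with its paired [ct_volume()]; 1 marks lung
#' parenchyma. Such masks ship with the common nodule-analysis datasets and
#' restrict all processing to the lungs.
#'
#' @param voxels 3D array of 0/1, same shape as the paired CT volume.
#' @param case_id identifier string.
#' @export
lung_mask <- function(voxels, case_id = "case") {
  if (length(dim(voxels)) != 3L) stopf("mask must be a 3D array")
  if (!is_binary_array(voxels)) stopf("mask values must be 0/1")
  structure(list(voxels = voxels, case_id = as.character(case_id)),
            class = "lung_mask")
}

#' Nodule annotation
#'
#' World-coordinate nodule center and maximum diameter, optionally with
#' per-slice contour polygons (each a data.frame of ordered world (x, y)
#' vertices for one slice index).
#'
#' @param case_id series/case identifier.
#' @param center_world nodule center (x, y, z) in mm.
#' @param diameter_mm maximum nodule diameter in mm, > 0.
#' @param contours optional named list: element `i` is a list with
#'   `slice_index` (0-based z index) and `xy`, an n x 2 matrix of world (x, y)
#'   vertices (n >= 3).
#' @export
nodule_annotation <- function(case_id, center_world, diameter_mm,
                              contours = NULL) {
  if (!(diameter_mm > 0)) stopf("diameter_mm must be > 0")
  if (length(center_world) != 3L) stopf("center_world must be (x, y, z) mm")
  if (!is.null(contours)) {
    for (ct in contours) {
      if (is.null(ct$xy) || nrow(ct$xy) < 3L)
        stopf("each contour polygon needs >= 3 vertices")
    }
  }
  structure(list(case_id = as.character(case_id),
                 center_world = as.double(center_world),
                 diameter_mm = as.double(diameter_mm),
                 contours = contours),
            class = "nodule_annotation")
}

# ---------------------------------------------------------------------------
# MetaImage (.mhd + .raw). Uncompressed, axis-aligned volumes only — the
# subset the nodule-analysis datasets actually use. No installed R package
# reads MetaImage, so the header/raw handling lives here.

.met_types <- list(
  MET_UCHAR  = list(what = "integer", size = 1L, signed = FALSE),
  MET_CHAR   = list(what = "integer", size = 1L, signed = TRUE),
  MET_SHORT  = list(what = "integer", size = 2L, signed = TRUE),
  MET_USHORT = list(what = "integer", size = 2L, signed = FALSE),
  MET_INT    = list(what = "integer", size = 4L, signed = TRUE),
  MET_FLOAT  = list(what = "numeric", size = 4L, signed = TRUE),
  MET_DOUBLE = list(what = "numeric", size = 8L, signed = TRUE)
)

read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z0-9_]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3) kv[[m[2]]] <- m[3]
  }
  if (!identical(kv$NDims, "3")) stopf("'%s': only 3D MetaImage volumes are supported", path)
  if (isTRUE(toupper(kv$CompressedData %||% "FALSE") == "TRUE"))
    stopf("'%s': compressed MetaImage data is not supported", path)
  dims <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])       # nx ny nz
  spacing <- as.double(strsplit(kv$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  origin <- as.double(strsplit(kv$Offset %||% kv$Position %||% "0 0 0", "\\s+")[[1]])
  type <- .met_types[[kv$ElementType %||% "MET_FLOAT"]]
  if (is.null(type)) stopf("'%s': unsupported ElementType %s", path, kv$ElementType)
  big_endian <- isTRUE(toupper(kv$BinaryDataByteOrderMSB %||% "FALSE") == "TRUE")
  datafile <- kv$ElementDataFile
  if (is.null(datafile)) stopf("'%s': missing ElementDataFile", path)
  if (identical(datafile, "LOCAL")) stopf("'%s': LOCAL data not supported", path)
  raw_path <- file.path(dirname(path), datafile)
  if (!file.exists(raw_path))
    stopf("missing companion raw file: header '%s' names '%s'", path, raw_path)
  n <- prod(dims)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = type$what, n = n, size = type$size,
               signed = type$signed, endian = if (big_endian) "big" else "little")
  if (length(v) != n) stopf("'%s': expected %d voxels, read %d", raw_path, n, length(v))
  a <- array(as.double(v), dim = dims)          # (x, y, z), x fastest on disk
  list(voxels = aperm(a, c(3, 2, 1)), origin = origin, spacing = spacing)
}

write_mhd <- function(vol, path, element_type = "MET_FLOAT") {
  type <- .met_types[[element_type]]
  if (is.null(type)) stopf("unsupported ElementType %s", element_type)
  d <- dim(vol$voxels)                           # (z, y, x)
  raw_name <- sub("\\.mhd$", ".raw", basename(path))
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    sprintf("Offset = %.9g %.9g %.9g", vol$origin[1], vol$origin[2], vol$origin[3]),
    "CenterOfRotation = 0 0 0",
    "AnatomicalOrientation = RAI",
    sprintf("ElementSpacing = %.9g %.9g %.9g", vol$spacing[1], vol$spacing[2], vol$spacing[3]),
    sprintf("DimSize = %d %d %d", d[3], d[2], d[1]),
    sprintf("ElementType = %s", element_type),
    sprintf("ElementDataFile = %s", raw_name)
  )
  ok <- tryCatch({ writeLines(header, path); TRUE }, error = function(e) FALSE)
  if (!ok) stopf("cannot write '%s'", path)
  a <- aperm(vol$voxels, c(3, 2, 1))             # back to x fastest
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (type$what == "integer") {
    writeBin(as.integer(a), con, size = type$size, endian = "little")
  } else {
    writeBin(as.double(a), con, size = type$size, endian = "little")
  }
  invisible(path)
}

# ---------------------------------------------------------------------------

#' Read a CT volume (MetaImage or NIfTI)
#'
#' MetaImage `.mhd` (with companion `.raw`) is parsed directly; `.nii` /
#' `.nii.gz` go through \pkg{RNifti}. Origin and spacing are copied from the
#' header; intensities are returned as stored (beyond any slope/intercept the
#' NIfTI header itself declares). For NIfTI the translation column of the
#' stored affine is taken as the origin verbatim — no LPS/RAS axis flip is
#' applied, which round-trips files this package wrote itself.
#'
#' @param path file path ending in `.mhd`, `.nii` or `.nii.gz`.
#' @param case_id optional identifier; default derives from the file name.
#' @return A [ct_volume()] with dim (depth, height, width).
#' @export
read_volume <- function(path, case_id = NULL) {
  if (!file.exists(path)) stopf("no such file: '%s'", path)
  case_id <- case_id %||% sub("\\.(mhd|nii|nii\\.gz)$", "", basename(path))
  if (grepl("\\.mhd$", path)) {
    r <- read_mhd(path)
    return(ct_volume(r$voxels, origin = r$origin, spacing = r$spacing,
                     case_id = case_id))
  }
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    if (length(dim(img)) != 3L) stopf("'%s': only 3D images are supported", path)
    aff <- RNifti::xform(img)
    spacing <- abs(c(aff[1, 1], aff[2, 2], aff[3, 3]))
    origin <- as.double(aff[1:3, 4])
    a <- array(as.double(img), dim = dim(img))   # (x, y, z)
    return(ct_volume(aperm(a, c(3, 2, 1)), origin = origin, spacing = spacing,
                     case_id = case_id))
  }
  stopf("unrecognized volume format: '%s' (expected .mhd, .nii or .nii.gz)", path)
}

#' Write a CT volume (MetaImage or NIfTI)
#'
#' The written file re-reads voxel- and metadata-identical (float32 precision
#' for MetaImage, which stores `MET_FLOAT` by default).
#'
#' @param vol a [ct_volume()].
#' @param path destination ending in `.mhd`, `.nii` or `.nii.gz`.
#' @param element_type MetaImage element type (default `MET_FLOAT`;
#'   `MET_UCHAR` is handy for masks and gray cubes).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, element_type = "MET_FLOAT") {
  if (!inherits(vol, "ct_volume")) stopf("expected a ct_volume")
  if (!dir.exists(dirname(path))) stopf("cannot write '%s': no such directory", path)
  if (grepl("\\.mhd$", path)) return(invisible(write_mhd(vol, path, element_type)))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    a <- aperm(vol$voxels, c(3, 2, 1))           # (x, y, z)
    aff <- diag(c(vol$spacing, 1))
    aff[1:3, 4] <- vol$origin
    img <- RNifti::asNifti(a)
    RNifti::sform(img) <- structure(aff, code = 2L)
    RNifti::qform(img) <- structure(aff, code = 2L)
    RNifti::pixdim(img) <- vol$spacing
    RNifti::writeNifti(img, path)
    return(invisible(path))
  }
  stopf("unrecognized volume format: '%s'", path)
}

#' World (mm) to voxel index
#'
#' `round((world - origin) / spacing)` per axis with round-half-away-from-zero,
#' reordered to the array's (z, y, x) axis order. Indices are 0-based (add 1
#' when subscripting the R array) and may legally fall outside the array —
#' the caller decides how to handle out-of-bounds points.
#'
#' @param vol a [ct_volume()].
#' @param point_world numeric (x, y, z) in mm.
#' @return Integer vector (z, y, x), 0-based.
#' @export
world_to_voxel <- function(vol, point_world) {
  idx_xyz <- round_half_away((as.double(point_world) - vol$origin) / vol$spacing)
  rev(idx_xyz)
}

#' Voxel index to world (mm)
#'
#' Inverse of [world_to_voxel()] up to rounding: returns the world coordinate
#' of the voxel center.
#'
#' @param vol a [ct_volume()].
#' @param idx_zyx integer (z, y, x), 0-based.
#' @return Numeric (x, y, z) in mm.
#' @export
voxel_to_world <- function(vol, idx_zyx) {
  vol$origin + rev(as.double(idx_zyx)) * vol$spacing
}

#' Read nodule annotations from CSV
#'
#' Canonical dialect: header `seriesuid,coordX,coordY,coordZ,diameter_mm`
#' (a `case_id` column is accepted in place of `seriesuid`), world mm.
#' Rows with non-positive diameter are dropped with a warning. An optional
#' companion contour CSV (`seriesuid,slice_index,vertex_order,worldX,worldY`)
#' attaches per-slice polygons to matching annotations of the same case
#' (contours are matched to the case, applied to every annotation of it).
#'
#' @param path annotation CSV path.
#' @param contours_path optional contour CSV path.
#' @return List of [nodule_annotation()].
#' @export
read_annotations <- function(path, contours_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  idcol <- if ("seriesuid" %in% names(df)) "seriesuid"
           else if ("case_id" %in% names(df)) "case_id" else NA
  required <- c(idcol, "coordX", "coordY", "coordZ", "diameter_mm")
  for (col in required) {
    if (is.na(col) || !(col %in% names(df)))
      stopf("annotation CSV '%s' is missing required column '%s'", path,
            if (is.na(col)) "seriesuid" else col)
  }
  bad <- df$diameter_mm <= 0
  if (any(bad)) {
    warning(sprintf("dropping %d annotation(s) with non-positive diameter", sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  contours_by_case <- NULL
  if (!is.null(contours_path)) {
    cf <- utils::read.csv(contours_path, stringsAsFactors = FALSE)
    for (col in c("seriesuid", "slice_index", "vertex_order", "worldX", "worldY")) {
      if (!(col %in% names(cf)))
        stopf("contour CSV '%s' is missing required column '%s'", contours_path, col)
    }
    contours_by_case <- split(cf, cf$seriesuid)
  }
  lapply(seq_len(nrow(df)), function(i) {
    cid <- df[[idcol]][i]
    contours <- NULL
    if (!is.null(contours_by_case) && cid %in% names(contours_by_case)) {
      cc <- contours_by_case[[cid]]
      contours <- lapply(split(cc, cc$slice_index), function(s) {
        s <- s[order(s$vertex_order), ]
        list(slice_index = s$slice_index[1],
             xy = cbind(s$worldX, s$worldY))
      })
      names(contours) <- NULL
    }
    nodule_annotation(cid, c(df$coordX[i], df$coordY[i], df$coordZ[i]),
                      df$diameter_mm[i], contours = contours)
  })
}

#' Write nodule annotations to CSV
#'
#' Emits the canonical `seriesuid,coordX,coordY,coordZ,diameter_mm` dialect
#' that [read_annotations()] consumes.
#'
#' @param annotations list of [nodule_annotation()].
#' @param path destination CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- do.call(rbind, lapply(annotations, function(a) {
    data.frame(seriesuid = a$case_id,
               coordX = a$center_world[1], coordY = a$center_world[2],
               coordZ = a$center_world[3], diameter_mm = a$diameter_mm,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
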