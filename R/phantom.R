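#' Synthetic CT phantom specification
#'
#' Parameters of the synthetic chest-CT generator: two ellipsoidal "lungs" of
#' parenchyma-density tissue inside a soft-tissue background, with nodules of
#' known ground truth placed inside the lungs, Gaussian HU noise, and
#' LUNA16-style annotations (world-coordinate centers + maximum diameters).
#' Defaults emulate the data regime the pipeline assumes: thin in-plane
#' spacing with thicker slices, parenchyma around -800 HU, soft-tissue-density
#' nodules of clinically common size.
#'
#' @param volume_shape case shape (depth, height, width) in voxels.
#' @param spacing voxel spacing (x, y, z) in mm.
#' @param n_nodules nodules per case.
#' @param nodule_diameter_range min/max nodule diameter in mm.
#' @param nodule_hu_range nodule tissue HU range (drawn per nodule).
#' @param parenchyma_hu_range lung parenchyma HU range (drawn per case).
#' @param noise_sd additive Gaussian noise, HU.
#' @param seed RNG seed; the generated case is fully determined by it.
#' @param shape_family `"sphere"`, `"ellipsoid"` or `"lobulated"` (sphere with
#'   low-order angular radius perturbation, mimicking irregular nodules).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(32L, 160L, 160L),
                         spacing = c(0.7, 0.7, 2.5),
                         n_nodules = 1L,
                         nodule_diameter_range = c(6, 16),
                         nodule_hu_range = c(-100, 100),
                         parenchyma_hu_range = c(-900, -700),
                         noise_sd = 30,
                         seed = 1L,
                         shape_family = c("sphere", "ellipsoid", "lobulated")) {
  shape_family <- match.arg(shape_family)
  if (any(nodule_diameter_range <= 0) ||
      nodule_diameter_range[1] > nodule_diameter_range[2])
    stopf("nodule_diameter_range must be positive and ordered")
  if (any(volume_shape < 1L)) stopf("volume_shape must be positive")
  structure(list(volume_shape = as.integer(volume_shape),
                 spacing = as.double(spacing),
                 n_nodules = as.integer(n_nodules),
                 nodule_diameter_range = as.double(nodule_diameter_range),
                 nodule_hu_range = as.double(nodule_hu_range),
                 parenchyma_hu_range = as.double(parenchyma_hu_range),
                 noise_sd = as.double(noise_sd),
                 seed = as.integer(seed),
                 shape_family = shape_family),
            class = "phantom_spec")
}

# World coordinates of every voxel center along each axis (x, y, z lists).
axis_world <- function(shape, origin, spacing) {
  list(x = origin[1] + (seq_len(shape[3]) - 1) * spacing[1],
       y = origin[2] + (seq_len(shape[2]) - 1) * spacing[2],
       z = origin[3] + (seq_len(shape[1]) - 1) * spacing[3])
}

#' Generate one synthetic CT case
#'
#' Deterministic in `spec$seed`: volume, lung mask, annotations and the exact
#' ground-truth nodule mask are all reproducible byte-for-byte.
#'
#' @param spec a [phantom_spec()].
#' @param case_id identifier for the generated case.
#' @return List with `volume` ([ct_volume()]), `mask` ([lung_mask()]),
#'   `annotations` (list of [nodule_annotation()]) and `truth` (binary 3D
#'   array (z, y, x) marking nodule voxels exactly).
#' @export
generate_case <- function(spec, case_id = "case_001") {
  set.seed(spec$seed)
  shp <- spec$volume_shape                      # (nz, ny, nx)
  sp <- spec$spacing
  extent <- c((shp[3] - 1) * sp[1], (shp[2] - 1) * sp[2], (shp[1] - 1) * sp[3])
  origin <- -extent / 2
  ax <- axis_world(shp, origin, sp)

  # two ellipsoidal lungs, mirrored about the sagittal midplane
  semi <- c(0.18 * extent[1], 0.32 * extent[2], 0.42 * extent[3])
  lung_centers <- list(c(-0.25 * extent[1], 0, 0), c(0.25 * extent[1], 0, 0))
  in_lung <- array(FALSE, shp)
  for (lc in lung_centers) {
    qx <- ((ax$x - lc[1]) / semi[1])^2
    qy <- ((ax$y - lc[2]) / semi[2])^2
    qz <- ((ax$z - lc[3]) / semi[3])^2
    q <- outer(outer(qz, qy, `+`), qx, `+`)     # (z, y, x)
    in_lung <- in_lung | (q <= 1)
  }

  parenchyma_hu <- stats::runif(1, spec$parenchyma_hu_range[1],
                                spec$parenchyma_hu_range[2])
  vox <- array(40, shp)                         # soft tissue
  vox[in_lung] <- parenchyma_hu

  # place nodules fully inside a lung, non-overlapping
  truth <- array(0, shp)
  annotations <- list()
  placed <- list()
  for (k in seq_len(spec$n_nodules)) {
    diam <- stats::runif(1, spec$nodule_diameter_range[1],
                         spec$nodule_diameter_range[2])
    r <- diam / 2
    hu <- stats::runif(1, spec$nodule_hu_range[1], spec$nodule_hu_range[2])
    ok <- FALSE
    for (try in 1:100) {
      lc <- lung_centers[[sample(2L, 1)]]
      margin <- pmax(semi - r - 1, 0.1 * semi)
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
      rad <- stats::runif(1)^(1 / 3)
      ctr <- lc + u * rad * margin
      clear <- TRUE
      for (p in placed) {
        if (sqrt(sum((ctr - p$ctr)^2)) < r + p$r + 2) { clear <- FALSE; break }
      }
      if (clear) { ok <- TRUE; break }
    }
    if (!ok) stopf("could not place nodule %d without overlap after 100 tries", k)
    placed[[k]] <- list(ctr = ctr, r = r)
    nod <- nodule_voxels(shp, ax, ctr, r, spec$shape_family)
    truth[nod] <- 1
    vox[nod] <- hu
    annotations[[k]] <- nodule_annotation(case_id, ctr, diam)
  }

  vox <- vox + stats::rnorm(length(vox), sd = spec$noise_sd)
  vol <- ct_volume(array(vox, shp), origin = origin, spacing = sp,
                   case_id = case_id)
  list(volume = vol,
       mask = lung_mask(array(as.double(in_lung), shp), case_id = case_id),
       annotations = annotations,
       truth = truth)
}

# Logical index array of the voxels belonging to one nodule.
nodule_voxels <- function(shp, ax, ctr, r, family) {
  dx <- ax$x - ctr[1]; dy <- ax$y - ctr[2]; dz <- ax$z - ctr[3]
  if (family == "sphere") {
    d2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
    return(d2 <= r^2)
  }
  if (family == "ellipsoid") {
    semi <- r * c(1, stats::runif(1, 0.6, 1), stats::runif(1, 0.6, 1))
    semi <- sample(semi)                        # random orientation of axes
    q <- outer(outer((dz / semi[3])^2, (dy / semi[2])^2, `+`),
               (dx / semi[1])^2, `+`)
    return(q <= 1)
  }
  # lobulated: radius modulated by low-order angular harmonics
  ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
  nz <- length(dz); ny <- length(dy); nx <- length(dx)
  DX <- array(rep(dx, each = nz * ny), c(nz, ny, nx))
  DY <- array(rep(rep(dy, each = nz), nx), c(nz, ny, nx))
  DZ <- array(rep(dz, ny * nx), c(nz, ny, nx))
  rad <- sqrt(DX^2 + DY^2 + DZ^2)
  theta <- atan2(DY, DX)
  phi <- acos(ifelse(rad > 0, DZ / pmax(rad, 1e-9), 1))
  rmod <- r * (1 + 0.15 * sin(3 * theta + ph1) * sin(2 * phi + ph2))
  rad <= rmod
}

#' Generate an on-disk phantom dataset
#'
#' Writes the layout [preprocess_dataset()] consumes: `volumes/<case>.mhd`,
#' `masks/<case>.mhd`, `truth/<case>.mhd` and `annotations.csv`. Case seeds
#' are spawned deterministically from `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @param n_cases number of cases to generate.
#' @param out_dir output directory (created if missing).
#' @return Data.frame manifest (case_id, n_nodules, seed), invisibly.
#' @export
generate_dataset <- function(spec, n_cases, out_dir) {
  if (n_cases < 1) stopf("n_cases must be >= 1")
  for (sub in c("volumes", "masks", "truth"))
    dir.create(file.path(out_dir, sub), showWarnings = FALSE, recursive = TRUE)
  all_ann <- list()
  rows <- list()
  for (i in seq_len(n_cases)) {
    cid <- sprintf("case_%03d", i)
    cs <- spec
    cs$seed <- spawn_seed(spec$seed, i)
    case <- generate_case(cs, case_id = cid)
    write_volume(case$volume, file.path(out_dir, "volumes", paste0(cid, ".mhd")))
    write_volume(ct_volume(case$mask$voxels, case$volume$origin,
                           case$volume$spacing, cid),
                 file.path(out_dir, "masks", paste0(cid, ".mhd")), "MET_UCHAR")
    write_volume(ct_volume(case$truth, case$volume$origin,
                           case$volume$spacing, cid),
                 file.path(out_dir, "truth", paste0(cid, ".mhd")), "MET_UCHAR")
    all_ann <- c(all_ann, case$annotations)
    rows[[i]] <- data.frame(case_id = cid, n_nodules = length(case$annotations),
                            seed = cs$seed, stringsAsFactors = FALSE)
  }
  write_annotations(all_ann, file.path(out_dir, "annotations.csv"))
  invisible(do.call(rbind, rows))
}
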