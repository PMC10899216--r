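test_that("HU clipping clamps, is idempotent, and keeps metadata", {
  vol <- ct_volume(array(c(-2000, 500, 0, -1000), c(4, 1, 1)),
                   origin = c(1, 2, 3), spacing = c(1, 1, 2))
  cl <- clip_hu(vol)
  expect_equal(as.vector(cl$voxels), c(-1000, 400, 0, -1000))
  expect_equal(clip_hu(cl)$voxels, cl$voxels)
  expect_equal(cl$origin, vol$origin)
})

test_that("lung masking keeps exactly the masked-in voxels", {
  vol <- tiny_volume()
  ones <- lung_mask(array(1, dim(vol$voxels)))
  expect_equal(apply_lung_mask(vol, ones)$voxels, vol$voxels)
  zeros <- lung_mask(array(0, dim(vol$voxels)))
  expect_true(all(apply_lung_mask(vol, zeros)$voxels == -1000))

  set.seed(4)
  m <- array(rep_len(c(0, 1), length(vol$voxels)), dim(vol$voxels))
  out <- apply_lung_mask(vol, lung_mask(m), fill = -1234)
  expect_equal(sum(out$voxels == -1234), sum(m == 0))
  expect_equal(out$voxels[m == 1], vol$voxels[m == 1])
  bad <- lung_mask(array(1, dim(vol$voxels) + c(1, 0, 0)))
  expect_error(apply_lung_mask(vol, bad), "differ")
})

test_that("sphere rasterization matches the analytic volume within 15%", {
  ann <- nodule_annotation("s", c(0, 0, 0), 10)
  m <- rasterize_label(c(40, 40, 40), ann, origin = c(-20, -20, -20),
                       spacing = c(1, 1, 1))
  analytic <- 4 / 3 * pi * 5^3
  expect_true(abs(sum(m) - analytic) / analytic < 0.15)
})

test_that("a nodule no larger than one voxel still sets the center voxel", {
  ann <- nodule_annotation("s", c(0.2, -0.3, 0.1), 0.9)
  m <- rasterize_label(c(8, 8, 8), ann, origin = c(-4, -4, -4),
                       spacing = c(1, 1, 1))
  expect_gte(sum(m), 1)
  expect_error(rasterize_label(c(8, 8, 8),
                               nodule_annotation("s", c(100, 100, 100), 2),
                               origin = c(-4, -4, -4)),
               "empty mask")
})

test_that("contour polygons fill by the even-odd rule on voxel centers", {
  # 4 x 4 world-unit square spanning voxel centers 2..5 on slice 2
  sq <- list(list(slice_index = 2L,
                  xy = rbind(c(1.5, 1.5), c(5.5, 1.5), c(5.5, 5.5), c(1.5, 5.5))))
  ann <- nodule_annotation("c", c(3.5, 3.5, 2), 4, contours = sq)
  m <- rasterize_label(c(6, 10, 10), ann, origin = c(0, 0, 0),
                       spacing = c(1, 1, 1))
  expect_equal(sum(m), 16)          # 4x4 centers inside, one slice
  expect_equal(sum(m[3, , ]), 16)   # slice index 2 is 0-based
  expect_true(all(m[3, 3:6, 3:6] == 1))
})

test_that("cube extraction centers the nodule and pads out-of-bounds", {
  vox <- array(rnorm(32 * 200 * 200, mean = -500, sd = 100), c(32, 200, 200))
  vol <- ct_volume(vox, origin = c(0, 0, 0), spacing = c(1, 1, 1), case_id = "cc")
  lbl <- array(0, dim(vox))
  lbl[17, 101, 101] <- 1            # voxel (16, 100, 100), 0-based
  ann <- nodule_annotation("cc", c(100, 100, 16), 2)
  cube <- extract_cube(vol, lbl, ann)
  expect_equal(cube$provenance$crop_origin, c(8L, 52L, 52L))
  expect_equal(dim(cube$image$voxels), c(16L, 96L, 96L))
  expect_equal(cube$label[9, 49, 49], 1)   # center lands at 0-based (8,48,48)
  expect_equal(sum(cube$label), 1)

  # corner nodule: padded crop keeps shape, pad value is air (gray 0)
  lbl2 <- array(0, dim(vox)); lbl2[2, 3, 3] <- 1
  ann2 <- nodule_annotation("cc", c(2, 2, 1), 2)
  cube2 <- extract_cube(vol, lbl2, ann2)
  expect_equal(dim(cube2$image$voxels), c(16L, 96L, 96L))
  expect_equal(cube2$image$voxels[1, 1, 1], 0)
  expect_equal(sum(cube2$label), 1)

  expect_error(extract_cube(vol, lbl, nodule_annotation("cc", c(500, 0, 0), 2)),
               "outside the volume")
})

test_that("nodule_cube enforces congruence, binarity and non-empty label", {
  img <- gray_volume(array(0L, c(4, 6, 6)))
  expect_error(nodule_cube(img, array(0, c(4, 6, 6))), "no foreground")
  expect_error(nodule_cube(img, array(2, c(4, 6, 6))), "binary")
  expect_error(nodule_cube(img, array(1, c(4, 6, 5))), "differ")
})

test_that("the per-case pipeline is deterministic and cube-complete", {
  spec <- phantom_spec(seed = 21, n_nodules = 2L)
  case <- generate_case(spec, "case_a")
  c1 <- preprocess_case(case$volume, case$mask, case$annotations)
  c2 <- preprocess_case(case$volume, case$mask, case$annotations)
  expect_length(c1, 2)
  expect_identical(c1[[1]]$image$voxels, c2[[1]]$image$voxels)
  expect_identical(c1[[2]]$label, c2[[2]]$label)
  fg_frac <- vapply(c1, function(cb) mean(cb$label), 0)
  expect_true(all(fg_frac > 0 & fg_frac < 0.5))
})
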