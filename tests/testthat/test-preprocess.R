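test_that("resample_inplane follows the voxel-center grid convention", {
  # 2x2 mm input of shape (H, W) -> (2H-1, 2W-1) at 1x1 mm
  sc <- tiny_scene(seed = 1, shape = c(32, 32, 3))
  v <- render_contrast(sc, "T2", noise_sd = 0, seed = 1)
  v$spacing <- c(2, 2, 3)
  r <- resample_inplane(v, 1)
  expect_identical(dim(r$data)[1:2], c(63L, 63L))
  expect_equal(r$spacing, c(1, 1, 3))
  # original voxels sit on the refined grid
  expect_equal(r$data[seq(1, 63, 2), seq(1, 63, 2), 2], v$data[, , 2],
               tolerance = 1e-12)

  # identity at the target spacing
  v1 <- render_contrast(sc, "T2", noise_sd = 0, seed = 1)
  r1 <- resample_inplane(v1, 1)
  expect_equal(r1$data, v1$data, tolerance = 1e-12)

  # interpolation preserves constants at any spacing
  vc <- contrast_volume(array(3.7, c(20, 20, 2)), spacing = c(1.3, 0.7, 3))
  rc <- resample_inplane(vc, 1)
  expect_true(all(abs(rc$data - 3.7) < 1e-12))
})

test_that("cap_and_scale pins the percentile convention and its inverse", {
  v <- contrast_volume(array(0:100, c(101, 1, 1)))
  cs <- cap_and_scale(v)
  expect_equal(cs$record$p_low, 1)
  expect_equal(cs$record$p_high, 99)
  # value 50 maps to exactly 0
  expect_identical(cs$volume$data[51, 1, 1], 0)
  expect_equal(range(cs$volume$data), c(-1, 1))
  # stored inverse undoes the scaling on the clipped range
  inv <- invert_cap_scale(cs$volume, cs$record)
  expect_equal(inv$data[2:100, 1, 1], as.numeric(1:99), tolerance = 1e-12)

  # constant image: degenerate branch, all zeros, flagged
  vc <- contrast_volume(array(5, c(8, 8, 2)))
  expect_warning(csc <- cap_and_scale(vc), "degenerate")
  expect_true(all(csc$volume$data == 0))
  expect_true(csc$record$degenerate)
})

test_that("cap_and_scale output range is contained in [-1, 1]", {
  withr::with_seed(42, {
    for (i in 1:100) {
      v <- contrast_volume(array(rnorm(6 * 6 * 2, sd = runif(1, 0.1, 50)),
                                 c(6, 6, 2)))
      out <- cap_and_scale(v)$volume$data
      expect_gte(min(out), -1)
      expect_lte(max(out), 1)
    }
  })
})

test_that("rigid registration recovers known misalignments", {
  sc <- tiny_scene(seed = 3, shape = c(64, 64, 4))
  fixed <- render_contrast(sc, "T2", noise_sd = 0, seed = 1)
  # moving = fixed: estimated transform at identity
  reg0 <- rigid_register(fixed, fixed)
  expect_lt(abs(reg0$transform$rotation), 0.1)
  expect_lt(max(abs(reg0$transform$translation)), 0.1)

  # known (5 deg, 3 mm, -2 mm): recovered within 0.5 deg / 0.5 mm
  mis <- misalign(fixed, 5, c(3, -2))
  reg <- rigid_register(mis$volume, fixed)
  rec <- invert_rigid_2d(reg$transform)
  expect_lt(abs(rec$rotation - 5), 0.5)
  expect_lt(max(abs(rec$translation - c(3, -2))), 0.5)

  # translation-only shift of 4 mm
  mis2 <- misalign(fixed, 0, c(4, 0))
  rec2 <- invert_rigid_2d(rigid_register(mis2$volume, fixed)$transform)
  expect_lt(max(abs(rec2$translation - c(4, 0))), 0.5)

  # degenerate images are rejected
  const <- contrast_volume(array(1, dim(fixed$data)))
  expect_error(rigid_register(const, const), "registration undefined")
})

test_that("rigid transforms compose with their inverse to identity", {
  tf <- rigid_transform_2d(7, c(4, -3))
  inv <- invert_rigid_2d(tf)
  th <- tf$rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(inv$rotation + tf$rotation, 0)
  expect_equal(as.numeric(R %*% inv$translation + tf$translation), c(0, 0),
               tolerance = 1e-12)
})

test_that("paired slice extraction preserves slices and validates shapes", {
  sc <- tiny_scene(seed = 1, shape = c(48, 48, 15))
  tr <- rendered_triple(sc, noise_sd = 0.01, scaled = TRUE)
  ds <- extract_sagittal_slices(tr$t1, tr$t2, tr$t2fs)
  expect_s3_class(ds, "paired_slice_dataset")
  expect_identical(nrow(ds), 15L)
  # channels round-trip to their source slices bit-exactly
  expect_identical(ds$t1[[4]], tr$t1$data[, , 4])
  expect_identical(ds$t2fs[[15]], tr$t2fs$data[, , 15])
  # inference mode: no target
  ds0 <- extract_sagittal_slices(tr$t1, tr$t2)
  expect_identical(nrow(ds0), 15L)
  expect_null(ds0$t2fs[[1]])
  # shape mismatch
  small <- contrast_volume(array(0, c(48, 48, 3)))
  expect_error(extract_sagittal_slices(tr$t1, small), "identical shape")
})

test_that("volumes round-trip through NIfTI with spacing and contrast", {
  sc <- tiny_scene(seed = 1, shape = c(32, 32, 3))
  v <- render_contrast(sc, "T2FS", noise_sd = 0.01, seed = 2)
  v$spacing <- c(1, 1, 3.3)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_contrast_volume(v, path)
  r <- read_contrast_volume(path)
  expect_equal(r$data, v$data, tolerance = 1e-7, ignore_attr = TRUE)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-6)
  expect_identical(r$contrast, "T2FS")
})
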