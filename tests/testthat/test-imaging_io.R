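# Preprocessing front end: DICOM/NIfTI loading, resampling, segmentation,
# slice filtering, ROI cropping, resizing/normalization, augmentation.

test_that("DICOM round trip applies rescale and preserves pixels", {
  dir <- withr::local_tempdir()
  img <- matrix(1024, 16, 16)            # stored value
  write_dicom_slice(img - 1024, file.path(dir, "s1.dcm"),
                    z = 0, slope = 1, intercept = -1024)
  # stored = (HU - intercept)/slope = HU + 1024 = 1024 -> HU 0
  vol <- load_ct_volume(dir, format = "dicom-series")
  expect_equal(unique(as.vector(vol$voxels)), 0)
  expect_equal(dim(vol$voxels), c(16L, 16L, 1L))
})

test_that("DICOM series is sorted superior-first and gaps are caught", {
  dir <- withr::local_tempdir()
  for (z in c(0, -3, -6))
    write_dicom_slice(matrix(z, 8, 8), file.path(dir, sprintf("z%d.dcm", z)),
                      z = z)
  vol <- load_ct_volume(dir)
  # slice order (0, -3, -6): axial index 1 at z = 0
  expect_equal(vol$voxels[1, 1, ], c(0, -3, -6))
  expect_equal(vol$spacing[3], 3)

  dir2 <- withr::local_tempdir()
  for (z in c(0, -3, -9))                # missing slice at -6
    write_dicom_slice(matrix(0, 8, 8), file.path(dir2, sprintf("z%d.dcm", z)),
                      z = z)
  expect_error(load_ct_volume(dir2), "missing or irregular")

  dir3 <- withr::local_tempdir()
  write_dicom_slice(matrix(0, 8, 8), file.path(dir3, "a.dcm"), z = 0)
  write_dicom_slice(matrix(0, 10, 10), file.path(dir3, "b.dcm"), z = -3)
  expect_error(load_ct_volume(dir3), "inconsistent")
})

test_that("NIfTI write/read round-trips voxels and spacing", {
  path <- withr::local_tempfile(fileext = ".nii.gz")
  set.seed(2)
  vox <- array(rnorm(10 * 12 * 6, sd = 300), dim = c(10L, 12L, 6L))
  write_nifti(vox, c(1, 1, 3), path)
  nii <- read_nifti(path)
  expect_equal(nii$voxels, vox, tolerance = 1e-6)
  expect_equal(nii$spacing, c(1, 1, 3))
  vol <- load_ct_volume(path, format = "nifti")
  expect_s3_class(vol, "ct_volume")
})

test_that("resample_volume: shape arithmetic, identity and constants", {
  set.seed(3)
  vol <- ct_volume(array(rnorm(40 * 40 * 8), dim = c(40L, 40L, 8L)),
                   c(0.8, 0.8, 3.0))
  out <- resample_volume(vol, c(1, 1, 3))
  expect_equal(dim(out$voxels), c(32L, 32L, 8L))  # round(40*0.8/1) = 32
  expect_equal(out$spacing, c(1, 1, 3))

  same <- resample_volume(resample_volume(vol, c(0.8, 0.8, 3)), c(0.8, 0.8, 3))
  expect_equal(dim(same$voxels), dim(vol$voxels))

  const <- ct_volume(array(7, dim = c(12L, 12L, 12L)), c(2, 2, 2))
  rc <- resample_volume(const, c(1.5, 1.5, 3))
  expect_true(all(abs(rc$voxels - 7) < 1e-12))

  ident <- ct_volume(array(rnorm(8^3), dim = c(8L, 8L, 8L)), c(1, 1, 3))
  ri <- resample_volume(ident, c(1, 1, 3))
  expect_equal(ri$voxels, ident$voxels, tolerance = 1e-12)

  expect_error(resample_volume(vol, c(0, 1, 3)), "positive")
})

test_that("segment_lungs recovers phantom lungs and rejects pure air", {
  ph <- generate_phantom(small_phantom(seed = 5))
  mask <- segment_lungs(ph$volume)
  gt <- ph$mask$mask
  expect_gte(sum(mask$mask & gt) / sum(gt), 0.95)
  body <- ph$volume$voxels > -400 & !gt
  expect_lte(sum(mask$mask & body) / sum(body), 0.01)

  air <- ct_volume(array(-1000, dim = c(32L, 32L, 32L)), c(1, 1, 3))
  expect_warning(m0 <- segment_lungs(air), "no lung-like")
  expect_false(any(m0$mask))
  expect_identical(attr(m0, "n_components"), 0L)

  # pass-through segmenter returns the ground truth unchanged
  pass <- function(vol, ...) ph$mask
  expect_identical(segment_lungs(ph$volume, segmenter = pass)$mask, gt)
})

test_that("lung_fraction_per_slice counts pixels exactly", {
  m <- array(FALSE, dim = c(224L, 224L, 3L))
  m[, , 2] <- TRUE
  m[seq_len(5018)] <- TRUE               # first slice: 5018 pixels
  lm <- lung_mask(m)
  fr <- lung_fraction_per_slice(lm)
  expect_equal(fr, c(5018 / 50176, 1, 0))
})

test_that("filter_slices applies the 2% rule with a retained boundary", {
  fr <- c(0.0, 0.01, 0.05, 0.30, 0.015)
  m <- array(FALSE, dim = c(20L, 20L, 5L))
  for (i in seq_along(fr)) {
    sl <- matrix(FALSE, 20L, 20L)
    sl[seq_len(round(fr[i] * 400))] <- TRUE
    m[, , i] <- sl
  }
  vol <- ct_volume(array(0, dim = dim(m)), c(1, 1, 3))
  expect_equal(filter_slices(vol, lung_mask(m)), c(3L, 4L))

  # boundary: exactly 2% is retained
  m2 <- array(FALSE, dim = c(10L, 10L, 2L))
  m2[1:2, 1, 1] <- TRUE                  # 2/100 = 0.02
  m2[, 1:5, 2] <- TRUE
  expect_equal(filter_slices(ct_volume(array(0, dim = dim(m2)), c(1, 1, 3)),
                             lung_mask(m2)), c(1L, 2L))

  # all-below-threshold errors and names the patient
  m3 <- array(FALSE, dim = c(10L, 10L, 2L))
  expect_error(filter_slices(ct_volume(array(0, dim = dim(m3)), c(1, 1, 3),
                                       patient_id = "P9"), lung_mask(m3)),
               "P9")

  # retained count monotone nonincreasing in the threshold
  ph <- generate_phantom(small_phantom(seed = 8))
  mk <- ph$mask
  vol2 <- ph$volume
  counts <- vapply(c(0, 0.005, 0.01, 0.02, 0.04),
                   function(th) length(filter_slices(vol2, mk, th)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("crop_roi takes the union bounding box over retained slices", {
  m <- array(FALSE, dim = c(64L, 64L, 4L))
  m[11:51, 21:61, 2] <- TRUE             # rows 10-50, cols 20-80 in 0-based
  m[11:51, 21:61, 3] <- TRUE
  vol <- ct_volume(array(rnorm(64 * 64 * 4), dim = dim(m)), c(1, 1, 3))
  out <- crop_roi(vol, lung_mask(m), c(2L, 3L))
  expect_equal(dim(out$voxels), c(41L, 41L, 2L))

  # union of two disjoint per-slice boxes
  m2 <- array(FALSE, dim = c(50L, 50L, 2L))
  m2[11:21, 5:10, 1] <- TRUE
  m2[31:41, 5:10, 2] <- TRUE
  out2 <- crop_roi(ct_volume(array(0, dim = dim(m2)), c(1, 1, 3)),
                   lung_mask(m2), 1:2)
  expect_equal(dim(out2$voxels)[1], 31L)   # rows 11..41

  # full-plane mask: identity crop
  m3 <- array(TRUE, dim = c(12L, 12L, 2L))
  out3 <- crop_roi(ct_volume(array(1, dim = dim(m3)), c(1, 1, 3)),
                   lung_mask(m3), 1:2)
  expect_equal(dim(out3$voxels), c(12L, 12L, 2L))

  # crop never discards a masked voxel of a retained slice
  ph <- generate_phantom(small_phantom(seed = 13))
  ret <- filter_slices(ph$volume, ph$mask)
  cr <- crop_roi(ph$volume, ph$mask, ret)
  box <- attr(cr, "bbox")
  expect_equal(sum(ph$mask$mask[box[1]:box[2], box[3]:box[4], ret]),
               sum(ph$mask$mask[, , ret]))
})

test_that("resize_and_normalize windows HU and assigns relative positions", {
  vox <- array(0, dim = c(30L, 20L, 5L))
  vox[, , 1] <- -1000; vox[, , 2] <- 400; vox[, , 3] <- -1500
  vox[, , 4] <- 1000;  vox[, , 5] <- -300
  vol <- ct_volume(vox, c(1, 1, 3))
  st <- resize_and_normalize(vol, out_size = 64L)
  expect_equal(st$R, 5L)
  expect_equal(max(abs(st$slices[[1]])), 0, tolerance = 1e-12) # -1000 -> 0
  expect_equal(range(st$slices[[2]]), c(1, 1), tolerance = 1e-12) # 400 -> 1
  expect_equal(max(abs(st$slices[[3]])), 0, tolerance = 1e-12) # clip below
  expect_equal(range(st$slices[[4]]), c(1, 1), tolerance = 1e-12) # clip above
  expect_equal(range(st$slices[[5]]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(st$relative_positions, c(0, 0.25, 0.5, 0.75, 1))
  expect_true(all(vapply(st$slices, function(s)
    all(s >= 0 & s <= 1), logical(1))))
  expect_error(resize_and_normalize(vol, out_size = 4L), "at least 8")

  one <- resize_and_normalize(
    ct_volume(array(0, dim = c(10L, 10L, 1L)), c(1, 1, 3)), out_size = 16L)
  expect_equal(one$relative_positions, 0)
})

test_that("augment_slice is seeded and honours its probabilities", {
  set.seed(10)
  sl <- matrix(runif(48 * 48), 48, 48)
  expect_identical(augment_slice(sl, augment_config(apply_probability = 0)),
                   sl)
  # zero rotation range and no flip: identity up to interpolation
  cfg0 <- augment_config(apply_probability = 1, rotation_range_degrees = 0,
                         flip_probability = 0)
  expect_equal(augment_slice(sl, cfg0), sl, tolerance = 1e-12)
  # identical seeds give bit-identical outputs
  cfg <- augment_config(apply_probability = 1)
  set.seed(77); a <- augment_slice(sl, cfg)
  set.seed(77); b <- augment_slice(sl, cfg)
  expect_identical(a, b)
  expect_false(identical(a, sl))
  expect_error(augment_config(apply_probability = 1.4), "\\[0, 1\\]")
})

test_that("full pipeline is deterministic and respects lesion geometry", {
  cfg <- small_phantom(seed = 21, lesion_relative_depth = 0.5)
  ph <- generate_phantom(cfg)
  p1 <- preprocess_volume(ph$volume, out_size = 64L)
  p2 <- preprocess_volume(generate_phantom(cfg)$volume, out_size = 64L)
  expect_identical(p1$stack$slices, p2$stack$slices)
  expect_identical(p1$retained, p2$retained)
  # lesion slices survive filtering and map to mid relative depth
  idx <- match(ph$lesion_slices, p1$retained)
  expect_true(all(!is.na(idx)))
  rel <- p1$stack$relative_positions[idx]
  expect_true(all(abs(rel - 0.5) < 0.25))
})
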