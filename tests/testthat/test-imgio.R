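test_that("NIfTI write-read round-trips data and spacing", {
  vol <- image_volume(array(rnorm(2 * 3 * 4), dim = c(2, 3, 4)),
                      c(0.5, 1, 2))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(vol, f)
  back <- read_nifti(f)
  expect_equal(back$data, vol$data, tolerance = 1e-7)
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
})

test_that("reading reorients non-canonical axis order to the pipeline convention", {
  # a 2x3x4 counter volume written with a permuted orientation
  arr <- array(seq_len(24), dim = c(2, 3, 4))
  img <- RNifti::asNifti(arr)
  # voxel axes: i -> Right, j -> Anterior, k -> Superior ("RAS"), spacing 1
  RNifti::qform(img) <- structure(diag(c(1, 1, 1, 1)), code = 2L)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(img, f)
  back <- read_nifti(f)
  # canonical order is (S-I, A-P, R-L): expect dims permuted to (4, 3, 2)
  expect_equal(dim(back$data), c(4, 3, 2))
  # reference reorientation computed by hand: canonical axis 1 is the
  # source k axis, axis 2 the source j axis, axis 3 the source i axis
  ref <- aperm(arr, c(3, 2, 1))
  expect_equal(array(back$data, dim = dim(back$data)), ref,
               ignore_attr = TRUE)
})

test_that("missing file errors rather than returning an empty volume", {
  expect_error(read_nifti(file.path(tempdir(), "does-not-exist.nii.gz")),
               "not found")
})

test_that("label volumes round-trip as one 4-channel file", {
  lab <- label_volume(rand_mask(c(4, 4, 4, 3)), c(1, 1, 2))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti(lab, f)
  back <- read_nifti(f)
  expect_s3_class(back, "label_volume")
  expect_equal(back$data, lab$data, ignore_attr = TRUE)
  expect_equal(back$spacing, lab$spacing, tolerance = 1e-6)
})

test_that("resampling preserves physical extent within one voxel", {
  vol <- image_volume(array(rnorm(100 * 10 * 10), dim = c(100, 10, 10)),
                      c(0.5, 1, 1))
  out <- resample(vol, c(1, 1, 1))
  expect_equal(dim(out$data)[1], 50) # 100 voxels at 0.5 mm -> 50 at 1 mm
  expect_equal(physical_extent(out)[1], 50, tolerance = 1e-9)
  for (ax in 1:3) {
    expect_lte(abs(physical_extent(out)[ax] - physical_extent(vol)[ax]),
               max(vol$spacing[ax], 1))
  }
})

test_that("resampling a volume already at target spacing is a no-op", {
  vol <- image_volume(array(rnorm(8 * 8 * 8), dim = c(8, 8, 8)), c(1, 1, 2))
  out <- resample(vol, c(1, 1, 2))
  expect_equal(out$data, vol$data, tolerance = 1e-12)
})

test_that("nearest-neighbour resampling keeps masks binary", {
  vol <- image_volume(rand_mask(c(20, 20, 10)), c(0.7, 0.7, 3.1))
  out <- resample(vol, c(1, 1, 2), interp = "nearest")
  expect_true(all(out$data %in% c(0, 1)))
})

test_that("non-positive target spacing is rejected", {
  vol <- image_volume(array(1.0 * (1:8), dim = c(2, 2, 2)), c(1, 1, 1))
  expect_error(resample(vol, c(1, 0, 1)), "positive")
})

test_that("centre crop-or-pad follows the declared arithmetic", {
  # identity
  vol <- image_volume(array(rnorm(16 * 8 * 4), dim = c(16, 8, 4)), c(1, 1, 2))
  out <- center_crop_or_pad(vol, c(16, 8, 4))
  expect_equal(out$vol$data, vol$data)
  expect_equal(out$record$crop_lo, c(0L, 0L, 0L))

  # crop: 600 -> 512 starts at (600 - 512) / 2 = 44
  vol2 <- image_volume(array(rnorm(600 * 4 * 4), dim = c(600, 4, 4)), c(1, 1, 1))
  out2 <- center_crop_or_pad(vol2, c(512, 4, 4))
  expect_equal(out2$record$crop_lo[1], 44L)
  expect_equal(out2$vol$data[1, 1, 1], vol2$data[45, 1, 1])

  # pad: 200 -> 256 pads 28 both sides
  vol3 <- image_volume(array(rnorm(4 * 200 * 4), dim = c(4, 200, 4)), c(1, 1, 1))
  out3 <- center_crop_or_pad(vol3, c(4, 256, 4))
  expect_equal(out3$record$crop_lo[2], -28L)
  expect_true(all(out3$vol$data[, 1:28, ] == 0))
  expect_equal(out3$vol$data[, 29:228, ], vol3$data)

  # odd difference: the extra voxel goes to the high-index side
  vol4 <- image_volume(array(rnorm(7 * 4 * 4), dim = c(7, 4, 4)), c(1, 1, 1))
  out4 <- center_crop_or_pad(vol4, c(4, 4, 4))
  expect_equal(out4$record$crop_lo[1], 1L) # keeps indices 1..4 (0-based),
  # i.e. drops 1 low / 2 high
})

test_that("z-score normalisation meets its contract", {
  vol <- image_volume(array(rnorm(10 * 10 * 10, 50, 7), dim = c(10, 10, 10)),
                      c(1, 1, 1))
  out <- zscore_normalize(vol)
  expect_lt(abs(mean(out$data)), 1e-6)
  expect_lt(abs(sqrt(mean(out$data^2)) - 1), 1e-6)

  # closed form: equal counts of 0 and 2 -> mean 1, sd 1, values -1 and +1
  half <- image_volume(array(c(0, 2), dim = c(2, 5, 2)), c(1, 1, 1))
  hn <- zscore_normalize(half)
  expect_equal(sort(unique(as.vector(hn$data))), c(-1, 1), tolerance = 1e-12)

  # idempotence up to the sample-sd factor: normalising twice == once
  expect_equal(zscore_normalize(out)$data, out$data, tolerance = 1e-6)

  expect_error(zscore_normalize(image_volume(array(3, dim = c(4, 4, 4)),
                                             c(1, 1, 1))), "constant")
})

test_that("preprocessing inverts exactly for labels inside the crop", {
  # crop-only record: support inside the crop round-trips voxelwise
  vol <- image_volume(array(0, dim = c(30, 20, 10)), c(1, 1, 2))
  vol$data[10:15, 8:12, 4:6] <- 1
  cp <- center_crop_or_pad(vol, c(16, 12, 8))
  stopifnot(sum(cp$vol$data) > 0)
  lab4 <- array(0, dim = c(16, 12, 8, 4))
  for (c in 1:4) lab4[, , , c] <- cp$vol$data
  back <- invert_to_native(label_volume(lab4, c(1, 1, 2)), cp$record)
  expect_equal(back$data[, , , 1], vol$data)

  # identity record returns the input unchanged
  idcp <- center_crop_or_pad(vol, c(30, 20, 10))
  lab_id <- array(rep(rand_mask(c(30, 20, 10)), 4), dim = c(30, 20, 10, 4))
  expect_equal(invert_to_native(label_volume(lab_id, c(1, 1, 2)),
                                idcp$record)$data, lab_id)
})

test_that("resample round trip of a cube keeps Dice >= 0.8", {
  vol <- image_volume(array(0, dim = c(40, 40, 20)), c(1, 1, 1))
  vol$data[16:25, 16:25, 6:15] <- 1 # 10-voxel cube
  pre <- preprocess_volume(vol, preproc_config(c(2, 2, 2), c(20, 20, 10)),
                           kind = "mask")
  lab <- array(rep(pre$vol$data, 4), dim = c(dim(pre$vol$data), 4))
  back <- invert_to_native(label_volume(lab, c(2, 2, 2)), pre$record)
  inter <- sum(back$data[, , , 1] * vol$data)
  dice <- 2 * inter / (sum(back$data[, , , 1]) + sum(vol$data))
  expect_gte(dice, 0.8)
})

test_that("crop/pad inverse consistency holds over random shapes", {
  set.seed(71)
  for (i in 1:20) {
    d <- sample(5:40, 3, replace = TRUE)
    t <- sample(5:40, 3, replace = TRUE)
    vol <- image_volume(rand_mask(d), c(1, 1, 1))
    cp <- center_crop_or_pad(vol, t)
    lab <- array(rep(cp$vol$data, 4), dim = c(t, 4))
    back <- invert_to_native(label_volume(lab, c(1, 1, 1)), cp$record)
    expect_equal(dim(back$data)[1:3], d)
    # voxels that survived the crop must round-trip exactly
    lo <- pmax(cp$record$crop_lo, 0L)
    hi <- pmin(d, cp$record$crop_lo + t)
    if (all(hi > lo)) {
      expect_equal(back$data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                             (lo[3] + 1):hi[3], 1],
                   vol$data[(lo[1] + 1):hi[1], (lo[2] + 1):hi[2],
                            (lo[3] + 1):hi[3]])
    }
  }
})
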