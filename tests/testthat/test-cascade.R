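test_that("mask_to_bbox dilates by the ceiling of margin/spacing and clips", {
  m <- array(0, dim = c(20, 20, 20))
  m[11, 11, 11] <- 1
  b0 <- mask_to_bbox(m, c(0, 0, 0), c(1, 1, 1))
  expect_equal(b0$lo, c(10L, 10L, 10L)) # 0-based [10, 11)
  expect_equal(b0$hi, c(11L, 11L, 11L))
  # margin 10 mm at 2 mm spacing -> 5 voxels
  b1 <- mask_to_bbox(m, c(10, 10, 10), c(1, 1, 2))
  expect_equal(b1$lo, c(0L, 0L, 5L))
  expect_equal(b1$hi, c(20L, 20L, 16L))
  expect_error(mask_to_bbox(array(0, dim = c(4, 4, 4))), "empty")
  # a cord tube spanning the full superior-inferior extent keeps axis 1 full
  rc <- rasterize_cord(c(32, 48, 24), c(1, 1, 2), 0, 1)
  bt <- mask_to_bbox(rc$tube_mask, c(0, 0, 0), c(1, 1, 2))
  expect_equal(bt$lo[1], 0L)
  expect_equal(bt$hi[1], 32L)
})

test_that("stitching equals brute-force accumulate-and-divide", {
  set.seed(61)
  for (trial in 1:5) {
    out_shape <- c(sample(20:40, 1), sample(20:40, 1), sample(8:16, 1))
    patch <- pmin(c(16, 16, 8), out_shape)
    stride <- pmax(patch %/% 2, 1)
    grid <- extract_patches(array(0, dim = out_shape), patch, stride)
    C <- 2
    preds <- lapply(seq_len(nrow(grid$origins)), function(i) {
      array(runif(prod(patch) * C), dim = c(patch, C))
    })
    got <- stitch_patches(preds, grid$origins, out_shape)
    # naive oracle
    acc <- array(0, dim = c(out_shape, C)); cnt <- array(0, dim = out_shape)
    for (i in seq_len(nrow(grid$origins))) {
      o <- grid$origins[i, ]
      for (c in 1:C) {
        acc[(o[1] + 1):(o[1] + patch[1]), (o[2] + 1):(o[2] + patch[2]),
            (o[3] + 1):(o[3] + patch[3]), c] <-
          acc[(o[1] + 1):(o[1] + patch[1]), (o[2] + 1):(o[2] + patch[2]),
              (o[3] + 1):(o[3] + patch[3]), c] + preds[[i]][, , , c]
      }
      cnt[(o[1] + 1):(o[1] + patch[1]), (o[2] + 1):(o[2] + patch[2]),
          (o[3] + 1):(o[3] + patch[3])] <-
        cnt[(o[1] + 1):(o[1] + patch[1]), (o[2] + 1):(o[2] + patch[2]),
            (o[3] + 1):(o[3] + patch[3])] + 1
    }
    for (c in 1:C) acc[, , , c] <- acc[, , , c] / cnt
    expect_lt(max(abs(got - acc)), 1e-6)
  }
  # two overlapping patches averaging 0.2 and 0.6 -> 0.4 on the overlap
  p1 <- array(0.2, dim = c(4, 4, 4, 1)); p2 <- array(0.6, dim = c(4, 4, 4, 1))
  st <- stitch_patches(list(p1, p2), rbind(c(0, 0, 0), c(2, 0, 0)),
                       c(6, 4, 4))
  expect_equal(st[3, 1, 1, 1], 0.4)
  expect_equal(st[1, 1, 1, 1], 0.2)
  # coverage gaps are an error
  expect_error(stitch_patches(list(p1), rbind(c(0, 0, 0)), c(6, 4, 4)),
               "cover")
})

test_that("localization failure raises instead of producing an empty crop", {
  cfg <- unet_config(1, 1, depth = 2, base_filters = 2)
  model <- empty_output_model(cfg)
  x <- array(0, dim = c(16, 16, 8))
  expect_error(localize_cord(x, model), "localization failure")
})

test_that("localizer masks are binary", {
  cfg <- unet_config(1, 1, depth = 2, base_filters = 2)
  model <- build_unet(cfg, seed = 9)
  x <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
  m <- tryCatch(localize_cord(x, model), error = function(e) NULL)
  if (!is.null(m)) expect_true(all(m %in% c(0, 1)))
})

test_that("segment_tumor pads, patches and restores the crop grid", {
  cfg <- unet_config(2, 4, depth = 2, base_filters = 2)
  model <- build_unet(cfg, seed = 4)
  ccfg <- cascade_config(seg_patch = c(16, 16, 8), seg_stride = c(8, 8, 8))
  crop <- array(rnorm(20 * 12 * 6), dim = c(20, 12, 6))
  soft <- segment_tumor(crop, crop, model, ccfg)
  expect_equal(dim(soft), c(20, 12, 6, 4))
  expect_true(all(soft > 0 & soft < 1))
  # deterministic across repeated calls
  expect_identical(soft, segment_tumor(crop, crop, model, ccfg))
  expect_error(segment_tumor(crop, crop[1:10, , ], model, ccfg),
               "misaligned")
})

test_that("the full cascade produces native-space labels and a QC log", {
  spec <- tiny_spec(p_cavity = 1, p_edema = 1)
  s <- generate_subject(spec, 21)
  pre <- tiny_preproc()
  loc_cfg <- unet_config(1, 1, depth = 2, base_filters = 2)
  seg_cfg <- unet_config(2, 4, depth = 2, base_filters = 2)
  ccfg <- cascade_config(localizer_patch = pre$crop_shape,
                         seg_patch = c(16, 16, 8), seg_stride = c(8, 8, 8))
  # use a localizer that marks everything, so the bbox is defined
  loc <- build_unet(loc_cfg, seed = 2)
  loc$params$head_b <- rep(20, 1)
  seg <- build_unet(seg_cfg, seed = 3)
  res <- run_cascade(s, loc, seg, ccfg, pre)
  expect_s3_class(res, "cascade_result")
  expect_equal(dim(res$native_labels$data)[1:3], dim(s$t2w$data))
  expect_equal(res$native_labels$spacing, s$t2w$spacing)
  expect_true(all(res$native_labels$data %in% c(0, 1)))
  expect_s3_class(res$bbox, "bbox3d")
  expect_equal(nrow(res$qc), 1)
  # the recorded bbox equals mask_to_bbox of the step-1 output
  t2std <- preprocess_volume(s$t2w, pre, "image")$vol
  mask <- localize_cord(t2std, loc, ccfg)
  expect_equal(res$bbox, mask_to_bbox(mask, ccfg$bbox_margin_mm,
                                      pre$target_spacing))
})

test_that("cohort runs flag per-subject failures without crashing", {
  spec <- tiny_spec()
  subjects <- list(generate_subject(spec, 31, "sub-a"),
                   generate_subject(spec, 32, "sub-b"))
  pre <- tiny_preproc()
  ccfg <- cascade_config(localizer_patch = pre$crop_shape,
                         seg_patch = c(16, 16, 8), seg_stride = c(8, 8, 8))
  loc <- empty_output_model(unet_config(1, 1, depth = 2, base_filters = 2))
  seg <- build_unet(unet_config(2, 4, depth = 2, base_filters = 2), seed = 3)
  run <- run_cascade_cohort(subjects, loc, seg, ccfg, pre)
  expect_equal(length(run$results), 0)
  expect_equal(length(run$failed), 2)
  expect_match(run$failed[["sub-a"]], "localization failure")
})

test_that("the single-step arm segments the full volume without a localizer", {
  spec <- tiny_spec()
  s <- generate_subject(spec, 41)
  pre <- tiny_preproc()
  ccfg <- cascade_config(localizer_patch = pre$crop_shape,
                         seg_patch = c(16, 16, 8), seg_stride = c(8, 8, 8))
  seg <- build_unet(unet_config(2, 4, depth = 2, base_filters = 2), seed = 3)
  res <- run_cascade(s, localizer = NULL, seg, ccfg, pre, use_cascade = FALSE)
  expect_equal(res$bbox$lo, c(0L, 0L, 0L))
  expect_equal(res$bbox$hi, pre$crop_shape)
})
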