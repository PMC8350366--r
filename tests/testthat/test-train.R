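test_that("Dice loss follows its closed form", {
  g <- array(0, dim = c(2, 2, 2)); g[1:4] <- 1
  # perfect prediction -> 0 in the smooth -> 0 limit
  expect_equal(dice_loss(g, g, smooth = 1e-12), 0, tolerance = 1e-9)
  # disjoint non-empty -> 1
  p <- 1 - g
  expect_equal(dice_loss(p, g, smooth = 1e-12), 1, tolerance = 1e-9)
  # pred = 0.5 everywhere, target half ones on 2x2x2:
  # 1 - (2 * 2 + s) / (4 + 4 + s); brute-force voxel sums
  ph <- array(0.5, dim = c(2, 2, 2))
  sp <- 0; si <- 0; sg <- 0
  for (i in 1:8) { sp <- sp + ph[i]; sg <- sg + g[i]; si <- si + ph[i] * g[i] }
  expect_equal(dice_loss(ph, g, smooth = 1),
               1 - (2 * si + 1) / (sp + sg + 1))
  expect_error(dice_loss(array(0, c(2, 2, 2)), array(0, c(2, 2, 3))),
               "shape")
})

test_that("multiclass Dice loss averages the per-channel losses", {
  # two channels perfect, two fully wrong -> 0.5
  g <- array(rbinom(2 * 2 * 2 * 4, 1, 0.5), dim = c(2, 2, 2, 4))
  g[, , , 1][1] <- 1; g[, , , 2][1] <- 1 # ensure non-empty
  p <- g
  p[, , , 3] <- 1 - g[, , , 3]
  p[, , , 4] <- 1 - g[, , , 4]
  expect_equal(multiclass_dice_loss(p, g, smooth = 1e-12), 0.5,
               tolerance = 1e-6)
  # equals the mean of four independently computed losses
  set.seed(8)
  ps <- array(runif(4^3 * 4), dim = c(4, 4, 4, 4))
  gs <- array(rbinom(4^3 * 4, 1, 0.4), dim = c(4, 4, 4, 4))
  per <- sapply(1:4, function(c) dice_loss(ps[, , , c], gs[, , , c], 1))
  expect_equal(multiclass_dice_loss(ps, gs, 1), mean(per))
  expect_error(multiclass_dice_loss(ps[, , , 1:3], gs, 1), "shape|identical")
})

test_that("patch origins form the clamped stride grid", {
  v <- array(0, dim = c(128, 128, 32))
  pp <- extract_patches(v, c(128, 128, 32), c(64, 64, 32))
  expect_equal(nrow(pp$origins), 1)
  expect_equal(pp$origins[1, ], c(0, 0, 0))

  v2 <- array(rnorm(192 * 128 * 32), dim = c(192, 128, 32))
  pp2 <- extract_patches(v2, c(128, 128, 32), c(64, 64, 32))
  expect_equal(sort(unique(pp2$origins[, 1])), c(0, 64))

  v3 <- array(0, dim = c(200, 128, 32))
  pp3 <- extract_patches(v3, c(128, 128, 32), c(64, 64, 32))
  expect_equal(sort(unique(pp3$origins[, 1])), c(0, 64, 72))

  expect_error(extract_patches(v, c(128, 128, 32), c(0, 64, 32)), "stride")
  # every voxel covered at least once
  cov <- array(0, dim = dim(v3))
  for (r in seq_len(nrow(pp3$origins))) {
    o <- pp3$origins[r, ]
    cov[(o[1] + 1):(o[1] + 128), (o[2] + 1):(o[2] + 128),
        (o[3] + 1):(o[3] + 32)] <- 1
  }
  expect_true(all(cov == 1))
  # patches slice the volume faithfully
  expect_equal(pp2$patches[[1]], v2[1:128, 1:128, 1:32])
})

test_that("augmentation with zero amplitudes is the identity", {
  set.seed(3)
  img <- array(rnorm(16 * 16 * 8), dim = c(16, 16, 8))
  lab <- array(rbinom(16 * 16 * 8 * 4, 1, 0.2), dim = c(16, 16, 8, 4))
  cfg <- train_config(aug_rotate_deg = 0, aug_scale = 0, aug_translate = 0)
  out <- augment(img, lab, c(1, 1, 2), cfg)
  expect_equal(out$images, img, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(out$labels, lab, ignore_attr = TRUE)
})

test_that("augmented labels stay binary and transforms stay within bounds", {
  set.seed(11)
  lab <- array(0, dim = c(24, 24, 8, 4))
  lab[12, 12, 4, ] <- 1
  img <- array(rnorm(24 * 24 * 8), dim = c(24, 24, 8))
  cfg <- train_config()
  for (i in 1:10) {
    out <- augment(img, lab, c(1, 1, 2), cfg)
    expect_true(all(out$labels %in% c(0, 1)))
    tf <- out$transform
    expect_lte(abs(tf$angle_deg), 5)
    expect_gte(tf$scale, 0.9); expect_lte(tf$scale, 1.1)
    # translation bounded by 3% of the sagittal extents, zero out of plane
    expect_lte(abs(tf$translate_vox[1]), 0.03 * 24)
    expect_lte(abs(tf$translate_vox[2]), 0.03 * 24)
    expect_equal(tf$translate_vox[3], 0)
    # the marked voxel moves by at most the analytic bound: rotation and
    # scaling about the centre plus translation
    ctr <- (c(24, 24, 8) - 1) / 2
    v0 <- c(12, 12, 4) - 1
    moved <- as.vector(tf$A %*% (v0 - ctr)) + ctr + tf$translate_vox
    bound <- sqrt(sum(((v0 - ctr) * c(1, 1, 2))^2)) # physical radius, mm
    shift_phys <- sqrt(sum(((moved - v0) * c(1, 1, 2))^2))
    max_shift <- bound * (0.1 + sin(5 * pi / 180)) +
      sqrt(sum((c(0.03 * 24, 0.03 * 24, 0) * c(1, 1, 2))^2)) + 1e-6
    expect_lte(shift_phys, max_shift)
  }
})

test_that("cosine annealing interpolates lr0 to lr_min", {
  expect_equal(cosine_lr(0, 200, 0.001), 0.001)
  expect_equal(cosine_lr(200, 200, 0.001), 0)
  expect_equal(cosine_lr(100, 200, 0.001), 0.0005)
  lrs <- sapply(0:200, cosine_lr, max_epochs = 200, lr0 = 0.001)
  expect_true(all(diff(lrs) <= 1e-12))
})

test_that("early stopping follows the strict-improvement rule", {
  # strictly decreasing by 0.01 -> never stops
  h <- seq(1, 0.5, by = -0.01)
  expect_false(early_stop_check(h, patience = 5, min_delta = 0.001))
  # flat history of length patience + 1 -> stops
  expect_true(early_stop_check(rep(0.5, 6), patience = 5, min_delta = 0.001))
  # improvements of exactly min_delta are not improvements
  h2 <- 1 - cumsum(rep(0.001, 8))
  expect_true(early_stop_check(h2, patience = 5, min_delta = 0.001))
  # improvements just above min_delta keep training
  h3 <- 1 - cumsum(rep(0.0011, 8))
  expect_false(early_stop_check(h3, patience = 5, min_delta = 0.001))
})

test_that("dataset splits are exhaustive, disjoint and reproducible", {
  mf <- tibble::tibble(subject_id = sprintf("s%02d", 1:10))
  plan <- split_dataset(mf, c(0.6, 0.2, 0.2), seed = 4)
  expect_equal(sum(plan$split == "train"), 6)
  expect_equal(sum(plan$split == "validation"), 2)
  expect_equal(sum(plan$split == "test"), 2)
  expect_identical(plan, split_dataset(mf, c(0.6, 0.2, 0.2), seed = 4))
  expect_error(split_dataset(mf[1:2, ], seed = 1), "at least 3")

  for (seed in 1:100) {
    p <- split_dataset(mf, seed = seed)
    expect_setequal(p$subject_id, mf$subject_id)
    expect_false(anyNA(p$split))
  }
  # different seeds give distinct plans (12 random splittings)
  plans <- vapply(1:12, function(s) {
    paste(split_dataset(mf, seed = s)$split, collapse = "")
  }, character(1))
  expect_gt(length(unique(plans)), 1)
})

test_that("dice loss equals 1 - dice score on binary masks (smooth -> 0)", {
  set.seed(20)
  for (i in 1:20) {
    p <- rand_mask(c(6, 6, 4)); g <- rand_mask(c(6, 6, 4))
    if (sum(p) + sum(g) == 0) next
    expect_equal(dice_loss(p, g, smooth = 1e-12),
                 1 - dice_score(p, g), tolerance = 1e-8)
  }
})

test_that("a forced early stop halts training and logs every epoch", {
  cohort <- generate_cohort(6, tiny_spec(), seed = 13)
  cfg <- train_config(batch_size = 1L, patch_size = c(64L, 48L, 24L),
                      max_epochs = 5L, patience = 1L, min_delta = 10,
                      augment = FALSE, seed = 2L)
  net <- unet_config(1, 1, depth = 2, base_filters = 1, dropout_rate = 0)
  split <- tibble::tibble(subject_id = sprintf("sub-%03d", 1:6),
                          split = c("train", "train", "train", "train",
                                    "validation", "validation"))
  fit <- train_model(cohort, "localizer", net, cfg, tiny_preproc(),
                     split = split)
  expect_equal(fit$stopped_epoch, 2) # no improvement can beat min_delta = 10
  expect_equal(nrow(fit$log), 2)
  expect_true(all(c("epoch", "lr", "train_loss", "val_loss") %in%
                    names(fit$log)))
  # best weights reproduce the logged best validation loss
  sm <- cohort$subjects[[5]]
  pre <- preprocess_subject(sm, tiny_preproc())
  prob <- forward_infer(fit$model, pre$t2w)
  # (single validation subject of epoch best is averaged over two here;
  # just confirm the stored best is one of the logged values)
  expect_true(any(abs(fit$log$val_loss - fit$best_val_loss) < 1e-12))
})
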