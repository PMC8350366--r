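test_that("Dice score follows the false-positive and absent-case conventions", {
  g <- rand_mask(c(6, 6, 4), 0.4); g[1] <- 1
  expect_equal(dice_score(g, g), 1)
  empty <- array(0, dim = c(6, 6, 4))
  expect_equal(dice_score(g, empty), 0)     # false positive -> 0
  expect_true(is.na(dice_score(empty, empty))) # absent case -> excluded
  # shifted cube with half overlap: 2 * 4 / 16 = 0.5
  p <- array(0, dim = c(6, 6, 4)); p[1:2, 1:2, 1:2] <- 1
  g2 <- array(0, dim = c(6, 6, 4)); g2[1:2, 1:2, 2:3] <- 1
  expect_equal(dice_score(p, g2), 2 * 4 / 16)
  expect_error(dice_score(p, rand_mask(c(6, 6, 5))), "differ")
})

test_that("detection uses the inclusive 6 mm^3 physical overlap", {
  sp <- c(1, 1, 2) # 2 mm^3 voxels
  g <- array(0, dim = c(6, 6, 4)); g[1:4, 1, 1] <- 1
  p3 <- array(0, dim = c(6, 6, 4)); p3[1:3, 1, 1] <- 1 # overlap 3 vox = 6 mm3
  expect_true(detection_flags(p3, g, sp)$tp)
  p2 <- array(0, dim = c(6, 6, 4)); p2[1:2, 1, 1] <- 1 # 4 mm3 < 6
  expect_false(detection_flags(p2, g, sp)$tp)
  # absent structure: false positive iff predicted volume >= 6 mm3
  empty <- array(0, dim = c(6, 6, 4))
  expect_true(detection_flags(p3, empty, sp)$fp)
  expect_false(detection_flags(empty, empty, sp)$fp)
  expect_true(is.na(detection_flags(empty, empty, sp)$tp))
})

test_that("precision and recall follow the voxel-count definitions", {
  g <- array(0, dim = c(4, 4, 4)); g[1:8] <- 1
  expect_equal(precision_recall(g, g), list(precision = 1, recall = 1))
  p <- array(0, dim = c(4, 4, 4)); p[1:16] <- 1 # superset, |P| = 2|G|
  expect_equal(precision_recall(p, g), list(precision = 0.5, recall = 1))
  q <- array(0, dim = c(4, 4, 4)); q[17:20] <- 1
  expect_equal(precision_recall(q, g), list(precision = 0, recall = 0))
  empty <- array(0, dim = c(4, 4, 4))
  expect_true(is.na(precision_recall(empty, g)$precision))
})

test_that("volume differences use the (gt - pred) / gt sign convention", {
  sp <- c(1, 1, 1)
  g <- array(0, dim = c(10, 10, 10)); g[1:100] <- 1
  expect_equal(volume_differences(g, g, sp), list(rvd = 0, avd = 0))
  p <- array(0, dim = c(10, 10, 10)); p[1:120] <- 1 # 1.2 x over-segmented
  vd <- volume_differences(p, g, sp)
  expect_equal(vd$rvd, -0.2, tolerance = 1e-12)
  expect_equal(vd$avd, 0.2, tolerance = 1e-12)
  empty <- array(0, dim = c(10, 10, 10))
  expect_equal(volume_differences(empty, g, sp), list(rvd = 1, avd = 1))
  expect_true(is.na(volume_differences(g, empty, sp)$rvd))
})

test_that("bbox inclusion respects the half-open convention", {
  whole <- array(0, dim = c(10, 10, 10))
  whole[3:5, 3:5, 3:5] <- 1
  box <- bbox3d(c(2, 2, 2), c(5, 5, 5)) # 0-based [2,5): covers indices 3..5
  incl <- bbox_inclusion(whole, box)
  expect_true(incl$fully_contained)
  expect_equal(incl$fraction, 1)
  # a voxel exactly at the hi index is excluded
  whole[6, 3, 3] <- 1 # 0-based index 5 == hi -> outside
  incl2 <- bbox_inclusion(whole, box)
  expect_false(incl2$fully_contained)
  expect_lt(incl2$fraction, 1)
  # empty lesion counts as contained
  expect_true(bbox_inclusion(array(0, dim = c(4, 4, 4)),
                             bbox3d(c(0, 0, 0), c(1, 1, 1)))$fully_contained)
})

test_that("metric kernels are symmetric where mathematics demands", {
  set.seed(33)
  for (i in 1:25) {
    p <- rand_mask(c(6, 6, 4)); g <- rand_mask(c(6, 6, 4))
    dp <- dice_score(p, g); dg <- dice_score(g, p)
    if (sum(p) > 0 && sum(g) > 0) expect_equal(dp, dg)
  }
})

test_that("aggregation takes cohort means then mean +/- population sd over splits", {
  mk_row <- function(split, dice) {
    tibble::tibble(subject_id = "s", structure = "whole", gt_present = TRUE,
                   dice = dice, tp = TRUE, fp = NA, precision = dice,
                   recall = dice, rvd = 0, avd = 0, split = split)
  }
  df <- dplyr::bind_rows(mk_row(1, 0.6), mk_row(2, 0.8))
  rep <- aggregate_metrics(df)
  dice <- rep$summary[rep$summary$metric == "dice", ]
  expect_equal(dice$mean, 0.7)
  expect_equal(dice$sd, 0.1) # population sd of {0.6, 0.8}
  # a single split has sd 0
  rep1 <- aggregate_metrics(mk_row(1, 0.6))
  expect_equal(rep1$summary$sd[rep1$summary$metric == "dice"], 0)
  # absent cases are excluded, not counted as zero
  df2 <- dplyr::bind_rows(
    tibble::tibble(subject_id = "a", structure = "cavity", gt_present = FALSE,
                   dice = NA_real_, tp = NA, fp = FALSE, precision = NA_real_,
                   recall = NA_real_, rvd = NA_real_, avd = NA_real_, split = 1),
    tibble::tibble(subject_id = "b", structure = "cavity", gt_present = TRUE,
                   dice = 0.9, tp = TRUE, fp = NA, precision = 0.9,
                   recall = 0.9, rvd = 0.1, avd = 0.1, split = 1))
  rep2 <- aggregate_metrics(df2)
  expect_equal(rep2$per_split$dice, 0.9)
  expect_equal(rep2$per_split$n_absent_excluded, 1)
  # all subjects absent -> not evaluable, never reported as 0
  df3 <- df2[1, ]
  rep3 <- aggregate_metrics(df3)
  expect_true(is.nan(rep3$per_split$dice) | is.na(rep3$per_split$dice))
  expect_s3_class(tidy(rep2), "tbl_df")
})

test_that("per-subject evaluation assembles all metrics per structure", {
  set.seed(52)
  gt <- label_volume(rand_mask(c(8, 8, 4, 3), 0.2), c(1, 1, 2))
  pred <- label_volume(rand_mask(c(8, 8, 4, 3), 0.2), c(1, 1, 2))
  df <- evaluate_subject(pred, gt, subject_id = "s1")
  expect_equal(nrow(df), 4)
  expect_setequal(df$structure, c("whole", "tumor", "cavity", "edema"))
  w <- df[df$structure == "whole", ]
  expect_equal(w$dice, dice_score(label_channel(pred, "whole"),
                                  label_channel(gt, "whole")))
})
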