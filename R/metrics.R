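# Segmentation evaluation: per-structure Dice with the
# zero-on-false-positive convention, detection at a 6 mm^3 overlap,
# voxel precision/recall, signed and absolute volume differences,
# bounding-box inclusion, and mean +/- std aggregation over repeated
# random splits.

#' Metrics configuration
#'
#' @param detection_overlap_mm3 Physical overlap between prediction and
#'   ground truth at which a structure counts as detected (6 mm^3,
#'   inclusive).
#' @param structures Structures evaluated.
#' @return A `metrics_config` list.
#' @export
metrics_config <- function(detection_overlap_mm3 = 6,
                           structures = c("whole", "tumor", "cavity", "edema")) {
  stopifnot(detection_overlap_mm3 > 0)
  structure(list(detection_overlap_mm3 = detection_overlap_mm3,
                 structures = match.arg(structures, LABEL_CHANNELS,
                                        several.ok = TRUE)),
            class = "metrics_config")
}

check_aligned <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) {
    stop("prediction and ground truth shapes differ", call. = FALSE)
  }
}

#' Dice score with the false-positive convention
#'
#' `2|P n G| / (|P| + |G|)`. A non-empty prediction of a structure absent
#' from the subject scores 0; the empty-empty case is an absent-case and
#' returns `NA` so it can be excluded from cohort averaging.
#'
#' @param pred_bin,gt_bin Aligned binary arrays.
#' @return Dice in `[0, 1]`, 0 for a pure false positive, `NA` for
#'   empty-empty.
#' @export
dice_score <- function(pred_bin, gt_bin) {
  check_aligned(pred_bin, gt_bin)
  np <- sum(pred_bin); ng <- sum(gt_bin)
  if (ng == 0 && np == 0) return(NA_real_)
  if (ng == 0) return(0)
  2 * sum(pred_bin * gt_bin) / (np + ng)
}

#' Detection flags at a physical overlap threshold
#'
#' For a present structure, true positive iff the physical overlap volume
#' is at least the threshold. For an absent structure, false positive iff
#' the predicted physical volume is at least the threshold.
#'
#' @param pred_bin,gt_bin Aligned binary arrays.
#' @param spacing Voxel spacing, mm.
#' @param cfg A [metrics_config()].
#' @return List `tp`, `fp` (logical, `NA` where not applicable).
#' @export
detection_flags <- function(pred_bin, gt_bin, spacing,
                            cfg = metrics_config()) {
  check_aligned(pred_bin, gt_bin)
  vox <- prod(spacing)
  if (sum(gt_bin) > 0) {
    list(tp = sum(pred_bin * gt_bin) * vox >= cfg$detection_overlap_mm3,
         fp = NA)
  } else {
    list(tp = NA, fp = sum(pred_bin) * vox >= cfg$detection_overlap_mm3)
  }
}

#' Voxel precision and recall
#'
#' @param pred_bin,gt_bin Aligned binary arrays.
#' @return List `precision` (`NA` when the prediction is empty) and
#'   `recall` (`NA` when the ground truth is empty).
#' @export
precision_recall <- function(pred_bin, gt_bin) {
  check_aligned(pred_bin, gt_bin)
  inter <- sum(pred_bin * gt_bin)
  np <- sum(pred_bin); ng <- sum(gt_bin)
  list(precision = if (np > 0) inter / np else NA_real_,
       recall = if (ng > 0) inter / ng else NA_real_)
}

#' Relative and absolute volume differences
#'
#' `rvd = (V_gt - V_pred) / V_gt` (negative means over-segmentation);
#' `avd = |rvd|`. Volumes are physical. Undefined for an empty ground
#' truth.
#'
#' @param pred_bin,gt_bin Aligned binary arrays.
#' @param spacing Voxel spacing, mm.
#' @return List `rvd`, `avd`.
#' @export
volume_differences <- function(pred_bin, gt_bin, spacing) {
  check_aligned(pred_bin, gt_bin)
  vox <- prod(spacing)
  vg <- sum(gt_bin) * vox
  if (vg == 0) return(list(rvd = NA_real_, avd = NA_real_))
  vp <- sum(pred_bin) * vox
  rvd <- (vg - vp) / vg
  list(rvd = rvd, avd = abs(rvd))
}

#' Whole-lesion inclusion in a bounding box
#'
#' Checks whether every nonzero whole-lesion voxel index lies inside the
#' half-open box, and the fraction that does. An empty lesion counts as
#' fully contained.
#'
#' @param gt_labels A `label_volume` (its whole channel is used) or a
#'   binary 3D array.
#' @param bbox A [bbox3d()] in the same voxel space.
#' @return List `fully_contained` (logical) and `fraction`.
#' @export
bbox_inclusion <- function(gt_labels, bbox) {
  whole <- if (inherits(gt_labels, "label_volume")) {
    label_channel(gt_labels, "whole")
  } else gt_labels
  idx <- which(whole != 0, arr.ind = TRUE) - 1L # 0-based
  if (nrow(idx) == 0) return(list(fully_contained = TRUE, fraction = 1.0))
  inside <- idx[, 1] >= bbox$lo[1] & idx[, 1] < bbox$hi[1] &
    idx[, 2] >= bbox$lo[2] & idx[, 2] < bbox$hi[2] &
    idx[, 3] >= bbox$lo[3] & idx[, 3] < bbox$hi[3]
  list(fully_contained = all(inside), fraction = mean(inside))
}

#' Evaluate one subject's multiclass prediction
#'
#' Computes, per structure, the Dice score (with the
#' zero-on-false-positive and absent-case conventions), detection flags,
#' precision/recall and volume differences.
#'
#' @param pred_labels,gt_labels Aligned `label_volume`s.
#' @param spacing Voxel spacing, mm; defaults to the ground-truth
#'   spacing.
#' @param cfg A [metrics_config()].
#' @param subject_id Optional identifier carried into the result.
#' @return Tibble with one row per structure.
#' @export
evaluate_subject <- function(pred_labels, gt_labels,
                             spacing = gt_labels$spacing,
                             cfg = metrics_config(),
                             subject_id = NA_character_) {
  rows <- lapply(cfg$structures, function(st) {
    p <- label_channel(pred_labels, st)
    g <- label_channel(gt_labels, st)
    det <- detection_flags(p, g, spacing, cfg)
    pr <- precision_recall(p, g)
    vd <- volume_differences(p, g, spacing)
    tibble::tibble(subject_id = subject_id, structure = st,
                   gt_present = sum(g) > 0,
                   dice = dice_score(p, g),
                   tp = det$tp, fp = det$fp,
                   precision = pr$precision, recall = pr$recall,
                   rvd = vd$rvd, avd = vd$avd)
  })
  dplyr::bind_rows(rows)
}

#' Aggregate per-subject metrics over subjects and splits
#'
#' Per structure: the cohort mean within each split (absent-case and
#' undefined entries excluded), then mean and population standard
#' deviation across splits. Exclusion counts are reported. Detection
#' rates are the fraction of present-structure subjects detected (true
#' positive rate) and of absent-structure subjects with a false-positive
#' prediction.
#'
#' @param per_subject Tibble from [evaluate_subject()] rows, with an
#'   added `split` column (a single unnamed split is tolerated).
#' @return A `metrics_report` with `per_split` and `summary` tibbles.
#' @export
aggregate_metrics <- function(per_subject) {
  if (!"split" %in% names(per_subject)) per_subject$split <- 1L
  per_split <- per_subject |>
    dplyr::group_by(.data$split, .data$structure) |>
    dplyr::summarise(
      n_subjects = dplyr::n(),
      n_absent_excluded = sum(is.na(.data$dice)),
      dice = mean(.data$dice, na.rm = TRUE),
      tp_rate = mean(.data$tp, na.rm = TRUE),
      fp_rate = mean(.data$fp, na.rm = TRUE),
      precision = mean(.data$precision, na.rm = TRUE),
      recall = mean(.data$recall, na.rm = TRUE),
      rvd = mean(.data$rvd, na.rm = TRUE),
      avd = mean(.data$avd, na.rm = TRUE),
      .groups = "drop")
  pop_sd <- function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NA_real_)
    sqrt(mean((x - mean(x))^2))
  }
  summary <- per_split |>
    tidyr::pivot_longer(cols = c("dice", "tp_rate", "fp_rate", "precision",
                                 "recall", "rvd", "avd"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$structure, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value[is.finite(.data$value)]),
                     sd = pop_sd(.data$value),
                     n_splits = dplyr::n(), .groups = "drop")
  structure(list(per_split = per_split, summary = summary),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  dice <- x$summary[x$summary$metric == "dice", ]
  for (r in seq_len(nrow(dice))) {
    cat(sprintf("  %-7s Dice %.3f +/- %.3f (%d splits)\n",
                dice$structure[r], dice$mean[r], dice$sd[r], dice$n_splits[r]))
  }
  invisible(x)
}

#' Turn a metrics report into a tidy tibble
#'
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return The summary tibble (structure, metric, mean, sd, n_splits).
#' @importFrom generics tidy
#' @export
tidy.metrics_report <- function(x, ...) x$summary

#' @export
generics::tidy
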