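# Two-step inference: localize the cord on T2w, crop both contrasts
# around the predicted mask, segment the crop patch-wise, stitch by
# averaging, postprocess and map back to native space.

#' Cascade configuration
#'
#' @param localizer_patch Localizer input patch (defaults to the standard
#'   crop, 512 x 256 x 32 — one patch, batch size 1).
#' @param seg_patch,seg_stride Segmenter patch and stride
#'   (128 x 128 x 32 / 64 x 64 x 32).
#' @param bbox_margin_mm Margin added around the predicted cord mask per
#'   axis, mm (default 5: a small buffer against tight localizer masks).
#' @param threshold Binarization threshold for the localizer mask.
#' @param largest_component Keep only the largest connected component of
#'   the localizer mask before the bounding box (off by default).
#' @return A `cascade_config` list.
#' @export
cascade_config <- function(localizer_patch = c(512L, 256L, 32L),
                           seg_patch = c(128L, 128L, 32L),
                           seg_stride = c(64L, 64L, 32L),
                           bbox_margin_mm = c(5, 5, 5),
                           threshold = 0.5,
                           largest_component = FALSE) {
  stopifnot(all(bbox_margin_mm >= 0), threshold > 0, threshold < 1)
  structure(list(localizer_patch = as.integer(localizer_patch),
                 seg_patch = as.integer(seg_patch),
                 seg_stride = as.integer(seg_stride),
                 bbox_margin_mm = as.numeric(bbox_margin_mm),
                 threshold = threshold,
                 largest_component = isTRUE(largest_component)),
            class = "cascade_config")
}

#' Localize the spinal cord on a standard-space T2w volume
#'
#' Runs the localizer network on the preprocessed T2w volume and
#' binarizes at the configured threshold. An empty mask raises a
#' localization-failure error rather than producing an empty crop.
#'
#' @param t2w_std Standard-space, normalised `image_volume` (or 3D
#'   array).
#' @param localizer A trained localizer `unet_model`.
#' @param cfg A [cascade_config()].
#' @return Binary 3D array (cord mask, standard space).
#' @export
localize_cord <- function(t2w_std, localizer, cfg = cascade_config()) {
  arr <- if (inherits(t2w_std, "image_volume")) t2w_std$data else t2w_std
  prob <- forward_infer(localizer, arr)
  mask <- (prob[, , , 1] >= cfg$threshold) * 1
  if (cfg$largest_component && sum(mask) > 0) {
    lab <- cpp_label3d(mask, dim(mask), 26L)
    tab <- tabulate(lab[lab > 0])
    mask <- (lab == which.max(tab)) * 1
  }
  if (sum(mask) == 0) {
    stop("localization failure: empty cord mask", call. = FALSE)
  }
  mask
}

#' Bounding box of a mask with a physical margin
#'
#' The tightest half-open voxel box containing all nonzero voxels,
#' dilated by `ceiling(margin_mm / spacing)` voxels per axis and clipped
#' to the volume bounds.
#'
#' @param mask Binary 3D array (non-empty).
#' @param margin_mm Margin per axis, mm.
#' @param spacing Voxel spacing, mm.
#' @return A [bbox3d()].
#' @export
mask_to_bbox <- function(mask, margin_mm = c(5, 5, 5), spacing = c(1, 1, 2)) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty", call. = FALSE)
  m_vox <- ceiling(margin_mm / spacing)
  lo <- pmax(0L, apply(idx, 2, min) - 1L - m_vox)
  hi <- pmin(dim(mask), apply(idx, 2, max) + m_vox)
  bbox3d(lo, hi, margin_voxels = m_vox)
}

#' Stitch overlapping patch predictions
#'
#' Each voxel of the output is the arithmetic mean of all patch
#' predictions covering it; voxels covered once pass through unchanged. A
#' coverage gap is an error.
#'
#' @param patch_preds List of 4D arrays `(px, py, pz, C)`.
#' @param origins Matrix of 0-based voxel origins, one row per patch.
#' @param out_shape Integer length-3 spatial output shape.
#' @return 4D array `(out_shape, C)`.
#' @export
stitch_patches <- function(patch_preds, origins, out_shape) {
  C <- dim(patch_preds[[1]])[4]
  acc <- array(0, dim = c(out_shape, C))
  cnt <- array(0, dim = out_shape)
  for (r in seq_along(patch_preds)) {
    o <- origins[r, ]
    p <- dim(patch_preds[[r]])[1:3]
    xi <- (o[1] + 1):(o[1] + p[1]); yi <- (o[2] + 1):(o[2] + p[2])
    zi <- (o[3] + 1):(o[3] + p[3])
    acc[xi, yi, zi, ] <- acc[xi, yi, zi, , drop = FALSE] + patch_preds[[r]]
    cnt[xi, yi, zi] <- cnt[xi, yi, zi] + 1
  }
  if (any(cnt == 0)) stop("patch grid does not cover the volume", call. = FALSE)
  for (c in seq_len(C)) acc[, , , c] <- acc[, , , c] / cnt
  acc
}

# Pad an array up to at least `patch` and to a multiple of 2^depth per
# axis (architecture requirement); returns the padded array and the
# offset of the original data inside it.
pad_for_patching <- function(arr, patch, depth) {
  d <- dim(arr)[1:3]
  mult <- 2L^depth
  target <- pmax(d, patch)
  target <- as.integer(ceiling(target / mult) * mult)
  cp <- crop_pad_array(arr, target)
  list(data = cp$data, offset = -cp$crop_lo, orig_shape = d)
}

#' Segment the tumor components on a cord crop
#'
#' Concatenates the two aligned, normalised crops (Gd-T1w first, then
#' T2w), pads to the patch grid, runs the multiclass segmenter on every
#' patch of the stride grid and stitches the soft predictions by overlap
#' averaging.
#'
#' @param crop_gd_t1w,crop_t2w Aligned 3D arrays (the cropped, normalised
#'   contrasts).
#' @param segmenter A trained 2-channel, 4-channel-output `unet_model`.
#' @param cfg A [cascade_config()].
#' @return 4D soft prediction `(crop dims, 4)`, channel order tumor,
#'   cavity, edema, whole.
#' @export
segment_tumor <- function(crop_gd_t1w, crop_t2w, segmenter,
                          cfg = cascade_config()) {
  if (!all(dim(crop_gd_t1w) == dim(crop_t2w))) {
    stop("contrast crops are misaligned", call. = FALSE)
  }
  depth <- segmenter$cfg$depth
  pg <- pad_for_patching(crop_gd_t1w, cfg$seg_patch, depth)
  pt <- pad_for_patching(crop_t2w, cfg$seg_patch, depth)
  d <- dim(pg$data)
  x <- array(c(pg$data, pt$data), dim = c(d, 2L))
  pp <- extract_patches(x, cfg$seg_patch, cfg$seg_stride)
  preds <- lapply(pp$patches, function(patch) forward_infer(segmenter, patch))
  soft <- stitch_patches(preds, pp$origins, d)
  off <- pg$offset
  os <- pg$orig_shape
  soft[(off[1] + 1):(off[1] + os[1]), (off[2] + 1):(off[2] + os[2]),
       (off[3] + 1):(off[3] + os[3]), , drop = FALSE]
}

#' Run the full cascaded pipeline on one subject
#'
#' Composes preprocessing (resample to standard space, centre crop-or-pad,
#' z-score), cord localization on T2w, bounding-box cropping of both
#' contrasts, patch-wise multiclass segmentation with overlap-averaged
#' stitching, postprocessing, and inversion to the native grid.
#'
#' @param subject A `subject_record` (or any list with `t2w`, `gd_t1w`
#'   `image_volume`s).
#' @param localizer,segmenter Trained `unet_model`s.
#' @param cfg A [cascade_config()].
#' @param preproc A [preproc_config()].
#' @param postproc A [postproc_config()], or `NULL` to return soft
#'   predictions binarized at 0.5 without cleanup.
#' @param use_cascade `FALSE` runs the segmenter on the full standard
#'   crop without the localization step (the single-step comparison arm);
#'   the localizer is then unused and the bounding box covers the full
#'   volume.
#' @return A `cascade_result`: `native_labels` and `std_labels`
#'   (`label_volume`), `bbox` (`bbox3d`, standard space), `qc` (tibble of
#'   stage timings and mask volumes).
#' @export
run_cascade <- function(subject, localizer, segmenter,
                        cfg = cascade_config(), preproc = preproc_config(),
                        postproc = postproc_config(), use_cascade = TRUE) {
  t0 <- proc.time()[3]
  t2p <- preprocess_volume(subject$t2w, preproc, "image")
  g1p <- preprocess_volume(subject$gd_t1w, preproc, "image")
  t_pre <- proc.time()[3] - t0

  t0 <- proc.time()[3]
  if (use_cascade) {
    mask <- localize_cord(t2p$vol, localizer, cfg)
    bbox <- mask_to_bbox(mask, cfg$bbox_margin_mm, preproc$target_spacing)
    cord_volume_mm3 <- sum(mask) * prod(preproc$target_spacing)
  } else {
    bbox <- bbox3d(c(0L, 0L, 0L), preproc$crop_shape)
    cord_volume_mm3 <- NA_real_
  }
  t_loc <- proc.time()[3] - t0

  t0 <- proc.time()[3]
  soft_crop <- segment_tumor(crop_to_bbox(g1p$vol$data, bbox),
                             crop_to_bbox(t2p$vol$data, bbox),
                             segmenter, cfg)
  soft <- array(0, dim = c(preproc$crop_shape, 4L))
  soft[(bbox$lo[1] + 1):bbox$hi[1], (bbox$lo[2] + 1):bbox$hi[2],
       (bbox$lo[3] + 1):bbox$hi[3], ] <- soft_crop
  t_seg <- proc.time()[3] - t0

  t0 <- proc.time()[3]
  std_labels <- if (!is.null(postproc)) {
    postprocess(soft, postproc, preproc$target_spacing)
  } else {
    label_volume((soft >= 0.5) * 1, preproc$target_spacing)
  }
  native_labels <- invert_to_native(std_labels, t2p$record)
  t_post <- proc.time()[3] - t0

  qc <- tibble::tibble(
    subject_id = subject$subject_id %||% NA_character_,
    t_preprocess = t_pre, t_localize = t_loc, t_segment = t_seg,
    t_postprocess = t_post,
    cord_volume_mm3 = cord_volume_mm3,
    whole_volume_mm3 = sum(label_channel(std_labels, "whole")) *
      prod(preproc$target_spacing))
  structure(list(native_labels = native_labels, std_labels = std_labels,
                 bbox = bbox, record = t2p$record, qc = qc),
            class = "cascade_result")
}

#' Run the cascade over a cohort, tolerating per-subject failures
#'
#' @param subjects List of `subject_record`s.
#' @inheritParams run_cascade
#' @return List with `results` (named list of `cascade_result`), `failed`
#'   (named list of error messages) and `qc` (bound QC tibble).
#' @export
run_cascade_cohort <- function(subjects, localizer, segmenter,
                               cfg = cascade_config(),
                               preproc = preproc_config(),
                               postproc = postproc_config(),
                               use_cascade = TRUE) {
  results <- list(); failed <- list()
  for (s in subjects) {
    res <- tryCatch(run_cascade(s, localizer, segmenter, cfg, preproc,
                                postproc, use_cascade),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed[[s$subject_id]] <- conditionMessage(res)
    } else {
      results[[s$subject_id]] <- res
    }
  }
  qc <- if (length(results)) {
    dplyr::bind_rows(lapply(results, function(r) r$qc))
  } else tibble::tibble()
  list(results = results, failed = failed, qc = qc)
}
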