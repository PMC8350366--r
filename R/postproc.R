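# Prediction cleanup: threshold, fill holes, remove components below a
# physical volume. Channels are processed independently; the whole-lesion
# channel is NOT recomputed as the union of the structure channels
# afterwards — both are emitted and any discrepancy is recorded.

#' Postprocessing configuration
#'
#' @param threshold Binarization threshold (ties go to foreground).
#' @param min_volume Named minimum component volume in cm^3 per channel:
#'   components strictly smaller are removed. Defaults: tumor 0.2,
#'   cavity 0.5, edema 0.5, whole 0.2.
#' @param fg_connectivity Neighbourhood order for foreground components
#'   (26).
#' @param hole_connectivity Neighbourhood order for the background flood
#'   fill (6).
#' @return A `postproc_config` list.
#' @export
postproc_config <- function(threshold = 0.5,
                            min_volume = c(tumor = 0.2, cavity = 0.5,
                                           edema = 0.5, whole = 0.2),
                            fg_connectivity = 26L,
                            hole_connectivity = 6L) {
  stopifnot(threshold > 0, threshold < 1, all(min_volume >= 0),
            all(LABEL_CHANNELS %in% names(min_volume)))
  structure(list(threshold = threshold, min_volume = min_volume,
                 fg_connectivity = as.integer(fg_connectivity),
                 hole_connectivity = as.integer(hole_connectivity)),
            class = "postproc_config")
}

#' Binarize a soft prediction
#'
#' Voxels at or above the threshold become 1 (ties go to foreground).
#'
#' @param soft Numeric array in `[0, 1]`.
#' @param threshold Threshold in (0, 1).
#' @return Binary array of the same shape.
#' @export
binarize <- function(soft, threshold = 0.5) {
  (soft >= threshold) * 1
}

#' Fill interior holes of a binary mask
#'
#' Background components (6-connectivity) not connected to the volume
#' border are set to foreground; everything else is untouched.
#'
#' @param binary Binary 3D array.
#' @return Binary 3D array.
#' @export
fill_holes <- function(binary) {
  cpp_fill_holes(binary, dim(binary))
}

#' Remove small connected components by physical volume
#'
#' Components (26-connectivity) whose physical volume (voxel count times
#' voxel volume) is strictly below `min_volume_cm3` are deleted; others
#' are untouched.
#'
#' @param binary Binary 3D array.
#' @param min_volume_cm3 Volume threshold in cm^3.
#' @param spacing Voxel spacing, mm.
#' @param connectivity 26 (default) or 6.
#' @return Binary 3D array.
#' @export
remove_small_components <- function(binary, min_volume_cm3, spacing,
                                    connectivity = 26L) {
  if (sum(binary) == 0 || min_volume_cm3 <= 0) return(binary)
  lab <- cpp_label3d(binary, dim(binary), as.integer(connectivity))
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0) return(binary)
  vox_mm3 <- prod(spacing)
  counts <- tabulate(lab[lab > 0], nbins = ncomp)
  keep <- which(counts * vox_mm3 >= min_volume_cm3 * 1000)
  out <- array(as.numeric(lab %in% keep & lab > 0), dim = dim(binary))
  out
}

#' Postprocess a 4-channel soft prediction
#'
#' Applies, per channel and in this order: binarization at the threshold,
#' hole filling, and removal of components below the channel's physical
#' volume minimum. The chain is idempotent. The whole-lesion channel is
#' cleaned independently, not recomputed as a union; the voxel count on
#' which it disagrees with the union of the structure channels is
#' attached as attribute `"whole_union_mismatch"`.
#'
#' @param soft 4D soft prediction `(X, Y, Z, 4)`, channel order tumor,
#'   cavity, edema, whole (a 4D binary array is also accepted).
#' @param cfg A [postproc_config()].
#' @param spacing Voxel spacing, mm.
#' @return A `label_volume`.
#' @export
postprocess <- function(soft, cfg = postproc_config(), spacing = c(1, 1, 2)) {
  d <- dim(soft)
  stopifnot(length(d) == 4L, d[4] == 4L)
  out <- array(0, dim = d)
  for (c in seq_len(4L)) {
    ch <- LABEL_CHANNELS[c]
    b <- binarize(soft[, , , c], cfg$threshold)
    b <- fill_holes(b)
    b <- remove_small_components(b, cfg$min_volume[[ch]], spacing,
                                 cfg$fg_connectivity)
    out[, , , c] <- b
  }
  lv <- label_volume(out, spacing)
  union3 <- pmin(out[, , , 1] + out[, , , 2] + out[, , , 3], 1)
  attr(lv, "whole_union_mismatch") <- sum(union3 != out[, , , 4])
  lv
}
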