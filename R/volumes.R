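#' @useDynLib imsctseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical axis order used pipeline-wide: axis 1 = superior-inferior,
# axis 2 = anterior-posterior, axis 3 = right-left. Voxel indices are
# 0-based in all physical/box arithmetic; R arrays are addressed 1-based.

LABEL_CHANNELS <- c("tumor", "cavity", "edema", "whole")

#' Create an image volume
#'
#' The universal image carrier of the pipeline: a 3D scalar array with
#' per-axis physical voxel spacing in millimetres. Axis order is fixed:
#' superior-inferior, anterior-posterior, right-left.
#'
#' @param data 3D numeric array.
#' @param spacing Numeric length-3, voxel spacing in mm per axis; all
#'   strictly positive.
#' @return An object of class `image_volume` with elements `data` and
#'   `spacing`.
#' @export
image_volume <- function(data, spacing) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3D array", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  }
  if (any(!is.finite(data))) stop("`data` must be finite", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels @ (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  intensity range [%.3g, %.3g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Physical extent of a volume in mm
#' @param vol An `image_volume`.
#' @return Numeric length-3: voxel count times spacing per axis.
#' @export
physical_extent <- function(vol) {
  dim(vol$data) * vol$spacing
}

#' Create a multiclass label volume
#'
#' A stack of four aligned binary masks: tumor core, cavity (syrinx),
#' edema, and the whole lesion. Unless supplied, the whole-lesion channel
#' is the voxelwise union of the other three.
#'
#' @param data 4D binary array `(X, Y, Z, 4)` with channels ordered
#'   tumor, cavity, edema, whole; or a 3D/4D array of the three structure
#'   channels from which `whole` is derived.
#' @param spacing Voxel spacing, mm.
#' @param recompute_whole If `TRUE` (default when only 3 channels are
#'   given), set the whole channel to the union of the other three.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(data, spacing, recompute_whole = FALSE) {
  d <- dim(data)
  if (length(d) == 4L && d[4] == 3L) {
    data <- array(c(data, pmin(data[, , , 1] + data[, , , 2] + data[, , , 3], 1)),
                  dim = c(d[1:3], 4L))
  } else if (length(d) != 4L || d[4] != 4L) {
    stop("`data` must be a 4D array with 3 or 4 channels", call. = FALSE)
  } else if (recompute_whole) {
    data[, , , 4] <- pmin(data[, , , 1] + data[, , , 2] + data[, , , 3], 1)
  }
  if (!all(data %in% c(0, 1))) stop("label data must be binary", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  }
  structure(list(data = data, spacing = spacing, channels = LABEL_CHANNELS),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<label_volume> %d x %d x %d voxels @ (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  for (i in seq_along(x$channels)) {
    cat(sprintf("  %-6s %d voxels\n", x$channels[i], sum(x$data[, , , i])))
  }
  invisible(x)
}

#' Extract one binary channel from a label volume
#' @param labels A `label_volume`.
#' @param channel One of `"tumor"`, `"cavity"`, `"edema"`, `"whole"`.
#' @return 3D binary array.
#' @export
label_channel <- function(labels, channel) {
  i <- match(match.arg(channel, LABEL_CHANNELS), labels$channels)
  labels$data[, , , i, drop = TRUE]
}

#' Create a half-open 3D bounding box
#'
#' Voxel-index box `[lo, hi)` per axis, 0-based, used for the cascade crop
#' and the lesion inclusion check.
#'
#' @param lo,hi Integer length-3; `lo < hi` per axis.
#' @param margin_voxels Margin that was applied, for bookkeeping.
#' @return A `bbox3d` object.
#' @export
bbox3d <- function(lo, hi, margin_voxels = c(0L, 0L, 0L)) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || any(lo >= hi) || any(lo < 0)) {
    stop("bbox requires 0 <= lo < hi per axis", call. = FALSE)
  }
  structure(list(lo = lo, hi = hi, margin_voxels = as.integer(margin_voxels)),
            class = "bbox3d")
}

#' @export
print.bbox3d <- function(x, ...) {
  cat(sprintf("<bbox3d> [%d,%d) x [%d,%d) x [%d,%d)\n",
              x$lo[1], x$hi[1], x$lo[2], x$hi[2], x$lo[3], x$hi[3]))
  invisible(x)
}

#' Shape of a bounding box (voxels per axis)
#' @param box A `bbox3d`.
#' @return Integer length-3.
#' @export
bbox_shape <- function(box) box$hi - box$lo

# Crop a 3D array to a bbox (0-based half-open indices).
crop_to_bbox <- function(arr, box) {
  arr[(box$lo[1] + 1):box$hi[1], (box$lo[2] + 1):box$hi[2],
      (box$lo[3] + 1):box$hi[3], drop = FALSE]
}
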